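#' Exhaustive Hamming-distance alignment of one read against a reference set
#'
#' Reports every position (on the plus strand, and optionally the reverse
#' complement for the minus strand) where the read matches a reference with
#' at most `max_mismatches` substitutions; indels are not considered. The
#' scan is exhaustive over all references and offsets.
#'
#' @param sequence Read sequence (length >= 1; the pipeline only aligns
#'   reads of >= 16 nt).
#' @param references Named character vector of reference sequences.
#' @param max_mismatches Maximum Hamming distance (default 1).
#' @param both_strands Also search the minus strand (used for the genome
#'   tier; small RNA libraries are stranded, so hairpin/ncRNA/contaminant
#'   tiers are searched sense-only).
#' @return Data frame with columns `ref_id`, `start` (0-based offset on the
#'   reference), `strand`, `mismatches`; zero rows when unmapped.
#' @examples
#' align_simple("ACGTACGT", c(r1 = "TTACGTACGTTT"))
#' @export
align_simple <- function(sequence, references, max_mismatches = 1L,
                         both_strands = FALSE) {
  pat <- Biostrings::DNAString(sequence)
  plen <- length(pat)
  hits <- list()
  for (ref_id in names(references)) {
    subj <- Biostrings::DNAString(references[[ref_id]])
    if (plen > length(subj)) next
    for (strand in c("+", if (both_strands) "-")) {
      p <- if (strand == "-") Biostrings::reverseComplement(pat) else pat
      m <- Biostrings::matchPattern(p, subj, max.mismatch = max_mismatches,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0) next
      st <- BiocGenerics::start(m)
      mm <- Biostrings::neditStartingAt(p, subj, starting.at = st,
                                        with.indels = FALSE)
      hits[[length(hits) + 1L]] <- data.frame(
        ref_id = ref_id, start = st - 1L, strand = strand, mismatches = mm)
    }
  }
  if (!length(hits))
    return(data.frame(ref_id = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  do.call(rbind, hits)
}

#' Classify a hairpin alignment as mature, star, or hairpin-only
#'
#' A read interval is mature if it lies entirely within a mature window
#' extended by `pad` bases on either side; star analogously; otherwise
#' hairpin-only. Mature is checked before star.
#'
#' @param start,end 0-based half-open read interval on the hairpin.
#' @param hairpin A hairpin record (see [make_reference()]).
#' @param pad Window extension in nt (default 3).
#' @return List with `class` (`"mature"`, `"star"`, or `"hairpin_only"`) and
#'   `name` (the matched window's miRNA id, or the hairpin id).
#' @export
classify_hairpin_hit <- function(start, end, hairpin, pad = 3L) {
  for (k in seq_len(nrow(hairpin$mature_intervals))) {
    iv <- hairpin$mature_intervals[k, ]
    if (start >= iv$start - pad && end <= iv$end + pad)
      return(list(class = "mature", name = iv$name))
  }
  for (k in seq_len(nrow(hairpin$star_intervals))) {
    iv <- hairpin$star_intervals[k, ]
    if (start >= iv$start - pad && end <= iv$end + pad)
      return(list(class = "star", name = iv$name))
  }
  list(class = "hairpin_only", name = hairpin$id)
}

#' Assign one read given its per-tier alignment hits
#'
#' Implements the prioritisation: contaminant hits short-circuit; otherwise
#' miRNA beats ncRNA beats genome (class priority over mismatch distance
#' across classes); within the winning class only minimum-mismatch hits
#' survive; each of the k distinct surviving feature targets receives weight
#' 1/k. miRNA hits are classified into mature / star / hairpin-only windows,
#' and ties across window categories resolve mature > star > hairpin-only.
#'
#' @param hits_contaminant,hits_mirna,hits_ncrna,hits_genome Data frames as
#'   returned by [align_simple()] (the miRNA tier's `ref_id`s are hairpin
#'   ids). Pass zero-row frames for tiers without hits.
#' @param hairpins Hairpin records, for window classification.
#' @param read_length Read length, to derive hit end coordinates.
#' @param pad Window extension passed to [classify_hairpin_hit()].
#' @return Object of class `read_assignment`: list with `category` (one of
#'   mature, star, hairpin_only, ncrna, genome, contaminant, unmapped),
#'   `targets` (data frame `feature_id`, `category`, `weight`), `k`.
#' @export
assign_read <- function(hits_contaminant, hits_mirna, hits_ncrna, hits_genome,
                        hairpins, read_length, pad = 3L) {
  empty <- data.frame(feature_id = character(0), category = character(0),
                      weight = numeric(0))
  res <- function(category, targets, k)
    structure(list(category = category, targets = targets, k = k),
              class = "read_assignment")

  if (nrow(hits_contaminant) > 0)
    return(res("contaminant", empty, length(unique(hits_contaminant$ref_id))))

  if (nrow(hits_mirna) > 0) {
    keep <- hits_mirna[hits_mirna$mismatches == min(hits_mirna$mismatches), ,
                       drop = FALSE]
    cls <- character(nrow(keep)); feat <- character(nrow(keep))
    for (i in seq_len(nrow(keep))) {
      h <- classify_hairpin_hit(keep$start[i], keep$start[i] + read_length,
                                hairpins[[keep$ref_id[i]]], pad = pad)
      cls[i] <- h$class; feat[i] <- h$name
    }
    tab <- unique(data.frame(feature_id = feat, category = cls))
    k <- nrow(tab)
    tab$weight <- 1 / k
    rank <- c(mature = 1L, star = 2L, hairpin_only = 3L)
    return(res(names(rank)[min(rank[tab$category])], tab, k))
  }

  if (nrow(hits_ncrna) > 0) {
    keep <- hits_ncrna[hits_ncrna$mismatches == min(hits_ncrna$mismatches), ,
                       drop = FALSE]
    ids <- unique(keep$ref_id)
    tab <- data.frame(feature_id = ids, category = "ncrna",
                      weight = 1 / length(ids))
    return(res("ncrna", tab, length(ids)))
  }

  if (nrow(hits_genome) > 0) {
    keep <- hits_genome[hits_genome$mismatches == min(hits_genome$mismatches), ,
                        drop = FALSE]
    ids <- unique(keep$ref_id)
    tab <- data.frame(feature_id = ids, category = "genome",
                      weight = 1 / length(ids))
    return(res("genome", tab, length(ids)))
  }

  res("unmapped", empty, 0L)
}

#' Align and assign a set of cleaned reads against a reference bundle
#'
#' Runs the three-tier search for every read: contaminants first (hits are
#' excluded from counting), then miRNA hairpins and other ncRNAs (miRNA
#' prioritised), then the genome (both strands). Identical read sequences
#' share one alignment (the result is cached per unique sequence); counting
#' stays per-read.
#'
#' @param reads Named character vector of cleaned read sequences.
#' @param bundle A [make_reference()] bundle.
#' @param max_mismatches Maximum Hamming distance per alignment (default 1).
#' @param pad Mature/star window extension (default 3).
#' @return List of `read_assignment` objects, named by read id.
#' @export
assign_reads <- function(reads, bundle, max_mismatches = 1L, pad = 3L) {
  hairpin_seqs <- vapply(bundle$hairpins, `[[`, "", "sequence")
  # one concatenated subject per tier: a single matchPattern call scans the
  # whole tier; hits are mapped back to per-reference coordinates and any
  # hit crossing a separator is discarded (agrees exactly with align_simple)
  ix_con <- build_tier_index(bundle$contaminants, max_mismatches)
  ix_mir <- build_tier_index(hairpin_seqs, max_mismatches)
  ix_nc <- build_tier_index(bundle$ncrnas, max_mismatches)
  ix_gen <- build_tier_index(bundle$genome, max_mismatches)
  assign_one <- function(s) {
    pat <- Biostrings::DNAString(s)
    hc <- align_concat(pat, ix_con, max_mismatches)
    hm <- hn <- hg <- hc[0, ]
    if (nrow(hc) == 0) {
      hm <- align_concat(pat, ix_mir, max_mismatches)
      hn <- align_concat(pat, ix_nc, max_mismatches)
      if (nrow(hm) == 0 && nrow(hn) == 0)
        hg <- rbind(align_concat(pat, ix_gen, max_mismatches),
                    align_concat(pat, ix_gen, max_mismatches, strand = "-"))
    }
    assign_read(hc, hm, hn, hg, bundle$hairpins,
                read_length = nchar(s), pad = pad)
  }
  # identical sequences share one alignment; counting stays per-read
  uniq <- unique(reads)
  res <- lapply(uniq, assign_one)
  out <- res[match(reads, uniq)]
  names(out) <- names(reads)
  out
}

empty_hits <- function() {
  data.frame(ref_id = character(0), start = integer(0),
             strand = character(0), mismatches = integer(0))
}

# concatenate a tier's references with N-runs longer than the mismatch
# budget; segment coordinates let hits be mapped back per reference
build_tier_index <- function(references, max_mismatches, sep = NULL) {
  sep <- sep %||% (max_mismatches + 11L)
  lens <- nchar(references)
  subject <- Biostrings::DNAString(paste(references,
                                         collapse = strrep("N", sep)))
  starts <- cumsum(c(0L, head(lens + sep, -1L)))  # 0-based segment starts
  list(subject = subject, starts = starts, lens = lens,
       ids = names(references))
}

align_concat <- function(pat, index, max_mismatches, strand = "+") {
  p <- if (strand == "-") Biostrings::reverseComplement(pat) else pat
  if (length(p) > length(index$subject)) return(empty_hits())
  m <- Biostrings::matchPattern(p, index$subject,
                                max.mismatch = max_mismatches,
                                with.indels = FALSE, fixed = TRUE)
  if (length(m) == 0) return(empty_hits())
  st0 <- BiocGenerics::start(m) - 1L
  seg <- findInterval(st0, index$starts)
  local <- st0 - index$starts[seg]
  ok <- local + length(p) <= index$lens[seg]
  if (!any(ok)) return(empty_hits())
  st <- BiocGenerics::start(m)[ok]
  mm <- Biostrings::neditStartingAt(p, index$subject, starting.at = st,
                                    with.indels = FALSE)
  data.frame(ref_id = index$ids[seg[ok]], start = local[ok],
             strand = strand, mismatches = mm)
}

#' Build the fractional count matrix from read assignments
#'
#' Accumulates 1/k weights per (feature, library). Mature and star windows
#' are counted as features separate from their hairpin; contaminant and
#' unmapped reads contribute nothing.
#'
#' @param assignments_by_library Named list (one element per library) of
#'   assignment lists as returned by [assign_reads()].
#' @return Numeric matrix of fractional counts (features x libraries) with a
#'   `category` attribute: named character vector giving each feature's
#'   category (mature, star, hairpin_only, ncrna, genome).
#' @export
build_count_matrix <- function(assignments_by_library) {
  libs <- names(assignments_by_library)
  rows <- list()
  for (l in libs) {
    for (a in assignments_by_library[[l]]) {
      if (nrow(a$targets) == 0) next
      rows[[length(rows) + 1L]] <- cbind(a$targets, library = l)
    }
  }
  if (!length(rows)) {
    m <- matrix(0, 0, length(libs), dimnames = list(NULL, libs))
    attr(m, "category") <- setNames(character(0), character(0))
    return(m)
  }
  tab <- do.call(rbind, rows)
  feats <- unique(tab[, c("feature_id", "category")])
  m <- matrix(0, nrow(feats), length(libs),
              dimnames = list(feats$feature_id, libs))
  idx <- cbind(match(tab$feature_id, feats$feature_id),
               match(tab$library, libs))
  for (r in seq_len(nrow(tab)))
    m[idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + tab$weight[r]
  attr(m, "category") <- setNames(feats$category, feats$feature_id)
  m
}

#' Per-library assignment summary
#'
#' @param assignments_by_library As for [build_count_matrix()].
#' @return Data frame of read counts per category per library.
#' @export
assignment_summary <- function(assignments_by_library) {
  cats <- c("mature", "star", "hairpin_only", "ncrna", "genome",
            "contaminant", "unmapped")
  do.call(rbind, lapply(names(assignments_by_library), function(l) {
    got <- table(factor(vapply(assignments_by_library[[l]], `[[`, "",
                               "category"), levels = cats))
    data.frame(library = l, category = cats, n_reads = as.integer(got))
  }))
}

#' Drop features below the background read cutoff
#'
#' Removes features whose summed raw count across all libraries is strictly
#' below `min_total`; a feature at exactly the cutoff is retained.
#'
#' @param counts Count matrix (features x libraries).
#' @param min_total Background cutoff (default 100 reads across all
#'   libraries).
#' @return The filtered matrix (the `category` attribute, if present, is
#'   subset accordingly).
#' @examples
#' m <- matrix(c(60, 50, 40, 49), 2, dimnames = list(c("a", "b"), NULL))
#' rownames(filter_background(m))
#' @export
filter_background <- function(counts, min_total = 100) {
  keep <- rowSums(counts) >= min_total
  out <- counts[keep, , drop = FALSE]
  cat_attr <- attr(counts, "category")
  if (!is.null(cat_attr))
    attr(out, "category") <- cat_attr[rownames(out)]
  out
}
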