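#' Synthetic reference bundle
#'
#' Builds the three-tier reference stack the aligner searches: contaminant
#' sequences (the 3' adaptor and adaptor-dimer/concatemer), miRNA hairpins
#' with mature and star sub-windows, a handful of other ncRNAs, and genome
#' contigs embedding each hairpin in random flank. To exercise fractional
#' 1/k counting, the first two hairpins share an identical mature sequence.
#'
#' Hairpin coordinates are 0-based half-open on the hairpin sequence. Each
#' hairpin `hp<i>` carries one mature window (`mir<i>-5p`, length 20-24 nt on
#' the 5' arm) and one star window (`mir<i>-3p`, on the 3' arm).
#'
#' @param config A [sim_config()] with `n_hairpins >= 1`.
#' @return An object of class `reference_bundle`: a list with elements
#'   `contaminants`, `hairpins` (list of hairpin records, each with `id`,
#'   `sequence`, `mature_intervals`, `star_intervals`), `ncrnas`, `genome`
#'   (all named character vectors of DNA sequences except `hairpins`).
#' @examples
#' ref <- make_reference(sim_config(seed = 1, n_hairpins = 5))
#' length(ref$hairpins)
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_hairpins < 1) stop("n_hairpins must be >= 1")
  with_seed(config$seed + 1L, {
    n <- config$n_hairpins
    five_off <- sample(4:8, n, replace = TRUE)
    # mature/star lengths peak at the canonical 22 nt
    len_p <- c(0.05, 0.2, 0.5, 0.2, 0.05)
    mlen <- sample(20:24, n, replace = TRUE, prob = len_p)
    loop <- sample(8:15, n, replace = TRUE)
    slen <- sample(20:24, n, replace = TRUE, prob = len_p)
    tail_len <- sample(4:8, n, replace = TRUE)
    if (n >= 2) mlen[2] <- mlen[1]
    len <- five_off + mlen + loop + slen + tail_len
    hairpins <- vector("list", n)
    for (i in seq_len(n)) {
      seq_i <- rand_dna(len[i])
      if (i == 2) {
        # duplicate hairpin 1's mature sequence into hairpin 2
        m1 <- hairpins[[1]]
        shared <- substr(m1$sequence,
                         m1$mature_intervals$start + 1L,
                         m1$mature_intervals$end)
        substr(seq_i, five_off[i] + 1L, five_off[i] + mlen[i]) <- shared
      }
      hairpins[[i]] <- list(
        id = paste0("hp", i),
        sequence = seq_i,
        mature_intervals = data.frame(
          name = paste0("mir", i, "-5p"),
          start = five_off[i],
          end = five_off[i] + mlen[i]),
        star_intervals = data.frame(
          name = paste0("mir", i, "-3p"),
          start = five_off[i] + mlen[i] + loop[i],
          end = five_off[i] + mlen[i] + loop[i] + slen[i]))
      class(hairpins[[i]]) <- "hairpin_record"
    }
    names(hairpins) <- vapply(hairpins, `[[`, "", "id")

    adaptor <- config$adaptor_sequence
    contaminants <- c(
      adaptor = adaptor,
      adaptor_dimer = strrep(adaptor, 2L),
      adaptor_concatemer = strrep(adaptor,
                                  ceiling(config$read_length / nchar(adaptor)) + 1L))

    ncrnas <- setNames(
      vapply(sample(80:120, 5, replace = TRUE), rand_dna, ""),
      paste0("ncrna", 1:5))

    genome <- vapply(hairpins, function(h) {
      paste0(rand_dna(60), h$sequence, rand_dna(60))
    }, "")
    names(genome) <- paste0("ctg_", names(hairpins))
    genome <- c(genome, ctg_random = rand_dna(500))

    structure(list(contaminants = contaminants, hairpins = hairpins,
                   ncrnas = ncrnas, genome = genome),
              class = "reference_bundle")
  })
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("Reference bundle: ", length(x$hairpins), " hairpins, ",
      length(x$contaminants), " contaminants, ", length(x$ncrnas),
      " ncRNAs, ", length(x$genome), " genome contigs\n", sep = "")
  invisible(x)
}

#' Extract a sub-sequence of a hairpin by 0-based half-open coordinates
#' @noRd
hairpin_subseq <- function(hairpin, start, end) {
  substr(hairpin$sequence, start + 1L, end)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Write the hairpin mature/star coordinate table
#'
#' Tab-separated with columns `hairpin_id`, `name`, `type` (mature/star),
#' `start`, `end` (0-based half-open).
#'
#' @param hairpins List of hairpin records (see [make_reference()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hairpin_table <- function(hairpins, path) {
  rows <- do.call(rbind, lapply(hairpins, function(h) {
    rbind(cbind(hairpin_id = h$id, h$mature_intervals, type = "mature"),
          cbind(hairpin_id = h$id, h$star_intervals, type = "star"))
  }))
  rows <- rows[, c("hairpin_id", "name", "type", "start", "end")]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
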