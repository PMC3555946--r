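# Small shared fixtures and independent oracles. The oracles deliberately use
# only base-R string/loop primitives so they stay independent of the
# implementation paths they check.

small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed, n_hairpins = 10,
                                 reads_per_library = 400), list(...))
  do.call(sim_config, args)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""), ""))
}

# exhaustive position-by-position Hamming scan
brute_align <- function(sequence, references, max_mismatches,
                        both_strands = FALSE) {
  out <- list()
  for (ref_id in names(references)) {
    ref <- strsplit(references[[ref_id]], "")[[1]]
    for (strand in c("+", if (both_strands) "-")) {
      p <- if (strand == "-") revcomp(sequence) else sequence
      pc <- strsplit(p, "")[[1]]
      L <- length(pc)
      if (L > length(ref)) next
      for (st in 0:(length(ref) - L)) {
        mm <- sum(ref[(st + 1):(st + L)] != pc)
        if (mm <= max_mismatches)
          out[[length(out) + 1]] <- data.frame(
            ref_id = ref_id, start = st, strand = strand, mismatches = mm)
      }
    }
  }
  if (!length(out))
    return(data.frame(ref_id = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  do.call(rbind, out)
}

sort_hits <- function(h) {
  h <- h[order(h$ref_id, h$start, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# leftmost clip position by exhaustive scan
brute_clip <- function(read, adaptor, min_overlap) {
  n <- nchar(read)
  for (pos in seq_len(max(0, n - min_overlap + 1))) {
    ov <- min(nchar(adaptor), n - pos + 1)
    if (substr(read, pos, pos + ov - 1) == substr(adaptor, 1, ov))
      return(substr(read, 1, pos - 1))
  }
  read
}

# exhaustive-search single-linkage clusters cut strictly below `height`:
# start from singletons and repeatedly join the closest pair of clusters
# (minimum over cross-pair distances) while that minimum is < height
brute_single_linkage <- function(d, height) {
  d <- as.matrix(d)
  cl <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(cl) == 1) break
    best <- c(Inf, NA, NA)
    for (i in seq_along(cl)) for (j in seq_len(i - 1)) {
      m <- min(d[cl[[i]], cl[[j]]])
      if (m < best[1]) best <- c(m, i, j)
    }
    if (best[1] >= height) break
    cl[[best[3]]] <- c(cl[[best[3]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  membership <- integer(nrow(d))
  for (k in seq_along(cl)) membership[cl[[k]]] <- k
  membership
}

unclip <- function(x) { attr(x, "n_clipped") <- NULL; x }

# whether a call in profile `prof` (possibly "a+b" merged) covers tissue `t`
call_covers <- function(prof, t) {
  vapply(strsplit(prof, "+", fixed = TRUE), function(p) t %in% p, TRUE)
}
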