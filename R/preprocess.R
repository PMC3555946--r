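#' Clip the 3' adaptor from read sequences
#'
#' Removes everything from the leftmost exact match of an adaptor prefix of
#' length at least `min_overlap` onwards. At interior positions the full
#' remaining read must match the adaptor prefix of the corresponding length;
#' a read with no qualifying match is returned unchanged. A read that is pure
#' adaptor clips to the empty string (and is then removed by the length
#' filter).
#'
#' @param sequences Character vector of read sequences.
#' @param adaptor Non-empty adaptor sequence.
#' @param min_overlap Minimum matched adaptor prefix length (default 6).
#' @return Character vector of clipped sequences (same length and names).
#' @examples
#' clip_adaptor(c("ACGTACGTTGGAATTCTCGG", "ACGTACGT"), "TGGAATTCTCGG")
#' @export
clip_adaptor <- function(sequences, adaptor, min_overlap = 6L) {
  stopifnot(nchar(adaptor) >= 1, min_overlap >= 1)
  adaptor <- toupper(adaptor)
  out <- sequences
  n <- nchar(sequences)
  alen <- nchar(adaptor)
  cut_at <- rep(NA_integer_, length(sequences))  # 1-based clip position
  maxpos <- max(0L, max(n, 0L) - min_overlap + 1L)
  for (pos in seq_len(maxpos)) {
    live <- which(is.na(cut_at) & n - pos + 1L >= min_overlap)
    if (!length(live)) break
    ov <- pmin(alen, n[live] - pos + 1L)
    hit <- substring(sequences[live], pos, pos + ov - 1L) ==
      substring(adaptor, 1L, ov)
    cut_at[live[hit]] <- pos
  }
  clipped <- !is.na(cut_at)
  out[clipped] <- substr(sequences[clipped], 1L, cut_at[clipped] - 1L)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Filter clipped reads by length and N content
#'
#' Retains reads that are at least `min_length` nt after clipping and whose
#' fraction of N bases does not exceed `max_n_fraction`. Length is checked
#' first: a read failing both criteria is counted once, as short.
#'
#' @param reads Named character vector of clipped read sequences.
#' @param min_length Minimum retained length (default 16).
#' @param max_n_fraction Maximum tolerated N fraction (default 0.5,
#'   operationalising "primarily N bases").
#' @param n_clipped Optional count of clipped reads to carry into the report.
#' @return Object of class `clean_read_set`: list with `reads` (retained),
#'   `n_input`, `n_removed_short`, `n_removed_n`, `n_clipped`.
#' @examples
#' filter_reads(c(a = "ACGTACGTACGTACGT", b = "ACGT"))
#' @export
filter_reads <- function(reads, min_length = 16L, max_n_fraction = 0.5,
                         n_clipped = NA_integer_) {
  n <- nchar(reads)
  short <- n < min_length
  n_frac <- ifelse(n > 0,
                   vapply(gregexpr("N", reads, fixed = TRUE), function(m)
                     sum(m > 0), 0L) / pmax(n, 1L),
                   1)
  n_rich <- !short & n_frac > max_n_fraction
  out <- list(reads = reads[!short & !n_rich],
              n_input = length(reads),
              n_removed_short = sum(short),
              n_removed_n = sum(n_rich),
              n_clipped = n_clipped)
  class(out) <- "clean_read_set"
  out
}

#' @export
print.clean_read_set <- function(x, ...) {
  cat("Clean read set: ", length(x$reads), " retained of ", x$n_input,
      " (", x$n_removed_short, " removed short, ", x$n_removed_n,
      " removed N-rich",
      if (!is.na(x$n_clipped)) paste0(", ", x$n_clipped, " clipped"),
      ")\n", sep = "")
  invisible(x)
}

#' Clip and filter a raw read library
#'
#' Convenience wrapper: [clip_adaptor()] then [filter_reads()].
#'
#' @inheritParams clip_adaptor
#' @inheritParams filter_reads
#' @return A `clean_read_set` (see [filter_reads()]).
#' @export
preprocess_reads <- function(sequences, adaptor, min_overlap = 6L,
                             min_length = 16L, max_n_fraction = 0.5) {
  clipped <- clip_adaptor(sequences, adaptor, min_overlap)
  filter_reads(clipped, min_length, max_n_fraction,
               n_clipped = attr(clipped, "n_clipped"))
}

#' Read-length histogram
#'
#' @param reads Character vector of (retained) read sequences.
#' @return Data frame with columns `length` and `count`; counts sum to
#'   `length(reads)`.
#' @examples
#' length_histogram(c("ACGT", "ACGTA", "TTTT"))
#' @export
length_histogram <- function(reads) {
  if (!length(reads))
    return(data.frame(length = integer(0), count = integer(0)))
  tab <- table(nchar(reads))
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}
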