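#' Per-library inflation factors (median-of-ratios)
#'
#' For each library l, the inflation factor is the median over features g of
#' `n_gl / GM_g`, where `GM_g` is the geometric mean of feature g's counts
#' across libraries. Only features with strictly positive counts in every
#' library enter the median (the geometric mean is zero otherwise and the
#' ratio undefined). With an even number of qualifying features the median is
#' the midpoint of the central pair.
#'
#' @param counts Count matrix (features x libraries), nonnegative.
#' @return Named numeric vector of inflation factors, one per library.
#' @examples
#' inflation_factors(matrix(c(2, 8, 4, 16), 2))  # 0.7071, 1.4142
#' @export
inflation_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("lib", seq_len(ncol(counts)))
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no feature has strictly positive counts in every library; ",
         "inflation factors are undefined")
  gm <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
  apply(counts[ok, , drop = FALSE] / gm, 2, median)
}

#' Log2-normalized expression
#'
#' `v_gl = log2((n_gl + pseudocount) / i_l)`. With the default pseudocount of
#' 0, zero counts map to `-Inf`, the below-detection sentinel; downstream
#' correlation operations treat these as missing (pairwise-complete).
#'
#' @param counts Count matrix.
#' @param factors Inflation factors from [inflation_factors()] on the same
#'   matrix.
#' @param pseudocount Added to every count before the log (default 0).
#' @return Matrix of log2-normalized values (same shape as `counts`).
#' @examples
#' log2_normalize(matrix(8), setNames(2, "lib1"))  # 2
#' @export
log2_normalize <- function(counts, factors, pseudocount = 0) {
  stopifnot(ncol(counts) == length(factors))
  if (any(factors <= 0)) stop("inflation factors must be positive")
  log2(sweep(as.matrix(counts) + pseudocount, 2, factors, "/"))
}

#' Linear-scale depth-adjusted counts
#'
#' `n_gl / i_l`; the scale on which the minimum-expression filter and the
#' tissue-specificity score operate.
#'
#' @inheritParams log2_normalize
#' @return Matrix of normalized linear counts.
#' @examples
#' normalized_linear(matrix(100), setNames(0.5, "lib1"))  # 200
#' @export
normalized_linear <- function(counts, factors) {
  stopifnot(ncol(counts) == length(factors))
  if (any(factors <= 0)) stop("inflation factors must be positive")
  sweep(as.matrix(counts), 2, factors, "/")
}
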