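#' Storey robust q-values
#'
#' The proportion of true nulls pi0 is estimated by the smoother method: the
#' naive estimates `pi0(lambda) = #(p > lambda) / (m (1 - lambda))` on
#' `lambda = 0.05, 0.10, ..., 0.95` are fit with a cubic polynomial and
#' evaluated at the largest lambda, then clamped into (0, 1]. With fewer
#' than 10 p-values the smoother is unstable and pi0 = 1 is used. The robust
#' q-value of the i-th ranked p-value is
#' `pi0 * m * p_i / (i * (1 - (1 - p_i)^m))`, with the usual running-minimum
#' monotonicity enforcement from the largest p downwards and capping at 1.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param robust Use the robust denominator (default TRUE); otherwise the
#'   plain `pi0 * m * p_i / i`.
#' @param pi0 Optional fixed pi0 overriding the smoother estimate.
#' @param lambda Grid for the smoother.
#' @return Numeric vector of q-values in the input order.
#' @examples
#' qvalues(0.05, pi0 = 1)  # 0.05 / (1 - 0.95) = 1
#' @export
qvalues <- function(pvals, robust = TRUE, pi0 = NULL,
                    lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(pi0)) {
    if (m < 10) {
      pi0 <- 1
    } else {
      pl <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), 0)
      fit <- lm(pl ~ poly(lambda, 3))
      pi0 <- predict(fit, newdata = data.frame(lambda = max(lambda)))
      pi0 <- min(1, max(pi0, 0))
      if (pi0 == 0) pi0 <- .Machine$double.eps  # all-signal edge case
    }
  }
  o <- order(pvals)
  p <- pvals[o]
  i <- seq_len(m)
  denom <- if (robust) i * (1 - (1 - p)^m) else i
  q <- pi0 * m * p / denom
  q <- rev(cummin(rev(pmin(q, 1))))
  q[order(o)]
}
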