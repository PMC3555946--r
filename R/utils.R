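#' @importFrom stats cor cutree dist hclust lm median model.matrix na.omit
#'   predict quantile residuals rbinom rhyper rlnorm rmultinom rnorm rpois
#'   runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards,
# so every generator is a pure function of (config, seed).
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Dirichlet draw via normalized gamma variates; rows of the result sum to 1.
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
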