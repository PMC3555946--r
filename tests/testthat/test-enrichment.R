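test_that("gene scoring takes the minimum p over assigned variants", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(0, 1000, 5000), end = c(500, 1500, 5100))
  v <- data.frame(id = paste0("v", 1:5), chrom = "chr1",
                  pos = c(10, 400, 1200, 1499, 4000),
                  pvalue = c(0.2, 0.01, 0.5, 0.3, 0.9))
  sc <- score_genes(v, genes)
  expect_equal(sc$raw_p[sc$gene_id == "gA"], 0.01)
  expect_equal(sc$raw_p[sc$gene_id == "gB"], 0.3)
  expect_false("gC" %in% sc$gene_id)  # no assigned variant -> unscored
  # window extension pulls in nearby variants; just-outside stays out
  # (variant pos 4000 is 0-based 3999; gene gC starts at 0-based 5000)
  sc2 <- score_genes(v, genes, window_bp = 1001)
  expect_true("gC" %in% sc2$gene_id)
  expect_equal(sc2$raw_p[sc2$gene_id == "gC"], 0.9)
  sc3 <- score_genes(v, genes, window_bp = 1000)
  expect_false("gC" %in% sc3$gene_id)
})

test_that("gene scoring matches an exhaustive assignment oracle", {
  set.seed(61)
  genes <- data.frame(gene_id = paste0("g", 1:5),
                      chrom = sample(c("chr1", "chr2"), 5, replace = TRUE),
                      start = sample.int(2000, 5))
  genes$end <- genes$start + sample.int(800, 5)
  v <- data.frame(id = paste0("v", 1:12),
                  chrom = sample(c("chr1", "chr2"), 12, replace = TRUE),
                  pos = sample.int(3000, 12), pvalue = runif(12))
  sc <- score_genes(v, genes, window_bp = 50)
  for (i in 1:5) {
    inside <- v$chrom == genes$chrom[i] &
      v$pos - 1 >= genes$start[i] - 50 & v$pos - 1 < genes$end[i] + 50
    if (any(inside)) {
      expect_equal(sc$raw_p[sc$gene_id == genes$gene_id[i]],
                   min(v$pvalue[inside]))
    } else {
      expect_false(genes$gene_id[i] %in% sc$gene_id)
    }
  }
})

test_that("confounder adjustment preserves ranking when confounders are flat", {
  set.seed(62)
  sc <- data.frame(gene_id = paste0("g", 1:30), raw_p = runif(30))
  cf <- data.frame(gene_id = sc$gene_id, span_bp = 100, n_variants = 5,
                   n_proxies = 2)
  adj <- suppressWarnings(adjust_confounders(sc, cf))
  expect_equal(order(adj$adjusted_score), order(-log10(sc$raw_p)))
})

test_that("confounder adjustment removes a planted span trend", {
  set.seed(63)
  n <- 400
  span <- runif(n, 1e3, 1e5)
  # genes with longer spans get systematically smaller p
  y <- 0.5 + span / 4e4 + rnorm(n, 0, 0.3)  # -log10 p
  sc <- data.frame(gene_id = paste0("g", 1:n), raw_p = 10^(-y))
  cf <- data.frame(gene_id = sc$gene_id, span_bp = span,
                   n_variants = rpois(n, 6) + 1, n_proxies = rpois(n, 3))
  adj <- adjust_confounders(sc, cf)
  # raw scores correlate with span; residuals do not
  expect_gt(cor(span, -log10(sc$raw_p)), 0.5)
  expect_lt(abs(cor(span, adj$adjusted_score)), 3 / sqrt(n))
  expect_lt(abs(cor(cf$n_variants, adj$adjusted_score)), 3 / sqrt(n))
  expect_error(adjust_confounders(sc[1:5, ], cf), "at least 10")
})

test_that("collinear confounders are dropped with a warning", {
  set.seed(64)
  sc <- data.frame(gene_id = paste0("g", 1:40), raw_p = runif(40))
  cf <- data.frame(gene_id = sc$gene_id, span_bp = 1:40,
                   n_variants = 2 * (1:40), n_proxies = rpois(40, 3))
  expect_warning(adj <- adjust_confounders(sc, cf), "collinear")
  expect_equal(nrow(adj), 40)
})

test_that("the percentile permutation test behaves at the extremes", {
  set.seed(65)
  sc <- data.frame(gene_id = paste0("g", 1:1000),
                   adjusted_score = rnorm(1000))
  top10 <- sc$gene_id[order(-sc$adjusted_score)][1:10]
  r <- enrichment_test(top10, sc, n_permutations = 2000, seed = 1)
  expect_equal(r$perm_p, 1 / 2001)  # maximal enrichment hits the floor
  expect_equal(r$n_above_cutoff, 10)
  expect_equal(r$expected_above, 2.5)
  bottom <- sc$gene_id[order(sc$adjusted_score)][1:40]
  r2 <- enrichment_test(bottom, sc, n_permutations = 2000, seed = 1)
  expect_gt(r2$perm_p, 0.5)  # below expectation
  r3 <- enrichment_test(sc$gene_id[1:2], sc, n_permutations = 200, seed = 1)
  expect_true(is.na(r3$perm_p))  # fewer than 3 scored members: excluded
  # p floor respected in general
  expect_gte(r$perm_p, 1 / (2000 + 1))
})

test_that("hypergeometric null draws match explicit same-size permutations", {
  set.seed(66)
  sc <- data.frame(gene_id = paste0("g", 1:200), adjusted_score = rnorm(200))
  cutoff <- quantile(sc$adjusted_score, 0.75, names = FALSE)
  above <- sc$adjusted_score > cutoff
  s <- 25
  # explicit permutation: draw s genes without replacement, count above
  explicit <- replicate(4000, sum(sample(above, s)))
  hyper <- rhyper(4000, sum(above), 200 - sum(above), s)
  expect_equal(mean(explicit), mean(hyper), tolerance = 0.05)
  expect_gt(suppressWarnings(ks.test(explicit, hyper))$p.value, 0.001)
})

test_that("doubling the permutation count moves perm_p by less than 3 binomial sd", {
  set.seed(67)
  sc <- data.frame(gene_id = paste0("g", 1:500), adjusted_score = rnorm(500))
  some <- sample(sc$gene_id, 40)
  p1 <- enrichment_test(some, sc, n_permutations = 2000, seed = 5)$perm_p
  p2 <- enrichment_test(some, sc, n_permutations = 4000, seed = 6)$perm_p
  expect_lt(abs(p1 - p2), 3 * sqrt(p1 * (1 - p1) / 2000) + 1e-3)
})

test_that("q-values match the robust closed form and are monotone", {
  expect_equal(qvalues(0.05, pi0 = 1), 0.05 / (1 - 0.95), tolerance = 1e-12)
  expect_equal(qvalues(0.05, pi0 = 1), 1)
  # all-identical p-values get identical q-values
  expect_equal(diff(range(qvalues(rep(0.2, 8), pi0 = 1))), 0)
  # spot-check the robust formula at rank i: pi0*m*p/(i*(1-(1-p)^m))
  p <- c(0.01, 0.2, 0.5, 0.9)
  q <- qvalues(p, pi0 = 1)
  m <- 4
  raw <- sapply(seq_along(p), function(i)
    m * p[i] / (i * (1 - (1 - p[i])^m)))
  expect_equal(q, rev(cummin(rev(pmin(raw, 1)))), tolerance = 1e-12)
  # monotone in ranked p on random input
  set.seed(68)
  pr <- runif(200)
  qr <- qvalues(pr)
  expect_true(all(diff(qr[order(pr)]) >= -1e-12))
  expect_true(all(qr <= 1 & qr > 0))
  expect_length(qvalues(numeric(0)), 0)
  expect_error(qvalues(c(0.5, 0)), "0, 1")
})

test_that("pi0 smoother lands near truth on a null/signal mixture", {
  set.seed(69)
  p <- c(runif(800), rbeta(200, 0.1, 10))  # pi0 = 0.8
  q <- qvalues(p)
  # reconstruct the smoother estimate: q of the largest p equals pi0-ish
  lam <- seq(0.05, 0.95, 0.05)
  pl <- vapply(lam, function(l) mean(p > l) / (1 - l), 0)
  fit <- lm(pl ~ poly(lam, 3))
  pi0 <- min(1, max(0, predict(fit, data.frame(lam = 0.95))))
  expect_gt(pi0, 0.6); expect_lt(pi0, 1.01)
})

test_that("significance calls use strict double thresholds", {
  res <- data.frame(perm_p = c(0.009, 0.01, 0.005, 0.02),
                    q = c(0.09, 0.05, 0.11, 0.09))
  out <- call_significant(res)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("target-set intersection across prediction sources", {
  a <- data.frame(set_id = c("m1", "m1", "m2"), gene_id = c("g1", "g2", "g9"))
  b <- data.frame(set_id = c("m1", "m1", "m3"), gene_id = c("g2", "g3", "g7"))
  c3 <- data.frame(set_id = c("m1", "m1"), gene_id = c("g2", "g4"))
  out <- intersect_target_sets(a, b, c3)
  expect_equal(out$set_id, "m1")
  expect_equal(out$gene_id, "g2")
})

test_that("planted enriched sets reach significance; null sets do not", {
  g <- simulate_gwas(sim_config(seed = 70))
  sc <- adjust_confounders(score_genes(g$variants, g$genes), g$genes)
  res <- enrichment_analysis(g$gene_sets, sc, n_permutations = 2000, seed = 3)
  planted <- res$set_id %in% g$truth$planted_sets
  expect_true(all(res$significant[planted]))
  expect_lt(mean(res$significant[!planted]), 0.2)
})
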