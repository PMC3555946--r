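#' Score genes by their best local association p-value
#'
#' Assigns each variant to every gene whose body (extended by `window_bp` on
#' both sides) contains it; a gene's raw score is the minimum p-value over
#' its assigned variants. Genes with no assigned variant are unscored and
#' excluded.
#'
#' @param variants Data frame with `id`, `chrom`, `pos` (1-based), `pvalue`.
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param window_bp Symmetric extension of the gene body (default 0).
#' @return Data frame `gene_id`, `raw_p`, `n_assigned`.
#' @export
score_genes <- function(variants, genes, window_bp = 0L) {
  g2 <- genes
  g2$start <- pmax(0L, g2$start - window_bp)
  g2$end <- g2$end + window_bp
  idx <- variant_gene_index(variants, g2)
  if (!nrow(idx))
    return(data.frame(gene_id = character(0), raw_p = numeric(0),
                      n_assigned = integer(0)))
  by_gene <- split(idx$variant_idx, idx$gene_idx)
  gi <- as.integer(names(by_gene))
  data.frame(gene_id = genes$gene_id[gi],
             raw_p = vapply(by_gene, function(v) min(variants$pvalue[v]), 0),
             n_assigned = lengths(by_gene), row.names = NULL)
}

#' Confounder-adjusted association scores
#'
#' Regresses `-log10(raw_p)` on the per-gene confounders (transcript span,
#' variant count, LD-proxy count) by ordinary least squares; the adjusted
#' score is the residual, so larger means more signal than the confounders
#' predict. Collinear confounders are dropped with a warning.
#'
#' @param scores Data frame from [score_genes()] (>= 10 rows).
#' @param confounders Data frame with `gene_id` and confounder columns
#'   (default `span_bp`, `n_variants`, `n_proxies`).
#' @param columns Confounder columns to use.
#' @return `scores` with an added `adjusted_score` column.
#' @export
adjust_confounders <- function(scores, confounders,
                               columns = c("span_bp", "n_variants",
                                           "n_proxies")) {
  if (nrow(scores) < 10) stop("need at least 10 scored genes")
  cf <- confounders[match(scores$gene_id, confounders$gene_id), columns,
                    drop = FALSE]
  if (any(is.na(cf))) stop("missing confounders for some scored genes")
  y <- -log10(scores$raw_p)
  X <- cbind(`(Intercept)` = 1, as.matrix(cf))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(X), colnames(X)[keep])
    warning("dropping collinear confounder(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  scores$adjusted_score <- as.numeric(qr.resid(qrX, y))
  scores
}

#' Percentile-cutoff permutation test for one gene set
#'
#' The cutoff is the 75th (by default) percentile of the adjusted scores of
#' all scored genes; the observed statistic is the number of set members
#' strictly above it. The null is the count above the cutoff in random
#' draws, without replacement, of the same number of genes from all scored
#' genes (sampled as hypergeometric counts, which is the exact distribution
#' of such draws), and `perm_p = (1 + #(null >= observed)) / (B + 1)`.
#'
#' @param set_genes Character vector of member gene ids.
#' @param scores Data frame with `gene_id` and `adjusted_score` (all scored
#'   genes).
#' @param percentile Cutoff percentile (default 75).
#' @param n_permutations Number of null draws B (default 10000).
#' @param seed RNG seed.
#' @return One-row data frame: `n_genes` (scored members), `n_above_cutoff`,
#'   `expected_above` (`n_genes * (1 - percentile/100)`), `perm_p`. Sets
#'   with fewer than 3 scored members return `perm_p = NA` (excluded).
#' @export
enrichment_test <- function(set_genes, scores, percentile = 75,
                            n_permutations = 10000L, seed = 1L) {
  stopifnot(n_permutations >= 100)
  adj <- scores$adjusted_score
  members <- scores$gene_id %in% set_genes
  s <- sum(members)
  if (s < 3)
    return(data.frame(n_genes = s, n_above_cutoff = NA_integer_,
                      expected_above = NA_real_, perm_p = NA_real_))
  cutoff <- quantile(adj, percentile / 100, names = FALSE)
  above <- adj > cutoff
  K <- sum(above)
  N <- length(adj)
  obs <- sum(above & members)
  null <- with_seed(seed, rhyper(n_permutations, K, N - K, s))
  data.frame(n_genes = s, n_above_cutoff = obs,
             expected_above = s * (1 - percentile / 100),
             perm_p = (1 + sum(null >= obs)) / (n_permutations + 1))
}

#' Enrichment analysis over a collection of gene sets
#'
#' Runs [enrichment_test()] for every set, attaches Storey robust q-values
#' over the testable sets, and flags significance at `perm_p < p_cut` and
#' `q < q_cut` (both strict).
#'
#' @param gene_sets Data frame with `set_id`, `gene_id`.
#' @param scores Data frame with `gene_id`, `adjusted_score`.
#' @param percentile,n_permutations Passed to [enrichment_test()].
#' @param seed Base seed; set i uses `seed + i`.
#' @param p_cut,q_cut Significance thresholds (defaults 0.01 and 0.1).
#' @return Data frame with one row per set: `set_id`, `n_genes`,
#'   `n_above_cutoff`, `expected_above`, `perm_p`, `q`, `significant`. Sets
#'   with fewer than 3 scored members carry NA statistics.
#' @export
enrichment_analysis <- function(gene_sets, scores, percentile = 75,
                                n_permutations = 10000L, seed = 1L,
                                p_cut = 0.01, q_cut = 0.1) {
  ids <- unique(gene_sets$set_id)
  res <- do.call(rbind, lapply(seq_along(ids), function(i) {
    members <- gene_sets$gene_id[gene_sets$set_id == ids[i]]
    cbind(set_id = ids[i],
          enrichment_test(members, scores, percentile, n_permutations,
                          seed + i))
  }))
  res$q <- NA_real_
  ok <- !is.na(res$perm_p)
  if (any(ok)) res$q[ok] <- qvalues(res$perm_p[ok])
  call_significant(res, p_cut, q_cut)
}

#' Flag significant enrichment results
#'
#' @param results Data frame with `perm_p` and `q` columns.
#' @param p_cut,q_cut Strict thresholds (defaults 0.01, 0.1).
#' @return `results` with a logical `significant` column.
#' @export
call_significant <- function(results, p_cut = 0.01, q_cut = 0.1) {
  results$significant <- !is.na(results$perm_p) &
    results$perm_p < p_cut & results$q < q_cut
  results
}

#' Intersect per-miRNA target-gene sets across prediction sources
#'
#' @param ... Two or more data frames with `set_id`, `gene_id` (one per
#'   prediction algorithm).
#' @return Data frame `set_id`, `gene_id` with, per set id, the genes
#'   present in every source.
#' @export
intersect_target_sets <- function(...) {
  sources <- list(...)
  stopifnot(length(sources) >= 2)
  ids <- Reduce(intersect, lapply(sources, function(s) unique(s$set_id)))
  do.call(rbind, lapply(ids, function(id) {
    genes <- Reduce(intersect, lapply(sources, function(s)
      s$gene_id[s$set_id == id]))
    if (!length(genes)) return(NULL)
    data.frame(set_id = id, gene_id = genes)
  }))
}
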