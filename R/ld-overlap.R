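#' Haplotype r-squared between two variants
#'
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))` over the
#' haplotypes of the panel.
#'
#' @param a,b Variant ids (columns of `panel`).
#' @param panel 0/1 haplotype matrix (haplotypes x variants, columns named
#'   by variant id).
#' @return r-squared in `[0, 1]`.
#' @examples
#' panel <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 1))
#' r_squared("a", "b", panel)  # 1/3
#' @export
r_squared <- function(a, b, panel) {
  for (v in c(a, b))
    if (!v %in% colnames(panel)) stop("variant absent from panel: ", v)
  ha <- panel[, a]; hb <- panel[, b]
  pa <- mean(ha); pb <- mean(hb)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("r-squared undefined for monomorphic variant: ",
         if (pa %in% c(0, 1)) a else b)
  pab <- mean(ha * hb)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Expand lead variants by LD proxies
#'
#' Returns the leads plus every panel variant in strong LD (r-squared
#' strictly greater than `r2_min`) with at least one lead, annotated with
#' its best lead. Monomorphic panel variants cannot be proxies and are
#' skipped.
#'
#' @param leads Character vector of lead variant ids (must be in the panel).
#' @param panel 0/1 haplotype matrix with variant-id column names.
#' @param r2_min Strict lower bound on r-squared (default 0.8).
#' @return Data frame with columns `variant`, `lead` (best lead), `r2`;
#'   leads are listed with themselves at r2 = 1.
#' @export
ld_proxies <- function(leads, panel, r2_min = 0.8) {
  absent <- setdiff(leads, colnames(panel))
  if (length(absent))
    stop("lead variant absent from panel: ", paste(absent, collapse = ", "))
  p <- colMeans(panel)
  poly <- p > 0 & p < 1
  mono_leads <- leads[!poly[leads]]
  if (length(mono_leads))
    stop("r-squared undefined for monomorphic lead: ",
         paste(mono_leads, collapse = ", "))
  r2 <- suppressWarnings(
    cor(panel[, leads, drop = FALSE],
        panel[, poly, drop = FALSE]))^2  # leads x polymorphic variants
  best <- apply(r2, 2, which.max)
  best_r2 <- r2[cbind(best, seq_along(best))]
  keep <- best_r2 > r2_min
  out <- data.frame(variant = colnames(r2)[keep],
                    lead = leads[best[keep]],
                    r2 = unname(best_r2[keep]))
  # leads always included, with themselves
  miss <- setdiff(leads, out$variant)
  if (length(miss))
    out <- rbind(out, data.frame(variant = miss, lead = miss, r2 = 1))
  out[order(match(out$variant, colnames(panel))), , drop = FALSE]
}

#' Overlap variants with genomic intervals
#'
#' A variant at 1-based position p overlaps a 0-based half-open interval
#' `[start, end)` iff `start <= p - 1 < end`. Strand is ignored (a SNP hits
#' a target site regardless of strand). All overlapping pairs are reported
#' in deterministic (chrom, pos, feature_id) order.
#'
#' @param variants Data frame with columns `id`, `chrom`, `pos` (1-based).
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `feature_id`, and optionally `feature_type`,
#'   `locus`.
#' @return Data frame of pairs: `variant`, `chrom`, `pos`, `feature_id`,
#'   plus `feature_type`/`locus` when present in `intervals`.
#' @export
overlap_variants <- function(variants, intervals) {
  gr_v <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, width = 1))
  gr_i <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals$start + 1L,
                                                  intervals$end))
  # disjoint chromosome sets are a legitimate no-overlap case, not a
  # user error worth a warning
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_v, gr_i, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out <- data.frame(variant = variants$id[qi],
                    chrom = variants$chrom[qi],
                    pos = variants$pos[qi],
                    feature_id = intervals$feature_id[si])
  for (col in intersect(c("feature_type", "locus"), names(intervals)))
    out[[col]] <- intervals[[col]][si]
  out[order(out$chrom, out$pos, out$feature_id), , drop = FALSE]
}

#' Collapse variant-interval overlaps to locus-level counts
#'
#' @param overlaps Data frame from [overlap_variants()] including a `locus`
#'   column (or a `locus_map` supplied separately).
#' @param locus_map Optional named character vector, feature_id -> locus.
#' @return List with `n_loci`, `n_variants` (distinct variants overlapping
#'   anything), and `per_locus` (data frame `locus`, `n_variants`).
#' @export
count_locus_hits <- function(overlaps, locus_map = NULL) {
  if (!is.null(locus_map))
    overlaps$locus <- locus_map[overlaps$feature_id]
  if (is.null(overlaps$locus)) stop("no locus annotation available")
  pairs <- unique(overlaps[, c("locus", "variant")])
  if (!nrow(pairs)) {
    return(list(n_loci = 0L, n_variants = 0L,
                per_locus = data.frame(locus = character(0),
                                       n_variants = integer(0))))
  }
  per_locus <- as.data.frame(table(pairs$locus), stringsAsFactors = FALSE)
  names(per_locus) <- c("locus", "n_variants")
  list(n_loci = nrow(per_locus),
       n_variants = length(unique(pairs$variant)),
       per_locus = per_locus[order(per_locus$locus), , drop = FALSE])
}
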