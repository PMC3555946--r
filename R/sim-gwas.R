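#' Simulate GWAS summary statistics, an LD panel, genes and target-gene sets
#'
#' Emulates the inputs of the target-enrichment analysis: a haplotype panel
#' with block LD structure (within blocks of 10 consecutive variants, each
#' column is the previous one copied with a 5% per-site flip probability, so
#' pairwise r-squared spans (0,1]); per-variant association p-values that are
#' uniform under the null; gene annotations carrying the confounders the
#' adjustment step corrects for (transcript span, number of variants, number
#' of LD proxies); and predicted target-gene sets. Sets named in
#' `config$planted_enriched_sets` draw their members from a shared pool of
#' associated genes whose variants get `p = u^effect_inflation`; with
#' `effect_inflation = 1` every p-value is uniform and all sets are null.
#'
#' @param config A [sim_config()] with `n_variants >= n_genes`.
#' @param n_haplotypes Haplotypes in the LD panel (default 120).
#' @param block_size Variants per LD block (default 10).
#' @param flip_prob Per-site copy-error probability within a block
#'   (default 0.05); smaller means tighter LD.
#' @return Object of class `gwas_sim`: list with `variants` (data frame `id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `pvalue`), `haplotypes` (0/1
#'   matrix, haplotypes x variants, columns named by variant id), `genes`
#'   (data frame `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `span_bp`, `n_variants`, `n_proxies`), `gene_sets` (data frame `set_id`,
#'   `gene_id`), `intervals` (data frame of precursor/target-site intervals
#'   with `locus` ids), and `truth` (planted set ids, inflated gene ids).
#' @examples
#' g <- simulate_gwas(sim_config(seed = 3, n_variants = 300, n_genes = 50,
#'                               n_gene_sets = 6,
#'                               planted_enriched_sets = "set1"))
#' head(g$variants)
#' @export
simulate_gwas <- function(config, n_haplotypes = 120L, block_size = 10L,
                          flip_prob = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_variants < config$n_genes)
    stop("n_variants must be >= n_genes")
  with_seed(config$seed + 4L, {
    ng <- config$n_genes
    nv <- config$n_variants

    # gene geometry: genes laid end-to-end with gaps, split over two chroms
    span <- pmax(2000L, round(rlnorm(ng, log(2e4), 0.5)))
    gap <- rpois(ng, 5000)
    chrom_of <- rep(c("chr1", "chr2"), length.out = ng)
    genes <- do.call(rbind, lapply(c("chr1", "chr2"), function(ch) {
      i <- which(chrom_of == ch)
      end <- cumsum(span[i] + gap[i])
      data.frame(gene_id = paste0("g", i), chrom = ch,
                 start = end - span[i], end = end, span_bp = span[i])
    }))
    chrom_len <- tapply(genes$end, genes$chrom, max) + 10000

    # variants uniform over each chromosome
    nv_chr <- round(nv * chrom_len / sum(chrom_len))
    nv_chr[1] <- nv - sum(nv_chr[-1])
    vr <- do.call(rbind, lapply(seq_along(chrom_len), function(k) {
      ch <- names(chrom_len)[k]
      data.frame(chrom = ch,
                 pos = sort(sample.int(as.integer(chrom_len[[k]]), nv_chr[k])))
    }))
    vr$id <- paste0("rs", seq_len(nrow(vr)))
    bases <- c("A", "C", "G", "T")
    vr$ref <- sample(bases, nrow(vr), replace = TRUE)
    vr$alt <- vapply(vr$ref, function(b) sample(setdiff(bases, b), 1), "")

    # haplotype panel with block LD
    H <- matrix(0L, n_haplotypes, nrow(vr),
                dimnames = list(NULL, vr$id))
    block <- rep(seq_len(ceiling(nrow(vr) / block_size)),
                 each = block_size, length.out = nrow(vr))
    for (j in seq_len(nrow(vr))) {
      if (j == 1 || block[j] != block[j - 1]) {
        maf <- runif(1, 0.1, 0.5)
        H[, j] <- as.integer(runif(n_haplotypes) < maf)
      } else {
        flip <- runif(n_haplotypes) < flip_prob
        H[, j] <- ifelse(flip, 1L - H[, j - 1L], H[, j - 1L])
      }
    }

    # gene sets: planted sets draw from a shared pool of associated genes
    # (predicted target sets of related miRNAs overlap heavily)
    set_ids <- paste0("set", seq_len(config$n_gene_sets))
    planted <- intersect(config$planted_enriched_sets, set_ids)
    pool_size <- min(ng, max(50L, round(ng / 5)))
    pool <- sample(genes$gene_id, pool_size)
    sizes <- sample(50:250, config$n_gene_sets, replace = TRUE)
    gene_sets <- do.call(rbind, lapply(seq_along(set_ids), function(s) {
      universe <- if (set_ids[s] %in% planted) pool else genes$gene_id
      data.frame(set_id = set_ids[s],
                 gene_id = sample(universe, min(sizes[s], length(universe))))
    }))

    # association p-values: uniform, then deflated for variants inside
    # member genes of planted sets
    u <- runif(nrow(vr))
    inflated_genes <- unique(gene_sets$gene_id[gene_sets$set_id %in% planted])
    vr$pvalue <- u
    if (length(inflated_genes) && config$effect_inflation != 1) {
      gi <- genes[genes$gene_id %in% inflated_genes, ]
      hit <- variant_in_any_gene(vr, gi)
      vr$pvalue[hit] <- u[hit]^config$effect_inflation
    }

    # confounders: variant count per gene and LD-proxy count (block-wise r2)
    vg <- variant_gene_index(vr, genes)
    nvar <- tabulate(vg$gene_idx, nbins = ng)
    genes$n_variants <- nvar
    genes$n_proxies <- count_gene_proxies(H, block, vg, ng)

    # intervals for the overlap analyses: miRNA precursors at random
    # positions, predicted target sites placed on a subset of variants
    prec <- data.frame(chrom = sample(names(chrom_len), 20, replace = TRUE),
                       start = 0L, end = 0L, strand = "+",
                       feature_id = paste0("pre_mir", 1:20),
                       feature_type = "precursor",
                       locus = paste0("locus", ceiling(1:20 / 4)))
    for (k in seq_len(nrow(prec)))
      prec$start[k] <- sample.int(as.integer(chrom_len[[prec$chrom[k]]]) - 100L, 1)
    prec$end <- prec$start + 80L
    tv <- vr[sample(nrow(vr), min(30L, nrow(vr))), ]
    sites <- data.frame(chrom = tv$chrom, start = tv$pos - 4L,
                        end = tv$pos + 3L, strand = "+",
                        feature_id = paste0("site", seq_len(nrow(tv))),
                        feature_type = "target_site",
                        locus = paste0("locus", 5 + ceiling(seq_len(nrow(tv)) / 5)))
    vr <- vr[, c("id", "chrom", "pos", "ref", "alt", "pvalue")]
    structure(list(variants = vr, haplotypes = H, genes = genes,
                   gene_sets = gene_sets, intervals = rbind(prec, sites),
                   truth = list(planted_sets = planted,
                                inflated_genes = inflated_genes,
                                pool = pool)),
              class = "gwas_sim")
  })
}

# logical: variant (1-based pos) falls inside any of the given gene bodies
# (0-based half-open)
variant_in_any_gene <- function(variants, genes) {
  if (!nrow(genes)) return(rep(FALSE, nrow(variants)))
  gr_v <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, width = 1))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  IRanges::overlapsAny(gr_v, gr_g)
}

# data.frame(variant_idx, gene_idx) for variants inside gene bodies
variant_gene_index <- function(variants, genes) {
  gr_v <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos, width = 1))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_v, gr_g)
  data.frame(variant_idx = S4Vectors::queryHits(ov),
             gene_idx = S4Vectors::subjectHits(ov))
}

# per-gene count of distinct panel variants in strong LD (r2 > 0.8) with any
# of the gene's variants; LD is confined to blocks by construction
count_gene_proxies <- function(H, block, vg, ng) {
  n_prox <- integer(ng)
  if (!nrow(vg)) return(n_prox)
  r2_cache <- new.env(parent = emptyenv())
  block_r2 <- function(b) {
    key <- as.character(b)
    if (!is.null(r2_cache[[key]])) return(r2_cache[[key]])
    idx <- which(block == b)
    r2 <- suppressWarnings(cor(H[, idx, drop = FALSE]))^2
    r2[is.na(r2)] <- 0
    r2_cache[[key]] <- list(idx = idx, r2 = r2)
    r2_cache[[key]]
  }
  by_gene <- split(vg$variant_idx, vg$gene_idx)
  for (g in names(by_gene)) {
    prox <- integer(0)
    for (v in by_gene[[g]]) {
      b <- block_r2(block[v])
      j <- match(v, b$idx)
      prox <- c(prox, b$idx[b$r2[j, ] > 0.8])
    }
    n_prox[as.integer(g)] <- length(unique(prox))
  }
  n_prox
}
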