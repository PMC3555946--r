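#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults describe the study conditions the rest of the package
#' is exercised under: libraries of 50 bp reads dominated by ~22 nt mature
#' miRNA inserts with 3' adaptor read-through, an 8-tissue expression panel of
#' medium complexity (a few dozen miRNAs carrying ~90% of reads) with twelve
#' planted tissue-specific miRNAs and one pair of near-duplicate tissue
#' profiles, and GWAS summary statistics with block LD structure and a dozen
#' planted signal-enriched target-gene sets.
#'
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   outputs from every generator.
#' @param n_hairpins Number of miRNA hairpins in the reference (each with one
#'   mature and one star window).
#' @param n_tissues Number of tissues in the expression panel (>= 3); the
#'   first is named `"islet"`, the last two are generated as near-duplicates.
#' @param n_libraries_per_tissue Sequencing libraries per tissue in the panel.
#' @param reads_per_library Target library depth; realised depths vary
#'   log-normally (sdlog 0.3) around it so normalization has work to do.
#' @param adaptor_sequence 3' adaptor appended to every insert (default: the
#'   Illumina TruSeq small RNA adaptor).
#' @param planted_specific Named character vector mapping miRNA ids to the
#'   tissue each is planted as specific to (>= 80% of its cross-tissue
#'   expression). Default: twelve miRNAs spread round-robin over the
#'   non-duplicate tissues.
#' @param abundance_concentration Log-scale spread (sdlog) of the log-normal
#'   miRNA abundance distribution; 1.2 puts ~90% of reads on roughly half of
#'   a 60-miRNA reference.
#' @param n_variants,n_genes GWAS panel sizes; `n_variants >= n_genes`.
#' @param n_gene_sets Number of predicted target-gene sets to simulate.
#' @param planted_enriched_sets Character vector of set ids whose member
#'   genes receive inflated association signal.
#' @param effect_inflation Association-signal boost for planted sets: member
#'   variants get `p = u^effect_inflation` for uniform `u` (1 = null).
#' @param read_length Read length before clipping, in nt.
#' @param dimer_fraction Fraction of pure adaptor-dimer reads per library.
#' @param n_read_fraction Fraction of reads with > 50% N bases.
#' @param star_fraction Probability that an insert comes from the star rather
#'   than the mature strand of its hairpin.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_hairpins = 5)
#' cfg$n_hairpins
#' @export
sim_config <- function(seed = 1L,
                       n_hairpins = 60L,
                       n_tissues = 8L,
                       n_libraries_per_tissue = 1L,
                       reads_per_library = 10000L,
                       adaptor_sequence = "TGGAATTCTCGGGTGCCAAGG",
                       planted_specific = NULL,
                       abundance_concentration = 1.2,
                       n_variants = 6000L,
                       n_genes = 1500L,
                       n_gene_sets = 60L,
                       planted_enriched_sets = paste0("set", 1:12),
                       effect_inflation = 5,
                       read_length = 50L,
                       dimer_fraction = 0.05,
                       n_read_fraction = 0.01,
                       star_fraction = 0.05) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_hairpins >= 0, n_tissues >= 1,
            n_libraries_per_tissue >= 1, reads_per_library >= 1,
            nchar(adaptor_sequence) >= 1,
            abundance_concentration > 0, effect_inflation > 0,
            read_length >= 16,
            dimer_fraction >= 0, dimer_fraction < 1,
            n_read_fraction >= 0, n_read_fraction < 1,
            star_fraction >= 0, star_fraction < 1)
  tissues <- tissue_names(n_tissues)
  if (is.null(planted_specific)) {
    # plant into the non-duplicate tissues only (the last two tissues are
    # generated as near-duplicates of each other)
    plantable <- tissues[seq_len(max(1L, n_tissues - 2L))]
    k <- min(12L, n_hairpins)
    planted_specific <- if (k < 1) character(0) else setNames(
      plantable[((seq_len(k) - 1L) %% length(plantable)) + 1L],
      paste0("mir", seq_len(k), "-5p"))
  }
  if (length(planted_specific) &&
      !all(planted_specific %in% tissues)) {
    stop("planted_specific maps to tissues that are not generated: ",
         paste(setdiff(planted_specific, tissues), collapse = ", "))
  }
  cfg <- list(seed = as.integer(seed),
              n_hairpins = as.integer(n_hairpins),
              n_tissues = as.integer(n_tissues),
              n_libraries_per_tissue = as.integer(n_libraries_per_tissue),
              reads_per_library = as.integer(reads_per_library),
              adaptor_sequence = toupper(adaptor_sequence),
              planted_specific = planted_specific,
              abundance_concentration = abundance_concentration,
              n_variants = as.integer(n_variants),
              n_genes = as.integer(n_genes),
              n_gene_sets = as.integer(n_gene_sets),
              planted_enriched_sets = planted_enriched_sets,
              effect_inflation = effect_inflation,
              read_length = as.integer(read_length),
              dimer_fraction = dimer_fraction,
              n_read_fraction = n_read_fraction,
              star_fraction = star_fraction)
  class(cfg) <- "sim_config"
  cfg
}

tissue_names <- function(n) {
  if (n < 1) return(character(0))
  c("islet", if (n > 1) paste0("tissue", seq(2, n)))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config (seed ", x$seed, "): ",
      x$n_hairpins, " hairpins, ", x$n_tissues, " tissues, ",
      length(x$planted_specific), " planted specific miRNAs, ",
      x$n_variants, " variants / ", x$n_genes, " genes / ",
      x$n_gene_sets, " gene sets (", length(x$planted_enriched_sets),
      " planted)\n", sep = "")
  invisible(x)
}
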