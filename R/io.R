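#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read a hairpin mature/star coordinate table
#'
#' Inverse of [write_hairpin_table()]: rebuilds hairpin records from a
#' hairpin FASTA plus the coordinate TSV (0-based half-open).
#'
#' @param fasta_path Hairpin FASTA.
#' @param table_path Coordinate TSV with columns `hairpin_id`, `name`,
#'   `type` (mature/star), `start`, `end`.
#' @return Named list of hairpin records.
#' @export
read_hairpin_records <- function(fasta_path, table_path) {
  seqs <- read_fasta(fasta_path)
  tab <- read.delim(table_path, stringsAsFactors = FALSE)
  lapply(setNames(names(seqs), names(seqs)), function(id) {
    sub <- tab[tab$hairpin_id == id, ]
    h <- list(id = id, sequence = seqs[[id]],
              mature_intervals = sub[sub$type == "mature",
                                     c("name", "start", "end")],
              star_intervals = sub[sub$type == "star",
                                   c("name", "start", "end")])
    class(h) <- "hairpin_record"
    h
  })
}

#' Read a reference directory into a bundle
#'
#' Expects `contaminants.fa`, `hairpins.fa`, `hairpins.tsv`, `ncrnas.fa`,
#' `genome.fa` as written by [write_reference()].
#'
#' @param dir Directory path.
#' @return A `reference_bundle`.
#' @export
read_reference <- function(dir) {
  structure(list(
    contaminants = read_fasta(file.path(dir, "contaminants.fa")),
    hairpins = read_hairpin_records(file.path(dir, "hairpins.fa"),
                                    file.path(dir, "hairpins.tsv")),
    ncrnas = read_fasta(file.path(dir, "ncrnas.fa")),
    genome = read_fasta(file.path(dir, "genome.fa"))),
    class = "reference_bundle")
}

#' Write a reference bundle to a directory
#'
#' @param bundle A `reference_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$contaminants, file.path(dir, "contaminants.fa"))
  write_fasta(vapply(bundle$hairpins, `[[`, "", "sequence"),
              file.path(dir, "hairpins.fa"))
  write_hairpin_table(bundle$hairpins, file.path(dir, "hairpins.tsv"))
  write_fasta(bundle$ncrnas, file.path(dir, "ncrnas.fa"))
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  invisible(dir)
}

#' Write / read a count (or any numeric) matrix as TSV
#'
#' Feature ids in the first column (`feature`), one column per library.
#'
#' @param m Numeric matrix with row and column names.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(feature = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write intervals as BED (plus feature_type / locus extra columns)
#'
#' @param intervals Data frame with `chrom`, `start`, `end`, `feature_id`,
#'   optional `strand`, `feature_type`, `locus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom, start = intervals$start,
                    end = intervals$end, name = intervals$feature_id,
                    score = 0,
                    strand = intervals$strand %||% "+")
  for (col in intersect(c("feature_type", "locus"), names(intervals)))
    bed[[col]] <- intervals[[col]]
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path (columns chrom, start, end, name, score, strand,
#'   and optionally feature_type, locus).
#' @return Data frame with `chrom`, `start`, `end`, `feature_id`, `strand`
#'   (+ extras when present).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "feature_id", "score",
                      "strand")[seq_len(min(6, ncol(df)))]
  if (ncol(df) >= 7) names(df)[7] <- "feature_type"
  if (ncol(df) >= 8) names(df)[8] <- "locus"
  df$score <- NULL
  df
}

#' Write every synthetic input of the pipeline to a directory
#'
#' Emits the reference bundle, per-library FASTQ files, the tissue-panel
#' count matrix, the GWAS variant table, haplotype panel, gene annotations,
#' gene sets and intervals -- plus ground-truth tables so recovery analyses
#' never re-derive truth from the pipeline under test.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param n_read_libraries FASTQ libraries to simulate (abundances drawn
#'   from the tissue panel's islet profile).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(config, dir, n_read_libraries = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- make_reference(config)
  write_reference(bundle, file.path(dir, "reference"))

  panel <- simulate_tissue_panel(config)
  write_matrix_tsv(panel$counts, file.path(dir, "panel_counts.tsv"))
  write.table(data.frame(library = names(panel$tissue),
                         tissue = unname(panel$tissue)),
              file.path(dir, "panel_libraries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(panel$truth$weights, file.path(dir, "truth_weights.tsv"))
  write.table(data.frame(mirna = names(panel$truth$planted),
                         tissue = unname(panel$truth$planted)),
              file.path(dir, "truth_planted.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  libs <- simulate_reads(bundle, panel$truth$abundance, config,
                         n_libraries = n_read_libraries)
  for (l in names(libs)) {
    write_fastq(libs[[l]]$reads, file.path(dir, paste0(l, ".fastq")))
    write.table(libs[[l]]$truth, file.path(dir, paste0(l, "_truth.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  g <- simulate_gwas(config)
  write.table(g$variants, file.path(dir, "variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(g$haplotypes, file.path(dir, "haplotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(g$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(g$gene_sets, file.path(dir, "gene_sets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(g$intervals, file.path(dir, "intervals.bed"))
  write.table(data.frame(set_id = g$truth$planted_sets),
              file.path(dir, "truth_planted_sets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
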