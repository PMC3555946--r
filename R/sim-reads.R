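#' Simulate small RNA sequencing libraries
#'
#' Draws reads from the mature (or, at a low rate, star) sequences of the
#' reference hairpins in proportion to the supplied abundance weights,
#' applies 0-2 nt end jitter within the hairpin, appends the 3' adaptor and
#' truncates to the fixed read length, then injects a configurable fraction
#' of pure adaptor-dimer reads and of reads dominated by N bases. Library
#' depths vary log-normally around `reads_per_library` so that downstream
#' normalization is exercised.
#'
#' @param bundle A [make_reference()] bundle.
#' @param abundances Named non-negative weights over mature miRNA ids (names
#'   must match mature window names in the bundle); not all zero.
#' @param config A [sim_config()].
#' @param n_libraries Number of libraries to simulate.
#' @return Object of class `sim_reads`: a list of libraries, each a list with
#'   `reads` (named character vector of read sequences) and `truth` (data
#'   frame `id`, `source`: originating mature/star id, `"adaptor_dimer"`, or
#'   `"n_rich"`).
#' @examples
#' cfg <- sim_config(seed = 1, n_hairpins = 5, reads_per_library = 200)
#' ref <- make_reference(cfg)
#' ab <- setNames(rep(1, 5), paste0("mir", 1:5, "-5p"))
#' libs <- simulate_reads(ref, ab, cfg, n_libraries = 2)
#' length(libs[[1]]$reads)
#' @export
simulate_reads <- function(bundle, abundances, config, n_libraries = 3L) {
  stopifnot(inherits(bundle, "reference_bundle"), inherits(config, "sim_config"))
  if (length(abundances) == 0) stop("abundance map must be non-empty")
  if (any(abundances < 0) || all(abundances == 0))
    stop("abundance weights must be nonnegative and not all zero")
  mature_tab <- hairpin_window_table(bundle$hairpins)
  unknown <- setdiff(names(abundances),
                     mature_tab$name[mature_tab$type == "mature"])
  if (length(unknown))
    stop("abundances name miRNAs absent from the reference: ",
         paste(unknown, collapse = ", "))

  adaptor <- config$adaptor_sequence
  dimer <- substr(strrep(adaptor, ceiling(config$read_length / nchar(adaptor)) + 1L),
                  1L, config$read_length)
  jitter_p <- c(0.05, 0.15, 0.6, 0.15, 0.05)  # offsets -2..2, mostly 0

  with_seed(config$seed + 2L, {
    libs <- vector("list", n_libraries)
    for (l in seq_len(n_libraries)) {
      depth <- max(1L, round(config$reads_per_library * exp(rnorm(1, 0, 0.3))))
      kind <- sample(c("dimer", "n_rich", "insert"), depth, replace = TRUE,
                     prob = c(config$dimer_fraction, config$n_read_fraction,
                              1 - config$dimer_fraction - config$n_read_fraction))
      sources <- character(depth)
      seqs <- character(depth)
      n_ins <- sum(kind == "insert")
      if (n_ins > 0) {
        pick <- sample(names(abundances), n_ins, replace = TRUE,
                       prob = abundances)
        use_star <- runif(n_ins) < config$star_fraction
        d5 <- sample(-2:2, n_ins, replace = TRUE, prob = jitter_p)
        d3 <- sample(-2:2, n_ins, replace = TRUE, prob = jitter_p)
        ins_idx <- which(kind == "insert")
        for (j in seq_len(n_ins)) {
          hp_i <- as.integer(sub("^mir([0-9]+)-5p$", "\\1", pick[j]))
          h <- bundle$hairpins[[hp_i]]
          win <- if (use_star[j]) h$star_intervals else h$mature_intervals
          s <- max(0L, win$start + d5[j])
          e <- min(nchar(h$sequence), win$end + d3[j])
          if (e - s < 10L) { s <- win$start; e <- win$end }
          insert <- hairpin_subseq(h, s, e)
          seqs[ins_idx[j]] <- substr(paste0(insert, dimer), 1L, config$read_length)
          sources[ins_idx[j]] <- if (use_star[j]) h$star_intervals$name else win$name
        }
      }
      if (any(kind == "dimer")) {
        seqs[kind == "dimer"] <- dimer
        sources[kind == "dimer"] <- "adaptor_dimer"
      }
      if (any(kind == "n_rich")) {
        for (j in which(kind == "n_rich")) {
          x <- strsplit(rand_dna(config$read_length), "")[[1]]
          nn <- sample(seq(ceiling(0.6 * config$read_length), config$read_length), 1)
          x[sample(config$read_length, nn)] <- "N"
          seqs[j] <- paste(x, collapse = "")
        }
        sources[kind == "n_rich"] <- "n_rich"
      }
      ids <- sprintf("lib%d_read%06d", l, seq_len(depth))
      libs[[l]] <- list(reads = setNames(seqs, ids),
                        truth = data.frame(id = ids, source = sources))
    }
    names(libs) <- paste0("lib", seq_len(n_libraries))
    structure(libs, class = "sim_reads")
  })
}

hairpin_window_table <- function(hairpins) {
  do.call(rbind, lapply(hairpins, function(h) {
    rbind(cbind(hairpin_id = h$id, h$mature_intervals, type = "mature"),
          cbind(hairpin_id = h$id, h$star_intervals, type = "star"))
  }))
}

#' Write reads as FASTQ (Phred+33, dummy qualities)
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n) strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}
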