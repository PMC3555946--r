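#' Preprocess, align and count a collection of raw read libraries
#'
#' The full read-level chain for each library: 3' adaptor clipping, removal
#' of short and N-dominated reads, three-tier prioritised alignment, 1/k
#' fractional counting, and the background filter across libraries.
#'
#' @param read_sets Named list of raw read libraries (each a named character
#'   vector of sequences, e.g. one element of [simulate_reads()] output's
#'   `$reads`).
#' @param bundle A [make_reference()] bundle.
#' @param adaptor 3' adaptor sequence.
#' @param max_mismatches Alignment mismatch budget (default 1).
#' @param min_total Background cutoff across all libraries (default 100).
#' @param min_overlap,min_length,max_n_fraction Preprocessing settings.
#' @return List with `counts` (filtered fractional count matrix with
#'   `category` attribute), `counts_raw` (unfiltered), `summary`
#'   (per-library reads per category), `preprocess` (per-library clip/filter
#'   counters), `histograms` (per-library retained-length histograms).
#' @export
quantify_libraries <- function(read_sets, bundle, adaptor,
                               max_mismatches = 1L, min_total = 100,
                               min_overlap = 6L, min_length = 16L,
                               max_n_fraction = 0.5) {
  stopifnot(!is.null(names(read_sets)))
  pre <- lapply(read_sets, preprocess_reads, adaptor = adaptor,
                min_overlap = min_overlap, min_length = min_length,
                max_n_fraction = max_n_fraction)
  assignments <- lapply(pre, function(cl)
    assign_reads(cl$reads, bundle, max_mismatches = max_mismatches))
  counts <- build_count_matrix(assignments)
  list(counts = filter_background(counts, min_total),
       counts_raw = counts,
       summary = assignment_summary(assignments),
       preprocess = lapply(pre, function(cl)
         cl[c("n_input", "n_clipped", "n_removed_short", "n_removed_n")]),
       histograms = lapply(pre, function(cl) length_histogram(cl$reads)))
}

#' Restrict a count matrix to one feature category
#'
#' @param counts Count matrix with a `category` attribute (see
#'   [build_count_matrix()]).
#' @param category Category to keep (default `"mature"`).
#' @return The subset matrix.
#' @export
counts_by_category <- function(counts, category = "mature") {
  cat_attr <- attr(counts, "category")
  if (is.null(cat_attr)) stop("counts carries no category attribute")
  out <- counts[rownames(counts) %in%
                  names(cat_attr)[cat_attr %in% category], , drop = FALSE]
  attr(out, "category") <- cat_attr[rownames(out)]
  out
}
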