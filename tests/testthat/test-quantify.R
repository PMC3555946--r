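test_that("align_simple agrees exactly with a brute-force Hamming scan", {
  set.seed(11)
  refs <- setNames(vapply(c(60, 80, 100), function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    ""), c("r1", "r2", "r3"))
  for (i in 1:40) {
    # half the queries are planted substrings (with occasional mutations),
    # half are random
    if (i %% 2 == 0) {
      r <- sample(names(refs), 1)
      st <- sample(nchar(refs[[r]]) - 20, 1)
      q <- substr(refs[[r]], st, st + 19)
      if (i %% 4 == 0) substr(q, sample(20, 1), sample(20, 1)) <- "T"
    } else {
      q <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                 collapse = "")
    }
    for (mm in 0:2) for (both in c(FALSE, TRUE)) {
      got <- sort_hits(align_simple(q, refs, mm, both_strands = both))
      want <- sort_hits(brute_align(q, refs, mm, both_strands = both))
      expect_equal(got, want)
    }
  }
  # exact substring: single 0-mismatch hit; absent sequence: empty
  expect_equal(nrow(align_simple(substr(refs[[1]], 5, 26), refs[1], 0)), 1)
  expect_equal(nrow(align_simple(strrep("ACGT", 6), refs, 0)), 0)
})

test_that("the concatenated-tier fast path equals align_simple", {
  cfg <- small_cfg(seed = 21)
  ref <- make_reference(cfg)
  hp <- vapply(ref$hairpins, `[[`, "", "sequence")
  ix <- isletmir:::build_tier_index(hp, 1L)
  set.seed(2)
  for (i in 1:30) {
    h <- sample(hp, 1)
    st <- sample(nchar(h) - 22, 1)
    q <- substr(h, st, st + 21)
    if (i %% 3 == 0) substr(q, sample(22, 1), sample(22, 1)) <- "A"
    got <- sort_hits(isletmir:::align_concat(Biostrings::DNAString(q), ix, 1L))
    want <- sort_hits(align_simple(q, hp, 1L))
    expect_equal(got, want)
  }
})

test_that("read assignment follows the decision table", {
  cfg <- small_cfg(seed = 22)
  ref <- make_reference(cfg)
  hp <- ref$hairpins
  empty <- data.frame(ref_id = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0))
  hit <- function(id, start, mm = 0L)
    data.frame(ref_id = id, start = start, strand = "+", mismatches = mm)

  # contaminant short-circuits even with a perfect miRNA hit
  a <- assign_read(hit("adaptor", 0), hit("hp1", hp$hp1$mature_intervals$start),
                   empty, empty, hp, read_length = 21)
  expect_equal(a$category, "contaminant")
  expect_equal(nrow(a$targets), 0)

  # two equal-distance mature hits split 1/2 each
  a <- assign_read(empty,
                   rbind(hit("hp1", hp$hp1$mature_intervals$start),
                         hit("hp2", hp$hp2$mature_intervals$start)),
                   empty, empty, hp, read_length = 20)
  expect_equal(a$category, "mature")
  expect_equal(a$k, 2)
  expect_setequal(a$targets$feature_id, c("mir1-5p", "mir2-5p"))
  expect_equal(a$targets$weight, c(0.5, 0.5))
  expect_equal(sum(a$targets$weight), 1)

  # class priority beats mismatch distance: miRNA at 1 mismatch wins over
  # ncRNA at 0
  a <- assign_read(empty, hit("hp1", hp$hp1$mature_intervals$start, mm = 1L),
                   hit("ncrna1", 0, mm = 0L), empty, hp, read_length = 20)
  expect_equal(a$category, "mature")

  # within the winning class only minimum-mismatch targets survive
  a <- assign_read(empty,
                   rbind(hit("hp1", hp$hp1$mature_intervals$start, 0L),
                         hit("hp3", hp$hp3$mature_intervals$start, 1L)),
                   empty, empty, hp, read_length = 20)
  expect_equal(a$targets$feature_id, "mir1-5p")
  expect_equal(a$k, 1)

  # ncRNA beats genome; unmapped when nothing hits
  a <- assign_read(empty, empty, hit("ncrna2", 3), hit("ctg_hp1", 9), hp, 20)
  expect_equal(a$category, "ncrna")
  a <- assign_read(empty, empty, empty, empty, hp, 20)
  expect_equal(a$category, "unmapped")
})

test_that("mature/star window classification honours the 3 nt pad", {
  cfg <- small_cfg(seed = 23)
  h <- make_reference(cfg)$hairpins[[1]]
  m <- h$mature_intervals
  len <- m$end - m$start
  # exactly the window, and 3 nt upstream with same end: mature
  expect_equal(classify_hairpin_hit(m$start, m$end, h)$class, "mature")
  expect_equal(classify_hairpin_hit(m$start - 3, m$end, h)$class, "mature")
  expect_equal(classify_hairpin_hit(m$start, m$end + 3, h)$class, "mature")
  # 4 nt upstream: outside the padded window
  expect_equal(classify_hairpin_hit(m$start - 4, m$end, h)$class,
               "hairpin_only")
  s <- h$star_intervals
  expect_equal(classify_hairpin_hit(s$start - 2, s$end, h)$class, "star")
  expect_equal(classify_hairpin_hit(s$start - 2, s$end, h)$name, s$name)
})

test_that("counts conserve mapped non-contaminant reads and split 1/k", {
  cfg <- small_cfg(seed = 24, reads_per_library = 800)
  ref <- make_reference(cfg)
  ab <- setNames(rep(1, 10), paste0("mir", 1:10, "-5p"))
  libs <- simulate_reads(ref, ab, cfg, n_libraries = 2)
  asn <- lapply(libs, function(l) {
    cl <- preprocess_reads(l$reads, cfg$adaptor_sequence)
    assign_reads(cl$reads, ref)
  })
  counts <- build_count_matrix(asn)
  for (l in names(asn)) {
    cats <- vapply(asn[[l]], `[[`, "", "category")
    n_counted <- sum(!cats %in% c("contaminant", "unmapped"))
    expect_equal(sum(counts[, l]), n_counted, tolerance = 1e-9)
  }
  # hairpins 1 and 2 share a mature sequence: unjittered reads from either
  # multi-map and are split 0.5/0.5
  ks <- unlist(lapply(asn, function(x) vapply(x, function(a) a$k, 0L)))
  expect_true(any(ks == 2))
  for (l in names(asn)) {
    w <- unlist(lapply(asn[[l]], function(a) a$targets$weight))
    expect_true(all(w > 0 & w <= 1))
  }
})

test_that("reads from a single source all quantify to that source", {
  cfg <- small_cfg(seed = 25, reads_per_library = 300, dimer_fraction = 0,
                   n_read_fraction = 0, star_fraction = 0)
  ref <- make_reference(cfg)
  ab <- setNames(c(0, 0, 0, 1, rep(0, 6)), paste0("mir", 1:10, "-5p"))
  libs <- simulate_reads(ref, ab, cfg, n_libraries = 1)
  cl <- preprocess_reads(libs[[1]]$reads, cfg$adaptor_sequence)
  asn <- list(lib1 = assign_reads(cl$reads, ref))
  counts <- build_count_matrix(asn)
  expect_equal(rownames(counts), "mir4-5p")
  expect_equal(sum(counts), length(cl$reads))
})

test_that("adaptor-dimer reads align to the contaminant tier when unclipped", {
  cfg <- small_cfg(seed = 26, reads_per_library = 10000, dimer_fraction = 0.1,
                   n_read_fraction = 0)
  ref <- make_reference(cfg)
  ab <- setNames(rep(1, 10), paste0("mir", 1:10, "-5p"))
  lib <- simulate_reads(ref, ab, cfg, n_libraries = 1)[[1]]
  # align raw (unclipped) reads: dimers hit the contaminant reference and
  # are excluded from counting
  n_dimer_truth <- sum(lib$truth$source == "adaptor_dimer")
  dimers <- lib$reads[lib$truth$source == "adaptor_dimer"]
  asn <- assign_reads(unique(dimers), ref)
  expect_true(all(vapply(asn, `[[`, "", "category") == "contaminant"))
  n <- length(lib$reads)
  expect_lt(abs(n_dimer_truth - 0.1 * n), 3 * sqrt(n * 0.1 * 0.9) + 1)
})

test_that("background filter drops below 100 and keeps exactly 100", {
  m <- matrix(c(50, 50, 49.5, 40, 60, 80), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("l1", "l2")))
  attr(m, "category") <- c(a = "mature", b = "mature", c = "mature")
  f <- filter_background(m)
  expect_setequal(rownames(f), c("a", "c"))   # a totals exactly 100
  expect_equal(rowSums(f)[["a"]], 100)
  expect_named(attr(f, "category"), rownames(f))
  all_high <- matrix(100, 2, 2, dimnames = list(c("x", "y"), c("l1", "l2")))
  expect_equal(filter_background(all_high), all_high, ignore_attr = TRUE)
})

test_that("planted abundances are recovered with high rank correlation", {
  cfg <- sim_config(seed = 27, n_hairpins = 30, reads_per_library = 3000)
  ref <- make_reference(cfg)
  set.seed(1)
  ab <- setNames(rlnorm(30, 0, 1.2), paste0("mir", 1:30, "-5p"))
  libs <- simulate_reads(ref, ab, cfg, n_libraries = 2)
  q <- quantify_libraries(lapply(libs, `[[`, "reads"), ref,
                          cfg$adaptor_sequence, min_total = 0)
  mat <- counts_by_category(q$counts_raw, "mature")
  got <- rowSums(mat)[names(ab)]
  got[is.na(got)] <- 0
  expect_gt(suppressWarnings(cor(ab, got, method = "spearman")), 0.9)
})
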