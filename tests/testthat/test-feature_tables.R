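# Peak-list I/O, mass arithmetic, annotation and cross-run alignment.

test_that("monoisotopic masses match independent atom sums", {
  # oracle: explicit sums over atomic masses, written out by hand
  expect_equal(monoisotopic_mass("H2O"),
               2 * 1.00782503 + 15.99491462, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("C15H14O7"),
               15 * 12 + 14 * 1.00782503 + 7 * 15.99491462,
               tolerance = 1e-9)
  expect_equal(monoisotopic_mass("C15H14O7"), 306.0740, tolerance = 1e-3)
  expect_equal(monoisotopic_mass("C11H3O13P3"),
               11 * 12 + 3 * 1.00782503 + 13 * 15.99491462 +
                 3 * 30.97376163, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("H3O3PSe"),
               3 * 1.00782503 + 3 * 15.99491462 + 30.97376163 +
                 73.92247640, tolerance = 1e-9)
  expect_error(monoisotopic_mass("C2Xx3"), class = "fnacmet_format_error")
  expect_error(monoisotopic_mass("(CH3)2"), class = "fnacmet_format_error")
})

test_that("neutral mass inverts the proton adduct in both modes", {
  expect_equal(neutral_mass_from_mz(307.083, "positive"),
               307.083 - 1.00727646, tolerance = 1e-9)
  expect_equal(neutral_mass_from_mz(307.083, "positive"), 306.0758,
               tolerance = 1e-4)
  expect_equal(neutral_mass_from_mz(434.872, "negative"),
               434.872 + 1.00727646, tolerance = 1e-9)
  expect_error(neutral_mass_from_mz(1.00727646, "positive"),
               class = "fnacmet_domain_error")
  # adduct round trip for a spread of formulas
  for (f in c("H2O", "C15H14O7", "C6H12O6", "C11H3O13P3", "H3O3PSe")) {
    m <- monoisotopic_mass(f)
    expect_equal(neutral_mass_from_mz(m + 1.00727646, "positive"), m,
                 tolerance = 1e-9)
    expect_equal(neutral_mass_from_mz(m - 1.00727646, "negative"), m,
                 tolerance = 1e-9)
  }
})

test_that("peak-list CSVs parse, preserve order, and fail loudly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt_min,intensity", "100.1,5.2,1e5", "200.2,9.9,2e4",
               "300.3,1.1,3e3"), path)
  pl <- read_peak_list(path, run_id = "r1", role = "sample",
                       mode = "positive", class_label = "benign")
  expect_s3_class(pl, "peak_list")
  expect_equal(nrow(pl$peaks), 3L)
  expect_equal(pl$peaks$mz, c(100.1, 200.2, 300.3))
  expect_equal(pl$peaks$rt, c(5.2, 9.9, 1.1))

  writeLines("mz,rt_min,intensity", path)
  expect_equal(nrow(read_peak_list(path, "r1", class_label = "benign")$peaks),
               0L)

  writeLines(c("mz,intensity", "100,1"), path)
  expect_error(read_peak_list(path, "r1", class_label = "benign"),
               "rt_min", class = "fnacmet_format_error")

  writeLines(c("mz,rt_min,intensity", "100,1,5", "100,1,-2"), path)
  expect_error(read_peak_list(path, "r1", class_label = "benign"),
               "row 2", class = "fnacmet_validation_error")

  expect_error(peak_list("b1", role = "blank", class_label = "benign"),
               class = "fnacmet_validation_error")
})

test_that("annotation finds proton-adduct matches within tolerance", {
  compounds <- data.frame(
    compound_id = c("HMDB0038361", "CPD2"),
    name = c("(-)-Epigallocatechin", "other"),
    formula = c("C15H14O7", ""),
    monoisotopic_mass = c(NA, 500.0))
  feats <- data.frame(feature_id = c("a", "b", "c"),
                      mode = c("positive", "positive", "negative"),
                      mz = c(307.083,               # ~6 ppm from C15H14O7
                             400.0,                 # matches nothing
                             500.0 - 1.00727646))   # exact [M-H]- of CPD2
  ann <- annotate(feats, compounds, tol_ppm = 15)
  a <- ann[ann$feature_id == "a", ]
  expect_equal(nrow(a), 1L)
  expect_equal(a$compound_id, "HMDB0038361")
  expect_equal(a$adduct, "[M+H]+")
  expect_gt(a$ppm_error, 5)
  expect_lt(a$ppm_error, 7)
  expect_false("b" %in% ann$feature_id)
  c_ann <- ann[ann$feature_id == "c", ]
  expect_equal(c_ann$adduct, "[M-H]-")
  expect_equal(c_ann$ppm_error, 0, tolerance = 1e-9)

  # 20 ppm off: outside the 15 ppm tolerance
  off <- data.frame(feature_id = "d", mode = "positive",
                    mz = (306.074 * (1 + 20e-6)) + 1.00727646)
  expect_equal(nrow(annotate(off, compounds, 15)), 0L)
})

test_that("aligning a single run is the identity", {
  pk <- data.frame(mz = c(100, 200, 300), rt = c(1, 2, 3),
                   intensity = c(10, 20, 30))
  tab <- join_align(list(peak_list("r1", "sample", "positive", "benign",
                                   pk)))
  expect_equal(nrow(tab$features), 3L)
  expect_equal(as.numeric(tab$intensities[, 1]), pk$intensity)
  expect_equal(tab$features$mz, pk$mz)
})

test_that("alignment joins within tolerance and separates beyond it", {
  mk <- function(id, mz) peak_list(id, "sample", "positive", "benign",
                                   data.frame(mz = mz, rt = 5,
                                              intensity = 100))
  same <- join_align(list(mk("r1", 100.0000), mk("r2", 100.0005)))
  expect_equal(nrow(same$features), 1L)
  expect_equal(sum(same$intensities > 0), 2L)
  apart <- join_align(list(mk("r1", 100.0000), mk("r2", 100.0050)))
  expect_equal(nrow(apart$features), 2L)
  expect_error(join_align(list(mk("r1", 100),
                               peak_list("r2", "sample", "negative",
                                         "benign",
                                         data.frame(mz = 100, rt = 5,
                                                    intensity = 1)))),
               class = "fnacmet_validation_error")
})

test_that("jittered replicate runs align back to the planted ions", {
  set.seed(42)
  true_mz <- sort(runif(20, 100, 900))
  true_rt <- runif(20, 1, 24)
  runs <- lapply(1:5, function(r) {
    peak_list(sprintf("r%02d", r), "sample", "positive", "benign",
              data.frame(mz = true_mz * (1 + runif(20, -3e-6, 3e-6)),
                         rt = true_rt + runif(20, -0.2, 0.2),
                         intensity = runif(20, 1e4, 1e6)))
  })
  tab <- join_align(runs)
  expect_equal(nrow(tab$features), 20L)
  expect_true(all(tab$intensities > 0))
})

test_that("greedy alignment agrees with a single-linkage oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n_true <- sample(3:8, 1)
    true_mz <- 100 + cumsum(runif(n_true, 0.5, 5))
    true_rt <- runif(n_true, 2, 22)
    rows <- do.call(rbind, lapply(1:4, function(r) {
      keep <- runif(n_true) < 0.8
      data.frame(run = r, mz = true_mz[keep] * (1 + runif(sum(keep),
                                                          -3e-6, 3e-6)),
                 rt = true_rt[keep] + runif(sum(keep), -0.2, 0.2),
                 intensity = runif(sum(keep), 1e3, 1e5))
    }))
    runs <- lapply(split(rows, rows$run), function(d)
      peak_list(sprintf("r%d", d$run[1]), "sample", "positive", "benign",
                d[, c("mz", "rt", "intensity")]))
    tab <- join_align(runs, 10, 1.0)
    oracle <- single_linkage_features(rows, 10, 1.0)
    expect_equal(nrow(tab$features), length(unique(oracle)))
  }
})

test_that("raising tolerances never increases the feature count", {
  set.seed(7)
  true_mz <- 100 + cumsum(runif(10, 0.3, 3))
  true_rt <- runif(10, 2, 22)
  runs <- lapply(1:4, function(r)
    peak_list(sprintf("r%d", r), "sample", "positive", "benign",
              data.frame(mz = true_mz * (1 + runif(10, -3e-6, 3e-6)),
                         rt = true_rt + runif(10, -0.2, 0.2),
                         intensity = runif(10, 1e3, 1e5))))
  counts <- sapply(c(5, 10, 20, 50), function(tol)
    nrow(join_align(runs, mz_tol_ppm = tol)$features))
  expect_true(all(diff(counts) <= 0))
  counts_rt <- sapply(c(0.25, 0.5, 1, 2), function(tol)
    nrow(join_align(runs, rt_tol_min = tol)$features))
  expect_true(all(diff(counts_rt) <= 0))
})

test_that("mode merging concatenates features over a shared cohort", {
  mk_tab <- function(mode, n) {
    pre <- if (mode == "positive") "pos" else "neg"
    feature_table(
      data.frame(feature_id = sprintf("%s_F%02d", pre, seq_len(n)),
                 mode = mode, mz = 100 + seq_len(n), rt = 1,
                 evidence_flag = TRUE),
      data.frame(run_id = c("s1", "s2"), role = "sample",
                 class_label = "benign"),
      matrix(seq_len(2 * n), n, 2))
  }
  pos <- mk_tab("positive", 10); neg <- mk_tab("negative", 5)
  merged <- merge_modes(pos, neg)
  expect_equal(nrow(merged$features), 15L)
  expect_equal(merged$samples$run_id, pos$samples$run_id)

  empty_neg <- subset_features(mk_tab("negative", 5), logical(5))
  expect_equal(merge_modes(pos, empty_neg)$features, pos$features)

  bad <- mk_tab("negative", 5)
  bad$samples$run_id <- c("s1", "s3")
  rownames(bad$intensities) <- NULL
  colnames(bad$intensities) <- bad$samples$run_id
  expect_error(merge_modes(pos, bad), "s3",
               class = "fnacmet_validation_error")
})

test_that("feature tables round-trip through the wide-CSV format", {
  fx <- get_fixture()
  tab <- subset_features(fx$truth_table, 1:25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$features$feature_id, tab$features$feature_id)
  expect_equal(back$samples, tab$samples)
  expect_equal(unname(back$intensities), unname(tab$intensities),
               tolerance = 1e-12)
})
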