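test_that("identical design and seed reproduce the dataset exactly", {
  d <- small_design(seed = 7)
  expect_identical(generate_cohort(d), generate_cohort(d))
})

test_that("cohort labels honour the design margins and converter counts", {
  d <- cohort_design(n_patients = 90, case_fraction = 49 / 90,
                     n_converts = 13, n_suspicious = 2,
                     n_proteins = 50, n_regulated = 5,
                     n_replicate_pairs = 0, seed = 3)
  ds <- generate_cohort(d)
  cl <- ds$clinical
  expect_equal(sum(cl$cancer_2016 == "Yes"), 49)
  expect_equal(sum(cl$cancer_2016 == "No"), 39)
  expect_equal(sum(cl$cancer_2016 == "S"), 2)
  expect_equal(sum(cl$cancer_2014 == "No" & cl$cancer_2016 == "Yes"), 13)
  expect_true(all(cl$batch %in% 1:5))
})

test_that("design invariant violations name the offending field", {
  expect_error(cohort_design(n_converts = 50, n_patients = 90),
               "n_converts")
  expect_error(cohort_design(n_regulated = 100, n_proteins = 50),
               "n_regulated")
  expect_error(cohort_design(effect_log2_range = c(2, 1)),
               "effect_log2_range")
  expect_error(cohort_design(n_patients = -1), "n_patients")
})

test_that("a null design plants nothing and groups have equal means", {
  d <- noiseless_design(n_regulated = 0)
  ds <- generate_cohort(d)
  expect_equal(nrow(ds$truth$regulated), 0)
  x <- log2(ds$matrices[["A.protein_LFQ"]]$values)
  lab <- cancer_labels(ds$clinical)
  diff <- rowMeans(x[, names(lab)[lab == "case"]]) -
    rowMeans(x[, names(lab)[lab == "control"]])
  expect_equal(unname(diff), rep(0, nrow(x)), tolerance = 1e-12)
})

test_that("planted effects appear exactly in noise-free group differences", {
  d <- noiseless_design(n_proteins = 250, n_regulated = 200)
  ds <- generate_cohort(d)
  x <- log2(ds$matrices[["A.protein_LFQ"]]$values)
  lab <- cancer_labels(ds$clinical)
  diff <- rowMeans(x[, names(lab)[lab == "case"], drop = FALSE]) -
    rowMeans(x[, names(lab)[lab == "control"], drop = FALSE])
  reg <- ds$truth$regulated
  expected <- ifelse(reg$direction == "up", 1, -1) * reg$log2_effect
  expect_equal(unname(diff[reg$protein]), expected, tolerance = 1e-9)
  unreg <- setdiff(rownames(x), reg$protein)
  expect_equal(unname(diff[unreg]), rep(0, length(unreg)), tolerance = 1e-9)
})

test_that("zero engine noise and no dropout make the engines agree on intensities", {
  ds <- generate_cohort(noiseless_design())
  for (qt in c("protein_LFQ", "iBAQ", "peptide_LFQ")) {
    expect_equal(ds$matrices[[paste0("A.", qt)]]$values,
                 ds$matrices[[paste0("B.", qt)]]$values)
  }
})

test_that("spectral count matrices are nonnegative integers", {
  ds <- generate_cohort(small_design(seed = 11))
  for (nm in grep("spectral_count", names(ds$matrices), value = TRUE)) {
    v <- ds$matrices[[nm]]$values
    expect_true(all(v >= 0))
    expect_equal(v, round(v))
  }
})

test_that("detection follows the logistic dropout law", {
  d <- small_design(engine_noise_sd = 0, engine_b_missing_rate = 0)
  # one protein 10 steepness-units below the midpoint, one far above
  lat <- matrix(c(d$dropout_midpoint - 10 * d$dropout_steepness,
                  d$dropout_midpoint + 10 * d$dropout_steepness),
                2, 1000,
                dimnames = list(c("low", "high"), sprintf("r%04d", 1:1000)))
  set.seed(1)
  sim <- simulate_engine_matrices(lat, d)
  det <- sim$matrices[["A.protein_LFQ"]]$values > 0
  expect_lt(mean(det["low", ]), 0.01)
  expect_gt(mean(det["high", ]), 0.99)
})

test_that("detection frequency is non-decreasing in latent abundance", {
  d <- small_design(engine_noise_sd = 0, engine_b_missing_rate = 0)
  grid <- seq(d$dropout_midpoint - 8, d$dropout_midpoint + 8, by = 2)
  lat <- matrix(grid, length(grid), 2000,
                dimnames = list(sprintf("lv%02d", seq_along(grid)),
                                sprintf("r%04d", 1:2000)))
  set.seed(2)
  sim <- simulate_engine_matrices(lat, d)
  freq <- rowMeans(sim$matrices[["A.protein_LFQ"]]$values > 0)
  expect_true(all(diff(freq) > -0.03))  # Monte-Carlo slack
  expect_gt(freq[length(freq)], freq[1])
})

test_that("cancer-exclusive proteins are absent outside signal samples", {
  ds <- generate_cohort(small_design(seed = 9))
  lab16 <- ds$clinical$cancer_2016
  ctrl_cols <- ds$clinical$sample_id[lab16 != "Yes"]
  for (p in ds$truth$cancer_exclusive) {
    expect_equal(sum(ds$matrices[["A.iBAQ"]]$values[p, ctrl_cols]), 0)
  }
})

test_that("make_replicates is the identity at zero pairs and exact at zero noise", {
  ds <- generate_cohort(noiseless_design())
  expect_identical(make_replicates(ds, 0), ds)
  set.seed(4)
  ds2 <- make_replicates(ds, 3, within_noise_sd = 0)
  rep_cols <- setdiff(names(ds2$replicate_map), ds$clinical$sample_id)
  expect_length(rep_cols, 3)
  for (rc in rep_cols) {
    orig <- ds2$replicate_map[[rc]]
    expect_equal(ds2$matrices[["A.protein_LFQ"]]$values[, rc],
                 ds2$matrices[["A.protein_LFQ"]]$values[, orig])
  }
  expect_error(make_replicates(ds, 2, within_noise_sd = -1), "nonnegative")
})

test_that("replicate runs sit closer together than unrelated samples", {
  ds <- generate_cohort(small_design(seed = 21, n_replicate_pairs = 6,
                                     n_proteins = 150))
  m <- log2_plus_one(ds$matrices[["A.protein_LFQ"]])
  qc <- distance_qc(m, ds$replicate_map)
  expect_lt(qc$mean_replicate_pairs, qc$mean_all_pairs)
})

test_that("simulated study tables are concordant with the planted truth", {
  ds <- generate_cohort(small_design(seed = 13))
  tab <- simulate_study_tables(ds$truth, n_studies = 4, concordance = 1,
                               report_rate = 1, seed = 2)
  expect_setequal(unique(tab$study_id),
                  sprintf("study_%02d", 1:4))
  truth_dir <- setNames(ds$truth$regulated$direction,
                        unname(ds$truth$gene_map[ds$truth$regulated$protein]))
  expect_true(all(tab$direction == truth_dir[tab$gene]))
})
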