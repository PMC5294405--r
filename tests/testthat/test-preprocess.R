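test_that("contaminant removal drops listed rows and preserves order", {
  m <- qm(matrix(1:15, 5, 3))
  expect_identical(remove_contaminants(m, character(0))$values, m$values)
  expect_equal(nrow(remove_contaminants(m, rownames(m$values))$values), 0)
  ids <- rownames(m$values)
  out <- remove_contaminants(m, ids[c(2, 4)])
  expect_identical(rownames(out$values), ids[c(1, 3, 5)])
  # unknown ids are ignored
  expect_identical(remove_contaminants(m, "nope")$values, m$values)
})

test_that("log2(x+1) maps 0->0, 1->1, 3->2 and rejects negatives", {
  m <- qm(matrix(c(0, 1, 3, 7), 2, 2))
  out <- log2_plus_one(m)
  expect_equal(sort(as.vector(out$values)), c(0, 1, 2, 3))
  expect_equal(out$variant, "log")
  bad <- qm(matrix(c(0, 1, 3, 7), 2, 2))
  bad$values[1] <- -1
  expect_error(log2_plus_one(bad), "nonnegative")
})

test_that("quantile normalization equalizes column distributions", {
  m <- qm(matrix(c(2, 4, 6, 1, 3, 5), 3, 2), variant = "log")
  out <- quantile_normalize(m)
  expect_equal(unname(out$values[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out$values[, 2]), c(1.5, 3.5, 5.5))
  expect_equal(out$variant, "log+qn")
  # rank order within columns is preserved
  m2 <- qm(matrix(c(6, 2, 4, 3, 5, 1), 3, 2), variant = "log")
  out2 <- quantile_normalize(m2)
  expect_equal(order(out2$values[, 1]), order(m2$values[, 1]))
})

test_that("quantile normalization fixed points: identical columns, single column", {
  x <- matrix(rep(c(1, 5, 9), 3), 3, 3)
  m <- qm(x, variant = "log")
  expect_equal(quantile_normalize(m)$values, m$values, ignore_attr = FALSE)
  single <- qm(matrix(c(3, 1, 2), 3, 1), variant = "log")
  expect_equal(quantile_normalize(single)$values, single$values)
})

test_that("quantile normalization is idempotent and columns share the reference", {
  set.seed(8)
  for (rep in 1:5) {
    m <- qm(matrix(rexp(120), 30, 4), variant = "log")
    q1 <- quantile_normalize(m)
    sorted <- apply(q1$values, 2, sort)
    ref <- rowMeans(sorted)
    expect_equal(max(abs(sorted - ref)), 0, tolerance = 1e-12)
    q2 <- quantile_normalize(q1)
    expect_equal(q2$values, q1$values, tolerance = 1e-12)
  }
})

test_that("quantile normalization ties receive the mean reference of their ranks", {
  m <- qm(matrix(c(1, 1, 4, 2, 3, 5), 3, 2), variant = "log")
  out <- quantile_normalize(m)
  ref <- rowMeans(apply(m$values, 2, sort))
  expect_equal(unname(out$values[1:2, 1]), rep(mean(ref[1:2]), 2))
})

test_that("quantile normalization agrees with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(3)
  x <- matrix(rlnorm(200), 50, 4)
  m <- qm(x, variant = "log")
  expect_equal(unname(quantile_normalize(m)$values),
               unname(limma::normalizeQuantiles(x, ties = TRUE)),
               tolerance = 1e-10)
})

test_that("abundance filter keeps everything when the pool is already Gaussian", {
  set.seed(14)
  x <- matrix(rnorm(80 * 20, 20, 2) + rep(rnorm(80, 0, 2), 20), 80, 20)
  m <- qm(x, variant = "log")
  res <- gaussian_abundance_filter(m)
  expect_equal(res$threshold, res$trace$threshold[1])
  expect_equal(nrow(res$matrix$values), nrow(x))
  expect_equal(nrow(res$trace), 11)
})

test_that("abundance filter removes a zero-inflated low mode", {
  set.seed(15)
  low <- matrix(rnorm(30 * 20, 2, 0.5), 30, 20)
  low[runif(length(low)) < 0.5] <- 0
  high <- matrix(rnorm(100 * 20, 20, 2), 100, 20)
  m <- qm(rbind(low, high), variant = "log")
  res <- gaussian_abundance_filter(m)
  expect_gt(res$threshold, max(rowMeans(low)))
  # the entire low mode is removed; nearly all of the Gaussian mode is kept
  # (the quantile grid may cut marginally into it)
  expect_gte(nrow(res$matrix$values), 95)
  expect_true(all(rowMeans(res$matrix$values) > 10))
  # the retained pool scores better than the unfiltered pool
  expect_lt(min(res$trace$score), res$trace$score[1])
})

test_that("abundance filter never removes rows above its threshold and errors on empty input", {
  set.seed(16)
  m <- qm(matrix(rnorm(200, 10, 3), 20, 10), variant = "log")
  res <- gaussian_abundance_filter(m)
  kept <- rownames(res$matrix$values)
  expect_setequal(kept,
                  rownames(m$values)[rowMeans(m$values) >= res$threshold])
  empty <- quant_matrix(
    matrix(numeric(0), 0, 2, dimnames = list(character(0), c("a", "b"))),
    variant = "log")
  expect_error(gaussian_abundance_filter(empty), "empty")
})

test_that("the matrix family holds three variants per raw matrix", {
  ds <- generate_cohort(small_design(seed = 2, n_proteins = 40))
  fam <- build_matrix_family(ds$matrices, ds$truth$contaminants)
  expect_length(fam, 30)
  for (qt in c("protein_spectral_count", "peptide_spectral_count",
               "protein_LFQ", "peptide_LFQ", "iBAQ")) {
    expect_length(grep(paste0("\\.", qt, "\\."), names(fam)), 6)
  }
  one <- build_matrix_family(ds$matrices["A.iBAQ"], ds$truth$contaminants)
  expect_length(one, 3)
  expect_error(build_matrix_family(list(a = 1)), "slot")
})

test_that("family variants compose in the stated pipeline order", {
  ds <- generate_cohort(small_design(seed = 6, n_proteins = 40))
  fam <- build_matrix_family(ds$matrices["A.iBAQ"], character(0))
  m <- ds$matrices[["A.iBAQ"]]
  expect_equal(fam[["A.iBAQ.log"]]$values, log2(m$values + 1))
  expect_equal(fam[["A.iBAQ.log+qn"]]$values,
               quantile_normalize(log2_plus_one(m))$values)
  filt <- gaussian_abundance_filter(quantile_normalize(log2_plus_one(m)))
  expect_equal(fam[["A.iBAQ.log+qn+filter"]]$values, filt$matrix$values)
  expect_equal(fam[["A.iBAQ.log+qn+filter"]]$variant, "log+qn+filter")
})
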