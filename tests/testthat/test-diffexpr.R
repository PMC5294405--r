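make_labels <- function(case_ids, ctrl_ids) {
  factor(setNames(c(rep("case", length(case_ids)), rep("control", length(ctrl_ids))),
                  c(case_ids, ctrl_ids)),
         levels = c("control", "case"))
}

test_that("group contrast reproduces hand-computed folds and pooled variances", {
  x <- rbind(P1 = c(2, 2, 1, 1), P2 = c(3, 1, 1, 3))
  colnames(x) <- c("c1", "c2", "n1", "n2")
  m <- qm(x, variant = "log")
  lab <- make_labels(c("c1", "c2"), c("n1", "n2"))
  ct <- fit_group_contrast(m, lab)
  expect_equal(ct$log2_fold, c(1, 0))
  expect_equal(ct$s2, c(0, 2))
  expect_equal(ct$df, c(2, 2))
  expect_error(fit_group_contrast(m, make_labels(c("c1", "c2", "n1", "n2"),
                                                 character(0))),
               "at least 2")
})

test_that("prior estimation returns infinite d0 without excess spread", {
  pr <- estimate_prior(rep(2, 50), df = 20)
  expect_identical(pr$d0, Inf)
  # two proteins only: finite output, no crash
  pr2 <- estimate_prior(c(1, 3), df = 4)
  expect_true(is.numeric(pr2$s0_sq) && pr2$s0_sq > 0)
  expect_error(estimate_prior(c(0, 0), df = 4), "at least 2")
})

test_that("prior estimation recovers known hyperparameters", {
  set.seed(101)
  d0 <- 4; s0 <- 1.5; df <- 8
  s2 <- s0 * rf(2000, df, d0)
  pr <- estimate_prior(s2, df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.25)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.15)
})

test_that("prior estimation matches the reference moderation machinery", {
  skip_if_not_installed("limma")
  set.seed(7)
  s2 <- 1.2 * rf(500, 10, 6)
  pr <- estimate_prior(s2, 10)
  sq <- limma::squeezeVar(s2, df = 10)
  expect_equal(pr$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(pr$s0_sq, sq$var.prior, tolerance = 1e-6)
  post <- moderated_test(
    data.frame(protein = paste0("P", seq_along(s2)), log2_fold = 1,
               s2 = s2, df = 10, n_case = 6, n_control = 6),
    pr)
  expect_equal(post$s2_post, sq$var.post, tolerance = 1e-6)
})

test_that("posterior variance follows the shrinkage formula", {
  ct <- data.frame(protein = "P1", log2_fold = 1, s2 = 4, df = 4,
                   n_case = 3, n_control = 3)
  res <- moderated_test(ct, list(d0 = 4, s0_sq = 1))
  expect_equal(res$s2_post, 2.5)
  expect_equal(res$df_total, 8)
})

test_that("moderated t collapses to the ordinary pooled t at d0 = 0", {
  set.seed(22)
  x <- matrix(rnorm(40 * 10, 10), 40, 10)
  m <- qm(x, variant = "log")
  x <- m$values
  lab <- make_labels(colnames(x)[1:5], colnames(x)[6:10])
  ct <- fit_group_contrast(m, lab)
  res <- moderated_test(ct, list(d0 = 0, s0_sq = 1))
  ordinary <- apply(x, 1, function(v) {
    t.test(v[1:5], v[6:10], var.equal = TRUE)$statistic
  })
  expect_equal(res$t, unname(ordinary), tolerance = 1e-10)
  expect_equal(res$df_total, rep(8, 40))
})

test_that("d0 = Inf uses the prior variance everywhere", {
  set.seed(23)
  x <- matrix(rnorm(20 * 8, 5), 20, 8)
  m <- qm(x, variant = "log")
  x <- m$values
  lab <- make_labels(colnames(x)[1:4], colnames(x)[5:8])
  ct <- fit_group_contrast(m, lab)
  res <- moderated_test(ct, list(d0 = Inf, s0_sq = 3))
  expect_equal(res$s2_post, rep(3, 20))
  expect_equal(res$t, ct$log2_fold / sqrt(3 * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
})

test_that("moderated |t| interpolates between the d0 limits", {
  ct <- data.frame(protein = c("a", "b"), log2_fold = c(2, 2),
                   s2 = c(4, 0.5), df = 6, n_case = 4, n_control = 4)
  t0 <- abs(moderated_test(ct, list(d0 = 0, s0_sq = 1))$t)
  tI <- abs(moderated_test(ct, list(d0 = Inf, s0_sq = 1))$t)
  tm <- abs(moderated_test(ct, list(d0 = 5, s0_sq = 1))$t)
  for (i in 1:2) {
    expect_gte(tm[i], min(t0[i], tI[i]) - 1e-12)
    expect_lte(tm[i], max(t0[i], tI[i]) + 1e-12)
  }
  # equality when s2 equals the prior variance
  ct_eq <- data.frame(protein = "c", log2_fold = 1, s2 = 1, df = 6,
                      n_case = 4, n_control = 4)
  expect_equal(moderated_test(ct_eq, list(d0 = 3, s0_sq = 1))$t,
               moderated_test(ct_eq, list(d0 = 0, s0_sq = 1))$t)
})

test_that("zero posterior variance with nonzero fold is flagged with limiting p", {
  ct <- data.frame(protein = c("a", "b"), log2_fold = c(1, 0), s2 = 0,
                   df = 2, n_case = 2, n_control = 2)
  res <- moderated_test(ct, list(d0 = 0, s0_sq = 1))
  expect_true(res$zero_variance[1])
  expect_equal(res$p, c(0, 1))
})

test_that("BH adjustment matches the hand step-up on the worked example", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH adjustment is monotone and dominates the raw p-values", {
  set.seed(31)
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    sorted <- bh_adjust(sort(p))
    expect_true(all(diff(sorted) >= -1e-15))
  }
})

test_that("run_diffexpr drops never-detected proteins and tags provenance", {
  ds <- generate_cohort(small_design(seed = 19))
  fam <- build_matrix_family(ds$matrices["A.iBAQ"], ds$truth$contaminants)
  m <- fam[["A.iBAQ.log"]]
  res <- run_diffexpr(m, ds$clinical)
  x <- m$values[, names(cancer_labels(ds$clinical)), drop = FALSE]
  expect_setequal(res$protein, rownames(x)[rowSums(x > 0) > 0])
  expect_equal(unique(res$engine), "A")
  expect_equal(unique(res$quant_type), "iBAQ")
  expect_true(all(res$adj_p >= res$p - 1e-15))
})
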