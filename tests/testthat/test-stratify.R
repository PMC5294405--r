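test_that("PCA captures a single direction of variance completely", {
  base <- c(5, 5, 5, 5)
  x <- outer(c(1, 2, -1, 0.5), c(-1, 0, 1, 2)) + 10
  rownames(x) <- paste0("P", 1:4)
  colnames(x) <- paste0("s", 1:4)
  res <- pca_stratify(qm(x, variant = "log"), min_detect_frac = 0)
  expect_equal(res$variance_fractions[1], 1, tolerance = 1e-12)
})

test_that("PCA scores reconstruct the centered matrix and duplicates coincide", {
  set.seed(51)
  x <- matrix(rlnorm(30 * 8, 3), 30, 8,
              dimnames = list(paste0("P", 1:30), paste0("s", 1:8)))
  x <- cbind(x, s9 = x[, "s1"])   # duplicated sample
  res <- pca_stratify(qm(x, variant = "log"), min_detect_frac = 0)
  centered <- scale(t(x), center = TRUE, scale = FALSE)
  expect_equal(res$scores %*% t(res$loadings), centered,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(res$scores["s1", ], res$scores["s9", ], tolerance = 1e-9)
  # orthogonal score columns, non-increasing variance fractions
  g <- crossprod(res$scores)
  expect_equal(g[lower.tri(g)], rep(0, sum(lower.tri(g))), tolerance = 1e-6)
  expect_true(all(diff(res$variance_fractions) <= 1e-12))
})

test_that("two planted clusters separate on PC1 with the case side positive", {
  set.seed(52)
  n <- 40
  lab <- factor(rep(c("control", "case"), each = n / 2),
                levels = c("control", "case"))
  names(lab) <- sprintf("s%02d", 1:n)
  x <- matrix(rnorm(100 * n, 10), 100, n,
              dimnames = list(paste0("P", 1:100), names(lab)))
  x[1:30, lab == "case"] <- x[1:30, lab == "case"] + 4
  res <- pca_stratify(qm(x, variant = "log"), min_detect_frac = 0, labels = lab)
  pb <- cor(res$scores[, 1], as.numeric(lab == "case"))
  expect_gt(abs(pb), 0.9)
  expect_gt(mean(res$scores[lab == "case", 1]),
            mean(res$scores[lab == "control", 1]))
  expect_error(pca_stratify(qm(x[, 1:2, drop = FALSE])), "3 samples")
})

test_that("separation probability reproduces the published cohort arithmetic", {
  est <- separation_probability(18, 54, 13)
  expect_equal(est$q, 0.33)
  expect_equal(est$probability, 0.005)
  expect_equal(separation_probability(10, 30, 0)$probability, 1)
  expect_equal(separation_probability(54, 54, 1)$probability, 0)
  expect_error(separation_probability(55, 54, 1), "n_separated")
})

test_that("separation probability strictly decreases with more converters", {
  probs <- vapply(0:10, function(k) {
    separation_probability(18, 54, k)$probability_unrounded
  }, numeric(1))
  expect_true(all(diff(probs) < 0))
})

test_that("distance QC computes Euclidean means and replicate means", {
  x <- cbind(a = c(0, 0), b = c(3, 4))
  rownames(x) <- c("P1", "P2")
  qc <- distance_qc(qm(x, variant = "log"))
  expect_equal(qc$mean_all_pairs, 5)
  # identical replicate columns sit at distance zero
  x2 <- cbind(a = c(1, 2), a_r2 = c(1, 2), b = c(5, 9))
  rownames(x2) <- c("P1", "P2")
  rmap <- c(a = "a", a_r2 = "a", b = "b")
  qc2 <- distance_qc(qm(x2, variant = "log"), rmap)
  expect_equal(qc2$mean_replicate_pairs, 0)
  expect_s3_class(qc2$tree, "hclust")
  expect_error(distance_qc(qm(x2, variant = "log"), c(zz = "zz")), "unknown")
})

test_that("Jaccard indices follow the set definition", {
  J <- jaccard_identifications(list(r1 = c("a", "b", "c"),
                                    r2 = c("b", "c", "d"),
                                    r3 = c("x", "y"),
                                    r4 = character(0),
                                    r5 = character(0)))
  expect_equal(J["r1", "r2"], 0.5)
  expect_equal(J["r1", "r3"], 0)        # disjoint
  expect_equal(J["r4", "r5"], 1)        # both empty
  expect_equal(diag(J), rep(1, 5), ignore_attr = TRUE)
  expect_equal(J, t(J))
})

test_that("saturation curves accumulate unions and end at the total", {
  runs <- list(c("a", "b"), c("b", "c"), c("c", "d"))
  sat <- saturation_curve(runs, n_permutations = 20, seed = 3)
  expect_equal(sat$observed, c(2, 3, 4))
  expect_equal(sat$total, 4)
  flat <- saturation_curve(list(c("a", "b"), c("a", "b")), 5, seed = 1)
  expect_equal(flat$observed, c(2, 2))
  # every ordering is non-decreasing and terminates at the union
  set.seed(4)
  sets <- replicate(6, sample(letters, sample(3:10, 1)), simplify = FALSE)
  for (i in 1:10) {
    perm <- sample(6)
    cur <- saturation_curve(sets[perm], n_permutations = 1, seed = i)
    expect_true(all(diff(cur$observed) >= 0))
    expect_equal(cur$observed[6], length(unique(unlist(sets))))
  }
  expect_error(saturation_curve(runs, n_permutations = 0), "n_permutations")
})

test_that("the equal-proportions chi-square matches the printed cohort table", {
  male <- cohort_chisq(20, 38)
  expect_equal(round(male$p, 2), 0.02)
  expect_equal(round(cohort_chisq(12, 13)$p, 1), 0.8)
  expect_equal(round(cohort_chisq(9, 7)$p, 1), 0.6)
  expect_equal(round(cohort_chisq(7, 15)$p, 1), 0.1)
  sym <- cohort_chisq(10, 10)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p, 1)
  expect_error(cohort_chisq(0, 0), "positive")
})

test_that("cohort summary counts the published joint margins", {
  # clinical table built to the printed gender/smoking joint counts
  rows <- rbind(
    data.frame(gender = "M", smoking = "C", cancer_2014 = rep(c("No", "Yes", "S"), c(20, 38, 1))),
    data.frame(gender = "F", smoking = "N", cancer_2014 = rep(c("No", "Yes", "S"), c(11, 19, 1)))
  )
  clin <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(rows))), rows,
                     cancer_2016 = rows$cancer_2014, age_group = "60-79")
  cs <- cohort_summary(clin)
  male <- cs[cs$variable == "gender" & cs$level == "M", ]
  expect_equal(male$No, 20)
  expect_equal(male$Yes, 38)
  expect_equal(male$S, 1)
  expect_equal(round(male$p, 2), 0.02)
  expect_true(all(cs$adj_p >= cs$p, na.rm = TRUE))
  # single-level variables produce a single row
  expect_equal(sum(cs$variable == "age_group"), 1)
  # unknown smoking levels are counted but not tested
  clin$smoking[1] <- "U"
  cs2 <- cohort_summary(clin)
  expect_true(is.na(cs2$p[cs2$variable == "smoking" & cs2$level == "U"]))
})
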