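#' PCA stratification of samples
#'
#' Principal component analysis of samples on the abundant proteins:
#' rows detected in at least `min_detect_frac` of the samples are kept,
#' each protein is mean-centered (no unit-variance scaling by default, since
#' spectral counts share a scale), and the centered matrix is decomposed by
#' SVD. When case/control labels are supplied, each component's sign is
#' fixed so the case-group mean score is at least the control-group mean
#' (orientation convention); otherwise the sign is fixed by making the
#' largest-magnitude loading positive.
#'
#' @param m A preprocessed [quant_matrix()] (>= 3 samples).
#' @param min_detect_frac Abundance rule: minimum fraction of samples in
#'   which a protein must be detected (nonzero), default 0.5.
#' @param scale. Also scale proteins to unit variance (default `FALSE`).
#' @param labels Optional named control/case factor for orientation.
#' @return A `pca_result` list: `scores` (samples x components), `loadings`
#'   (proteins x components), `variance_fractions`, `abundant_protein_ids`.
#' @export
pca_stratify <- function(m, min_detect_frac = 0.5, scale. = FALSE,
                         labels = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  x <- m$values
  if (ncol(x) < 3) stop("PCA stratification needs at least 3 samples")
  abundant <- rowMeans(x > 0) >= min_detect_frac
  if (!any(abundant)) stop("no proteins pass the abundance rule")
  xa <- x[abundant, , drop = FALSE]
  X <- t(xa)
  X <- scale(X, center = TRUE, scale = scale.)
  if (scale.) X[, attr(X, "scaled:scale") == 0] <- 0
  sv <- svd(X)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  if (!is.null(labels)) {
    lab <- labels[names(labels) %in% rownames(X)]
    idx <- match(names(lab), rownames(X))
    for (j in seq_len(ncol(scores))) {
      mu_case <- mean(scores[idx[lab == "case"], j])
      mu_ctrl <- mean(scores[idx[lab == "control"], j])
      if (is.finite(mu_case) && is.finite(mu_ctrl) && mu_case < mu_ctrl) {
        scores[, j] <- -scores[, j]
        loadings[, j] <- -loadings[, j]
      }
    }
  } else {
    for (j in seq_len(ncol(scores))) {
      k <- which.max(abs(loadings[, j]))
      if (loadings[k, j] < 0) {
        scores[, j] <- -scores[, j]
        loadings[, j] <- -loadings[, j]
      }
    }
  }
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncol(scores)))
  structure(
    list(scores = scores, loadings = loadings,
         variance_fractions = sv$d^2 / sum(sv$d^2),
         abundant_protein_ids = rownames(xa)),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d abundant proteins; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), length(x$abundant_protein_ids),
              100 * x$variance_fractions[1],
              100 * x$variance_fractions[min(2, length(x$variance_fractions))]))
  invisible(x)
}

#' Separation probability of converter patients
#'
#' The chance statistic for converter placement: if `n_separated` of the
#' `n_total` non-cancer (and suspicious) samples separate from the cancer
#' cluster, the probability of picking a separated one is
#' `q = round(n_separated / n_total, 2)`, and the probability that none of
#' the `k` converter patients lands on the separated side by chance is
#' `(1 - q)^k` (reported rounded to 3 decimals; the unrounded value is also
#' kept). The rounded `q` is canonical, reproducing the published
#' arithmetic.
#'
#' @param n_separated Non-cancer samples in the control-side cluster.
#' @param n_total All non-cancer plus suspicious samples.
#' @param k Number of converter patients.
#' @return A `separation_estimate` list: `n_separated`, `n_total`, `k`, `q`,
#'   `probability`, plus `q_exact` and `probability_unrounded`.
#' @export
separation_probability <- function(n_separated, n_total, k) {
  if (n_total <= 0) stop("`n_total` must be positive")
  if (k < 0) stop("`k` must be nonnegative")
  if (n_separated < 0 || n_separated > n_total) {
    stop("`n_separated` must lie in [0, n_total]")
  }
  q_exact <- n_separated / n_total
  q <- round(q_exact, 2)
  structure(
    list(n_separated = n_separated, n_total = n_total, k = k,
         q = q, probability = round((1 - q)^k, 3),
         q_exact = q_exact, probability_unrounded = (1 - q_exact)^k),
    class = "separation_estimate"
  )
}

#' @export
print.separation_estimate <- function(x, ...) {
  cat(sprintf("separation: q = %d/%d = %.2f; P(none of %d separated) = (1 - %.2f)^%d = %.3f\n",
              x$n_separated, x$n_total, x$q, x$k, x$q, x$k, x$probability))
  invisible(x)
}

#' Replicate distance quality control
#'
#' Pairwise Euclidean distances between sample columns of a preprocessed
#' matrix, summarized as the mean over all distinct pairs and the mean over
#' technical replicate pairs, together with a complete-linkage hierarchical
#' clustering of the samples. Columns are ordered by sample id before
#' clustering so ties break deterministically.
#'
#' @param m A [quant_matrix()] with >= 2 samples.
#' @param replicate_map Named character vector mapping every run id to its
#'   replicate group (runs sharing a group are replicates).
#' @return List with `mean_all_pairs`, `mean_replicate_pairs` (NA when there
#'   are no replicate pairs), `tree` (an `hclust`), and `dist`.
#' @export
distance_qc <- function(m, replicate_map = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  x <- m$values[, order(colnames(m$values)), drop = FALSE]
  if (ncol(x) < 2) stop("distance QC needs at least 2 samples")
  d <- stats::dist(t(x))
  dm <- as.matrix(d)
  mean_all <- mean(d)
  mean_rep <- NA_real_
  if (!is.null(replicate_map)) {
    unknown <- setdiff(names(replicate_map), colnames(x))
    if (length(unknown)) {
      stop("replicate map references unknown samples: ",
           paste(unknown, collapse = ", "))
    }
    groups <- split(names(replicate_map), unname(replicate_map))
    pairs <- list()
    for (g in groups) {
      if (length(g) >= 2) {
        cmb <- utils::combn(g, 2)
        pairs[[length(pairs) + 1]] <- dm[cbind(cmb[1, ], cmb[2, ])]
      }
    }
    if (length(pairs)) mean_rep <- mean(unlist(pairs))
  }
  list(mean_all_pairs = mean_all, mean_replicate_pairs = mean_rep,
       tree = stats::hclust(d, method = "complete"), dist = d)
}

#' Jaccard similarity of identification sets
#'
#' `J(A, B) = |A intersect B| / |A union B|` for every pair of runs; a pair
#' of empty sets is defined to have similarity 1.
#'
#' @param runs Named (or unnamed) list of character id-sets.
#' @return Symmetric matrix of Jaccard indices with unit diagonal.
#' @export
jaccard_identifications <- function(runs) {
  n <- length(runs)
  runs <- lapply(runs, unique)
  out <- matrix(1, n, n)
  if (!is.null(names(runs))) dimnames(out) <- list(names(runs), names(runs))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- length(union(runs[[i]], runs[[j]]))
      out[i, j] <- out[j, i] <-
        if (u == 0) 1 else length(intersect(runs[[i]], runs[[j]])) / u
    }
  }
  out
}

#' Identification saturation curve
#'
#' Cumulative number of distinct identifications as runs are added. The
#' curve of the supplied order is returned together with the mean and range
#' over random orderings; the terminal value equals the total union size
#' regardless of order.
#'
#' @param runs Ordered list of character id-sets.
#' @param n_permutations Number of random orderings (>= 1).
#' @param seed Seed for the permutations.
#' @return List with `observed` (curve in the given order), `mean`, `lower`,
#'   `upper` (pointwise over permutations), `total` (union size).
#' @export
saturation_curve <- function(runs, n_permutations = 100, seed = 1L) {
  if (length(runs) < 1) stop("need at least one run")
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  cum_curve <- function(ord) {
    seen <- character(0)
    vapply(ord, function(i) {
      seen <<- union(seen, runs[[i]])
      length(seen)
    }, integer(1))
  }
  observed <- cum_curve(seq_along(runs))
  perms <- withr_seed(seed, {
    replicate(n_permutations, cum_curve(sample.int(length(runs))))
  })
  perms <- matrix(perms, nrow = length(runs))
  list(observed = unname(observed),
       mean = rowMeans(perms),
       lower = apply(perms, 1, min),
       upper = apply(perms, 1, max),
       total = length(unique(unlist(runs))))
}

# Evaluate `code` under a local RNG seed without disturbing the caller's RNG.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Equal-proportions chi-square test of case/control counts
#'
#' One-degree-of-freedom goodness-of-fit of the (non-cancer, cancer) counts
#' of a patient category against equal expected proportions:
#' `X^2 = sum((observed - total/2)^2 / (total/2))`.
#'
#' @param n_no,n_yes Non-cancer and cancer counts.
#' @return List with `statistic` and `p`.
#' @export
cohort_chisq <- function(n_no, n_yes) {
  if (n_no < 0 || n_yes < 0) stop("counts must be nonnegative")
  total <- n_no + n_yes
  if (total == 0) stop("total count must be positive")
  stat <- sum((c(n_no, n_yes) - total / 2)^2 / (total / 2))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Baseline-characteristics summary of a clinical table
#'
#' Per category level (age group, gender, smoking level), counts of
#' suspicious/non-cancer/cancer patients with the equal-proportions
#' chi-square p-value ([cohort_chisq()]) and Benjamini-Hochberg adjustment
#' across all tested levels. Levels coded `"U"` or `"Unknown"` are counted
#' but not tested; missing values are grouped as `"Unknown"`.
#'
#' @param clinical Clinical table.
#' @param time Diagnosis time point used for the counts, default `"2014"`.
#' @param variables Clinical variables to summarize.
#' @return data.frame: `variable`, `level`, `n`, `S`, `No`, `Yes`,
#'   `statistic`, `p`, `adj_p`.
#' @export
cohort_summary <- function(clinical, time = "2014",
                           variables = c("age_group", "gender", "smoking")) {
  if (!nrow(clinical)) stop("clinical table is empty")
  col <- paste0("cancer_", time)
  status <- as.character(clinical[[col]])
  rows <- list()
  for (v in variables) {
    if (!v %in% names(clinical)) next
    val <- as.character(clinical[[v]])
    val[is.na(val) | val == ""] <- "Unknown"
    for (lev in unique(val)) {
      sel <- val == lev
      n_s <- sum(sel & status == "S")
      n_no <- sum(sel & status == "No")
      n_yes <- sum(sel & status == "Yes")
      testable <- !(lev %in% c("U", "Unknown")) && (n_no + n_yes) > 0
      ct <- if (testable) cohort_chisq(n_no, n_yes) else
        list(statistic = NA_real_, p = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lev, n = sum(sel),
        S = n_s, No = n_no, Yes = n_yes,
        statistic = ct$statistic, p = ct$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  tested <- !is.na(out$p)
  out$adj_p[tested] <- bh_adjust(out$p[tested])
  out
}
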