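#' Per-protein two-group contrast statistics
#'
#' Fits the lung-cancer vs non-lung-cancer contrast protein by protein:
#' the log2 fold change is the difference of group means (case minus
#' control), the residual variance is the pooled within-group variance, and
#' the residual degrees of freedom are `n_case + n_control - 2`.
#'
#' @param m A (log-scale) [quant_matrix()].
#' @param labels Named factor with levels `control`/`case` (see
#'   [cancer_labels()]); only matrix columns named in `labels` are used.
#' @return data.frame with columns `protein`, `log2_fold`, `s2`, `df`,
#'   `n_case`, `n_control`.
#' @export
fit_group_contrast <- function(m, labels) {
  stopifnot(inherits(m, "quant_matrix"))
  labels <- labels[names(labels) %in% colnames(m$values)]
  if (!all(levels(labels) %in% c("control", "case"))) {
    stop("`labels` must be a factor with levels control/case")
  }
  x <- m$values[, names(labels), drop = FALSE]
  case <- x[, labels == "case", drop = FALSE]
  ctrl <- x[, labels == "control", drop = FALSE]
  n1 <- ncol(case)
  n0 <- ncol(ctrl)
  if (n1 < 2 || n0 < 2) {
    stop("each group needs at least 2 samples (case: ", n1,
         ", control: ", n0, ")")
  }
  mu1 <- rowMeans(case)
  mu0 <- rowMeans(ctrl)
  ss1 <- rowSums((case - mu1)^2)
  ss0 <- rowSums((ctrl - mu0)^2)
  df <- n1 + n0 - 2
  data.frame(
    protein = rownames(x),
    log2_fold = mu1 - mu0,
    s2 = (ss1 + ss0) / df,
    df = rep(df, nrow(x)),
    n_case = n1, n_control = n0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Newton solve of trigamma(x) = y, y > 0 (vectorized).
trigamma_inverse <- function(y) {
  out <- y
  lo <- y > 1e7
  out[lo] <- 1 / sqrt(y[lo])
  hi <- y < 1e-6
  out[hi] <- 1 / y[hi]
  mid <- !lo & !hi
  x <- 0.5 + 1 / y[mid]
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(-dif / x) < 1e-8) break
  }
  out[mid] <- x
  out
}

#' Estimate the variance-moderation prior
#'
#' Empirical-Bayes estimation of the prior degrees of freedom `d0` and prior
#' variance `s0_sq` by method of moments on the log residual variances under
#' a scaled-F sampling model: each observed `s2_g` is `s0_sq * F(d_g, d0)`.
#' The log variances are bias-corrected by the digamma moments of the
#' chi-square law; when the empirical spread of the corrected logs does not
#' exceed the spread implied by the residual degrees of freedom alone,
#' `d0 = Inf` is returned (no excess variability, complete shrinkage).
#'
#' @param s2 Vector of residual variances (zeros are excluded from the fit).
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List with elements `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(ok) < 2) {
    stop("need at least 2 positive residual variances to estimate the prior")
  }
  z <- log(s2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = unname(d0), s0_sq = unname(s0_sq))
}

#' Moderated t-test with Benjamini-Hochberg control
#'
#' Shrinks each protein's residual variance toward the prior,
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)`, forms the moderated
#' t-statistic `log2_fold / sqrt(s2_post * (1/n_case + 1/n_control))`, takes
#' two-sided p-values from the t distribution with `d0 + df` degrees of
#' freedom, and adjusts them by the Benjamini-Hochberg step-up over all
#' tested proteins. `d0 = 0` recovers the ordinary pooled two-sample t;
#' `d0 = Inf` uses the prior variance for every protein.
#'
#' @param contrast data.frame from [fit_group_contrast()].
#' @param prior List with `d0`, `s0_sq` (see [estimate_prior()]).
#' @param engine,quant_type,variant Optional provenance tags copied into the
#'   result.
#' @return A `de_result` data.frame: `protein`, `log2_fold`, `s2`, `df`,
#'   `s2_post`, `t`, `df_total`, `p`, `adj_p`, `zero_variance` flag, plus
#'   provenance columns.
#' @export
moderated_test <- function(contrast, prior, engine = NA_character_,
                           quant_type = NA_character_,
                           variant = NA_character_) {
  if (!all(c("log2_fold", "s2", "df") %in% names(contrast))) {
    stop("`contrast` must come from fit_group_contrast()")
  }
  d0 <- prior$d0
  s0 <- prior$s0_sq
  if (is.null(d0) || is.na(d0) || d0 < 0) {
    stop("invalid prior degrees of freedom")
  }
  if (d0 > 0 && (is.null(s0) || is.na(s0) || s0 <= 0)) {
    stop("invalid prior variance")
  }
  if (d0 == 0) s0 <- 0
  s2_post <- if (is.infinite(d0)) {
    rep(s0, nrow(contrast))
  } else {
    (d0 * s0 + contrast$df * contrast$s2) / (d0 + contrast$df)
  }
  se <- sqrt(s2_post * (1 / contrast$n_case + 1 / contrast$n_control))
  tstat <- contrast$log2_fold / se
  zero_var <- se == 0
  tstat[zero_var & contrast$log2_fold == 0] <- 0
  df_total <- d0 + contrast$df
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[zero_var & contrast$log2_fold != 0] <- 0  # limit of the t law
  p[zero_var & contrast$log2_fold == 0] <- 1
  res <- data.frame(
    protein = contrast$protein,
    log2_fold = contrast$log2_fold,
    s2 = contrast$s2,
    df = contrast$df,
    s2_post = s2_post,
    t = tstat,
    df_total = rep_len(df_total, nrow(contrast)),
    p = p,
    adj_p = bh_adjust(p),
    zero_variance = zero_var,
    engine = engine, quant_type = quant_type, variant = variant,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around the standard step-up procedure: adjusted values
#' are monotone-enforced, clipped at 1, and ties are preserved.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise >= `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

#' Moderated differential expression of a quantitative matrix
#'
#' Convenience wrapper running the full moderated analysis on one matrix:
#' proteins undetected in every used sample are dropped, the two-group
#' contrast is fitted, the moderation prior estimated, and the moderated
#' test applied.
#'
#' @param m A log-scale [quant_matrix()].
#' @param clinical Clinical table (see [cancer_labels()]), or `NULL` if
#'   `labels` is given.
#' @param labels Optional named control/case factor overriding `clinical`.
#' @param time Diagnosis time point for the labels (default `"2014"`).
#' @return A `de_result` data.frame (see [moderated_test()]) with the prior
#'   in attribute `"prior"`.
#' @export
run_diffexpr <- function(m, clinical = NULL, labels = NULL, time = "2014") {
  if (is.null(labels)) {
    if (is.null(clinical)) stop("provide `clinical` or `labels`")
    labels <- cancer_labels(clinical, time = time)
  }
  labels <- labels[names(labels) %in% colnames(m$values)]
  x <- m$values[, names(labels), drop = FALSE]
  detected <- rowSums(x > 0) > 0
  m_used <- qm_replace(m, x[detected, , drop = FALSE])
  contrast <- fit_group_contrast(m_used, labels)
  prior <- estimate_prior(contrast$s2, contrast$df)
  res <- moderated_test(contrast, prior, engine = m$engine,
                        quant_type = m$quant_type, variant = m$variant)
  attr(res, "prior") <- prior
  res
}
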