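#' Remove common MS contaminants
#'
#' Drops rows whose id appears in the contaminant list; the relative order of
#' the remaining rows is preserved and unknown ids are ignored.
#'
#' @param m A [quant_matrix()].
#' @param contaminants Character vector of row ids to remove.
#' @return The filtered [quant_matrix()].
#' @export
remove_contaminants <- function(m, contaminants) {
  stopifnot(inherits(m, "quant_matrix"))
  keep <- !(rownames(m$values) %in% contaminants)
  qm_replace(m, m$values[keep, , drop = FALSE])
}

#' log2(x + 1) transformation
#'
#' Entry-wise `log2(x + 1)`; zeros (undetected values) map to zero, so the
#' transform needs no missing-value marker.
#'
#' @param m A [quant_matrix()] of nonnegative values.
#' @return The transformed [quant_matrix()] with variant `"log"`.
#' @export
log2_plus_one <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  if (any(m$values < 0)) stop("log2(x + 1) requires nonnegative values")
  qm_replace(m, log2(m$values + 1), variant = "log")
}

#' Quantile normalization
#'
#' Forces every sample column to share the same empirical distribution: the
#' entry-wise mean of the per-column sorted value vectors, re-assigned within
#' each column by rank. Tied values within a column receive the mean of the
#' reference values at their tied ranks. The operation is idempotent.
#'
#' @param m A [quant_matrix()] (at least one row and one column).
#' @return The normalized [quant_matrix()].
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  x <- m$values
  if (nrow(x) < 1 || ncol(x) < 1) stop("matrix must be non-empty")
  variant <- if (identical(m$variant, "log")) "log+qn" else m$variant
  if (ncol(x) == 1) return(qm_replace(m, x, variant = variant))
  ref <- rowMeans(apply(x, 2, sort))
  cs <- cumsum(ref)
  out <- apply(x, 2, function(col) {
    rmin <- rank(col, ties.method = "min")
    rmax <- rank(col, ties.method = "max")
    # mean of the reference values over each tie group's rank range
    (cs[rmax] - c(0, cs)[rmin]) / (rmax - rmin + 1)
  })
  dimnames(out) <- dimnames(x)
  qm_replace(m, out, variant = variant)
}

# Anderson-Darling departure-from-normality score of the pooled nonzero
# values, normalized by the pool size: the raw A^2 statistic grows linearly
# with n at a fixed distributional discrepancy, which would mechanically
# favor the smallest pool when comparing candidate filters; A^2/n estimates
# the size-invariant weighted L2 discrepancy instead. +Inf when too few
# values remain to score.
ad_normality_score <- function(values) {
  v <- values[values > 0]
  if (length(v) < 8 || stats::sd(v) == 0) return(Inf)
  unname(nortest::ad.test(v)$statistic) / length(v)
}

#' Abundance filtering optimizing overall Gaussianity
#'
#' Removes low-abundance rows so that the pooled distribution of the
#' remaining nonzero quantitative values is as close to Gaussian as possible.
#' Candidate thresholds are the 0%, 5%, ..., 50% quantiles of the row mean
#' abundances; for each candidate, rows with mean abundance below it are
#' dropped and the Anderson-Darling statistic of the pooled nonzero values of
#' the retained rows is computed. The threshold minimizing the statistic is
#' chosen (ties break toward the smallest threshold, i.e. least filtering).
#'
#' @param m A log-scale [quant_matrix()].
#' @param grid_probs Candidate quantile probabilities of the row-mean
#'   abundance distribution.
#' @return A list with `matrix` (the filtered [quant_matrix()], variant
#'   `"log+qn+filter"`), `threshold` (the chosen row-mean cutoff), and
#'   `trace` (data.frame of candidate `prob`, `threshold`, `score`,
#'   `n_rows_kept` for audit).
#' @export
gaussian_abundance_filter <- function(m, grid_probs = seq(0, 0.5, by = 0.05)) {
  stopifnot(inherits(m, "quant_matrix"))
  x <- m$values
  if (nrow(x) == 0 || ncol(x) == 0) stop("cannot filter an empty matrix")
  rm_ab <- rowMeans(x)
  thresholds <- unname(stats::quantile(rm_ab, probs = grid_probs, type = 7))
  scores <- numeric(length(thresholds))
  kept <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    keep <- rm_ab >= thresholds[i]
    kept[i] <- sum(keep)
    scores[i] <- if (any(keep)) {
      ad_normality_score(x[keep, , drop = FALSE])
    } else Inf
  }
  trace <- data.frame(prob = grid_probs, threshold = thresholds,
                      score = scores, n_rows_kept = kept)
  if (all(!is.finite(scores))) {
    stop("degenerate input: no candidate threshold leaves a scorable matrix")
  }
  best <- which.min(scores)   # first minimum: least filtering on ties
  chosen <- thresholds[best]
  variant <- if (m$variant %in% c("log", "log+qn")) "log+qn+filter" else m$variant
  out <- qm_replace(m, x[rm_ab >= chosen, , drop = FALSE], variant = variant)
  list(matrix = out, threshold = chosen, trace = trace)
}

#' Build the full preprocessed matrix family
#'
#' Applies the three preprocessing approaches to each raw per-engine matrix,
#' in the fixed order contaminant removal, log2(x + 1), quantile
#' normalization, Gaussian abundance filtering: variant `"log"` is
#' contaminant removal + log transform; `"log+qn"` adds quantile
#' normalization; `"log+qn+filter"` adds the abundance filter. Two engines
#' and five quantitation types therefore yield 30 matrices — six per
#' quantitation type.
#'
#' @param raw Named list of raw [quant_matrix()] objects (one per
#'   engine/quantitation-type slot, names `"<engine>.<quant_type>"`).
#' @param contaminants Character vector of contaminant row ids.
#' @return A `matrix_family`: named list of [quant_matrix()] with names
#'   `"<engine>.<quant_type>.<variant>"`, with the per-slot filter traces in
#'   attribute `"filter_trace"`.
#' @export
build_matrix_family <- function(raw, contaminants = character(0)) {
  if (!length(raw) || is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("`raw` must be a named list of quant_matrix objects")
  }
  fam <- list()
  traces <- list()
  for (nm in names(raw)) {
    m <- raw[[nm]]
    if (!inherits(m, "quant_matrix")) {
      stop("missing or invalid raw matrix in slot `", nm, "`")
    }
    logm <- log2_plus_one(remove_contaminants(m, contaminants))
    qnm <- quantile_normalize(logm)
    filt <- gaussian_abundance_filter(qnm)
    fam[[paste0(nm, ".log")]] <- logm
    fam[[paste0(nm, ".log+qn")]] <- qnm
    fam[[paste0(nm, ".log+qn+filter")]] <- filt$matrix
    traces[[nm]] <- filt$trace
  }
  structure(fam, filter_trace = traces, class = c("matrix_family", "list"))
}

#' @export
print.matrix_family <- function(x, ...) {
  cat(sprintf("matrix_family: %d preprocessed matrices\n", length(x)))
  for (nm in names(x)) cat("  ", nm, "\n", sep = "")
  invisible(x)
}
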