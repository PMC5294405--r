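#' Consensus filter configuration
#'
#' @param alpha Adjusted-p threshold (strict `<`), default 0.05.
#' @param fold_threshold Linear fold-change threshold; membership requires
#'   `|log2_fold| > log2(fold_threshold)` ("more than `fold_threshold`-fold
#'   regulated") in at least one engine. Default 2.
#' @return A `consensus_config` list.
#' @export
consensus_config <- function(alpha = 0.05, fold_threshold = 2) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)")
  if (!(fold_threshold > 1)) stop("`fold_threshold` must be > 1")
  structure(list(alpha = alpha, fold_threshold = fold_threshold),
            class = "consensus_config")
}

#' Cross-engine consensus list of regulated proteins
#'
#' Combines per-engine differential expression results by three rules: a
#' protein is a consensus member iff (1) its Benjamini-Hochberg adjusted p is
#' below `alpha` in both engines, (2) it is more than `fold_threshold`-fold
#' regulated (|log2 fold| strictly above `log2(fold_threshold)`) in at least
#' one engine, and (3) the direction of regulation agrees (same nonzero sign
#' of the log2 fold) in both engines. Proteins reported by only one engine
#' are dropped (their count is recorded in attribute `"n_unmatched"`).
#'
#' @param de_a,de_b `de_result` data.frames for engines A and B.
#' @param cfg A [consensus_config()].
#' @return A `consensus_list` data.frame: `protein`, `direction`,
#'   `log2_fold_A`, `log2_fold_B`, `adj_p_A`, `adj_p_B`, and the rule flags
#'   `rule_significant`, `rule_fold`, `rule_direction`, `member`; rows are
#'   the shared proteins, members flagged. Summary counts in attribute
#'   `"summary"`.
#' @export
consensus_filter <- function(de_a, de_b, cfg = consensus_config()) {
  shared <- intersect(de_a$protein, de_b$protein)
  if (!length(shared)) stop("engines share no protein ids")
  n_unmatched <- (nrow(de_a) - length(shared)) + (nrow(de_b) - length(shared))
  a <- de_a[match(shared, de_a$protein), ]
  b <- de_b[match(shared, de_b$protein), ]
  lfc_thr <- log2(cfg$fold_threshold)
  rule1 <- a$adj_p < cfg$alpha & b$adj_p < cfg$alpha
  rule2 <- abs(a$log2_fold) > lfc_thr | abs(b$log2_fold) > lfc_thr
  rule3 <- sign(a$log2_fold) == sign(b$log2_fold) & sign(a$log2_fold) != 0
  member <- rule1 & rule2 & rule3
  out <- data.frame(
    protein = shared,
    direction = ifelse(a$log2_fold > 0, "up", "down"),
    log2_fold_A = a$log2_fold, log2_fold_B = b$log2_fold,
    adj_p_A = a$adj_p, adj_p_B = b$adj_p,
    rule_significant = rule1, rule_fold = rule2, rule_direction = rule3,
    member = member,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$direction[member == FALSE & sign(a$log2_fold) == 0] <- NA
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "summary") <- list(
    n_shared = length(shared), n_unmatched = n_unmatched,
    n_rule_significant = sum(rule1), n_rule_fold = sum(rule2),
    n_rule_direction = sum(rule3), n_members = sum(member),
    n_up = sum(member & out$direction == "up"),
    n_down = sum(member & out$direction == "down"),
    alpha = cfg$alpha, fold_threshold = cfg$fold_threshold
  )
  class(out) <- c("consensus_list", "data.frame")
  out
}

#' Members of a consensus list
#'
#' @param x A `consensus_list` from [consensus_filter()].
#' @return The member rows only.
#' @export
consensus_members <- function(x) {
  stopifnot(inherits(x, "consensus_list"))
  x[x$member, , drop = FALSE]
}

#' Proteins identified exclusively in cancer samples
#'
#' Returns proteins detected (nonzero) in at least one cancer sample and in
#' no control or suspicious sample, candidate markers of cancer sub-types.
#'
#' @param m A [quant_matrix()] (raw or log scale; zero = undetected).
#' @param clinical Clinical table; the 2014 (collection-time) annotation
#'   defines the cancer samples, as for the published exclusive list.
#' @param time Diagnosis time point, default `"2014"`.
#' @return Character vector of protein ids.
#' @export
cancer_exclusive_proteins <- function(m, clinical, time = "2014") {
  stopifnot(inherits(m, "quant_matrix"))
  col <- paste0("cancer_", time)
  status <- stats::setNames(as.character(clinical[[col]]), clinical$sample_id)
  ids <- colnames(m$values)
  known <- ids[ids %in% names(status)]
  if (!length(known)) stop("clinical table covers none of the matrix columns")
  x <- m$values[, known, drop = FALSE]
  is_case <- status[known] == "Yes"
  in_case <- rowSums(x[, is_case, drop = FALSE] > 0) > 0
  in_other <- rowSums(x[, !is_case, drop = FALSE] > 0) > 0
  rownames(x)[in_case & !in_other]
}
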