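#' Collapse protein-level regulation to genes
#'
#' MS data rarely resolve protein isoforms consistently across search
#' engines and studies, so regulation calls are compared at the gene level.
#' A gene inherits the common direction of its significant isoforms;
#' genes whose isoforms disagree in direction are excluded (conservative)
#' and recorded, as are proteins missing from the gene map.
#'
#' @param results data.frame with columns `protein` and `direction`
#'   (`"up"`/`"down"`), e.g. the members of a [consensus_filter()] list.
#' @param gene_map Named vector, protein id -> gene id.
#' @return data.frame `gene`, `direction`, `n_isoforms`, with excluded
#'   conflicting genes in attribute `"conflicts"` and unmapped proteins in
#'   attribute `"unmapped"`.
#' @export
collapse_to_genes <- function(results, gene_map) {
  stopifnot(all(c("protein", "direction") %in% names(results)))
  genes <- unname(gene_map[results$protein])
  unmapped <- results$protein[is.na(genes)]
  if (length(unmapped)) {
    message("collapse_to_genes: ", length(unmapped),
            " protein(s) missing from the gene map were dropped")
  }
  ok <- !is.na(genes)
  df <- data.frame(gene = genes[ok], direction = results$direction[ok],
                   stringsAsFactors = FALSE)
  if (!nrow(df)) {
    out <- data.frame(gene = character(), direction = character(),
                      n_isoforms = integer(), stringsAsFactors = FALSE)
    attr(out, "conflicts") <- character(0)
    attr(out, "unmapped") <- unmapped
    return(out)
  }
  dirs <- tapply(df$direction, df$gene, function(d) unique(d))
  n_iso <- tapply(df$direction, df$gene, length)
  conflicted <- names(dirs)[vapply(dirs, length, integer(1)) > 1]
  keep <- setdiff(names(dirs), conflicted)
  out <- data.frame(
    gene = keep,
    direction = vapply(dirs[keep], `[`, character(1), 1),
    n_isoforms = as.integer(n_iso[keep]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicted
  attr(out, "unmapped") <- unmapped
  out
}

# Normalize study tables to a long data.frame(gene, study_id, direction).
as_study_table <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  long <- do.call(rbind, lapply(tables, function(t) {
    stopifnot(all(c("gene", "study_id", "direction") %in% names(t)))
    t[, c("gene", "study_id", "direction")]
  }))
  long$direction <- as.character(long$direction)
  bad <- !long$direction %in% c("up", "down", "NS")
  long$direction[bad] <- "NS"
  long
}

#' Multi-study consensus biomarker selection
#'
#' A gene enters the consensus set iff at least `min_support` studies report
#' it regulated in the identical direction; non-significant and not-detected
#' are merged into one code. Genes reaching `min_support` in both directions
#' are excluded as ambiguous. The coded gene x study regulation matrix
#' (-1 down, 0 NS/absent, +1 up) is returned for heatmapping, with the
#' studies clustered by Hamming distance on their regulation vectors
#' (complete linkage).
#'
#' @param tables Long data.frame (or list of data.frames) with columns
#'   `gene`, `study_id`, `direction` in `up`/`down`/`NS`.
#' @param min_support Minimum number of direction-concordant studies
#'   (default 3).
#' @return List with `members` (data.frame `gene`, `direction`, `support`,
#'   `studies`), `codes` (gene x study integer matrix), and `study_tree`
#'   (an `hclust`, `NULL` for fewer than 3 studies).
#' @export
multi_study_consensus <- function(tables, min_support = 3) {
  if (min_support < 1) stop("`min_support` must be >= 1")
  long <- as_study_table(tables)
  studies <- sort(unique(long$study_id))
  if (length(studies) < min_support) {
    stop("need at least `min_support` = ", min_support, " studies, got ",
         length(studies))
  }
  genes <- sort(unique(long$gene))
  codes <- matrix(0L, length(genes), length(studies),
                  dimnames = list(genes, studies))
  code_of <- c(up = 1L, down = -1L, NS = 0L)
  codes[cbind(match(long$gene, genes), match(long$study_id, studies))] <-
    code_of[long$direction]
  n_up <- rowSums(codes == 1L)
  n_down <- rowSums(codes == -1L)
  # dominant direction must reach min_support; an exact tie is ambiguous
  member <- pmax(n_up, n_down) >= min_support & n_up != n_down
  is_up <- n_up > n_down
  direction <- ifelse(is_up, "up", "down")[member]
  support <- pmax(n_up, n_down)[member]
  supporting <- vapply(which(member), function(i) {
    want <- if (is_up[i]) 1L else -1L
    paste(studies[codes[i, ] == want], collapse = ",")
  }, character(1))
  members <- data.frame(
    gene = genes[member], direction = direction,
    support = as.integer(support), studies = supporting,
    row.names = NULL, stringsAsFactors = FALSE
  )
  study_tree <- NULL
  if (length(studies) >= 3) {
    hd <- matrix(0, length(studies), length(studies),
                 dimnames = list(studies, studies))
    for (i in seq_along(studies)) {
      for (j in seq_along(studies)) {
        hd[i, j] <- sum(codes[, i] != codes[, j])
      }
    }
    study_tree <- stats::hclust(stats::as.dist(hd), method = "complete")
  }
  structure(list(members = members, codes = codes, study_tree = study_tree,
                 min_support = min_support),
            class = "consensus_biomarkers")
}

#' @export
print.consensus_biomarkers <- function(x, ...) {
  cat(sprintf("consensus_biomarkers: %d genes supported by >= %d studies (of %d)\n",
              nrow(x$members), x$min_support, ncol(x$codes)))
  invisible(x)
}

#' Flag COPD-overlapping consensus biomarkers
#'
#' Marks each consensus gene whose direction of regulation is also reported,
#' in the same direction, by any COPD-vs-control comparison — candidate
#' confounding with chronic obstructive pulmonary disease.
#'
#' @param consensus A `consensus_biomarkers` object.
#' @param copd_tables Long data.frame(s) with `gene`, `study_id`,
#'   `direction` from COPD comparisons (may be empty).
#' @return The `consensus` object with a logical `copd_flag` column added to
#'   `members`.
#' @export
flag_copd_overlap <- function(consensus, copd_tables) {
  stopifnot(inherits(consensus, "consensus_biomarkers"))
  members <- consensus$members
  members$copd_flag <- FALSE
  long <- if (is.null(copd_tables) ||
              (is.data.frame(copd_tables) && !nrow(copd_tables))) {
    NULL
  } else {
    as_study_table(copd_tables)
  }
  if (!is.null(long) && nrow(long) && nrow(members)) {
    key <- paste(long$gene, long$direction)
    members$copd_flag <- paste(members$gene, members$direction) %in% key
  }
  consensus$members <- members
  consensus
}
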