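#' Gene-set annotation collection
#'
#' A set of functional categories (e.g. GO cellular component terms or KEGG
#' pathways) over a background universe of gene ids. The background defaults
#' to all genes identified across the dataset rather than the genome, which
#' is the appropriate universe when comparing enrichment across samples.
#' Category members absent from the background are trimmed and recorded as
#' orphans.
#'
#' @param categories Named list of character gene-id sets.
#' @param background Character vector of background gene ids (nonempty).
#' @param namespace Annotation namespace, e.g. `"CC"`, `"BP"`, `"MF"`,
#'   `"KEGG"`.
#' @return An `annotation_set` list with `categories`, `background`,
#'   `namespace` and attribute `"orphans"`.
#' @export
annotation_set <- function(categories, background, namespace = "CC") {
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be nonempty")
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("categories must be named")
  }
  orphans <- character(0)
  categories <- lapply(categories, function(g) {
    g <- unique(as.character(g))
    orphans <<- union(orphans, setdiff(g, background))
    intersect(g, background)
  })
  structure(list(categories = categories, background = background,
                 namespace = namespace),
            class = "annotation_set", orphans = orphans)
}

#' Hypergeometric enrichment of a gene set
#'
#' For each category, the upper-tail hypergeometric probability of observing
#' at least the realized overlap between the query set and the category,
#' drawing `n` genes from a background of `N` containing `K` category
#' members: `p = P(X >= k)`. P-values are Benjamini-Hochberg adjusted across
#' the categories of the annotation set. Query genes outside the background
#' are dropped (count recorded in attribute `"n_dropped"`).
#'
#' @param query Character vector of gene ids.
#' @param ann An [annotation_set()].
#' @return data.frame: `category`, `N`, `K`, `n`, `k`, `p`, `adj_p`.
#' @export
hypergeom_enrich <- function(query, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  query <- unique(as.character(query))
  q0 <- intersect(query, ann$background)
  n_dropped <- length(query) - length(q0)
  N <- length(ann$background)
  n <- length(q0)
  K <- vapply(ann$categories, length, integer(1))
  k <- vapply(ann$categories, function(g) length(intersect(q0, g)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    category = names(ann$categories), N = N, K = unname(K), n = n,
    k = unname(k), p = unname(p), adj_p = bh_adjust(unname(p)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Per-sample functional enrichment
#'
#' Runs [hypergeom_enrich()] on each sample's identification set and retains
#' the categories significantly enriched (adjusted p < `alpha`) in at least
#' one sample. For the retained categories, the per-sample protein counts
#' are emitted both raw and log2(count + 1)-transformed for heatmapping.
#'
#' @param sample_sets Named list of per-sample gene-id sets.
#' @param ann An [annotation_set()].
#' @param alpha Adjusted-p threshold, default 0.05.
#' @return List with `retained` (category ids), `results` (long data.frame
#'   of all per-sample tests), `counts` and `log2_counts` (retained
#'   categories x samples).
#' @export
per_sample_enrichment <- function(sample_sets, ann, alpha = 0.05) {
  if (!length(sample_sets)) stop("need at least one sample")
  if (is.null(names(sample_sets))) {
    names(sample_sets) <- paste0("sample", seq_along(sample_sets))
  }
  res <- lapply(names(sample_sets), function(s) {
    r <- hypergeom_enrich(sample_sets[[s]], ann)
    r$sample <- s
    r
  })
  long <- do.call(rbind, res)
  sig_by_cat <- tapply(long$adj_p < alpha, long$category, any)
  retained <- names(sig_by_cat)[sig_by_cat]
  retained <- retained[order(match(retained, names(ann$categories)))]
  counts <- matrix(0, length(retained), length(sample_sets),
                   dimnames = list(retained, names(sample_sets)))
  for (r in res) {
    counts[, r$sample[1]] <- r$k[match(retained, r$category)]
  }
  list(retained = retained, results = long,
       counts = counts, log2_counts = log2(counts + 1))
}

# Two-sided Mann-Whitney U p-value: exact for groups of at most 10 without
# ties, normal approximation with tie correction otherwise.
mann_whitney_p <- function(x, y) {
  exact <- length(x) <= 10 && length(y) <= 10 && !any(duplicated(c(x, y)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)$p.value
  )
  # fully tied data give a degenerate normal approximation: no evidence
  if (is.na(p)) p <- 1
  p
}

#' Compare per-category protein counts between groups
#'
#' For each functional category, compares the two sample groups by (a) a
#' chi-square test on the 2x2 table of summed in-category versus
#' out-of-category counts per group and (b) a two-sided Mann-Whitney U-test
#' on the per-sample counts, each family Benjamini-Hochberg adjusted.
#'
#' @param counts Category x sample matrix of protein counts (e.g. from
#'   [per_sample_enrichment()]).
#' @param groups Factor over the columns with exactly two levels, each with
#'   at least two samples.
#' @return data.frame: `category`, per-group summed counts, `chisq_stat`,
#'   `chisq_p`, `chisq_adj_p`, `mw_p`, `mw_adj_p`.
#' @export
compare_category_counts <- function(counts, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("`groups` must have exactly two levels")
  if (length(groups) != ncol(counts)) {
    stop("`groups` must have one entry per sample column")
  }
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  g1 <- groups == levels(groups)[1]
  t1 <- sum(counts[, g1])
  t2 <- sum(counts[, !g1])
  if (t1 == 0 || t2 == 0) stop("a group has zero total counts")
  stat <- p_chi <- p_mw <- numeric(nrow(counts))
  a1 <- rowSums(counts[, g1, drop = FALSE])
  a2 <- rowSums(counts[, !g1, drop = FALSE])
  for (i in seq_len(nrow(counts))) {
    tab <- rbind(c(a1[i], t1 - a1[i]), c(a2[i], t2 - a2[i]))
    if (a1[i] + a2[i] == 0) {
      stat[i] <- 0
      p_chi[i] <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      # a zero table margin gives an undefined statistic: no association
      stat[i] <- if (is.finite(ct$statistic)) unname(ct$statistic) else 0
      p_chi[i] <- if (is.finite(ct$p.value)) ct$p.value else 1
    }
    p_mw[i] <- mann_whitney_p(counts[i, g1], counts[i, !g1])
  }
  data.frame(
    category = rownames(counts),
    sum_group1 = unname(a1), sum_group2 = unname(a2),
    chisq_stat = stat, chisq_p = p_chi, chisq_adj_p = bh_adjust(p_chi),
    mw_p = p_mw, mw_adj_p = bh_adjust(p_mw),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Total category abundance comparison between groups
#'
#' Sums the quantitative values of all rows belonging to a category per
#' sample (e.g. total spectral counts of exosome proteins, total iBAQ of CD
#' molecules) and compares the two groups by a two-sided Mann-Whitney
#' U-test.
#'
#' @param m A [quant_matrix()].
#' @param category Character vector of member ids; matched against rownames,
#'   or against genes when `gene_map` is given.
#' @param groups Named factor (sample -> group) with two levels.
#' @param gene_map Optional named vector mapping row ids to gene ids.
#' @param category_name Name used in error messages.
#' @return List with `totals` (per sample), `group_totals`, `p`.
#' @export
category_abundance_test <- function(m, category, groups, gene_map = NULL,
                                    category_name = "category") {
  stopifnot(inherits(m, "quant_matrix"))
  ids <- rownames(m$values)
  keys <- if (is.null(gene_map)) ids else unname(gene_map[ids])
  rows <- which(keys %in% category)
  if (!length(rows)) {
    stop("category `", category_name, "` maps to no rows of the matrix")
  }
  groups <- as.factor(groups)
  use <- names(groups)[names(groups) %in% colnames(m$values)]
  groups <- droplevels(groups[use])
  if (nlevels(groups) != 2) stop("`groups` must have exactly two levels")
  totals <- colSums(m$values[rows, use, drop = FALSE])
  g1 <- groups == levels(groups)[1]
  list(
    totals = totals,
    group_totals = tapply(totals, groups, sum),
    p = mann_whitney_p(totals[g1], totals[!g1])
  )
}

#' Compartment-specific abundance summary
#'
#' Assigns each row (gene) to a major cellular component only if it is
#' annotated to exactly one of the supplied compartments (the specificity
#' rule); multiply-annotated rows are excluded from every compartment but
#' counted in the Venn overlap partition. Reports the mean log2(x + 1)
#' value per compartment as an overall abundance estimate.
#'
#' @param m A [quant_matrix()] of raw-scale values (e.g. iBAQ).
#' @param compartments Named list of id-sets (row ids, or gene ids when
#'   `gene_map` is given).
#' @param gene_map Optional named vector mapping row ids to gene ids.
#' @return List with `means` (named, mean log2(x+1) per compartment),
#'   `n_specific` (rows specific per compartment), and `venn` (data.frame
#'   `pattern`, `count` over all annotated rows).
#' @export
compartment_abundance_summary <- function(m, compartments, gene_map = NULL) {
  stopifnot(inherits(m, "quant_matrix"))
  ids <- rownames(m$values)
  keys <- if (is.null(gene_map)) ids else unname(gene_map[ids])
  member <- vapply(compartments, function(g) keys %in% g,
                   logical(length(keys)))
  member <- matrix(member, nrow = length(keys),
                   dimnames = list(ids, names(compartments)))
  n_annot <- rowSums(member)
  specific <- n_annot == 1
  means <- vapply(names(compartments), function(cn) {
    rows <- which(specific & member[, cn])
    if (!length(rows)) return(NA_real_)
    mean(log2(m$values[rows, , drop = FALSE] + 1))
  }, numeric(1))
  annotated <- n_annot > 0
  pattern <- apply(member[annotated, , drop = FALSE], 1, function(z) {
    paste(names(compartments)[z], collapse = "&")
  })
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("pattern", "count")
  list(means = means,
       n_specific = colSums(member & specific),
       venn = venn)
}
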