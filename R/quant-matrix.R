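#' Protein-by-sample quantitative matrix
#'
#' The central data container of the package: a nonnegative numeric matrix of
#' quantitative values with proteins (or peptides) as rows and samples (LC-MS
#' runs) as columns, carrying its provenance: which search engine produced it,
#' which of the five quantitation types it holds, and which preprocessing
#' variant has been applied.
#'
#' @param values Numeric matrix, rows = proteins or peptides, columns =
#'   samples. Must have unique rownames and colnames and no negative or
#'   missing entries.
#' @param engine Search-engine tag, conventionally `"A"` or `"B"`.
#' @param quant_type One of `"protein_spectral_count"`,
#'   `"peptide_spectral_count"`, `"protein_LFQ"`, `"peptide_LFQ"`, `"iBAQ"`
#'   (free text is accepted for user-supplied matrices).
#' @param variant Preprocessing variant: `"raw"`, `"log"`, `"log+qn"` or
#'   `"log+qn+filter"`.
#' @return An object of class `quant_matrix`: a list with elements `values`,
#'   `engine`, `quant_type`, `variant`.
#' @export
#' @examples
#' m <- quant_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("P", 1:3), c("s1", "s2"))),
#'   engine = "A", quant_type = "protein_spectral_count")
#' dim(m)
quant_matrix <- function(values, engine = NA_character_,
                         quant_type = NA_character_, variant = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    if (nrow(values) > 0) {
      stop("`values` must have row ids (rownames)", call. = FALSE)
    }
    rownames(values) <- character(0)
  }
  if (is.null(colnames(values))) {
    if (ncol(values) > 0) {
      stop("`values` must have sample ids (colnames)", call. = FALSE)
    }
    colnames(values) <- character(0)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicate row ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) {
    stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (any(values < 0)) stop("`values` must be nonnegative", call. = FALSE)
  variant <- as.character(variant)
  if (!variant %in% c("raw", "log", "log+qn", "log+qn+filter")) {
    stop("unknown preprocessing variant: ", variant, call. = FALSE)
  }
  structure(
    list(values = values, engine = as.character(engine),
         quant_type = as.character(quant_type), variant = variant),
    class = "quant_matrix"
  )
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d rows x %d samples [engine=%s, type=%s, variant=%s]\n",
              nrow(x$values), ncol(x$values), x$engine, x$quant_type, x$variant))
  invisible(x)
}

#' Extract the value matrix of a quant_matrix
#'
#' @param m A [quant_matrix()].
#' @return The underlying numeric matrix.
#' @export
qm_values <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  m$values
}

# Internal: replace values, keeping provenance, optionally bumping variant.
qm_replace <- function(m, values, variant = m$variant) {
  quant_matrix(values, engine = m$engine, quant_type = m$quant_type,
               variant = variant)
}

#' Case/control labels from a clinical table
#'
#' Builds the two-group contrast labels (lung cancer vs non-lung cancer) from
#' a clinical annotation table. Samples with a suspicious diagnosis (`"S"`)
#' are excluded by default, so the contrast is strictly cancer vs non-cancer.
#'
#' @param clinical Clinical table with columns `sample_id` and the diagnosis
#'   columns `cancer_2014` / `cancer_2016` coded `"No"`, `"Yes"`, `"S"`.
#' @param time Which diagnosis time point to use: `"2014"` (time of sample
#'   collection, the default, as used for the differential contrast) or
#'   `"2016"` (after two-year follow up).
#' @param drop_suspicious Drop `"S"` samples (default `TRUE`).
#' @return Named factor with levels `control`, `case`, names = sample ids.
#' @export
cancer_labels <- function(clinical, time = c("2014", "2016"),
                          drop_suspicious = TRUE) {
  time <- match.arg(time)
  col <- paste0("cancer_", time)
  if (!col %in% names(clinical)) stop("clinical table lacks column ", col)
  status <- as.character(clinical[[col]])
  keep <- if (drop_suspicious) status %in% c("No", "Yes") else rep(TRUE, length(status))
  lab <- factor(ifelse(status[keep] == "Yes", "case", "control"),
                levels = c("control", "case"))
  names(lab) <- clinical$sample_id[keep]
  lab
}
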