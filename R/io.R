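#' Read a tab-separated quantitative matrix
#'
#' Expects a header row of sample ids and a first column of row ids. Ragged
#' rows, duplicate ids and non-numeric cells are rejected with the offending
#' line number. Provenance is taken from a JSON sidecar `<path>.json` when
#' present, unless given explicitly.
#'
#' @param path File path.
#' @param engine,quant_type,variant Optional provenance overriding the
#'   sidecar.
#' @return A [quant_matrix()].
#' @export
read_quant_matrix <- function(path, engine = NULL, quant_type = NULL,
                              variant = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1) stop(path, ": empty file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncols <- length(header) - 1
  if (ncols < 1) stop(path, ": line 1: header must name at least one sample")
  sample_ids <- header[-1]
  body <- fields[-1]
  lens <- lengths(body)
  bad <- which(lens != ncols + 1)
  if (length(bad)) {
    stop(sprintf("%s: line %d: expected %d fields, found %d",
                 path, bad[1] + 1, ncols + 1, lens[bad[1]]))
  }
  ids <- vapply(body, `[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(path, ": duplicate row id: ", dup[1])
  }
  vals <- matrix(NA_real_, length(body), ncols,
                 dimnames = list(ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) {
      stop(sprintf("%s: line %d: non-numeric value `%s`", path, i + 1,
                   body[[i]][-1][which(is.na(v))[1]]))
    }
    vals[i, ] <- v
  }
  prov <- list(engine = NA_character_, quant_type = NA_character_,
               variant = "raw")
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (f in names(prov)) if (!is.null(sc[[f]])) prov[[f]] <- sc[[f]]
  }
  if (!is.null(engine)) prov$engine <- engine
  if (!is.null(quant_type)) prov$quant_type <- quant_type
  if (!is.null(variant)) prov$variant <- variant
  quant_matrix(vals, engine = prov$engine, quant_type = prov$quant_type,
               variant = prov$variant)
}

#' Write a quantitative matrix as tab-separated text
#'
#' Numeric values are written with full double precision so a
#' write-then-read round trip reproduces the matrix exactly. Provenance is
#' stored in a JSON sidecar `<path>.json`.
#'
#' @param m A [quant_matrix()].
#' @param path Output file path.
#' @param sidecar Also write the provenance sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(m, path, sidecar = TRUE) {
  stopifnot(inherits(m, "quant_matrix"))
  x <- m$values
  txt <- matrix(sprintf("%.17g", x), nrow(x), ncol(x))
  lines <- c(
    paste(c("id", colnames(x)), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], txt[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  if (sidecar) {
    jsonlite::write_json(
      list(engine = m$engine, quant_type = m$quant_type, variant = m$variant),
      paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' Read / write a clinical annotation table
#'
#' Tab-separated with columns `sample_id`, `cancer_2014`, `cancer_2016`,
#' `stage`, `gender`, `smoking`, `age_group`, `batch`, `replicate_group`.
#'
#' @param path File path.
#' @return `read_clinical()`: a data.frame; `write_clinical()`: `path`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  required <- c("sample_id", "cancer_2014", "cancer_2016")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(path, ": clinical table lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  if ("batch" %in% names(df)) df$batch <- as.integer(df$batch)
  df
}

#' @rdname read_clinical
#' @param clinical Clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a contaminant id list
#'
#' Plain text, one id per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_contaminants <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read / write gene-set annotations in GMT format
#'
#' Tab-separated: category id, description, then member gene ids.
#'
#' @param path File path.
#' @return `read_gmt()`: named list of gene-id sets.
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 2]
  stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)])),
    vapply(fields, `[`, character(1), 1)
  )
}

#' @rdname read_gmt
#' @param categories Named list of gene-id sets.
#' @param descriptions Optional named descriptions (defaults to the ids).
#' @export
write_gmt <- function(categories, path, descriptions = NULL) {
  lines <- vapply(names(categories), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else nm
    paste(c(nm, desc, categories[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a differential-expression result table
#'
#' @param de A `de_result` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(de, path) {
  utils::write.table(format(de, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
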