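#' Pipeline configuration
#'
#' Assembles the configuration of [run_pipeline()]. When `simulate = TRUE`
#' the inputs are generated by [generate_cohort()] under `design`; otherwise
#' paths to raw matrices, a clinical table, a contaminant list and GMT
#' annotations must be supplied.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed; every stage derives its own seed from it.
#' @param simulate Generate synthetic inputs (default `TRUE`).
#' @param design A [cohort_design()] (its seed is overridden by the derived
#'   stage seed so that one root seed drives the whole run).
#' @param de_quant_type,de_variant Matrix fed to the differential contrast
#'   (defaults: iBAQ, `"log+qn"`; the abundance-filtered variant optimizes
#'   the value distribution for ordination but removes low-abundance
#'   proteins from the biomarker search, so it is not the contrast default).
#' @param pca_quant_type,pca_engine Matrix fed to the PCA stratification
#'   (defaults: spectral counts of engine A, filtered variant).
#' @param consensus A [consensus_config()].
#' @param inputs For `simulate = FALSE`: named list with `matrices` (named
#'   paths `"<engine>.<quant_type>"`), `clinical`, `contaminants`,
#'   `annotations` (GMT), optionally `study_tables`, `copd_tables` (TSV).
#' @param n_studies,min_support External-study simulation and consensus
#'   support for the cross-study stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            design = cohort_design(),
                            de_quant_type = "iBAQ",
                            de_variant = "log+qn",
                            pca_quant_type = "protein_spectral_count",
                            pca_engine = "A",
                            consensus = consensus_config(),
                            inputs = NULL,
                            n_studies = 8L, min_support = 3L) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
         design = design, de_quant_type = de_quant_type,
         de_variant = de_variant, pca_quant_type = pca_quant_type,
         pca_engine = pca_engine, consensus = consensus, inputs = inputs,
         n_studies = as.integer(n_studies),
         min_support = as.integer(min_support)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML or JSON document
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `design`
#' and `consensus` may be given as key-value maps overriding the
#' [cohort_design()] / [consensus_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$design)) {
    args$design <- do.call(cohort_design, raw$design)
  }
  if (!is.null(raw$consensus)) {
    args$consensus <- do.call(consensus_config, raw$consensus)
  }
  do.call(pipeline_config, args)
}

stage_seed <- function(root, k) (root * 97L + k * 1009L) %% 2147483629L

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> preprocess -> differential expression
#' per engine -> cross-engine consensus -> stratification and QC ->
#' functional enrichment -> cross-study consensus, writing every
#' intermediate artifact under `cfg$out_dir` and a JSON manifest recording
#' inputs, seeds, applied thresholds and the MD5 hash of every output file.
#' Identical configuration and seed give identical manifest hashes.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  for (d in file.path(out, c("matrices", "de", "consensus", "stratify",
                             "enrichment", "crossstudy"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  files <- character(0)
  log <- list()

  ## stage 0: inputs
  if (isTRUE(cfg$simulate)) {
    design <- cfg$design
    design$seed <- stage_seed(cfg$seed, 1L)
    ds <- generate_cohort(design)
    raw <- ds$matrices
    clinical <- ds$clinical
    contaminants <- ds$truth$contaminants
    categories <- ds$truth$categories
    gene_map <- ds$truth$gene_map
    files <- c(files, write_tsv(clinical, file.path(out, "clinical.tsv")))
    writeLines(contaminants, file.path(out, "contaminants.txt"))
    files <- c(files, file.path(out, "contaminants.txt"))
    jsonlite::write_json(
      list(regulated = ds$truth$regulated,
           cancer_exclusive = ds$truth$cancer_exclusive,
           gene_map = as.list(gene_map)),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out, "truth.json"))
    write_gmt(categories, file.path(out, "annotations.gmt"))
    files <- c(files, file.path(out, "annotations.gmt"))
    study_tables <- simulate_study_tables(ds$truth, n_studies = cfg$n_studies,
                                          seed = stage_seed(cfg$seed, 2L))
    copd_tables <- simulate_study_tables(ds$truth, n_studies = 2,
                                         concordance = 0.5, report_rate = 0.3,
                                         contexts = "COPD",
                                         seed = stage_seed(cfg$seed, 3L))
    replicate_map <- ds$replicate_map
  } else {
    ins <- cfg$inputs
    if (is.null(ins$clinical) || !file.exists(ins$clinical)) {
      stop("pipeline stage 0: clinical table missing")
    }
    clinical <- read_clinical(ins$clinical)
    raw <- lapply(ins$matrices, read_quant_matrix)
    for (nm in names(raw)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      raw[[nm]]$engine <- parts[1]
      raw[[nm]]$quant_type <- paste(parts[-1], collapse = ".")
    }
    contaminants <- if (!is.null(ins$contaminants)) {
      read_contaminants(ins$contaminants)
    } else character(0)
    categories <- if (!is.null(ins$annotations)) {
      read_gmt(ins$annotations)
    } else NULL
    gene_map <- NULL
    study_tables <- if (!is.null(ins$study_tables)) {
      utils::read.delim(ins$study_tables, colClasses = "character")
    } else NULL
    copd_tables <- if (!is.null(ins$copd_tables)) {
      utils::read.delim(ins$copd_tables, colClasses = "character")
    } else NULL
    ds <- NULL
    replicate_map <- stats::setNames(clinical$replicate_group,
                                     clinical$sample_id)
  }
  for (nm in names(raw)) {
    files <- c(files, write_quant_matrix(
      raw[[nm]], file.path(out, "matrices", paste0(nm, ".raw.tsv"))))
  }

  ## stage 1: preprocessing (30 matrices)
  family <- build_matrix_family(raw, contaminants)
  for (nm in names(family)) {
    files <- c(files, write_quant_matrix(
      family[[nm]], file.path(out, "matrices", paste0(nm, ".tsv"))))
  }
  log$n_preprocessed_matrices <- length(family)
  log$filter_thresholds <- lapply(attr(family, "filter_trace"), function(tr) {
    tr$threshold[which.min(tr$score)]
  })

  ## stage 2: differential expression per engine
  labels <- cancer_labels(clinical, time = "2014")
  de <- list()
  for (engine in c("A", "B")) {
    key <- paste(engine, cfg$de_quant_type, cfg$de_variant, sep = ".")
    if (!key %in% names(family)) {
      stop("pipeline stage de: no matrix in slot `", key, "`")
    }
    de[[engine]] <- run_diffexpr(family[[key]], labels = labels)
    files <- c(files, write_de_result(
      de[[engine]], file.path(out, "de", paste0("de_", engine, ".tsv"))))
  }

  ## stage 3: cross-engine consensus + cancer-exclusive proteins
  cons <- consensus_filter(de$A, de$B, cfg$consensus)
  files <- c(files, write_tsv(as.data.frame(cons),
                              file.path(out, "consensus", "consensus.tsv")))
  jsonlite::write_json(attr(cons, "summary"),
                       file.path(out, "consensus", "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out, "consensus", "summary.json"))
  raw_key <- paste(cfg$pca_engine, cfg$de_quant_type, sep = ".")
  exclusive <- cancer_exclusive_proteins(raw[[raw_key]], clinical)
  writeLines(exclusive, file.path(out, "consensus", "cancer_exclusive.txt"))
  files <- c(files, file.path(out, "consensus", "cancer_exclusive.txt"))

  ## stage 4: stratification and QC
  pca_key <- paste(cfg$pca_engine, cfg$pca_quant_type, "log+qn+filter",
                   sep = ".")
  pca_m <- family[[pca_key]]
  pca <- pca_stratify(pca_m, labels = labels)
  scores <- data.frame(sample_id = rownames(pca$scores),
                       pca$scores[, seq_len(min(5, ncol(pca$scores))),
                                  drop = FALSE])
  files <- c(files, write_tsv(scores,
                              file.path(out, "stratify", "pca_scores.tsv")))
  sep_est <- pc1_separation(pca, clinical)
  jsonlite::write_json(unclass(sep_est),
                       file.path(out, "stratify", "separation.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out, "stratify", "separation.json"))

  qc <- distance_qc(pca_m, replicate_map)
  jsonlite::write_json(list(mean_all_pairs = qc$mean_all_pairs,
                            mean_replicate_pairs = qc$mean_replicate_pairs),
                       file.path(out, "stratify", "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, file.path(out, "stratify", "qc.json"))
  ape::write.tree(ape::as.phylo(qc$tree),
                  file.path(out, "stratify", "linkage_tree.nwk"))
  files <- c(files, file.path(out, "stratify", "linkage_tree.nwk"))

  idsets <- identification_sets(raw[[raw_key]])
  sat <- saturation_curve(idsets, n_permutations = 50,
                          seed = stage_seed(cfg$seed, 4L))
  files <- c(files, write_tsv(
    data.frame(n_runs = seq_along(sat$observed), observed = sat$observed,
               mean = sat$mean, lower = sat$lower, upper = sat$upper),
    file.path(out, "stratify", "saturation.tsv")))
  files <- c(files, write_tsv(cohort_summary(clinical),
                              file.path(out, "stratify", "cohort_summary.tsv")))

  ## stage 5: functional enrichment
  if (!is.null(categories)) {
    id_genes <- if (is.null(gene_map)) idsets else {
      lapply(idsets, function(s) unique(unname(gene_map[s])))
    }
    background <- unique(unlist(id_genes))
    ann <- annotation_set(categories, background)
    enr <- per_sample_enrichment(id_genes, ann)
    files <- c(files, write_tsv(enr$results,
                                file.path(out, "enrichment", "enrichment.tsv")))
    if (nrow(enr$counts)) {
      cm <- data.frame(category = rownames(enr$log2_counts),
                       enr$log2_counts, check.names = FALSE)
      files <- c(files, write_tsv(cm,
                                  file.path(out, "enrichment", "counts_log2.tsv")))
      grp <- labels[colnames(enr$counts)[colnames(enr$counts) %in% names(labels)]]
      cc <- compare_category_counts(
        enr$counts[, names(grp), drop = FALSE], grp)
      files <- c(files, write_tsv(cc,
                                  file.path(out, "enrichment", "category_tests.tsv")))
    }
    comp <- categories[startsWith(names(categories), "CC:")]
    if (length(comp) >= 2 && !is.null(gene_map)) {
      ibaq_key <- paste(cfg$pca_engine, "iBAQ", sep = ".")
      cs <- compartment_abundance_summary(raw[[ibaq_key]], comp, gene_map)
      jsonlite::write_json(list(means = as.list(cs$means),
                                n_specific = as.list(cs$n_specific),
                                venn = cs$venn),
                           file.path(out, "enrichment", "compartments.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, file.path(out, "enrichment", "compartments.json"))
    }
  }

  ## stage 6: cross-study consensus
  if (!is.null(study_tables) && nrow(study_tables) && !is.null(gene_map)) {
    own <- collapse_to_genes(consensus_members(cons), gene_map)
    own_table <- data.frame(gene = own$gene, study_id = "this_study",
                            context = "BAL", direction = own$direction,
                            stringsAsFactors = FALSE)
    all_tables <- rbind(own_table,
                        study_tables[, c("gene", "study_id", "context",
                                         "direction")])
    files <- c(files, write_tsv(all_tables,
                                file.path(out, "crossstudy", "study_tables.tsv")))
    msc <- multi_study_consensus(all_tables, min_support = cfg$min_support)
    msc <- flag_copd_overlap(msc, copd_tables)
    files <- c(files, write_tsv(msc$members,
                                file.path(out, "crossstudy", "consensus_genes.tsv")))
    codes_df <- data.frame(gene = rownames(msc$codes), msc$codes,
                           check.names = FALSE)
    files <- c(files, write_tsv(codes_df,
                                file.path(out, "crossstudy", "heatmap_codes.tsv")))
  }

  ## manifest
  files <- unique(c(files, paste0(files, ".json")[file.exists(paste0(files, ".json"))]))
  files <- files[file.exists(files)]
  hashes <- tools::md5sum(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("balproteo")),
    seed = cfg$seed,
    stage_seeds = list(simulate = stage_seed(cfg$seed, 1L),
                       study_tables = stage_seed(cfg$seed, 2L),
                       copd_tables = stage_seed(cfg$seed, 3L),
                       saturation = stage_seed(cfg$seed, 4L)),
    thresholds = list(alpha = cfg$consensus$alpha,
                      fold_threshold = cfg$consensus$fold_threshold,
                      pca_abundance_rule = "detected in >= 50% of samples",
                      filter_thresholds = log$filter_thresholds),
    n_preprocessed_matrices = log$n_preprocessed_matrices,
    de = list(quant_type = cfg$de_quant_type, variant = cfg$de_variant),
    outputs = lapply(seq_along(files), function(i) {
      list(path = sub(paste0("^", out, "/?"), "", files[i]),
           md5 = unname(hashes[i]))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Per-run identification sets of a quantitative matrix
#'
#' @param m A [quant_matrix()].
#' @return Named list of row ids with nonzero value per sample column.
#' @export
identification_sets <- function(m) {
  stopifnot(inherits(m, "quant_matrix"))
  x <- m$values
  stats::setNames(
    lapply(seq_len(ncol(x)), function(j) rownames(x)[x[, j] > 0]),
    colnames(x)
  )
}

#' Converter placement and separation estimate from a PCA
#'
#' Computes where the converter patients (non-cancer at collection, cancer
#' at follow up) fall relative to the PC1 midpoint between the case and
#' control group means, and derives the [separation_probability()] estimate:
#' `n_total` is the number of non-cancer plus suspicious samples at
#' collection time, and `n_separated` those of them on the control side of
#' the midpoint.
#'
#' @param pca A `pca_result` (oriented with cases high on PC1).
#' @param clinical Clinical table with both diagnosis time points.
#' @return A `separation_estimate` with extra fields `n_converts_case_side`
#'   and `pc1_midpoint`.
#' @export
pc1_separation <- function(pca, clinical) {
  pc1 <- pca$scores[, 1]
  status14 <- stats::setNames(clinical$cancer_2014, clinical$sample_id)
  status16 <- stats::setNames(clinical$cancer_2016, clinical$sample_id)
  use <- intersect(names(pc1), clinical$sample_id)
  pc1 <- pc1[use]
  s14 <- status14[use]
  s16 <- status16[use]
  mid <- mean(c(mean(pc1[s14 == "Yes"]), mean(pc1[s14 == "No"])))
  converts <- s14 != "Yes" & s16 == "Yes"
  noncancer14 <- s14 %in% c("No", "S")
  # separated = collection-time non-cancer/suspicious samples on the
  # control side of the PC1 midpoint (converters included in the pool)
  separated <- noncancer14 & pc1 < mid
  est <- separation_probability(
    n_separated = sum(separated),
    n_total = sum(noncancer14),
    k = sum(converts)
  )
  est$n_converts_case_side <- sum(converts & pc1 >= mid)
  est$pc1_midpoint <- mid
  est
}
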