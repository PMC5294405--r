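#' Design of a synthetic BAL proteomics cohort
#'
#' Collects every parameter of the synthetic-data generator. The defaults
#' emulate a 90-patient observational cohort of suspected lung cancer cases
#' followed for two years: 49 cancer cases and 39 non-cancer controls plus 2
#' still-suspicious patients at follow up, 13 "converter" patients labeled
#' non-cancer at collection but diagnosed with cancer during follow up, five
#' sample batches, and 34 technical replicate runs (90 + 34 = 124 LC-MS runs).
#'
#' The quantitative model is: per-protein baseline log2 abundance drawn from
#' N(`baseline_log2_mean`, `baseline_log2_sd`); planted log2 effects (uniform
#' in `effect_log2_range`, random sign) added to every sample that carries
#' the cancer proteome signal (cases *and* converters); additive per-protein
#' batch offsets (sd `batch_sd`) and per-sample biological noise (sd
#' `biological_sd`) on the log2 scale. Each search engine observes the latent
#' value through independent multiplicative noise (additive on log2 scale, sd
#' `engine_noise_sd`) and independent logistic abundance-dependent detection:
#' a value with latent log2 abundance `y` is detected with probability
#' `plogis((y - dropout_midpoint) / dropout_steepness)`; undetected values
#' are stored as 0. Spectral counts are Poisson with rate
#' `count_scale * 2^(y - baseline_log2_mean)`; intensity types are the
#' exponentiated latent value (iBAQ additionally divided by a per-protein
#' theoretical peptide count). Engine B drops each protein entirely with
#' probability `engine_b_missing_rate` to emulate search-engine disagreement.
#'
#' @param n_patients Number of patients.
#' @param case_fraction Fraction of patients with lung cancer at follow up.
#' @param n_converts Patients labeled non-cancer at collection (2014) but
#'   cancer at follow up (2016); they carry the full cancer proteome signal.
#' @param n_suspicious Patients still suspicious ("S") at follow up.
#' @param n_batches Number of sample-preparation/LC-MS batches.
#' @param n_replicate_pairs Number of samples rerun as technical replicas.
#' @param covariate_specs Named list of categorical count (or probability)
#'   vectors for `gender`, `smoking` and `age_group`.
#' @param n_proteins,n_regulated,n_cancer_exclusive,n_contaminants Number of
#'   simulated proteins; of planted differentially regulated proteins; of
#'   proteins expressed exclusively in cancer samples; of spiked common MS
#'   contaminants (ids prefixed `CON_`).
#' @param effect_log2_range Range (low, high) of planted |log2| effects.
#' @param baseline_log2_mean,baseline_log2_sd Baseline abundance law
#'   (log-normal on the log2 scale).
#' @param biological_sd,batch_sd Per-sample biological and per-batch additive
#'   log2 noise.
#' @param dropout_midpoint,dropout_steepness Logistic detection parameters
#'   (location and scale on the log2-abundance axis).
#' @param engine_noise_sd,engine_b_missing_rate Per-engine measurement noise
#'   and engine-B whole-protein missing rate.
#' @param replicate_noise_sd Measurement noise of technical replicate runs
#'   (smaller than `engine_noise_sd`).
#' @param count_scale Expected spectral count of a protein at baseline mean
#'   abundance.
#' @param seed Integer seed; identical design + seed gives identical output.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_patients = 90L,
                          case_fraction = 49 / 90,
                          n_converts = 13L,
                          n_suspicious = 2L,
                          n_batches = 5L,
                          n_replicate_pairs = 34L,
                          covariate_specs = list(
                            gender = c(M = 59, F = 31),
                            smoking = c(C = 23, E = 22, N = 16, U = 29),
                            age_group = c("<60" = 25, "60-79" = 59, "80+" = 6)
                          ),
                          n_proteins = 1200L,
                          n_regulated = 120L,
                          n_cancer_exclusive = 5L,
                          n_contaminants = 10L,
                          effect_log2_range = c(1.5, 3.5),
                          baseline_log2_mean = 20,
                          baseline_log2_sd = 3,
                          biological_sd = 1,
                          batch_sd = 0.3,
                          dropout_midpoint = 14,
                          dropout_steepness = 2,
                          engine_noise_sd = 0.5,
                          engine_b_missing_rate = 0.02,
                          replicate_noise_sd = 0.25,
                          count_scale = 20,
                          seed = 1L) {
  design <- list(
    n_patients = as.integer(n_patients), case_fraction = case_fraction,
    n_converts = as.integer(n_converts), n_suspicious = as.integer(n_suspicious),
    n_batches = as.integer(n_batches),
    n_replicate_pairs = as.integer(n_replicate_pairs),
    covariate_specs = covariate_specs,
    n_proteins = as.integer(n_proteins), n_regulated = as.integer(n_regulated),
    n_cancer_exclusive = as.integer(n_cancer_exclusive),
    n_contaminants = as.integer(n_contaminants),
    effect_log2_range = as.numeric(effect_log2_range),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    biological_sd = biological_sd, batch_sd = batch_sd,
    dropout_midpoint = dropout_midpoint,
    dropout_steepness = dropout_steepness,
    engine_noise_sd = engine_noise_sd,
    engine_b_missing_rate = engine_b_missing_rate,
    replicate_noise_sd = replicate_noise_sd,
    count_scale = count_scale, seed = as.integer(seed)
  )
  class(design) <- "cohort_design"
  validate_design(design)
  design
}

validate_design <- function(d) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort design: field `%s` %s", field, why),
         call. = FALSE)
  }
  counts <- c("n_patients", "n_converts", "n_suspicious", "n_batches",
              "n_replicate_pairs", "n_proteins", "n_regulated",
              "n_cancer_exclusive", "n_contaminants")
  for (f in counts) {
    if (length(d[[f]]) != 1 || is.na(d[[f]]) || d[[f]] < 0) {
      fail(f, "must be a single nonnegative count")
    }
  }
  if (d$case_fraction < 0 || d$case_fraction > 1) {
    fail("case_fraction", "must lie in [0, 1]")
  }
  n_controls <- round(d$n_patients * (1 - d$case_fraction))
  if (d$n_converts + d$n_suspicious > n_controls) {
    fail("n_converts", sprintf(
      "+ n_suspicious (%d) exceeds the non-cancer pool (%d)",
      d$n_converts + d$n_suspicious, n_controls))
  }
  if (d$n_regulated + d$n_cancer_exclusive > d$n_proteins) {
    fail("n_regulated", "+ n_cancer_exclusive exceeds n_proteins")
  }
  r <- d$effect_log2_range
  if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
    fail("effect_log2_range", "must be 0 < low <= high")
  }
  if (d$dropout_steepness <= 0) fail("dropout_steepness", "must be > 0")
  for (f in c("engine_noise_sd", "batch_sd", "biological_sd",
              "replicate_noise_sd")) {
    if (d[[f]] < 0) fail(f, "must be nonnegative")
  }
  if (d$n_batches < 1) fail("n_batches", "must be >= 1")
  if (d$count_scale <= 0) fail("count_scale", "must be > 0")
  if (d$n_replicate_pairs > d$n_patients) {
    fail("n_replicate_pairs", "exceeds n_patients")
  }
  invisible(TRUE)
}

# Assign categorical covariates by sampling from the given distribution.
draw_covariate <- function(spec, n) {
  sample(names(spec), n, replace = TRUE, prob = spec / sum(spec))
}

simulate_clinical <- function(design) {
  n <- design$n_patients
  ids <- sprintf("S%03d", seq_len(n))
  n_yes16 <- round(n * design$case_fraction)
  perm <- sample.int(n)
  status16 <- rep("No", n)
  yes16 <- perm[seq_len(n_yes16)]
  status16[yes16] <- "Yes"
  if (design$n_suspicious > 0) {
    status16[perm[n_yes16 + seq_len(design$n_suspicious)]] <- "S"
  }
  converts <- if (design$n_converts > 0 && n_yes16 > 0) {
    sample(yes16, min(design$n_converts, n_yes16))
  } else integer(0)
  status14 <- status16
  status14[converts] <- "No"
  stage <- rep("", n)
  stage[status16 == "Yes"] <- sample(c("I", "II", "III", "IV"),
                                     sum(status16 == "Yes"), replace = TRUE,
                                     prob = c(0.15, 0.10, 0.30, 0.45))
  cs <- design$covariate_specs
  # batches stratified by follow-up status for an even case split per batch
  batch <- integer(n)
  for (st in unique(status16)) {
    idx <- which(status16 == st)
    batch[idx] <- rep_len(seq_len(design$n_batches),
                          length(idx))[sample.int(length(idx))]
  }
  data.frame(
    sample_id = ids,
    cancer_2014 = status14,
    cancer_2016 = status16,
    stage = stage,
    gender = draw_covariate(cs$gender, n),
    smoking = draw_covariate(cs$smoking, n),
    age_group = draw_covariate(cs$age_group, n),
    batch = batch,
    replicate_group = ids,
    stringsAsFactors = FALSE
  )
}

simulate_truth <- function(design) {
  P <- design$n_proteins
  proteins <- sprintf("P%04d", seq_len(P))
  contaminants <- if (design$n_contaminants > 0) {
    sprintf("CON_%03d", seq_len(design$n_contaminants))
  } else character(0)
  # ~15% of proteins share the gene of the previous protein (isoforms)
  new_gene <- c(TRUE, stats::runif(P - 1) > 0.15)
  gene_idx <- cumsum(new_gene)
  gene_map <- stats::setNames(sprintf("G%04d", gene_idx), proteins)
  genes <- unique(gene_map)

  reg_idx <- if (design$n_regulated > 0) {
    sample.int(P, design$n_regulated)
  } else integer(0)
  direction <- sample(c("up", "down"), length(reg_idx), replace = TRUE)
  effect <- stats::runif(length(reg_idx), design$effect_log2_range[1],
                         design$effect_log2_range[2])
  regulated <- data.frame(
    protein = proteins[reg_idx], direction = direction,
    log2_effect = effect, stringsAsFactors = FALSE
  )
  pool <- setdiff(seq_len(P), reg_idx)
  excl_idx <- if (design$n_cancer_exclusive > 0) {
    sample(pool, min(design$n_cancer_exclusive, length(pool)))
  } else integer(0)

  # five major cellular-component categories over genes, plus random process
  # categories; extracellular/vesicular genes are made more abundant below
  comp_names <- c("CC:extracellular_space", "CC:extracellular_vesicular_exosome",
                  "CC:cytoplasm", "CC:nucleus", "CC:membrane")
  comp_assign <- sample(comp_names, length(genes), replace = TRUE,
                        prob = c(0.15, 0.20, 0.30, 0.20, 0.15))
  categories <- split(genes, comp_assign)[comp_names]
  names(categories) <- comp_names
  for (j in seq_len(10)) {
    sz <- sample(20:80, 1)
    categories[[sprintf("BP:process_%02d", j)]] <-
      sample(genes, min(sz, length(genes)))
  }
  list(
    regulated = regulated,
    cancer_exclusive = proteins[excl_idx],
    gene_map = gene_map,
    categories = categories,
    contaminants = contaminants,
    compartment = stats::setNames(comp_assign, genes)
  )
}

# Latent per-(protein, sample) log2 abundance, including batch and biological
# noise but not engine effects. Rows: proteins then contaminants.
simulate_latent <- function(design, clinical, truth) {
  P <- design$n_proteins
  n <- nrow(clinical)
  proteins <- names(truth$gene_map)
  all_ids <- c(proteins, truth$contaminants)

  baseline <- stats::rnorm(P, design$baseline_log2_mean, design$baseline_log2_sd)
  # compartment abundance structure: secreted/vesicular proteins dominate BAL
  shift <- c("CC:extracellular_space" = 3, "CC:extracellular_vesicular_exosome" = 2,
             "CC:cytoplasm" = 0, "CC:nucleus" = -0.5, "CC:membrane" = 0)
  baseline <- baseline + shift[truth$compartment[truth$gene_map[proteins]]]
  cont_baseline <- stats::rnorm(design$n_contaminants,
                                design$baseline_log2_mean + 4, 1.5)
  b <- c(baseline, cont_baseline)

  signal <- clinical$cancer_2016 == "Yes"   # cases and converters
  eff <- numeric(length(all_ids))
  if (nrow(truth$regulated)) {
    sgn <- ifelse(truth$regulated$direction == "up", 1, -1)
    eff[match(truth$regulated$protein, all_ids)] <- sgn * truth$regulated$log2_effect
  }
  base_mat <- matrix(b, length(all_ids), n) + outer(eff, as.numeric(signal))

  batch_offsets <- matrix(stats::rnorm(length(all_ids) * design$n_batches,
                                       0, design$batch_sd),
                          length(all_ids), design$n_batches)
  bio <- matrix(stats::rnorm(length(all_ids) * n, 0, design$biological_sd),
                length(all_ids), n)
  latent <- base_mat + batch_offsets[, clinical$batch, drop = FALSE] + bio
  if (length(truth$cancer_exclusive)) {
    latent[match(truth$cancer_exclusive, all_ids), !signal] <- -Inf
  }
  dimnames(latent) <- list(all_ids, clinical$sample_id)
  list(latent = latent, base = base_mat, batch_offsets = batch_offsets)
}

# Peptide structure and per-engine fixed characteristics, shared between
# original runs and technical replicates.
simulate_engine_pars <- function(row_ids, design) {
  P <- length(row_ids)
  n_pep <- sample(2:6, P, replace = TRUE)
  pep_protein <- rep(seq_len(P), n_pep)
  w <- stats::rgamma(length(pep_protein), shape = 2)
  w <- w / rep(tapply(w, pep_protein, sum), n_pep)
  pep_ids <- paste0(row_ids[pep_protein], "|pep",
                    unlist(lapply(n_pep, seq_len), use.names = FALSE))
  list(
    n_pep = n_pep,
    pep_protein = pep_protein,
    pep_w = w,
    pep_ids = pep_ids,
    q_theoretical = sample(5:35, P, replace = TRUE),
    engineB_dropped = stats::runif(P) < design$engine_b_missing_rate
  )
}

#' Simulate the two-engine, five-quantitation-type matrix set
#'
#' Given latent per-(protein, sample) log2 abundances, produces the ten raw
#' quantitative matrices (engines A and B crossed with protein/peptide
#' spectral counts, protein/peptide LFQ and iBAQ). The two engines share the
#' latent truth and differ by independent measurement noise and independent
#' detection draws, so their log values for detected proteins are positively
#' correlated by construction.
#'
#' @param latent_abundances Matrix of latent log2 abundances (rows proteins,
#'   columns samples); `-Inf` encodes a truly absent protein.
#' @param design A [cohort_design()].
#' @param sim_pars Peptide structure and per-engine characteristics; drawn
#'   fresh when `NULL`. Pass the stored value to regenerate runs (e.g.
#'   technical replicates) consistent with an existing dataset.
#' @param noise_sd Measurement noise; defaults to `design$engine_noise_sd`.
#' @return List with `matrices` (named `"<engine>.<quant_type>"`) and
#'   `sim_pars`.
#' @export
simulate_engine_matrices <- function(latent_abundances, design,
                                     sim_pars = NULL, noise_sd = NULL) {
  if (any(is.nan(latent_abundances)) || any(latent_abundances == Inf)) {
    stop("internal error: latent abundances must be finite or -Inf")
  }
  if (is.null(sim_pars)) {
    sim_pars <- simulate_engine_pars(rownames(latent_abundances), design)
  }
  if (is.null(noise_sd)) noise_sd <- design$engine_noise_sd
  P <- nrow(latent_abundances)
  n <- ncol(latent_abundances)
  mats <- list()
  for (engine in c("A", "B")) {
    y <- latent_abundances +
      matrix(stats::rnorm(P * n, 0, noise_sd), P, n)
    if (engine == "B" && any(sim_pars$engineB_dropped)) {
      y[sim_pars$engineB_dropped, ] <- -Inf
    }
    pdet <- stats::plogis((y - design$dropout_midpoint) / design$dropout_steepness)
    pdet[is.nan(pdet)] <- 0   # -Inf latent with infinite-width detection
    det <- matrix(stats::rbinom(P * n, 1L, pdet), P, n)
    lin <- 2^y * det
    dimnames(lin) <- dimnames(latent_abundances)

    rate <- pmin(design$count_scale * lin / 2^design$baseline_log2_mean, 1e6)
    counts <- matrix(as.numeric(stats::rpois(P * n, rate)), P, n,
                     dimnames = dimnames(lin))
    ibaq <- lin / sim_pars$q_theoretical

    # peptide level: latent split among peptides by fixed weights, fresh
    # per-peptide detection
    yp <- y[sim_pars$pep_protein, , drop = FALSE] + log2(sim_pars$pep_w)
    pdet_p <- stats::plogis((yp - design$dropout_midpoint) /
                              design$dropout_steepness)
    pdet_p[is.nan(pdet_p)] <- 0
    det_p <- matrix(stats::rbinom(length(yp), 1L, pdet_p), nrow(yp), n)
    lin_p <- 2^yp * det_p
    dimnames(lin_p) <- list(sim_pars$pep_ids, colnames(latent_abundances))
    rate_p <- pmin(design$count_scale * lin_p / 2^design$baseline_log2_mean, 1e6)
    counts_p <- matrix(as.numeric(stats::rpois(length(rate_p), rate_p)),
                       nrow(lin_p), n, dimnames = dimnames(lin_p))

    mats[[paste0(engine, ".protein_spectral_count")]] <-
      quant_matrix(counts, engine, "protein_spectral_count")
    mats[[paste0(engine, ".peptide_spectral_count")]] <-
      quant_matrix(counts_p, engine, "peptide_spectral_count")
    mats[[paste0(engine, ".protein_LFQ")]] <-
      quant_matrix(lin, engine, "protein_LFQ")
    mats[[paste0(engine, ".peptide_LFQ")]] <-
      quant_matrix(lin_p, engine, "peptide_LFQ")
    mats[[paste0(engine, ".iBAQ")]] <-
      quant_matrix(ibaq, engine, "iBAQ")
  }
  list(matrices = mats, sim_pars = sim_pars)
}

#' Generate a complete synthetic BAL proteomics dataset
#'
#' Runs the full generative model of [cohort_design()]: clinical table,
#' ground truth (planted effects, cancer-exclusive proteins, gene map,
#' annotation categories, contaminants), latent abundances, the ten raw
#' quantitative matrices, and technical replicate runs. Identical design
#' (including its seed) gives bit-identical output.
#'
#' @param design A [cohort_design()].
#' @return A `bal_dataset` list with elements `clinical`, `matrices` (named
#'   list of [quant_matrix()]), `replicate_map` (named character vector,
#'   run id -> replicate group), `truth`, `latent`, `design`, and internal
#'   simulation state `sim`.
#' @export
#' @examples
#' d <- cohort_design(n_patients = 12, case_fraction = 0.5, n_converts = 2,
#'                    n_suspicious = 0, n_replicate_pairs = 2,
#'                    n_proteins = 50, n_regulated = 5, seed = 7)
#' ds <- generate_cohort(d)
#' names(ds$matrices)
generate_cohort <- function(design) {
  validate_design(design)
  set.seed(design$seed)
  clinical <- simulate_clinical(design)
  truth <- simulate_truth(design)
  lat <- simulate_latent(design, clinical, truth)
  sim <- simulate_engine_matrices(lat$latent, design)
  dataset <- structure(
    list(clinical = clinical,
         matrices = sim$matrices,
         replicate_map = stats::setNames(clinical$sample_id, clinical$sample_id),
         truth = truth,
         latent = lat$latent,
         design = design,
         sim = list(pars = sim$sim_pars, base = lat$base,
                    batch_offsets = lat$batch_offsets)),
    class = "bal_dataset"
  )
  if (design$n_replicate_pairs > 0) {
    dataset <- make_replicates(dataset, design$n_replicate_pairs,
                               design$replicate_noise_sd)
  }
  dataset
}

#' @export
print.bal_dataset <- function(x, ...) {
  cat(sprintf("bal_dataset: %d patients, %d runs, %d proteins, %d matrices\n",
              nrow(x$clinical), length(x$replicate_map),
              x$design$n_proteins, length(x$matrices)))
  invisible(x)
}

#' Add technical replicate runs to a synthetic dataset
#'
#' Selected samples are re-measured: the same latent protein abundances are
#' observed again with fresh measurement noise (at `within_noise_sd`, smaller
#' than the engine noise) and fresh detection draws, and the replicate run is
#' assigned to a different batch (receiving that batch's offset). Replicate
#' columns are named `<sample_id>_r2` and share the original sample's
#' replicate group.
#'
#' @param dataset A `bal_dataset`.
#' @param n_replicate_pairs Number of samples to replicate.
#' @param within_noise_sd Measurement noise sd of the replicate runs.
#' @return The dataset with replicate columns appended to every matrix and
#'   `replicate_map` extended.
#' @export
make_replicates <- function(dataset, n_replicate_pairs,
                            within_noise_sd = dataset$design$replicate_noise_sd) {
  stopifnot(inherits(dataset, "bal_dataset"))
  if (within_noise_sd < 0) stop("`within_noise_sd` must be nonnegative")
  if (n_replicate_pairs == 0) return(dataset)
  design <- dataset$design
  n <- nrow(dataset$clinical)
  if (n_replicate_pairs > n) {
    stop("`n_replicate_pairs` exceeds the number of samples")
  }
  chosen <- sort(sample.int(n, n_replicate_pairs))
  new_batch <- (dataset$clinical$batch[chosen] %% design$n_batches) + 1L
  # latent of the replicate run: same biology, the new batch's offset
  lat_rep <- dataset$sim$base[, chosen, drop = FALSE] +
    dataset$sim$batch_offsets[, new_batch, drop = FALSE]
  lat_orig <- dataset$latent[, chosen, drop = FALSE]
  lat_rep[!is.finite(lat_orig)] <- -Inf
  # biological noise of the aliquot is shared with the original draw
  bio <- lat_orig -
    (dataset$sim$base[, chosen, drop = FALSE] +
       dataset$sim$batch_offsets[, dataset$clinical$batch[chosen], drop = FALSE])
  bio[!is.finite(bio)] <- 0
  lat_rep <- lat_rep + bio
  colnames(lat_rep) <- paste0(dataset$clinical$sample_id[chosen], "_r2")
  rownames(lat_rep) <- rownames(dataset$latent)

  rep_sim <- simulate_engine_matrices(lat_rep, design,
                                      sim_pars = dataset$sim$pars,
                                      noise_sd = within_noise_sd)
  for (nm in names(dataset$matrices)) {
    m <- dataset$matrices[[nm]]
    dataset$matrices[[nm]] <- qm_replace(
      m, cbind(m$values, rep_sim$matrices[[nm]]$values))
  }
  dataset$replicate_map <- c(
    dataset$replicate_map,
    stats::setNames(dataset$clinical$sample_id[chosen], colnames(lat_rep))
  )
  dataset$latent <- cbind(dataset$latent, lat_rep)
  dataset
}

#' Simulate external study regulation tables
#'
#' Builds literature-style gene-level regulation tables for `n_studies`
#' external experiments, concordant with the dataset's planted truth with
#' probability `concordance` per reported gene, for exercising the
#' multi-study consensus stage without curated literature data.
#'
#' @param truth Ground-truth element of a `bal_dataset`.
#' @param n_studies Number of external studies.
#' @param concordance Probability that a study reports a truly regulated gene
#'   in the true direction (otherwise flipped).
#' @param report_rate Probability that a study reports a regulated gene at
#'   all (otherwise NS/absent).
#' @param contexts Sample-matrix contexts to cycle through.
#' @param seed Integer seed.
#' @return Long data.frame with columns `gene`, `study_id`, `context`,
#'   `direction`.
#' @export
simulate_study_tables <- function(truth, n_studies = 8, concordance = 0.8,
                                  report_rate = 0.6,
                                  contexts = c("BAL", "BAL cells", "plasma",
                                               "tissue"),
                                  seed = 1L) {
  set.seed(seed)
  reg <- truth$regulated
  if (!nrow(reg)) {
    return(data.frame(gene = character(), study_id = character(),
                      context = character(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  genes <- unname(truth$gene_map[reg$protein])
  dirs <- reg$direction
  keep1 <- !duplicated(genes)
  genes <- genes[keep1]
  dirs <- dirs[keep1]
  out <- list()
  for (s in seq_len(n_studies)) {
    reported <- stats::runif(length(genes)) < report_rate
    flip <- stats::runif(length(genes)) > concordance
    dir_s <- ifelse(flip, ifelse(dirs == "up", "down", "up"), dirs)
    out[[s]] <- data.frame(
      gene = genes[reported],
      study_id = sprintf("study_%02d", s),
      context = contexts[((s - 1) %% length(contexts)) + 1],
      direction = dir_s[reported],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
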