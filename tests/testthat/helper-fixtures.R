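# Shared fixtures and independent oracles used across the test files.

# quant_matrix from a bare matrix, auto-naming rows/columns
qm <- function(x, engine = "A", quant_type = "protein_spectral_count",
               variant = "raw") {
  if (is.null(rownames(x))) rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  quant_matrix(x, engine = engine, quant_type = quant_type, variant = variant)
}

small_design <- function(...) {
  defaults <- list(n_patients = 20, case_fraction = 0.5, n_converts = 2,
                   n_suspicious = 0, n_replicate_pairs = 2, n_proteins = 60,
                   n_regulated = 8, n_cancer_exclusive = 2,
                   n_contaminants = 3, seed = 42)
  do.call(cohort_design, utils::modifyList(defaults, list(...)))
}

# a design with every stochastic nuisance switched off (no measurement
# noise, no dropout, no batch/biological variation)
noiseless_design <- function(...) {
  defaults <- list(n_patients = 10, case_fraction = 0.5, n_converts = 0,
                   n_suspicious = 0, n_replicate_pairs = 0, n_proteins = 40,
                   n_regulated = 10, n_cancer_exclusive = 0,
                   n_contaminants = 0, biological_sd = 0, batch_sd = 0,
                   engine_noise_sd = 0, engine_b_missing_rate = 0,
                   dropout_midpoint = -1000, seed = 5)
  do.call(cohort_design, utils::modifyList(defaults, list(...)))
}

# independent Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j)*n/j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(p[o][i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

# exhaustive-enumeration upper-tail hypergeometric: draw n from N of which
# the first K are category members; fraction of draws with overlap >= k
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(matrix(draws <= K, nrow(draws)) |> colSums() >= k)
}

# enrichment p from the package for given (N, K, n, k) via constructed sets
hyper_tail_pkg <- function(N, K, n, k) {
  bg <- sprintf("g%02d", seq_len(N))
  cat_set <- bg[seq_len(K)]
  query <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
  ann <- annotation_set(list(cat = cat_set), bg)
  hypergeom_enrich(query, ann)$p
}
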