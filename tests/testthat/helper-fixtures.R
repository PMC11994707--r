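# Fixture builders and independent brute-force oracles shared across tests.

# Small cell_dataset from a dense count matrix and label vectors.
toy_dataset <- function(counts, patient, cell_type,
                        region = rep("core", ncol(counts)),
                        tam_subtype = NULL, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(counts)))
  ann <- data.frame(patient = patient, region = region,
                    cell_type = cell_type, stringsAsFactors = FALSE)
  if (!is.null(tam_subtype)) ann$tam_subtype <- tam_subtype
  cell_dataset(counts, gene_ids, paste0("c", seq_len(ncol(counts))), ann)
}

# Random small cohort for oracle-equivalence checks.
random_toy_dataset <- function(n_patients = 3, n_cells = 10, n_genes = 6,
                               seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, 2), nrow = n_genes)
  rownames(counts) <- c("CXCL9", "SPP1",
                        paste0("g", seq_len(n_genes - 2)))
  patient <- sort(sample(paste0("P", seq_len(n_patients)), n_cells,
                         replace = TRUE))
  cell_type <- sample(c("TAM", "T_cell"), n_cells, replace = TRUE,
                      prob = c(0.7, 0.3))
  region <- sample(c("core", "normal"), n_cells, replace = TRUE)
  toy_dataset(counts, patient, cell_type, region)
}

# Naive-loop oracle for the adjusted-means calculation: explicit loops over
# raw counts, no matrix algebra shared with the implementation.
oracle_adjusted_means <- function(ds, cell_type) {
  counts <- as.matrix(ds$counts)
  ann <- ds$annotation
  patients <- unique(ann$patient[ann$cell_type == cell_type])
  patients <- unique(ann$patient)[unique(ann$patient) %in% patients]
  mean_counts <- matrix(NA_real_, nrow(counts), length(patients),
                        dimnames = list(rownames(counts), patients))
  patient_mean <- numeric(length(patients))
  names(patient_mean) <- patients
  for (p in patients) {
    idx <- which(ann$patient == p & ann$cell_type == cell_type)
    for (g in seq_len(nrow(counts))) {
      s <- 0
      for (i in idx) s <- s + counts[g, i]
      mean_counts[g, p] <- s / length(idx)
    }
    patient_mean[p] <- sum(mean_counts[, p]) / nrow(counts)
  }
  cohort_mean <- sum(patient_mean) / length(patients)
  scaling <- patient_mean / cohort_mean
  adjusted <- mean_counts
  for (p in patients) adjusted[, p] <- mean_counts[, p] * scaling[p]
  list(mean_counts = mean_counts, patient_mean = patient_mean,
       cohort_mean = cohort_mean, scaling = scaling, adjusted = adjusted)
}

# Exact two-sided Fisher p by full enumeration of tables with the observed
# margins (sum of probabilities of tables at most as probable).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) dhyper(x, c1, n - c1, r1), numeric(1))
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand product-limit estimator (deaths before censorings at ties).
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    deaths <- sum(time == ut[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    out$surv[i] <- s
  }
  out
}

# Direct O-E/V two-group log-rank statistic.
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ut) {
    n <- sum(time >= t); n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Soft-threshold operator for the orthonormal-design LASSO closed form.
soft <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

# A degenerate config whose single-cell part is minimal, for stages that
# only need the latent polarity/feature/survival tables.
truth_only_config <- function(n_patients, seed, ...) {
  synthetic_config(n_patients = n_patients, cells_per_patient = 1,
                   n_genes = 3, n_mito_genes = 0, seed = seed, ...)
}

# Byte-level fingerprint of a model object (leak detection).
digest_model <- function(model) serialize(model, NULL, ascii = TRUE)

# Latent polarity and downstream tables without the count matrix cost.
make_truth <- function(n_patients, seed, ...) {
  cfg <- truth_only_config(n_patients, seed, ...)
  sc <- suppressWarnings(generate_sc_cohort(cfg))
  list(cfg = cfg, truth = sc$truth)
}
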