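#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure the downstream analyses assume: a latent
#' per-patient polarity on the log CXCL9:SPP1 scale, mutually exclusive marker
#' expression inside TAMs, polarity-coupled bulk expression, survival and
#' feature tables. Defaults describe a desk-scale multi-regional cohort:
#' 24 patients (the size of the single-cell compartment the method targets),
#' 300 cells each across three tissue regions, negative-binomial counts.
#'
#' @param n_patients number of patients.
#' @param cells_per_patient cells drawn per patient.
#' @param n_genes total genes, including the two marker genes and
#'   `n_mito_genes` mitochondrial genes.
#' @param regions tissue region labels.
#' @param region_probs probability of a cell falling in each region.
#' @param cell_types cell-type labels; must include `tam_type`.
#' @param cell_type_fractions named list (one entry per region) of probability
#'   vectors over `cell_types`; each must sum to 1 within 1e-9.
#' @param tam_type label of the tumor-associated macrophage type.
#' @param polarity_sd standard deviation of the latent polarity z_P
#'   (log CS scale).
#' @param base_rate baseline expected count per gene per cell.
#' @param coupling named per-cell-type coefficient linking z_P to the CXCL9
#'   (positively) and SPP1 (negatively) log-rates; types not named get 0.
#' @param dispersion negative-binomial overdispersion phi > 0
#'   (variance = mu + phi * mu^2; NB size = 1/phi).
#' @param n_mito_genes number of genes emitted with `mito_prefix` names so QC
#'   is exercisable.
#' @param mito_prefix name prefix for mitochondrial genes.
#' @param n_informative_features,n_noise_features feature-table block sizes.
#' @param informative_weights per-feature coefficients on z_P for the
#'   informative block (recycled to length `n_informative_features`).
#' @param feature_noise_sd additive Gaussian noise sd for informative
#'   features.
#' @param bulk_noise_sd sd of multiplicative lognormal noise on bulk marker
#'   TPM.
#' @param n_bulk_genes genes in the bulk matrix (markers included).
#' @param hazard_ratio_per_unit hazard multiplier per unit polarity; hazard is
#'   `base_hazard * hazard_ratio_per_unit^(-z_P)`, so higher polarity means
#'   lower hazard.
#' @param base_hazard baseline exponential event rate.
#' @param censor_rate probability a subject is censored (uniformly before its
#'   event time).
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 24,
                             cells_per_patient = 300,
                             n_genes = 200,
                             regions = c("normal", "peritumor", "core"),
                             region_probs = c(1, 1, 1) / 3,
                             cell_types = c("TAM", "T_cell", "NK_cell",
                                            "B_cell", "Fibroblast",
                                            "Hepatocyte"),
                             cell_type_fractions = NULL,
                             tam_type = "TAM",
                             polarity_sd = 1.0,
                             base_rate = 1.0,
                             coupling = c(TAM = 1.0, T_cell = 0.5,
                                          Fibroblast = 0.5),
                             dispersion = 0.5,
                             n_mito_genes = 5,
                             mito_prefix = "MT-",
                             n_informative_features = 5,
                             n_noise_features = 95,
                             informative_weights = 1.0,
                             feature_noise_sd = 0.3,
                             bulk_noise_sd = 0.2,
                             n_bulk_genes = 100,
                             hazard_ratio_per_unit = 3.0,
                             base_hazard = 0.1,
                             censor_rate = 0.3,
                             seed = 1L) {
  if (is.null(cell_type_fractions)) {
    # TAMs enriched toward the tumor core, hepatocytes depleted there
    cell_type_fractions <- list(
      normal    = c(0.10, 0.30, 0.10, 0.05, 0.10, 0.35),
      peritumor = c(0.25, 0.30, 0.10, 0.05, 0.15, 0.15),
      core      = c(0.35, 0.25, 0.10, 0.05, 0.20, 0.05))
    names(cell_type_fractions) <- regions[seq_len(3)]
    cell_type_fractions <- lapply(cell_type_fractions, function(p) {
      stats::setNames(p[seq_along(cell_types)] /
                        sum(p[seq_along(cell_types)]), cell_types)
    })
  }
  cfg <- list(n_patients = as.integer(n_patients),
              cells_per_patient = as.integer(cells_per_patient),
              n_genes = as.integer(n_genes),
              regions = regions, region_probs = region_probs,
              cell_types = cell_types,
              cell_type_fractions = cell_type_fractions,
              tam_type = tam_type,
              polarity_sd = polarity_sd, base_rate = base_rate,
              coupling = coupling, dispersion = dispersion,
              n_mito_genes = as.integer(n_mito_genes),
              mito_prefix = mito_prefix,
              n_informative_features = as.integer(n_informative_features),
              n_noise_features = as.integer(n_noise_features),
              informative_weights = informative_weights,
              feature_noise_sd = feature_noise_sd,
              bulk_noise_sd = bulk_noise_sd,
              n_bulk_genes = as.integer(n_bulk_genes),
              hazard_ratio_per_unit = hazard_ratio_per_unit,
              base_hazard = base_hazard,
              censor_rate = censor_rate, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$cells_per_patient >= 1,
            cfg$n_genes >= 3, cfg$dispersion > 0, cfg$base_rate > 0,
            cfg$polarity_sd >= 0, cfg$hazard_ratio_per_unit > 0,
            cfg$censor_rate >= 0, cfg$censor_rate <= 1,
            cfg$n_mito_genes >= 0,
            cfg$n_genes > cfg$n_mito_genes + 2)
  if (abs(sum(cfg$region_probs) - 1) > 1e-9)
    stop("region_probs must sum to 1")
  if (!cfg$tam_type %in% cfg$cell_types)
    stop("tam_type must be one of cell_types")
  for (r in cfg$regions) {
    p <- cfg$cell_type_fractions[[r]]
    if (is.null(p)) stop("cell_type_fractions lacks region '", r, "'")
    if (length(p) != length(cfg$cell_types))
      stop("cell_type_fractions['", r, "'] has wrong length")
    if (abs(sum(p) - 1) > 1e-9)
      stop("cell_type_fractions['", r, "'] must sum to 1")
  }
  invisible(cfg)
}

# Gene universe: CXCL9, SPP1, mito genes, then filler genes.
synthetic_gene_ids <- function(cfg) {
  n_other <- cfg$n_genes - 2L - cfg$n_mito_genes
  c("CXCL9", "SPP1",
    if (cfg$n_mito_genes > 0)
      paste0(cfg$mito_prefix, seq_len(cfg$n_mito_genes)),
    sprintf("GENE%03d", seq_len(n_other)))
}

#' Generate a synthetic multi-patient single-cell cohort
#'
#' Draws one latent polarity `z_P ~ N(0, polarity_sd)` per patient. Cells are
#' assigned a region and, per region, a cell type. For a cell of type `C` with
#' coupling coefficient `k_C`, the CXCL9 rate is
#' `base_rate * exp(+k_C * z_P)` and the SPP1 rate
#' `base_rate * exp(-k_C * z_P)` (in expectation over cells). TAM cells
#' additionally carry an anti-correlated Bernoulli state `w = +/-1` entering
#' both marker log-rates as `k * (z_P + w)`, normalized by `cosh(k)` so the
#' patient-level means above are preserved exactly; this plants cell-level
#' mutual exclusivity that vanishes when the coupling is 0. All other genes
#' have rate `base_rate`. Counts are negative binomial with overdispersion
#' `dispersion`. TAM cells are labeled `CXCL9_TAM`/`SPP1_TAM` by their state.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (a [cell_dataset()]) and `truth` (a
#'   `planted_truth` list: `patient_polarity`, `true_groups` split at the
#'   median polarity, TAM-less `flagged_patients`, and feature-block info
#'   filled in by [generate_feature_table()]).
#' @export
generate_sc_cohort <- function(config) {
  cfg <- validate_synthetic_config(config)
  set.seed(cfg$seed)
  patients <- sprintf("P%02d", seq_len(cfg$n_patients))
  z <- stats::rnorm(cfg$n_patients, 0, cfg$polarity_sd)
  names(z) <- patients

  genes <- synthetic_gene_ids(cfg)
  n_cells <- cfg$n_patients * cfg$cells_per_patient
  patient <- rep(patients, each = cfg$cells_per_patient)
  region <- sample(cfg$regions, n_cells, replace = TRUE,
                   prob = cfg$region_probs)
  cell_type <- character(n_cells)
  for (r in cfg$regions) {
    idx <- which(region == r)
    cell_type[idx] <- sample(cfg$cell_types, length(idx), replace = TRUE,
                             prob = cfg$cell_type_fractions[[r]])
  }
  is_tam <- cell_type == cfg$tam_type
  w <- numeric(n_cells)
  w[is_tam] <- sample(c(-1, 1), sum(is_tam), replace = TRUE)
  tam_subtype <- rep(NA_character_, n_cells)
  tam_subtype[is_tam] <- ifelse(w[is_tam] > 0, "CXCL9_TAM", "SPP1_TAM")

  k <- stats::setNames(rep(0, length(cfg$cell_types)), cfg$cell_types)
  k[names(cfg$coupling)] <- cfg$coupling
  kc <- k[cell_type]
  zc <- z[patient]
  # cosh normalization keeps E[rate | patient, type] at base_rate*exp(+-k*z)
  norm <- ifelse(is_tam, cosh(kc), 1)
  rate_cx <- cfg$base_rate * exp(kc * (zc + w)) / norm
  rate_sp <- cfg$base_rate * exp(-kc * (zc + w)) / norm

  size <- 1 / cfg$dispersion
  counts <- matrix(0, nrow = cfg$n_genes, ncol = n_cells,
                   dimnames = list(genes, NULL))
  counts["CXCL9", ] <- stats::rnbinom(n_cells, size = size, mu = rate_cx)
  counts["SPP1", ] <- stats::rnbinom(n_cells, size = size, mu = rate_sp)
  other <- setdiff(genes, c("CXCL9", "SPP1"))
  counts[other, ] <- stats::rnbinom(length(other) * n_cells, size = size,
                                    mu = cfg$base_rate)

  cell_ids <- sprintf("%s_C%04d", patient,
                      stats::ave(seq_len(n_cells), patient, FUN = seq_along))
  ann <- data.frame(patient = patient, region = region,
                    cell_type = cell_type, tam_subtype = tam_subtype,
                    stringsAsFactors = FALSE)
  ds <- cell_dataset(counts, genes, cell_ids, ann, tam_type = cfg$tam_type)

  no_tam <- patients[!patients %in% unique(patient[is_tam])]
  if (length(no_tam))
    warning("patients without TAM cells (flagged): ",
            paste(no_tam, collapse = ", "))
  med <- stats::median(z)
  truth <- structure(list(
    patient_polarity = z,
    true_groups = stats::setNames(ifelse(z > med, "high", "low"), patients),
    flagged_patients = no_tam,
    informative_feature_ids = NULL,
    informative_weights = NULL), class = "planted_truth")
  list(dataset = ds, truth = truth)
}

#' Generate a matched bulk TPM matrix
#'
#' CXCL9 and SPP1 columns are proportional to `exp(+z_P)` and `exp(-z_P)` with
#' multiplicative lognormal noise (`bulk_noise_sd`); other genes are drawn
#' independently of the polarity. Columns are rescaled to sum to one million
#' (TPM), which leaves all within-sample ratios unchanged.
#'
#' @param truth a `planted_truth` from [generate_sc_cohort()].
#' @param config the same [synthetic_config()].
#' @return numeric matrix, genes x patients, TPM scale.
#' @export
generate_bulk <- function(truth, config) {
  cfg <- validate_synthetic_config(config)
  set.seed(cfg$seed + 1L)
  z <- truth$patient_polarity
  n <- length(z)
  n_other <- cfg$n_bulk_genes - 2L
  genes <- c("CXCL9", "SPP1", sprintf("BGENE%03d", seq_len(n_other)))
  base <- 50
  m <- matrix(0, nrow = cfg$n_bulk_genes, ncol = n,
              dimnames = list(genes, names(z)))
  m["CXCL9", ] <- base * exp(z + stats::rnorm(n, 0, cfg$bulk_noise_sd))
  m["SPP1", ] <- base * exp(-z + stats::rnorm(n, 0, cfg$bulk_noise_sd))
  m[genes[-(1:2)], ] <- base *
    exp(stats::rnorm(n_other * n, 0, 0.5))
  sweep(m, 2L, colSums(m), "/") * 1e6
}

#' Generate polarity-coupled survival times
#'
#' Event times are exponential with hazard
#' `base_hazard * hazard_ratio_per_unit^(-z_P)`: higher polarity, lower
#' hazard, matching the favorable prognosis of a high CXCL9:SPP1 ratio.
#' A fraction `censor_rate` of subjects is independently censored at a
#' uniform time before their event.
#'
#' @param truth a `planted_truth`.
#' @param config the [synthetic_config()].
#' @return data.frame `id`, `time`, `event` (1 = death observed).
#' @export
generate_survival <- function(truth, config) {
  cfg <- validate_synthetic_config(config)
  set.seed(cfg$seed + 2L)
  z <- truth$patient_polarity
  n <- length(z)
  hazard <- cfg$base_hazard * cfg$hazard_ratio_per_unit^(-z)
  t_event <- stats::rexp(n, rate = hazard)
  censored <- stats::runif(n) < cfg$censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  data.frame(id = names(z), time = time,
             event = as.integer(!censored), stringsAsFactors = FALSE)
}

#' Generate a feature table with a planted informative block
#'
#' Informative features are `weight_j * z_P` plus Gaussian noise
#' (`feature_noise_sd`); noise features are standard normal. Column order is
#' shuffled so the table itself does not reveal which block a feature belongs
#' to; that information lives only in the returned truth.
#'
#' @param truth a `planted_truth`; returned updated with
#'   `informative_feature_ids` and `informative_weights`.
#' @param config the [synthetic_config()]; requires
#'   `n_informative_features >= 1`.
#' @return list with `features` (patients x features matrix) and the updated
#'   `truth`.
#' @export
generate_feature_table <- function(truth, config) {
  cfg <- validate_synthetic_config(config)
  if (cfg$n_informative_features < 1)
    stop("n_informative_features must be >= 1")
  set.seed(cfg$seed + 3L)
  z <- truth$patient_polarity
  n <- length(z)
  p_inf <- cfg$n_informative_features
  p_noise <- cfg$n_noise_features
  wts <- rep_len(cfg$informative_weights, p_inf)
  inf <- sapply(seq_len(p_inf), function(j)
    wts[j] * z + stats::rnorm(n, 0, cfg$feature_noise_sd))
  noise <- matrix(stats::rnorm(n * p_noise), nrow = n)
  x <- cbind(inf, noise)
  colnames(x) <- sprintf("feat_%03d", seq_len(p_inf + p_noise))
  rownames(x) <- names(z)
  ord <- sample(ncol(x))
  inf_names <- colnames(x)[seq_len(p_inf)]
  x <- x[, ord, drop = FALSE]
  truth$informative_feature_ids <- inf_names
  truth$informative_weights <- stats::setNames(wts, inf_names)
  list(features = x, truth = truth)
}

#' Write a full synthetic cohort to plain-text files
#'
#' Generates the single-cell cohort, bulk matrix, survival table and feature
#' table from one config and writes them as Matrix Market + TSV/CSV files,
#' plus the planted truth as JSON. The config may be a `synthetic_config` or
#' the path to a YAML file whose keys are [synthetic_config()] arguments.
#'
#' @param config a [synthetic_config()] or YAML path.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
simulate_cohort_files <- function(config, dir) {
  if (is.character(config)) {
    config <- do.call(synthetic_config, yaml::read_yaml(config))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- generate_sc_cohort(config)
  bulk <- generate_bulk(sc$truth, config)
  surv <- generate_survival(sc$truth, config)
  feat <- generate_feature_table(sc$truth, config)
  paths <- list(
    mtx = file.path(dir, "counts.mtx"),
    genes = file.path(dir, "genes.tsv"),
    cells = file.path(dir, "cells.tsv"),
    bulk = file.path(dir, "bulk_tpm.tsv"),
    survival = file.path(dir, "survival.csv"),
    features = file.path(dir, "features.csv"),
    truth = file.path(dir, "truth.json"))
  write_cell_dataset(sc$dataset, paths$mtx, paths$genes, paths$cells)
  utils::write.table(data.frame(gene = rownames(bulk), bulk,
                                check.names = FALSE),
                     paths$bulk, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(surv, paths$survival, row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(feat$features), feat$features,
                              check.names = FALSE),
                   paths$features, row.names = FALSE)
  truth <- feat$truth
  jsonlite::write_json(
    list(patient_polarity = as.list(truth$patient_polarity),
         true_groups = as.list(truth$true_groups),
         flagged_patients = truth$flagged_patients,
         informative_feature_ids = truth$informative_feature_ids,
         informative_weights = as.list(truth$informative_weights)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
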