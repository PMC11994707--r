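#' Per-patient adjusted mean counts with cohort scaling factor
#'
#' For a chosen cell type C, computes for every patient P and gene G the mean
#' raw count over that patient's cells of type C,
#' \deqn{\bar X_{P,C,G} = \frac{1}{m}\sum_{i=1}^m X^{(i)}_{P,C,G},}
#' the patient's all-gene mean \eqn{\bar X_{P,C} = \frac1g \sum_j \bar
#' X_{P,C,j}} over the full gene universe, the cohort mean \eqn{\bar X_C =
#' \frac1N \sum_k \bar X_{k,C}}, the scaling factor \eqn{S_C(P) = \bar
#' X_{P,C} / \bar X_C}, and the adjusted mean counts \eqn{\bar X^{adj}_{P,C,G}
#' = \bar X_{P,C,G} \cdot S_C(P)}. The scaling factor is computed over all
#' genes even when a `genes` subset is requested for the output; with a
#' single patient it is identically 1.
#'
#' Note the scaling factor multiplies by (rather than divides out) the
#' patient's relative depth; it cancels exactly in any within-patient gene
#' ratio such as the CS ratio, but per-gene adjusted means carry it.
#'
#' @param ds a [cell_dataset()] (raw counts; see Details in [qc_filter()]).
#' @param cell_type cell type to aggregate (default the dataset's TAM type).
#' @param genes optional character vector restricting the genes reported.
#' @return object of class `adjusted_means`: list with `cell_type`, `genes`,
#'   `patients`, `cell_counts` (m per patient), `mean_counts` (genes x
#'   patients), `patient_mean`, `cohort_mean`, `scaling`, `adjusted`
#'   (genes x patients), `n_genes_universe`, and `excluded` (patients with no
#'   cells of the type).
#' @export
compute_adjusted_means <- function(ds, cell_type = ds$tam_type,
                                   genes = NULL) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (!cell_type %in% ds$annotation$cell_type)
    stop("cell type '", cell_type, "' not present in dataset")
  all_patients <- unique(ds$annotation$patient)
  sel <- ds$annotation$cell_type == cell_type
  patients <- unique(ds$annotation$patient[sel])
  patients <- all_patients[all_patients %in% patients]  # stable order
  excluded <- setdiff(all_patients, patients)
  if (length(excluded))
    warning("patients with no ", cell_type, " cells excluded: ",
            paste(excluded, collapse = ", "))

  pat_f <- factor(ds$annotation$patient[sel], levels = patients)
  sub <- ds$counts[, sel, drop = FALSE]
  m <- as.integer(table(pat_f))
  # genes x patients sums, then divide by m -> mean counts per patient
  design <- Matrix::sparseMatrix(i = seq_len(sum(sel)),
                                 j = as.integer(pat_f), x = 1,
                                 dims = c(sum(sel), length(patients)))
  sums <- as.matrix(sub %*% design)
  mean_all <- sweep(sums, 2L, m, "/")
  dimnames(mean_all) <- list(ds$gene_ids, patients)

  g <- nrow(mean_all)
  patient_mean <- colMeans(mean_all)             # X-bar_{P,C}
  cohort_mean <- mean(patient_mean)              # X-bar_C
  if (cohort_mean == 0)
    stop("degenerate cohort: all-gene mean expression is zero for ",
         cell_type)
  scaling <- patient_mean / cohort_mean          # S_C(P)

  out_genes <- if (is.null(genes)) ds$gene_ids else {
    miss <- setdiff(genes, ds$gene_ids)
    if (length(miss)) stop("genes not in dataset: ",
                           paste(miss, collapse = ", "))
    genes
  }
  mean_counts <- mean_all[out_genes, , drop = FALSE]
  adjusted <- sweep(mean_counts, 2L, scaling, "*")
  structure(list(cell_type = cell_type, genes = out_genes,
                 patients = patients,
                 cell_counts = stats::setNames(m, patients),
                 mean_counts = mean_counts,
                 patient_mean = patient_mean,
                 cohort_mean = cohort_mean,
                 scaling = scaling,
                 adjusted = adjusted,
                 n_genes_universe = g,
                 excluded = excluded),
            class = "adjusted_means")
}

#' @export
print.adjusted_means <- function(x, ...) {
  cat("adjusted_means for cell type '", x$cell_type, "': ",
      length(x$genes), " genes x ", length(x$patients), " patients\n",
      sep = "")
  cat("  scaling factors: ",
      paste(sprintf("%s=%.3f", x$patients, x$scaling), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

new_polarity_table <- function(patient, num, den, ratio, group,
                               numerator, denominator,
                               threshold = NA_real_, rule = NA_character_) {
  structure(data.frame(patient = patient,
                       adjusted_cxcl9 = num,
                       adjusted_spp1 = den,
                       cs_ratio = ratio,
                       group = group,
                       stringsAsFactors = FALSE),
            numerator = numerator, denominator = denominator,
            threshold = threshold, threshold_rule = rule,
            class = c("polarity_table", "data.frame"))
}

#' Per-patient CS ratio from single-cell adjusted means
#'
#' The CS polarity of patient P is the ratio of the adjusted mean counts of
#' CXCL9 to those of SPP1 in TAMs,
#' \deqn{CS\_Ratio = \bar X^{adj}_{P,TAM,CXCL9} / \bar X^{adj}_{P,TAM,SPP1}.}
#' Because the scaling factor multiplies numerator and denominator alike, the
#' ratio equals the ratio of unadjusted means. Patients whose denominator is
#' zero are excluded by default; with `zero_policy = "pseudocount"` a
#' symmetric pseudocount is added to both adjusted means instead.
#'
#' @param am an [compute_adjusted_means()] result.
#' @param numerator,denominator marker gene names.
#' @param zero_policy `"exclude"` (default) or `"pseudocount"`.
#' @param pseudocount value added to both adjusted means under the
#'   pseudocount policy.
#' @return a `polarity_table` data.frame: `patient`, `adjusted_cxcl9`,
#'   `adjusted_spp1`, `cs_ratio`, `group` (all `"unassigned"` until
#'   [dichotomize()]; denominator-zero patients `"excluded"` with `NA` ratio).
#' @export
cs_ratio_sc <- function(am, numerator = "CXCL9", denominator = "SPP1",
                        zero_policy = c("exclude", "pseudocount"),
                        pseudocount = 0.5) {
  stopifnot(inherits(am, "adjusted_means"))
  zero_policy <- match.arg(zero_policy)
  for (gene in c(numerator, denominator))
    if (!gene %in% rownames(am$adjusted))
      stop("gene '", gene, "' absent from adjusted means")
  num <- am$adjusted[numerator, ]
  den <- am$adjusted[denominator, ]
  cs_ratio_core(am$patients, num, den, zero_policy, pseudocount,
                numerator, denominator)
}

cs_ratio_core <- function(patients, num, den, zero_policy, pseudocount,
                          numerator, denominator) {
  if (zero_policy == "pseudocount") {
    num <- num + pseudocount
    den <- den + pseudocount
  }
  ok <- den > 0
  ratio <- ifelse(ok, num / den, NA_real_)
  group <- ifelse(ok, "unassigned", "excluded")
  new_polarity_table(patients, num, den, ratio, group,
                     numerator, denominator)
}

#' Per-sample CS ratio from bulk expression
#'
#' For bulk cohorts the CXCL9/SPP1 expression ratio represents the polarity
#' directly; input should be TPM or another within-sample-normalized unit
#' (any per-sample rescaling cancels in the ratio).
#'
#' @param tpm numeric matrix or data.frame, genes x samples, with gene names
#'   as rownames (or a `gene` first column).
#' @inheritParams cs_ratio_sc
#' @return a `polarity_table` with one row per sample.
#' @export
cs_ratio_bulk <- function(tpm, numerator = "CXCL9", denominator = "SPP1",
                          zero_policy = c("exclude", "pseudocount"),
                          pseudocount = 0.5) {
  zero_policy <- match.arg(zero_policy)
  if (is.data.frame(tpm)) {
    if (is.character(tpm[[1L]]) || !is.null(tpm$gene)) {
      rn <- if (!is.null(tpm$gene)) tpm$gene else tpm[[1L]]
      tpm <- as.matrix(tpm[, vapply(tpm, is.numeric, TRUE), drop = FALSE])
      rownames(tpm) <- rn
    } else tpm <- as.matrix(tpm)
  }
  for (gene in c(numerator, denominator))
    if (!gene %in% rownames(tpm))
      stop("gene '", gene, "' absent from expression matrix")
  cs_ratio_core(colnames(tpm), tpm[numerator, ], tpm[denominator, ],
                zero_policy, pseudocount, numerator, denominator)
}

#' Split patients into high/low polarity groups
#'
#' Assigns `group = "high"` iff `cs_ratio > threshold` (ties at the threshold
#' go to `"low"`). The threshold is the median of the non-excluded ratios
#' under the `"median"` rule, or a fixed numeric cutoff (the responder
#' analysis uses 1.0). Excluded patients keep their label.
#'
#' @param pt a `polarity_table`.
#' @param rule `"median"` or a single numeric threshold.
#' @return the table with `group` filled in and attributes `threshold` and
#'   `threshold_rule` recorded.
#' @export
dichotomize <- function(pt, rule = "median") {
  stopifnot(inherits(pt, "polarity_table"))
  ok <- pt$group != "excluded" & !is.na(pt$cs_ratio)
  if (is.numeric(rule)) {
    threshold <- rule
    rule_name <- "fixed"
  } else if (identical(rule, "median")) {
    if (sum(ok) < 2)
      stop("median rule needs at least 2 non-excluded patients")
    if (length(unique(pt$cs_ratio[ok])) == 1L)
      stop("all CS ratios identical; no median split possible")
    threshold <- stats::median(pt$cs_ratio[ok])
    rule_name <- "median"
  } else stop("rule must be \"median\" or a numeric threshold")
  pt$group[ok] <- ifelse(pt$cs_ratio[ok] > threshold, "high", "low")
  attr(pt, "threshold") <- threshold
  attr(pt, "threshold_rule") <- rule_name
  pt
}

#' @export
print.polarity_table <- function(x, ...) {
  cat("polarity_table: ", nrow(x), " patients (",
      sum(x$group == "high"), " high, ", sum(x$group == "low"), " low, ",
      sum(x$group == "excluded"), " excluded)\n", sep = "")
  if (!is.na(attr(x, "threshold")))
    cat("  threshold: ", format(attr(x, "threshold")), " (",
        attr(x, "threshold_rule"), " rule)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}
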