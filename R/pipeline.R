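#' Run the CS-polarity pipeline from a config
#'
#' Orchestrates the analysis stages in dependency order on files produced by
#' [simulate_cohort_files()] or supplied by the user: QC, per-patient CS
#' polarity (TAM adjusted means, ratio, median dichotomization), tissue
#' composition (Ro/e), CXCL9/SPP1 mutual exclusivity, and survival
#' stratification of the polarity groups. Each stage writes a TSV/JSON
#' output, and a machine-readable manifest (parameter values, seed, input
#' file hashes, package version) makes a run reproducible: re-running with
#' the same config and inputs gives byte-identical numeric outputs.
#'
#' @param config named list or YAML path with entries: `mtx`, `genes`,
#'   `cells` (single-cell inputs), optional `survival` (CSV with id, time,
#'   event), `out_dir`, and optional parameter overrides `qc` (list of
#'   [qc_filter()] args), `roe_threshold`, `ratio_rule`, `seed`.
#' @param stages subset of `c("qc", "polarity", "roe", "exclusivity",
#'   "survival")`; dependency order is enforced internally.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("qc", "polarity", "roe", "exclusivity",
                                    "survival")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$out_dir %||% "cspolar_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  inputs <- c(mtx = config$mtx, genes = config$genes, cells = config$cells)
  for (nm in names(inputs))
    if (is.null(inputs[[nm]]) || !file.exists(inputs[[nm]]))
      stop("missing input for stage 'qc': ", nm)
  ds <- read_cell_dataset(config$mtx, config$genes, config$cells)

  if ("qc" %in% stages) {
    qc_args <- config$qc %||% list()
    ds <- do.call(qc_filter, c(list(ds = ds), qc_args))
    results$qc <- dim(ds)
  }

  pt <- NULL
  if ("polarity" %in% stages) {
    am <- compute_adjusted_means(ds)
    pt <- dichotomize(cs_ratio_sc(am), rule = config$ratio_rule %||% "median")
    utils::write.table(as.data.frame(pt),
                       file.path(out_dir, "polarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$polarity <- pt
  }

  if ("roe" %in% stages) {
    roe <- compute_roe(ds)
    enriched <- call_enrichment(roe, config$roe_threshold %||% 2.0)
    utils::write.table(
      data.frame(cell_type = rownames(roe$ratio), roe$ratio,
                 check.names = FALSE),
      file.path(out_dir, "roe.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    results$roe <- list(roe = roe, enriched = enriched)
  }

  if ("exclusivity" %in% stages) {
    ex <- fisher_exact_or(dichotomize_coexpression(ds))
    jsonlite::write_json(
      list(table = ex$table, odds_ratio = ex$odds_ratio,
           p_value = ex$p_value),
      file.path(out_dir, "exclusivity.json"), auto_unbox = TRUE,
      digits = NA)
    results$exclusivity <- ex
  }

  if ("survival" %in% stages) {
    if (is.null(config$survival) || !file.exists(config$survival %||% "")) {
      warning("survival CSV not provided; survival stage skipped")
    } else if (is.null(pt)) {
      stop("missing upstream output for stage 'survival': polarity")
    } else {
      surv <- utils::read.csv(config$survival, stringsAsFactors = FALSE)
      merged <- merge(surv, as.data.frame(pt)[, c("patient", "group")],
                      by.x = "id", by.y = "patient")
      merged <- merged[merged$group %in% c("high", "low"), , drop = FALSE]
      st <- as_survival_table(merged)
      lr <- logrank(st)
      jsonlite::write_json(
        list(logrank_chi2 = lr$chi2, logrank_p = lr$p,
             n = nrow(st)),
        file.path(out_dir, "survival.json"), auto_unbox = TRUE, digits = NA)
      results$survival <- list(km = km_curve(st), logrank = lr)
    }
  }

  in_files <- c(inputs, survival = config$survival)
  in_files <- in_files[!vapply(in_files, is.null, TRUE)]
  manifest <- list(
    package = "cspolar",
    version = as.character(utils::packageVersion("cspolar")),
    stages = stages,
    parameters = list(qc = config$qc %||% list(),
                      roe_threshold = config$roe_threshold %||% 2.0,
                      ratio_rule = config$ratio_rule %||% "median"),
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(unlist(in_files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
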