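#' Tissue-enrichment ratio Ro/e
#'
#' Cross-tabulates cells by cell type and tissue group and compares observed
#' counts with the expected counts of the chi-squared independence model,
#' `E_ct = row_c * col_t / n`. The ratio `Ro/e = O/E` quantifies how strongly
#' a cell type concentrates in a tissue; cells are pooled across patients.
#'
#' @param ann per-cell annotation data.frame (e.g. `ds$annotation`) or a
#'   [cell_dataset()].
#' @param cell_type_col column holding the cell type label.
#' @param group_by column holding the tissue group label.
#' @return object of class `roe_matrix`: list with integer `observed`,
#'   numeric `expected` and `ratio` matrices (cell types x tissues), plus
#'   `row_totals`, `col_totals`, `n`.
#' @export
compute_roe <- function(ann, cell_type_col = "cell_type",
                        group_by = "region") {
  if (inherits(ann, "cell_dataset")) ann <- ann$annotation
  ct <- ann[[cell_type_col]]
  tis <- ann[[group_by]]
  if (is.null(ct) || is.null(tis))
    stop("annotation lacks '", cell_type_col, "' or '", group_by, "'")
  if (anyNA(ct) || anyNA(tis)) stop("every cell must be labeled")
  # keep declared-but-empty tissue levels visible so they can be reported
  obs <- table(factor(ct), if (is.factor(tis)) tis else factor(tis))
  empty <- colSums(obs) == 0
  if (any(empty)) {
    warning("tissue groups with zero cells dropped: ",
            paste(colnames(obs)[empty], collapse = ", "))
    obs <- obs[, !empty, drop = FALSE]
  }
  if (ncol(obs) < 2) stop("need at least 2 tissue groups")
  obs <- unclass(obs)
  n <- sum(obs)
  row_tot <- rowSums(obs)
  col_tot <- colSums(obs)
  expected <- outer(row_tot, col_tot) / n
  structure(list(observed = obs, expected = expected,
                 ratio = obs / expected,
                 row_totals = row_tot, col_totals = col_tot, n = n),
            class = "roe_matrix")
}

#' @export
print.roe_matrix <- function(x, ...) {
  cat("roe_matrix: ", nrow(x$observed), " cell types x ",
      ncol(x$observed), " tissues, n = ", x$n, " cells\n", sep = "")
  print(round(x$ratio, 3))
  invisible(x)
}

#' Call tissue enrichment from an Ro/e matrix
#'
#' A (cell type, tissue) pair is called enriched iff its ratio is strictly
#' greater than the threshold (2 by convention; a ratio of exactly 2 is not
#' enriched).
#'
#' @param roe a [compute_roe()] result.
#' @param threshold strict lower bound for an enrichment call.
#' @return logical matrix, cell types x tissues.
#' @export
call_enrichment <- function(roe, threshold = 2.0) {
  stopifnot(inherits(roe, "roe_matrix"))
  roe$ratio > threshold
}

#' Minimum cells to capture a rare population
#'
#' Smallest number of sampled cells n such that at least `k` cells of a
#' population at frequency `freq` are captured with probability at least
#' `prob`, i.e. `P(X >= k) >= prob` with `X ~ Binomial(n, freq)`. Solved by
#' monotone bracketing plus binary search on the exact binomial tail (no
#' normal approximation). The canonical design question — at least 10 cells
#' of a 1% cluster with 95% probability — is
#' `min_cells_required(0.01, 10, 0.95)`.
#'
#' @param freq population frequency in (0, 1].
#' @param k minimum number of cells to capture (>= 1).
#' @param prob required capture probability in (0, 1).
#' @return integer, the minimal n.
#' @export
min_cells_required <- function(freq, k = 10, prob = 0.95) {
  stopifnot(freq > 0, freq <= 1, k >= 1, prob > 0, prob < 1)
  k <- as.integer(k)
  tail_ok <- function(n)
    stats::pbinom(k - 1L, n, freq, lower.tail = FALSE) >= prob
  lo <- k
  if (tail_ok(lo)) return(lo)
  hi <- lo
  while (!tail_ok(hi)) hi <- hi * 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (tail_ok(mid)) hi <- mid else lo <- mid
  }
  hi
}
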