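#' Dichotomized co-expression table for two genes
#'
#' Within a chosen cell type (TAMs by default), each cell is called "on" for
#' a gene iff its raw count exceeds `on_threshold` (default 0: detected at
#' all). Returns the 2x2 joint table with rows geneA on/off and columns geneB
#' on/off, i.e. `[both_on, A_only; B_only, neither]`.
#'
#' @param ds a [cell_dataset()].
#' @param geneA,geneB gene names.
#' @param cell_type cells to include (default the TAM type).
#' @param on_threshold count strictly above which a gene is "on".
#' @return 2x2 integer matrix with dimnames `A_on/A_off` x `B_on/B_off`.
#' @export
dichotomize_coexpression <- function(ds, geneA = "CXCL9", geneB = "SPP1",
                                     cell_type = ds$tam_type,
                                     on_threshold = 0) {
  stopifnot(inherits(ds, "cell_dataset"))
  for (gene in c(geneA, geneB))
    if (!gene %in% ds$gene_ids) stop("gene '", gene, "' not in dataset")
  sel <- ds$annotation$cell_type == cell_type
  if (!any(sel)) stop("no cells of type '", cell_type, "'")
  a_on <- as.vector(ds$counts[geneA, sel]) > on_threshold
  b_on <- as.vector(ds$counts[geneB, sel]) > on_threshold
  tab <- matrix(c(sum(a_on & b_on), sum(a_on & !b_on),
                  sum(!a_on & b_on), sum(!a_on & !b_on)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A_on", "A_off"), c("B_on", "B_off")))
  storage.mode(tab) <- "integer"
  tab
}

#' Odds ratio and Fisher's exact test for a 2x2 table
#'
#' The odds ratio is the sample cross-ratio `(a*d)/(b*c)` for the table
#' `[a, b; c, d]`; with `b*c = 0` it is `Inf` when `a*d > 0`, `0` when
#' `a*d = 0` and some off-diagonal mass exists, and `NaN` for an all-diagonal
#' degenerate table. The p-value is the standard two-sided Fisher exact test
#' (hypergeometric tail). An odds ratio below 1 with small p indicates
#' mutual exclusivity of the two "on" calls.
#'
#' @param table 2x2 nonnegative integer matrix (e.g. from
#'   [dichotomize_coexpression()]).
#' @return object of class `exclusivity_result`: list with `table`,
#'   `odds_ratio`, `p_value`.
#' @export
fisher_exact_or <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == trunc(table)))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c_ > 0) (a * d) / (b * c_)
        else if (a * d > 0) Inf
        else if (b + c_ > 0) 0
        else NaN
  p <- stats::fisher.test(table)$p.value
  structure(list(table = table, odds_ratio = or, p_value = p),
            class = "exclusivity_result")
}

#' @export
print.exclusivity_result <- function(x, ...) {
  print(x$table)
  cat("odds ratio = ", format(x$odds_ratio, digits = 4),
      ", Fisher exact p = ", format.pval(x$p_value, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' Binned-control gene signature score
#'
#' Scores a gene set per cell as the mean log-normalized expression of the
#' set minus the mean expression of control genes drawn from the same
#' average-expression bins (the module-score scheme used for M1/M2 and
#' subtype signatures): genes are ranked by their cross-cell average
#' expression into `n_control_bins` bins, and for each set gene
#' `n_control_per_gene` control genes are sampled (with replacement) from its
#' bin. Deterministic given `seed`.
#'
#' @param ds a [cell_dataset()].
#' @param gene_set character vector; intersected with the gene universe.
#' @param n_control_bins number of average-expression bins.
#' @param n_control_per_gene controls sampled per set gene.
#' @param seed RNG seed for control sampling.
#' @return numeric vector of per-cell scores, named by cell id.
#' @export
signature_score <- function(ds, gene_set, n_control_bins = 25,
                            n_control_per_gene = 100, seed = 1L) {
  stopifnot(inherits(ds, "cell_dataset"))
  gene_set <- intersect(gene_set, ds$gene_ids)
  if (!length(gene_set)) stop("gene set empty after intersection")
  expr <- lognorm_matrix(ds)
  avg <- rowMeans(expr)
  nbins <- min(n_control_bins, length(unique(avg)))
  bins <- cut(rank(avg, ties.method = "first"), breaks = nbins,
              labels = FALSE)
  names(bins) <- rownames(expr)
  set.seed(seed)
  ctrl <- unlist(lapply(gene_set, function(g) {
    pool <- names(bins)[bins == bins[g]]
    sample(pool, n_control_per_gene, replace = TRUE)
  }))
  score <- colMeans(expr[gene_set, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
  stats::setNames(score, ds$cell_ids)
}

#' Load a shipped marker signature
#'
#' The package ships editable one-gene-per-line M1 and M2 macrophage marker
#' lists under `inst/extdata/`; user files in the same format can be passed
#' to [signature_score()] directly.
#'
#' @param name `"m1"` or `"m2"`, or the path to a one-gene-per-line file.
#' @return character vector of gene symbols.
#' @export
load_signature <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, "_signature.txt"),
                package = "cspolar")
  if (!nzchar(path) || !file.exists(path))
    stop("no signature file for '", name, "'")
  readLines(path)
}

#' Per-subtype correlation between two markers
#'
#' Pearson correlation between log-normalized expression of two genes within
#' each TAM subtype (or any other per-cell grouping), with BH adjustment
#' across subtypes. Subtypes with fewer than `min_cells` cells are dropped
#' with a warning; constant expression yields `NA` correlation.
#'
#' @param ds a [cell_dataset()].
#' @param geneA,geneB gene names.
#' @param by annotation column defining the grouping.
#' @param min_cells minimum cells a subtype must have to be tested.
#' @return data.frame `subtype`, `n_cells`, `r`, `p`, `q` (BH across tested
#'   subtypes).
#' @export
subtype_marker_correlation <- function(ds, geneA = "CXCL9", geneB = "SPP1",
                                       by = "tam_subtype", min_cells = 3) {
  stopifnot(inherits(ds, "cell_dataset"))
  lab <- ds$annotation[[by]]
  if (is.null(lab)) stop("annotation lacks column '", by, "'")
  keep <- !is.na(lab)
  expr <- lognorm_matrix(subset_cells(ds, cells = which(keep)))
  lab <- lab[keep]
  sizes <- table(lab)
  small <- names(sizes)[sizes < min_cells]
  if (length(small))
    warning("subtypes with fewer than ", min_cells, " cells dropped: ",
            paste(small, collapse = ", "))
  subtypes <- names(sizes)[sizes >= min_cells]
  res <- lapply(subtypes, function(s) {
    xa <- expr[geneA, lab == s]
    xb <- expr[geneB, lab == s]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0)
      return(data.frame(subtype = s, n_cells = length(xa),
                        r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(xa, xb)
    data.frame(subtype = s, n_cells = length(xa),
               r = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
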