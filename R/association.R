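#' Order patients by CS ratio
#'
#' Descending by default (most CXCL9-polarized first); ties are broken
#' lexicographically by patient id, so the ordering is stable and
#' reproducible. Excluded patients are dropped.
#'
#' @param pt a `polarity_table`.
#' @param decreasing order direction.
#' @return character vector of patient ids.
#' @export
rank_patients <- function(pt, decreasing = TRUE) {
  stopifnot(inherits(pt, "polarity_table"))
  ok <- pt$group != "excluded" & !is.na(pt$cs_ratio)
  if (sum(ok) < 2) stop("need at least 2 patients with a defined CS ratio")
  d <- pt[ok, ]
  d$patient[order(if (decreasing) -d$cs_ratio else d$cs_ratio, d$patient)]
}

# correlation + p for each row of a matrix against one vector.
# Pearson r with the exact t-distribution p (identical to cor.test);
# "spearman" ranks both sides first (t approximation for the rank statistic).
row_cor_test <- function(m, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (method == "spearman") {
    m <- t(apply(m, 1L, rank))
    y <- rank(y)
  }
  n <- length(y)
  sds <- apply(m, 1L, stats::sd)
  r <- rep(NA_real_, nrow(m))
  testable <- sds > 0 & stats::sd(y) > 0
  if (any(testable))
    r[testable] <- as.vector(stats::cor(t(m[testable, , drop = FALSE]), y))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, testable = testable)
}

#' Correlate gene expression with CS polarity across patients
#'
#' For each cell type (an [compute_adjusted_means()] object) and gene,
#' correlates the per-patient adjusted mean expression with the patients' CS
#' ratio. The default is Spearman (rank) correlation for robustness;
#' `method = "pearson"` correlates against the log CS ratio. P-values are
#' BH-adjusted jointly across all (cell type, gene) pairs. Genes constant
#' across patients are skipped and counted as untested. The summary fraction
#' is the share of tested genes with `|r| > r_min` and `q < q_max`.
#'
#' @param am_list a single `adjusted_means` or a (optionally named) list of
#'   them, one per cell type.
#' @param pt a `polarity_table` (patients matched by id; excluded patients
#'   dropped).
#' @param genes optional gene subset (e.g. highly variable genes).
#' @param r_min,q_max thresholds for the "associated" call.
#' @param method `"spearman"` (default) or `"pearson"` (on log CS ratio).
#' @return data.frame of class `association_table`: `cell_type`, `gene`,
#'   `r`, `p`, `q`, `associated`; attributes `fraction_associated`,
#'   `n_tested`, `n_untested`.
#' @export
gene_polarity_correlation <- function(am_list, pt, genes = NULL,
                                      r_min = 0.3, q_max = 0.05,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(pt, "polarity_table"))
  if (inherits(am_list, "adjusted_means")) am_list <- list(am_list)
  if (is.null(names(am_list)))
    names(am_list) <- vapply(am_list, `[[`, "", "cell_type")
  ok <- pt$group != "excluded" & !is.na(pt$cs_ratio)
  ratio <- stats::setNames(pt$cs_ratio[ok], pt$patient[ok])
  target_all <- if (method == "pearson") log(ratio) else ratio

  pieces <- lapply(names(am_list), function(ct_name) {
    am <- am_list[[ct_name]]
    pats <- intersect(am$patients, names(target_all))
    if (length(pats) < 3)
      stop("cell type '", ct_name, "' has fewer than 3 patients with a ",
           "defined CS ratio")
    m <- am$adjusted[, pats, drop = FALSE]
    if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), ,
                                drop = FALSE]
    res <- row_cor_test(m, target_all[pats], method)
    data.frame(cell_type = ct_name, gene = rownames(m),
               r = res$r, p = res$p, tested = res$testable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$q <- NA_real_
  out$q[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out$associated <- out$tested & !is.na(out$q) &
    abs(out$r) > r_min & out$q < q_max
  n_tested <- sum(out$tested)
  structure(out[, c("cell_type", "gene", "r", "p", "q", "associated")],
            fraction_associated = if (n_tested) sum(out$associated) / n_tested
                                  else NA_real_,
            n_tested = n_tested,
            n_untested = sum(!out$tested),
            class = c("association_table", "data.frame"))
}

#' Differential expression between polarity groups (bulk)
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-scale expression between
#' the high and low CS groups, BH-adjusted across genes; direction is the
#' sign of the difference of group medians. Zero-variance genes get `p = 1`.
#'
#' @param tpm genes x samples matrix (TPM or comparable).
#' @param groups named character vector (`"high"`/`"low"`) or a dichotomized
#'   `polarity_table` whose patients match the matrix columns.
#' @return data.frame `gene`, `direction` (+1 up in high, -1 up in low, 0
#'   tie), `p`, `q`.
#' @export
de_between_groups <- function(tpm, groups) {
  if (inherits(groups, "polarity_table"))
    groups <- stats::setNames(groups$group, groups$patient)
  groups <- groups[groups %in% c("high", "low")]
  common <- intersect(colnames(tpm), names(groups))
  if (!length(common)) stop("no samples shared between matrix and groups")
  groups <- groups[common]
  if (!all(c("high", "low") %in% groups))
    stop("both groups must be non-empty")
  lx <- log1p(as.matrix(tpm[, common, drop = FALSE]))
  hi <- groups == "high"
  res <- apply(lx, 1L, function(v) {
    if (stats::sd(v) == 0) return(c(0, 1))
    w <- suppressWarnings(stats::wilcox.test(v[hi], v[!hi]))
    c(sign(stats::median(v[hi]) - stats::median(v[!hi])), w$p.value)
  })
  data.frame(gene = rownames(lx), direction = res[1L, ], p = res[2L, ],
             q = stats::p.adjust(res[2L, ], method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' GMT: one set per line, tab-separated — set name, description, then member
#' genes.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors, usable with
#'   [preranked_enrichment()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    f[-(1:2)]
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  sets
}

# weighted Kolmogorov-Smirnov running-sum enrichment score.
# Returns the running-sum value at its maximum absolute deviation.
gsea_es <- function(ord_stats, in_set, weight) {
  n <- length(ord_stats)
  nh <- sum(in_set)
  w <- abs(ord_stats)^weight
  hit <- ifelse(in_set, w, 0)
  denom <- sum(hit)
  if (denom == 0) return(0)
  run <- cumsum(ifelse(in_set, hit / denom, -1 / (n - nh)))
  run[which.max(abs(run))]
}

#' Preranked gene set enrichment on polarity-ordered genes
#'
#' Classical weighted Kolmogorov-Smirnov running-sum enrichment: genes are
#' ranked by their correlation with the CS ratio (any per-gene statistic
#' works), and each set's score is the extreme of the running sum that
#' increments by `|stat|^weight` (normalized) at set members and decrements
#' by `1/(N - K)` elsewhere. The null is gene-label permutation (random sets
#' of the same size), appropriate because expression is already aggregated
#' per patient. A positive score means the set concentrates among genes
#' positively associated with polarity.
#'
#' @param gene_stats named numeric vector of per-gene statistics (e.g. the
#'   `r` column of an [gene_polarity_correlation()] table for one cell type).
#' @param gene_sets named list of character vectors.
#' @param n_perm number of gene-label permutations.
#' @param weight exponent on `|stat|` (0 gives the unweighted KS statistic,
#'   bounded in [-1, 1]).
#' @param seed RNG seed for the permutations.
#' @param min_size sets smaller than this after intersection are dropped.
#' @return data.frame `set`, `size`, `es`, `p`, `q` (BH across sets).
#' @export
preranked_enrichment <- function(gene_stats, gene_sets, n_perm = 1000,
                                 weight = 1, seed = 1L, min_size = 5) {
  stopifnot(!is.null(names(gene_stats)))
  if (length(unique(gene_stats)) == 1L)
    stop("all gene statistics equal; no ranking possible")
  ord <- order(gene_stats, decreasing = TRUE)
  stats_ord <- gene_stats[ord]
  universe <- names(stats_ord)
  gene_sets <- lapply(gene_sets, intersect, y = universe)
  sizes <- lengths(gene_sets)
  keep <- sizes >= min_size & sizes < length(universe)
  if (!any(keep)) stop("no gene set with at least ", min_size,
                       " members in the universe")
  gene_sets <- gene_sets[keep]
  set.seed(seed)
  res <- lapply(names(gene_sets), function(nm) {
    members <- gene_sets[[nm]]
    k <- length(members)
    es <- gsea_es(stats_ord, universe %in% members, weight)
    perm <- vapply(seq_len(n_perm), function(i) {
      gsea_es(stats_ord,
              universe %in% sample(universe, k), weight)
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
    data.frame(set = nm, size = k, es = es, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
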