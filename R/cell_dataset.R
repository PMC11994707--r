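#' Single-cell count container
#'
#' A `cell_dataset` bundles a sparse genes x cells count matrix with per-cell
#' annotation (patient, tissue region, cell type and, for tumor-associated
#' macrophages, a TAM subtype label). It is the input container for QC,
#' polarity scoring, composition and exclusivity analyses.
#'
#' @param counts sparse (or dense) nonnegative integer matrix, genes in rows,
#'   cells in columns. Coerced to [Matrix::dgCMatrix-class].
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param cell_ids character vector of unique cell identifiers, one per column.
#' @param annotation data.frame with one row per cell, columns `patient`,
#'   `region`, `cell_type` and optionally `tam_subtype`. Row order must match
#'   `cell_ids`.
#' @param tam_type the `cell_type` label that designates tumor-associated
#'   macrophages; `tam_subtype` may only be non-missing for these cells.
#'
#' @return object of class `cell_dataset`: a list with elements `counts`,
#'   `gene_ids`, `cell_ids`, `annotation`, `tam_type`.
#' @export
cell_dataset <- function(counts, gene_ids, cell_ids, annotation,
                         tam_type = "TAM") {
  if (!methods::is(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids))
    stop("counts has ", nrow(counts), " rows but ", length(gene_ids),
         " gene ids")
  if (ncol(counts) != length(cell_ids))
    stop("counts has ", ncol(counts), " columns but ", length(cell_ids),
         " cell ids")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(cell_ids))
    stop("duplicate cell id: ", cell_ids[duplicated(cell_ids)][1L])
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != trunc(x))))
    stop("counts must be nonnegative integers")
  if (!is.data.frame(annotation) || nrow(annotation) != length(cell_ids))
    stop("annotation must be a data.frame with one row per cell")
  for (col in c("patient", "region", "cell_type")) {
    if (is.null(annotation[[col]]))
      stop("annotation lacks required column '", col, "'")
    if (anyNA(annotation[[col]]) || any(annotation[[col]] == ""))
      stop("annotation column '", col, "' has missing values")
  }
  if (is.null(annotation$tam_subtype))
    annotation$tam_subtype <- NA_character_
  bad <- !is.na(annotation$tam_subtype) & annotation$cell_type != tam_type
  if (any(bad))
    stop("tam_subtype set for non-", tam_type, " cell: ",
         cell_ids[which(bad)[1L]])
  dimnames(counts) <- list(gene_ids, cell_ids)
  rownames(annotation) <- cell_ids
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         annotation = annotation, tam_type = tam_type),
    class = "cell_dataset")
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat("cell_dataset: ", length(x$gene_ids), " genes x ", length(x$cell_ids),
      " cells\n", sep = "")
  cat("  patients: ", length(unique(x$annotation$patient)),
      " | regions: ", paste(sort(unique(x$annotation$region)), collapse = ", "),
      "\n", sep = "")
  ct <- table(x$annotation$cell_type)
  cat("  cell types: ",
      paste(names(ct), ct, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

#' Subset a cell dataset
#'
#' @param ds a [cell_dataset()].
#' @param genes,cells logical, integer or character index into genes/cells;
#'   `NULL` keeps all. Order of survivors is preserved as given.
#' @return a `cell_dataset` restricted to the requested rows/columns.
#' @export
subset_cells <- function(ds, genes = NULL, cells = NULL) {
  stopifnot(inherits(ds, "cell_dataset"))
  gi <- if (is.null(genes)) seq_along(ds$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(ds$cell_ids) else cells
  if (is.character(gi)) gi <- match(gi, ds$gene_ids)
  if (is.character(ci)) ci <- match(ci, ds$cell_ids)
  cell_dataset(ds$counts[gi, ci, drop = FALSE],
               ds$gene_ids[gi], ds$cell_ids[ci],
               ds$annotation[ci, , drop = FALSE],
               tam_type = ds$tam_type)
}

#' Read a cell dataset from Matrix Market + TSV files
#'
#' Expects the conventional sparse-matrix exchange triplet: a Matrix Market
#' coordinate file of integer counts (genes x cells), a genes file with one
#' gene id per line (first column), and a cells TSV with a header row and
#' columns `cell_id`, `patient`, `region`, `cell_type` and optionally
#' `tam_subtype` (empty or "NA" meaning absent).
#'
#' @param mtx_path path to the Matrix Market counts file.
#' @param genes_path path to the gene list (TSV, first column used).
#' @param cells_path path to the per-cell annotation TSV.
#' @param tam_type TAM cell-type label, passed to [cell_dataset()].
#' @return a validated [cell_dataset()] with file row/column order preserved.
#' @export
read_cell_dataset <- function(mtx_path, genes_path, cells_path,
                              tam_type = "TAM") {
  for (p in c(mtx_path, genes_path, cells_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.delim(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.delim(cells_path, header = TRUE,
                             stringsAsFactors = FALSE)
  if (is.null(cells$cell_id)) stop("cells file lacks a 'cell_id' column")
  if (nrow(m) != length(genes))
    stop("matrix has ", nrow(m), " rows but genes file lists ", length(genes))
  if (ncol(m) != nrow(cells))
    stop("matrix has ", ncol(m), " columns but cells file lists ", nrow(cells))
  if (!is.null(cells$tam_subtype)) {
    cells$tam_subtype[cells$tam_subtype %in% c("", "NA")] <- NA_character_
  }
  cell_dataset(m, genes, cells$cell_id,
               cells[, setdiff(names(cells), "cell_id"), drop = FALSE],
               tam_type = tam_type)
}

#' Write a cell dataset to Matrix Market + TSV files
#'
#' Inverse of [read_cell_dataset()].
#'
#' @param ds a [cell_dataset()].
#' @param mtx_path,genes_path,cells_path output paths.
#' @return invisibly, the three paths.
#' @export
write_cell_dataset <- function(ds, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(ds, "cell_dataset"))
  Matrix::writeMM(ds$counts, mtx_path)
  writeLines(ds$gene_ids, genes_path)
  ann <- cbind(data.frame(cell_id = ds$cell_ids, stringsAsFactors = FALSE),
               ds$annotation)
  utils::write.table(ann, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mtx_path, genes_path, cells_path))
}

#' Quality-control filter for single-cell counts
#'
#' Applies the standard cell-then-gene screen: cells with a detected-gene
#' count outside `[min_genes, max_genes]` or a mitochondrial count fraction
#' above `max_mito_frac` are removed first; genes detected in
#' `min_cells_per_gene` or fewer of the remaining cells are removed second.
#' Mitochondrial genes are recognized by name prefix on the raw counts,
#' before any normalization. Boundary semantics: a cell is kept iff
#' `min_genes <= detected genes <= max_genes` (so 199 detected genes is
#' removed at the default, 200 is kept), and a gene is removed when detected
#' in three or fewer cells at the default. The filter is idempotent and never
#' reorders surviving rows or columns.
#'
#' @param ds a [cell_dataset()].
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_mito_frac maximum mitochondrial count fraction per cell.
#' @param min_cells_per_gene genes detected in this many cells or fewer are
#'   dropped (strictly more required to survive).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes.
#' @param keep_cells optional character vector of cell ids from an external
#'   doublet caller; when given, cells not listed are dropped before the
#'   threshold filters.
#' @return the filtered `cell_dataset`.
#' @export
qc_filter <- function(ds, min_genes = 200, max_genes = 5000,
                      max_mito_frac = 0.20, min_cells_per_gene = 3,
                      mito_prefix = "MT-", keep_cells = NULL) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (min_genes <= 0 || max_genes <= 0 || min_genes >= max_genes)
    stop("require 0 < min_genes < max_genes")
  if (!is.null(keep_cells))
    ds <- subset_cells(ds, cells = ds$cell_ids %in% keep_cells)
  detected <- Matrix::colSums(ds$counts > 0)
  total <- Matrix::colSums(ds$counts)
  mito <- startsWith(ds$gene_ids, mito_prefix)
  mito_frac <- if (any(mito)) {
    mt <- Matrix::colSums(ds$counts[mito, , drop = FALSE])
    ifelse(total > 0, mt / total, 0)
  } else rep(0, length(total))
  keep_cell <- detected >= min_genes & detected <= max_genes &
    mito_frac <= max_mito_frac
  if (!any(keep_cell))
    stop("no cells survive QC; review min_genes/max_genes/max_mito_frac")
  ds <- subset_cells(ds, cells = which(keep_cell))
  n_cells_per_gene <- Matrix::rowSums(ds$counts > 0)
  keep_gene <- n_cells_per_gene > min_cells_per_gene
  if (!any(keep_gene))
    stop("no genes survive QC; review min_cells_per_gene")
  subset_cells(ds, genes = which(keep_gene))
}

#' Log-normalize counts (library-size CPM-style, natural log1p)
#'
#' Per cell: `log1p(count / total * scale)`. Used for signature scoring and
#' marker correlations; polarity statistics operate on raw counts.
#'
#' @param ds a [cell_dataset()].
#' @param scale library-size scale factor (default 1e4).
#' @return a dense genes x cells matrix of log-normalized values.
#' @export
lognorm_matrix <- function(ds, scale = 1e4) {
  stopifnot(inherits(ds, "cell_dataset"))
  total <- Matrix::colSums(ds$counts)
  total[total == 0] <- 1
  m <- as.matrix(ds$counts)
  log1p(sweep(m, 2L, total / scale, "/"))
}
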