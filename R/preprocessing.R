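# Preprocessing: library-size normalisation, ln(1+x) transform, gene/cell
# filtering, and per-cell-type summary statistics.
#
# The pipeline order follows the published workflow verbatim: normalise,
# log-transform, then filter genes/cells; size factors are NOT recomputed
# after filtering (a `refilter_renormalize` option in preprocess() offers
# the conventional filter-first order).

#' Validate and construct a count matrix
#'
#' @param values genes x cells numeric matrix of non-negative finite counts.
#' @param gene_names,cell_barcodes unique row/column labels; default to the
#'   matrix dimnames.
#' @return the validated matrix (genes as rows, barcodes as columns).
#' @export
count_matrix <- function(values, gene_names = rownames(values),
                         cell_barcodes = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_names) || is.null(cell_barcodes))
    stop("count_matrix needs gene names and cell barcodes", call. = FALSE)
  if (length(gene_names) != nrow(values) ||
      length(cell_barcodes) != ncol(values))
    stop("dimnames do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(gene_names))
    stop("duplicate gene names: ",
         paste(utils::head(unique(gene_names[duplicated(gene_names)]), 5),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(cell_barcodes))
    stop("duplicate cell barcodes", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0))
    stop("counts must be non-negative and finite", call. = FALSE)
  storage.mode(values) <- "double"
  dimnames(values) <- list(toupper(gene_names), cell_barcodes)
  values
}

#' Library-size normalisation
#'
#' Per cell j: library size `lb_j = sum_i X[i,j]`, size factor
#' `sf_j = lb_j / mean(lb)`, output `X[, j] / sf_j`.  The mean-anchored size
#' factor conserves the total count of the matrix.
#'
#' @param X genes x cells count matrix.
#' @return the normalised matrix, `attr(., "stage") == "normalized"`.
#' @export
normalize_library_size <- function(X) {
  lb <- colSums(X)
  if (any(lb == 0))
    stop("cells with zero library size: ",
         paste(utils::head(colnames(X)[lb == 0], 10), collapse = ", "),
         call. = FALSE)
  sf <- lb / mean(lb)
  out <- sweep(X, 2L, sf, "/")
  attr(out, "stage") <- "normalized"
  attr(out, "size_factors") <- sf
  out
}

#' Log transform
#'
#' Elementwise natural log: `ln(1 + x)` on a normalised matrix.
#'
#' @param Xn matrix with `stage == "normalized"` (from
#'   [normalize_library_size()]).
#' @return log-stage matrix, `attr(., "stage") == "log"`.
#' @export
log_transform <- function(Xn) {
  stage <- attr(Xn, "stage")
  if (is.null(stage) || stage != "normalized")
    stop("log_transform expects a matrix at the 'normalized' stage (got '",
         if (is.null(stage)) "raw" else stage, "')", call. = FALSE)
  out <- log1p(Xn)
  attr(out, "stage") <- "log"
  attr(out, "size_factors") <- attr(Xn, "size_factors")
  out
}

#' Filter genes and cells
#'
#' Single pass, genes first: drop genes with a non-zero count in fewer than
#' `min_cells_per_gene` cells, then drop cells expressing (count > 0) fewer
#' than `min_genes_per_cell` of the remaining genes.
#'
#' @param X genes x cells count matrix.
#' @param min_cells_per_gene,min_genes_per_cell non-negative thresholds
#'   (defaults 3 and 200).
#' @return filtered matrix with an attribute `dropped`
#'   (`c(genes = , cells = )`).
#' @export
filter_genes_cells <- function(X, min_cells_per_gene = 3,
                               min_genes_per_cell = 200) {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0)
  keep_g <- rowSums(X > 0) >= min_cells_per_gene
  Y <- X[keep_g, , drop = FALSE]
  keep_c <- colSums(Y > 0) >= min_genes_per_cell
  Y <- Y[, keep_c, drop = FALSE]
  if (nrow(Y) == 0L || ncol(Y) == 0L)
    stop("filtering removed every ", if (nrow(Y) == 0L) "gene" else "cell",
         "; relax min_cells_per_gene/min_genes_per_cell", call. = FALSE)
  attr(Y, "dropped") <- c(genes = sum(!keep_g), cells = sum(!keep_c))
  Y
}

#' Cell annotation
#'
#' Maps cell barcodes to cell-type labels.  The ordered unique label list is
#' the sorted set of labels, so downstream summaries are invariant to cell
#' ordering.
#'
#' @param barcode,cell_type equal-length character vectors, or a 2-column
#'   data frame passed as `barcode`.
#' @return a `cell_annotation` data frame with attribute `cell_types`.
#' @export
cell_annotation <- function(barcode, cell_type = NULL) {
  if (is.data.frame(barcode)) {
    df <- barcode
    if (!all(c("barcode", "cell_type") %in% names(df)))
      stop("annotation needs columns 'barcode' and 'cell_type'",
           call. = FALSE)
    barcode <- df$barcode; cell_type <- df$cell_type
  }
  barcode <- as.character(barcode); cell_type <- as.character(cell_type)
  if (length(barcode) != length(cell_type))
    stop("barcode and cell_type lengths differ", call. = FALSE)
  if (anyDuplicated(barcode))
    stop("duplicate barcodes in annotation", call. = FALSE)
  if (any(!nzchar(cell_type)))
    stop("empty cell-type labels", call. = FALSE)
  out <- data.frame(barcode = barcode, cell_type = cell_type,
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_annotation", "data.frame")
  attr(out, "cell_types") <- sort(unique(cell_type))
  out
}

#' Cell types of an annotation
#' @param ann a [cell_annotation()].
#' @return sorted character vector of labels.
#' @export
cell_types <- function(ann) attr(ann, "cell_types")

# labels aligned to matrix columns; errors list unannotated barcodes
aligned_labels <- function(X, ann) {
  idx <- match(colnames(X), ann$barcode)
  if (anyNA(idx))
    stop("barcodes in matrix absent from annotation: ",
         paste(utils::head(colnames(X)[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  ann$cell_type[idx]
}

# group means / non-zero fractions over columns, rows = sorted labels
group_summarize <- function(tX, labels, cpt) {
  sums <- rowsum(tX, labels)         # rows sorted by label
  sums / as.vector(cpt[rownames(sums)])
}

#' Per-cell-type summary statistics
#'
#' Shared precomputation for all scoring engines: per (cell type, gene) the
#' arithmetic mean of log expression and the fraction of cells with non-zero
#' expression (a log-stage value is positive iff the raw count was).
#'
#' @param Xlog log-stage matrix from [log_transform()].
#' @param ann a [cell_annotation()] covering every matrix barcode.
#' @return a `type_summary` with `mean_expr` and `expr_fraction`
#'   (cell type x gene matrices, rows in sorted label order) and
#'   `cells_per_type`.
#' @export
summarize_by_type <- function(Xlog, ann) {
  stage <- attr(Xlog, "stage")
  if (is.null(stage) || stage != "log")
    stop("summarize_by_type expects a log-stage matrix", call. = FALSE)
  labels <- aligned_labels(Xlog, ann)
  cpt <- table(labels)
  tX <- t(Xlog)
  structure(list(
    mean_expr = group_summarize(tX, labels, cpt),
    expr_fraction = group_summarize((tX > 0) * 1, labels, cpt),
    cells_per_type = stats::setNames(as.integer(cpt), names(cpt)),
    cell_types = names(cpt)), class = "type_summary")
}

#' Full preprocessing pipeline
#'
#' Default order: normalise, ln(1+x), then apply the gene/cell filter (the
#' filter mask is computed on the raw non-zero pattern and applied to the
#' log matrix; size factors are not recomputed).  With
#' `refilter_renormalize = TRUE` the conventional order is used instead:
#' filter the raw counts first, then normalise and log-transform.
#'
#' @param X raw count matrix.
#' @param ann a [cell_annotation()]; cells without annotation are dropped
#'   (count reported in `$stats`).
#' @param min_cells_per_gene,min_genes_per_cell filter thresholds.
#' @param refilter_renormalize logical; see above.
#' @return list with `Xlog`, aligned `ann`, filtered raw `counts`, and a
#'   `stats` list of entity counts.
#' @export
preprocess <- function(X, ann, min_cells_per_gene = 3,
                       min_genes_per_cell = 200,
                       refilter_renormalize = FALSE) {
  common <- intersect(colnames(X), ann$barcode)
  if (length(common) == 0L)
    stop("no overlap between matrix barcodes and annotation", call. = FALSE)
  dropped_unannotated <- ncol(X) - length(common)
  X <- X[, common, drop = FALSE]
  if (refilter_renormalize) {
    Xf <- filter_genes_cells(X, min_cells_per_gene, min_genes_per_cell)
    Xlog <- log_transform(normalize_library_size(Xf))
  } else {
    Xlog_full <- log_transform(normalize_library_size(X))
    Xf <- filter_genes_cells(X, min_cells_per_gene, min_genes_per_cell)
    Xlog <- Xlog_full[rownames(Xf), colnames(Xf), drop = FALSE]
    attr(Xlog, "stage") <- "log"
  }
  ann2 <- cell_annotation(ann[ann$barcode %in% colnames(Xf), , drop = FALSE])
  list(Xlog = Xlog, ann = ann2, counts = Xf,
       stats = list(
         genes_in = nrow(X), cells_in = ncol(X) + dropped_unannotated,
         cells_unannotated = dropped_unannotated,
         genes_dropped = unname(attr(Xf, "dropped")["genes"]),
         cells_dropped = unname(attr(Xf, "dropped")["cells"]),
         genes_out = nrow(Xf), cells_out = ncol(Xf)))
}
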