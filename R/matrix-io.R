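#' Construct a cell-by-peak accessibility matrix
#'
#' Thin validated container around a sparse matrix with rows = cells and
#' columns = peaks. Values are non-negative accessibility counts (or 0/1);
#' all model code binarizes at the point of consumption.
#'
#' @param values Numeric matrix or `Matrix` sparse matrix, cells x peaks.
#' @param cell_ids Character vector of unique cell barcodes (rows).
#' @param peak_ids Character vector of unique peak identifiers (columns).
#' @return A list of class `cell_peak_matrix` with elements `values`
#'   (a `dgCMatrix`), `cell_ids`, `peak_ids`.
#' @export
cell_peak_matrix <- function(values, cell_ids, peak_ids) {
  if (methods::is(values, "nMatrix") || methods::is(values, "lMatrix"))
    values <- methods::as(values, "dMatrix")  # pattern/logical MTX -> numeric
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  cell_ids <- as.character(cell_ids)
  peak_ids <- as.character(peak_ids)
  if (nrow(values) != length(cell_ids))
    stop(sprintf("matrix has %d rows but %d cell ids", nrow(values), length(cell_ids)))
  if (ncol(values) != length(peak_ids))
    stop(sprintf("matrix has %d columns but %d peak ids", ncol(values), length(peak_ids)))
  if (anyDuplicated(cell_ids)) stop("duplicated cell_ids")
  if (anyDuplicated(peak_ids)) stop("duplicated peak_ids")
  if (length(values@x) && min(values@x) < 0) stop("accessibility values must be >= 0")
  dimnames(values) <- list(cell_ids, peak_ids)
  structure(list(values = values, cell_ids = cell_ids, peak_ids = peak_ids),
            class = "cell_peak_matrix")
}

#' @export
print.cell_peak_matrix <- function(x, ...) {
  cat(sprintf("cell_peak_matrix: %d cells x %d peaks, %d nonzero entries\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' @export
dim.cell_peak_matrix <- function(x) dim(x$values)

#' Read a cell-by-peak matrix from MatrixMarket triplet files
#'
#' Reads the CellRanger-style trio of a sparse MTX matrix plus plain-text
#' barcode and peak sidecars. On-disk orientation varies between tools; the
#' `orientation` flag says which axis the MTX rows are, and the returned
#' matrix is always cells x peaks.
#'
#' @param matrix_path Path to the MatrixMarket coordinate file (1-based).
#' @param cells_path Path to the barcodes file, one cell id per line (extra
#'   tab-separated columns ignored).
#' @param peaks_path Path to the peaks file, one peak id per line.
#' @param orientation `"peaks_rows"` (CellRanger default) or `"cells_rows"`.
#' @return A [cell_peak_matrix()].
#' @export
read_cell_peak_mtx <- function(matrix_path, cells_path, peaks_path,
                               orientation = c("peaks_rows", "cells_rows")) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(matrix_path)
  cells <- vapply(strsplit(readLines(cells_path), "\t", fixed = TRUE), `[[`, "", 1)
  peaks <- vapply(strsplit(readLines(peaks_path), "\t", fixed = TRUE), `[[`, "", 1)
  expect_rows <- if (orientation == "peaks_rows") length(peaks) else length(cells)
  expect_cols <- if (orientation == "peaks_rows") length(cells) else length(peaks)
  if (nrow(m) != expect_rows || ncol(m) != expect_cols)
    stop(sprintf(
      "MTX dimension mismatch: header says %d x %d but sidecars imply %d x %d (%s)",
      nrow(m), ncol(m), expect_rows, expect_cols, orientation))
  if (orientation == "peaks_rows") m <- Matrix::t(m)
  cell_peak_matrix(m, cells, peaks)
}

#' Write a cell-by-peak matrix as MatrixMarket triplet files
#'
#' @param m A [cell_peak_matrix()].
#' @param matrix_path,cells_path,peaks_path Output paths.
#' @param orientation Axis to place on MTX rows (see [read_cell_peak_mtx()]).
#' @return `matrix_path`, invisibly.
#' @export
write_cell_peak_mtx <- function(m, matrix_path, cells_path, peaks_path,
                                orientation = c("peaks_rows", "cells_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(m, "cell_peak_matrix"))
  v <- if (orientation == "peaks_rows") Matrix::t(m$values) else m$values
  Matrix::writeMM(methods::as(v, "TsparseMatrix"), matrix_path)
  writeLines(m$cell_ids, cells_path)
  writeLines(m$peak_ids, peaks_path)
  invisible(matrix_path)
}

#' Drop peaks observed in too few cells
#'
#' @param m A [cell_peak_matrix()].
#' @param min_cells Minimum number of cells with a nonzero entry for a peak
#'   to be retained. `0` keeps everything.
#' @return A [cell_peak_matrix()] with the surviving peaks, order preserved.
#' @export
filter_peaks <- function(m, min_cells) {
  stopifnot(inherits(m, "cell_peak_matrix"), min_cells >= 0)
  n_cells <- Matrix::colSums(m$values > 0)
  keep <- n_cells >= min_cells
  if (!any(keep))
    stop(sprintf("filter_peaks(min_cells = %d) would drop every peak", min_cells))
  cell_peak_matrix(m$values[, keep, drop = FALSE], m$cell_ids, m$peak_ids[keep])
}

#' Stack two cell-by-peak matrices over a shared peak axis
#'
#' Used to fit a single joint embedding for reference and query cells so the
#' two domains share one latent coordinate system.
#'
#' @param a,b [cell_peak_matrix()] objects with identical `peak_ids` and
#'   disjoint `cell_ids`.
#' @return A [cell_peak_matrix()] holding the rows of `a` then the rows of `b`.
#' @export
bind_cells <- function(a, b) {
  stopifnot(inherits(a, "cell_peak_matrix"), inherits(b, "cell_peak_matrix"))
  if (!identical(a$peak_ids, b$peak_ids))
    stop("cannot bind cells: peak_ids differ (same peaks in the same order required)")
  if (length(intersect(a$cell_ids, b$cell_ids)))
    stop("cannot bind cells: overlapping cell_ids")
  cell_peak_matrix(rbind(a$values, b$values), c(a$cell_ids, b$cell_ids), a$peak_ids)
}

#' Construct a label table
#'
#' Encodes cell-type labels with a deterministic integer code: labels are
#' sorted lexicographically and assigned `label_index` 0..(n_classes-1), so
#' the same label set yields the same encoding regardless of input order.
#'
#' @param cell_id Character vector of unique cell identifiers.
#' @param label Character vector of cell-type labels.
#' @param levels Optional explicit class universe (sorted order is still
#'   used for encoding); defaults to the observed labels.
#' @return A `data.frame` of class `label_table` with columns `cell_id`,
#'   `label`, `label_index`.
#' @export
label_table <- function(cell_id, label, levels = NULL) {
  cell_id <- as.character(cell_id)
  label <- as.character(label)
  stopifnot(length(cell_id) == length(label))
  if (anyDuplicated(cell_id)) stop("duplicated cell_id in label table")
  if (is.null(levels)) levels <- sort(unique(label))
  else {
    levels <- sort(unique(as.character(levels)))
    if (length(setdiff(label, levels)))
      stop("labels outside the supplied class universe")
  }
  out <- data.frame(cell_id = cell_id, label = label,
                    label_index = match(label, levels) - 1L,
                    stringsAsFactors = FALSE)
  attr(out, "levels") <- levels
  class(out) <- c("label_table", "data.frame")
  out
}

#' Read reference labels for a set of cells
#'
#' Reads a two-column (or wider) TSV with a header whose first two columns
#' are cell id and label, and reorders rows to match `cell_ids`.
#'
#' @param path Path to the labels TSV.
#' @param cell_ids Cells that must all be present in the file.
#' @return A [label_table()] with rows in `cell_ids` order.
#' @export
read_labels <- function(path, cell_ids) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("labels file needs at least two columns (cell_id, label)")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicated cell ids in labels file")
  missing <- setdiff(cell_ids, ids)
  if (length(missing))
    stop(sprintf("labels file is missing %d cell id(s): %s", length(missing),
                 paste(utils::head(missing, 10), collapse = ", ")))
  idx <- match(cell_ids, ids)
  label_table(cell_ids, as.character(tab[[2]])[idx])
}

#' Write per-cell predictions with class probabilities
#'
#' @param path Output TSV path.
#' @param cell_ids Character vector of cell identifiers.
#' @param labels Predicted label per cell.
#' @param probabilities Numeric matrix, cells x classes, each row summing to
#'   1 within 1e-6; column names are the class names.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(path, cell_ids, labels, probabilities) {
  probabilities <- as.matrix(probabilities)
  stopifnot(length(cell_ids) == length(labels),
            nrow(probabilities) == length(cell_ids),
            !is.null(colnames(probabilities)))
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("probability rows must sum to 1 (within 1e-6)")
  out <- data.frame(cell_id = cell_ids, predicted_label = labels,
                    probabilities, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a predictions TSV written by [write_predictions()]
#'
#' @param path Path to the predictions file.
#' @return A data.frame with `cell_id`, `predicted_label` and one numeric
#'   probability column per class.
#' @export
read_predictions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
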