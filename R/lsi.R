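#' Construct a cell embedding matrix
#'
#' @param values Numeric matrix, cells x dimensions; all entries finite.
#' @param cell_ids Cell identifiers aligned to rows.
#' @return A list of class `cell_embedding_matrix`.
#' @export
cell_embedding_matrix <- function(values, cell_ids) {
  values <- as.matrix(values)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(cell_ids))
    stop("one embedding row per cell_id required")
  if (anyDuplicated(cell_ids)) stop("duplicated cell_ids")
  if (length(values) && !all(is.finite(values)))
    stop("cell embeddings must be finite")
  rownames(values) <- cell_ids
  structure(list(values = values, cell_ids = cell_ids, d = ncol(values)),
            class = "cell_embedding_matrix")
}

#' LSI cell embedding (binarize, TF-IDF, truncated SVD)
#'
#' The standard scATAC-seq linear embedding: the accessibility matrix is
#' binarized to peak presence/absence, term-frequency normalized per cell,
#' inverse-document-frequency weighted per peak with
#' `idf_j = log(1 + n_cells / n_cells_with_peak_j)`, and reduced with a
#' truncated SVD. Cell embeddings are the top left singular vectors scaled
#' by their singular values (`U S`), so Euclidean distances reflect
#' explained variance. Component signs are arbitrary; all downstream
#' consumers (kNN graphs, GCNs) are sign-invariant.
#'
#' @param m A [cell_peak_matrix()]; every cell row and peak column must have
#'   at least one nonzero entry (see [filter_peaks()]).
#' @param dim Number of latent dimensions (default 128); must be at most
#'   `min(n_cells, n_peaks) - 1`.
#' @param binarize Replace positive values with 1 before TF-IDF (default
#'   TRUE; the output is then invariant to the magnitude of positive counts).
#' @return A [cell_embedding_matrix()], cells x `dim`.
#' @export
lsi_embed_cells <- function(m, dim = 128L, binarize = TRUE) {
  stopifnot(inherits(m, "cell_peak_matrix"))
  n_cells <- nrow(m$values)
  n_peaks <- ncol(m$values)
  if (dim > min(n_cells, n_peaks) - 1L)
    stop(sprintf("dim = %d exceeds min(n_cells, n_peaks) - 1 = %d",
                 dim, min(n_cells, n_peaks) - 1L))
  B <- m$values
  if (binarize) B@x <- rep(1, length(B@x)) else B@x <- as.numeric(B@x)
  rs <- Matrix::rowSums(B)
  zero_cell <- which(rs == 0)
  if (length(zero_cell))
    stop(sprintf("cell '%s' has no accessible peaks; cannot embed",
                 m$cell_ids[zero_cell[1]]))
  df <- Matrix::colSums(m$values > 0)
  if (any(df == 0))
    stop("matrix contains all-zero peak columns; run filter_peaks() first")
  tf <- B / rs
  idf <- log(1 + n_cells / df)
  X <- as.matrix(tf %*% Matrix::Diagonal(x = idf))
  sv <- svd(X, nu = dim, nv = 0)
  emb <- sv$u * rep(sv$d[seq_len(dim)], each = n_cells)
  cell_embedding_matrix(emb, m$cell_ids)
}
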