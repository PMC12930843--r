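#' Build a kNN cell graph from embeddings
#'
#' Each cell gets directed edges to its k nearest distinct neighbours under
#' the chosen metric (exact exhaustive search); ties are broken by distance
#' then node index, ascending. The directed edge set is then symmetrized by
#' union, and the symmetrically normalized, self-looped adjacency used by
#' the GCNs is attached.
#'
#' @param emb A [cell_embedding_matrix()] or plain numeric matrix with
#'   rownames.
#' @param k Number of neighbours, `1 <= k < n_cells` (default 15).
#' @param metric `"euclidean"` or `"cosine"`.
#' @return A list of class `domain_graph` with `node_ids`, `features`
#'   (cells x D), `edges` (two-column integer matrix of directed pairs after
#'   symmetrization), `k`, `metric`, and `normalized_adjacency` (sparse,
#'   symmetric, self-looped).
#' @export
build_knn_graph <- function(emb, k = 15L, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (inherits(emb, "cell_embedding_matrix")) {
    X <- emb$values
    ids <- emb$cell_ids
  } else {
    X <- as.matrix(emb)
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("cell_%d", seq_len(nrow(X)))
  }
  C <- nrow(X)
  if (anyDuplicated(ids)) stop("duplicated cell ids in embedding")
  if (k < 1 || k >= C)
    stop(sprintf("k must satisfy 1 <= k < n_cells (k = %d, n_cells = %d)", k, C))
  if (!all(is.finite(X))) stop("embedding features must be finite")
  D <- pairwise_distances(X, metric)
  # k nearest per node, excluding self; ties by (distance, index) ascending
  nbr <- matrix(0L, C, k)
  for (i in seq_len(C)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(C))
    nbr[i, ] <- ord[seq_len(k)]
  }
  from <- rep(seq_len(C), each = k)
  to <- as.integer(t(nbr))
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(C, C))
  A <- ((A + Matrix::t(A)) > 0) * 1  # union symmetrization
  und <- methods::as(A, "TsparseMatrix")
  edges <- cbind(from = und@i + 1L, to = und@j + 1L)
  g <- structure(list(node_ids = ids, features = X, edges = edges, k = as.integer(k),
                      metric = metric, adjacency = A,
                      normalized_adjacency = NULL),
                 class = "domain_graph")
  normalize_adjacency(g)
}

# Exact pairwise distance matrix. Cosine distance = 1 - cosine similarity;
# zero vectors are treated as maximally distant from everything.
pairwise_distances <- function(X, metric) {
  if (metric == "euclidean") {
    as.matrix(stats::dist(X))
  } else {
    nrm <- sqrt(rowSums(X^2))
    safe <- ifelse(nrm == 0, 1, nrm)
    Xn <- X / safe
    S <- tcrossprod(Xn)
    S[nrm == 0, ] <- 0
    S[, nrm == 0] <- 0
    d <- 1 - S
    diag(d) <- 0
    pmin(pmax(d, 0), 2)
  }
}

#' Attach the symmetrically normalized adjacency to a graph
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` where `A` is the binary symmetric
#' adjacency and `D` the degree matrix of `A + I`. Isolated nodes are safe:
#' the self-loop gives them degree 1.
#'
#' @param g A `domain_graph` with its edge set built.
#' @return `g` with `normalized_adjacency` filled in.
#' @export
normalize_adjacency <- function(g) {
  stopifnot(inherits(g, "domain_graph"))
  C <- length(g$node_ids)
  Atilde <- g$adjacency + Matrix::Diagonal(C)
  dinv <- 1 / sqrt(Matrix::rowSums(Atilde))
  Dinv <- Matrix::Diagonal(x = dinv)
  g$normalized_adjacency <- Dinv %*% Atilde %*% Dinv
  g
}

#' @export
print.domain_graph <- function(x, ...) {
  cat(sprintf("domain_graph: %d cells, %d undirected edges (k = %d, %s)\n",
              length(x$node_ids), nrow(x$edges) / 2, x$k, x$metric))
  invisible(x)
}
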