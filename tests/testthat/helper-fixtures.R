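# Small in-code fixtures shared across test files.

# A tiny deterministic cell-by-peak matrix with two obvious cell groups.
tiny_cpm <- function(n_cells = 6, n_peaks = 10, seed = 1) {
  set.seed(seed)
  half <- n_peaks %/% 2
  groups <- rep(1:2, length.out = n_cells)
  m <- matrix(0, n_cells, n_peaks)
  for (i in seq_len(n_cells)) {
    cols <- if (groups[i] == 1) seq_len(half) else (half + 1):n_peaks
    m[i, cols] <- rbinom(length(cols), 1, 0.9)
    m[i, -cols] <- rbinom(n_peaks - length(cols), 1, 0.05)
  }
  m[rowSums(m) == 0, 1] <- 1  # no empty cells
  cell_peak_matrix(m, sprintf("c%02d", seq_len(n_cells)),
                   sprintf("p%02d", seq_len(n_peaks)))
}

# Domain graph over explicit coordinates.
graph_from_points <- function(pts, k = 1, metric = "euclidean") {
  build_knn_graph(cell_embedding_matrix(as.matrix(pts),
                                        sprintf("n%d", seq_len(nrow(as.matrix(pts))))),
                  k = k, metric = metric)
}

# Edgeless graph with given features: k-NN needs k >= 1, so build directly.
edgeless_graph <- function(X) {
  X <- as.matrix(X)
  C <- nrow(X)
  ids <- sprintf("n%d", seq_len(C))
  rownames(X) <- ids
  g <- structure(list(node_ids = ids, features = X,
                      edges = cbind(from = integer(0), to = integer(0)),
                      k = 0L, metric = "euclidean",
                      adjacency = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                       x = numeric(0), dims = c(C, C)),
                      normalized_adjacency = NULL),
                 class = "domain_graph")
  normalize_adjacency(g)
}

# Exhaustive kNN oracle: directed neighbour lists by brute-force sort with
# the (distance, index) tie rule, then union symmetrization.
brute_knn_edges <- function(X, k, metric = "euclidean") {
  D <- if (metric == "euclidean") as.matrix(dist(X)) else {
    n <- sqrt(rowSums(X^2)); Xn <- X / ifelse(n == 0, 1, n)
    d <- 1 - tcrossprod(Xn); diag(d) <- 0; d
  }
  C <- nrow(X)
  A <- matrix(0, C, C)
  for (i in seq_len(C)) {
    cand <- setdiff(seq_len(C), i)
    ord <- cand[order(D[i, cand], cand)]
    A[i, ord[seq_len(k)]] <- 1
  }
  (A + t(A)) > 0
}

# Random gda state + pair of small graphs for architecture tests.
random_gda_setup <- function(C = 12, d = 5, n_classes = 3, seed = 42, k = 3,
                             K = 3) {
  set.seed(seed)
  Xs <- matrix(rnorm(C * d), C, d)
  Xt <- matrix(rnorm(C * d), C, d)
  g_s <- graph_from_points(Xs, k = k)
  g_t <- graph_from_points(Xt, k = k)
  cfg <- gda_config(n_classes = n_classes, hidden1 = 8, hidden2 = 6, K = K,
                    discriminator_hidden = 5, seed = seed, epochs = 5)
  state <- atacAnno:::gda_init(d, cfg)
  labels <- sample(0:(n_classes - 1), C, replace = TRUE)
  list(state = state, g_s = g_s, g_t = g_t, labels = labels, cfg = cfg)
}

# Fast small simulation for unit tests.
small_sim <- function(seed = 1, n_types = 3, cells = 20, peaks = 300) {
  simulate_pair(sim_config(n_types = n_types, cells_per_type_source = cells,
                           cells_per_type_target = cells, n_peaks = peaks,
                           peak_length = 50L, motif_length = 6L, seed = seed))
}
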