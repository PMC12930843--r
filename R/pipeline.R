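#' Nearest-neighbour label transfer baseline
#'
#' Assigns each target cell the label of its single nearest source cell in
#' the shared embedding space. Used as the non-adaptive baseline against
#' which the graph domain adaptation model is compared.
#'
#' @param emb_s,emb_t [cell_embedding_matrix()] objects (or matrices) for
#'   source and target cells, in the same coordinate system.
#' @param labels_s A [label_table()] covering the source cells.
#' @param metric Distance metric, `"euclidean"` or `"cosine"`.
#' @return Character vector of predicted labels named by target cell id.
#' @export
nn_transfer <- function(emb_s, labels_s, emb_t,
                        metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  Xs <- if (inherits(emb_s, "cell_embedding_matrix")) emb_s$values else as.matrix(emb_s)
  Xt <- if (inherits(emb_t, "cell_embedding_matrix")) emb_t$values else as.matrix(emb_t)
  ids_s <- rownames(Xs)
  ids_t <- rownames(Xt)
  lab <- labels_s$label[match(ids_s, labels_s$cell_id)]
  if (anyNA(lab)) stop("labels missing for some source cells")
  if (metric == "cosine") {
    norm_rows <- function(X) {
      n <- sqrt(rowSums(X^2))
      X / ifelse(n == 0, 1, n)
    }
    S <- norm_rows(Xt) %*% t(norm_rows(Xs))
    nn <- max.col(S, ties.method = "first")
  } else {
    # squared euclidean via the expansion; argmin per target row
    d2 <- outer(rowSums(Xt^2), rowSums(Xs^2), `+`) - 2 * Xt %*% t(Xs)
    nn <- max.col(-d2, ties.method = "first")
  }
  stats::setNames(lab[nn], ids_t)
}

#' End-to-end annotation of a query dataset from a labelled reference
#'
#' Runs the full two-stage pipeline on in-memory objects: (1) a joint cell
#' embedding over the row-concatenated reference + query matrix (so both
#' domains share one latent coordinate system), via LSI or via the Stage-1
#' sequence encoder; (2) per-domain kNN graphs; (3) weight-shared
#' asymmetric GCN training with adversarial domain alignment; (4) target
#' annotation.
#'
#' @param ref A [cell_peak_matrix()] for the annotated reference.
#' @param ref_labels A [label_table()] covering the reference cells.
#' @param query A [cell_peak_matrix()] with the same peaks as `ref`.
#' @param embedding `"lsi"` (default) or `"encoder"`.
#' @param lsi_dim Latent dimension for the LSI route (default 128, capped at
#'   `min(total cells, peaks) - 1`).
#' @param peak_embeddings For the encoder route: a [peak_embedding_matrix()]
#'   aligned to the (filtered) peaks.
#' @param encoder_cfg For the encoder route: an [encoder_config()].
#' @param min_cells_per_peak Peaks observed in fewer cells (across both
#'   domains) are dropped before embedding (default 1 = no filtering beyond
#'   removing empty peaks).
#' @param k kNN graph neighbour count (default 15).
#' @param metric kNN metric (default euclidean).
#' @param gda A [gda_config()]; `n_classes` defaults to the number of
#'   reference label classes if the supplied config is `NULL`.
#' @return A list with `predictions` (data.frame from [annotate_cells()]),
#'   `state` (trained `gda_state`), `embedding` (joint
#'   [cell_embedding_matrix()]), and the two `domain_graph`s.
#' @export
annotate_transfer <- function(ref, ref_labels, query, embedding = c("lsi", "encoder"),
                              lsi_dim = 128L, peak_embeddings = NULL,
                              encoder_cfg = encoder_config(),
                              min_cells_per_peak = 1L, k = 15L,
                              metric = "euclidean", gda = NULL) {
  embedding <- match.arg(embedding)
  stopifnot(inherits(ref, "cell_peak_matrix"), inherits(query, "cell_peak_matrix"),
            inherits(ref_labels, "label_table"))
  joint <- bind_cells(ref, query)
  joint <- filter_peaks(joint, max(1L, min_cells_per_peak))
  n_ref <- length(ref$cell_ids)
  if (embedding == "lsi") {
    dim_use <- min(lsi_dim, min(dim(joint$values)) - 1L)
    emb <- lsi_embed_cells(joint, dim = dim_use)
  } else {
    if (is.null(peak_embeddings))
      stop("encoder route needs `peak_embeddings` for the retained peaks")
    keep <- match(joint$peak_ids, peak_embeddings$peak_ids)
    if (anyNA(keep)) stop("peak_embeddings missing some retained peaks")
    pe <- peak_embedding_matrix(peak_embeddings$values[keep, , drop = FALSE],
                                joint$peak_ids)
    enc <- train_encoder(pe, joint, encoder_cfg)
    emb <- extract_cell_embeddings(enc)
  }
  emb_s <- cell_embedding_matrix(emb$values[seq_len(n_ref), , drop = FALSE],
                                 ref$cell_ids)
  emb_t <- cell_embedding_matrix(emb$values[-seq_len(n_ref), , drop = FALSE],
                                 query$cell_ids)
  g_s <- build_knn_graph(emb_s, k = k, metric = metric)
  g_t <- build_knn_graph(emb_t, k = k, metric = metric)
  classes <- attr(ref_labels, "levels")
  if (is.null(classes)) classes <- sort(unique(ref_labels$label))
  if (is.null(gda)) gda <- gda_config(n_classes = length(classes))
  state <- train_gda(g_s, ref_labels, g_t, gda)
  preds <- annotate_cells(state, g_t, classes)
  list(predictions = preds, state = state, embedding = emb,
       source_graph = g_s, target_graph = g_t,
       emb_source = emb_s, emb_target = emb_t)
}
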