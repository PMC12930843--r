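#' Configuration for the graph domain adaptation classifier
#'
#' Stage 2 trains three weight-shared GCN layers plus an adversarial domain
#' discriminator. The source (reference) path uses shallow propagation —
#' one propagation in GCN1, a depth-zero (identity-adjacency) transform for
#' GCN2, one propagation in GCN3 — to avoid over-smoothing the fully
#' labelled domain. The target (query) path reuses the same weights but
#' propagates `K` extra steps in GCN2 to exploit neighbourhood context in
#' the absence of labels.
#'
#' @param n_classes Number of cell types.
#' @param hidden1,hidden2 Output widths of GCN1 and GCN2 (defaults 128, 64).
#' @param K Target-path propagation depth in GCN2 (default 3). `K = 0` makes
#'   the target path identical to the source path (equivalence mode).
#' @param lambda Static weight of the adversarial domain loss in the total
#'   loss (default 1).
#' @param epochs Total training epochs E (default 200); also the horizon of
#'   the gradient-reversal schedule.
#' @param learning_rate Adam step size (default 1e-3).
#' @param discriminator_hidden Hidden width of the two-layer domain
#'   discriminator (default 32).
#' @param seed Integer seed fixing initialization.
#' @param grl_gamma Optional fixed override of the scheduled gradient
#'   reversal coefficient; `NULL` (default) binds it to [grl_schedule()].
#' @return A list of class `gda_config`.
#' @export
gda_config <- function(n_classes, hidden1 = 128L, hidden2 = 64L, K = 3L,
                       lambda = 1, epochs = 200L, learning_rate = 1e-3,
                       discriminator_hidden = 32L, seed = 1L,
                       grl_gamma = NULL) {
  stopifnot(n_classes >= 1, hidden1 >= 1, hidden2 >= 1, K >= 0, lambda >= 0,
            epochs >= 1, learning_rate > 0, discriminator_hidden >= 1)
  structure(list(n_classes = as.integer(n_classes), hidden1 = as.integer(hidden1),
                 hidden2 = as.integer(hidden2), K = as.integer(K),
                 lambda = lambda, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 discriminator_hidden = as.integer(discriminator_hidden),
                 seed = as.integer(seed), grl_gamma = grl_gamma),
            class = "gda_config")
}

# Glorot-initialized shared GCN weights + discriminator. Source and target
# forward passes read this one parameter list, so weights are shared by
# construction.
gda_init <- function(input_dim, cfg) {
  set.seed(cfg$seed)
  glorot <- function(fin, fout)
    matrix(stats::runif(fin * fout, -1, 1) * sqrt(6 / (fin + fout)), fin, fout)
  params <- list(
    W1 = glorot(input_dim, cfg$hidden1),
    W2 = glorot(cfg$hidden1, cfg$hidden2),
    W3 = glorot(cfg$hidden2, cfg$n_classes),
    V1 = glorot(cfg$hidden2, cfg$discriminator_hidden),
    c1 = numeric(cfg$discriminator_hidden),
    V2 = glorot(cfg$discriminator_hidden, 2),
    c2 = numeric(2))
  structure(list(params = params, cfg = cfg, log = NULL),
            class = "gda_state")
}

#' @export
print.gda_state <- function(x, ...) {
  p <- x$params
  cat(sprintf("gda_state: %d -> %d -> %d -> %d classes (K = %d, lambda = %g)\n",
              nrow(p$W1), ncol(p$W1), ncol(p$W2), ncol(p$W3),
              x$cfg$K, x$cfg$lambda))
  if (!is.null(x$log))
    cat(sprintf("  trained %d epochs; final L_cls = %.4f, L_dom = %.4f\n",
                nrow(x$log), x$log$loss_cls[nrow(x$log)],
                x$log$loss_dom[nrow(x$log)]))
  invisible(x)
}

#' One graph convolution: transform then propagate
#'
#' Computes `A (X W)` (bias-free), optionally followed by ReLU. With
#' `A = I` this reduces to a plain linear (optionally ReLU) layer.
#'
#' @param X Node feature matrix (nodes x in_dim).
#' @param A Normalized adjacency (or `NULL` for identity propagation).
#' @param W Weight matrix (in_dim x out_dim).
#' @param relu Apply ReLU (default FALSE).
#' @return Numeric matrix, nodes x out_dim.
#' @export
gcn_layer <- function(X, A, W, relu = FALSE) {
  if (ncol(X) != nrow(W))
    stop(sprintf("gcn_layer shape mismatch: features %d vs weight rows %d",
                 ncol(X), nrow(W)))
  H <- X %*% W
  if (!is.null(A)) H <- as.matrix(A %*% H)
  if (relu) H <- pmax(H, 0)
  H
}

# Shared internal forward. K = 0 gives the source path (depth-zero GCN2);
# K >= 1 gives the target path with K propagation steps in GCN2. Returns
# intermediates needed for backprop.
gda_fwd <- function(params, g, K) {
  A <- g$normalized_adjacency
  X <- g$features
  H <- pmax(as.matrix(A %*% (X %*% params$W1)), 0)
  M <- H %*% params$W2
  if (K >= 1) for (i in seq_len(K)) M <- as.matrix(A %*% M)
  Z <- pmax(M, 0)
  logits <- as.matrix(A %*% (Z %*% params$W3))
  list(H = H, M = M, Z = Z, logits = logits)
}

#' Source-path forward pass (shallow propagation)
#'
#' `H_s = ReLU(A_s X_s W1)`; `Z_s = ReLU(H_s W2)` (depth-zero transform, no
#' propagation); `Yhat_s = A_s Z_s W3`.
#'
#' @param state A `gda_state`.
#' @param g A normalized `domain_graph`.
#' @return Logit matrix, nodes x n_classes.
#' @export
source_forward <- function(state, g) {
  stopifnot(inherits(state, "gda_state"), inherits(g, "domain_graph"))
  gda_fwd(state$params, g, K = 0L)$logits
}

#' Target-path forward pass (deep propagation)
#'
#' `H_t = ReLU(A_t X_t W1)`; `Z_t = ReLU(A_t^K (H_t W2))` — one transform by
#' the shared W2 followed by K propagation steps; `Yhat_t = A_t Z_t W3`.
#' Uses the same W1, W2, W3 as [source_forward()].
#'
#' @param state A `gda_state`.
#' @param g A normalized `domain_graph`.
#' @param K Propagation depth; defaults to the configured value. `K = 0` is
#'   the source-equivalence mode.
#' @return Logit matrix, nodes x n_classes.
#' @export
target_forward <- function(state, g, K = state$cfg$K) {
  stopifnot(inherits(state, "gda_state"), inherits(g, "domain_graph"), K >= 0)
  gda_fwd(state$params, g, K = as.integer(K))$logits
}

#' Gradient reversal layer (forward)
#'
#' Identity in the forward pass; during backpropagation the upstream
#' gradient is multiplied by `-gamma` (see [grl_backward()]), which drives
#' the encoder to make domains indistinguishable while the discriminator
#' learns to tell them apart.
#'
#' @param Z Encoded feature matrix.
#' @param gamma Non-negative reversal coefficient (consumed by the backward
#'   pass, [grl_backward()]; the forward output is bit-identical to `Z`).
#' @return `Z`, unchanged.
#' @export
grl <- function(Z, gamma) {
  stopifnot(gamma >= 0)
  Z
}

#' Gradient reversal layer (backward)
#'
#' @param grad Upstream gradient with respect to the GRL output.
#' @param gamma Reversal coefficient used in the forward pass.
#' @return `-gamma * grad`.
#' @export
grl_backward <- function(grad, gamma) -gamma * grad

#' Domain discriminator forward pass
#'
#' Two-layer perceptron `hidden2 -> discriminator_hidden -> 2` with ReLU
#' hidden activation. Class 0 is source, class 1 is target.
#'
#' @param state A `gda_state`.
#' @param Z Encoded features (nodes x hidden2), typically GRL output.
#' @return Logit matrix, nodes x 2.
#' @export
domain_discriminator <- function(state, Z) {
  p <- state$params
  if (ncol(Z) != nrow(p$V1))
    stop(sprintf("discriminator expects width %d, got %d", nrow(p$V1), ncol(Z)))
  R <- pmax(sweep(Z %*% p$V1, 2, p$c1, `+`), 0)
  sweep(R %*% p$V2, 2, p$c2, `+`)
}

log_softmax <- function(x) {
  mx <- apply(x, 1, max)
  xc <- x - mx
  xc - log(rowSums(exp(xc)))
}

softmax <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

#' Source classification loss
#'
#' Mean negative log-likelihood of the true class under the softmax of the
#' source logits.
#'
#' @param logits Source logit matrix, nodes x n_classes.
#' @param labels Integer class indices in `[0, n_classes)` (0-based, as in a
#'   [label_table()]), or a `label_table`.
#' @return Scalar loss.
#' @export
classification_loss <- function(logits, labels) {
  if (inherits(labels, "label_table")) labels <- labels$label_index
  labels <- as.integer(labels)
  if (any(labels < 0 | labels >= ncol(logits)))
    stop(sprintf("labels must lie in [0, %d)", ncol(logits)))
  ls <- log_softmax(as.matrix(logits))
  -mean(ls[cbind(seq_len(nrow(ls)), labels + 1L)])
}

#' Adversarial domain loss
#'
#' Concatenates source and target discriminator logits, labels the first
#' block 0 (source) and the second 1 (target), and returns the mean
#' cross-entropy.
#'
#' @param D_s,D_t Discriminator logits for source and target nodes
#'   (either may have zero rows).
#' @return Scalar loss.
#' @export
domain_loss <- function(D_s, D_t) {
  D <- rbind(as.matrix(D_s), as.matrix(D_t))
  yd <- c(rep(0L, nrow(as.matrix(D_s))), rep(1L, nrow(as.matrix(D_t))))
  classification_loss(D, yd)
}

#' Gradient reversal schedule
#'
#' `gamma = 2 / (1 + exp(-10 p)) - 1` with progress `p = e / E`: zero at the
#' start of training, saturating towards 1, so adversarial pressure ramps up
#' only once the classifier has begun to fit.
#'
#' @param e Current epoch, `0 <= e <= E`.
#' @param E Total epochs.
#' @return The reversal coefficient in `[0, 1)`, strictly increasing in `e`.
#' @export
grl_schedule <- function(e, E) {
  stopifnot(E >= 1, all(e >= 0), all(e <= E))
  2 / (1 + exp(-10 * e / E)) - 1
}

#' Total training loss
#'
#' @param loss_cls Source classification loss.
#' @param loss_dom Adversarial domain loss.
#' @param lambda Non-negative domain-loss weight.
#' @return `loss_cls + lambda * loss_dom`.
#' @export
total_loss <- function(loss_cls, loss_dom, lambda) {
  stopifnot(lambda >= 0)
  loss_cls + lambda * loss_dom
}

# Full gradient of the total loss w.r.t. all parameters. The adversarial
# part backpropagates normally into the discriminator and through the GRL
# (scaled by -gamma) into the shared encoder weights. Exposed internally so
# the adversarial-direction property can be tested step-by-step.
gda_grads <- function(params, g_s, labels0, g_t, K, gamma, lambda) {
  As <- g_s$normalized_adjacency
  At <- g_t$normalized_adjacency
  fs <- gda_fwd(params, g_s, K = 0L)
  ft <- gda_fwd(params, g_t, K = K)
  Ns <- nrow(fs$logits)
  Nt <- nrow(ft$logits)

  grads <- lapply(params, function(p) p * 0)

  # --- classification loss (source only) ---
  P <- softmax(fs$logits)
  G <- P
  G[cbind(seq_len(Ns), labels0 + 1L)] <- G[cbind(seq_len(Ns), labels0 + 1L)] - 1
  G <- G / Ns
  AG <- as.matrix(As %*% G)                 # A symmetric
  grads$W3 <- grads$W3 + crossprod(fs$Z, AG)
  dZs <- AG %*% t(params$W3)
  loss_cls <- classification_loss(fs$logits, labels0)

  # --- adversarial domain loss ---
  Zs <- grl(fs$Z, gamma)
  Zt <- grl(ft$Z, gamma)
  Rs <- pmax(sweep(Zs %*% params$V1, 2, params$c1, `+`), 0)
  Rt <- pmax(sweep(Zt %*% params$V1, 2, params$c1, `+`), 0)
  Ds <- sweep(Rs %*% params$V2, 2, params$c2, `+`)
  Dt <- sweep(Rt %*% params$V2, 2, params$c2, `+`)
  loss_dom <- domain_loss(Ds, Dt)

  Dall <- rbind(Ds, Dt)
  Q <- softmax(Dall)
  yd <- c(rep(1L, Ns), rep(2L, Nt))
  Q[cbind(seq_len(Ns + Nt), yd)] <- Q[cbind(seq_len(Ns + Nt), yd)] - 1
  Gd <- Q / (Ns + Nt)
  Rall <- rbind(Rs, Rt)
  Zall <- rbind(Zs, Zt)
  grads$V2 <- grads$V2 + lambda * crossprod(Rall, Gd)
  grads$c2 <- grads$c2 + lambda * colSums(Gd)
  dR <- (Gd %*% t(params$V2)) * (Rall > 0)
  grads$V1 <- grads$V1 + lambda * crossprod(Zall, dR)
  grads$c1 <- grads$c1 + lambda * colSums(dR)
  dZ_dom <- dR %*% t(params$V1)
  # gradient reversal into the shared encoder
  dZs <- dZs + lambda * grl_backward(dZ_dom[seq_len(Ns), , drop = FALSE], gamma)
  dZt <- lambda * grl_backward(dZ_dom[Ns + seq_len(Nt), , drop = FALSE], gamma)

  # --- shared encoder backward, source path (K = 0) ---
  dMs <- dZs * (fs$Z > 0)
  grads$W2 <- grads$W2 + crossprod(fs$H, dMs)
  dHs <- (dMs %*% t(params$W2)) * (fs$H > 0)
  grads$W1 <- grads$W1 + crossprod(g_s$features, as.matrix(As %*% dHs))

  # --- shared encoder backward, target path (K propagations; A^K symmetric) ---
  dMt <- dZt * (ft$Z > 0)
  if (K >= 1) for (i in seq_len(K)) dMt <- as.matrix(At %*% dMt)
  grads$W2 <- grads$W2 + crossprod(ft$H, dMt)
  dHt <- (dMt %*% t(params$W2)) * (ft$H > 0)
  grads$W1 <- grads$W1 + crossprod(g_t$features, as.matrix(At %*% dHt))

  list(grads = grads, loss_cls = loss_cls, loss_dom = loss_dom,
       total = total_loss(loss_cls, loss_dom, lambda))
}

#' Train the graph domain adaptation classifier
#'
#' Full-graph training: each epoch runs both forward paths, evaluates the
#' source classification loss and the adversarial domain loss with the
#' scheduled gradient-reversal coefficient, and takes a single Adam step on
#' the total loss over all shared and discriminator parameters.
#' Deterministic given `cfg$seed`. Target labels are never an input.
#'
#' @param g_s Source `domain_graph` (normalized).
#' @param labels_s A [label_table()] covering every source node (matched by
#'   `cell_id`), or an integer vector of 0-based class indices in node order.
#' @param g_t Target `domain_graph` (normalized).
#' @param cfg A [gda_config()].
#' @return A trained `gda_state` whose `log` records per-epoch
#'   `(epoch, loss_cls, loss_dom, gamma, total)`.
#' @export
train_gda <- function(g_s, labels_s, g_t, cfg) {
  stopifnot(inherits(g_s, "domain_graph"), inherits(g_t, "domain_graph"),
            inherits(cfg, "gda_config"))
  if (ncol(g_s$features) != ncol(g_t$features))
    stop("source and target graphs must share the feature dimension")
  if (inherits(labels_s, "label_table")) {
    missing <- setdiff(g_s$node_ids, labels_s$cell_id)
    if (length(missing))
      stop(sprintf("labels missing for %d source cell(s): %s", length(missing),
                   paste(utils::head(missing, 10), collapse = ", ")))
    labels0 <- labels_s$label_index[match(g_s$node_ids, labels_s$cell_id)]
  } else {
    labels0 <- as.integer(labels_s)
    if (length(labels0) != length(g_s$node_ids))
      stop("one label per source node required")
  }
  if (cfg$n_classes < length(unique(labels0)))
    stop(sprintf("n_classes = %d but %d distinct source labels observed",
                 cfg$n_classes, length(unique(labels0))))
  if (any(labels0 < 0 | labels0 >= cfg$n_classes))
    stop("label indices out of range")

  state <- gda_init(ncol(g_s$features), cfg)
  params <- state$params
  opt <- adam_init(params)
  log <- data.frame(epoch = seq_len(cfg$epochs), loss_cls = NA_real_,
                    loss_dom = NA_real_, gamma = NA_real_, total = NA_real_)
  for (e in seq_len(cfg$epochs)) {
    gamma <- if (is.null(cfg$grl_gamma)) grl_schedule(e, cfg$epochs) else cfg$grl_gamma
    res <- gda_grads(params, g_s, labels0, g_t, cfg$K, gamma, cfg$lambda)
    upd <- adam_step(params, res$grads, opt, cfg$learning_rate)
    params <- upd$params
    opt <- upd$opt
    log[e, c("loss_cls", "loss_dom", "gamma", "total")] <-
      c(res$loss_cls, res$loss_dom, gamma, res$total)
  }
  state$params <- params
  state$log <- log
  state
}

#' Annotate target cells with a trained classifier
#'
#' Runs the target forward path, applies softmax, and predicts the argmax
#' class (ties broken by lowest class index).
#'
#' @param state A trained `gda_state`.
#' @param g_t Target `domain_graph`.
#' @param class_names Character vector of length `n_classes`, in
#'   `label_index` order (i.e. sorted label order).
#' @return A data.frame with `cell_id`, `predicted_label`, and one
#'   probability column per class (rows sum to 1).
#' @export
annotate_cells <- function(state, g_t, class_names) {
  stopifnot(inherits(state, "gda_state"))
  if (length(class_names) != state$cfg$n_classes)
    stop(sprintf("%d class names supplied but model has %d classes",
                 length(class_names), state$cfg$n_classes))
  logits <- target_forward(state, g_t)
  probs <- softmax(logits)
  colnames(probs) <- class_names
  pred <- class_names[max.col(probs, ties.method = "first")]
  out <- data.frame(cell_id = g_t$node_ids, predicted_label = pred,
                    probs, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
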