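#' Configuration for the Stage-1 accessibility encoder
#'
#' The encoder is a feedforward network mapping each peak's sequence
#' embedding (dimension d) to that peak's predicted accessibility across all
#' C cells. Hidden layers apply affine transform, batch normalization, then
#' the activation; the output layer is affine only. Training samples are
#' peaks; targets are the binarized accessibility of each peak across cells.
#' After training, the columns of the output-layer weight matrix are the
#' per-cell embeddings.
#'
#' @param hidden_dims Integer vector of hidden layer widths (the last entry
#'   is the cell-embedding dimension D). Default `c(512, 128)`.
#' @param activation Only `"relu"` is currently implemented.
#' @param epochs Number of passes over the peaks (default 50).
#' @param batch_size Minibatch size in peaks (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed; fixes initialization and batch shuffling.
#' @param batch_norm Apply batch normalization on hidden layers (default
#'   TRUE; FALSE gives plain affine + activation, useful for closed-form
#'   checks).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(hidden_dims = c(512L, 128L), activation = "relu",
                           epochs = 50L, batch_size = 128L,
                           learning_rate = 1e-3, seed = 1L,
                           batch_norm = TRUE) {
  stopifnot(length(hidden_dims) >= 1, all(hidden_dims >= 1),
            identical(activation, "relu"), epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(hidden_dims = as.integer(hidden_dims), activation = activation,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 batch_norm = isTRUE(batch_norm)),
            class = "encoder_config")
}

# Seeded parameter initialization: He-scaled weights, zero biases, unit
# batch-norm scale. Layer widths: input_dim -> hidden_dims -> n_cells.
encoder_init <- function(input_dim, n_cells, cfg) {
  set.seed(cfg$seed)
  dims <- c(input_dim, cfg$hidden_dims, n_cells)
  L <- length(cfg$hidden_dims)
  W <- vector("list", L + 1)
  b <- vector("list", L + 1)
  bn <- vector("list", L)
  for (l in seq_len(L + 1)) {
    fan_in <- dims[l]
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / fan_in)),
                     dims[l], dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  for (l in seq_len(L)) {
    bn[[l]] <- list(gamma = rep(1, dims[l + 1]), beta = numeric(dims[l + 1]),
                    running_mean = numeric(dims[l + 1]),
                    running_var = rep(1, dims[l + 1]))
  }
  structure(list(W = W, b = b, bn = bn, L = L, dims = dims,
                 C = n_cells, D = dims[L + 1], cfg = cfg),
            class = "encoder_state")
}

#' @export
print.encoder_state <- function(x, ...) {
  cat(sprintf("encoder_state: %s -> %d cells (L = %d hidden layers)\n",
              paste(x$dims[-length(x$dims)], collapse = " -> "), x$C, x$L))
  if (!is.null(x$final_loss))
    cat(sprintf("  final training BCE: %.5f\n", x$final_loss))
  invisible(x)
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# Forward pass with caches for backprop. train_mode switches batch-norm
# between batch statistics (updating running estimates) and running
# statistics.
encoder_fwd <- function(state, X, train_mode = FALSE) {
  L <- state$L
  cache <- list(H = vector("list", L + 1), pre = vector("list", L),
                xhat = vector("list", L), invstd = vector("list", L))
  H <- X
  cache$H[[1]] <- H
  for (l in seq_len(L)) {
    pre <- sweep(H %*% state$W[[l]], 2, state$b[[l]], `+`)
    cache$pre[[l]] <- pre
    if (state$cfg$batch_norm) {
      bn <- state$bn[[l]]
      if (train_mode) {
        mu <- colMeans(pre)
        centred <- sweep(pre, 2, mu)
        v <- colMeans(centred^2)
        state$bn[[l]]$running_mean <- (1 - bn_momentum) * bn$running_mean + bn_momentum * mu
        state$bn[[l]]$running_var <- (1 - bn_momentum) * bn$running_var + bn_momentum * v
      } else {
        mu <- bn$running_mean
        v <- bn$running_var
        centred <- sweep(pre, 2, mu)
      }
      invstd <- 1 / sqrt(v + bn_eps)
      xhat <- sweep(centred, 2, invstd, `*`)
      out <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
      cache$xhat[[l]] <- xhat
      cache$invstd[[l]] <- invstd
    } else {
      out <- pre
    }
    H <- pmax(out, 0)
    cache$H[[l + 1]] <- H
  }
  logits <- sweep(H %*% state$W[[L + 1]], 2, state$b[[L + 1]], `+`)
  list(logits = logits, cache = cache, state = state)
}

#' Run the Stage-1 encoder forward
#'
#' @param state An `encoder_state` (from [train_encoder()] or internal
#'   initialization).
#' @param X A [peak_embedding_matrix()] or plain numeric matrix, peaks x d.
#' @param train_mode Use batch statistics in batch normalization (TRUE) or
#'   the stored running statistics (FALSE, the default); in eval mode each
#'   row's output is independent of the rest of the batch.
#' @return Numeric matrix of logits, peaks x cells.
#' @export
encoder_forward <- function(state, X, train_mode = FALSE) {
  stopifnot(inherits(state, "encoder_state"))
  if (inherits(X, "peak_embedding_matrix")) X <- X$values
  X <- as.matrix(X)
  if (ncol(X) != nrow(state$W[[1]]))
    stop(sprintf("layer 1 expects %d input features, got %d",
                 nrow(state$W[[1]]), ncol(X)))
  encoder_fwd(state, X, train_mode)$logits
}

#' Binary cross-entropy over logits
#'
#' Mean over all entries of `-[y log s(x) + (1-y) log(1-s(x))]` with
#' `s` the logistic function, computed in the numerically safe
#' `max(x,0) - x y + log(1 + exp(-|x|))` form.
#'
#' @param logits Numeric matrix or vector of raw scores.
#' @param y Binary targets of the same shape.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(logits, y) {
  logits <- as.matrix(logits)
  y <- as.matrix(y)
  if (!identical(dim(logits), dim(y))) stop("logits and targets differ in shape")
  if (length(y) && !all(y %in% c(0, 1))) stop("targets must be binary (0/1)")
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

# One Adam step over a flat list of parameter arrays. opt carries first and
# second moment estimates plus the step counter.
adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0)
}

# Flatten/unflatten encoder parameters for the generic Adam step.
encoder_params <- function(state) {
  p <- list()
  for (l in seq_along(state$W)) {
    p[[sprintf("W%d", l)]] <- state$W[[l]]
    p[[sprintf("b%d", l)]] <- state$b[[l]]
  }
  if (state$cfg$batch_norm) {
    for (l in seq_len(state$L)) {
      p[[sprintf("g%d", l)]] <- state$bn[[l]]$gamma
      p[[sprintf("beta%d", l)]] <- state$bn[[l]]$beta
    }
  }
  p
}

encoder_set_params <- function(state, p) {
  for (l in seq_along(state$W)) {
    state$W[[l]] <- p[[sprintf("W%d", l)]]
    state$b[[l]] <- p[[sprintf("b%d", l)]]
  }
  if (state$cfg$batch_norm) {
    for (l in seq_len(state$L)) {
      state$bn[[l]]$gamma <- p[[sprintf("g%d", l)]]
      state$bn[[l]]$beta <- p[[sprintf("beta%d", l)]]
    }
  }
  state
}

# Backward pass for mean BCE-with-logits. Returns gradients named like
# encoder_params(). Standard batch-norm backward per column.
encoder_backward <- function(state, fwd, Y) {
  L <- state$L
  cache <- fwd$cache
  n <- nrow(Y)
  g <- list()
  dlogits <- (1 / (1 + exp(-fwd$logits)) - Y) / (n * ncol(Y))
  g[[sprintf("W%d", L + 1)]] <- crossprod(cache$H[[L + 1]], dlogits)
  g[[sprintf("b%d", L + 1)]] <- colSums(dlogits)
  dH <- dlogits %*% t(state$W[[L + 1]])
  for (l in rev(seq_len(L))) {
    relu_in <- if (state$cfg$batch_norm) {
      sweep(sweep(cache$xhat[[l]], 2, state$bn[[l]]$gamma, `*`), 2,
            state$bn[[l]]$beta, `+`)
    } else cache$pre[[l]]
    dout <- dH * (relu_in > 0)
    if (state$cfg$batch_norm) {
      xhat <- cache$xhat[[l]]
      g[[sprintf("g%d", l)]] <- colSums(dout * xhat)
      g[[sprintf("beta%d", l)]] <- colSums(dout)
      dxhat <- sweep(dout, 2, state$bn[[l]]$gamma, `*`)
      m <- nrow(dout)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dpre <- sweep(m * dxhat - rep(s1, each = m) - xhat * rep(s2, each = m),
                    2, cache$invstd[[l]] / m, `*`)
    } else {
      dpre <- dout
    }
    g[[sprintf("W%d", l)]] <- crossprod(cache$H[[l]], dpre)
    g[[sprintf("b%d", l)]] <- colSums(dpre)
    if (l > 1) dH <- dpre %*% t(state$W[[l]])
  }
  g
}

#' Train the Stage-1 accessibility encoder
#'
#' Fits the encoder with minibatch Adam on binary cross-entropy: each
#' training sample is one peak, whose target is that peak's binarized
#' accessibility across all cells. Deterministic given `cfg$seed`.
#'
#' @param X A [peak_embedding_matrix()]; rows must correspond one-to-one, in
#'   order, to the peak columns of `m`.
#' @param m A [cell_peak_matrix()]; binarized internally (`value > 0`).
#' @param cfg An [encoder_config()].
#' @return An `encoder_state` carrying the trained parameters, `cell_ids`,
#'   per-epoch `loss_history` and `final_loss`.
#' @export
train_encoder <- function(X, m, cfg = encoder_config()) {
  stopifnot(inherits(X, "peak_embedding_matrix"),
            inherits(m, "cell_peak_matrix"),
            inherits(cfg, "encoder_config"))
  if (!identical(X$peak_ids, m$peak_ids))
    stop("peak order mismatch between embeddings and accessibility matrix")
  Xv <- X$values
  Y <- as.matrix(Matrix::t(m$values > 0)) * 1  # peaks x cells
  n <- nrow(Xv)
  state <- encoder_init(ncol(Xv), ncol(Y), cfg)
  params <- encoder_params(state)
  opt <- adam_init(params)
  loss_hist <- numeric(cfg$epochs)
  set.seed(cfg$seed + 1L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    tot <- 0
    for (s in starts) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      fwd <- encoder_fwd(state, Xv[idx, , drop = FALSE], train_mode = TRUE)
      state <- fwd$state  # running BN statistics updated
      Yb <- Y[idx, , drop = FALSE]
      tot <- tot + bce_loss(fwd$logits, Yb) * length(idx)
      grads <- encoder_backward(state, fwd, Yb)
      upd <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- upd$params
      opt <- upd$opt
      state <- encoder_set_params(state, params)
    }
    loss_hist[epoch] <- tot / n
  }
  state$cell_ids <- m$cell_ids
  state$loss_history <- loss_hist
  state$final_loss <- loss_hist[cfg$epochs]
  state
}

#' Extract per-cell embeddings from a trained encoder
#'
#' The embedding of cell c is column c of the output-layer weight matrix:
#' the projection vector that maps peak-level latent features to that cell's
#' predicted accessibility. The output-layer bias is not part of the
#' embedding.
#'
#' @param state A trained `encoder_state`.
#' @param cell_ids Cell identifiers, one per output column (defaults to the
#'   ids recorded at training time).
#' @return A [cell_embedding_matrix()], cells x D.
#' @export
extract_cell_embeddings <- function(state, cell_ids = state$cell_ids) {
  stopifnot(inherits(state, "encoder_state"))
  if (length(cell_ids) != state$C)
    stop(sprintf("%d cell ids supplied but encoder has %d output cells",
                 length(cell_ids), state$C))
  cell_embedding_matrix(t(state$W[[state$L + 1]]), cell_ids)
}
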