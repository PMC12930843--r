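test_that("gcn_layer propagates after transforming", {
  # identity adjacency reduces to a dense (ReLU) affine map
  X <- matrix(c(1, -2, 0.5, 3), 2, 2)
  W <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(gcn_layer(X, NULL, W, relu = TRUE), pmax(X, 0))

  # 2-node single-edge normalized adjacency averages one-hot features
  g2 <- graph_from_points(matrix(c(0, 1), 2, 1), k = 1)
  out <- gcn_layer(diag(2), g2$normalized_adjacency, diag(2))
  expect_equal(out, matrix(0.5, 2, 2), ignore_attr = TRUE)

  expect_equal(gcn_layer(matrix(0, 2, 2), g2$normalized_adjacency, W),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(gcn_layer(X, NULL, matrix(0, 3, 2)), "shape mismatch")
})

test_that("on an edgeless graph both paths collapse to the same MLP for any K", {
  su <- random_gda_setup()
  g0 <- edgeless_graph(su$g_s$features)
  s_out <- source_forward(su$state, g0)
  for (K in c(1, 3, 5))
    expect_equal(target_forward(su$state, g0, K = K), s_out, tolerance = 1e-8)
})

test_that("complete graph with uniform features yields identical output rows", {
  C <- 6
  X <- matrix(1, C, 4)
  g <- structure(list(node_ids = sprintf("n%d", 1:C), features = X,
                      edges = NULL, k = C - 1L, metric = "euclidean",
                      adjacency = Matrix::Matrix(1 - diag(C), sparse = TRUE),
                      normalized_adjacency = NULL), class = "domain_graph")
  g <- normalize_adjacency(g)
  su <- random_gda_setup(d = 4)
  for (K in c(1, 4)) {
    out <- target_forward(su$state, g, K = K)
    expect_lt(max(abs(sweep(out, 2, out[1, ]))), 1e-10)
  }
})

test_that("K-step propagation matches an explicit dense multiply oracle", {
  pts <- matrix(seq_len(5), 5, 1)  # 5-node path graph under k = 1
  g <- graph_from_points(pts, k = 1)
  su <- random_gda_setup(d = 1)
  p <- su$state$params
  su$state$params$W1 <- matrix(rnorm(ncol(p$W1)), 1, ncol(p$W1))
  out <- target_forward(su$state, g, K = 3)

  A <- as.matrix(g$normalized_adjacency)
  p <- su$state$params
  H <- pmax(A %*% (g$features %*% p$W1), 0)
  M <- H %*% p$W2
  M <- A %*% (A %*% (A %*% M))
  oracle <- A %*% (pmax(M, 0) %*% p$W3)
  expect_equal(out, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("both forward paths are permutation equivariant", {
  su <- random_gda_setup(C = 10)
  g <- su$g_s
  set.seed(13)
  perm <- sample(10)
  gp <- g
  gp$features <- g$features[perm, , drop = FALSE]
  gp$adjacency <- g$adjacency[perm, perm]
  gp$node_ids <- g$node_ids[perm]
  gp <- normalize_adjacency(gp)
  expect_equal(source_forward(su$state, gp), source_forward(su$state, g)[perm, ],
               tolerance = 1e-10)
  expect_equal(target_forward(su$state, gp, K = 3),
               target_forward(su$state, g, K = 3)[perm, ], tolerance = 1e-10)
})

test_that("gradient reversal: identity forward, reversed scaled backward", {
  set.seed(14)
  Z <- matrix(rnorm(12), 3, 4)
  expect_identical(grl(Z, 0.7), Z)

  # finite-difference-verified upstream gradient of h(U) = sum(sin(U))
  h <- function(U) sum(sin(U))
  fd <- matrix(NA_real_, 3, 4)
  eps <- 1e-6
  for (i in seq_along(Z)) {
    zp <- Z; zp[i] <- zp[i] + eps
    zm <- Z; zm[i] <- zm[i] - eps
    fd[i] <- (h(zp) - h(zm)) / (2 * eps)
  }
  expect_equal(fd, cos(Z), tolerance = 1e-5)
  # gradient through the GRL is -gamma times that upstream gradient
  expect_equal(grl_backward(fd, 0.7), -0.7 * fd, tolerance = 1e-12)
  expect_equal(grl_backward(fd, 0), fd * 0)
})

test_that("domain discriminator shapes, zero-weight uniformity, and row order", {
  su <- random_gda_setup()
  Z <- matrix(rnorm(8 * 6), 8, 6)
  D <- domain_discriminator(su$state, Z)
  expect_equal(dim(D), c(8L, 2L))

  zero <- su$state
  zero$params$V1[] <- 0; zero$params$V2[] <- 0
  zero$params$c1[] <- 0; zero$params$c2[] <- 0
  D0 <- domain_discriminator(zero, Z)
  expect_equal(D0, matrix(0, 8, 2))
  expect_equal(domain_loss(D0[1:3, ], D0[4:8, ]), log(2), tolerance = 1e-9)

  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  expect_equal(domain_discriminator(su$state, Z[perm, ]), D[perm, ])
  expect_error(domain_discriminator(su$state, Z[, 1:3]), "width")
})

test_that("classification loss matches closed forms and a softmax oracle", {
  expect_equal(classification_loss(matrix(0, 3, 4), c(0, 1, 3)), log(4),
               tolerance = 1e-9)
  hot <- matrix(0, 2, 3)
  hot[cbind(1:2, c(1, 3))] <- 20
  expect_lt(classification_loss(hot, c(0, 2)), 1e-7)

  set.seed(15)
  lg <- matrix(rnorm(12, sd = 2), 4, 3)
  y <- c(0, 2, 1, 1)
  oracle <- -mean(sapply(1:4, function(i)
    log(exp(lg[i, y[i] + 1]) / sum(exp(lg[i, ])))))
  expect_equal(classification_loss(lg, y), oracle, tolerance = 1e-10)
  expect_error(classification_loss(lg, c(0, 1, 3, 1)), "\\[0, 3\\)")
})

test_that("domain loss labels the source block 0 and the target block 1", {
  # strong class-0 logits for source, class-1 for target -> near-zero loss
  Ds <- matrix(c(20, -20), 2, 2, byrow = TRUE)
  Dt <- matrix(c(-20, 20), 3, 2, byrow = TRUE)
  expect_lt(domain_loss(Ds, Dt), 1e-7)
  # swapped blocks -> heavily penalized, confirming the [0,0,1,1,1] layout
  expect_gt(domain_loss(Dt, Ds), 10)
  # equals an explicit cross-entropy with that label vector
  set.seed(16)
  Ds <- matrix(rnorm(4), 2, 2); Dt <- matrix(rnorm(6), 3, 2)
  expect_equal(domain_loss(Ds, Dt),
               classification_loss(rbind(Ds, Dt), c(0, 0, 1, 1, 1)),
               tolerance = 1e-12)
})

test_that("the reversal schedule starts at zero and increases to ~1", {
  E <- 200
  expect_identical(grl_schedule(0, E), 0)
  expect_equal(grl_schedule(E, E), 2 / (1 + exp(-10)) - 1, tolerance = 1e-12)
  expect_equal(grl_schedule(E / 2, E), 2 / (1 + exp(-5)) - 1, tolerance = 1e-12)
  gam <- grl_schedule(0:E, E)
  expect_true(all(diff(gam) > 0))
  expect_true(all(gam >= 0 & gam < 1))
})

test_that("total loss is the lambda-weighted sum", {
  expect_equal(total_loss(log(4), log(2), 1), log(8), tolerance = 1e-12)
  expect_equal(total_loss(1.3, 0.7, 0), 1.3)
  l <- seq(0, 2, by = 0.5)
  expect_equal(total_loss(1, 2, l), 1 + 2 * l)
})

test_that("one adversarial step helps the discriminator and hurts the encoder", {
  su <- random_gda_setup(C = 20, seed = 21)
  p <- su$state$params
  full <- atacAnno:::gda_grads(p, su$g_s, su$labels, su$g_t, K = 2,
                               gamma = 1, lambda = 1)
  cls_only <- atacAnno:::gda_grads(p, su$g_s, su$labels, su$g_t, K = 2,
                                   gamma = 1, lambda = 0)
  gdom <- Map(`-`, full$grads, cls_only$grads)  # gradient of L_dom alone
  lr <- 1e-3
  loss_dom_at <- function(pp)
    atacAnno:::gda_grads(pp, su$g_s, su$labels, su$g_t, K = 2,
                         gamma = 1, lambda = 1)$loss_dom
  base <- loss_dom_at(p)

  p_disc <- p
  for (nm in c("V1", "c1", "V2", "c2")) p_disc[[nm]] <- p[[nm]] - lr * gdom[[nm]]
  expect_lt(loss_dom_at(p_disc), base)

  p_enc <- p
  for (nm in c("W1", "W2")) p_enc[[nm]] <- p[[nm]] - lr * gdom[[nm]]
  expect_gt(loss_dom_at(p_enc), base)
})

test_that("gda gradients pass a finite-difference check on the total loss", {
  su <- random_gda_setup(C = 8, d = 3, seed = 31, k = 2)
  p <- su$state$params
  res <- atacAnno:::gda_grads(p, su$g_s, su$labels, su$g_t, K = 2,
                              gamma = 0.5, lambda = 0.8)
  # with the GRL treated as identity in the forward pass, the encoder part of
  # the analytic gradient must equal -gamma times the true domain gradient
  # plus the classification gradient; check total-loss FD on the
  # discriminator and the classification path, where forward = loss
  total_at <- function(pp) {
    r <- atacAnno:::gda_grads(pp, su$g_s, su$labels, su$g_t, K = 2,
                              gamma = 0.5, lambda = 0.8)
    r$loss_cls + 0.8 * r$loss_dom
  }
  eps <- 1e-5
  set.seed(32)
  for (nm in c("V1", "V2", "c1", "c2", "W3")) {
    idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      fd <- (total_at(pp) - total_at(pm)) / (2 * eps)
      expect_equal(res$grads[[nm]][i], fd, tolerance = 1e-5)
    }
  }
})

test_that("node variance of the target representation shrinks as K grows", {
  pts <- matrix(seq_len(15) + rnorm(15, sd = 0.1), 15, 1)
  g <- graph_from_points(pts, k = 2)  # connected chain-like graph
  for (seed in c(1, 2, 3)) {
    su <- random_gda_setup(d = 1, seed = seed)
    su$state$params$W1 <- matrix(rnorm(8), 1, 8)
    v <- sapply(1:5, function(K) {
      f <- atacAnno:::gda_fwd(su$state$params, g, K = K)
      sum(apply(f$Z, 2, stats::var))
    })
    expect_true(all(diff(v) <= 1e-10))
  }
})

test_that("weights are shared: mutating W2 changes both forward paths", {
  su <- random_gda_setup()
  s0 <- source_forward(su$state, su$g_s)
  t0 <- target_forward(su$state, su$g_t)
  su$state$params$W2 <- su$state$params$W2 * 2
  expect_false(isTRUE(all.equal(source_forward(su$state, su$g_s), s0)))
  expect_false(isTRUE(all.equal(target_forward(su$state, su$g_t), t0)))
})

test_that("training is deterministic and, with lambda = 0 on identical graphs
           in equivalence mode, source and target predictions coincide", {
  su <- random_gda_setup(C = 15, seed = 51)
  cfg <- gda_config(n_classes = 3, hidden1 = 8, hidden2 = 6, K = 0, lambda = 0,
                    epochs = 30, discriminator_hidden = 4, seed = 51)
  st1 <- train_gda(su$g_s, su$labels, su$g_s, cfg)
  st2 <- train_gda(su$g_s, su$labels, su$g_s, cfg)
  expect_identical(st1$params, st2$params)
  expect_equal(target_forward(st1, su$g_s), source_forward(st1, su$g_s),
               tolerance = 1e-12)
  expect_equal(nrow(st1$log), 30L)
  expect_true(all(is.finite(st1$log$total)))

  expect_error(train_gda(su$g_s, su$labels, su$g_t,
                         gda_config(n_classes = 2, seed = 1)),
               "distinct source labels")
})

test_that("annotation returns normalized probabilities and breaks ties low", {
  # craft a state whose logits are [x, x, -x]: tie between classes 1 and 2
  cfg <- gda_config(n_classes = 3, hidden1 = 1, hidden2 = 1, K = 1,
                    seed = 1, epochs = 1, discriminator_hidden = 1)
  st <- atacAnno:::gda_init(1, cfg)
  st$params$W1 <- matrix(1, 1, 1)
  st$params$W2 <- matrix(1, 1, 1)
  st$params$W3 <- matrix(c(1, 1, -1), 1, 3)
  g <- edgeless_graph(matrix(1, 1, 1))
  out <- annotate_cells(st, g, c("alpha", "beta", "gamma"))
  expect_equal(out$predicted_label, "alpha")
  expect_equal(sum(out[1, c("alpha", "beta", "gamma")]), 1, tolerance = 1e-6)
  expect_error(annotate_cells(st, g, c("a", "b")), "class names")

  # permuting target nodes permutes predictions identically
  su <- random_gda_setup(C = 9, seed = 61)
  cfg2 <- gda_config(n_classes = 3, hidden1 = 8, hidden2 = 6, K = 2,
                     epochs = 10, discriminator_hidden = 4, seed = 61)
  stt <- train_gda(su$g_s, su$labels, su$g_t, cfg2)
  pred <- annotate_cells(stt, su$g_t, c("a", "b", "c"))
  perm <- sample(9)
  gp <- su$g_t
  gp$features <- gp$features[perm, , drop = FALSE]
  gp$adjacency <- gp$adjacency[perm, perm]
  gp$node_ids <- gp$node_ids[perm]
  gp <- normalize_adjacency(gp)
  predp <- annotate_cells(stt, gp, c("a", "b", "c"))
  expect_equal(predp$predicted_label, pred$predicted_label[perm])
})
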