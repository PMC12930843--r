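test_that("forward pass matches hand computation and the zero map", {
  cfg <- encoder_config(hidden_dims = 2L, batch_norm = FALSE, seed = 1)
  st <- atacAnno:::encoder_init(2L, 2L, cfg)
  st$W[[1]][] <- 0; st$W[[2]][] <- 0
  st$b[[1]][] <- 0; st$b[[2]][] <- 0
  expect_equal(encoder_forward(st, matrix(c(1, -2), 1)), matrix(0, 1, 2))

  # identity weights, no batch-norm: X = [1, -2] -> ReLU -> [1, 0]
  st$W[[1]] <- diag(2); st$W[[2]] <- diag(2)
  expect_equal(encoder_forward(st, matrix(c(1, -2), 1)), matrix(c(1, 0), 1))

  expect_error(encoder_forward(st, matrix(0, 1, 3)), "layer 1")
})

test_that("eval-mode outputs are row-independent of the rest of the batch", {
  cfg <- encoder_config(hidden_dims = c(4L, 3L), seed = 2, epochs = 2,
                        batch_size = 8)
  sim <- small_sim(seed = 3, n_types = 2, cells = 5, peaks = 60)
  pe <- embed_peaks(sim$sequences, embedder_spec(k = 2, d = 6, seed = 2))
  st <- train_encoder(pe, sim$source$matrix, cfg)
  X <- pe$values[1:4, ]
  single <- encoder_forward(st, X)
  doubled <- encoder_forward(st, rbind(X, X))
  expect_equal(doubled[1:4, ], single, tolerance = 1e-12)
})

test_that("bce_loss matches closed forms and a per-element oracle", {
  expect_equal(bce_loss(matrix(0), matrix(1)), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(matrix(0), matrix(0)), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(matrix(20), matrix(1)), log1p(exp(-20)), tolerance = 1e-12)

  set.seed(11)
  x <- matrix(rnorm(6, sd = 3), 3, 2)
  y <- matrix(rbinom(6, 1, 0.5), 3, 2)
  s <- 1 / (1 + exp(-x))
  oracle <- -mean(y * log(s) + (1 - y) * log(1 - s))
  expect_equal(bce_loss(x, y), oracle, tolerance = 1e-10)

  expect_error(bce_loss(matrix(0), matrix(0.5)), "binary")
  expect_error(bce_loss(matrix(0, 1, 2), matrix(0, 2, 1)), "shape")
})

test_that("analytic BCE gradient sigma(x) - y passes finite differences", {
  set.seed(12)
  x <- matrix(rnorm(8), 2, 4)
  y <- matrix(rbinom(8, 1, 0.5), 2, 4)
  analytic <- (1 / (1 + exp(-x)) - y) / length(x)  # grad of the mean
  h <- 1e-6
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    fd <- (bce_loss(xp, y) - bce_loss(xm, y)) / (2 * h)
    expect_equal(fd, analytic[i], tolerance = 1e-5)
  }
})

test_that("training is seed-deterministic and fits a learnable problem", {
  sim <- small_sim(seed = 4, n_types = 2, cells = 10, peaks = 200)
  pe <- embed_peaks(sim$sequences, embedder_spec(k = 3, d = 16, seed = 4))
  cfg <- encoder_config(hidden_dims = c(16L, 8L), epochs = 15, seed = 7)
  st1 <- train_encoder(pe, sim$source$matrix, cfg)
  st2 <- train_encoder(pe, sim$source$matrix, cfg)
  expect_identical(st1$W, st2$W)
  expect_identical(st1$bn, st2$bn)

  # loss mostly decreases epoch over epoch
  dec <- diff(st1$loss_history) <= 1e-8
  expect_gte(mean(dec), 0.8)
})

test_that("a single always-accessible cell is fit to near-zero loss", {
  set.seed(5)
  n <- 40
  X <- peak_embedding_matrix(matrix(rnorm(n * 3), n, 3), sprintf("p%d", 1:n))
  m <- cell_peak_matrix(matrix(1, 1, n), "only_cell", X$peak_ids)
  cfg <- encoder_config(hidden_dims = 4L, epochs = 150, batch_size = 40,
                        learning_rate = 0.05, seed = 5, batch_norm = FALSE)
  st <- train_encoder(X, m, cfg)
  expect_lt(st$final_loss, 0.05)
})

test_that("cell embeddings are the output-layer weight columns and satisfy
           the logit decomposition", {
  # embeddings are exactly t(W_out)
  cfg <- encoder_config(hidden_dims = 2L, seed = 3, batch_norm = FALSE)
  st <- atacAnno:::encoder_init(3L, 2L, cfg)
  st$W[[2]] <- matrix(c(1, 2, 3, 4), 2, 2)  # columns (1,2) and (3,4)
  emb <- extract_cell_embeddings(st, c("cell0", "cell1"))
  expect_equal(unname(emb$values), rbind(c(1, 2), c(3, 4)))

  # for random trained-ish states: logits[, c] == H_L %*% w_c + b_c
  sim <- small_sim(seed = 6, n_types = 2, cells = 6, peaks = 80)
  pe <- embed_peaks(sim$sequences, embedder_spec(k = 2, d = 8, seed = 6))
  st2 <- train_encoder(pe, sim$source$matrix,
                       encoder_config(hidden_dims = c(6L, 4L), epochs = 3, seed = 6))
  fwd <- atacAnno:::encoder_fwd(st2, pe$values, train_mode = FALSE)
  HL <- fwd$cache$H[[st2$L + 1]]
  W_out <- st2$W[[st2$L + 1]]
  emb2 <- extract_cell_embeddings(st2)
  for (c in c(1, 5, 12)) {
    expect_equal(fwd$logits[, c],
                 drop(HL %*% emb2$values[c, ]) + st2$b[[st2$L + 1]][c],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(emb2$values[c, ]), unname(W_out[, c]))
  }

  # permuting cell ids permutes rows
  expect_equal(extract_cell_embeddings(st, c("b", "a"))$values[2, ],
               extract_cell_embeddings(st, c("a", "b"))$values[2, ],
               ignore_attr = TRUE)
  expect_error(extract_cell_embeddings(st, letters[1:3]), "3 cell ids")
})

test_that("grouped accessibility with distinct sequence signals separates
           embeddings by cosine similarity", {
  margins <- sapply(0:1, function(s) {
    sim <- simulate_pair(sim_config(n_types = 4, cells_per_type_source = 25,
                                    cells_per_type_target = 25, n_peaks = 800,
                                    peak_length = 100L, seed = s))
    pe <- embed_peaks(sim$sequences, embedder_spec(k = 4, d = 64, seed = s))
    st <- train_encoder(pe, sim$source$matrix,
                        encoder_config(hidden_dims = c(64L, 32L), epochs = 60,
                                       seed = s))
    E <- extract_cell_embeddings(st)$values
    E <- E / sqrt(rowSums(E^2))
    S <- tcrossprod(E)
    diag(S) <- NA
    same <- outer(sim$source$labels$label, sim$source$labels$label, `==`)
    mean(S[same], na.rm = TRUE) - mean(S[!same], na.rm = TRUE)
  })
  expect_true(all(margins > 0))
})
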