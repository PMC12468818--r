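test_that("GRU cell reproduces hand-evaluated special cases", {
  H <- 3
  zero <- list(W_z = matrix(0, H, 2), U_z = matrix(0, H, H), b_z = numeric(H),
               W_r = matrix(0, H, 2), U_r = matrix(0, H, H), b_r = numeric(H),
               W_h = matrix(0, H, 2), U_h = matrix(0, H, H), b_h = numeric(H))
  expect_equal(gru_cell_step(c(1, -1), numeric(H), zero), numeric(H))

  # zero params, nonzero state: z = 0.5, candidate = 0, so h' = 0.5 * h
  v <- c(0.4, -0.6, 0.2)
  expect_equal(gru_cell_step(c(1, 2), v, zero), 0.5 * v)

  expect_error(gru_cell_step(c(1, 2, 3), v, zero), "sizes")
})

test_that("vectorized GRU cell matches the scalar-loop equations", {
  set.seed(10)
  for (rep in 1:20) {
    p <- random_cell_params(3, 2)
    x <- stats::rnorm(3)
    h <- stats::runif(2, -0.9, 0.9)
    expect_equal(gru_cell_step(x, h, p), gru_cell_scalar_oracle(x, h, p),
                 tolerance = 1e-10)
  }
})

test_that("bidirectional layer concatenates directions and respects symmetry", {
  set.seed(11)
  fwd <- random_cell_params(3, 2)
  bwd <- random_cell_params(3, 2)

  # T = 1: both directions see only x_1 from zero state
  X1 <- matrix(stats::rnorm(3), 1, 3)
  out1 <- run_layer_bidirectional(X1, fwd, bwd)
  expect_equal(out1[1, 1:2], gru_cell_step(X1[1, ], c(0, 0), fwd))
  expect_equal(out1[1, 3:4], gru_cell_step(X1[1, ], c(0, 0), bwd))

  # default-sized model: concatenation doubles the hidden width
  params <- model_init(model_config(), seed = 0)
  X <- matrix(stats::rnorm(5 * 64), 5, 64)
  expect_equal(ncol(run_layer_bidirectional(X, params$layers[[1]]$fwd,
                                            params$layers[[1]]$bwd)), 128)

  # tied parameters + time reversal: rows reverse and halves swap, exactly
  X5 <- matrix(stats::rnorm(15), 5, 3)
  tied <- run_layer_bidirectional(X5, fwd, fwd)
  rev_out <- run_layer_bidirectional(X5[5:1, ], fwd, fwd)
  expect_identical(tied, rev_out[5:1, c(3, 4, 1, 2)])

  expect_error(run_layer_bidirectional(matrix(numeric(0), 0, 3), fwd, bwd),
               "non-empty")
})

test_that("encode is deterministic in eval mode and collapses for L = 1", {
  params <- tiny_model(num_layers = 2, dropout_p = 0.5, seed = 3)
  X <- matrix(stats::rnorm(12), 4, 3)
  a <- encode(X, params, training = FALSE)
  b <- encode(X, params, training = FALSE)
  expect_identical(a, b)

  p0 <- tiny_model(num_layers = 2, dropout_p = 0, seed = 3)
  set.seed(99)
  tr <- encode(X, p0, training = TRUE)
  expect_identical(tr, encode(X, p0, training = FALSE))

  p1 <- tiny_model(num_layers = 1, seed = 4)
  expect_identical(encode(X, p1),
                   run_layer_bidirectional(X, p1$layers[[1]]$fwd,
                                           p1$layers[[1]]$bwd))
  expect_error(encode(matrix(0, 4, 5), p1), "input_size")
})

test_that("hidden states stay in (-1, 1) from zero init", {
  set.seed(12)
  params <- model_init(model_config(input_size = 8, hidden_size = 6,
                                    num_layers = 3, dropout_p = 0), seed = 5)
  X <- matrix(stats::rnorm(30 * 8, sd = 3), 30, 8)
  H <- encode(X, params)
  expect_true(all(H > -1 & H < 1))
})

test_that("temporal mean pooling matches a scalar-loop mean", {
  expect_equal(temporal_mean_pool(matrix(7, 4, 3)), c(7, 7, 7))
  one <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(temporal_mean_pool(one), c(1, 2, 3))
  set.seed(13)
  M <- matrix(stats::rnorm(20), 5, 4)
  loop_mean <- numeric(4)
  for (j in 1:4) {
    s <- 0
    for (i in 1:5) s <- s + M[i, j]
    loop_mean[j] <- s / 5
  }
  expect_equal(temporal_mean_pool(M), loop_mean, tolerance = 1e-12)
  expect_error(temporal_mean_pool(matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("head produces manual dot products and respects class count", {
  head <- list(W = matrix(0, 2, 4), b = c(0, 0))
  expect_equal(head_logits(c(1, 2, 3, 4), head), c(0, 0))

  head2 <- list(W = rbind(c(1, 0, 0, 0), c(0, 0, 0, 1)), b = c(0.5, -0.5))
  expect_equal(head_logits(c(1, 2, 3, 4), head2), c(1.5, 3.5))

  p3 <- tiny_model(n_classes = 3, hidden_size = 2)
  expect_equal(nrow(p3$head$W), 3)
  expect_equal(ncol(p3$head$W), 4)
  expect_error(head_logits(c(1, 2), head2), "width")
})

test_that("softmax prediction follows closed forms and shift invariance", {
  expect_equal(predict_class(c(0, 0))$probabilities, c(0.5, 0.5))
  p <- predict_class(c(log(3), 0))
  expect_equal(p$probabilities, c(0.75, 0.25))
  expect_equal(p$label, 1L)

  o <- c(0.3, -1, 2)
  expect_equal(softmax(o), softmax(o + 100))
  expect_equal(sum(softmax(o * 50)), 1)
  expect_equal(predict_class(c(1, 1))$label, 1L)   # tie -> lowest index
  expect_error(predict_class(c(1, NaN)), "finite")
})

test_that("end-to-end forward equals manual stage composition", {
  params <- model_init(model_config(n_classes = 2), seed = 8)
  set.seed(14)
  clip <- waveform(stats::rnorm(12000) * 0.1, 16000)
  out <- model_forward(clip, params)
  x <- preprocess(clip)
  manual <- predict_class(head_logits(
    temporal_mean_pool(encode(logmel(x)$values, params)), params$head))
  expect_identical(out$probabilities, manual$probabilities)
  expect_identical(out$label, manual$label)

  # determinism across calls
  expect_identical(model_forward(clip, params)$probabilities,
                   out$probabilities)
})

test_that("parameter initialization is seeded and respects layer widths", {
  cfg <- model_config(input_size = 5, hidden_size = 4, num_layers = 2)
  a <- model_init(cfg, seed = 21)
  b <- model_init(cfg, seed = 21)
  expect_identical(a$layers, b$layers)
  expect_false(identical(a$layers, model_init(cfg, seed = 22)$layers))
  expect_equal(dim(a$layers[[1]]$fwd$W_z), c(4, 5))
  expect_equal(dim(a$layers[[2]]$fwd$W_z), c(4, 8))   # deeper layers see 2H
  lim <- 1 / sqrt(4)
  expect_true(all(abs(unlist(a$layers)) <= lim))
})
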