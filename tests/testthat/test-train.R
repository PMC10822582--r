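test_that("loss weights are inverse-frequency, mean-1, and monotone", {
  w <- compute_loss_weights(c(a = 90, b = 9, c = 1))
  expect_equal(mean(w), 1)
  expect_true(w["a"] < w["b"] && w["b"] < w["c"])
  expect_equal(unname(w["a"] / w["b"]), 9 / 90 * 90 / 9 * (9 / 90),
               tolerance = 1e-12)  # ratio = count_b / count_a
  # exponent 0 disables balancing
  expect_equal(unname(compute_loss_weights(c(a = 90, b = 10), exponent = 0)),
               c(1, 1))
  # intermediate exponent interpolates
  w5 <- compute_loss_weights(c(a = 100, b = 1), exponent = 0.5)
  w1 <- compute_loss_weights(c(a = 100, b = 1), exponent = 1)
  expect_true(w5["b"] / w5["a"] < w1["b"] / w1["a"])
})

test_that("unseen classes get the largest observed weight", {
  w <- compute_loss_weights(c(a = 10, b = 0, c = 1))
  expect_equal(unname(w["b"]), unname(w["c"]))
  expect_error(compute_loss_weights(c(a = 0, b = 0)), "zero")
  expect_error(compute_loss_weights(c(a = -1, b = 2)), "negative")
})

test_that("loss weights recurse over lists of label spaces", {
  w <- compute_loss_weights(list(x = c(a = 1, b = 1), y = c(c = 3, d = 1)))
  expect_named(w, c("x", "y"))
  expect_equal(unname(w$x), c(1, 1))
})

test_that("adam decreases a quadratic and clips the gradient norm", {
  theta <- c(5, -3)
  st <- fgie:::adam_init(2)
  for (i in 1:300) {
    g <- 2 * theta          # d/dtheta of sum(theta^2)
    upd <- fgie:::adam_step(theta, g, st, lr = 0.1, clip = Inf)
    theta <- upd$theta
    st <- upd$state
  }
  expect_lt(sum(theta^2), 1e-2)
  # clipping: one step with a huge gradient moves no coordinate more than lr
  theta2 <- c(0, 0)
  st2 <- fgie:::adam_init(2)
  upd2 <- fgie:::adam_step(theta2, c(1e6, 0), st2, lr = 0.1, clip = 1)
  expect_lt(max(abs(upd2$theta)), 0.1 + 1e-8)
})

test_that("reference tagging loss is zero iff predictions are perfect", {
  P <- diag(3)[c(1, 2, 3), ]
  gold <- list(c(1L, 2L, 3L))
  expect_equal(tagging_loss(list(P), gold), 0)
  P2 <- matrix(1 / 3, 3, 3)
  expect_gt(tagging_loss(list(P2), gold), 0)
  # weights scale the per-class terms
  w <- list(c(2, 1, 1))
  expect_equal(tagging_loss(list(P2), gold, w),
               -(2 + 1 + 1) * log(1 / 3))
})

test_that("reference linking loss matches hand-computed BCE", {
  pred <- cbind(link = c(0.9, 0.2), same = c(0.5, 0.5))
  manual <- -(log(0.9) + log(1 - 0.2)) + 2 * (-2 * log(0.5))
  expect_equal(linking_loss(pred, c(1, 0), c(1, 0), lambda = 2), manual)
  # lambda = 0 ignores the same-tag head entirely
  expect_equal(linking_loss(c(0.9, 0.2), c(1, 0), lambda = 0),
               -(log(0.9) + log(1 - 0.2)))
})

test_that("compiled tagging loss agrees with the R reference", {
  set.seed(5)
  spec <- fg_encoder_spec(vocab_size = 20, max_len = 12, d_model = 8,
                          n_layers = 1, n_heads = 2, d_ff = 16)
  hs <- c(3L, 4L, 2L, 2L, 3L)
  n <- fgie:::cpp_tagger_param_count(spec, hs)
  theta <- c(fgie:::init_encoder_params(spec),
             rnorm(n - fgie:::cpp_encoder_param_count(spec), sd = 0.05))
  ids <- sample.int(20, 6)
  labs <- lapply(hs, function(C) sample.int(C, 6, replace = TRUE))
  ws <- lapply(hs, function(C) runif(C, 0.5, 1.5))
  probs <- fgie:::cpp_tagger_forward(theta, spec, hs, ids)
  ref <- tagging_loss(probs, labs, ws)
  got <- fgie:::cpp_tagger_loss_grad(theta, spec, hs, ids, labs, ws,
                                     rep(1, 5), FALSE)$loss
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("compiled tagger gradient matches finite differences", {
  set.seed(6)
  spec <- fg_encoder_spec(vocab_size = 20, max_len = 12, d_model = 8,
                          n_layers = 2, n_heads = 2, d_ff = 16)
  hs <- c(3L, 4L, 2L, 2L, 3L)
  n <- fgie:::cpp_tagger_param_count(spec, hs)
  theta <- c(fgie:::init_encoder_params(spec),
             rnorm(n - fgie:::cpp_encoder_param_count(spec), sd = 0.05))
  ids <- sample.int(20, 5)
  labs <- lapply(hs, function(C) sample.int(C, 5, replace = TRUE))
  ws <- lapply(hs, function(C) runif(C, 0.5, 1.5))
  scales <- c(1, 0.5, 1, 2, 1)
  an <- fgie:::cpp_tagger_loss_grad(theta, spec, hs, ids, labs, ws, scales,
                                    TRUE)$grad
  idx <- sample.int(n, 40)
  eps <- 1e-5
  f <- function(th) fgie:::cpp_tagger_loss_grad(th, spec, hs, ids, labs, ws,
                                                scales, FALSE)$loss
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - an[idx])), 1e-6)
})

test_that("compiled linker gradient matches finite differences", {
  set.seed(7)
  spec <- fg_encoder_spec(vocab_size = 20, max_len = 12, d_model = 8,
                          n_layers = 2, n_heads = 2, d_ff = 16)
  nl <- fgie:::cpp_linker_param_count(spec)
  theta <- c(fgie:::init_encoder_params(spec),
             rnorm(nl - fgie:::cpp_encoder_param_count(spec), sd = 0.05))
  ids <- sample.int(20, 6)
  pi_ <- c(1L, 2L, 3L, 1L); pj <- c(4L, 5L, 6L, 2L)
  yl <- c(1, 0, 1, 0); ys <- c(0, 1, 0, 1)
  wl <- runif(4, 0.5, 1.5); wsm <- runif(4, 0.5, 1.5)
  for (lambda in c(0.7, 0)) {
    an <- fgie:::cpp_linker_loss_grad(theta, spec, ids, pi_, pj, yl, ys,
                                      wl, wsm, lambda, TRUE)$grad
    idx <- sample.int(nl, 40)
    eps <- 1e-5
    f <- function(th) fgie:::cpp_linker_loss_grad(th, spec, ids, pi_, pj, yl,
                                                  ys, wl, wsm, lambda,
                                                  FALSE)$loss
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      (f(tp) - f(tm)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - an[idx])), 1e-6)
  }
})

test_that("compiled linker loss agrees with the R reference", {
  set.seed(8)
  spec <- fg_encoder_spec(vocab_size = 20, max_len = 12, d_model = 8,
                          n_layers = 1, n_heads = 2, d_ff = 16)
  nl <- fgie:::cpp_linker_param_count(spec)
  theta <- c(fgie:::init_encoder_params(spec),
             rnorm(nl - fgie:::cpp_encoder_param_count(spec), sd = 0.05))
  ids <- sample.int(20, 6)
  pi_ <- c(1L, 2L); pj <- c(4L, 5L)
  pred <- fgie:::cpp_linker_forward(theta, spec, ids, pi_, pj)
  ref <- linking_loss(pred, c(1, 0), c(0, 1), w_link = c(2, 1),
                      w_same = c(1, 3), lambda = 0.5)
  got <- fgie:::cpp_linker_loss_grad(theta, spec, ids, pi_, pj, c(1, 0),
                                     c(0, 1), c(2, 1), c(1, 3), 0.5,
                                     FALSE)$loss
  expect_equal(got, ref, tolerance = 1e-10)
})
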