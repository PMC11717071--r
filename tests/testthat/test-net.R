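test_that("attention weights normalize and builds are deterministic", {
  m <- build_model(net_config(seed = 4), seq_len = 12)
  X <- with_seed_local(9, matrix(runif(7 * 12), 7, 12))
  w <- attention_weights(m, X)
  expect_equal(dim(w), c(7L, 12L))
  expect_true(all(w >= 0))
  expect_equal(rowSums(w), rep(1, 7), tolerance = 1e-6)

  m2 <- build_model(net_config(seed = 4), seq_len = 12)
  p1 <- specalib:::cpp_net_forward(m$parameters, X, TRUE, TRUE)$pred
  p2 <- specalib:::cpp_net_forward(m2$parameters, X, TRUE, TRUE)$pred
  expect_identical(p1, p2)
  expect_length(p1, 7)

  m3 <- build_model(net_config(seed = 5), seq_len = 12)
  p3 <- specalib:::cpp_net_forward(m3$parameters, X, TRUE, TRUE)$pred
  expect_false(identical(p1, p3))
})

test_that("backpropagation matches finite differences", {
  cfg <- net_config(hidden1 = 3, hidden2 = 4, dense = 5, attn_dim = 3,
                    seed = 2)
  m <- build_model(cfg, seq_len = 8)
  X <- with_seed_local(1, matrix(runif(4 * 8), 4, 8))
  y <- with_seed_local(2, rnorm(4))
  lg <- specalib:::cpp_net_loss_grad(m$parameters, X, y, TRUE, TRUE)
  par <- m$parameters
  eps <- 1e-5
  rel_err <- with_seed_local(3, vapply(1:10, function(k) {
    nm <- sample(names(par), 1)
    ij <- sample(length(par[[nm]]), 1)
    pp <- par; pp[[nm]][ij] <- pp[[nm]][ij] + eps
    pm <- par; pm[[nm]][ij] <- pm[[nm]][ij] - eps
    fd <- (specalib:::cpp_net_loss_grad(pp, X, y, TRUE, TRUE)$loss -
             specalib:::cpp_net_loss_grad(pm, X, y, TRUE, TRUE)$loss) /
      (2 * eps)
    an <- lg$grads[[nm]][ij]
    abs(fd - an) / max(abs(fd), abs(an), 1e-8)
  }, 1))
  expect_lt(max(rel_err), 1e-4)
})

test_that("training recovers a target that is a function of the spectrum", {
  d <- with_seed_local(1, {
    X <- matrix(runif(200 * 20), 200, 20)
    list(X = X, y = rowMeans(X) * 10 + 20)
  })
  m <- bilstm_attention(d$X, d$y, net_config(num_epochs = 30, seed = 1))
  expect_gte(r_squared(d$y, predict(m, d$X)), 0.99)
  # loss decreased over training
  h <- m$history
  expect_equal(nrow(h), 30L)
  expect_lt(h$train_mse[30], h$train_mse[1])
})

test_that("zero-epoch training returns the initialized model", {
  X <- matrix(runif(40), 4, 10)
  m0 <- build_model(net_config(num_epochs = 0, seed = 3), 10)
  m <- train(m0, X, c(19, 22, 25, 28))
  expect_equal(nrow(m$history), 0L)
  expect_true(m$fitted)
  # parameters untouched by a 0-epoch run
  expect_identical(m$parameters, m0$parameters)
})

test_that("prediction is deterministic, batch-consistent and order-sensitive", {
  d <- with_seed_local(2, {
    X <- matrix(runif(80 * 10), 80, 10)
    list(X = X, y = drop(X %*% seq(0.1, 1, length.out = 10)) + 20)
  })
  m <- bilstm_attention(d$X, d$y, net_config(num_epochs = 15, seed = 2))
  p1 <- predict(m, d$X)
  p2 <- predict(m, d$X)
  expect_identical(p1, p2)
  single <- vapply(1:5, function(i)
    predict(m, d$X[i, , drop = FALSE]), 1)
  expect_equal(single, p1[1:5], tolerance = 1e-6)
  # a bidirectional sequence model is sensitive to wavelength order
  expect_false(isTRUE(all.equal(predict(m, d$X[, 10:1]), p1,
                                tolerance = 1e-4)))
  expect_error(predict(m, d$X[, 1:5]), "length mismatch")
  expect_error(predict(build_model(net_config(), 10), d$X), "not fitted")
})

test_that("the merge weights gate the directional streams", {
  m <- build_model(net_config(seed = 6), seq_len = 10)
  X <- with_seed_local(4, matrix(runif(5 * 10), 5, 10))
  par <- m$parameters
  par$m_Wf <- par$m_Wf * 0  # silence the forward stream at the merge
  base <- specalib:::cpp_net_forward(par, X, TRUE, TRUE)$pred
  # perturbing the forward layer-2 weights changes nothing...
  par_f <- par; par_f$l2f_U <- par_f$l2f_U * 2; par_f$l2f_W <- par_f$l2f_W + 0.3
  expect_equal(specalib:::cpp_net_forward(par_f, X, TRUE, TRUE)$pred,
               base, tolerance = 1e-12)
  # ...while perturbing the backward layer-2 weights does
  par_b <- par; par_b$l2b_U <- par_b$l2b_U * 2; par_b$l2b_W <- par_b$l2b_W + 0.3
  expect_false(isTRUE(all.equal(
    specalib:::cpp_net_forward(par_b, X, TRUE, TRUE)$pred, base,
    tolerance = 1e-6)))
})

test_that("architecture variants reduce as documented", {
  X <- with_seed_local(5, matrix(runif(30), 3, 10))
  uni <- build_model(net_config(seed = 1), 10, bidirectional = FALSE)
  expect_false("l1b_W" %in% names(uni$parameters))
  pool <- build_model(net_config(seed = 1), 10, attention = FALSE)
  w <- attention_weights(pool, X)
  expect_equal(w, matrix(0.1, 3, 10), tolerance = 1e-12)
})

test_that("checkpoints round-trip bit-exactly through JSON", {
  d <- with_seed_local(6, {
    X <- matrix(runif(50 * 8), 50, 8)
    list(X = X, y = rowMeans(X) + 20)
  })
  m <- bilstm_attention(d$X, d$y, net_config(num_epochs = 5, seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, d$X), predict(m, d$X))
  expect_equal(m2$target_scaler, m$target_scaler)
})
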