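sphere <- function(x) sum(x^2)
box2 <- search_space(c("x1", "x2"), c(-5, -5), c(5, 5))

test_that("the swarm minimizes the sphere function", {
  res <- woa_minimize(sphere, box2, n_whales = 30, max_iterations = 200,
                      seed = 1)
  expect_lt(res$best_fitness, 1e-2)
  expect_equal(unname(res$best_position), c(0, 0), tolerance = 0.1)
})

test_that("best-fitness curves are monotone and bounded to the box", {
  for (s in 1:5) {
    res <- woa_minimize(sphere, box2, n_whales = 8, max_iterations = 30,
                        seed = s)
    expect_true(all(diff(res$best_curve) <= 0))
    pos <- as.matrix(res$audit[, c("x1", "x2")])
    expect_true(all(pos >= -5 & pos <= 5))
  }
})

test_that("the trajectory is deterministic in the seed", {
  a <- woa_minimize(sphere, box2, n_whales = 6, max_iterations = 20,
                    seed = 9)
  b <- woa_minimize(sphere, box2, n_whales = 6, max_iterations = 20,
                    seed = 9)
  expect_identical(a$audit, b$audit)
  c <- woa_minimize(sphere, box2, n_whales = 6, max_iterations = 20,
                    seed = 10)
  expect_false(identical(a$best_position, c$best_position))
})

test_that("the shrinking coefficient collapses whales onto the best position", {
  # a decays linearly from 2 to 0; at the final iteration A = 0, so every
  # whale taking the encircling branch lands exactly on the incumbent best
  res <- woa_minimize(sphere, box2, n_whales = 20, max_iterations = 30,
                      seed = 6)
  pos <- as.matrix(res$audit[, c("x1", "x2")])
  final <- which(res$audit$iteration == 30)
  landed <- vapply(final, function(i) {
    prev <- pos[seq_len(i - 1), , drop = FALSE]
    any(prev[, 1] == pos[i, 1] & prev[, 2] == pos[i, 2])
  }, TRUE)
  expect_true(any(landed))
})

test_that("evaluation bookkeeping matches the swarm size", {
  res <- woa_minimize(sphere, box2, n_whales = 2, max_iterations = 1,
                      seed = 2)
  # 2 initialization evaluations + 2 update evaluations
  expect_equal(res$n_evaluations, 4L)
  expect_equal(nrow(res$audit), 4L)
  expect_equal(sum(res$audit$iteration == 0), 2L)
  expect_equal(sum(res$audit$iteration == 1), 2L)
})

test_that("NaN fitness values are quarantined as +Inf", {
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  expect_warning(res <- woa_minimize(bad, box2, n_whales = 6,
                                     max_iterations = 10, seed = 4),
                 "NaN")
  expect_true(is.finite(res$best_fitness))
})

test_that("positions decode into bounded, typed hyperparameters", {
  sp <- default_search_space()
  expect_equal(sp$names, c("lr", "num_epochs", "batch_size", "hidden1",
                           "hidden2", "dense", "attn_dim"))
  for (s in 1:20) {
    pos <- with_seed_local(s, runif(sp$d, sp$lower, sp$upper))
    v <- decode_position(sp, pos)
    expect_gte(v$lr, 1e-3); expect_lte(v$lr, 1e-1)
    expect_true(v$num_epochs %in% 10:100)
    expect_true(v$batch_size %in% 16:128)
    expect_true(v$hidden1 %in% 1:20 && v$hidden2 %in% 1:20)
    expect_true(v$dense %in% 1:100)
    expect_true(v$attn_dim %in% 1:50)
    expect_true(is.integer(v$num_epochs))
  }
  # rounding is half-up then clamped
  sp2 <- search_space("k", 1, 10, integer = TRUE)
  expect_identical(decode_position(sp2, 2.5)$k, 3L)
  expect_identical(decode_position(sp2, 0.2)$k, 1L)
})

test_that("whale tuning returns audited configs within the space", {
  d <- with_seed_local(2, {
    X <- matrix(runif(60 * 8), 60, 8)
    list(X = X, y = drop(X %*% seq(0.2, 1.6, length.out = 8)) + 20)
  })
  sp_small <- search_space(c("num_epochs", "hidden1"), c(2, 1), c(8, 4),
                           integer = c(TRUE, TRUE))
  tn <- tune_network(d$X[1:40, ], d$y[1:40], d$X[41:60, ], d$y[41:60],
                     space = sp_small, n_whales = 2, max_iterations = 1,
                     seed = 1)
  expect_s3_class(tn$config, "net_config")
  expect_equal(nrow(tn$audit), 4L)  # 2 whales x (init + 1 iteration)
  expect_true(all(tn$audit$num_epochs %in% 2:8))
  expect_true(all(tn$audit$hidden1 %in% 1:4))
  expect_equal(min(tn$audit$fitness), tn$best_fitness)
})
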