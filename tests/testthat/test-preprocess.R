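test_that("dark/white correction follows the reflectance ratio", {
  raw <- matrix(runif(12, 0.2, 0.9), 3, 4)
  dark <- matrix(0.1, 3, 4)
  white <- matrix(1.0, 3, 4)
  expect_equal(black_white_correct(dark, dark, white),
               matrix(0, 3, 4))
  expect_equal(black_white_correct(white, dark, white),
               matrix(1, 3, 4))
  expect_equal(black_white_correct(matrix(0.6), matrix(0.2), matrix(1.0)),
               matrix(0.5))
  expect_equal(black_white_correct(raw, dark, white),
               (raw - dark) / (white - dark))
  # single reference rows broadcast across spectra
  expect_equal(black_white_correct(raw, dark[1, , drop = FALSE],
                                   white[1, , drop = FALSE]),
               (raw - dark) / (white - dark))
})

test_that("zero white-dark denominators are reported, not clipped", {
  white <- matrix(1, 2, 3); white[, 2] <- 0.1
  dark <- matrix(0.1, 2, 3)
  expect_error(black_white_correct(matrix(0.5, 2, 3), dark, white), "2")
})

test_that("scaling operators learn and reproduce their statistics", {
  X <- matrix(rnorm(60, 5, 2), 12, 5)
  mc <- apply_chain(fit_chain(preprocess_chain(list("MC")), X), X)
  expect_lt(max(abs(colMeans(mc))), 1e-10)

  ss <- apply_chain(fit_chain(preprocess_chain(list("SS")), X), X)
  expect_lt(max(abs(colMeans(ss))), 1e-10)
  expect_equal(apply(ss, 2, sd), rep(1, 5), tolerance = 1e-10,
               ignore_attr = TRUE)

  mms <- apply_chain(fit_chain(preprocess_chain(list("MMS")), X), X)
  expect_equal(apply(mms, 2, min), rep(0, 5), ignore_attr = TRUE)
  expect_equal(apply(mms, 2, max), rep(1, 5), ignore_attr = TRUE)
})

test_that("constant columns are rejected with the offending band", {
  X <- matrix(rnorm(40), 10, 4)
  X[, 3] <- 2
  expect_error(fit_chain(preprocess_chain(list("SS")), X), "3")
  expect_error(fit_chain(preprocess_chain(list("MMS")), X), "3")
})

test_that("Savitzky-Golay filtering reproduces polynomials and derivatives", {
  idx <- seq_len(40)
  quad <- 2 + 0.3 * idx - 0.01 * idx^2
  X <- rbind(quad, quad + 1)
  sg <- fit_chain(preprocess_chain(list(list(op = "SG", window = 11,
                                             order = 2))), X)
  expect_equal(apply_chain(sg, X), X, tolerance = 1e-8,
               ignore_attr = TRUE)

  ramp <- rbind(0.5 * idx + 3, 0.5 * idx - 1)
  d1 <- fit_chain(preprocess_chain(list("D1")), ramp)
  expect_equal(as.numeric(apply_chain(d1, ramp)),
               rep(0.5, length(ramp)), tolerance = 1e-10)

  d2 <- fit_chain(preprocess_chain(list("D2")), ramp)
  expect_lt(max(abs(apply_chain(d2, ramp))), 1e-10)
})

test_that("finite-difference derivatives shrink the band count", {
  X <- matrix(rnorm(30), 3, 10)
  d1 <- fit_chain(preprocess_chain(list(list(op = "D1", mode = "diff"))), X)
  expect_equal(ncol(apply_chain(d1, X)), 9L)
  d2 <- fit_chain(preprocess_chain(list(list(op = "D2", mode = "diff"))), X)
  expect_equal(ncol(apply_chain(d2, X)), 8L)
})

test_that("chains keep calibration statistics when applied to shifted data", {
  X <- matrix(rnorm(50), 10, 5)
  ch <- fit_chain(preprocess_chain(list("MC")), X)
  X_mc <- apply_chain(ch, X)
  shifted <- apply_chain(ch, X + 3)
  expect_equal(shifted, X_mc + 3, tolerance = 1e-12)
})

test_that("chain application equals stepwise application", {
  X <- matrix(rnorm(200), 10, 20)
  chain <- fit_chain(preprocess_chain(list("MC",
                                           list(op = "SG", window = 7,
                                                order = 2))), X)
  mc_only <- fit_chain(preprocess_chain(list("MC")), X)
  step1 <- apply_chain(mc_only, X)
  sg_only <- fit_chain(preprocess_chain(list(list(op = "SG", window = 7,
                                                  order = 2))), step1)
  expect_equal(apply_chain(chain, X), apply_chain(sg_only, step1),
               tolerance = 1e-12)
})

test_that("smoothing does not inflate noise variance on smooth signals", {
  wl <- seq(400, 1000, length.out = 80)
  smooth <- 0.5 + 0.3 * sin(wl / 120)
  worse <- 0
  for (s in 1:50) {
    noisy <- smooth + with_seed_local(s, rnorm(80, 0, 0.01))
    sg <- fit_chain(preprocess_chain(list("SG")), rbind(noisy, noisy))
    filtered <- apply_chain(sg, rbind(noisy, noisy))[1, ]
    if (var(filtered - smooth) > var(noisy - smooth)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("misuse is caught early", {
  X <- matrix(rnorm(20), 4, 5)
  ch <- preprocess_chain(list("MC"))
  expect_error(apply_chain(ch, X), "not fitted")
  fitted <- fit_chain(ch, X)
  expect_error(apply_chain(fitted, X[, 1:3]), "mismatch")
  expect_error(preprocess_chain(list("XX")), "unknown")
  expect_error(preprocess_chain(list(list(op = "SG", window = 4))), "odd")
})
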