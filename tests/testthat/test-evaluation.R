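test_that("rmse follows its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2), tolerance = 1e-7)
  expect_equal(rmse(5, 7.5), 2.5)
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("r_squared follows its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1.0)
  y <- c(4, 7, 2, 9)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0.0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("rpd transforms prediction R2 as 1/sqrt(1 - R2)", {
  expect_equal(rpd(0), 1.0)
  expect_equal(rpd(0.75), 2.0)
  expect_equal(rpd(0.96), 5.0)
  expect_error(rpd(1), "rp2")
})

test_that("rpd equals sd(y)/RMSE for predictions scored by r_squared", {
  for (s in 1:200) {
    d <- with_seed_local(s, {
      n <- sample(5:50, 1)
      y <- rnorm(n, 22, 2)
      list(y = y, yhat = y + rnorm(n, 0, 0.5))
    })
    r2 <- r_squared(d$y, d$yhat)
    sd_pop <- sqrt(mean((d$y - mean(d$y))^2))
    expect_equal(rpd(r2), sd_pop / rmse(d$y, d$yhat), tolerance = 1e-9)
  }
})

test_that("metrics agree with independent two-line oracles", {
  for (s in 1:100) {
    d <- with_seed_local(300 + s, {
      n <- sample(4:60, 1)
      list(y = rnorm(n, 20, 3), yhat = rnorm(n, 20, 3))
    })
    expect_equal(rmse(d$y, d$yhat),
                 sqrt(sum((d$y - d$yhat)^2) / length(d$y)),
                 tolerance = 1e-12)
    expect_equal(r_squared(d$y, d$yhat),
                 1 - sum((d$y - d$yhat)^2) / sum((d$y - mean(d$y))^2),
                 tolerance = 1e-12)
  }
})

test_that("percent change reproduces the printed comparison arithmetic", {
  # test-set gain of mean centering over standardization
  expect_equal(percent_change(0.9361, 0.9421, "increase"), 0.641,
               tolerance = 5e-4)
  expect_equal(percent_change(0.1854, 0.1617, "decrease"), 12.78,
               tolerance = 5e-3)
  expect_equal(percent_change(3.7, 3.7, "increase"), 0)
  expect_error(percent_change(0, 1, "increase"), "nonzero")
})

test_that("standardizing targets rescales RMSE by exactly the sd factor", {
  d <- with_seed_local(12, {
    y <- rnorm(40, 23, 3)
    list(y = y, yhat = y + rnorm(40, 0, 0.4))
  })
  s <- sd(d$y); m <- mean(d$y)
  raw <- rmse(d$y, d$yhat)
  std <- rmse((d$y - m) / s, (d$yhat - m) / s)
  expect_equal(std * s, raw, tolerance = 1e-12)
  # R2 is scale-invariant
  expect_equal(r_squared(d$y, d$yhat),
               r_squared((d$y - m) / s, (d$yhat - m) / s),
               tolerance = 1e-12)
})

test_that("baselines fit linear synthetic data essentially perfectly", {
  ds <- noiseless_linear_dataset(seed = 2)
  sp <- split_spectra(ds, 0.7, seed = 1)
  pp <- preprocess(preprocess_chain(list("MC")), sp$train$reflectance,
                   sp$test$reflectance)
  rep <- fit_baselines(pp$train, sp$train$analyte, pp$test,
                       sp$test$analyte)
  expect_gte(rep$RP2[rep$model == "PLSR"], 0.999)
  expect_true(all(c("model", "RC2", "RMSEC", "RP2", "RMSEP", "RPD")
                  %in% names(rep)))
  expect_false(any(is.na(as.matrix(rep[, c("RC2", "RMSEC", "RP2",
                                           "RMSEP", "RPD")]))))
  expect_equal(rep$n_train, rep(70L, 3))  # 5 x 20 samples at 7:3
})

test_that("comparison tables recompute pairwise percent changes", {
  reports <- rbind(
    metrics_report("A", c(1, 2, 3), c(1.1, 2, 2.9), c(1, 2, 3),
                   c(0.9, 2.2, 3)),
    metrics_report("B", c(1, 2, 3), c(1, 2.1, 3), c(1, 2, 3),
                   c(1, 2, 3.1)))
  out <- compare_report(reports,
                        list(list("A", "B", "RP2", "increase"),
                             list("A", "B", "RMSEP", "decrease")))
  expect_equal(nrow(out), 2L)
  expect_equal(out$percent_change[1],
               percent_change(reports$RP2[1], reports$RP2[2], "increase"))
  expect_equal(nrow(compare_report(reports, list())), 0L)
  expect_error(compare_report(reports, list(list("A", "Z", "RP2",
                                                 "increase"))), "Z")
})
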