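test_that("spectra tables round-trip through delimited text", {
  ds <- toy_dataset(n = 3, p = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  back <- read_spectra(path)
  expect_equal(nrow(back$reflectance), 3)
  expect_equal(ncol(back$reflectance), 5)
  expect_equal(back$reflectance, ds$reflectance, tolerance = 1e-12)
  expect_equal(back$analyte, ds$analyte, tolerance = 1e-12)
  expect_identical(back$ids, ds$ids)
  # wavelengths survive with at least 6 significant digits
  expect_equal(back$wavelengths, ds$wavelengths, tolerance = 1e-7)

  # header carries >= 6 significant digits
  hdr <- strsplit(readLines(path, 1), ",")[[1]]
  expect_true(all(nchar(gsub("[.-]", "", hdr[-(1:3)])) >= 6 |
                    hdr[-(1:3)] == as.character(ds$wavelengths)))
})

test_that("an empty dataset writes a header-only file", {
  ds <- spectral_dataset(c(500, 600), matrix(numeric(0), 0, 2),
                         numeric(0), character(0), character(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  expect_length(readLines(path), 1)
  back <- read_spectra(path)
  expect_equal(nrow(back$reflectance), 0)
})

test_that("a large dataset writes and re-reads losslessly", {
  ds <- generate_synthetic(synthetic_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  back <- read_spectra(path)
  expect_equal(back$reflectance, ds$reflectance, tolerance = 1e-12)
  expect_equal(back$analyte, ds$analyte, tolerance = 1e-12)
})

test_that("validation rejects blank cells and bad grids", {
  ds <- toy_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  txt <- readLines(path)
  # blank out the analyte of data row 2
  fields <- strsplit(txt[3], ",")[[1]]
  fields[3] <- ""
  txt[3] <- paste(fields, collapse = ",")
  writeLines(txt, path)
  expect_error(read_spectra(path), "row 2")

  expect_error(spectral_dataset(c(600, 500), matrix(0, 1, 2), 20, "A"),
               "increasing")
  expect_error(spectral_dataset(c(500, 600), matrix(c(1, NA), 1, 2),
                                20, "A"), "missing")
  expect_error(spectral_dataset(c(500, 600), matrix(1, 1, 2), -3, "A"),
               "positive")
})

test_that("the default synthetic design yields 800 x 125 with the brand values", {
  ds <- generate_synthetic(synthetic_spec())
  expect_equal(dim(ds$reflectance), c(800L, 125L))
  expect_equal(length(unique(ds$brand)), 5L)
  expect_equal(range(ds$wavelengths), c(400, 1000))
  # per-brand mean analyte stays near its nominal value (jitter sd 0.1)
  nominal <- c(brand1 = 19.0, brand2 = 23.8, brand3 = 28.0,
               brand4 = 25.4, brand5 = 20.2)
  got <- tapply(ds$analyte, ds$brand, mean)[names(nominal)]
  expect_true(all(abs(got - nominal) < 0.15))
})

test_that("zero-noise generation collapses a brand to one spectrum", {
  ds <- generate_synthetic(synthetic_spec(
    rois_per_sample = 1, baseline_drift_sd = 0, sample_noise_sd = 0,
    roi_noise_sd = 0, analyte_jitter_sd = 0))
  b1 <- ds$reflectance[ds$brand == "brand1", ]
  expect_equal(max(apply(b1, 2, function(col) diff(range(col)))), 0)
})

test_that("generation is deterministic in the seed", {
  a <- generate_synthetic(synthetic_spec(seed = 7))
  b <- generate_synthetic(synthetic_spec(seed = 7))
  c <- generate_synthetic(synthetic_spec(seed = 8))
  expect_identical(a$reflectance, b$reflectance)
  expect_identical(a$analyte, b$analyte)
  expect_false(identical(a$reflectance, c$reflectance))
})

test_that("with noise off, band depth is an affine function of the analyte", {
  spec <- synthetic_spec(rois_per_sample = 1, baseline_drift_sd = 0,
                         sample_noise_sd = 0, roi_noise_sd = 0,
                         analyte_jitter_sd = 0.3, seed = 5)
  ds <- generate_synthetic(spec)
  # depth at an absorption center relative to the analyte-free base curve
  center_idx <- which.min(abs(ds$wavelengths - 960))
  base <- specalib:::.base_reflectance(ds$wavelengths)[center_idx]
  depth <- base - ds$reflectance[, center_idx]
  fit <- lm(depth ~ ds$analyte)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_gt(coef(fit)[2], 0)
})

test_that("splits partition the samples at the requested ratio", {
  ds <- generate_synthetic(synthetic_spec())
  sp <- split_spectra(ds, 0.7, seed = 1)
  expect_equal(nrow(sp$train$reflectance), 560L)
  expect_equal(nrow(sp$test$reflectance), 240L)
  # stratified: 112/48 per brand at 7:3
  expect_true(all(table(sp$train$brand) == 112))
  expect_true(all(table(sp$test$brand) == 48))

  small <- toy_dataset(n = 10, p = 4)
  sp2 <- split_spectra(small, 0.5, seed = 3, stratify = FALSE)
  expect_equal(nrow(sp2$train$reflectance), 5L)
  expect_length(intersect(sp2$train$ids, sp2$test$ids), 0)

  for (s in 1:100) {
    sp3 <- split_spectra(small, 0.6, seed = s, stratify = FALSE)
    expect_setequal(c(sp3$train$ids, sp3$test$ids), small$ids)
    expect_length(intersect(sp3$train$ids, sp3$test$ids), 0)
  }
})

test_that("stratification refuses brands with fewer than two samples", {
  ds <- spectral_dataset(c(500, 600), matrix(runif(6), 3, 2),
                         c(20, 21, 22), c("A", "A", "B"))
  expect_error(split_spectra(ds, 0.5, seed = 1, stratify = TRUE), "B")
})
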