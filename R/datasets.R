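#' Spectral calibration dataset
#'
#' Container tying together a reflectance matrix (rows = samples, columns =
#' wavelengths), the scalar reference analyte value per sample (e.g. protein,
#' g/100 g), a categorical brand label and a unique sample id.
#'
#' @param wavelengths numeric vector of band positions in nm, strictly
#'   increasing, length `p`.
#' @param reflectance numeric `n x p` matrix of reflectance values (unitless,
#'   non-negative; typically in `[0, 1]` after dark/white correction).
#' @param analyte numeric vector of length `n`, reference values in g/100 g;
#'   must be positive and free of missing values.
#' @param brand character (or factor) vector of length `n` of brand labels.
#' @param ids character vector of length `n` of unique sample identifiers;
#'   generated as `"s<row>"` when omitted.
#'
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavelengths`, `reflectance`, `analyte`, `brand` (character), `ids`.
#' @examples
#' ds <- spectral_dataset(c(500, 600, 700),
#'                        matrix(runif(6), 2, 3),
#'                        c(20.1, 24.3), c("A", "B"))
#' nrow(ds$reflectance)
#' @export
spectral_dataset <- function(wavelengths, reflectance, analyte, brand,
                             ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  analyte <- as.numeric(analyte)
  brand <- as.character(brand)
  n <- nrow(reflectance)
  p <- ncol(reflectance)
  if (is.null(ids)) ids <- paste0("s", seq_len(max(n, 0L)))
  ids <- as.character(ids)

  if (length(wavelengths) != p)
    stop("length(wavelengths) [", length(wavelengths),
         "] does not match ncol(reflectance) [", p, "]")
  if (p >= 2 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(analyte) != n || length(brand) != n || length(ids) != n)
    stop("analyte, brand and ids must each have one entry per spectrum (n = ",
         n, ")")
  if (anyNA(wavelengths)) stop("wavelengths contain missing values")
  if (anyNA(reflectance)) {
    bad <- which(is.na(reflectance), arr.ind = TRUE)[1, ]
    stop("reflectance contains missing values (first at row ", bad[1],
         ", band ", bad[2], ")")
  }
  if (anyNA(analyte)) stop("analyte contains missing values (first at row ",
                           which(is.na(analyte))[1], ")")
  if (n > 0 && any(analyte <= 0))
    stop("analyte values must be positive (row ",
         which(analyte <= 0)[1], " is not)")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  dimnames(reflectance) <- NULL

  structure(list(wavelengths = wavelengths, reflectance = reflectance,
                 analyte = analyte, brand = brand, ids = ids),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  n <- nrow(x$reflectance); p <- ncol(x$reflectance)
  cat("<spectral_dataset> ", n, " spectra x ", p, " bands", sep = "")
  if (p > 0)
    cat(" (", format(min(x$wavelengths)), "-", format(max(x$wavelengths)),
        " nm)", sep = "")
  cat("\n")
  if (n > 0) {
    cat("  analyte: ", format(min(x$analyte)), "-", format(max(x$analyte)),
        " g/100 g;  brands: ", paste(unique(x$brand), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$reflectance)

#' Subset a spectral dataset by sample and/or band
#'
#' @param x a [spectral_dataset()].
#' @param i sample (row) index.
#' @param j band (column) index into the wavelength grid.
#' @param ... ignored.
#' @return A `spectral_dataset` with the selected rows/bands.
#' @export
`[.spectral_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$reflectance))
  if (missing(j)) j <- seq_len(ncol(x$reflectance))
  spectral_dataset(x$wavelengths[j],
                   x$reflectance[i, j, drop = FALSE],
                   x$analyte[i], x$brand[i], x$ids[i])
}

#' @export
as.data.frame.spectral_dataset <- function(x, ...) {
  df <- data.frame(id = x$ids, brand = x$brand,
                   protein_g_per_100g = x$analyte,
                   stringsAsFactors = FALSE)
  refl <- as.data.frame(x$reflectance)
  names(refl) <- format(x$wavelengths, digits = 8, trim = TRUE,
                        scientific = FALSE)
  cbind(df, refl)
}

#' Read a spectra table from delimited text
#'
#' Expects the layout written by [write_spectra()]: columns `id`, `brand`,
#' `protein_g_per_100g`, then one column per wavelength whose name parses as
#' its position in nm.
#'
#' @param path file to read.
#' @param sep field delimiter (default comma).
#' @return A [spectral_dataset()].
#' @export
read_spectra <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("id", "brand", "protein_g_per_100g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  wl_cols <- setdiff(names(df), need)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl))
    stop("non-numeric wavelength column name(s): ",
         paste(wl_cols[is.na(wl)], collapse = ", "))
  if (length(wl) >= 2 && any(diff(wl) <= 0))
    stop("wavelength columns are not strictly increasing in ", path)
  if (anyNA(df$protein_g_per_100g))
    stop("blank/missing analyte value at row ",
         which(is.na(df$protein_g_per_100g))[1], " of ", path)
  refl <- as.matrix(df[, wl_cols, drop = FALSE])
  if (anyNA(refl)) {
    bad <- which(is.na(refl), arr.ind = TRUE)[1, ]
    stop("missing reflectance value at row ", bad[1], ", column '",
         wl_cols[bad[2]], "' of ", path)
  }
  spectral_dataset(wl, refl, df$protein_g_per_100g, df$brand, df$id)
}

#' Write a spectra table as delimited text
#'
#' Inverse of [read_spectra()]; wavelengths become column names with at least
#' six significant digits so the grid round-trips.
#'
#' @param ds a [spectral_dataset()].
#' @param path file to write.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- data.frame(id = ds$ids, brand = ds$brand,
                   protein_g_per_100g = format(ds$analyte, digits = 15,
                                               trim = TRUE,
                                               scientific = FALSE),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(ds$reflectance) > 0) {
    refl <- as.data.frame(format(ds$reflectance, digits = 15, trim = TRUE,
                                 scientific = FALSE))
    names(refl) <- format(ds$wavelengths, digits = 8, trim = TRUE,
                          scientific = FALSE)
    df <- cbind(df, refl)
  }
  ok <- tryCatch(write.table(df, path, sep = sep, row.names = FALSE,
                             quote = FALSE, fileEncoding = "UTF-8"),
                 error = function(e)
                   stop("failed to write spectra table to ", path, ": ",
                        conditionMessage(e)))
  invisible(path)
}

#' Specification of the synthetic spectra generator
#'
#' Describes a brand-structured visible/near-infrared reflectance simulation:
#' each brand carries one reference analyte value; each sample is measured in
#' several regions of interest (ROIs); each spectrum is a smooth base
#' reflectance curve minus Gaussian absorption bands whose depths grow
#' linearly with the analyte value, plus a low-order polynomial baseline
#' drift per sample and i.i.d. measurement noise per ROI.
#'
#' Defaults emulate a five-brand milk-powder study: 5 brands x 20 samples x
#' 8 ROIs = 800 spectra on a 125-band 400-1000 nm grid, with brand protein
#' values 19.0, 23.8, 28.0, 25.4 and 20.2 g/100 g.
#'
#' @param n_brands number of brands.
#' @param samples_per_brand physical samples per brand.
#' @param rois_per_sample spectra (regions of interest) per sample.
#' @param brand_analyte analyte value per brand, g/100 g.
#' @param n_bands number of wavelengths on the 400-1000 nm grid.
#' @param band_centers,band_widths nm centers and Gaussian widths of the
#'   analyte-sensitive absorption bands (protein/water overtones in the
#'   900-1000 nm region plus broad visible bands near 450/670 nm).
#' @param band_amplitudes absorption depth per unit analyte (per g/100 g)
#'   for each band; depths are affine (here proportional) in the analyte.
#' @param baseline_drift_sd sd of the per-sample low-order polynomial
#'   baseline drift coefficients (reflectance units).
#' @param sample_noise_sd sd of per-sample band-wise noise shared by all
#'   ROIs of a sample.
#' @param roi_noise_sd sd of i.i.d. per-ROI measurement noise.
#' @param analyte_jitter_sd sd of the per-sample jitter around the brand
#'   analyte value, g/100 g.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_brands = 5,
                           samples_per_brand = 20,
                           rois_per_sample = 8,
                           brand_analyte = c(19.0, 23.8, 28.0, 25.4, 20.2),
                           n_bands = 125,
                           band_centers = c(450, 670, 910, 935, 960, 985),
                           band_widths = c(40, 30, 12, 10, 12, 10),
                           band_amplitudes = c(8e-4, 1.2e-3, 4e-3, 5e-3,
                                               6e-3, 4.5e-3),
                           baseline_drift_sd = 0.01,
                           sample_noise_sd = 0.001,
                           roi_noise_sd = 0.002,
                           analyte_jitter_sd = 0.1,
                           seed = 123L) {
  stopifnot(n_brands >= 1, samples_per_brand >= 1, rois_per_sample >= 1,
            n_bands >= 1)
  if (length(brand_analyte) != n_brands)
    stop("brand_analyte must have one value per brand")
  if (any(brand_analyte <= 0)) stop("brand analyte values must be positive")
  k <- length(band_centers)
  if (length(band_widths) != k || length(band_amplitudes) != k)
    stop("band_centers, band_widths and band_amplitudes must have equal length")
  if (any(band_widths <= 0)) stop("band widths must be positive")
  sds <- c(baseline_drift_sd, sample_noise_sd, roi_noise_sd, analyte_jitter_sd)
  if (any(sds < 0)) stop("noise standard deviations must be non-negative")
  structure(list(n_brands = as.integer(n_brands),
                 samples_per_brand = as.integer(samples_per_brand),
                 rois_per_sample = as.integer(rois_per_sample),
                 brand_analyte = as.numeric(brand_analyte),
                 n_bands = as.integer(n_bands),
                 band_centers = as.numeric(band_centers),
                 band_widths = as.numeric(band_widths),
                 band_amplitudes = as.numeric(band_amplitudes),
                 baseline_drift_sd = baseline_drift_sd,
                 sample_noise_sd = sample_noise_sd,
                 roi_noise_sd = roi_noise_sd,
                 analyte_jitter_sd = analyte_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Smooth analyte-independent base reflectance: sigmoidal rise through the
# visible range to a plateau, with a fixed (brand-independent) dip near
# 760 nm so the curves have structure unrelated to the analyte.
.base_reflectance <- function(wl) {
  0.25 + 0.5 / (1 + exp(-(wl - 520) / 60)) -
    0.03 * exp(-((wl - 760)^2) / (2 * 15^2))
}

#' Generate a synthetic brand-structured spectral dataset
#'
#' @param spec a [synthetic_spec()].
#' @return A [spectral_dataset()] with
#'   `n_brands * samples_per_brand * rois_per_sample` rows. Ids encode
#'   brand, sample and ROI (`b1_s01_r1`). Deterministic given `spec$seed`.
#' @examples
#' ds <- generate_synthetic(synthetic_spec())
#' dim(ds$reflectance)  # 800 x 125
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  wl <- seq(400, 1000, length.out = spec$n_bands)
  base <- .base_reflectance(wl)
  # band shape matrix: p x k, one Gaussian per analyte-sensitive band
  shapes <- vapply(seq_along(spec$band_centers), function(j)
    exp(-((wl - spec$band_centers[j])^2) / (2 * spec$band_widths[j]^2)),
    numeric(spec$n_bands))
  shapes <- matrix(shapes, nrow = spec$n_bands)
  u <- if (spec$n_bands > 1) 2 * (wl - 700) / 600 else 0  # scaled to [-1, 1]

  n <- spec$n_brands * spec$samples_per_brand * spec$rois_per_sample
  refl <- matrix(0, n, spec$n_bands)
  analyte <- numeric(n)
  brand <- character(n)
  ids <- character(n)
  row <- 0L
  for (b in seq_len(spec$n_brands)) {
    for (s in seq_len(spec$samples_per_brand)) {
      a <- spec$brand_analyte[b] +
        if (spec$analyte_jitter_sd > 0) rnorm(1, 0, spec$analyte_jitter_sd)
        else 0
      a <- max(a, 0.01)
      depth <- drop(shapes %*% (spec$band_amplitudes * a))
      drift <- if (spec$baseline_drift_sd > 0) {
        co <- rnorm(3, 0, spec$baseline_drift_sd * c(1, 0.5, 0.3))
        co[1] + co[2] * u + co[3] * u^2
      } else 0
      samp_noise <- if (spec$sample_noise_sd > 0)
        rnorm(spec$n_bands, 0, spec$sample_noise_sd) else 0
      clean <- base - depth + drift + samp_noise
      for (r in seq_len(spec$rois_per_sample)) {
        row <- row + 1L
        roi_noise <- if (spec$roi_noise_sd > 0)
          rnorm(spec$n_bands, 0, spec$roi_noise_sd) else 0
        refl[row, ] <- pmax(clean + roi_noise, 0)
        analyte[row] <- a
        brand[row] <- paste0("brand", b)
        ids[row] <- sprintf("b%d_s%02d_r%d", b, s, r)
      }
    }
  }
  spectral_dataset(wl, refl, analyte, brand, ids)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}

# decouple an internal RNG stream from a user-facing seed (LCG step), so
# internal draws never replay a stream the caller used to build the data
scramble_seed <- function(seed) {
  as.integer((as.numeric(seed) * 1103515245 + 12345) %% 2147483647)
}

# run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Split a spectral dataset into calibration and prediction sets
#'
#' Deterministic, optionally brand-stratified random partition; the paper's
#' study design uses a 7:3 calibration:prediction ratio.
#'
#' @param ds a [spectral_dataset()].
#' @param ratio fraction of samples assigned to the training set, in (0, 1).
#' @param seed integer seed controlling the shuffle.
#' @param stratify draw the split within each brand so brand proportions are
#'   preserved to within one sample (default `TRUE`).
#' @return A list with elements `train` and `test`, both `spectral_dataset`s;
#'   together they partition the input rows.
#' @examples
#' sp <- split_spectra(generate_synthetic(synthetic_spec()), 0.7, seed = 1)
#' nrow(sp$train$reflectance)  # 560
#' @export
split_spectra <- function(ds, ratio = 0.7, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(ds, "spectral_dataset"), ratio > 0, ratio < 1)
  n <- nrow(ds$reflectance)
  idx_train <- with_seed(seed, {
    if (stratify) {
      groups <- split(seq_len(n), ds$brand)
      small <- names(groups)[vapply(groups, length, 1L) < 2]
      if (length(small))
        stop("stratified split needs >= 2 samples per brand; brand(s) ",
             paste(small, collapse = ", "), " have fewer")
      unlist(lapply(groups, function(g)
        sample(g, round(length(g) * ratio))), use.names = FALSE)
    } else sample(seq_len(n), round(n * ratio))
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(n), idx_train)
  list(train = ds[idx_train, ], test = ds[idx_test, ])
}
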