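#' Exponentially decreasing retention schedule used by CARS
#'
#' Closed-form ratio sequence `r_i = a * exp(-k * i)` with constants solved
#' so the first run keeps all `p` bands (`r_1 = 1`) and the last keeps two
#' (`r_N * p = 2`): `a = (p/2)^(1/(N-1))`, `k = log(p/2)/(N-1)`.
#'
#' @param p number of bands.
#' @param n_runs number of sampling runs `N`.
#' @return Numeric vector of length `n_runs`, non-increasing, `r[1] = 1`,
#'   `r[n_runs] = 2/p`.
#' @export
cars_retention_schedule <- function(p, n_runs) {
  stopifnot(p >= 2, n_runs >= 2)
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * seq_len(n_runs))
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Iterative selection coupling Monte Carlo row subsampling with the
#' magnitude of PLS1 regression coefficients. Each run: (1) fit a PLS model
#' on a random 80% row subsample restricted to the currently retained bands;
#' (2) enforce the exponentially decreasing retention count; (3) keep the
#' top bands by absolute coefficient, then resample among them with
#' probability proportional to absolute coefficient (adaptive reweighted
#' sampling); (4) record the k-fold RMSECV of the retained set (minimized
#' over 1..`a_max` latent variables). The selected set is the retained set
#' of the minimum-RMSECV run.
#'
#' @param X numeric `n x p` matrix (already preprocessed).
#' @param y numeric response vector.
#' @param n_runs Monte Carlo sampling runs (default 50, the study setting).
#' @param k_folds folds for the per-run RMSECV (default 10).
#' @param a_max maximum latent-variable count scanned (default 10).
#' @param mc_ratio row subsampling ratio per run (default 0.8).
#' @param seed integer seed; the whole trace is deterministic given it.
#' @return An object of class `cars_trace`: list with `selected` (band
#'   indices), `best_run`, `rmsecv` (length `n_runs`), `n_retained`
#'   (length `n_runs`), `retention_ratio`, `retained` (list of per-run
#'   index sets), `n_components` (per-run best component count).
#' @export
cars_select <- function(X, y, n_runs = 50L, k_folds = 10L, a_max = 10L,
                        mc_ratio = 0.8, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(p >= 2, n_runs >= 2, mc_ratio > 0, mc_ratio <= 1)
  ratios <- cars_retention_schedule(p, n_runs)
  counts <- pmax(2L, pmin(p, as.integer(round(ratios * p))))

  retained <- vector("list", n_runs)
  rmse_curve <- numeric(n_runs)
  ncomp_best <- integer(n_runs)
  cur <- seq_len(p)
  with_seed(scramble_seed(seed), {
    for (i in seq_len(n_runs)) {
      cur <- sort(cur)
      retained[[i]] <- cur
      a_eval <- min(a_max, length(cur), n - ceiling(n / k_folds) - 1)
      path <- .cv_rmse_path(X[, cur, drop = FALSE], y, a_eval, k_folds,
                            seed = sample.int(.Machine$integer.max, 1))
      ncomp_best[i] <- which.min(path)
      rmse_curve[i] <- min(path)
      if (i == n_runs) break
      # PLS coefficients on a Monte Carlo row subsample
      sub <- sample.int(n, max(2, round(mc_ratio * n)))
      a_fit <- min(ncomp_best[i], length(sub) - 1, length(cur))
      m <- pls_fit(X[sub, cur, drop = FALSE], y[sub], a_fit)
      w <- abs(coef(m))
      k_next <- min(counts[i + 1], length(cur))
      # forced selection: top |coefficient|
      forced <- cur[order(w, decreasing = TRUE)[seq_len(k_next)]]
      wf <- w[match(forced, cur)]
      # adaptive reweighted sampling among the forced set
      if (all(wf == 0)) wf <- rep(1, length(wf))
      drawn <- unique(sample(forced, size = k_next, replace = TRUE,
                             prob = wf))
      if (length(drawn) < 2)
        drawn <- forced[seq_len(min(2, length(forced)))]
      cur <- drawn
    }
  })
  best <- which.min(rmse_curve)
  structure(list(selected = retained[[best]], best_run = best,
                 rmsecv = rmse_curve,
                 n_retained = lengths(retained),
                 retention_ratio = ratios,
                 retained = retained,
                 n_components = ncomp_best,
                 n_runs = n_runs, p = p, seed = seed),
            class = "cars_trace")
}

#' @export
print.cars_trace <- function(x, ...) {
  cat("<cars_trace> ", x$n_runs, " runs on ", x$p, " bands; best run ",
      x$best_run, " (RMSECV = ", format(min(x$rmsecv), digits = 4),
      ") retains ", length(x$selected), " bands\n", sep = "")
  invisible(x)
}

#' @export
plot.cars_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$n_retained, type = "l", xlab = "sampling run",
       ylab = "retained bands", ...)
  plot(x$rmsecv, type = "l", xlab = "sampling run", ylab = "RMSECV", ...)
  graphics::abline(v = x$best_run, col = 2, lty = 2)
  invisible(x)
}

#' Uninformative variable elimination (UVE) wavelength selection
#'
#' Appends as many tiny-amplitude standard-normal noise bands as there are
#' real bands, refits a PLS1 model over resampling splits, and scores each
#' band by the stability of its regression coefficient (mean across splits
#' divided by standard deviation). Real bands whose absolute stability does
#' not exceed `cutoff_factor` times the maximum absolute noise-band
#' stability are eliminated.
#'
#' The internal random stream is decoupled from the user-facing seed by a
#' fixed linear scrambling, so generating data under `set.seed(s)` and then
#' calling `uve_select(..., seed = s)` cannot hand the noise bands the very
#' same normal draws the data were built from (which would make each noise
#' band a scaled copy of a real band and void the cutoff).
#'
#' @param X numeric `n x p` matrix.
#' @param y numeric response.
#' @param a_max maximum latent-variable count scanned when choosing the
#'   model dimension (default 10).
#' @param n_splits resampling splits; by default leave-one-out when
#'   `n <= 200`, otherwise 20 jackknife splits each leaving out a fifth.
#' @param cutoff_factor multiplier on the maximum absolute noise stability
#'   (default 1).
#' @param noise_scale amplitude of the appended noise bands relative to the
#'   mean absolute data value (default 1e-10; the classical choice keeps the
#'   noise numerically irrelevant to the fit while still ranking chance
#'   stability).
#' @param seed integer seed.
#' @return An object of class `uve_result`: `selected` (real-band indices),
#'   `stability` (length p), `noise_stability` (length p), `cutoff`,
#'   `n_components`.
#' @export
uve_select <- function(X, y, a_max = 10L, n_splits = NULL,
                       cutoff_factor = 1.0, noise_scale = 1e-10,
                       seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(p >= 1, n >= 3)
  loo <- n <= 200
  if (is.null(n_splits)) n_splits <- if (loo) n else 20L
  stopifnot(n_splits >= 2, n_splits <= n)

  with_seed(scramble_seed(seed), {
    scale_ref <- mean(abs(X))
    if (scale_ref == 0) scale_ref <- 1
    amp <- noise_scale * scale_ref
    a_eval <- min(a_max, n - 2, 2 * p)
    Z <- cbind(X, matrix(rnorm(n * p), n, p) * amp)
    path <- .cv_rmse_path(Z, y, a_eval,
                          k_folds = min(10L, n),
                          seed = sample.int(.Machine$integer.max, 1))
    A <- which.min(path)

    coefs <- matrix(NA_real_, n_splits, 2 * p)
    for (s in seq_len(n_splits)) {
      omit <- if (loo && n_splits == n) s
              else sample.int(n, max(1, round(n / 5)))
      m <- pls_fit(Z[-omit, , drop = FALSE], y[-omit],
                   min(A, n - length(omit) - 1))
      coefs[s, ] <- coef(m)
    }
  })
  mu <- colMeans(coefs)
  sg <- apply(coefs, 2, sd)
  stab <- mu / sg
  if (any(sg == 0)) {
    warning("zero coefficient spread across splits at band(s) ",
            paste(which(sg == 0), collapse = ", "),
            "; stability set to signed infinity")
    stab[sg == 0] <- sign(mu[sg == 0]) * Inf
    stab[sg == 0 & mu == 0] <- 0
  }
  stability <- stab[seq_len(p)]
  noise_stability <- stab[p + seq_len(p)]
  cutoff <- cutoff_factor * max(abs(noise_stability))
  selected <- which(abs(stability) > cutoff)
  structure(list(selected = selected, stability = stability,
                 noise_stability = noise_stability, cutoff = cutoff,
                 cutoff_factor = cutoff_factor, n_components = A,
                 p = p, seed = seed),
            class = "uve_result")
}

#' @export
print.uve_result <- function(x, ...) {
  cat("<uve_result> ", length(x$selected), " of ", x$p,
      " bands retained (cutoff = ", format(x$cutoff, digits = 4),
      ", ", x$n_components, " component(s))\n", sep = "")
  invisible(x)
}

#' CARS followed by UVE (the "CU" cascade)
#'
#' Runs [cars_select()] on the full band set, then [uve_select()] restricted
#' to the CARS-selected columns; the result is reported in original band
#' coordinates and is by construction a subset of the CARS selection.
#'
#' @param X numeric matrix (already preprocessed).
#' @param y numeric response.
#' @param cars_params named list of arguments for [cars_select()].
#' @param uve_params named list of arguments for [uve_select()].
#' @return List with `selected` (original-coordinate band indices), `cars`
#'   (the `cars_trace`) and `uve` (the `uve_result` in CARS-subset
#'   coordinates).
#' @export
cu_cascade <- function(X, y, cars_params = list(), uve_params = list()) {
  X <- as.matrix(X)
  ct <- do.call(cars_select, c(list(X = X, y = y), cars_params))
  Xc <- X[, ct$selected, drop = FALSE]
  uv <- do.call(uve_select, c(list(X = Xc, y = y), uve_params))
  list(selected = ct$selected[uv$selected], cars = ct, uve = uv)
}
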