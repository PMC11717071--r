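#' Root mean squared error
#'
#' `sqrt(sum((y - yhat)^2) / n)`.
#'
#' @param y,yhat numeric vectors of equal, nonzero length.
#' @return Non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) == 0 || length(y) != length(yhat))
    stop("y and yhat must have equal nonzero length")
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y,yhat numeric vectors (length >= 2); `y` must not be constant.
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) < 2 || length(y) != length(yhat))
    stop("y and yhat must have equal length >= 2")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("y is constant; R-squared is undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Relative percent deviation from a prediction R-squared
#'
#' `RPD = 1 / sqrt(1 - R2)`; values above 2.0 conventionally indicate good
#' predictive ability. Note the identity `RPD = sd(y) / RMSE` (population
#' sd) when `R2` is computed by [r_squared()] on the same vectors.
#'
#' @param rp2 prediction R-squared in `[0, 1)`.
#' @return Scalar `>= 1`.
#' @export
rpd <- function(rp2) {
  if (!is.finite(rp2) || rp2 >= 1)
    stop("rp2 must be finite and < 1, got ", rp2)
  1 / sqrt(1 - rp2)
}

#' Percent change between two metric values
#'
#' `increase`: `(value - reference) / reference * 100`;
#' `decrease`: `(reference - value) / reference * 100`.
#'
#' @param reference baseline value (nonzero).
#' @param value comparison value.
#' @param direction `"increase"` or `"decrease"`.
#' @return Percentage (scalar).
#' @examples
#' percent_change(0.9361, 0.9421, "increase")  # 0.641
#' percent_change(0.1854, 0.1617, "decrease")  # 12.78
#' @export
percent_change <- function(reference, value,
                           direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (reference == 0) stop("reference must be nonzero")
  if (direction == "increase") (value - reference) / reference * 100
  else (reference - value) / reference * 100
}

#' Calibration/prediction metrics for one model
#'
#' Computes the standard chemometric quadruple plus RPD: RC2/RMSEC on the
#' training (calibration) set, RP2/RMSEP on the test (prediction) set, and
#' RPD from the held-out predictions via the `sd(y_test)/RMSEP` identity
#' (equal, at full precision, to `1/sqrt(1 - RP2)`).
#'
#' @param model character model label.
#' @param y_train,yhat_train training responses and predictions.
#' @param y_test,yhat_test test responses and predictions.
#' @param scale label recording which target scale the vectors are on
#'   (`"raw"` or `"standardized"`).
#' @return A one-row data.frame of class `metrics_report` with columns
#'   `model`, `RC2`, `RMSEC`, `RP2`, `RMSEP`, `RPD`, `scale`, `n_train`,
#'   `n_test`.
#' @export
metrics_report <- function(model, y_train, yhat_train, y_test, yhat_test,
                           scale = "raw") {
  rp2 <- r_squared(y_test, yhat_test)
  out <- data.frame(model = model,
                    RC2 = r_squared(y_train, yhat_train),
                    RMSEC = rmse(y_train, yhat_train),
                    RP2 = rp2,
                    RMSEP = rmse(y_test, yhat_test),
                    RPD = if (rp2 < 1) 1 / sqrt(1 - rp2) else Inf,
                    scale = scale,
                    n_train = length(y_train),
                    n_test = length(y_test),
                    stringsAsFactors = FALSE)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Fit the classical chemometric baselines
#'
#' Fits any of the reference models on an already preprocessed,
#' band-selected train/test pair and reports the metric quadruple + RPD:
#' \describe{
#'   \item{PLSR}{PLS1 regression with 3 latent variables (clamped to the
#'     feasible maximum).}
#'   \item{PCA-PLSR}{PCA to 2 principal components feeding a PLS1
#'     regression.}
#'   \item{SVR}{epsilon support-vector regression with an RBF kernel
#'     (via \pkg{e1071}).}
#' }
#'
#' @param x_train,y_train,x_test,y_test numeric matrices/vectors.
#' @param which subset of `c("PLSR", "PCA-PLSR", "SVR")`.
#' @param plsr_ncomp latent variables for PLSR (default 3).
#' @param pca_ncomp principal components for PCA-PLSR (default 2).
#' @return A `metrics_report` data.frame, one row per model.
#' @export
fit_baselines <- function(x_train, y_train, x_test, y_test,
                          which = c("PLSR", "PCA-PLSR", "SVR"),
                          plsr_ncomp = 3L, pca_ncomp = 2L) {
  which <- match.arg(which, several.ok = TRUE)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  rows <- list()
  if ("PLSR" %in% which) {
    nc <- min(plsr_ncomp, nrow(x_train) - 1, ncol(x_train))
    m <- pls_fit(x_train, y_train, nc)
    rows$PLSR <- metrics_report("PLSR", y_train, predict(m, x_train),
                                y_test, predict(m, x_test))
  }
  if ("PCA-PLSR" %in% which) {
    nc_pca <- min(pca_ncomp, nrow(x_train) - 1, ncol(x_train))
    pc <- prcomp(x_train, center = TRUE, scale. = FALSE)
    ztr <- pc$x[, seq_len(nc_pca), drop = FALSE]
    zte <- predict(pc, x_test)[, seq_len(nc_pca), drop = FALSE]
    m <- pls_fit(ztr, y_train, min(nc_pca, nrow(ztr) - 1))
    rows$`PCA-PLSR` <- metrics_report("PCA-PLSR", y_train,
                                      predict(m, ztr),
                                      y_test, predict(m, zte))
  }
  if ("SVR" %in% which) {
    m <- e1071::svm(x_train, y_train, type = "eps-regression",
                    kernel = "radial")
    rows$SVR <- metrics_report("SVR", y_train, predict(m, x_train),
                               y_test, predict(m, x_test))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Pairwise percent-change comparison of model metrics
#'
#' Reproduces the study's comparison arithmetic: for each
#' `(reference, candidate, metric, direction)` pair, the percent change of
#' the candidate relative to the reference.
#'
#' @param reports a `metrics_report` data.frame (rows = models).
#' @param pairs a list of lists/character vectors
#'   `(reference, candidate, metric, direction)`, where `metric` is a
#'   column of the report (e.g. `"RP2"`) and `direction` is `"increase"`
#'   or `"decrease"`.
#' @return A data.frame with one row per pair: `reference`, `candidate`,
#'   `metric`, `direction`, `reference_value`, `candidate_value`,
#'   `percent_change`.
#' @export
compare_report <- function(reports, pairs) {
  if (length(pairs) == 0)
    return(data.frame(reference = character(0), candidate = character(0),
                      metric = character(0), direction = character(0),
                      reference_value = numeric(0),
                      candidate_value = numeric(0),
                      percent_change = numeric(0)))
  rows <- lapply(pairs, function(p) {
    p <- as.list(p)
    names(p)[seq_along(p)] <- c("reference", "candidate", "metric",
                                "direction")[seq_along(p)]
    for (who in c(p$reference, p$candidate))
      if (!who %in% reports$model)
        stop("unknown model in comparison pair: ", who)
    rv <- reports[reports$model == p$reference, p$metric][1]
    cv <- reports[reports$model == p$candidate, p$metric][1]
    data.frame(reference = p$reference, candidate = p$candidate,
               metric = p$metric, direction = p$direction,
               reference_value = rv, candidate_value = cv,
               percent_change = percent_change(rv, cv, p$direction),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
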