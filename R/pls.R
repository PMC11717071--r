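#' Fit a PLS1 regression model
#'
#' Single-response partial least squares by the NIPALS algorithm (for a
#' scalar response the weight extraction is non-iterative). With
#' `n_components` equal to the rank of the centered predictor matrix the
#' fitted values coincide with ordinary least squares.
#'
#' @param X numeric `n x p` predictor matrix.
#' @param y numeric response vector of length `n`; must not be constant.
#' @param n_components number of latent variables, in
#'   `[1, min(n - 1, p)]`.
#' @return An object of class `pls1` with elements `coefficients` (length
#'   `p`, mapping centered X to centered y), `x_mean`, `y_mean`,
#'   `n_components`, `coef_path` (p x n_components matrix of coefficient
#'   vectors for every truncation 1..n_components) and `training_meta`.
#' @examples
#' x <- matrix(1:6, 6, 1)
#' m <- pls_fit(x, 2 * (1:6), 1)
#' coef(m)  # 2
#' @export
pls_fit <- function(X, y, n_components) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  if (sd(y) == 0) stop("response y is constant; PLS1 fit is undefined")
  a_max <- min(n - 1, p)
  if (n_components < 1 || n_components > a_max)
    stop("n_components must be in [1, ", a_max, "], got ", n_components)
  A <- as.integer(n_components)

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2, x_mean)
  f <- y - y_mean

  W <- matrix(0, p, A)  # X weights
  P <- matrix(0, p, A)  # X loadings
  q <- numeric(A)       # y loadings
  ssq <- numeric(A)     # variance share captured per component
  tot_ss <- sum(E^2)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {  # residual orthogonal to y; stop extracting
      A <- a - 1L
      break
    }
    w <- w / nw
    tt <- drop(E %*% w)
    tt2 <- sum(tt^2)
    pl <- drop(crossprod(E, tt)) / tt2
    qa <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pl)
    f <- f - qa * tt
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
    ssq[a] <- if (tot_ss > 0) sum(tt^2 * sum(pl^2)) / tot_ss else 0
  }
  if (A < 1) stop("no informative component could be extracted")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]

  # B_a = W_a (P_a' W_a)^{-1} q_a for every truncation a = 1..A
  coef_path <- matrix(0, p, A)
  PtW <- crossprod(P, W)
  for (a in seq_len(A)) {
    Ra <- W[, 1:a, drop = FALSE] %*%
      solve(PtW[1:a, 1:a, drop = FALSE])
    coef_path[, a] <- drop(Ra %*% q[1:a])
  }
  b <- coef_path[, A]
  if (any(!is.finite(b))) stop("PLS coefficients are not finite")

  structure(list(coefficients = b, coef_path = coef_path,
                 x_mean = x_mean, y_mean = y_mean,
                 n_components = A,
                 training_meta = list(n = n, p = p,
                                      x_variance_share = ssq[seq_len(A)])),
            class = "pls1")
}

#' @export
coef.pls1 <- function(object, ...) object$coefficients

#' @export
print.pls1 <- function(x, ...) {
  cat("<pls1> ", x$n_components, " component(s), p = ", x$training_meta$p,
      ", n = ", x$training_meta$n, "\n", sep = "")
  invisible(x)
}

#' Predict from a PLS1 model
#'
#' @param object a [pls_fit()] model.
#' @param newdata numeric matrix with the same band count the model was
#'   fitted on.
#' @param n_components optional truncation (<= the fitted component count)
#'   at which to evaluate the coefficient path.
#' @param ... ignored.
#' @return Numeric vector `y_mean + (X - x_mean) %*% b`.
#' @export
predict.pls1 <- function(object, newdata, n_components = NULL, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean))
    stop("band count mismatch: model has ", length(object$x_mean),
         " bands, newdata has ", ncol(X))
  b <- if (is.null(n_components)) object$coefficients
       else object$coef_path[, n_components]
  drop(sweep(X, 2, object$x_mean) %*% b) + object$y_mean
}

#' @export
pls_predict <- function(m, X, ...) predict(m, X, ...)

# k-fold CV returning the RMSE over all held-out predictions for every
# component count 1..a_max (vector of length a_max). Folds are contiguous
# blocks of a seeded shuffle. Components infeasible inside a fold are
# evaluated at that fold's feasible maximum.
.cv_rmse_path <- function(X, y, a_max, k_folds, seed) {
  n <- nrow(X)
  stopifnot(k_folds >= 2, k_folds <= n)
  ord <- with_seed(seed, sample.int(n))
  fold_id <- integer(n)
  fold_id[ord] <- cut(seq_len(n), breaks = k_folds, labels = FALSE)
  pred <- matrix(NA_real_, n, a_max)
  clamped <- FALSE
  for (kf in seq_len(k_folds)) {
    te <- which(fold_id == kf)
    tr <- setdiff(seq_len(n), te)
    a_fit <- min(a_max, length(tr) - 1, ncol(X))
    if (a_fit < a_max) clamped <- TRUE
    m <- pls_fit(X[tr, , drop = FALSE], y[tr], a_fit)
    a_got <- m$n_components
    Xc <- sweep(X[te, , drop = FALSE], 2, m$x_mean)
    pr <- Xc %*% m$coef_path + m$y_mean  # n_te x a_got
    pred[te, seq_len(a_got)] <- pr
    if (a_got < a_max)  # carry the deepest feasible model forward
      pred[te, (a_got + 1):a_max] <- pr[, a_got]
  }
  if (clamped)
    message("rmsecv: component count reduced inside fold(s) to the feasible maximum")
  sqrt(colMeans((pred - y)^2))
}

#' Cross-validated RMSE of a PLS1 model
#'
#' k-fold root-mean-square error of cross-validation: folds are contiguous
#' blocks of a seeded shuffle, and the RMSE aggregates all `n` held-out
#' predictions. If `n_components` is infeasible within a fold it is reduced
#' to that fold's feasible maximum (with a message), never an error.
#'
#' @param X numeric predictor matrix.
#' @param y numeric response.
#' @param n_components latent-variable count to evaluate.
#' @param k_folds number of folds (default 10, the study's setting);
#'   `k_folds = n` gives leave-one-out.
#' @param seed integer seed for the fold shuffle.
#' @return A single non-negative RMSECV value.
#' @export
rmsecv <- function(X, y, n_components, k_folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  path <- .cv_rmse_path(X, y, n_components, k_folds, seed)
  path[n_components]
}
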