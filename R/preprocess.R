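#' Dark/white reflectance correction
#'
#' Converts raw sensor intensities to relative reflectance using the dark
#' (shutter closed) and white (reference panel) frames:
#' `Ic = (Ir - Ib) / (Iw - Ib)` elementwise.
#'
#' @param raw numeric matrix of raw intensities (rows = spectra).
#' @param dark numeric matrix of dark-current intensities; either the same
#'   shape as `raw` or a single reference row recycled across spectra.
#' @param white numeric matrix of white-reference intensities; same
#'   broadcasting rule as `dark`.
#' @return Matrix of corrected reflectance, same shape as `raw`.
#' @examples
#' black_white_correct(matrix(0.6), matrix(0.2), matrix(1.0))  # 0.5
#' @export
black_white_correct <- function(raw, dark, white) {
  raw <- as.matrix(raw)
  bcast <- function(m, what) {
    m <- as.matrix(m)
    if (nrow(m) == 1 && nrow(raw) > 1)
      m <- m[rep(1L, nrow(raw)), , drop = FALSE]
    if (!identical(dim(m), dim(raw)))
      stop(what, " must match raw's shape (", nrow(raw), " x ", ncol(raw),
           ") or be a single reference row")
    m
  }
  dark <- bcast(dark, "dark")
  white <- bcast(white, "white")
  denom <- white - dark
  if (any(denom == 0)) {
    bands <- sort(unique(which(denom == 0, arr.ind = TRUE)[, 2]))
    stop("white - dark is zero at band index(es): ",
         paste(bands, collapse = ", "))
  }
  (raw - dark) / denom
}

.pp_ops <- c("MC", "SS", "MMS", "SG", "D1", "D2")

#' Spectral preprocessing chain
#'
#' An ordered sequence of column-wise (per-wavelength) preprocessing
#' operators, fit on a calibration matrix and then applied to any matrix on
#' the same band grid. Operators:
#' \describe{
#'   \item{MC}{mean centering (subtract column means).}
#'   \item{SS}{standardization to zero mean / unit variance per column.}
#'   \item{MMS}{min-max scaling of each column to `[0, 1]`.}
#'   \item{SG}{Savitzky-Golay smoothing (local least-squares polynomial).}
#'   \item{D1, D2}{first/second derivative, by default via the
#'     Savitzky-Golay filter (band count preserved), optionally as finite
#'     differences (band count shrinks by the derivative order).}
#' }
#' MC/SS/MMS learn their statistics from the fit matrix only, so applying a
#' fitted chain to test data reuses the calibration statistics.
#'
#' @param steps list of steps; each either an operator name from
#'   `c("MC","SS","MMS","SG","D1","D2")` or a list with element `op` and
#'   optional parameters (`window`, odd, default 11; `order`, default 2;
#'   `mode = "sg"` or `"diff"` for derivatives).
#' @return An object of class `preprocess_chain` (unfitted).
#' @examples
#' ch <- preprocess_chain(list("SS", list(op = "SG", window = 11, order = 2)))
#' @export
preprocess_chain <- function(steps = list("MC")) {
  if (is.character(steps)) steps <- as.list(steps)
  steps <- lapply(steps, function(s) {
    if (is.character(s)) s <- list(op = s)
    if (is.null(s$op) || !s$op %in% .pp_ops)
      stop("unknown preprocessing operator: ",
           if (is.null(s$op)) "<missing>" else s$op,
           " (expected one of ", paste(.pp_ops, collapse = ", "), ")")
    if (s$op %in% c("SG", "D1", "D2")) {
      if (is.null(s$window)) s$window <- 11L
      if (is.null(s$order)) s$order <- 2L
      s$window <- as.integer(s$window)
      s$order <- as.integer(s$order)
      if (s$window < 3 || s$window %% 2 == 0)
        stop(s$op, ": window must be odd and >= 3, got ", s$window)
      if (s$order >= s$window)
        stop(s$op, ": polynomial order must be < window")
      deriv_ord <- switch(s$op, SG = 0L, D1 = 1L, D2 = 2L)
      if (s$op != "SG" && s$order < deriv_ord)
        stop(s$op, ": polynomial order must be >= derivative order")
      if (is.null(s$mode)) s$mode <- "sg"
      if (!s$mode %in% c("sg", "diff"))
        stop("derivative mode must be 'sg' or 'diff'")
    }
    s
  })
  structure(list(steps = steps, fitted_state = NULL),
            class = "preprocess_chain")
}

#' @export
print.preprocess_chain <- function(x, ...) {
  nm <- vapply(x$steps, function(s) s$op, "")
  cat("<preprocess_chain> ", paste(nm, collapse = " -> "),
      if (is.null(x$fitted_state)) "  (unfitted)" else "  (fitted)",
      "\n", sep = "")
  invisible(x)
}

#' Fit a preprocessing chain on a calibration matrix
#'
#' Learns the per-column statistics each scaling step needs (means for MC,
#' means/sds for SS, min/max for MMS) from `X` only, propagating each step's
#' output to the next step's fit.
#'
#' @param chain a [preprocess_chain()].
#' @param X numeric calibration matrix (rows = spectra); needs >= 2 rows for
#'   any of MC/SS/MMS.
#' @return The chain with `fitted_state` populated.
#' @export
fit_chain <- function(chain, X) {
  stopifnot(inherits(chain, "preprocess_chain"))
  X <- as.matrix(X)
  scale_ops <- vapply(chain$steps, function(s)
    s$op %in% c("MC", "SS", "MMS"), TRUE)
  if (any(scale_ops) && nrow(X) < 2)
    stop("fitting MC/SS/MMS requires at least 2 rows")
  state <- vector("list", length(chain$steps))
  cur <- X
  for (k in seq_along(chain$steps)) {
    s <- chain$steps[[k]]
    st <- switch(s$op,
      MC = list(center = colMeans(cur)),
      SS = {
        sds <- apply(cur, 2, sd)
        if (any(sds == 0))
          stop("SS: constant column at band index(es) ",
               paste(which(sds == 0), collapse = ", "))
        list(center = colMeans(cur), scale = sds)
      },
      MMS = {
        lo <- apply(cur, 2, min); hi <- apply(cur, 2, max)
        if (any(hi - lo == 0))
          stop("MMS: constant column at band index(es) ",
               paste(which(hi - lo == 0), collapse = ", "))
        list(min = lo, max = hi)
      },
      list()  # SG/D1/D2 are stateless
    )
    st$p_in <- ncol(cur)
    state[[k]] <- st
    cur <- .apply_step(s, st, cur)
  }
  chain$fitted_state <- state
  chain
}

.apply_step <- function(s, st, X) {
  switch(s$op,
    MC = sweep(X, 2, st$center),
    SS = sweep(sweep(X, 2, st$center), 2, st$scale, "/"),
    MMS = sweep(sweep(X, 2, st$min), 2, st$max - st$min, "/"),
    SG = t(apply(X, 1, function(r)
      signal::sgolayfilt(r, p = s$order, n = s$window, m = 0))),
    D1 = .deriv_step(X, s, 1L),
    D2 = .deriv_step(X, s, 2L)
  )
}

.deriv_step <- function(X, s, m) {
  if (s$mode == "diff") {
    t(apply(X, 1, function(r) diff(r, differences = m)))
  } else {
    t(apply(X, 1, function(r)
      signal::sgolayfilt(r, p = s$order, n = s$window, m = m)))
  }
}

#' Apply a fitted preprocessing chain
#'
#' @param chain a fitted [preprocess_chain()] (see [fit_chain()]).
#' @param X numeric matrix on the same band grid the chain was fitted on.
#' @return The transformed matrix. Band count shrinks only for
#'   finite-difference derivative steps.
#' @export
apply_chain <- function(chain, X) {
  stopifnot(inherits(chain, "preprocess_chain"))
  if (is.null(chain$fitted_state))
    stop("chain is not fitted; call fit_chain() first")
  X <- as.matrix(X)
  for (k in seq_along(chain$steps)) {
    st <- chain$fitted_state[[k]]
    if (ncol(X) != st$p_in)
      stop("band count mismatch at step ", k, " (", chain$steps[[k]]$op,
           "): chain was fitted with ", st$p_in, " bands, got ", ncol(X))
    X <- .apply_step(chain$steps[[k]], st, X)
  }
  X
}

#' Fit and apply a chain on the train matrix, apply to the test matrix
#'
#' Convenience wrapper enforcing the calibration/prediction asymmetry.
#'
#' @param chain a [preprocess_chain()] (or list of steps accepted by it).
#' @param X_train,X_test matrices on a common band grid (`X_test` optional).
#' @return List with `chain` (fitted), `train`, and `test` (`NULL` when no
#'   test matrix was supplied).
#' @export
preprocess <- function(chain, X_train, X_test = NULL) {
  if (!inherits(chain, "preprocess_chain")) chain <- preprocess_chain(chain)
  chain <- fit_chain(chain, X_train)
  list(chain = chain,
       train = apply_chain(chain, X_train),
       test = if (!is.null(X_test)) apply_chain(chain, X_test))
}
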