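# Time-lagged independent component analysis (TICA): linear dimensionality
# reduction maximizing time-autocorrelation.  The generalized eigenproblem
# C(tau) v = lambda C(0) v is solved after whitening C(0) (directions below a
# variance floor are discarded); eigenvalues encode relaxation timescales of
# the slow modes.

#' Fit a TICA model
#'
#' Features are made mean-free using the pooled mean over all series; the
#' instantaneous covariance C(0) uses every frame, while the time-lagged
#' covariance C(tau) is estimated within each series only (no cross-series
#' products across the lag boundary) and symmetrized,
#' `C(tau) <- (C~(tau) + t(C~(tau))) / 2`, so eigenvalues are real without
#' assuming reversibility of the data.
#'
#' @param features numeric matrix (frames x features) or list of such
#'   matrices (independent series, e.g. one per simulation).
#' @param lag lag time in frames (>= 1, shorter than every series).
#' @param n_components number of components kept (default 10, capped at the
#'   retained rank).
#' @param var_floor discard C(0) eigendirections whose variance is below
#'   `var_floor * total variance` (default 1e-8; guards collinear features).
#' @return object of class `tica_model`: `lag`, `mean`, `c0`, `ctau`,
#'   `eigenvalues` (sorted descending), `components` (columns, C(0)-
#'   orthonormal: `t(v) C0 v = I`), `n_components`.
#' @export
tica_fit <- function(features, lag, n_components = 10L, var_floor = 1e-8) {
  if (is.matrix(features) || is.data.frame(features))
    features <- list(as.matrix(features))
  features <- lapply(features, as.matrix)
  stopifnot(length(features) >= 1L, lag >= 1L)
  if (any(vapply(features, nrow, integer(1L)) <= lag))
    stop("every series must be longer than the lag")
  d <- ncol(features[[1L]])
  mu <- colMeans(do.call(rbind, features))
  xs <- lapply(features, function(m) sweep(m, 2L, mu))
  n0 <- 0L; c0 <- matrix(0, d, d)
  nt <- 0L; ct <- matrix(0, d, d)
  for (x in xs) {
    n <- nrow(x)
    c0 <- c0 + crossprod(x)
    n0 <- n0 + n
    a <- x[seq_len(n - lag), , drop = FALSE]
    b <- x[seq_len(n - lag) + lag, , drop = FALSE]
    ct <- ct + crossprod(a, b)
    nt <- nt + (n - lag)
  }
  c0 <- c0 / n0
  ct <- (ct + t(ct)) / (2 * nt)
  e0 <- eigen(c0, symmetric = TRUE)
  tot <- sum(pmax(e0$values, 0))
  keep <- which(e0$values > var_floor * tot)
  if (!length(keep))
    stop("C(0) is singular at this variance floor; raise var_floor or ",
         "remove constant features")
  # whitening transform restricted to retained directions
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), length(keep))
  m <- crossprod(W, ct %*% W)
  m <- (m + t(m)) / 2
  em <- eigen(m, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  k <- min(as.integer(n_components), length(keep))
  V <- W %*% em$vectors[, ord[seq_len(k)], drop = FALSE]
  structure(list(lag = as.integer(lag), mean = mu, c0 = c0, ctau = ct,
                 eigenvalues = em$values[ord][seq_len(k)],
                 components = V, n_components = k),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tica_model: lag %d, %d component(s); leading eigenvalues: %s\n",
              x$lag, x$n_components,
              paste(sprintf("%.3f", utils::head(x$eigenvalues, 3L)),
                    collapse = ", ")))
  invisible(x)
}

#' Project features onto TICA components
#'
#' @param model a `tica_model`.
#' @param features frames x features matrix (or list of matrices, projected
#'   and concatenated in order).
#' @return numeric matrix (frames x n_components) of projections.
#' @export
tica_transform <- function(model, features) {
  if (is.list(features) && !is.data.frame(features))
    return(do.call(rbind, lapply(features, tica_transform, model = model)))
  x <- sweep(as.matrix(features), 2L, model$mean)
  x %*% model$components
}

#' Backbone pairwise-distance features for a residue region
#'
#' The standard TICA featurization for a loop: all pairwise distances among
#' the backbone atoms of the stated residues, one feature column per pair,
#' evaluated per frame over every simulation of the ensemble.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param region integer residue indices.
#' @param atoms atom names used (default backbone N, CA, C, O).
#' @return list of frames x n_pairs matrices, one per simulation.
#' @export
distance_features <- function(ensemble, region,
                              atoms = BACKBONE_ATOMS) {
  topo <- ensemble$topology
  sel <- which(topo$atoms$resid %in% region & topo$atoms$atom %in% atoms)
  if (length(sel) < 2L) stop("region selects fewer than 2 atoms")
  pairs <- utils::combn(seq_along(sel), 2L)
  lapply(ensemble$sims, function(arr) {
    nf <- dim(arr)[3L]
    t(vapply(seq_len(nf), function(f) {
      fr <- arr[sel, , f, drop = FALSE]; dim(fr) <- c(length(sel), 3L)
      d <- as.matrix(stats::dist(fr))
      d[cbind(pairs[1L, ], pairs[2L, ])]
    }, numeric(ncol(pairs))))
  })
}
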