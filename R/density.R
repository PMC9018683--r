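# Density-map simulation and rigid-body docking by random-orientation
# cross-correlation search, plus minimal MRC2014 (mode 2) map I/O.

#' Construct a density grid
#'
#' @param values 3-D numeric array of voxel values.
#' @param origin Cartesian position of the first voxel center, in A.
#' @param voxel voxel edge length in A (> 0, cubic voxels).
#' @return object of class `density_grid`.
#' @export
density_grid <- function(values, origin = c(0, 0, 0), voxel = 1) {
  stopifnot(is.array(values), length(dim(values)) == 3L, voxel > 0,
            all(is.finite(values)))
  structure(list(values = values, origin = as.numeric(origin),
                 voxel = as.numeric(voxel)), class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid: %d x %d x %d voxels, %.2f A/voxel, origin (%.1f, %.1f, %.1f)\n",
              d[1L], d[2L], d[3L], x$voxel, x$origin[1L], x$origin[2L], x$origin[3L]))
  invisible(x)
}

# Voxel-center coordinates along each axis.
grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(k) grid$origin[k] + (seq_len(d[k]) - 1L) * grid$voxel)
}

# Atomic-number weights for the common protein heavy atoms.
ATOMIC_NUMBER <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

#' Simulate a density map from coordinates
#'
#' Sum of isotropic Gaussians at atom centers with
#' `sigma = resolution / (2 * sqrt(2 * log(2)))` (so FWHM equals the nominal
#' resolution) and amplitude proportional to atomic number.
#'
#' @param model a `structure_model` or n x 3 coordinate matrix.
#' @param resolution nominal resolution in A; must be >= 2 * voxel.
#' @param voxel voxel edge in A.
#' @param grid optional template `density_grid`: simulate on its exact
#'   lattice (for scoring against a target map).
#' @param pad margin in A around the model bounding box (default 4 sigma).
#' @param weights per-atom amplitudes; defaults to atomic number for models
#'   and 6 (carbon) for bare matrices.
#' @return a [density_grid()].
#' @export
simulate_density <- function(model, resolution, voxel = 1, grid = NULL,
                             pad = NULL, weights = NULL) {
  if (inherits(model, "structure_model")) {
    xyz <- coords(model)
    w <- weights %||% {
      w0 <- ATOMIC_NUMBER[model$atoms$element]
      w0[is.na(w0)] <- 6
      w0
    }
  } else {
    xyz <- model
    w <- weights %||% rep(6, nrow(xyz))
  }
  sigma <- resolution / (2 * sqrt(2 * log(2)))
  if (!is.null(grid)) {
    voxel <- grid$voxel
    origin <- grid$origin
    dims <- dim(grid$values)
  } else {
    if (resolution < 2 * voxel)
      stop("voxel too coarse: need resolution >= 2 * voxel")
    if (is.null(pad)) pad <- 4 * sigma
    lo <- apply(xyz, 2L, min) - pad
    hi <- apply(xyz, 2L, max) + pad
    origin <- lo
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)) + 1L)
  }
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1L) * voxel)
  vals <- array(0, dims)
  cut <- 4 * sigma
  for (i in seq_len(nrow(xyz))) {
    rng <- lapply(1:3, function(k) {
      which(ax[[k]] >= xyz[i, k] - cut & ax[[k]] <= xyz[i, k] + cut)
    })
    if (any(lengths(rng) == 0L)) next
    gx <- exp(-(ax[[1L]][rng[[1L]]] - xyz[i, 1L])^2 / (2 * sigma^2))
    gy <- exp(-(ax[[2L]][rng[[2L]]] - xyz[i, 2L])^2 / (2 * sigma^2))
    gz <- exp(-(ax[[3L]][rng[[3L]]] - xyz[i, 3L])^2 / (2 * sigma^2))
    cur <- vals[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE]
    vals[rng[[1L]], rng[[2L]], rng[[3L]]] <-
      cur + w[i] * outer(outer(gx, gy), gz)
  }
  density_grid(vals, origin = origin, voxel = voxel)
}

#' Masked cross-correlation of two density grids
#'
#' About-mean Pearson correlation over the voxels where `grid_a` exceeds
#' `threshold`; both grids must share one lattice.  In [-1, 1]; invariant to
#' scale and offset of either grid.
#'
#' @param grid_a,grid_b `density_grid`s on the same lattice.
#' @param threshold mask level applied to `grid_a` (default 0: all positive
#'   voxels).
#' @return correlation score.
#' @export
cross_correlation <- function(grid_a, grid_b, threshold = 0) {
  if (!identical(dim(grid_a$values), dim(grid_b$values)) ||
      max(abs(grid_a$origin - grid_b$origin)) > 1e-6 ||
      abs(grid_a$voxel - grid_b$voxel) > 1e-9)
    stop("grids must share one lattice (resample first)")
  mask <- grid_a$values > threshold
  if (!any(mask)) stop("empty mask: no voxels of grid_a exceed the threshold")
  va <- grid_a$values[mask]; vb <- grid_b$values[mask]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("degenerate (constant) masked values")
  stats::cor(va, vb)
}

#' Rigid-body global search against a density map
#'
#' Samples uniformly random rotations (quaternion method) about the model
#' centroid and uniform centroid translations within the map bounding box,
#' combined round-robin (or as a full product), scores the simulated density
#' of every placement against the target by [cross_correlation()], and
#' returns the best.  The identity placement is evaluated first when
#' `include_identity` is TRUE (the default), so a model already placed in
#' its own map is always recovered.
#'
#' @param model a `structure_model`.
#' @param target target `density_grid`.
#' @param n_rotations,n_translations sample counts (defaults 5000 + 5000).
#' @param resolution simulation resolution in A.
#' @param seed integer seed (search is deterministic given the seed).
#' @param threshold correlation mask threshold (default 0).
#' @param mode `"round_robin"` (pair i-th rotation with i-th translation,
#'   recycling the shorter list) or `"product"` (all combinations).
#' @param include_identity evaluate the unmoved placement first.
#' @return object of class `dock_result`: `rotation`, `translation`
#'   (centroid position), `score`, `n_evaluated`, `seed`, `transform`
#'   (4 x 4 homogeneous matrix).
#' @export
global_search <- function(model, target, n_rotations = 5000,
                          n_translations = 5000, resolution, seed = 1L,
                          threshold = 0, mode = c("round_robin", "product"),
                          include_identity = TRUE) {
  mode <- match.arg(mode)
  if (n_rotations < 1 || n_translations < 1)
    stop("need at least one rotation and one translation")
  if (all(target$values == target$values[1L]))
    stop("degenerate target map")
  xyz <- coords(model)
  wts <- ATOMIC_NUMBER[model$atoms$element]
  wts[is.na(wts)] <- 6
  cen <- colMeans(xyz)
  ax <- grid_axes(target)
  lo <- vapply(ax, min, numeric(1L)); hi <- vapply(ax, max, numeric(1L))
  samp <- with_rng(seed, {
    q <- random_quaternions(n_rotations)
    tr <- cbind(stats::runif(n_translations, lo[1L], hi[1L]),
                stats::runif(n_translations, lo[2L], hi[2L]),
                stats::runif(n_translations, lo[3L], hi[3L]))
    list(q = q, tr = tr)
  })
  rots <- lapply(seq_len(n_rotations), function(i) quat_to_rot(samp$q[i, ]))
  if (mode == "round_robin") {
    k <- max(n_rotations, n_translations)
    ridx <- rep_len(seq_len(n_rotations), k)
    tidx <- rep_len(seq_len(n_translations), k)
  } else {
    g <- expand.grid(r = seq_len(n_rotations), t = seq_len(n_translations))
    ridx <- g$r; tidx <- g$t
  }
  if (include_identity) {
    rots <- c(list(diag(3)), rots)
    ridx <- c(1L, ridx + 1L)
    samp$tr <- rbind(cen, samp$tr)
    tidx <- c(1L, tidx + 1L)
  }
  centered <- sweep(xyz, 2L, cen)
  best <- list(score = -Inf)
  for (k in seq_along(ridx)) {
    R <- rots[[ridx[k]]]
    pos <- sweep(centered %*% t(R), 2L, samp$tr[tidx[k], ], `+`)
    sim <- simulate_density(pos, resolution = resolution, grid = target,
                            weights = wts)
    sc <- tryCatch(cross_correlation(target, sim, threshold = threshold),
                   error = function(e) NA_real_)
    if (is.finite(sc) && sc > best$score)
      best <- list(score = sc, rotation = R,
                   translation = samp$tr[tidx[k], ], index = k)
  }
  if (!is.finite(best$score)) stop("no placement produced a finite score")
  tf <- diag(4)
  tf[1:3, 1:3] <- best$rotation
  tf[1:3, 4L] <- best$translation - as.vector(best$rotation %*% cen)
  structure(list(rotation = best$rotation, translation = best$translation,
                 score = best$score, n_evaluated = length(ridx),
                 seed = seed, transform = tf),
            class = "dock_result")
}

#' @export
print.dock_result <- function(x, ...) {
  cat(sprintf("dock_result: score %.4f over %d placements (seed %d)\n",
              x$score, x$n_evaluated, x$seed))
  invisible(x)
}

# ---- MRC2014 I/O (mode 2, float32) ------------------------------------------

#' Write a density grid as an MRC/CCP4 map
#'
#' MRC2014, mode 2 (32-bit float), axis order x, y, z; the origin is stored
#' in the ORIGIN fields (A).
#'
#' @param grid a `density_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                      # NX NY NZ
  wi(2L)                     # MODE 2: float32
  wi(c(0L, 0L, 0L))          # NXSTART..
  wi(d)                      # MX MY MZ
  wf(d * grid$voxel)         # CELLA
  wf(c(90, 90, 90))          # CELLB
  wi(c(1L, 2L, 3L))          # MAPC MAPR MAPS: x, y, z
  v <- grid$values
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))              # ISPG, NSYMBT
  writeBin(raw(100L), con)   # EXTRA (25 words)
  wf(grid$origin)            # ORIGIN
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.vector(v)))  # RMS
  wi(0L)                     # NLABL
  writeBin(raw(800L), con)   # labels
  writeBin(as.numeric(as.vector(v)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC/CCP4 map
#'
#' Supports modes 0/1/2; axis order is normalized to (x, y, z) using the
#' MAPC/MAPR/MAPS fields.  The origin is taken from ORIGIN when set,
#' otherwise from NXSTART * voxel.
#'
#' @param path MRC file path.
#' @return a [density_grid()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  nxyz <- ri(3L)
  mode <- ri(1L)
  nstart <- ri(3L)
  mxyz <- ri(3L)
  cella <- rf(3L)
  rf(3L)                     # cell angles
  mapcrs <- ri(3L)
  rf(3L)                     # dmin dmax dmean
  ri(2L)                     # ispg nsymbt
  readBin(con, "raw", 100L)
  origin <- rf(3L)
  readBin(con, "raw", 4L)    # "MAP "
  readBin(con, "raw", 4L)    # MACHST
  rf(1L)                     # RMS
  nlabl <- ri(1L)
  readBin(con, "raw", 800L)
  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little")),
    "2" = rf(n),
    stop("unsupported MRC mode: ", mode))
  arr <- array(vals, nxyz)   # stored fastest-first in MAPC/MAPR/MAPS order
  perm <- order(mapcrs)      # permutation taking column axes -> x,y,z
  if (!identical(perm, 1:3)) arr <- aperm(arr, perm)
  voxel <- cella[1L] / mxyz[1L]
  if (all(origin == 0) && any(nstart != 0)) origin <- nstart[perm] * voxel
  density_grid(arr, origin = origin, voxel = voxel)
}
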