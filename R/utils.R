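# Internal numerical helpers shared across modules.

#' Evaluate an expression with a private, seeded RNG stream
#'
#' Saves and restores the global `.Random.seed` so that generators never leak
#' state between calls (every stochastic operation in this package takes an
#' explicit `seed`).
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees into (-180, 180]
#' @keywords internal
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

# Rotation about the z axis by `deg` degrees (right-handed).
rotz <- function(deg) {
  th <- deg2rad(deg)
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0,        0,       1), 3L, 3L, byrow = TRUE)
}

# Unit quaternion (w, x, y, z) -> 3x3 rotation matrix.
quat_to_rot <- function(q) {
  q <- q / vnorm(q)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

# n uniform random rotations via the quaternion (Shoemake) method.
# Returns an n x 4 matrix of unit quaternions.
random_quaternions <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Element inferred from a PDB-style atom name: first alphabetic character
# (adequate for C/N/O/S protein heavy atoms).
infer_element <- function(atom_name) {
  el <- sub("^[0-9]*", "", atom_name)
  toupper(substr(el, 1L, 1L))
}
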