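# Distance-restraint data model and bookkeeping: sequence-separation
# classification, bound conversion, summary tabulation, per-residue counts,
# and violation statistics over a structure bundle.

#' Construct a restraint set
#'
#' A `restraint_set` is a data frame with one row per member atom pair.
#' Unambiguous restraints have a single member; ambiguous restraints list one
#' row per surviving assignment possibility (an OR-group, collapsed by
#' r^-6 summation when evaluated).  Columns: `restraint_id`, `member`,
#' `res_a`, `atom_a`, `res_b`, `atom_b`, `lower`, `upper` (A), `category`,
#' `sep` (|i-j|), `ambiguous`, `experiment`, `peak_id`.
#'
#' @param df data frame as above (missing bookkeeping columns are filled).
#' @return an object of class `restraint_set`.
#' @export
restraint_set <- function(df = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(restraint_id = integer(0), member = integer(0),
                     res_a = integer(0), atom_a = character(0),
                     res_b = integer(0), atom_b = character(0),
                     lower = numeric(0), upper = numeric(0),
                     category = character(0), sep = integer(0),
                     ambiguous = logical(0), experiment = character(0),
                     peak_id = integer(0), stringsAsFactors = FALSE)
  } else {
    need <- c("restraint_id", "res_a", "atom_a", "res_b", "atom_b",
              "lower", "upper")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("restraint set missing columns: ",
                           paste(miss, collapse = ", "))
    if (is.null(df$member))
      df$member <- stats::ave(df$restraint_id, df$restraint_id,
                              FUN = seq_along)
    if (is.null(df$sep)) df$sep <- abs(df$res_a - df$res_b)
    if (is.null(df$category)) df$category <- classify_separation(df$sep)
    if (is.null(df$ambiguous))
      df$ambiguous <- stats::ave(df$restraint_id, df$restraint_id,
                                 FUN = length) > 1L
    if (is.null(df$experiment)) df$experiment <- NA_character_
    if (is.null(df$peak_id)) df$peak_id <- NA_integer_
    for (col in c("restraint_id", "member", "res_a", "res_b", "sep", "peak_id"))
      df[[col]] <- as.integer(df[[col]])
    for (col in c("atom_a", "atom_b", "category", "experiment"))
      df[[col]] <- as.character(df[[col]])
    df$ambiguous <- as.logical(df$ambiguous)
    df$lower <- as.numeric(df$lower); df$upper <- as.numeric(df$upper)
    if (any(df$lower <= 0) || any(df$lower >= df$upper))
      stop("restraint bounds must satisfy 0 < lower < upper")
  }
  df <- df[, c("restraint_id", "member", "res_a", "atom_a", "res_b", "atom_b",
               "lower", "upper", "category", "sep", "ambiguous", "experiment",
               "peak_id")]
  class(df) <- c("restraint_set", "data.frame")
  df
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d restraints (%d unambiguous, %d ambiguous)\n",
              length(unique(x$restraint_id)),
              length(unique(x$restraint_id[!x$ambiguous])),
              length(unique(x$restraint_id[x$ambiguous]))))
  invisible(x)
}

#' Classify a restraint by sequence separation
#'
#' |i-j| = 0 is intra-residue, 1 sequential, 2-4 medium range, >= 5 long
#' range.  The conventional category bounds leave |i-j| = 4 unallocated
#' between "1 < |i-j| < 4" and "|i-j| > 4"; this package assigns it to
#' medium by default (`four_is_medium = FALSE` moves it to long).
#'
#' @param sep non-negative integer sequence separation(s).
#' @param four_is_medium allocate |i-j| = 4 to medium (default) or long.
#' @return character vector: "intra", "sequential", "medium" or "long".
#' @export
classify_separation <- function(sep, four_is_medium = TRUE) {
  if (any(sep < 0)) stop("sequence separation must be >= 0")
  long_min <- if (four_is_medium) 5L else 4L
  ifelse(sep == 0L, "intra",
    ifelse(sep == 1L, "sequential",
      ifelse(sep < long_min, "medium", "long")))
}

#' Distance bounds implied by a correlation
#'
#' Cross peaks are converted to generous bounds: 1.5-6.5 A for intra-residue
#' correlations and 2.0-7.2 A for inter-residue correlations (constants
#' configurable).
#'
#' @param kind `"intra"` or `"inter"`.
#' @param intra,inter length-2 numeric bound pairs.
#' @return c(lower, upper) in A.
#' @export
to_bounds <- function(kind = c("intra", "inter"), intra = c(1.5, 6.5),
                      inter = c(2.0, 7.2)) {
  kind <- match.arg(kind)
  b <- if (kind == "intra") intra else inter
  stopifnot(length(b) == 2L, b[1L] > 0, b[1L] < b[2L])
  b
}

#' Tabulate a restraint set
#'
#' Counts per sequence-separation category, split by ambiguity status and by
#' nucleus pair (CC vs NC), in the layout of a standard restraint-summary
#' table.  Category counts sum to the totals by construction.
#'
#' @param rset a `restraint_set`.
#' @return data frame with rows intra/sequential/medium/long/total and count
#'   columns `cc_unambiguous`, `cc_ambiguous`, `nc`, `total`.
#' @export
tabulate_restraints <- function(rset) {
  cats <- c("intra", "sequential", "medium", "long")
  # per-restraint attributes from the first member
  first <- !duplicated(rset$restraint_id)
  r <- rset[first, , drop = FALSE]
  is_nc <- infer_element(r$atom_a) == "N" | infer_element(r$atom_b) == "N"
  count <- function(keep) {
    v <- table(factor(r$category[keep], levels = cats))
    as.integer(v)
  }
  out <- data.frame(
    category = c(cats, "total"),
    cc_unambiguous = c(count(!r$ambiguous & !is_nc),
                       sum(!r$ambiguous & !is_nc)),
    cc_ambiguous = c(count(r$ambiguous & !is_nc), sum(r$ambiguous & !is_nc)),
    nc = c(count(is_nc), sum(is_nc)),
    stringsAsFactors = FALSE)
  out$total <- out$cc_unambiguous + out$cc_ambiguous + out$nc
  out
}

#' Per-residue unambiguous restraint counts
#'
#' Each unambiguous restraint increments both partner residues (an
#' intra-residue restraint increments its residue twice).  Ambiguous
#' restraints are excluded by default.
#'
#' @param rset a `restraint_set`.
#' @param resids residue index range to report (defaults to observed range).
#' @param include_ambiguous include ambiguous restraints (each member group
#'   counted once via its first member).
#' @return data frame `resid`, `count`.
#' @export
per_residue_counts <- function(rset, resids = NULL,
                               include_ambiguous = FALSE) {
  first <- !duplicated(rset$restraint_id)
  r <- rset[first & (include_ambiguous | !rset$ambiguous), , drop = FALSE]
  touched <- c(r$res_a, r$res_b)
  if (is.null(resids)) {
    resids <- if (length(touched)) seq(min(touched), max(touched)) else integer(0)
  }
  data.frame(resid = resids,
             count = as.integer(table(factor(touched, levels = resids))))
}

# Effective distance of a (possibly ambiguous) restraint in one model:
# r^-6 summation over member pairs, the standard ambiguous-NOE convention.
effective_distance <- function(d) {
  if (length(d) == 1L) return(d)
  sum(d^-6)^(-1 / 6)
}

resolve_atom <- function(model, resid, atom) {
  i <- which(model$atoms$resid == resid & model$atoms$atom == atom)
  if (length(i) != 1L)
    stop("cannot resolve atom (resid ", resid, ", name ", atom, ")")
  i
}

#' Construct torsion restraints
#'
#' @param df data frame with `resid`, `angle` ("phi"/"psi"), `center`
#'   (degrees in (-180, 180]), `halfwidth` (degrees > 0).
#' @return an object of class `torsion_restraints`.
#' @export
torsion_restraints <- function(df) {
  stopifnot(all(c("resid", "angle", "center", "halfwidth") %in% names(df)))
  if (!all(df$angle %in% c("phi", "psi"))) stop("angle must be phi or psi")
  if (any(df$center <= -180 | df$center > 180))
    stop("centers must lie in (-180, 180]")
  if (any(df$halfwidth <= 0)) stop("halfwidths must be > 0")
  class(df) <- c("torsion_restraints", "data.frame")
  df
}

# Backbone dihedral of one residue in one model; NA at chain termini.
model_torsion <- function(model, resid, angle) {
  a <- model$atoms
  g <- function(r, at) {
    i <- which(a$resid == r & a$atom == at)
    if (length(i) != 1L) return(NULL)
    c(a$x[i], a$y[i], a$z[i])
  }
  pts <- if (angle == "phi") {
    list(g(resid - 1L, "C"), g(resid, "N"), g(resid, "CA"), g(resid, "C"))
  } else {
    list(g(resid, "N"), g(resid, "CA"), g(resid, "C"), g(resid + 1L, "N"))
  }
  if (any(vapply(pts, is.null, logical(1L)))) return(NA_real_)
  dihedral(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
}

#' Violation statistics of a bundle against restraints
#'
#' Per model, the distance violation of a restraint is
#' `max(0, d - upper, lower - d)` where `d` is the effective distance
#' (r^-6-summed over ambiguous group members); torsion violations are the
#' angular excess beyond `center +/- halfwidth` (shortest arc).  Reported as
#' the per-model mean aggregated across models (mean +/- sd) plus overall
#' maxima.
#'
#' @param bundle a `structure_bundle`.
#' @param rset a `restraint_set` (atoms must resolve in the topology).
#' @param torsions optional `torsion_restraints`.
#' @return list of class `violation_report`: `distance` (per model x
#'   restraint matrix), `torsion`, and `summary` (data frame with mean, sd,
#'   max rows).
#' @export
compute_violations <- function(bundle, rset, torsions = NULL) {
  stopifnot(inherits(bundle, "structure_bundle"))
  topo <- bundle$models[[1L]]
  ia <- mapply(function(r, at) resolve_atom(topo, r, at), rset$res_a, rset$atom_a)
  ib <- mapply(function(r, at) resolve_atom(topo, r, at), rset$res_b, rset$atom_b)
  rids <- unique(rset$restraint_id)
  n_m <- length(bundle$models)
  dmat <- matrix(NA_real_, n_m, length(rids),
                 dimnames = list(NULL, as.character(rids)))
  for (m in seq_len(n_m)) {
    xyz <- coords(bundle$models[[m]])
    d_all <- sqrt(rowSums((xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE])^2))
    for (k in seq_along(rids)) {
      rows <- which(rset$restraint_id == rids[k])
      d <- effective_distance(d_all[rows])
      lo <- rset$lower[rows[1L]]; up <- rset$upper[rows[1L]]
      dmat[m, k] <- max(0, d - up, lo - d)
    }
  }
  tmat <- NULL
  if (!is.null(torsions) && nrow(torsions)) {
    tmat <- matrix(NA_real_, n_m, nrow(torsions))
    for (m in seq_len(n_m)) {
      for (k in seq_len(nrow(torsions))) {
        ang <- model_torsion(bundle$models[[m]], torsions$resid[k],
                             torsions$angle[k])
        if (is.na(ang)) { tmat[m, k] <- NA_real_; next }
        dev <- abs(wrap_angle(ang - torsions$center[k]))
        tmat[m, k] <- max(0, dev - torsions$halfwidth[k])
      }
    }
  }
  per_model_dist <- rowMeans(dmat)
  summ <- data.frame(
    quantity = c("distance_mean", "distance_sd", "distance_max"),
    value = c(mean(per_model_dist), stats::sd(per_model_dist), max(dmat)))
  if (!is.null(tmat)) {
    per_model_tor <- rowMeans(tmat, na.rm = TRUE)
    summ <- rbind(summ, data.frame(
      quantity = c("torsion_mean", "torsion_sd", "torsion_max"),
      value = c(mean(per_model_tor), stats::sd(per_model_tor),
                max(tmat, na.rm = TRUE))))
  }
  structure(list(distance = dmat, torsion = tmat, summary = summ),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat("violation_report\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
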