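# Coordinate analytics over models and bundles: least-squares superposition
# (Kabsch), pairwise-bundle and regional RMSD, hydrogen-bond geometry,
# specific atom distances, and helical filament construction from per-subunit
# twist/rise.

#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' matched atom selections of two models, via SVD of the covariance matrix
#' with determinant correction (no improper rotations).
#'
#' @param A,B `structure_model`s (B is fitted onto A) or plain n x 3
#'   coordinate matrices.
#' @param selection selection (string/logical/indices) applied to both
#'   models; must map 1:1 and contain >= 3 non-collinear atoms.
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3; the fitted B is `B %*% t(R) + t`), `rmsd`
#'   (A), `selection`.
#' @export
superpose_rmsd <- function(A, B, selection = "all") {
  xa <- if (inherits(A, "structure_model")) coords(A, selection) else A
  xb <- if (inherits(B, "structure_model")) coords(B, selection) else B
  if (!is.matrix(xa) || !is.matrix(xb) || nrow(xa) != nrow(xb))
    stop("selections must map 1:1 between A and B")
  if (nrow(xa) < 3L) stop("need at least 3 atoms to superpose")
  ca <- colMeans(xa); cb <- colMeans(xb)
  ya <- sweep(xa, 2L, ca); yb <- sweep(xb, 2L, cb)
  if (min(svd(ya)$d) < 1e-9 * max(svd(ya)$d) && nrow(xa) == 3L)
    stop("degenerate (collinear) selection")
  H <- crossprod(yb, ya)          # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- yb %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - ya)^2)))
  t_vec <- ca - as.vector(R %*% cb)
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 selection = if (is.character(selection)) selection else "custom"),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A over selection '%s'\n",
              x$rmsd, x$selection))
  invisible(x)
}

# Apply a superposition to a coordinate matrix or model.
apply_superposition <- function(sp, x) {
  if (inherits(x, "structure_model"))
    return(set_coords(x, apply_superposition(sp, coords(x))))
  sweep(x %*% t(sp$rotation), 2L, sp$translation, `+`)
}

#' Mean pairwise RMSD across a bundle
#'
#' RMSD from [superpose_rmsd()] over every unordered model pair of the
#' bundle, the standard precision statistic of an NMR ensemble.
#'
#' @param bundle a `structure_bundle` with >= 2 models.
#' @param selection residue/atom selection string; combined with `atoms`.
#' @param atoms `"backbone"` (N, CA, C, O) or `"heavy"` (all non-H).
#' @return list `mean`, `sd`, `n_pairs`, `values`.
#' @export
bundle_pairwise_rmsd <- function(bundle, selection = "all",
                                 atoms = c("backbone", "heavy")) {
  stopifnot(inherits(bundle, "structure_bundle"))
  if (length(bundle) < 2L)
    stop("pairwise RMSD needs >= 2 models (bundle of one: statistic undefined)")
  atoms <- match.arg(atoms)
  sel <- sprintf("(%s) and %s", selection, atoms)
  n <- length(bundle)
  vals <- numeric(0)
  xs <- lapply(bundle$models, coords, selection = sel)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    vals <- c(vals, superpose_rmsd(xs[[i]], xs[[j]])$rmsd)
  }
  list(mean = mean(vals), sd = stats::sd(vals), n_pairs = length(vals),
       values = vals)
}

#' Global-fit then regional RMSD
#'
#' Superposes B on A over the global selection, then evaluates the RMSD over
#' the region atoms WITHOUT re-fitting (a "local RMSD" contrasted with the
#' global one).  Set `refit = TRUE` for an independent local fit instead.
#'
#' @param A,B `structure_model`s.
#' @param global_selection selection string used for fitting.
#' @param region integer vector of residue indices evaluated regionally.
#' @param atoms atom class for both selections ("backbone" or "heavy").
#' @param refit fit again on the region before evaluating (default FALSE).
#' @return list `global_rmsd`, `regional_rmsd`.
#' @export
region_rmsd <- function(A, B, global_selection = "all", region,
                        atoms = c("backbone", "heavy"), refit = FALSE) {
  if (!length(region)) stop("empty region")
  atoms <- match.arg(atoms)
  gsel <- sprintf("(%s) and %s", global_selection, atoms)
  sp <- superpose_rmsd(A, B, gsel)
  rsel <- sprintf("resid %s and %s",
                  paste(range(region), collapse = "-"), atoms)
  xa <- coords(A, rsel)
  xb <- coords(B, rsel)
  if (refit) {
    regional <- superpose_rmsd(xa, xb)$rmsd
  } else {
    fitted <- apply_superposition(sp, xb)
    regional <- sqrt(mean(rowSums((fitted - xa)^2)))
  }
  list(global_rmsd = sp$rmsd, regional_rmsd = regional)
}

#' Detect hydrogen bonds by donor-acceptor geometry
#'
#' Pairs a donor heavy-atom selection with an acceptor selection and reports
#' pairs within the heavy-atom distance cutoff; when an attached hydrogen is
#' present the D-H...A angle must also exceed `angle_min`.  For bundles,
#' per-model distances of each detected pair and their mean are returned.
#'
#' @param x a `structure_model` or `structure_bundle`.
#' @param donor_sel,acceptor_sel selection strings (default backbone
#'   N donors / carbonyl O acceptors).
#' @param dist_cutoff heavy-atom distance cutoff in A (default 3.5).
#' @param angle_min minimum D-H...A angle in degrees (default 120; only
#'   enforced when hydrogens exist).
#' @param min_sep skip pairs closer in sequence than this (default 2,
#'   excluding self/sequential backbone contacts).
#' @return data frame of class `hbond_table`: donor/acceptor residue and
#'   atom, `distance` (mean over models for bundles), `sd`, `n_models`.
#' @export
detect_hbonds <- function(x, donor_sel = "name N", acceptor_sel = "name O",
                          dist_cutoff = 3.5, angle_min = 120, min_sep = 2L) {
  models <- if (inherits(x, "structure_bundle")) x$models else list(x)
  topo <- models[[1L]]
  don <- select_atoms(topo, donor_sel)
  acc <- select_atoms(topo, acceptor_sel)
  if (!length(don) || !length(acc))
    return(structure(data.frame(), class = c("hbond_table", "data.frame")))
  a <- topo$atoms
  pairs <- expand.grid(d = don, a = acc)
  pairs <- pairs[abs(a$resid[pairs$d] - a$resid[pairs$a]) >= min_sep, ,
                 drop = FALSE]
  if (!nrow(pairs))
    return(structure(data.frame(), class = c("hbond_table", "data.frame")))
  dmat <- sapply(models, function(m) {
    xyz <- coords(m)
    sqrt(rowSums((xyz[pairs$d, , drop = FALSE] -
                  xyz[pairs$a, , drop = FALSE])^2))
  })
  dmat <- matrix(dmat, nrow = nrow(pairs))
  dmean <- rowMeans(dmat)
  keep <- dmean <= dist_cutoff
  # angle criterion: look for a hydrogen bonded to the donor (name H*, same
  # residue, within 1.3 A); enforced only when present
  if (any(keep)) {
    xyz0 <- coords(topo)
    for (r in which(keep)) {
      di <- pairs$d[r]
      hs <- which(a$resid == a$resid[di] & a$element == "H")
      if (!length(hs)) next
      hd <- sqrt(rowSums(sweep(xyz0[hs, , drop = FALSE], 2L, xyz0[di, ], `-`)^2))
      hi <- hs[which.min(hd)]
      if (hd[which.min(hd)] > 1.3) next
      v1 <- xyz0[di, ] - xyz0[hi, ]
      v2 <- xyz0[pairs$a[r], ] - xyz0[hi, ]
      ang <- rad2deg(acos(sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))
      if (ang < angle_min) keep[r] <- FALSE
    }
  }
  if (!any(keep))
    return(structure(data.frame(), class = c("hbond_table", "data.frame")))
  out <- data.frame(
    donor_resid = a$resid[pairs$d[keep]], donor_atom = a$atom[pairs$d[keep]],
    acceptor_resid = a$resid[pairs$a[keep]],
    acceptor_atom = a$atom[pairs$a[keep]],
    distance = dmean[keep],
    sd = apply(dmat[keep, , drop = FALSE], 1L, stats::sd),
    n_models = length(models), stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hbond_table", "data.frame"))
}

#' Distance between two uniquely selected atoms
#'
#' @param model a `structure_model`.
#' @param sel1,sel2 selection strings, each resolving to exactly one atom.
#' @return distance in A.
#' @export
atom_distance <- function(model, sel1, sel2) {
  i <- select_atoms(model, sel1)
  j <- select_atoms(model, sel2)
  if (length(i) != 1L) stop("selector 1 matches ", length(i), " atoms (need 1)")
  if (length(j) != 1L) stop("selector 2 matches ", length(j), " atoms (need 1)")
  xyz <- coords(model)
  vnorm(xyz[i, ] - xyz[j, ])
}

#' Helical parameters
#'
#' @param twist degrees of rotation per subunit (e.g. -162.1 for an actin
#'   filament).
#' @param rise translation per subunit along the helix axis in A (e.g. 27.6).
#' @param n_subunits number of subunits (>= 1).
#' @return object of class `helical_params`.
#' @export
helical_params <- function(twist, rise, n_subunits) {
  if (n_subunits < 1) stop("n_subunits must be >= 1")
  structure(list(twist = twist, rise = rise,
                 n_subunits = as.integer(n_subunits)),
            class = "helical_params")
}

#' Build a helical assembly from one protomer
#'
#' Subunit k (k = 0 .. n-1) is the protomer rotated by `k * twist` about the
#' z axis and translated by `k * rise` along it; chain identifiers are
#' assigned sequentially (A, B, C, ...).  Every consecutive subunit pair is
#' therefore related by the same rototranslation.
#'
#' @param protomer a `structure_model` (placed relative to the z axis).
#' @param params a [helical_params()].
#' @return a `structure_model` containing all subunits.
#' @export
build_helical_assembly <- function(protomer, params) {
  stopifnot(inherits(protomer, "structure_model"),
            inherits(params, "helical_params"))
  xyz <- coords(protomer)
  chains <- c(LETTERS, letters, as.character(0:9))
  if (params$n_subunits > length(chains))
    stop("too many subunits for distinct chain identifiers")
  blocks <- lapply(seq_len(params$n_subunits) - 1L, function(k) {
    R <- rotz(k * params$twist)
    newxyz <- xyz %*% t(R)
    newxyz[, 3L] <- newxyz[, 3L] + k * params$rise
    a <- protomer$atoms
    a$x <- newxyz[, 1L]; a$y <- newxyz[, 2L]; a$z <- newxyz[, 3L]
    a$chain <- chains[k + 1L]
    a
  })
  structure_model(do.call(rbind, blocks))
}
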