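# Trajectory-ensemble statistics: contact occupancy (pooled across
# simulations and interfaces), per-atom RMSF, and pairwise-distance maps.

#' Contact specification
#'
#' A contact holds when the minimum distance between the sidechain heavy
#' atoms of two residues does not exceed the cutoff (default 3.4 A).
#' Glycine, which has no sidechain heavy atom, falls back to CA.
#'
#' @param pairs data frame `res_a`, `res_b` and optional `interface`
#'   (integer j of m interfaces; default one interface per pair).
#' @param cutoff contact cutoff in A (> 0).
#' @return object of class `contact_spec`.
#' @export
contact_spec <- function(pairs, cutoff = 3.4) {
  stopifnot(is.data.frame(pairs), all(c("res_a", "res_b") %in% names(pairs)),
            cutoff > 0)
  if (is.null(pairs$interface)) pairs$interface <- seq_len(nrow(pairs))
  structure(list(pairs = pairs, cutoff = cutoff), class = "contact_spec")
}

# Sidechain heavy-atom indices of one residue (CA fallback for glycine).
sidechain_indices <- function(model, resid) {
  a <- model$atoms
  i <- which(a$resid == resid & a$element != "H" &
             !a$atom %in% BACKBONE_ATOMS)
  if (!length(i)) i <- which(a$resid == resid & a$atom == "CA")
  if (!length(i)) stop("residue ", resid, " has no sidechain or CA atom")
  i
}

#' Contact occupancy over a trajectory ensemble
#'
#' For each residue pair, occupancy is the pooled fraction
#' `sum_ij C_ab^{i,j} / sum_ij C_total^{i,j} * 100` over the n simulations
#' (i) and m interfaces (j): contact frames over total frames, as a
#' percentage.  `per_sim_average = TRUE` instead averages per-simulation
#' percentages (the alternative pooling convention).
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param spec a [contact_spec()].
#' @param per_sim_average average per-simulation percentages instead of
#'   pooling frame counts (default FALSE: the pooled double-sum formula).
#' @return data frame of class `occupancy_table`: `res_a`, `res_b`,
#'   `interface`, `contact_frames`, `total_frames`, `occupancy` (percent).
#' @export
contact_occupancy <- function(ensemble, spec,
                              per_sim_average = FALSE) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(spec, "contact_spec"))
  topo <- ensemble$topology
  pairs <- spec$pairs
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    ia <- sidechain_indices(topo, pairs$res_a[p])
    ib <- sidechain_indices(topo, pairs$res_b[p])
    cab <- 0L; ctot <- 0L; per_sim <- numeric(0)
    for (s in seq_along(ensemble$sims)) {
      arr <- ensemble$sims[[s]]
      nf <- dim(arr)[3L]
      hits <- vapply(seq_len(nf), function(f) {
        xa <- arr[ia, , f, drop = FALSE]; dim(xa) <- c(length(ia), 3L)
        xb <- arr[ib, , f, drop = FALSE]; dim(xb) <- c(length(ib), 3L)
        mind <- min(sqrt(outer(rowSums(xa^2), rowSums(xb^2), `+`) -
                           2 * xa %*% t(xb)))
        mind <= spec$cutoff
      }, logical(1L))
      cab <- cab + sum(hits); ctot <- ctot + nf
      per_sim <- c(per_sim, 100 * sum(hits) / nf)
    }
    occ <- if (per_sim_average) mean(per_sim) else 100 * cab / ctot
    data.frame(res_a = pairs$res_a[p], res_b = pairs$res_b[p],
               interface = pairs$interface[p],
               contact_frames = cab, total_frames = ctot, occupancy = occ)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("occupancy_table", "data.frame"))
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF of each selected atom about its time-average position,
#' `sqrt(mean |r - <r>|^2)`, optionally after per-frame least-squares
#' superposition onto a reference (which removes rigid-body motion).
#'
#' @param traj a `trajectory_ensemble` (frames pooled across simulations) or
#'   a single `n_atoms x 3 x n_frames` array.
#' @param topology `structure_model` topology (taken from the ensemble when
#'   omitted).
#' @param selection atom selection evaluated for the RMSF (and used for
#'   fitting).
#' @param superpose superpose each frame onto `reference` first.
#' @param reference reference coordinates for fitting (default: first
#'   frame).
#' @return data frame `atom_index`, `resid`, `atom`, `rmsf` (A).
#' @export
rmsf <- function(traj, topology = NULL, selection = "all", superpose = TRUE,
                 reference = NULL) {
  if (inherits(traj, "trajectory_ensemble")) {
    topology <- traj$topology
    frames <- do.call(c, lapply(traj$sims, function(arr)
      lapply(seq_len(dim(arr)[3L]), function(f) {
        m <- arr[, , f, drop = FALSE]; dim(m) <- dim(arr)[1:2]; m
      })))
  } else {
    stopifnot(is.array(traj), length(dim(traj)) == 3L, !is.null(topology))
    frames <- lapply(seq_len(dim(traj)[3L]), function(f) {
      m <- traj[, , f, drop = FALSE]; dim(m) <- dim(traj)[1:2]; m
    })
  }
  if (length(frames) < 2L) stop("RMSF needs >= 2 frames")
  sel <- select_atoms(topology, selection)
  if (is.null(reference)) reference <- frames[[1L]]
  mats <- lapply(frames, function(fr) {
    if (superpose) {
      sp <- superpose_rmsd(reference[sel, , drop = FALSE],
                           fr[sel, , drop = FALSE])
      apply_superposition(sp, fr[sel, , drop = FALSE])
    } else fr[sel, , drop = FALSE]
  })
  cube <- simplify2array(mats)            # n_sel x 3 x n_frames
  mean_pos <- apply(cube, c(1L, 2L), mean)
  dev2 <- sweep(cube, c(1L, 2L), mean_pos)^2
  # dev2 is n_sel x 3 x n_frames; per atom mean over frames of |dr|^2
  msf <- vapply(seq_along(sel), function(i) {
    mean(colSums(matrix(dev2[i, , ], nrow = 3L)))
  }, numeric(1L))
  data.frame(atom_index = sel,
             resid = topology$atoms$resid[sel],
             atom = topology$atoms$atom[sel],
             rmsf = sqrt(msf))
}

#' Pairwise distance map
#'
#' Symmetric matrix of CA-CA (or other selected-atom) distances for a model,
#' or the per-entry mean over a set of frames.  With `other` given, the
#' elementwise difference `A - B` is also returned.
#'
#' @param x a `structure_model`, or a `trajectory_ensemble`/3-D frame array
#'   (mean over frames).
#' @param selection atom selection (default `"calpha"`).
#' @param topology required when `x` is a bare array.
#' @param other optional second distance matrix (same shape) to subtract.
#' @return list `map` (matrix) and, when `other` is given, `difference`.
#' @export
pairwise_distance_map <- function(x, selection = "calpha", topology = NULL,
                                  other = NULL) {
  dist_of <- function(xyz) as.matrix(stats::dist(xyz))
  if (inherits(x, "structure_model")) {
    m <- dist_of(coords(x, selection))
    labels <- x$atoms$resid[select_atoms(x, selection)]
  } else {
    if (inherits(x, "trajectory_ensemble")) {
      topology <- x$topology
      arrs <- x$sims
    } else {
      stopifnot(is.array(x), !is.null(topology))
      arrs <- list(x)
    }
    sel <- select_atoms(topology, selection)
    if (!length(sel)) stop("empty selection")
    acc <- NULL; nf_tot <- 0L
    for (arr in arrs) {
      for (f in seq_len(dim(arr)[3L])) {
        fr <- arr[sel, , f, drop = FALSE]; dim(fr) <- c(length(sel), 3L)
        d <- dist_of(fr)
        acc <- if (is.null(acc)) d else acc + d
        nf_tot <- nf_tot + 1L
      }
    }
    m <- acc / nf_tot
    labels <- topology$atoms$resid[sel]
  }
  dimnames(m) <- list(labels, labels)
  out <- list(map = m)
  if (!is.null(other)) {
    if (!all(dim(other) == dim(m))) stop("difference requires matching shapes")
    out$difference <- m - other
  }
  out
}
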