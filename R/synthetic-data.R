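# Synthetic-data generators.  Every downstream stage of the pipeline can be
# exercised against these with known ground truth: an ideal helix model,
# Gaussian-perturbed coordinate bundles, cross-peak lists generated from a
# structure under a labeling scheme, trajectory ensembles with scheduled
# contacts, and a two-state Markov series for slow-mode analysis.

# Amino-acid alphabet used for synthetic residues (3-letter codes).
SYN_RESTYPES <- c("ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "GLY", "HIS",
                  "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
                  "TRP", "TYR", "VAL")

#' Generate an ideal alpha-helix model
#'
#' Builds a poly-peptide backbone (N, CA, C, O per residue) on canonical
#' helical geometry — 1.5 A rise and 100 degrees of twist per residue about
#' the z axis, giving consecutive CA-CA distances of ~3.8 A — plus a single
#' pseudo-sidechain CB atom for every non-glycine residue.  Residue types are
#' drawn deterministically from `seed`; the geometry itself is deterministic.
#'
#' @param n_res number of residues (>= 2).
#' @param seed integer seed controlling the residue-type sequence.
#' @return a [structure_model()].
#' @examples
#' m <- make_helix_model(10, seed = 1)
#' @export
make_helix_model <- function(n_res, seed = 1L) {
  if (!is.numeric(n_res) || n_res < 2) stop("n_res must be >= 2")
  n_res <- as.integer(n_res)
  restypes <- with_rng(seed, sample(SYN_RESTYPES, n_res, replace = TRUE))

  rise <- 1.5; twist <- 100
  # cylindrical backbone parameters (radius A, phase deg, z-offset A) giving
  # canonical helical geometry: CA-CA 3.80 A, O(i)...N(i+4) ~3.35 A
  cyl <- list(N = c(1.56, -28.4, -0.70), CA = c(2.28, 0, 0),
              C = c(1.67, 28.9, 0.76), O = c(1.98, 23.9, 2.00))
  cyl_pos <- function(i, p) {
    phi <- deg2rad((i - 1L) * twist + p[2L])
    c(p[1L] * cos(phi), p[1L] * sin(phi), (i - 1L) * rise + p[3L])
  }
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    ca <- cyl_pos(i, cyl$CA)
    outward <- unit(c(ca[1L], ca[2L], 0))
    n_at <- cyl_pos(i, cyl$N)
    c_at <- cyl_pos(i, cyl$C)
    o_at <- cyl_pos(i, cyl$O)
    atoms <- data.frame(
      resid = i, restype = restypes[i],
      atom = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      x = c(n_at[1L], ca[1L], c_at[1L], o_at[1L]),
      y = c(n_at[2L], ca[2L], c_at[2L], o_at[2L]),
      z = c(n_at[3L], ca[3L], c_at[3L], o_at[3L]),
      stringsAsFactors = FALSE)
    if (restypes[i] != "GLY") {
      cb <- ca + 1.53 * unit(0.92 * outward - c(0, 0, 0.39))
      atoms <- rbind(atoms, data.frame(
        resid = i, restype = restypes[i], atom = "CB", element = "C",
        x = cb[1L], y = cb[2L], z = cb[3L], stringsAsFactors = FALSE))
    }
    rows[[i]] <- atoms
  }
  structure_model(do.call(rbind, rows))
}

#' Perturb a model into a coordinate bundle
#'
#' Each of `n_models` copies receives independent isotropic Gaussian
#' displacement (standard deviation `sigma` per coordinate, in A) on every
#' atom — a noise model for an NMR-style conformer ensemble.
#'
#' @param model a `structure_model`.
#' @param n_models number of models (>= 1).
#' @param sigma per-coordinate displacement standard deviation in A (>= 0).
#' @param seed integer seed.
#' @return a [structure_bundle()].
#' @export
perturb_bundle <- function(model, n_models, sigma, seed = 1L) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (!is.numeric(n_models) || n_models < 1) stop("n_models must be >= 1")
  n_models <- as.integer(n_models)
  xyz <- coords(model)
  models <- with_rng(seed, lapply(seq_len(n_models), function(k) {
    noise <- matrix(stats::rnorm(length(xyz), sd = sigma), nrow(xyz), 3L)
    set_coords(model, xyz + noise)
  }))
  structure_bundle(models)
}

#' Synthetic chemical-shift table for a model
#'
#' Draws one shift per C/N atom from packaged per-atom-type mean/sd ranges
#' (typical solution values; realistic overlap without external downloads).
#' A fraction of residues can be made degenerate: their CA and CB shifts are
#' copied from a distant donor residue, emulating the chemical-shift overlap
#' that makes cross-peak assignment ambiguous.
#'
#' Residues close in sequence are kept resolvable: their carbon shifts are
#' forced at least `min_separation` ppm apart (rejection sampling within the
#' type distribution).  Accidental degeneracy between sequence-DISTANT
#' residues is retained — those collisions are what the homolog distance
#' filter resolves downstream, as in a real assignment workflow.
#'
#' @param model a `structure_model`.
#' @param seed integer seed.
#' @param degeneracy fraction of residues (0-0.5) given duplicated CA/CB
#'   shifts (donors at least 25 residues away).
#' @param min_separation minimum carbon shift spacing (ppm) enforced among
#'   residues within `window` of each other in sequence; should exceed
#'   twice the matching tolerance (default 0.45).
#' @param window sequence-separation window for the spacing constraint
#'   (default 14 residues).
#' @return a `shift_table` (see [shift_table()]); attribute
#'   `"degenerate_pairs"` records (acceptor, donor) residue pairs.
#' @export
synthetic_shift_table <- function(model, seed = 1L, degeneracy = 0,
                                  min_separation = 0.45, window = 14L) {
  stopifnot(inherits(model, "structure_model"), degeneracy >= 0, degeneracy <= 0.5)
  ref <- mean_shift_ranges()
  a <- model$atoms[model$atoms$element %in% c("C", "N"), , drop = FALSE]
  key <- match(paste(a$restype, a$atom), paste(ref$restype, ref$atom))
  generic <- match(paste("*", a$atom), paste(ref$restype, ref$atom))
  key[is.na(key)] <- generic[is.na(key)]
  if (anyNA(key)) stop("no packaged shift range for atom(s): ",
                       paste(unique(a$atom[is.na(key)]), collapse = ", "))
  tab <- with_rng(seed, {
    shift <- numeric(nrow(a))
    is_c <- a$element == "C"
    # nitrogen shifts: plain draws (NC matching uses its own tolerance and
    # nitrogen count per residue is 1, so collisions are residue-level only)
    shift[!is_c] <- stats::rnorm(sum(!is_c), mean = ref$mean[key[!is_c]],
                                 sd = ref$sd[key[!is_c]])
    # carbon shifts: sequential draw with local spacing constraint
    cidx <- which(is_c)
    placed_res <- a$resid[cidx]
    placed <- rep(NA_real_, length(cidx))
    for (k in seq_along(cidx)) {
      mu <- ref$mean[key[cidx[k]]]; sdv <- ref$sd[key[cidx[k]]]
      near <- which(!is.na(placed) &
                    abs(placed_res - placed_res[k]) <= window)
      ok <- FALSE
      for (try in seq_len(200L)) {
        cand <- stats::rnorm(1L, mu, sdv)
        if (!length(near) || min(abs(placed[near] - cand)) >= min_separation) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        # deterministic fallback: widest feasible slot in mean +/- 4 sd
        grid <- seq(mu - 4 * sdv, mu + 4 * sdv, by = min_separation / 4)
        gap <- vapply(grid, function(g)
          min(abs(placed[near] - g)), numeric(1L))
        cand <- grid[which.max(gap)]
        if (max(gap) < min_separation)
          warning("could not fully separate shifts near residue ",
                  placed_res[k])
      }
      placed[k] <- cand
    }
    shift[cidx] <- placed
    st <- data.frame(resid = a$resid, restype = a$restype, atom = a$atom,
                     element = a$element, shift = shift,
                     stringsAsFactors = FALSE)
    pairs <- NULL
    n_res <- length(unique(a$resid))
    k <- floor(degeneracy * n_res)
    if (k > 0L) {
      resids <- sort(unique(a$resid))
      ok <- FALSE; tries <- 0L
      while (!ok && tries < 100L) {
        acceptors <- sample(resids, k)
        donors <- vapply(acceptors, function(r) {
          far <- setdiff(resids[abs(resids - r) >= 25L], acceptors)
          if (!length(far)) NA_integer_ else sample(far, 1L)
        }, integer(1L))
        ok <- !anyNA(donors); tries <- tries + 1L
      }
      if (!ok) stop("could not place degenerate pairs; lower degeneracy")
      for (j in seq_len(k)) {
        for (at in c("CA", "CB")) {
          src <- which(st$resid == donors[j] & st$atom == at)
          dst <- which(st$resid == acceptors[j] & st$atom == at)
          if (length(src) && length(dst)) st$shift[dst] <- st$shift[src]
        }
      }
      pairs <- data.frame(acceptor = acceptors, donor = donors)
    }
    attr(st, "degenerate_pairs") <- pairs
    st
  })
  shift_table(tab, keep_attrs = TRUE)
}

# Packaged mean/sd shift ranges per (restype, atom); "*" rows are fallbacks.
mean_shift_ranges <- function() {
  path <- system.file("extdata", "mean_shifts.tsv", package = "masnmr")
  if (path == "") path <- file.path("inst", "extdata", "mean_shifts.tsv")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Covalently bonded carbon pairs within the synthetic topology
# (CA-CB and CA-C of the same residue).
is_bonded_pair <- function(a, idx1, idx2) {
  same <- a$resid[idx1] == a$resid[idx2]
  p <- paste(pmin(a$atom[idx1], a$atom[idx2]), pmax(a$atom[idx1], a$atom[idx2]))
  same & p %in% c("CA CB", "C CA")
}

#' Simulate a cross-peak list from a structure
#'
#' Emits one peak per ordered pair of observable carbon atoms (per the
#' labeling scheme) whose model distance is at most `r_max` — emulating a
#' dipolar-recoupling CC spectrum, where detectable distances are bounded by
#' the mixing condition.  Peak coordinates are the true shifts plus Gaussian
#' noise.  The returned truth map links every peak to its generating atom
#' pair, which is what recovery tests score against.
#'
#' @param model a `structure_model`.
#' @param shifts a `shift_table` covering every observable atom.
#' @param scheme a `labeling_scheme`.
#' @param r_max distance cutoff in A (> 0).
#' @param shift_noise ppm standard deviation added per dimension.
#' @param seed integer seed.
#' @param experiment experiment tag stored on peaks (default `"CORD"`).
#' @param mixing_ms mixing time metadata.
#' @param exclude_bonded drop covalently bonded pairs (CA-CB, CA-C).
#' @return list with `peaks` (a `peak_list`) and `truth` (data frame
#'   `peak_id`, `res_a`, `atom_a`, `res_b`, `atom_b`, `distance`).
#' @export
simulate_peaklist <- function(model, shifts, scheme, r_max, shift_noise = 0,
                              seed = 1L, experiment = "CORD", mixing_ms = 50,
                              exclude_bonded = FALSE) {
  stopifnot(inherits(model, "structure_model"), r_max > 0)
  a <- model$atoms
  carbons <- which(a$element == "C")
  obs <- carbons[vapply(carbons, function(i) {
    label_fraction(scheme, a$restype[i], a$atom[i]) >= scheme$threshold
  }, logical(1L))]
  # every observable atom must have a shift
  skey <- paste(shifts$resid, shifts$atom)
  akey <- paste(a$resid, a$atom)
  missing <- setdiff(akey[obs], skey)
  if (length(missing)) stop("shift table is missing atom(s): ",
                            paste(missing, collapse = ", "))
  shift_of <- shifts$shift[match(akey, skey)]

  xyz <- coords(model)
  if (length(obs) < 2L) {
    peaks <- empty_peak_list()
    return(list(peaks = peaks, truth = empty_truth()))
  }
  d <- as.matrix(stats::dist(xyz[obs, , drop = FALSE]))
  idx <- which(d <= r_max & upper.tri(d), arr.ind = TRUE)
  i1 <- obs[idx[, 1L]]; i2 <- obs[idx[, 2L]]
  if (exclude_bonded && length(i1)) {
    keep <- !is_bonded_pair(a, i1, i2)
    i1 <- i1[keep]; i2 <- i2[keep]
  }
  # ordered pairs: both (a,b) and (b,a), as in a 2-D spectrum's two halves
  from <- c(i1, i2); to <- c(i2, i1)
  n <- length(from)
  if (n == 0L) return(list(peaks = empty_peak_list(), truth = empty_truth()))
  w <- with_rng(seed, {
    cbind(shift_of[from] + stats::rnorm(n, sd = shift_noise),
          shift_of[to] + stats::rnorm(n, sd = shift_noise))
  })
  peaks <- peak_list(data.frame(
    peak_id = seq_len(n), w1 = w[, 1L], w2 = w[, 2L],
    experiment = experiment, mixing_ms = mixing_ms, intensity = 1,
    stringsAsFactors = FALSE))
  truth <- data.frame(
    peak_id = seq_len(n),
    res_a = a$resid[from], atom_a = a$atom[from],
    res_b = a$resid[to], atom_b = a$atom[to],
    distance = sqrt(rowSums((xyz[from, , drop = FALSE] -
                             xyz[to, , drop = FALSE])^2)),
    stringsAsFactors = FALSE)
  list(peaks = peaks, truth = truth)
}

empty_peak_list <- function() {
  peak_list(data.frame(peak_id = integer(0), w1 = numeric(0), w2 = numeric(0),
                       experiment = character(0), mixing_ms = numeric(0),
                       intensity = numeric(0), stringsAsFactors = FALSE))
}

empty_truth <- function() {
  data.frame(peak_id = integer(0), res_a = integer(0), atom_a = character(0),
             res_b = integer(0), atom_b = character(0), distance = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate a trajectory ensemble with scheduled contacts
#'
#' Produces `n_sims` independent frame sequences over the model's topology.
#' Per-frame coordinates are the reference plus iid Gaussian noise
#' (`fluct_sigma` per coordinate); residue pairs listed in the schedule are
#' translated into contact (sidechain minimum distance set to `contact_dist`)
#' on their scheduled frames and pushed apart (to `apart_dist`) otherwise, so
#' downstream contact occupancy equals the scheduled fraction exactly.
#'
#' @param model a `structure_model` (reference topology and coordinates).
#' @param n_sims number of independent simulations (>= 1).
#' @param n_frames frames per simulation (>= 2).
#' @param fluct_sigma per-coordinate noise sd in A.
#' @param contact_schedule data frame with columns `sim` (NA = every
#'   simulation), `res_a`, `res_b`, `from`, `to` (inclusive frame range in
#'   contact); `NULL` for none.
#' @param seed integer seed.
#' @param contact_dist sidechain distance imposed on in-contact frames (A).
#' @param apart_dist sidechain distance imposed on out-of-contact frames (A).
#' @return a `trajectory_ensemble`: list with `topology`, `sims` (list of
#'   `n_atoms x 3 x n_frames` arrays) and `dt` (frame interval, arbitrary
#'   units).
#' @export
simulate_trajectory_ensemble <- function(model, n_sims, n_frames, fluct_sigma,
                                         contact_schedule = NULL, seed = 1L,
                                         contact_dist = 3.0, apart_dist = 8.0,
                                         dt = 1) {
  stopifnot(inherits(model, "structure_model"))
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (n_frames < 2) stop("n_frames must be >= 2")
  n_sims <- as.integer(n_sims); n_frames <- as.integer(n_frames)
  a <- model$atoms
  if (!is.null(contact_schedule)) {
    need <- c("res_a", "res_b", "from", "to")
    stopifnot(all(need %in% names(contact_schedule)))
    if (is.null(contact_schedule$sim)) contact_schedule$sim <- NA_integer_
    absent <- setdiff(unique(c(contact_schedule$res_a, contact_schedule$res_b)),
                      a$resid)
    if (length(absent)) stop("schedule references absent residue(s): ",
                             paste(absent, collapse = ", "))
  }
  xyz0 <- coords(model)
  sc_idx <- function(resid) {
    i <- which(a$resid == resid & a$atom == "CB")
    if (!length(i)) i <- which(a$resid == resid & a$atom == "CA")
    i[1L]
  }
  sims <- with_rng(seed, lapply(seq_len(n_sims), function(s) {
    arr <- array(NA_real_, c(nrow(xyz0), 3L, n_frames))
    sched <- if (is.null(contact_schedule)) NULL else
      contact_schedule[is.na(contact_schedule$sim) | contact_schedule$sim == s, ,
                       drop = FALSE]
    for (f in seq_len(n_frames)) {
      fr <- xyz0 + matrix(stats::rnorm(length(xyz0), sd = fluct_sigma),
                          nrow(xyz0), 3L)
      if (!is.null(sched) && nrow(sched)) {
        for (r in seq_len(nrow(sched))) {
          ia <- sc_idx(sched$res_a[r]); ib <- sc_idx(sched$res_b[r])
          in_contact <- f >= sched$from[r] & f <= sched$to[r]
          target <- if (in_contact) contact_dist else apart_dist
          dir <- fr[ib, ] - fr[ia, ]
          if (vnorm(dir) < 1e-9) dir <- c(1, 0, 0)
          new_b <- fr[ia, ] + unit(dir) * target
          shift <- new_b - fr[ib, ]
          atoms_b <- which(a$resid == sched$res_b[r])
          fr[atoms_b, ] <- sweep(fr[atoms_b, , drop = FALSE], 2L, shift, `+`)
        }
      }
      arr[, , f] <- fr
    }
    arr
  }))
  structure(list(topology = model, sims = sims, dt = dt),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d simulation(s) x %d frames, %d atoms\n",
              length(x$sims), dim(x$sims[[1L]])[3L], dim(x$sims[[1L]])[1L]))
  invisible(x)
}

#' Simulate a two-state Markov series
#'
#' Symmetric two-state chain on {-1, +1} with per-step flip probability
#' `p_flip`, emitting the state plus small Gaussian noise.  The lag-1
#' autocorrelation of the state sequence is 1 - 2 p_flip, which is the
#' analytic leading eigenvalue a slow-mode analysis should recover.
#'
#' @param p_flip flip probability per step, in (0, 0.5).
#' @param n_steps series length.
#' @param seed integer seed.
#' @param noise_sd emission noise sd (default 0.05).
#' @return list with `series` (numeric) and `states` (integer, the truth).
#' @export
simulate_two_state_series <- function(p_flip, n_steps, seed = 1L,
                                      noise_sd = 0.05) {
  if (!is.numeric(p_flip) || p_flip <= 0 || p_flip >= 0.5)
    stop("p_flip must be in (0, 0.5)")
  stopifnot(n_steps >= 2)
  with_rng(seed, {
    flips <- stats::runif(n_steps - 1L) < p_flip
    states <- integer(n_steps)
    states[1L] <- sample(c(-1L, 1L), 1L)
    for (t in 2L:n_steps) states[t] <- if (flips[t - 1L]) -states[t - 1L] else states[t - 1L]
    list(series = states + stats::rnorm(n_steps, sd = noise_sd),
         states = states)
  })
}
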