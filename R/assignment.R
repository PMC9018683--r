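# Cross-peak to distance-restraint assignment.
#
# Pipeline per peak: shift matching within tolerance and labeling filter
# (match_candidates) -> three unambiguity criteria applied in fixed order
# (resolve_unambiguity): an intra-residue possibility, a sequential
# possibility, or corroboration by other peaks of the same spin system ->
# homolog distance filter for peaks still ambiguous (candidates farther than
# a cutoff in a homolog structure are discarded) -> ambiguity cap (peaks with
# more than max_candidates surviving possibilities contribute no restraint).
#
# Matching is performed for the whole peak list at once (a single vectorized
# candidate table) so that lists of 10^4 peaks assign in seconds.

#' Assignment configuration
#'
#' @param tol_C 13C matching tolerance in ppm (> 0).
#' @param tol_N 15N matching tolerance in ppm (> 0).
#' @param homolog_cutoff discard candidates farther than this in the homolog
#'   structure, in A (default 9).
#' @param max_candidates ambiguity cap: a peak with more surviving
#'   possibilities contributes no restraint ("fewer than 4" = at most 3).
#' @param region residue range (integer vector) for [refilter_region()].
#' @param spin_system_min minimum number of corroborating peaks (default 2).
#' @param dev_margin shift-deviation dominance margin in ppm: after the
#'   distance filter, the closest-matching candidate is accepted as
#'   unambiguous when the runner-up deviates by more than this margin
#'   beyond it (0 disables the rule; default 0.05, a quarter of `tol_C`).
#' @return an object of class `assignment_config`.
#' @export
assignment_config <- function(tol_C = 0.2, tol_N = 0.3, homolog_cutoff = 9,
                              max_candidates = 3L, region = NULL,
                              spin_system_min = 2L, dev_margin = 0.05) {
  stopifnot(tol_C > 0, tol_N > 0, homolog_cutoff > 0, max_candidates >= 1,
            dev_margin >= 0)
  structure(list(tol_C = tol_C, tol_N = tol_N,
                 homolog_cutoff = homolog_cutoff,
                 max_candidates = as.integer(max_candidates), region = region,
                 spin_system_min = as.integer(spin_system_min),
                 dev_margin = dev_margin),
            class = "assignment_config")
}

# Per-shift-row label fractions, computed once (lookups are cached over the
# unique (restype, atom) pairs).
shift_label_fractions <- function(shifts, scheme) {
  key <- paste(shifts$restype, shifts$atom)
  uk <- unique(key)
  uf <- vapply(uk, function(k) {
    parts <- strsplit(k, " ", fixed = TRUE)[[1L]]
    label_fraction(scheme, parts[1L], parts[2L])
  }, numeric(1L))
  uf[match(key, uk)]
}

# Global candidate table for a whole peak list: one row per (peak, atom-pair)
# candidate.  Columns are plain atomic vectors for speed.
build_candidate_table <- function(peaks, shifts, scheme, cfg) {
  if (nrow(shifts) == 0L) stop("shift table is empty")
  exp_tag <- toupper(peaks$experiment)
  het <- exp_tag %in% c("PAIN-CP", "PAINCP", "NCACX", "NCOCX")
  frac <- shift_label_fractions(shifts, scheme)
  obs_c <- shifts$element == "C" & frac >= scheme$threshold
  obs_n <- shifts$element == "N" & scheme$nitrogen_labeled

  match_dim <- function(w, nucleus) {
    # rows of `shifts` (restricted to the nucleus) within tolerance of each w
    ok <- if (nucleus == "N") obs_n else obs_c
    rows <- which(ok)
    s <- shifts$shift[rows]
    ord <- order(s)
    rows <- rows[ord]; s <- s[ord]
    tol <- if (nucleus == "N") cfg$tol_N else cfg$tol_C
    lo <- findInterval(w - tol, s) + 1L
    hi <- findInterval(w + tol, s)
    list(rows = rows, lo = lo, hi = hi, n = pmax(hi - lo + 1L, 0L))
  }

  pieces <- list()
  for (h in unique(het)) {
    idx <- which(het == h)
    d1 <- match_dim(peaks$w1[idx], if (h) "N" else "C")
    d2 <- match_dim(peaks$w2[idx], "C")
    n1 <- d1$n; n2 <- d2$n
    npair <- n1 * n2
    if (!sum(npair)) next
    peak_of <- rep.int(idx, npair)
    # enumerate (i in d1 window) x (j in d2 window) per peak
    i_idx <- unlist(lapply(seq_along(idx), function(p) {
      if (npair[p] == 0L) return(integer(0))
      rep(d1$rows[seq(d1$lo[p], d1$hi[p])], each = n2[p])
    }), use.names = FALSE)
    j_idx <- unlist(lapply(seq_along(idx), function(p) {
      if (npair[p] == 0L) return(integer(0))
      rep.int(d2$rows[seq(d2$lo[p], d2$hi[p])], n1[p])
    }), use.names = FALSE)
    pieces[[length(pieces) + 1L]] <-
      list(peak = peak_of, i = i_idx, j = j_idx)
  }
  if (!length(pieces))
    return(data.frame(peak = integer(0), i = integer(0), j = integer(0)))
  cand <- data.frame(peak = unlist(lapply(pieces, `[[`, "peak")),
                     i = unlist(lapply(pieces, `[[`, "i")),
                     j = unlist(lapply(pieces, `[[`, "j")))
  cand <- cand[cand$i != cand$j, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  # deviation, flags
  w1 <- peaks$w1[cand$peak]; w2 <- peaks$w2[cand$peak]
  cand$dev <- abs(shifts$shift[cand$i] - w1) + abs(shifts$shift[cand$j] - w2)
  cand$res_a <- shifts$resid[cand$i]; cand$atom_a <- shifts$atom[cand$i]
  cand$res_b <- shifts$resid[cand$j]; cand$atom_b <- shifts$atom[cand$j]
  cand$intra <- cand$res_a == cand$res_b
  cand$sequential <- abs(cand$res_a - cand$res_b) == 1L
  # drop duplicate unordered pairs within a peak (CC matching is symmetric)
  ka <- paste(cand$res_a, cand$atom_a); kb <- paste(cand$res_b, cand$atom_b)
  key <- paste(cand$peak, pmin(ka, kb), pmax(ka, kb))
  cand <- cand[!duplicated(key), , drop = FALSE]
  cand[order(cand$peak, cand$dev), , drop = FALSE]
}

# Vectorized homolog distances for a candidate table: NA where either atom is
# absent from the homolog.
homolog_distances <- function(cand, homolog, residue_map = NULL) {
  a <- homolog$atoms
  map_res <- function(r) {
    if (is.null(residue_map)) return(r)
    residue_map$to[match(r, residue_map$from)]
  }
  hkey <- paste(a$resid, a$atom)
  ia <- match(paste(map_res(cand$res_a), cand$atom_a), hkey)
  ib <- match(paste(map_res(cand$res_b), cand$atom_b), hkey)
  d <- rep(NA_real_, nrow(cand))
  ok <- !is.na(ia) & !is.na(ib)
  d[ok] <- sqrt((a$x[ia[ok]] - a$x[ib[ok]])^2 +
                (a$y[ia[ok]] - a$y[ib[ok]])^2 +
                (a$z[ia[ok]] - a$z[ib[ok]])^2)
  d
}

candidate_frame <- function(cand) {
  if (!nrow(cand)) return(empty_candidates())
  out <- data.frame(res_a = cand$res_a, atom_a = cand$atom_a,
                    res_b = cand$res_b, atom_b = cand$atom_b,
                    dev = cand$dev, intra = cand$intra,
                    sequential = cand$sequential,
                    homolog_distance = cand$homolog_distance %||% NA_real_,
                    unfilterable = cand$unfilterable %||% FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(res_a = integer(0), atom_a = character(0), res_b = integer(0),
             atom_b = character(0), dev = numeric(0), intra = logical(0),
             sequential = logical(0), homolog_distance = numeric(0),
             unfilterable = logical(0), stringsAsFactors = FALSE)
}

#' Candidate assignments for one cross peak
#'
#' All atom pairs whose shifts match each dimension within tolerance and
#' that can produce an observable correlation under the labeling scheme,
#' sorted by total shift deviation.  CC peaks match carbon shifts on both
#' dimensions; PAIN-CP/NCACX/NCOCX peaks match nitrogen on dimension 1.
#'
#' @param peak one-row `peak_list` slice (or list with `w1`, `w2`,
#'   `experiment`).
#' @param shifts a `shift_table`.
#' @param scheme a `labeling_scheme`.
#' @param cfg an `assignment_config`.
#' @return candidate data frame (possibly empty): `res_a`, `atom_a`,
#'   `res_b`, `atom_b`, `dev`, `intra`, `sequential`, `homolog_distance`
#'   (NA until filtered), `unfilterable`.
#' @export
match_candidates <- function(peak, shifts, scheme, cfg = assignment_config()) {
  pk <- data.frame(peak_id = 1L, w1 = peak$w1, w2 = peak$w2,
                   experiment = peak$experiment %||% "CORD",
                   stringsAsFactors = FALSE)
  cand <- build_candidate_table(pk, shifts, scheme, cfg)
  candidate_frame(cand)
}

#' Apply the unambiguity criteria to a candidate list
#'
#' The three criteria, in order: (1) exactly one possibility is an
#' intra-residue correlation; (2) exactly one possibility is a sequential
#' correlation; (3) exactly one possibility is corroborated by other peaks
#' of the same spin system in the same spectrum.  A single surviving
#' candidate is unambiguous outright.  If two applicable criteria select
#' different candidates the peak is demoted to ambiguous (conflict rule).
#'
#' @param candidates candidate data frame from [match_candidates()].
#' @param corroboration optional logical vector marking spin-system
#'   corroborated candidates (supplied by [assign_peaklist()]).
#' @return list with `status` ("unambiguous", "ambiguous", "unassigned"),
#'   `selected` (one-row candidate data frame or NULL), `candidates`, and
#'   `criterion` (which rule fired).
#' @export
resolve_unambiguity <- function(candidates, corroboration = NULL) {
  n <- nrow(candidates)
  if (n == 0L)
    return(list(status = "unassigned", selected = NULL,
                candidates = candidates, criterion = "no_match"))
  if (n == 1L)
    return(list(status = "unambiguous", selected = candidates,
                candidates = candidates, criterion = "unique_match"))
  picks <- list()
  if (sum(candidates$intra) == 1L) picks$intra <- which(candidates$intra)
  if (sum(candidates$sequential) == 1L)
    picks$sequential <- which(candidates$sequential)
  if (!is.null(corroboration) && sum(corroboration) == 1L)
    picks$spin_system <- which(corroboration)
  if (!length(picks))
    return(list(status = "ambiguous", selected = NULL,
                candidates = candidates, criterion = "none"))
  sel <- unique(unlist(picks))
  if (length(sel) > 1L)  # conflicting criteria: demote
    return(list(status = "ambiguous", selected = NULL,
                candidates = candidates, criterion = "conflict"))
  list(status = "unambiguous", selected = candidates[sel, , drop = FALSE],
       candidates = candidates, criterion = names(picks)[1L])
}

#' Distance-filter candidates against a homolog structure
#'
#' Candidates whose atom-pair distance in the homolog exceeds the cutoff are
#' discarded; distances are recorded on survivors.  Candidates whose atoms
#' are absent from the homolog are kept and flagged `unfilterable`
#' (conservative: absence of evidence removes nothing).
#'
#' @param candidates candidate data frame.
#' @param homolog a `structure_model` sharing residue numbering (or mapped
#'   through `residue_map`).
#' @param cfg an `assignment_config` (uses `homolog_cutoff`).
#' @param residue_map optional data frame `from`, `to` mapping candidate
#'   residue numbers to homolog numbering (default identity).
#' @return filtered candidate data frame with `homolog_distance` filled in.
#' @export
homolog_distance_filter <- function(candidates, homolog,
                                    cfg = assignment_config(),
                                    residue_map = NULL) {
  if (!nrow(candidates)) return(candidates)
  d <- homolog_distances(candidates, homolog, residue_map)
  candidates$homolog_distance <- d
  candidates$unfilterable <- is.na(d)
  candidates[is.na(d) | d <= cfg$homolog_cutoff, , drop = FALSE]
}

# Spin-system corroboration keys: unordered residue pair per candidate.
candidate_respair_keys <- function(cands) {
  if (!nrow(cands)) return(character(0))
  paste(pmin(cands$res_a, cands$res_b), pmax(cands$res_a, cands$res_b))
}

#' Assign a peak list to a restraint set
#'
#' Orchestrates matching, unambiguity resolution, homolog distance
#' filtering and the ambiguity cap over a whole peak list, and converts the
#' survivors to distance restraints with provenance back-links.
#'
#' @param peaks a `peak_list`.
#' @param shifts a `shift_table`.
#' @param scheme a `labeling_scheme`.
#' @param homolog optional `structure_model` for the distance filter.
#' @param cfg an `assignment_config`.
#' @param residue_map optional homolog numbering map (see
#'   [homolog_distance_filter()]).
#' @return a [restraint_set()] with attributes `"log"` (per-peak decision
#'   data frame: `peak_id`, `status`, `criterion`, `n_candidates`) and
#'   `"discarded"` (peaks contributing no restraint, with reasons).
#' @export
assign_peaklist <- function(peaks, shifts, scheme, homolog = NULL,
                            cfg = assignment_config(), residue_map = NULL) {
  n <- nrow(peaks)
  cand <- build_candidate_table(peaks, shifts, scheme, cfg)
  hom_d <- if (!is.null(homolog) && nrow(cand))
    homolog_distances(cand, homolog, residue_map) else
    rep(NA_real_, nrow(cand))

  # spin-system corroboration: count, per spectrum, how many peaks carry
  # each unordered residue pair among their candidates
  spectrum <- paste(peaks$experiment, peaks$mixing_ms)
  corro <- logical(nrow(cand))
  if (nrow(cand)) {
    rp <- candidate_respair_keys(cand)
    sp <- spectrum[cand$peak]
    peak_pair <- !duplicated(paste(cand$peak, rp))  # count each peak once
    cnt <- table(paste(sp, rp)[peak_pair])
    corro <- as.integer(cnt[paste(sp, rp)]) - 1L >= cfg$spin_system_min
    corro[is.na(corro)] <- FALSE
  }

  # atomic vectors for the resolution loop
  by_peak <- split(seq_len(nrow(cand)), factor(cand$peak, levels = seq_len(n)))
  v_intra <- cand$intra; v_seq <- cand$sequential; v_dev <- cand$dev
  v_resa <- cand$res_a; v_resb <- cand$res_b
  keep_rows <- integer(0); keep_rid <- integer(0); keep_amb <- logical(0)
  status <- character(n); criterion <- character(n); n_surv <- integer(n)
  rid <- 0L
  for (p in seq_len(n)) {
    rows <- by_peak[[p]]
    m <- length(rows)
    if (m == 0L) {
      status[p] <- "unassigned"; criterion[p] <- "no_match"; n_surv[p] <- 0L
      next
    }
    sel <- NA_integer_; crit <- "none"
    if (m == 1L) {
      sel <- rows; crit <- "unique_match"
    } else {
      picks <- integer(0); names_p <- character(0)
      ii <- rows[v_intra[rows]]
      if (length(ii) == 1L) { picks <- c(picks, ii); names_p <- c(names_p, "intra") }
      ss <- rows[v_seq[rows]]
      if (length(ss) == 1L) { picks <- c(picks, ss); names_p <- c(names_p, "sequential") }
      cc <- rows[corro[rows]]
      if (length(cc) == 1L) { picks <- c(picks, cc); names_p <- c(names_p, "spin_system") }
      u <- unique(picks)
      if (length(u) == 1L) { sel <- u; crit <- names_p[1L] }
      else if (length(u) > 1L) crit <- "conflict"
    }
    if (!is.na(sel)) {
      status[p] <- "unambiguous"; criterion[p] <- crit; n_surv[p] <- 1L
      rid <- rid + 1L
      keep_rows <- c(keep_rows, sel); keep_rid <- c(keep_rid, rid)
      keep_amb <- c(keep_amb, FALSE)
      next
    }
    # distance-filter approach for peaks the criteria leave ambiguous
    surv <- rows
    if (!is.null(homolog)) {
      d <- hom_d[rows]
      surv <- rows[is.na(d) | d <= cfg$homolog_cutoff]
      crit <- if (length(surv) == 1L) "distance_filter"
              else if (length(surv) == 0L) "distance_filter_empty"
              else if (crit == "conflict") "conflict"
              else "distance_filter_ambiguous"
    }
    # shift-deviation dominance: the closest candidate wins when the
    # runner-up is worse by more than the margin (exact at zero noise,
    # where the true candidate's deviation is identically 0)
    if (length(surv) > 1L && cfg$dev_margin > 0) {
      dv <- sort(v_dev[surv])
      if (dv[2L] - dv[1L] > cfg$dev_margin) {
        surv <- surv[which.min(v_dev[surv])]
        crit <- "deviation_dominance"
      }
    }
    n_surv[p] <- length(surv)
    criterion[p] <- crit
    if (length(surv) == 0L) { status[p] <- "unassigned"; next }
    if (length(surv) == 1L) {
      status[p] <- "unambiguous"
      rid <- rid + 1L
      keep_rows <- c(keep_rows, surv); keep_rid <- c(keep_rid, rid)
      keep_amb <- c(keep_amb, FALSE)
      next
    }
    if (length(surv) > cfg$max_candidates) { status[p] <- "discarded_cap"; next }
    status[p] <- "ambiguous"
    rid <- rid + 1L
    keep_rows <- c(keep_rows, surv)
    keep_rid <- c(keep_rid, rep.int(rid, length(surv)))
    keep_amb <- c(keep_amb, rep(TRUE, length(surv)))
  }

  if (length(keep_rows)) {
    kind_intra <- tapply(v_intra[keep_rows], keep_rid, all)
    b_intra <- to_bounds("intra"); b_inter <- to_bounds("inter")
    is_intra <- kind_intra[as.character(keep_rid)]
    df <- data.frame(
      restraint_id = keep_rid,
      member = stats::ave(keep_rid, keep_rid, FUN = seq_along),
      res_a = v_resa[keep_rows], atom_a = cand$atom_a[keep_rows],
      res_b = v_resb[keep_rows], atom_b = cand$atom_b[keep_rows],
      lower = ifelse(is_intra, b_intra[1L], b_inter[1L]),
      upper = ifelse(is_intra, b_intra[2L], b_inter[2L]),
      ambiguous = keep_amb,
      experiment = peaks$experiment[cand$peak[keep_rows]],
      peak_id = peaks$peak_id[cand$peak[keep_rows]],
      stringsAsFactors = FALSE)
    df$sep <- abs(df$res_a - df$res_b)
    df$category <- classify_separation(df$sep)
    out <- restraint_set(df)
  } else out <- restraint_set()

  log <- data.frame(peak_id = peaks$peak_id, status = status,
                    criterion = criterion, n_candidates = n_surv,
                    stringsAsFactors = FALSE)
  attr(out, "log") <- log
  attr(out, "discarded") <- log[!log$status %in% c("unambiguous", "ambiguous"),
                                , drop = FALSE]
  out
}

#' Re-inspect restraints in a residue region against a new structure
#'
#' After an initial structure calculation the distance filter can be re-run
#' against the new coordinates for a stated residue region (e.g. the region
#' near a rearranged helix), so that no restraint was erroneously discarded
#' or retained on the basis of the homolog.  Changes are PROPOSED in the
#' returned report, never silently applied.
#'
#' @param rset a `restraint_set`.
#' @param new_structure a `structure_model`.
#' @param region integer vector of residue indices.
#' @param cfg an `assignment_config`.
#' @return list with `restraints` (unchanged input) and `report` (data
#'   frame: `restraint_id`, `res_a`, `res_b`, `distance`, `action` of
#'   "keep"/"remove"/"unfilterable").  Empty region: no-op with a warning.
#' @export
refilter_region <- function(rset, new_structure, region,
                            cfg = assignment_config()) {
  if (!length(region)) {
    warning("empty region: nothing to re-inspect")
    return(list(restraints = rset,
                report = data.frame(restraint_id = integer(0))))
  }
  touch <- rset$res_a %in% region | rset$res_b %in% region
  sub <- rset[touch, , drop = FALSE]
  if (!nrow(sub)) {
    return(list(restraints = rset, report = data.frame(
      restraint_id = integer(0), res_a = integer(0), res_b = integer(0),
      distance = numeric(0), action = character(0))))
  }
  d <- homolog_distances(sub, new_structure)
  report <- data.frame(
    restraint_id = sub$restraint_id, res_a = sub$res_a, res_b = sub$res_b,
    distance = d,
    action = ifelse(is.na(d), "unfilterable",
                    ifelse(d > cfg$homolog_cutoff, "remove", "keep")),
    stringsAsFactors = FALSE)
  list(restraints = rset, report = report)
}
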