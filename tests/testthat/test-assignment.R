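# Peak -> restraint assignment: matching, unambiguity criteria, distance
# filter, ambiguity cap, and end-to-end recovery on synthetic truth.

mini_shifts <- function() {
  # 4 residues; residues 1 and 3 share an engineered CA shift
  shift_table(data.frame(
    resid = c(1, 1, 2, 2, 3, 3, 4, 4),
    restype = c("ALA", "ALA", "SER", "SER", "LEU", "LEU", "GLU", "GLU"),
    atom = rep(c("CA", "CB"), 4),
    element = "C",
    shift = c(53.0, 19.0, 58.7, 63.8, 53.0, 42.3, 57.4, 30.0)))
}

test_that("match_candidates finds pairs within tolerance and sorts by deviation", {
  sh <- mini_shifts()
  sc <- fix_scheme_u()
  # unique pair at exact shifts
  cand <- match_candidates(list(w1 = 19.0, w2 = 63.8, experiment = "CORD"), sh, sc)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$res_a, 1); expect_equal(cand$res_b, 2)
  # degenerate CA (residues 1 and 3) gives two candidates, deviations recorded
  cand2 <- match_candidates(list(w1 = 53.05, w2 = 63.8, experiment = "CORD"), sh, sc)
  expect_equal(nrow(cand2), 2)
  expect_setequal(cand2$res_a, c(1, 3))
  expect_true(all(abs(cand2$dev - 0.05) < 1e-9))
  expect_false(is.unsorted(cand2$dev))
  # labeling filter: zero-fraction atom excluded
  sc0 <- labeling_scheme("t", data.frame(
    restype = c("ALA", "*"), atom = c("CA", "*"), fraction = c(0, 1)))
  cand3 <- match_candidates(list(w1 = 53.0, w2 = 63.8, experiment = "CORD"), sh, sc0)
  expect_true(all(cand3$res_a != 1 | cand3$atom_a != "CA"))
  # no match inside tolerance: empty, not an error
  expect_equal(nrow(match_candidates(list(w1 = 100, w2 = 100,
                                          experiment = "CORD"), sh, sc)), 0)
})

test_that("tightening the tolerance never increases candidate counts", {
  m <- fix_helix20()
  sh <- synthetic_shift_table(m, seed = 5)
  sc <- fix_scheme_u()
  sim <- simulate_peaklist(m, sh, sc, r_max = 6.5, shift_noise = 0.05, seed = 2)
  for (p in c(1, 7, 20, 44)) {
    peak <- sim$peaks[p, ]
    wide <- match_candidates(peak, sh, sc, assignment_config(tol_C = 0.3))
    tight <- match_candidates(peak, sh, sc, assignment_config(tol_C = 0.1))
    expect_lte(nrow(tight), nrow(wide))
  }
})

test_that("resolve_unambiguity applies the criteria in order and demotes conflicts", {
  base <- data.frame(dev = c(0.01, 0.02), intra = FALSE, sequential = FALSE,
                     homolog_distance = NA_real_, unfilterable = FALSE)
  # one intra possibility wins
  c1 <- cbind(data.frame(res_a = c(5, 5), atom_a = "CA",
                         res_b = c(5, 14), atom_b = "CB"), base)
  c1$intra <- c(TRUE, FALSE)
  r1 <- resolve_unambiguity(c1)
  expect_equal(r1$status, "unambiguous")
  expect_equal(r1$criterion, "intra")
  expect_equal(r1$selected$res_b, 5)
  # one sequential possibility wins
  c2 <- cbind(data.frame(res_a = c(5, 5), atom_a = "CA",
                         res_b = c(6, 14), atom_b = "CB"), base)
  c2$sequential <- c(TRUE, FALSE)
  r2 <- resolve_unambiguity(c2)
  expect_equal(r2$status, "unambiguous")
  expect_equal(r2$criterion, "sequential")
  expect_equal(r2$selected$res_b, 6)
  # spin-system corroboration singles out a candidate
  c3 <- cbind(data.frame(res_a = c(5, 7), atom_a = "CA",
                         res_b = c(14, 16), atom_b = "CB"), base)
  r3 <- resolve_unambiguity(c3, corroboration = c(TRUE, FALSE))
  expect_equal(r3$status, "unambiguous")
  expect_equal(r3$criterion, "spin_system")
  # conflicting criteria demote to ambiguous
  c4 <- cbind(data.frame(res_a = c(5, 5), atom_a = "CA",
                         res_b = c(5, 6), atom_b = "CB"), base)
  c4$intra <- c(TRUE, FALSE); c4$sequential <- c(FALSE, TRUE)
  r4 <- resolve_unambiguity(c4)
  expect_equal(r4$status, "ambiguous")
  expect_equal(r4$criterion, "conflict")
  # no candidates / single candidate
  expect_equal(resolve_unambiguity(c4[0, ])$status, "unassigned")
  expect_equal(resolve_unambiguity(c4[1, ])$status, "unambiguous")
})

test_that("homolog distance filter discards far pairs and keeps unfilterable ones", {
  m <- fix_helix20()  # CA(i)-CA(i+1) = 3.8, CA(1)-CA(10) >> 9
  cand <- data.frame(
    res_a = c(1, 1, 1), atom_a = "CA",
    res_b = c(2, 10, 21), atom_b = "CA",  # residue 21 absent from homolog
    dev = 0, intra = FALSE, sequential = c(TRUE, FALSE, FALSE),
    homolog_distance = NA_real_, unfilterable = FALSE)
  out <- homolog_distance_filter(cand, m, assignment_config(homolog_cutoff = 9))
  expect_equal(out$res_b, c(2, 21))
  expect_equal(out$homolog_distance[1], 3.8, tolerance = 0.01)
  expect_true(out$unfilterable[2])
  # all candidates far -> empty
  far <- cand[2, , drop = FALSE]
  expect_equal(nrow(homolog_distance_filter(far, m)), 0)
  # residue mapping shifts numbering
  map <- data.frame(from = c(101, 102), to = c(1, 2))
  cand_m <- cand[1, ]; cand_m$res_a <- 101; cand_m$res_b <- 102
  out_m <- homolog_distance_filter(cand_m, m, residue_map = map)
  expect_equal(out_m$homolog_distance, 3.8, tolerance = 0.01)
})

test_that("assign_peaklist caps ambiguity and logs every discarded peak", {
  sh <- shift_table(data.frame(
    resid = 1:6, restype = "ALA", atom = "CA", element = "C",
    shift = c(50, 50, 50, 50, 50, 60)))
  sc <- fix_scheme_u()
  # peak matching five 50-ppm CAs in both dims: >3 surviving pairs -> capped
  peaks <- peak_list(data.frame(peak_id = 1, w1 = 50, w2 = 50,
                                experiment = "CORD"))
  rs <- assign_peaklist(peaks, sh, sc, cfg = assignment_config(dev_margin = 0))
  expect_equal(nrow(rs), 0)
  log <- attr(rs, "log")
  expect_equal(log$status, "discarded_cap")
  expect_gt(log$n_candidates, 3)
  expect_equal(nrow(attr(rs, "discarded")), 1)
  # empty peak list -> empty restraint set
  rs0 <- assign_peaklist(peaks[0, ], sh, sc)
  expect_s3_class(rs0, "restraint_set")
  expect_equal(nrow(rs0), 0)
})

test_that("noise-free synthetic data with resolvable shifts recovers fully", {
  m <- make_helix_model(30, seed = 2)
  sh <- synthetic_shift_table(m, seed = 3)
  sc <- fix_scheme_u()
  sim <- simulate_peaklist(m, sh, sc, r_max = 6.5, shift_noise = 0, seed = 4)
  rs <- assign_peaklist(sim$peaks, sh, sc, homolog = m)
  rec <- oracle_recovery(rs, sim$truth)
  expect_equal(rec$false_unambiguous, 0)
  expect_gte(rec$recovered, 0.95)
  # every restraint traces back to a peak; every peak has a logged outcome
  expect_true(all(rs$peak_id %in% sim$peaks$peak_id))
  expect_equal(nrow(attr(rs, "log")), nrow(sim$peaks))
  # restraint bounds follow the intra/inter conversion
  intra <- as.data.frame(rs)[rs$category == "intra", ]
  inter <- as.data.frame(rs)[rs$category != "intra", ]
  expect_true(all(intra$lower == 1.5 & intra$upper == 6.5))
  expect_true(all(inter$lower == 2.0 & inter$upper == 7.2))
})

test_that("refilter_region proposes changes without applying them", {
  m <- fix_helix20()
  rs <- restraint_set(data.frame(
    restraint_id = 1:3,
    res_a = c(2, 5, 15), atom_a = "CA",
    res_b = c(4, 17, 16), atom_b = "CA",
    lower = 2, upper = 7.2))
  out <- refilter_region(rs, m, region = 2:6)
  # restraint 3 lies outside the region: untouched
  expect_false(3 %in% out$report$restraint_id)
  # (5,17) spans ~18 A in the helix: flagged for removal, not removed
  rep5 <- out$report[out$report$restraint_id == 2, ]
  expect_equal(rep5$action, "remove")
  expect_identical(as.data.frame(out$restraints), as.data.frame(rs))
  # close pair kept
  expect_equal(out$report$action[out$report$restraint_id == 1], "keep")
  # idempotence
  out2 <- refilter_region(rs, m, region = 2:6)
  expect_identical(out$report, out2$report)
  expect_warning(refilter_region(rs, m, region = integer(0)), "empty")
})
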