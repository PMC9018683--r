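# Restraint bookkeeping: classification, bounds, tabulation, per-residue
# counts, violation statistics, and file I/O.

sample_rset <- function() {
  restraint_set(data.frame(
    restraint_id = c(1, 2, 3, 4, 5, 5),
    res_a = c(3, 3, 3, 3, 3, 3), atom_a = "CA",
    res_b = c(3, 4, 6, 10, 8, 9), atom_b = c("CB", "CA", "CA", "CA", "CA", "CA"),
    lower = c(1.5, 2, 2, 2, 2, 2), upper = c(6.5, 7.2, 7.2, 7.2, 7.2, 7.2)))
}

test_that("classify_separation partitions |i-j| per the category table", {
  expect_equal(classify_separation(0), "intra")
  expect_equal(classify_separation(1), "sequential")
  expect_equal(classify_separation(c(2, 3, 4)), rep("medium", 3))
  expect_equal(classify_separation(c(5, 7, 100)), rep("long", 3))
  # the |i-j| = 4 gap is configurable
  expect_equal(classify_separation(4, four_is_medium = FALSE), "long")
  expect_error(classify_separation(-1), "separation")
})

test_that("to_bounds returns the printed conversion constants", {
  expect_equal(to_bounds("intra"), c(1.5, 6.5))
  expect_equal(to_bounds("inter"), c(2.0, 7.2))
  expect_equal(to_bounds("inter", inter = c(1.8, 8)), c(1.8, 8))
  b <- to_bounds("intra")
  expect_lt(b[1], b[2])
  expect_error(to_bounds("sideways"))
})

test_that("tabulate_restraints counts conserve totals", {
  rset <- sample_rset()
  tab <- tabulate_restraints(rset)
  expect_equal(tab$total[tab$category == "total"], 5)
  body <- tab[tab$category != "total", ]
  tot <- tab[tab$category == "total", ]
  expect_equal(colSums(body[, -1]), unlist(tot[, -1]), ignore_attr = TRUE)
  expect_equal(tab$cc_unambiguous[tab$category == "intra"], 1)
  expect_equal(tab$cc_unambiguous[tab$category == "sequential"], 1)
  expect_equal(tab$cc_unambiguous[tab$category == "medium"], 1)
  expect_equal(tab$cc_unambiguous[tab$category == "long"], 1)
  expect_equal(tab$cc_ambiguous[tab$category == "total"], 1)
  # empty set: all-zero table
  tab0 <- tabulate_restraints(restraint_set())
  expect_true(all(tab0$total == 0))
  # NC restraints land in the NC column
  rnc <- restraint_set(data.frame(restraint_id = 1, res_a = 2, atom_a = "N",
                                  res_b = 5, atom_b = "CA",
                                  lower = 2, upper = 7.2))
  expect_equal(tabulate_restraints(rnc)$nc[5], 1)
})

test_that("per_residue_counts increments both partners of unambiguous restraints", {
  rs <- restraint_set(data.frame(restraint_id = 1, res_a = 5, atom_a = "CA",
                                 res_b = 80, atom_b = "CA",
                                 lower = 2, upper = 7.2))
  prc <- per_residue_counts(rs)
  expect_equal(prc$count[prc$resid == 5], 1)
  expect_equal(prc$count[prc$resid == 80], 1)
  expect_equal(sum(prc$count), 2)
  # conservation: totals are twice the unambiguous restraint count
  rset <- sample_rset()
  prc2 <- per_residue_counts(rset)
  n_unamb <- length(unique(rset$restraint_id[!rset$ambiguous]))
  expect_equal(sum(prc2$count), 2 * n_unamb)
  expect_equal(sum(per_residue_counts(restraint_set())$count), 0)
})

test_that("compute_violations measures bound excess with r^-6 group collapse", {
  # two atoms 7.1 A apart against an upper bound of 6.5 -> violation 0.6
  m <- structure_model(data.frame(
    resid = c(1, 2), restype = "ALA", atom = "CA", element = "C",
    x = c(0, 7.1), y = 0, z = 0))
  b <- structure_bundle(list(m))
  rs <- restraint_set(data.frame(restraint_id = 1, res_a = 1, atom_a = "CA",
                                 res_b = 2, atom_b = "CA",
                                 lower = 1.5, upper = 6.5))
  v <- compute_violations(b, rs)
  expect_equal(unname(v$distance[1, 1]), 0.6, tolerance = 1e-9)
  # within bounds -> 0; lower-bound violation measured too
  rs2 <- restraint_set(data.frame(restraint_id = 1, res_a = 1, atom_a = "CA",
                                  res_b = 2, atom_b = "CA",
                                  lower = 2, upper = 8))
  expect_equal(unname(compute_violations(b, rs2)$distance[1, 1]), 0)
  rs3 <- restraint_set(data.frame(restraint_id = 1, res_a = 1, atom_a = "CA",
                                  res_b = 2, atom_b = "CA",
                                  lower = 7.5, upper = 9))
  expect_equal(unname(compute_violations(b, rs3)$distance[1, 1]), 0.4,
               tolerance = 1e-9)
  # ambiguous group: effective distance is the r^-6 sum, below the closest
  m3 <- structure_model(data.frame(
    resid = c(1, 2, 3), restype = "ALA", atom = "CA", element = "C",
    x = c(0, 5, 6), y = 0, z = 0))
  rs4 <- restraint_set(data.frame(restraint_id = c(1, 1),
                                  res_a = 1, atom_a = "CA",
                                  res_b = c(2, 3), atom_b = "CA",
                                  lower = 2, upper = 4.5))
  d_eff <- (5^-6 + 6^-6)^(-1 / 6)  # ~4.765, below the closest member (5)
  v4 <- compute_violations(structure_bundle(list(m3)), rs4)
  expect_equal(unname(v4$distance[1, 1]), d_eff - 4.5, tolerance = 1e-9)
  # unresolvable selector errors
  rs5 <- restraint_set(data.frame(restraint_id = 1, res_a = 1, atom_a = "CZ",
                                  res_b = 2, atom_b = "CA",
                                  lower = 2, upper = 4))
  expect_error(compute_violations(b, rs5), "CZ")
})

test_that("violations are zero on a bundle satisfying its own restraints", {
  m <- fix_helix20()
  bundle <- perturb_bundle(m, 5, 0.05, seed = 3)
  sh <- synthetic_shift_table(m, seed = 4)
  sc <- fix_scheme_u()
  # non-bonded pairs only: bonded CA-C sits below the generic 1.5 A floor
  sim <- simulate_peaklist(m, sh, sc, r_max = 6.0, shift_noise = 0, seed = 5,
                           exclude_bonded = TRUE)
  rs <- assign_peaklist(sim$peaks, sh, sc, homolog = m)
  # unambiguous restraints bound true distances (<= 6.0 vs upper 6.5/7.2);
  # ambiguous OR-groups can dip below the lower bound by r^-6 pooling, so
  # the self-consistency invariant is asserted on the unambiguous subset
  un <- restraint_set(as.data.frame(rs)[!rs$ambiguous, ])
  v <- compute_violations(bundle, un)
  expect_equal(max(v$distance), 0)
  expect_equal(v$summary$value[v$summary$quantity == "distance_mean"], 0)
})

test_that("torsion violations measure angular excess beyond the half-width", {
  m <- make_helix_model(6, seed = 1)
  b <- structure_bundle(list(m))
  phi3 <- masnmr:::model_torsion(m, 3, "phi")
  tors <- torsion_restraints(data.frame(
    resid = c(3, 3), angle = "phi",
    center = c(phi3, masnmr:::wrap_angle(phi3 + 50)), halfwidth = c(10, 10)))
  v <- compute_violations(b, restraint_set(data.frame(
    restraint_id = 1, res_a = 1, atom_a = "CA", res_b = 2, atom_b = "CA",
    lower = 2, upper = 8)), tors)
  expect_equal(v$torsion[1, 1], 0)
  expect_equal(v$torsion[1, 2], 40, tolerance = 1e-6)
  expect_error(torsion_restraints(data.frame(resid = 1, angle = "phi",
                                             center = 0, halfwidth = -5)))
})

test_that("native TSV and XPLOR round-trips preserve restraints", {
  rset <- sample_rset()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_restraints_tsv(rset, tmp)
  expect_identical(as.data.frame(read_restraints_tsv(tmp)),
                   as.data.frame(rset))
  # XPLOR: bounds algebra d - dminus = lower, d + dplus = upper
  tbl <- withr::local_tempfile(fileext = ".tbl")
  write_xplor(rset, tbl)
  lines <- readLines(tbl)
  expect_length(lines, 5)  # one assign per restraint, OR-group inline
  r2 <- read_xplor(tbl)
  expect_equal(length(unique(r2$restraint_id)), 5)
  expect_equal(r2$lower, rset$lower, tolerance = 1e-9)
  expect_equal(r2$upper, rset$upper, tolerance = 1e-9)
  expect_equal(r2$res_b, rset$res_b)
  expect_equal(sum(r2$ambiguous), 2)  # the two-member OR group survives
  # byte-stable emission
  tbl2 <- withr::local_tempfile(fileext = ".tbl")
  write_xplor(rset, tbl2)
  expect_identical(readLines(tbl), readLines(tbl2))
})

test_that("the minimal NMR-STAR reader extracts distance and torsion loops", {
  tmp <- withr::local_tempfile(fileext = ".str")
  writeLines(fix_nmrstar_text(), tmp)
  out <- read_nmrstar_restraints(tmp)
  expect_equal(length(unique(out$distance$restraint_id)), 3)
  # OR-group: constraint 2 has two members and is flagged ambiguous
  g2 <- as.data.frame(out$distance)[out$distance$restraint_id == 2, ]
  expect_equal(nrow(g2), 2)
  expect_true(all(g2$ambiguous))
  expect_equal(sort(g2$res_b), c(12, 14))
  expect_equal(out$torsion$angle, c("phi", "psi"))
  expect_equal(out$torsion$center, c(-60, -40))
  expect_equal(out$torsion$halfwidth, c(20, 20))
})

test_that("the TALOS-style reader takes uncertainties and skips non-Good rows", {
  tmp <- withr::local_tempfile(fileext = ".tab")
  writeLines(fix_talos_text(), tmp)
  tors <- read_talos(tmp)
  expect_equal(sort(unique(tors$resid)), c(2, 3))  # the "Dyn" row is skipped
  phi2 <- tors[tors$resid == 2 & tors$angle == "phi", ]
  expect_equal(phi2$center, -63)
  expect_equal(phi2$halfwidth, 12)
  psi3 <- tors[tors$resid == 3 & tors$angle == "psi", ]
  expect_equal(psi3$halfwidth, 15)
})
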