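# Superposition/RMSD, hydrogen bonds, atom distances, helical assembly,
# and the PDB/selection infrastructure they rest on.

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  masnmr:::quat_to_rot(q)
}

test_that("superpose_rmsd is exact on congruent point sets", {
  m <- fix_helix20()
  sp <- superpose_rmsd(m, m)
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  set.seed(11)
  R <- random_rotation(); t_vec <- c(4, -2, 9)
  m2 <- masnmr:::set_coords(m, sweep(coords(m) %*% t(R), 2, t_vec, `+`))
  sp2 <- superpose_rmsd(m, m2)
  expect_lt(sp2$rmsd, 1e-6)
  # returned rotation is orthonormal with det +1
  expect_equal(crossprod(sp2$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-8)
  expect_error(superpose_rmsd(coords(m)[1:2, ], coords(m)[1:2, ]), "3 atoms")
})

test_that("Kabsch route matches the quaternion oracle on random point sets", {
  set.seed(7)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    A <- matrix(rnorm(3 * n, sd = 3), n, 3)
    B <- matrix(rnorm(3 * n, sd = 3), n, 3)
    expect_equal(superpose_rmsd(A, B)$rmsd, oracle_quaternion_rmsd(A, B),
                 tolerance = 1e-8)
  }
  # RMSD is symmetric in its arguments
  set.seed(8)
  A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_rmsd(A, B)$rmsd, superpose_rmsd(B, A)$rmsd,
               tolerance = 1e-10)
})

test_that("bundle pairwise RMSD matches the perturbation expectation", {
  m <- make_helix_model(40, seed = 5)
  ident <- structure_bundle(list(m, m, m))
  pr0 <- bundle_pairwise_rmsd(ident, atoms = "backbone")
  expect_equal(pr0$mean, 0)
  expect_equal(pr0$sd, 0)
  sigma <- 0.3
  b <- perturb_bundle(m, 12, sigma, seed = 6)
  pr <- bundle_pairwise_rmsd(b, atoms = "backbone")
  expect_equal(pr$n_pairs, choose(12, 2))
  expect_lt(abs(pr$mean - sigma * sqrt(6)) / (sigma * sqrt(6)), 0.2)
  # selection restricts the atom set
  pr_sel <- bundle_pairwise_rmsd(b, selection = "resid 5-20", atoms = "heavy")
  expect_true(is.finite(pr_sel$mean))
})

test_that("region_rmsd evaluates the region under the global fit", {
  m <- fix_helix20()
  rr <- region_rmsd(m, m, region = 5:10)
  expect_equal(rr$global_rmsd, 0, tolerance = 1e-10)
  expect_equal(rr$regional_rmsd, 0, tolerance = 1e-10)
  # region = everything: regional equals global
  m2 <- perturb_bundle(m, 1, 0.4, seed = 2)$models[[1]]
  rr2 <- region_rmsd(m, m2, region = 1:20)
  expect_equal(rr2$regional_rmsd, rr2$global_rmsd, tolerance = 1e-9)
  # a locally displaced region shows up in the regional value only
  xyz <- coords(m)
  sel <- m$atoms$resid %in% 8:12
  xyz[sel, 1] <- xyz[sel, 1] + 3
  m3 <- masnmr:::set_coords(m, xyz)
  rr3 <- region_rmsd(m, m3, region = 8:12)
  expect_gt(rr3$regional_rmsd, rr3$global_rmsd)
  # the local-fit alternative reduces the regional value
  rr3_fit <- region_rmsd(m, m3, region = 8:12, refit = TRUE)
  expect_lt(rr3_fit$regional_rmsd, rr3$regional_rmsd)
  expect_error(region_rmsd(m, m, region = integer(0)), "empty")
})

test_that("detect_hbonds applies distance and angle criteria", {
  # constructed N donor with hydrogen, O acceptor at 2.9 A, angle ~170 deg
  mk <- function(o_pos, h_pos = c(0.5, 0.86, 0)) structure_model(data.frame(
    resid = c(1, 1, 4), restype = c("GLY", "GLY", "GLY"),
    atom = c("N", "H", "O"), element = c("N", "H", "O"),
    x = c(0, h_pos[1], o_pos[1]), y = c(0, h_pos[2], o_pos[2]),
    z = c(0, h_pos[3], o_pos[3])))
  hb <- detect_hbonds(mk(c(1.45, 2.51, 0)))   # N...O ~ 2.9, nearly linear
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, sqrt(1.45^2 + 2.51^2), tolerance = 1e-9)
  # too far
  expect_equal(nrow(detect_hbonds(mk(c(4.0, 0, 0)))), 0)
  # bad D-H...A angle (acceptor behind the hydrogen direction)
  expect_equal(nrow(detect_hbonds(mk(c(0, -2.9, 0)))), 0)
  # helix backbone: the O(i)...N(i+4) ladder is detected in full
  m <- fix_helix20()
  hb_all <- detect_hbonds(m, dist_cutoff = 3.5)
  ladder <- paste(hb_all$donor_resid, hb_all$acceptor_resid)
  expect_true(all(paste(5:20, 1:16) %in% ladder))
  # count is non-increasing as the cutoff decreases
  hb_tight <- detect_hbonds(m, dist_cutoff = 3.0)
  expect_lte(nrow(hb_tight), nrow(hb_all))
  # bundle means: distances averaged over models
  b <- perturb_bundle(m, 10, 0.05, seed = 4)
  hb_b <- detect_hbonds(b, dist_cutoff = 3.5)
  expect_true(all(hb_b$n_models == 10))
  expect_true(all(hb_b$sd > 0))
})

test_that("atom_distance requires unique selectors and measures Euclid", {
  m <- structure_model(data.frame(
    resid = c(1, 2), restype = "GLY", atom = "CA", element = "C",
    x = c(0, 3), y = c(0, 4), z = 0))
  expect_equal(atom_distance(m, "resid 1 and name CA", "resid 2 and name CA"), 5)
  expect_equal(atom_distance(m, "resid 1", "resid 1"), 0)
  m2 <- fix_helix20()
  expect_error(atom_distance(m2, "name CA", "resid 1 and name CA"), "atoms")
})

test_that("helical assembly applies a constant rototranslation per subunit", {
  protomer <- fix_helix20()
  params <- helical_params(twist = -162.1, rise = 27.6, n_subunits = 4)
  fil <- build_helical_assembly(protomer, params)
  n_at <- nrow(protomer$atoms)
  expect_equal(nrow(fil$atoms), 4 * n_at)
  expect_equal(unique(fil$atoms$chain), c("A", "B", "C", "D"))
  # n = 1 is the identity
  fil1 <- build_helical_assembly(protomer, helical_params(-162.1, 27.6, 1))
  expect_equal(coords(fil1), coords(protomer), ignore_attr = TRUE)
  # consecutive-subunit centroid z offsets are exactly the rise
  xyz <- coords(fil)
  blocks <- lapply(0:3, function(k) xyz[k * n_at + seq_len(n_at), ])
  z_off <- vapply(1:3, function(k)
    mean(blocks[[k + 1]][, 3]) - mean(blocks[[k]][, 3]), numeric(1))
  expect_equal(z_off, rep(27.6, 3), tolerance = 1e-10)
  # every consecutive pair is related by the SAME rototranslation (1e-8)
  tf <- lapply(1:3, function(k) {
    sp <- superpose_rmsd(blocks[[k + 1]], blocks[[k]])
    expect_lt(sp$rmsd, 1e-8)
    sp
  })
  for (k in 2:3) {
    expect_equal(tf[[k]]$rotation, tf[[1]]$rotation, tolerance = 1e-8)
    expect_equal(tf[[k]]$translation, tf[[1]]$translation, tolerance = 1e-8)
  }
  # cumulative twist after 2 steps = -324.2 = +35.8 mod 360
  R2 <- tf[[1]]$rotation %*% tf[[1]]$rotation
  ang <- atan2(R2[2, 1], R2[1, 1]) * 180 / pi
  expect_equal(ang, 35.8, tolerance = 1e-6)
  # composition property: n+m subunits restrict to the n-subunit assembly
  fil6 <- build_helical_assembly(protomer, helical_params(-162.1, 27.6, 6))
  expect_equal(coords(fil6)[seq_len(4 * n_at), ], coords(fil),
               ignore_attr = TRUE)
  expect_error(helical_params(-162.1, 27.6, 0), "n_subunits")
})

test_that("multi-model PDB round-trips through write/read", {
  m <- fix_helix20()
  b <- perturb_bundle(m, 3, 0.2, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(b, tmp)
  b2 <- read_pdb(tmp, as_bundle = TRUE)
  expect_length(b2, 3)
  expect_identical(b2$models[[1]]$atoms$atom, m$atoms$atom)
  expect_identical(b2$models[[2]]$atoms$resid, m$atoms$resid)
  # coordinates preserved to the 3-decimal PDB precision
  expect_equal(coords(b2$models[[3]]), round(coords(b$models[[3]]), 3),
               ignore_attr = TRUE)
  # single model writes without MODEL records
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, tmp2)
  expect_false(any(grepl("^MODEL", readLines(tmp2))))
  m2 <- read_pdb(tmp2)
  expect_s3_class(m2, "structure_model")
})

test_that("the selection mini-language parses its documented grammar", {
  m <- fix_helix20()
  a <- m$atoms
  expect_equal(select_atoms(m, "all"), seq_len(nrow(a)))
  expect_setequal(a$atom[select_atoms(m, "backbone")], c("N", "CA", "C", "O"))
  expect_true(all(a$resid[select_atoms(m, "resid 6-10")] %in% 6:10))
  expect_true(all(a$atom[select_atoms(m, "resid 3-5 and name CA CB")] %in%
                    c("CA", "CB")))
  sel_or <- select_atoms(m, "resid 1 or resid 20")
  expect_setequal(unique(a$resid[sel_or]), c(1, 20))
  expect_equal(select_atoms(m, "not heavy"), integer(0))  # no hydrogens
  expect_setequal(select_atoms(m, "(resid 2 and name CA) or (resid 3 and name CB)"),
                  which((a$resid == 2 & a$atom == "CA") |
                        (a$resid == 3 & a$atom == "CB")))
  # sidechain = heavy non-backbone = the CB pseudo-atoms
  expect_true(all(a$atom[select_atoms(m, "sidechain")] == "CB"))
  expect_error(parse_selection("resid and name"), "parse")
  expect_error(parse_selection("bogus_token"), "parse")
  expect_error(parse_selection("resid 1 ("), "parse")
})
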