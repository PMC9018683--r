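# Shared fixtures, built in code and memoized per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixture_env)) assign(key, builder(), envir = fixture_env)
  get(key, envir = fixture_env)
}

fix_helix20 <- function() memo("helix20", function() make_helix_model(20, seed = 1))

fix_scheme_u <- function() memo("scheme_u", function() load_scheme("U-13C6"))

# A tiny hand-built two-residue model with exact coordinates, for arithmetic
# checks that should not depend on the helix generator.
fix_two_res <- function() {
  structure_model(data.frame(
    resid = c(1, 1, 1, 2, 2, 2),
    restype = c("ALA", "ALA", "ALA", "SER", "SER", "SER"),
    atom = c("N", "CA", "CB", "N", "CA", "CB"),
    element = c("N", "C", "C", "N", "C", "C"),
    x = c(0, 1.5, 2.0, 0, 3, 4.5),
    y = c(0, 0, 1.2, 4, 4, 4),
    z = 0))
}

# Minimal NMR-STAR text with three distance rows (one OR-group of two
# members sharing constraint ID 2) and two dihedral rows.
fix_nmrstar_text <- function() c(
  "data_synthetic_test",
  "",
  "save_distance_constraints",
  "loop_",
  "_Gen_dist_constraint.ID",
  "_Gen_dist_constraint.Comp_index_ID_1",
  "_Gen_dist_constraint.Atom_ID_1",
  "_Gen_dist_constraint.Comp_index_ID_2",
  "_Gen_dist_constraint.Atom_ID_2",
  "_Gen_dist_constraint.Distance_lower_bound_val",
  "_Gen_dist_constraint.Distance_upper_bound_val",
  "1 5 CA 9 CB 2.0 7.2",
  "2 7 CA 12 CB 2.0 7.2",
  "2 7 CA 14 CB 2.0 7.2",
  "3 3 CA 3 CB 1.5 6.5",
  "stop_",
  "save_",
  "",
  "save_torsion_constraints",
  "loop_",
  "_Torsion_angle_constraint.ID",
  "_Torsion_angle_constraint.Torsion_angle_name",
  "_Torsion_angle_constraint.Comp_index_ID_2",
  "_Torsion_angle_constraint.Angle_lower_bound_val",
  "_Torsion_angle_constraint.Angle_upper_bound_val",
  "1 PHI 4 -80 -40",
  "2 PSI 4 -60 -20",
  "stop_",
  "save_")

# TALOS-style prediction table with an uncertainty column and one bad row.
fix_talos_text <- function() c(
  "DATA SEQUENCE MNPQR",
  "VARS RESID RESNAME PHI PSI DPHI DPSI DIST S2 COUNT CLASS",
  "FORMAT %4d %s %8.3f %8.3f %8.3f %8.3f %8.3f %5.3f %2d %s",
  "   2 N  -63.000  -42.000   12.000    9.000    0.000 0.900 10 Good",
  "   3 P  -70.000  -35.000   20.000   15.000    0.000 0.850 10 Good",
  "   4 Q  -65.000  -40.000    5.000    7.000    0.000 0.880 10 Dyn")
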