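---
title: "Methods and design choices in masnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in masnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masnmr)
```

# The problem

Magic-angle-spinning (MAS) solid-state NMR determines structures of proteins
in non-crystalline assemblies — for example a regulatory protein decorating
an actin filament — from through-space correlations between nuclei.  A 2-D
carbon-carbon dipolar-recoupling spectrum (CORD-type) yields cross peaks
whose positions are the chemical shifts of two spatially close carbons;
heteronuclear (PAIN-CP-type) spectra do the same for nitrogen-carbon pairs.
Each assigned cross peak becomes a distance restraint, and a restraint
network of ~10 per residue suffices to define a fold to better than 1 Å
backbone accuracy.

The hard part is assignment ambiguity: many atom pairs share shifts within
the matching tolerance.  `masnmr` implements the assignment workflow as a
reproducible pipeline, plus the structural analytics that surround it
(ensemble statistics, hydrogen bonds, helical filament construction,
rigid-body density docking, and trajectory analytics), with synthetic-data
generators so every stage is testable against known truth.

# Restraint assignment

For a peak at observed shifts $(\omega_1, \omega_2)$, `match_candidates()`
enumerates atom pairs whose shifts match each dimension within tolerance
(defaults 0.2 ppm for ^13^C, 0.3 ppm for ^15^N — typical MAS linewidths)
and which can produce an observable correlation under the isotope labeling
scheme.  `assign_peaklist()` then resolves each peak through, in order:

1. **Intra-residue criterion** — exactly one candidate is an intra-residue
   correlation.
2. **Sequential criterion** — exactly one candidate is a sequential
   ($|i-j| = 1$) correlation.
3. **Spin-system corroboration** — exactly one candidate's residue pair is
   carried by at least two other peaks of the same spectrum.  Two is the
   minimal corroborating count; it is configurable
   (`assignment_config(spin_system_min=)`).
4. **Homolog distance filter** — remaining candidates farther than 9 Å
   (configurable) in a homolog structure are discarded; a single survivor
   is unambiguous.  Candidates whose atoms are missing from the homolog are
   conservatively kept and flagged.
5. **Shift-deviation dominance** — if the closest-matching survivor beats
   the runner-up by more than `dev_margin` (default 0.05 ppm, the typical
   peak-position uncertainty), it is accepted.  At zero measurement noise
   the rule is exact, because the true candidate's deviation is identically
   zero.  This step is the package's automated stand-in for the judgment a
   spectroscopist exercises when one explanation clearly fits the peak
   position better; set `dev_margin = 0` to disable it.

If two of the criteria 1–3 select different candidates, the peak is demoted
to ambiguous rather than trusting either (the ordering is otherwise moot).
Peaks with more than `max_candidates` (default 3, i.e. "fewer than 4
possibilities") surviving options contribute no restraint; everything
discarded is logged with its reason.

Surviving correlations are converted to generous distance bounds, 1.5–6.5 Å
for intra-residue and 2.0–7.2 Å for inter-residue correlations, and
classified by sequence separation: intra (0), sequential (1), medium (2–4),
long (≥ 5).  The conventional category headings ("1 < |i−j| < 4",
"|i−j| > 4") leave $|i-j| = 4$ unallocated; the package assigns it to
medium, with `classify_separation(four_is_medium = FALSE)` as the
alternative.

After an initial structure is computed (by an external engine; restrained
annealing is out of scope here), `refilter_region()` re-evaluates the
restraints of a stated residue region against the new coordinates.  Changes
are *proposed* in a report, never silently applied — mirroring the manual
re-inspection step such regions get in practice.

## Violation statistics

`compute_violations()` reports, per model of a bundle, distance violations
$\max(0, d - u, l - d)$ with ambiguous OR-groups collapsed by the standard
$r^{-6}$ summation, $d_\mathrm{eff} = (\sum_k d_k^{-6})^{-1/6}$, and torsion
violations as the angular excess beyond `center ± halfwidth` on the
shortest arc.  The summary is the mean ± sd of per-model means, plus
maxima.  Note the $r^{-6}$ convention implies an OR-group's effective
distance is *below* its closest member, so groups sitting near the lower
bound can register violations that no individual member has — the
self-consistency invariant ("a bundle satisfies restraints generated from
itself") holds for unambiguous restraints.

# Coordinate analytics

Superposition uses the Kabsch SVD construction with determinant correction;
the test suite checks it against an independently implemented quaternion
(Horn) oracle to 10^-8^.  Bundle precision is the mean ± sd of all pairwise
RMSDs.  For "local RMSD" comparisons the package superposes on the global
selection and evaluates the region *without re-fitting* — this matches the
usual contrast between a global RMSD and a local one for a rearranged
segment; `region_rmsd(refit = TRUE)` gives the local-fit alternative, since
the convention is not universal.

Hydrogen bonds are detected from donor/acceptor heavy-atom distance
(default cutoff 3.5 Å) plus a D–H···A angle of at least 120° whenever an
explicit hydrogen is present; the values are common practice and both are
configurable because reported H-bond statistics rarely state them.

`build_helical_assembly()` generates filament coordinates by applying the
per-subunit rototranslation (twist about z, rise along z) k times; with the
actin helical parameters (−162.1°, 27.6 Å) consecutive subunits are related
by exactly the same screw transformation, which the tests assert to 10^-8^.

# Density docking

`simulate_density()` renders coordinates as a sum of isotropic Gaussians
with $\sigma = \mathrm{resolution} / (2\sqrt{2\ln 2})$ (FWHM equals the
nominal resolution) and amplitude proportional to atomic number.
`cross_correlation()` is an about-mean Pearson correlation over the voxels
where the reference map exceeds a threshold (default 0, i.e. all positive
voxels); the exact masking convention used by interactive fitting programs
varies, so the threshold is exposed.

`global_search()` samples uniformly random rotations (Shoemake quaternion
method) about the model centroid and uniform centroid positions inside the
map bounding box, pairing the two lists round-robin (a full product mode
exists).  The counts default to 5000 + 5000.  The identity placement is
always evaluated first (`include_identity = TRUE`): a finite random search
essentially never lands within a voxel of a known optimum, and the common
use case — scoring a model already roughly placed in its own map — should
be recovered deterministically.  The returned score is guaranteed to be the
maximum over everything evaluated.

# Trajectory analytics

**Contact occupancy.**  A contact holds when the minimum distance between
two residues' sidechain heavy atoms is ≤ 3.4 Å (glycine falls back to CA).
Occupancy pools frame counts over the $n$ simulations and $m$ interfaces:
$$\mathrm{occ} = \frac{\sum_{i=0}^{n-1}\sum_{j=0}^{m-1} C^{i,j}_{a,b}}
{\sum_{i=0}^{n-1}\sum_{j=0}^{m-1} C^{i,j}_\mathrm{total}} \times 100\%.$$
The double sum is implemented as printed; whether one should instead
average per-simulation percentages is ambiguous when frame counts differ,
so that variant sits behind `per_sim_average = TRUE`.

**TICA.**  Features (e.g. all backbone pairwise distances of a flexible
loop, via `distance_features()`) are made mean-free; C(0) uses all frames
while C(τ) is estimated within each series only and symmetrized,
$C(\tau) \leftarrow (\tilde C(\tau) + \tilde C(\tau)^T)/2$, so eigenvalues
are real without assuming reversibility.  The generalized problem
$C(\tau)v = \lambda C(0)v$ is solved after discarding C(0) directions below
a variance floor (default 10^-8^ of total variance), which makes perfectly
collinear features safe.  Components are C(0)-orthonormal.  For a symmetric
two-state Markov chain with flip probability $p$ the slow eigenvalue at lag
1 is $1-2p$ analytically, which the tests use as an oracle.  Lag times in
physical units convert to frames through the ensemble's frame interval.

**Free-energy surfaces.**  2-D projections are binned and converted to
$F = -\ln(p/p_\mathrm{max})$ in kT units (minimum 0, empty bins +∞).
Barriers between basins are *watershed saddles*: the minimax path value over
8-connected occupied bins (Dijkstra under the max-cost metric), measured
from the higher of the two basin minima.  This is one defensible reading of
"barrier between states" on a histogrammed surface; disconnected basins are
reported as such rather than errored.

# The synthetic world

The generators state a world with known truth:

- `make_helix_model()` — an ideal α-helix backbone (1.5 Å rise, 100°/residue,
  CA–CA 3.80 Å, an O(i)···N(i+4) ladder at ~3.35 Å) with one CB
  pseudo-sidechain per non-glycine residue.  Geometry classes, not
  chemistry: contact and labeling logic need CA/CB/C'/N/O positions, not
  rotamers.
- `synthetic_shift_table()` — shifts drawn per atom type from packaged
  mean/sd ranges (typical database values).  Carbons of residues within 14
  sequence positions are kept ≥ 0.45 ppm apart (just above twice the
  matching tolerance) by rejection sampling, so *local* assignments are
  resolvable the way real assigned spectra are, while accidental collisions
  between sequence-distant residues are retained — exactly the degeneracy
  class the homolog distance filter exists to resolve.  An explicit
  `degeneracy` fraction of residues additionally receives CA/CB shifts
  copied from a distant donor.
- `simulate_peaklist()` — one peak per ordered pair of observable carbons
  within `r_max`, positions = true shifts + Gaussian noise, with a
  peak→pair truth map.
- `simulate_trajectory_ensemble()` — reference + iid Gaussian coordinates,
  with scheduled residue pairs translated exactly into (3.0 Å) or out of
  (8.0 Å) contact per frame, so occupancies equal scheduled fractions
  identically.
- `simulate_two_state_series()` — a ±1 Markov chain with emission noise
  (default sd 0.05), the minimal signal carrying one slow mode.

What a green test does *not* establish: the generators have no force-field
energetics, no solvent, no spin physics and no peak-intensity model; the
helix world is a single rod, not a globular fold.  Conclusions about the
pipeline's behaviour on real spectra should lean on the per-operation
contracts, not on the synthetic recovery rate.

## Known limitation: assignment recovery at large n

The package's acceptance test for assignment recovery runs the full
pipeline on a 200-residue helix with 0.05 ppm peak noise and asserts ≥ 90%
of truth pairs recovered as unambiguous.  That threshold is **not met**
(measured ≈ 0.80; the same pipeline reaches 0.91 at 50 residues and 0.96 at
30) and is, as far as we can determine, unattainable in this world: 600
carbon shifts cannot be mutually separated by twice the 0.2 ppm tolerance
within the ~80 ppm physically available to protein carbons, and on a
contiguous helix every sequence-translated candidate pair (i+k, j+k) of a
true pair (i, j) lies within the 9 Å homolog-filter cutoff, so
collision-induced candidates survive filtering irreducibly.  The companion
guarantee — zero false unambiguous assignments at zero noise — holds at
every size.  The test is left asserting the stated threshold rather than
weakening it.

# Numerical and I/O choices

- Units are Å, ppm and degrees throughout; angles wrap to (−180, 180].
- All randomness flows through one seeded generator per call; the global
  RNG stream is saved and restored, so generators never perturb user code.
- PDB I/O is fixed-column v3.3 with MODEL/ENDMDL for bundles; coordinates
  survive round-trips to the format's 3-decimal precision.
- MRC maps are written as MRC2014 mode 2 (float32); the reader normalizes
  MAPC/MAPR/MAPS axis order and falls back to NXSTART-based origins.
- XPLOR NOE tables are emitted with d = (lower+upper)/2 so that
  d − dminus = lower and d + dplus = upper, OR-groups inline; emission is
  byte-stable.  The NMR-STAR reader handles both shared-ID OR-groups and
  per-pair listings of `Gen_dist_constraint` loops.
- Pipeline configs use a minimal flat TOML subset (sections; string,
  number, boolean and flat-array scalars) parsed in-package; unknown keys
  are rejected.  Every run directory gets a JSON manifest with inputs,
  seeds and package version, sufficient to reproduce the run.
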