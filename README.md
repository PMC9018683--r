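# masnmr

Distance-restraint assignment and structural analytics for magic-angle-spinning
(MAS) solid-state NMR studies of protein assemblies — the computations behind
an NMR structure of a protein bound to a filament, packaged as a tested,
reusable pipeline.

MAS NMR yields 2-D/3-D spectra whose cross peaks report through-space
proximity between nuclei.  Turning a peak list into distance restraints means
resolving assignment ambiguity: for a peak at shifts (ω₁, ω₂), every atom pair
matching both dimensions within tolerance is a candidate.  `masnmr`
implements the standard resolution workflow —

* shift matching under a **sparse ¹³C labeling scheme** (U-¹³C₆,
  2-¹³C-glucose, 1,6-¹³C-glucose; editable per-atom tables),
* the **unambiguity criteria** (intra-residue, sequential, spin-system
  corroboration, applied in that order),
* a **homolog distance filter** (candidates > 9 Å in a homolog structure are
  discarded),
* an **ambiguity cap** (≤ 3 surviving possibilities, else the peak is
  dropped and logged), and
* conversion to bounds (1.5–6.5 Å intra-residue, 2.0–7.2 Å inter-residue)
  with |i−j| classification (intra / sequential / medium 2–4 / long ≥ 5),

plus the surrounding analytics: restraint tabulation and per-residue counts,
violation statistics over conformer bundles (r⁻⁶ pooling for ambiguous
groups), Kabsch superposition and pairwise-bundle/regional RMSD, hydrogen-bond
geometry, helical filament construction from twist/rise (e.g. −162.1°,
27.6 Å per actin subunit), rigid-body docking into density maps by
random-orientation cross-correlation search, and trajectory-ensemble
statistics: contact occupancy

```
occ = Σᵢ Σⱼ C(i,j)_ab / Σᵢ Σⱼ C(i,j)_total × 100 %   (contact: min sidechain distance ≤ 3.4 Å)
```

time-lagged independent component analysis (TICA, eigenvalue 1−2p for a
two-state chain with flip rate p), and free-energy surfaces
F = −ln(p/p_max) with minimax (watershed-saddle) barrier estimation.

Synthetic-data generators with exact ground truth (helix models, perturbed
bundles, peak lists, scheduled-contact trajectory ensembles, two-state
series) make the whole pipeline testable offline.  File formats: PDB
(multi-model), MRC/CCP4 maps, XPLOR/CNS NOE tables, minimal NMR-STAR
restraint loops, TALOS-style torsion predictions, TSV everywhere else.

## Worked example

```r
library(masnmr)

# a 50-residue ideal helix with realistic, locally resolvable shifts,
# 10% engineered shift degeneracy and 0.05 ppm peak noise
model  <- make_helix_model(50, seed = 11)
shifts <- synthetic_shift_table(model, seed = 12, degeneracy = 0.1)
scheme <- load_scheme("U-13C6")
sim    <- simulate_peaklist(model, shifts, scheme, r_max = 6.5,
                            shift_noise = 0.05, seed = 13)
sim$peaks[1:3, ]
#>   peak_id        w1        w2 experiment mixing_ms intensity
#> 1       1  56.72954 176.15785       CORD        50         1
#> 2       2  56.68781  31.37039       CORD        50         1
#> 3       3 176.26342  31.47166       CORD        50         1

restraints <- assign_peaklist(sim$peaks, shifts, scheme, homolog = model)
restraints
#> restraint_set: 2841 restraints (2662 unambiguous, 179 ambiguous)

tabulate_restraints(restraints)
#>     category cc_unambiguous cc_ambiguous nc total
#> 1      intra            283           17  0   300
#> 2 sequential            905           28  0   933
#> 3     medium           1468          125  0  1593
#> 4       long              6            9  0    15
#> 5      total           2662          179  0  2841
```

Peaks matching several shift-degenerate explanations survive as ambiguous
OR-group restraints (179 here); everything else resolved through the
criteria, the 9 Å homolog filter, or shift-deviation dominance.  On this
fixture 91% of true atom pairs come back as unambiguous restraints, and at
zero peak noise the pipeline emits no false unambiguous assignment.

```r
# ensemble precision, as reported for NMR bundles (mean ± sd pairwise RMSD)
bundle <- perturb_bundle(model, 25, 0.5, seed = 14)
bundle_pairwise_rmsd(bundle, selection = "resid 6-45", atoms = "backbone")[c("mean", "sd")]
#> $mean
#> [1] 1.223108
#> $sd
#> [1] 0.03932535

# filament construction from helical parameters (3 subunits -> chains A-C)
fil <- build_helical_assembly(model, helical_params(-162.1, 27.6, 3))
fil
#> structure_model: 732 atoms, 50 residues (model 1)
```

The perturbation σ = 0.5 Å implies an expected pairwise backbone RMSD of
σ√6 ≈ 1.22 Å — which is what the bundle statistic returns.

A command-line entry point wraps the stages
(`simulate`, `assign`, `tabulate`, `validate`, `rmsd`, `hbonds`,
`build-filament`, `dock`, `occupancy`, `tica`, `fes`):

```sh
Rscript inst/cli/masnmr assign config.toml run_dir/
```

Each run directory receives the stage artifacts plus a `manifest.json`
(inputs, seeds, package version) sufficient to reproduce the run.

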