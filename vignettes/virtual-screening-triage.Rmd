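---
title: "Triage machinery for ensemble-docking virtual screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage machinery for ensemble-docking virtual screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`vstriage` implements the decision layer of a structure-based virtual
screening campaign against a receptor ensemble, patterned on a type I
(ATP-competitive) kinase-inhibitor discovery workflow for the LRRK2 kinase
domain: conformer selection by enrichment benchmarking, post-docking hit
triage, and enzyme-assay quantification. It deliberately does *not* dock,
generate poses or conformers, estimate torsion strain, or predict binding
energies — those are external engines for which the package provides
interfaces (score tables, pose files, strain tables) and, for testing,
synthetic stand-ins with known ground truth.

## Enrichment metrics and conformer selection

A benchmark set of known actives and property-matched decoys is docked
against each conformer; `compute_roc()` ranks the pooled table by docking
energy (ascending) and builds the ROC step curve. Tied energies advance TPR
and FPR jointly — one diagonal step per tie group — which is exactly the
Mann–Whitney half-credit convention, so the trapezoidal `auc_percent()`
equals pair counting with 0.5 for ties (an invariant the test suite checks
exhaustively on small random instances).

`logauc_percent()` measures *early* enrichment: with λ = 10⁻³,

> LogAUC = 100 × ( (1/3) ∫ TPR d(log₁₀ FPR) over [λ, 1] − 0.145 ).

Numerical conventions, chosen once:

* The integral is evaluated segment-by-segment on the ROC polyline with the
  linear segments integrated analytically (∫(a + bx) dlog₁₀x =
  (a ln x + bx)/ln 10), so tie diagonals, plateaus and the exact diagonal
  need no quadrature grid.
* FPR below λ is clamped to λ (zero log-width), not extrapolated; this is
  the established convention and makes a perfect ranking score exactly
  100 × (1 − 0.145) = 85.5.
* The subtracted baseline is the *printed* constant 0.145, not the exact
  (1 − λ)/(3 ln 10) = 0.14462; the exact diagonal therefore scores −0.038
  rather than 0.000. We keep the printed constant because it is the
  published convention for this metric; the residual is far below any
  decision threshold.

`rank_conformers()` reports AUC, LogAUC, mean active energy and the
active/decoy separation ⟨E_dec⟩ − ⟨E_act⟩ per conformer, ranks each metric
(ties broken by conformer id so ranks are always a permutation), and sorts
by LogAUC, then AUC, then id. Mean (not median) energies are used for the
separation ranking; the choice is visible in the report columns.

## 2D chemistry: fingerprints, curation, filters, clustering

All similarity logic runs on 1024-bit ECFP4 (radius 2) fingerprints with
Tanimoto similarity |A∩B|/|A∪B| (0 for two empty sets). Fingerprints come
from OpenBabel; its native 4096-bit ECFP4 is folded to 1024 bits by modular
OR-folding. Two backends — the `obabel` executable (batched, fast) and the
`ChemmineOB` library binding — produce identical bit sets and are
cross-checked in the tests. SMILES are canonicalized on ingest so duplicate
structures collapse deterministically.

Threshold semantics are boundary-exact and unit-tested:

| operation | rule |
|---|---|
| benchmark curation | MW < 500 Da, top 60 by pChEMBL, then greedy dedup from most potent: drop if TC ≥ 0.6 to a kept molecule |
| decoy matching | property windows (±25 Da, ±1 clogP, ±1 HBD, ±2 HBA, ±2 rotatable bonds, exact net charge) and TC to the active < 0.35, most dissimilar first |
| novelty filter | excluded iff max TC over references > 0.35 (strict: exactly 0.35 is kept) |
| property filter | kept iff MW ≤ 400 and clogP ≤ 4.0 (caps inclusive) |
| clustering | leader clustering at TC ≥ 0.5, scan in ascending energy |

Design choices made where the workflow description left room:

* **Energy-ordered leader clustering** rather than complete linkage: the
  published protocol names only a cutoff and a "lowest-energy
  representative"; scanning in ascending energy makes that representative
  property true *by construction* and gives pairwise-dissimilar leaders.
* **Decoy windows are configuration**, defaulting to the values above: the
  original decoys came from an external server, so the package exposes the
  property-match/topology-mismatch contract explicitly.
* **clogP** is OpenBabel's atom-contribution estimator; the provider is a
  single choke point (`molecule_table()`) and can be overridden by
  `attach_properties()` with vendor-computed values.
* The 0.6 dedup is applied **within** the top-60 potency list, not during
  its construction.
* Stage order in `run_triage()` is energy cut → novelty → property →
  clustering → geometry → strain; the order is config-visible and each
  stage logs an audit verdict per molecule.

## Pose geometry

A `pose_scene` holds heavy atoms only, with donor/acceptor typing on N/O/S.
A polar contact is a donor↔acceptor pair under 3.5 Å (strict); opposite
formal charges make it a salt bridge. Hydrogens are never placed — the
criterion is a heavy-atom distance cutoff, so orientation-dependent
hydrogen-bond geometry is out of scope. The key-residue filter counts
*distinct* key residues contacted (two bonds to one hinge residue count
once); raw-pair counting is available via `count = "pairs"`.

"Buried with an unsatisfied polar atom" is made operational as: ≥ 12
receptor heavy atoms within 4.5 Å (both configurable) and no complementary
receptor polar atom within the contact cutoff. The exclusion rule is the
printed conjunction — unsatisfied acceptors > 2 AND donors > 0 — with
`combine = "or"` available because the conjunction is plausibly a
transcription of two independent rules; the package asserts neither as the
author's intent and defaults to the literal reading.

Receptor PDB atoms are typed by residue/atom-name rules (backbone N donor /
O acceptor; standard side-chain chemistry at pH 7.4); ligand SDF atoms by
element, formal charge and heavy-atom degree. The docking grid writer
centers a 10 Å inner / 30 Å outer cubic box on the unweighted heavy-atom
centroid of the key residues Lys1906, Glu1948, Ala1950, Asn1999, Asp2017.

## Assay quantification

`fit_michaelis_menten()` and `fit_dose_response()` are bounded
Levenberg–Marquardt least-squares fits (`minpack.lm`), with IC₅₀ fitted on
the log scale and a few shifted restarts to avoid degenerate Jacobians at
unlucky starting points. The Hill slope is fitted by default (bounds
0.05–10) because published dose–response figures rarely state a fixed-slope
model; `fix_hill = 1` restores the classical logistic. Tables with no
observable transition (all activities > 0.8 or < 0.2) are flagged
non-converged rather than extrapolated. Km has **no default**: it must come
from a titration, because Cheng–Prusoff, Ki = IC₅₀/(1 + [S]/Km), is only as
good as Km. ΔG = RT ln Ki uses R = 0.0019872 kcal/(mol K), T = 298.15 K and
a 1 M standard state; Pearson correlation of experimental vs predicted
energies is offset- and scale-invariant, which sidesteps any unit-convention
mismatch in the predicted energies.

## What the generators emulate — and what they do not

* `gen_score_tables()`: Gaussian per-class energies. Only rank structure
  matters to ROC metrics, and the model gives the closed-form expected AUC
  Φ(Δμ/(σ√2)) used as a test oracle. Real docking scores are heavier-tailed
  and correlated across conformers; nothing here mimics a physical score
  distribution.
* `gen_molecule_set()`: scaffold × substituent enumeration with planted
  cluster labels. The default fixtures use large fused-ring scaffolds and
  single-atom substituents so intra-scaffold TC stays above the 0.5
  clustering cutoff and inter-scaffold TC below it — a property verified,
  not assumed, in the tests.
* `gen_pose_scene()`: idealized binding site — one polar side-chain atom
  plus two carbons per key residue on a 6 Å circle, contacts planted at
  2.9 Å, optional buried-atom carbon cages. Real pockets have rotamers,
  waters and marginal geometries; passing on toy scenes shows the *counting
  logic* is right, not that real poses would be judged correctly.
* `gen_assay_data()`: noiseless activities on the exact competitive-
  inhibition curve with midpoint Ki(1 + [S]/Km); noise is multiplicative
  lognormal with unit mean, reflecting luminescence CV roughly proportional
  to signal. Plate effects, outliers and normalization error are not
  modeled.
* `gen_triage_scenario()` assembles a full docked-library scenario whose
  energy cut keeps exactly the planted candidates; the planted molecules
  are *selected* (deterministically) to satisfy every filter, so the
  scenario tests the cascade's bookkeeping and thresholds, not filter
  sensitivity on borderline chemistry.

Problem sizes used by the test suite and kept deliberately modest: 10
conformers × (36 actives + 1800 decoys) × 20 seeds for conformer recovery;
a 1000-molecule library with 5 planted hits for the cascade; 500 random toy
scenes for the contact oracle; 100–200 simulated assays for parameter
recovery. Each was chosen as the smallest size at which the corresponding
statistical claim is stable.

## Known limitations

* ECFP4 bits come from OpenBabel, which differs bit-for-bit from other
  toolkits' ECFP4; Tanimoto values on the same molecule pairs are close but
  not identical across toolkits, so thresholds tuned elsewhere transfer
  only approximately.
* Donor/acceptor typing is rule-based and heavy-atom only; tautomers,
  protonation states and explicit-hydrogen geometry are upstream concerns.
* The unsatisfied-polar burial heuristic is a desk-scale surrogate for a
  solvent-accessibility calculation.
* `correlate_energies()` reports the parametric p-value (t distribution,
  n − 2 df); for small n with non-Gaussian errors a permutation test would
  be more defensible.
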