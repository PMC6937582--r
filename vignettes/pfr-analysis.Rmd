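---
title: "Dissecting peptide-flanking residues of class II epitopes with pfrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting peptide-flanking residues of class II epitopes with pfrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfrkit)
```

## The system and the questions

Class II MHC molecules present peptides in a groove that is open at both
ends. Nine residues — the core, numbered P1 to P9 — sit inside the groove
with side-chain anchors in the P1, P4, P6 and P9 pockets; the residues
overhanging either end are the peptide-flanking residues (PFRs), numbered
P(−1), P(−2), … towards the N terminus (zero is skipped) and P10, P11, …
towards the C terminus. pfrkit quantifies three kinds of evidence about
how PFRs behave:

1. **Static structure**: which PFRs touch the receptor, and how much; how
   flexible each residue is (crystallographic B-factors); whether the
   C-terminal flank folds into a defined reverse turn; and how similar
   that turn is to the equivalent loop of the free, native antigen.
2. **Ensembles**: how much each residue fluctuates over a trajectory
   (RMSF), how its share of receptor contacts changes, how often a turn
   window occupies a given dihedral state, and which distinct
   conformations the ensemble visits.
3. **Controlled synthetic data**: generators with exact ground-truth
   ledgers, so that every statistic above can be validated by parameter
   recovery rather than by eyeballing.

## Register assignment

`assign_register()` takes the core start as an *input* rather than
predicting it. Register inference is a binding-prediction problem in its
own right (pocket preferences, predictor ensembles); in a structural
analysis the register is normally fixed by the crystallographic anchor
occupancy, optionally cross-checked against an external predictor, and we
see no value in re-deriving it badly. The register object is a tibble
with one row per modeled residue and carries the P-position map, the
region partition (N-PFR / core / C-PFR) and the anchor flags.

Flanking residues frequently lack interpretable electron density.
`declare_sequence_gap()` therefore compares the modeled sequence against
the declared (synthesised) sequence and reports each unmodeled residue
with the P-position it would occupy, instead of silently renumbering.

## Contacts

`find_contacts()` enumerates every peptide-atom/receptor-atom pair within
the van der Waals cutoff (default 4.0 Å) and labels as hydrogen bonds the
subset whose atoms form a donor/acceptor couple within the H-bond cutoff
(default 3.4 Å); each pair is counted in exactly one class. Choices worth
stating explicitly:

* **Chemistry table.** Donors: backbone N; Lys NZ; Arg NE/NH1/NH2;
  His ND1/NE2; Trp NE1; Asn ND2; Gln NE2; Ser OG; Thr OG1; Tyr OH.
  Acceptors: backbone O/OXT; Asp OD1/OD2; Glu OE1/OE2; Asn OD1; Gln OE1;
  His ND1/NE2; Ser OG; Thr OG1; Tyr OH; Met SD. The criterion is
  distance-only between heavy atoms; an optional donor-angle filter
  (`min_donor_angle`) exists but is off by default, because a 3.4 Å
  heavy-atom criterion is the convention this analysis mirrors and
  crystal models carry no hydrogens to support a stricter geometric test.
  The backbone N of proline is retained in the donor set for simplicity;
  at these cutoffs the effect is limited to rare borderline pairs, and
  the vdW/H-bond *split* — unlike the grand total, which depends only on
  the 4.0 Å cutoff — is in any case sensitive to the exact typing table.
* **Hydrogens.** `hydrogen_policy = "exclude"` is the static-structure
  default (a ~2 Å crystal model has no informative hydrogens); the
  trajectory contact statistic defaults to `"include"` with a 3.0 Å
  cutoff, the usual all-atom short-range definition for simulation
  frames with modeled hydrogens.
* **Receptor selection** defaults to every receptor chain passed in, all
  domains: N-terminal flanks can reach receptor regions outside the
  canonical α1/β1 groove helices, so pre-restricting the selection would
  drop genuine contacts.
* **Scope.** Contacts are intra-model only: no crystal-symmetry
  expansion, no buried-surface-area or energy estimates. When an
  asymmetric unit carries several complex copies, the copy to analyse is
  an explicit parameter (`model` plus chain choice), and validation
  should try each copy.

`summarize_contacts()` reports per-residue vdW/H-bond/total counts,
percentage contributions, and regional subtotals; zero-contact registered
residues appear with zeros rather than vanishing.

## Turn geometry and the ST loop

A four-residue window i…i+3 is classified by the (φ, ψ) of its two
central residues against named windows (`turn_window_spec()`). The
defaults are the ideal type II β-turn, (φ, ψ)ᵢ₊₁ = (−60°, +120°) and
(φ, ψ)ᵢ₊₂ = (+80°, 0°), and a glycine-extended window in which the i+2
residue relaxes to (−60°, ±140°) while i+1 stays turn-like. The ±40°
tolerance is the conventional half-width for calling a window
"conforming"; membership uses the minimal circular difference, so +180°
and −180° coincide and a "±140°" target is simply two centres. Specs are
matched in list order, first hit wins, and anything else is `"other"` —
this is deliberately not a full turn taxonomy, just the states this
analysis distinguishes.

`hairpin_evidence()` adds the distance evidence: the Cα(i)–Cα(i+3)
separation (≤ 7 Å for a closed hairpin), the i-carbonyl → (i+3)
side-chain-hydroxyl hydrogen bond that defines a serine/threonine-capped
(ST) loop (≤ 3.4 Å), and the longer-range carbonyl → amide polar contact
(≤ 3.6 Å). ω is reported by `backbone_dihedrals()` but never used for
classification.

`superpose_segments()` performs a least-squares (Kabsch) rigid
superposition over an explicit residue-by-residue, name-by-name atom
pairing and reports the post-fit RMSD. The default pairing is backbone
N, CA, C, O of the loop residues; because published loop-RMSD values
rarely state their atom set, the pairing is a parameter, it is echoed in
every result, and comparisons against a reference value should scan the
small space of conventional pairings (backbone with and without O,
Cα-only) and report which one matches.

## B-factor profiles

`bfactor_profile()` averages isotropic B-factors per residue over either
all non-water heavy atoms or the backbone only — the selection is a
recorded parameter, not a hidden default, because plots of this kind do
not always state it. Categories follow the conventional reading at
moderate resolution: mean B below 40 Å² is a stably ordered residue,
above 80 Å² approaches disorder, in between is intermediate. These
thresholds are descriptive buckets, not statistics.

## Trajectory statistics

A trajectory is a topology plus an atoms × 3 × frames array; multi-model
PDB is the native on-disk dialect and anything richer can adapt to the
same contract via `as_trajectory()`.

* **Fitting** (`fit_frames()`): every frame is rigidly superposed onto
  the first frame's coordinates of the fit selection, mass-weighted by
  default — the standard receptor-Cα fit that removes global tumbling
  before fluctuation analysis. The fluctuation itself is unweighted.
* **RMSF** (`rmsf_profile()`): RMSFᵣ = √(meanₜ ‖xᵣ(t) − ⟨xᵣ⟩‖²) per
  selected atom (default Cα). For isotropic Gaussian displacement with
  per-coordinate σ the closed form is σ√3, which is what the jitter
  generator's recovery test checks.
* **Occupancy** (`dihedral_occupancy()`): per-frame window
  classification. The joint mode (default) demands both central residues
  in-state simultaneously — the natural reading of "the hairpin is
  maintained" — and yields exclusive, exhaustive fractions that sum to 1.
  The marginal mode reports per-residue memberships separately; both are
  provided because published occupancy statements do not always say
  which was used.
* **Clustering** (`cluster_frames()`): hierarchical agglomeration
  (`stats::hclust`) on the pairwise coordinate RMSD of the selected
  atoms, stopping when the minimum inter-cluster distance exceeds the
  threshold (default 2.5 Å, the customary value for peptide-conformation
  clustering); this is exactly `cutree(h = threshold)` because merge
  heights are monotone for the offered linkages. Average linkage is the
  default — the stopping rule is usually quoted without naming a linkage,
  so it is configurable and logged. Representatives are medoids. The
  exact pairwise matrix is limited to 5000 frames; beyond that an
  explicit `stride` is required rather than silently subsampling.

## Synthetic data: what it does and does not show

The generators emulate exactly the features the statistics measure, and
nothing more:

* `build_peptide()` places backbone atoms (plus CB stubs and Ser/Thr
  hydroxyls) by internal-coordinate chaining with ideal bond geometry
  (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; angles 111.2°/116.2°/121.7°;
  ω = 180° unless overridden). Re-measured dihedrals reproduce the
  request to well under 0.5°. No rotamer library, no sterics: only the
  atoms the tests touch are built.
* `build_contact_scene()` plants atom pairs at controlled distances with
  far-field decoys, using one-atom residues so the planted count is
  provably exact.
* `make_jitter_traj()` adds isotropic Gaussian noise per residue;
  `make_switch_traj()` alternates a window between two dihedral states
  with a Bernoulli draw per frame. Both return ledgers with the realised
  ground truth, and both are bit-reproducible under a fixed seed without
  disturbing the caller's RNG stream.

Passing the recovery tests therefore demonstrates that the estimators
are correct on data matching their assumptions. It does *not* show that
real trajectories are Gaussian or two-state (they are neither — real
ensembles have correlated, anharmonic motions and gradual transitions),
nor anything about force-field accuracy. Real-ensemble values of RMSF or
occupancy depend on the simulations themselves, which this package
deliberately does not run.

Problem sizes used by the validation suite were chosen so sampling error
sits well inside the asserted tolerances: 10,000 frames for two-state
occupancy recovery (binomial SD ≈ 0.004 at p ≈ 0.28, asserted within
0.01), 5,000 frames for the σ√3 RMSF closed form (asserted within 2%),
and 30-frame, 3-conformer fixtures for clustering, where inter-conformer
separations exceed the 2.5 Å threshold by construction.

## Numerical and degenerate-input choices

* Altloc resolution keeps the highest-occupancy conformer; exact ties
  break alphabetically by altloc, so results are order-independent.
  A `strict` policy errors, listing the affected residues.
* Residue numbering is taken as authored (PDB resSeq, insertion codes
  kept); nothing is renumbered on input. Elements missing from the
  element column are inferred from the atom name, trusting two-letter
  symbols only outside polymer atoms where "CA" is calcium, not Cα.
* Terminal φ/ψ are `NA`, never 0; windows containing undefined angles
  refuse classification rather than guessing.
* An atom-free file parses to an empty model with a warning, not an
  error; a zero-contact summary is an all-zero table.
* Superposition requires ≥ 3 paired atoms and resolves every requested
  atom name or errors; RMSD of identical sets is 0 to numerical noise
  (< 10⁻⁶ Å for rigidly moved copies).

## Known limitations

* mmCIF is read (atom_site loop, via bio3d) but not written.
* No symmetry expansion: lattice-contact analysis is out of scope, so a
  turn stabilised by a crystal neighbour would need external checking.
* The hydrogen-bond criterion is distance-plus-typing only by default;
  donor-angle filtering is crude (nearest-heavy-neighbour geometry) and
  off unless requested.
* Trajectory input is multi-model PDB; binary formats (DCD/XTC) need an
  external conversion step to frames.
* B-factor categories assume isotropic B values on a roughly
  moderate-resolution scale; TLS-dominated or very high-resolution
  models need judgement.
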