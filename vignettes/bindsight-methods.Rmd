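---
title: "bindsight: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bindsight: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindsight)
```

bindsight quantifies how small-molecule inhibitors and ions engage a
neurotransmitter sodium symporter (NSS) — the setting is a dopamine
transporter solved with a central-site tropane inhibitor, an allosteric
nucleoside analogue and a bridging Zn²⁺ ion — from three kinds of evidence:
static atomic coordinates, molecular-dynamics trajectories, and
dose-response assays. This vignette records the models, the conventions the
package fixes where the field's usage is loose, and what the synthetic-data
generators do and do not emulate.

## Coordinates and selections

Structures are read from fixed-column PDB into a flat atom table
(`read_structure()`); heteroatoms (ions, ligands) keep their deposited
residue names, residue numbers are never remapped (full-length numbering,
e.g. the indole tryptophan is residue 84 even in an N-terminally truncated
construct), and only blank/'A' alternate locations are retained because all
downstream measurements are single-conformer. Trajectories are a fixed
topology plus per-frame coordinates, from multi-model PDB or a plain
XYZ-per-frame dialect; every frame must match the topology's atom count and
a mismatch names the offending frame. Selections (`selection()`) are
declarative AND-filters over chain, residue range, residue name, atom name
and a heavy-atom flag, and resolve to deterministic, ordered index lists.

## Superposition and helix metrics

Rigid superposition is the Kabsch SVD solution with the determinant
correction, so reflections are never returned; the reported RMSD is the
exact least-squares minimum (the test suite checks it against a 5°
rotation-grid brute force on toy point sets). Cross-species comparisons
superpose α-carbons paired by an explicit residue-correspondence table
(`pair_calpha()`), never by automatic sequence alignment; approximate
tables for the dopamine/serotonin/fly-transporter core helices ship in
`inst/extdata/` and are meant to be replaced by alignment-derived tables
when precision matters.

Helix comparison (`compare_helix()`) fits the transform on scaffold helices
(typically TM3/TM8), applies it to the target, then reports:

* **displacement** — distance between the helix Cα centroids after
  alignment. The source literature prints displacement values without
  defining them; the centroid convention is this package's choice because it
  is stable to end-fraying and leaves pure rotations to the second metric.
* **reorientation** — the acute angle between fitted axis directions
  (axis sign is conventional, so angles are folded to [0°, 90°]).

The helix axis is the principal component of the Cα trace after a sliding
four-residue (≈ one turn) centroid smoothing. Raw PCA of helix Cα positions
is biased by up to ~2.5° when the helix spans a non-integer number of
turns; the one-turn smoothing cancels the circular component and recovers
the generator's axis to better than 0.2° on ideal helices while remaining
deterministic. Helix residue ranges are always inputs (a curated table is
shipped), never inferred.

Residue-pair distances support four explicit rules: named atom, Cα,
side-chain aromatic ring centroid, and minimum heavy-atom distance. The
extracellular-gate separation between the aromatic gate residues is
measured with the ring-centroid rule; that choice is a convention of this
package, flagged as such, because the literature value (~13 Å) is printed
without naming atoms.

## Trajectory interaction statistics

* **Contacts** (`contact_profile()`): a residue is in contact in a frame if
  *any* of its heavy atoms is within 4.0 Å of *any* ligand heavy atom;
  hydrogens are never counted. The per-residue contact probability is the
  fraction of frames in contact, and the *stable contact* flag is a strict
  inequality — more than 40% of the time — so a residue at exactly 0.40
  is not stable. Ranking (`top_coordinating_residues()`) breaks probability
  ties by (chain, resseq) ascending. Statistics are computed per
  trajectory; replicas can be pooled by concatenating frames (probabilities
  are invariant to frame permutation and duplication), or summarised per
  replica and averaged — both views are legitimate and the package leaves
  the choice to the caller.
* **π-stacking** (`stacking_series()`): two rings are stacked when their
  heavy-atom centers of mass are ≤ 5 Å apart *and* their least-squares
  plane normals subtend ≤ 45°. COM is mass-weighted over the listed ring
  atoms; the normal is the smallest principal component of the ring
  coordinates, and the inter-normal angle is folded to [0°, 90°] because a
  plane normal's sign depends on atom ordering — any other convention
  would make occupancy depend on how the ring atoms are listed. The
  shipped 9-atom indole and adenine-ring atom sets
  (`indole_ring_atoms`, `adenine_ring_atoms`) reproduce the
  adenosine-sandwich stacking measurement.
* **Hydrogen bonds** (`hbond_series()`): donor–acceptor ≤ 3.5 Å and
  D–H–A ≥ 120°. These cutoffs are a common geometric convention, not a
  value fixed by the source analyses (which do not print theirs); both are
  configurable, and the angle criterion can be disabled for hydrogen-free
  topologies (recorded in the result).
* **RMSF** (`rmsf_per_atom()`, `moiety_rmsf()`): each frame is superposed
  onto the first using a fit selection (typically Cα), and RMSF is the RMS
  deviation of each measured atom about its time-mean position; moiety
  values average per-atom RMSF within named groups (e.g. tropane /
  fluorophenyl / carbomethoxy). For isotropic Gaussian jitter with
  per-coordinate σ the closed form is σ√3, which the tests verify.
* **RDF** (`radial_distribution()`): minimum-image distances in an
  orthorhombic box, histogram normalised by shell volume 4πr²dr, probe bulk
  density, reference count and frame count, so an ideal gas gives
  g(r) = 1. Minimum-image wrapping is applied only here; protein–ligand
  contacts assume an unwrapped solute.

## Ion coordination shells

`find_coordination_shell()` lists every N/O/S atom inside an
element-specific distance window around the ion (defaults Zn 1.9–2.6 Å,
Na 2.2–2.9 Å). The windows bracket typical first-shell metal–donor
distances with standard coordination-chemistry margins; the structure
validator named in the source names no thresholds, so these are this
package's encoding and are configurable. Histidine contributes only the
nearer of ND1/NE2 (the tautomer at a site is not assumed). A nearby
carboxylate that earlier work treated as second-shell is listed whenever it
falls inside the window — the summary reports plain geometry and leaves
interpretation to the user. `geometry_deviation()` scores the shell
against ideal trigonal-planar, tetrahedral, trigonal-bipyramidal and
octahedral templates, minimising the ligand-angle RMS over all
ligand-to-vertex assignments (exhaustive, ≤ 6! = 720), which makes the
result invariant to ligand input order and to rigid motion of the site.

## Dose-response models

Three printed model families are fitted by trust-region
Levenberg–Marquardt (minpack.lm) with concentration parameters on the log
scale and multi-start from the geometric mean and quartiles of the
concentration grid — the originating analyses name only their software's
model, not its numerics, so the optimizer is this package's choice:

* Michaelis–Menten uptake: v = V~max~·S/(K~m~+S)
* single-site binding: B = B~max~·L/(K~d~+L)
* Hill inhibition, normalized variant: y = 100/(1+(x/IC₅₀)^h^)
  (bottom ≡ 0, top ≡ 100), and the variable variant:
  y = bottom + (top−bottom)/(1+(x/IC₅₀)^h^)

Standard errors come from the Jacobian at the optimum, back-transformed by
the delta method for log-scale parameters; no bootstrap by default. Fitting
uses unweighted least squares; replicate means or pooled replicates are
both accepted (the caller passes whichever vector they prefer — pooled
replicates are the package's documented default in examples, since the
originals do not state their choice). Preprocessing
(`subtract_background_normalize()`) subtracts the mean background and sets
the mean specific signal at the control concentration to 100%; results are
invariant to rescaling all raw signals. `free_zn_concentration()` encodes
the free-Zn bookkeeping used for Zn inhibition curves: zero after a
chelator wash, otherwise added + 0.1 µM ambient. IC₅₀ fold changes
propagate uncertainty to first order (delta method).

## Synthetic data: what it does and does not show

Every analysis stage has a seeded generator with known ground truth:
ideal α-helices (exact axis, rise, twist), planted contact fractions
(atoms placed 1 Å inside / 2 Å outside the cutoff so recoveries are
threshold-exact, never boundary-sensitive), planted stacking fractions,
ideal polyhedral metal sites with optional jitter, uniform ideal-gas
solvent boxes (the RDF null model), and constant-CV Gaussian dose-response
noise at the published kinetic parameters (K~m~ 0.55 µM, V~max~
342.8 fmol min⁻¹ per well; K~d~ 6.5 nM — B~max~ is not published and is
set to a plausible assay-scale 2000). Generators restore the caller's RNG
state and are byte-deterministic under a fixed seed.

The generators are *constructions*, not simulations: no force field, no
correlated dynamics, no chemically realistic packing, no instrument model
beyond constant-CV noise. Passing tests therefore demonstrate that the
measurement rules are implemented exactly and that the fitting machinery
is unbiased under the stated noise model — they do not validate force
fields or sampling adequacy on real trajectories, and measurements on real
deposited coordinates additionally depend on the shipped (approximate)
residue-correspondence tables.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen so sampling error is well inside
the asserted bands: 100–500-frame planted trajectories; a 20 000-point,
120-frame ideal-gas box for the RDF flatness check (worst-bin counting
error ≈ 1.7%, against a ±0.05 band); 200 seeded repeats for the
parameter-recovery bias and coverage checks; 2000 frames for the RMSF
closed-form check. Degenerate inputs error early and descriptively:
collinear point sets in superposition, < 4 Cα for an axis, empty
selections, frame/topology mismatches, non-positive control means,
constant responses. Ties and signs are fixed by documented conventions
(acute angles, first-to-last axis sign, resseq tie-breaks).

## Known limitations

* PDB fixed-column only (no mmCIF); no bond perception or force-field
  topology; engine-native binary trajectory formats must be converted to
  multi-model PDB or XYZ frames externally.
* Shipped helix ranges and cross-species mappings are curated
  approximations for demonstration, not alignment-derived.
* The RDF assumes an orthorhombic box; contacts assume an unwrapped
  solute.
* Hydrogen-bond cutoffs are conventions; report them alongside any
  occupancy.
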