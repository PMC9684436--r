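---
title: "Designing and evaluating water-soluble QTY variants of membrane proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating water-soluble QTY variants of membrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtyshift)
```

## The problem

Multi-pass membrane proteins — solute-carrier (SLC) transporters being a
prominent family, with mostly 10–12 transmembrane (TM) helices — expose
lipid-facing surfaces rich in leucine, isoleucine, valine and
phenylalanine.  Outside a bilayer or detergent micelle they aggregate,
which makes expression, purification, antibody generation and assay
development difficult.  The QTY code is a deterministic design rule that
rewrites those surfaces: inside annotated TM helices every

* L becomes Q (glutamine),
* I and V become T (threonine),
* F becomes Y (tyrosine),

and nothing else changes.  The replacement residues have side chains of
closely matched shape and volume but hydrogen-bond with water, so the
variant is expected to keep the native fold while becoming water-soluble.
`qtyshift` implements the code and, around it, the quantitative
evaluation a designer needs: variation percentages, molecular weight and
isoelectric point, rigid-body superposition of native versus predicted
variant structures, and a surface-hydrophobicity index.

## The substitution model

`qty_convert()` applies a residue map (default `{L→Q, I→T, V→T, F→Y}`,
identity elsewhere) to every position inside the record's TM intervals,
including partially helical edge positions — the code is defined on the
annotation, with no further qualification.  Three properties follow from
the construction and are enforced by tests:

* **Locality** — positions outside TM intervals are byte-identical.
* **Idempotence** — the image residues Q, T, Y are fixed points of the
  map, so converting twice equals converting once.  `qty_code_map()`
  rejects custom maps that break this.
* **Charge conservation** — D, E, K, R, H are never touched, which is
  why the isoelectric point barely moves (see below).

Variation is reported two ways, mirroring the standard presentation:
*TM variation* = substitutions / TM residues, and *overall variation* =
substitutions / chain length.  Raw doubles are kept internally;
reports round half-up to two decimals.

TM intervals follow the UniProt TRANSMEM convention (1-based, inclusive),
which is the reproducible public source of helix boundaries;
user-supplied interval files override the fetched annotation.

## Sequence properties

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da).  Average rather than monoisotopic masses are used because
that is what the standard web calculators report and what the reference
tables for these proteins contain.  Each substitution shifts the mass by
a fixed amount (Q−L = +14.9713 Da, T−I = −12.0543, T−V = +1.9725,
Y−F = +15.9994), so the total shift is a closed-form function of the
substitution ledger — a few hundred Daltons on a ~50 kDa transporter —
and the package's tests verify MW against that closed form to 0.01 Da.

The isoelectric point uses the Bjellqvist pK set exactly as implemented
by the Expasy compute-pI service (side-chain pKs for D 4.05, E 4.45,
C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0; C-terminus 3.55 with D/E
overrides; N-terminus 7.5 with residue-specific overrides), because
reproducing published pI tables requires the same constants.  EMBOSS
values are selectable via `charge_model("emboss")`.  The net charge is a
Henderson–Hasselbalch sum, strictly decreasing in pH, and the pI is
found by bisection on `[0, 14]` to a charge tolerance of 1e-4 —
tests compare it against a 1e-4-step grid scan (agreement within
0.001 pH) and against an independent implementation of the same method.
Since the QTY code conserves charged residues, only added tyrosines
(pK 10) can move the pI, and only when the pI lies near that pK; on the
synthetic cohort the drift stays well below 0.3 pH units.

Ambiguity code `X` passes through conversion unchanged, contributes the
mean residue mass (110.0 Da) and no charge.

## Structure handling and superposition

`read_structure()` parses PDB and mmCIF files (via bio3d) down to a
CA-only model: polymer ATOM records, one chain, alternate locations
resolved by highest occupancy (ties alphabetically first), waters and
heteroatoms dropped, missing residues simply absent.  Non-standard
residues map to their parent one-letter code where known, else `X`.
`write_structure_pdb()` emits CA-only ATOM records; a write→read round
trip preserves coordinates at the format's 3-decimal precision.

`map_sequence_to_structure()` aligns a sequence to a model's residue
string globally with identity scoring (match +1, mismatch 0, gap −2).
Identity scoring is deliberate: a QTY variant differs from its native at
roughly a quarter of positions yet must align gaplessly, which a
substitution matrix tuned for homology search does not guarantee.
Coverage is defined as the fraction of model residues aligned to an
*identical* letter — a variant still scores ~0.75 while a wrong chain
scores near the random ~0.05 — and mappings below 0.3 fail loudly.

`kabsch()` computes the least-squares optimal proper rotation by SVD of
the cross-covariance matrix, with the determinant sign flip that
prevents reflections; collinear point sets draw a warning (the rotation
about the common axis is then arbitrary).  `superpose_models()` adds the
protocol used by the common structure-alignment tools: an initial fit
over all pairs (reported as `rmsd_all`), then up to 5 cycles of
rejecting pairs deviating more than 2.0 Å and refitting (`rmsd_refined`).
Both numbers are always reported because published RMSDs depend on this
protocol, and the exact trimming used elsewhere is rarely stated.
Termini handling follows the same convention such comparisons use: when
a TM-annotated record is supplied, residues before the first and after
the last TM helix are dropped before fitting; `trim_policy()` exposes
explicit N-/C-terminal counts and an option to keep only TM residues.
The returned `"superposition"` object behaves like a fitted model:
`coef()` gives the rotation and translation, `residuals()` the per-pair
deviations, `predict()` applies the transform to new coordinates.

## Surface hydrophobicity

The package quantifies the surface change that structure figures show
qualitatively.  SASA is computed at residue (CA) resolution: each
residue is one sphere centred on its CA with an effective radius from
mean residue volumes, a probe of 1.4 Å, and quadrature by a
deterministic golden-spiral lattice of 960 points per sphere
(Shrake–Rupley point counting).  This coarse model is intentional: the
pipeline compares backbone-level predicted models, and the claim being
tested is directional.  An isolated sphere reproduces the analytic
4π(r+probe)² within 1 %, and doubling the points changes a bundle's
total by under 0.5 %.

The *surface hydrophobicity index* is the SASA-weighted mean
Kyte–Doolittle hydropathy over exposed residues (SASA ≥ 10 Å², a
conventional buried/exposed cut; both threshold and scale are
arguments).  Because every QTY substitution strictly lowers the residue
hydropathy (L 3.8→−3.5, I 4.5→−0.7, V 4.2→−0.7, F 2.8→−1.3), the index
on fixed coordinates can only decrease under conversion, strictly so
when any exposed residue was substituted.  With no exposed residue the
index is reported as `NA` rather than a number.

## The synthetic study conditions

Because the published inputs (UniProt entries, PDB depositions,
externally deposited predicted models) live outside the package, every
stage is exercised on generated data with known ground truth:

* `generate_membrane_protein()` builds loop–TM–…–TM–loop sequences.
  Defaults: 12 TM helices (the common SLC architecture) of 21 residues
  (a bilayer-spanning helix), loops of 15 residues, and a 0.5 L/I/V/F
  fraction inside TM segments, which lands TM variation in the 44–55 %
  band reported for real transporters.  Loops draw from
  {G,S,N,D,K,E,P} — a set disjoint from {L,I,V,F} — so substitution
  locality is sharply testable.
* `generate_helix_coords()` places CAs on an ideal α-helix (rise 1.5 Å,
  twist 100°, radius 2.3 Å), giving exactly regular consecutive-CA
  chords of 3.83 Å.
* `perturb_structure()` adds isotropic Gaussian noise (sd σ per
  coordinate) and a uniform random rigid motion (rotation via
  normalized quaternions, avoiding axis bias).  After optimal
  superposition the expected RMSD is σ√3, giving the superposition
  module a quantitative ground truth: at σ = 0.5 Å and 500 residues the
  recovered ratio lies in [0.8, 1.2] in ≥95 % of seeds.
* `make_helix_bundle()` packs parallel helices on an 8 Å circle to
  create buried and exposed faces for SASA tests.

All generators are pure functions of their spec and seed, and they
restore the caller's RNG state.

What the synthetic data does *not* emulate: real loop length
distributions, sequence correlations, side-chain packing, membrane
geometry, or prediction-model error structure.  Green tests therefore
demonstrate algorithmic correctness under controlled conditions, not
agreement with any particular database release; the published-reference
checks in the test suite perform that comparison when network access
and the deposited model files are available.

## Numerical choices and degenerate inputs

* pI bisection: 200 iterations max, tolerance |charge| < 1e-4; the
  charge is strictly monotone so bracketing cannot fail.
* Kabsch: < 3 pairs is an error (underdetermined); collinear sets warn
  but return; reflection correction flips the smallest singular
  direction.
* Refinement: rejecting down to < 3 pairs raises a refinement-collapse
  error rather than returning a meaningless fit.
* Empty sequences, out-of-bounds or overlapping TM intervals,
  non-alphabet letters, negative noise or lengths all raise immediate
  parameter errors.
* Report percentages and kDa round half-up to 2 decimals; internal
  values stay full precision.

## Problem sizes used in the checks

The bundled verification uses 50-record synthetic cohorts for the
conversion invariants, 100 random 30-mers for the pI oracle comparison,
500-residue helices with 50–100 noise seeds for RMSD recovery, and
960–1920 quadrature points for SASA convergence — sizes at which every
statistical band in the checks is comfortably stable.

## Known limitations

* The SASA model is single-sphere-per-residue; absolute areas are not
  comparable to all-atom SASA, only contrasts on like geometry are.
* TM boundaries come from annotation, not prediction; proteins without
  TRANSMEM features convert to themselves.
* The superposition protocol (2.0 Å cutoff, 5 cycles, TM-span trimming)
  approximates, but cannot bit-reproduce, RMSDs published with other
  tools' unstated trimming choices.
* Back-conversion of a variant is available only through the stored
  substitution ledger; the package does not predict structures.
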