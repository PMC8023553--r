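---
title: "Featurizing membrane-protein dimer interfaces with mpdimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Featurizing membrane-protein dimer interfaces with mpdimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpdimer)
```

## What the package computes

`mpdimer` turns a dimeric membrane-protein structure into a per-residue
feature table. The pipeline has five stages, each usable on its own:

1. **Structure intake** (`read_structure()`, `sanitize_structure()`,
   `enumerate_dimers()`, `apply_tm_mask()`): parse PDB ATOM/HETATM
   records, resolve alternate locations, strip waters and ligands, map
   modified residues back to their standard parents (selenomethionine to
   methionine with the selenium renamed to the sulfur position, and
   similar), enumerate contacting chain pairs of oligomers, and
   optionally trim each chain to an annotated transmembrane span.
2. **Surface and classification** (`compute_asa()`,
   `classify_residues()`): accessible surface areas in monomer and
   complex form, the derived descriptors, and the three-way residue
   classification.
3. **Conservation** (`read_pssm()`, `jsd_score()`): per-position
   Jensen-Shannon divergence between PSSM columns and a background.
4. **Interactions** (`interaction_fingerprint()` and the individual
   detectors): counts of eight interaction kinds per residue.
5. **Statistics** (`propensities()`, `correct_features()`,
   `summarize_features()`, `group_tests()`): class-propensity correction
   and the tabular summaries.

## Surface model and classification

ASA uses Shrake-Rupley spherical sampling: each heavy atom's van der
Waals sphere is inflated by the probe radius, covered with a
deterministic Fibonacci point lattice, and the fraction of points outside
every neighbouring inflated sphere scales the sphere area. Defaults: a
water-sized probe of 1.4 Å and 960 points per atom, which keeps the
per-residue error against a brute-force high-resolution integration
under 2% (the test suite verifies this on twenty random structures
against an independent 4×10⁴-points-per-atom Monte-Carlo oracle, and
checks the isolated atom against the closed form 4π(r+1.4)²).
Hydrogens are excluded from the surface calculation; van der Waals radii
are C 1.70, N 1.55, O 1.52, S 1.80 Å with a 1.80 Å fallback, all
configurable.

Relative solvent accessibility divides a residue's ASA by its area in an
extended Gly-X-Gly tripeptide (Sander-Rost constants). Classification
rules, applied in order:

- **surface** iff monomer-form RSA strictly exceeds 0.20 (a residue at
  exactly 0.20 is core — "above the cutoff" is read strictly);
- a surface residue is **interfacial** iff its minimum heavy-atom
  distance to the partner chain is strictly below 5 Å.

Classification deliberately uses *monomer-form* RSA. Interface residues
are buried by their partner; complex-form RSA would label exactly the
residues of interest as core, which would contradict the idea of
splitting surface residues into interfacial and non-interfacial sets.
This is a genuine design choice: with monomer RSA, "core" means "buried
within its own chain".

Two conventions are offered for the relative area change. The literal
definition, `relASA = ΔASA / mon_ASA` with `ΔASA = comp_ASA − mon_ASA`,
is the default and is negative at buried positions. Published interface
tables are sometimes reported on a buried-fraction scale instead
(positive, in percent); `rel_asa_convention = "buried_fraction"` produces
`−100·ΔASA/mon_ASA` for compatibility with that convention. A zero
monomer area with a non-zero change is geometrically impossible but
handled defensively (missing value plus a warning); 0/0 is defined as 0.

## Conservation scoring

A PSSM's weighted-observed-percentage block (the right-hand 20 columns of
the PSI-BLAST ASCII format) is divided by 100 and renormalized per
position; all-zero rows (positions with no alignment evidence) are
replaced by the background with a warning. The score is the
Jensen-Shannon divergence in bits,

$$\mathrm{JSD}(p, f) = H\!\left(\tfrac{p+f}{2}\right)
  - \tfrac12 H(p) - \tfrac12 H(f),$$

which is symmetric, zero iff the column equals the background, and
bounded by 1 in log base 2. `0·log 0` is taken as 0 before a 1e-10 floor
is applied inside the logarithms, and tiny negative rounding is clamped
so the reported score always lies in [0, 1]. No window smoothing or
gap-weighting refinements are applied: the score is the bare divergence.

Three named backgrounds ship with the package. The BLOSUM62 background
uses the standard published target frequencies (renormalized, since the
printed values sum to 1.002). The α-helical-TM and β-barrel-TM
backgrounds are **synthetic stand-ins** — the corresponding published
substitution-model background vectors are not redistributed — built from
typical residue compositions of TM helices (Leu/Ile/Val/Phe/Ala-rich,
charge-depleted) and TM strands (aromatic-girdle, alternating-polar).
Their files are marked `.synthetic` and any user-supplied 20-vector can
replace them. `appropriate_background()` picks the helix background for
`alpha_helical` folds and the strand background for `beta_barrel`;
scores under different backgrounds are similar in rank but not equal, so
a dataset should fix one background throughout.

## Interaction geometry

All detectors operate on interchain pairs only and are symmetric under
chain exchange and rigid motion (verified by test). Thresholds are
BINANA-style defaults; each is a configuration key:

| kind          | criterion                                        | default |
|---------------|--------------------------------------------------|---------|
| close contact | any heavy-atom pair distance                     | ≤ 2.5 / 4.0 Å |
| hydrophobic   | apolar-C to apolar-C distance                    | ≤ 4.0 Å |
| hydrogen bond | donor-acceptor distance; D-H-A deviation         | ≤ 4.0 Å; ≤ 40° |
| salt bridge   | closest cation-group/anion-group atom pair       | ≤ 5.5 Å |
| π–π stacking  | ring centroids; inter-normal angle; lateral offset | ≤ 7.5 Å; ≤ 30°; ≤ r + 0.75 Å |
| T-stacking    | ring centroids; inter-normal angle               | ≤ 5.0 Å; 90° ± 30° |
| cation–π      | cation centroid to ring centroid; offset         | ≤ 6.0 Å; ≤ r + 0.75 Å |

An apolar carbon is a side-chain carbon bonded only to carbon or
hydrogen (e.g. LEU CB/CG/CD1/CD2 but not MET CG, which binds sulfur).
Aromatic rings (PHE/TYR six-ring, TRP five- and six-ring, HIS five-ring)
are fitted by least squares; rings with missing atoms are skipped with a
warning. A ring pair receives at most one π class, π–π taking precedence
over T-stacking. Hydrogen-bond angles are evaluated only when the
structure carries explicit hydrogens (the package never adds them); the
heavy-atom fallback accepts on distance and flags the record. Histidine
counts as cationic only under the `his_charged` flag, because protonation
cannot be inferred from heavy atoms. Counts are per residue pair for
bonds/bridges/π records and per atom pair for contact counts; the long
record table retains the deciding geometry so every record can be
audited against its own thresholds.

The pair search uses a cell-list spatial index whose results are
exactly — not approximately — equal to exhaustive enumeration (tested on
random dimers at several cutoffs).

## Propensity correction and statistics

For class *c* and residue type *i*, `C_factor(c,i)` is the frequency of
*i* within *c* divided by the frequency of *i* in the whole dataset. The
identity `Σ_i f_total(i)·C_factor(c,i) = 1` holds algebraically per class
and is asserted to 1e-12. Feature values are multiplied by their class
factor; relASA is excluded from correction by default since it is already
a ratio. Types absent from the dataset get an undefined (not zero)
factor, and such rows pass through flagged.

Summaries report Q1/Q2/Q3 (linear interpolation between order
statistics — the convention of the mainstream Python/R data stacks, fixed
here because quartile conventions differ), mean and sample SD, with rows
ordered by increasing Kyte-Doolittle hydropathy (ARG first, ILE last).
Group comparisons use the classic pooled-variance independent t-test
(Welch available via `var_equal = FALSE`) and one-way ANOVA; raw
p-values by default with an optional Benjamini-Hochberg switch. The
physicochemical subsets (charged, positive, negative, polar, non-polar,
aromatic, and the small GAS set) are available via `residue_subsets()`;
Cys/Gly/Pro stay outside the hydropathy-based subsets.

## The fixture generator

`build_fixture()` emits structures whose key geometric quantity is exact
by construction: donor-acceptor distance and D-H-A angle for hydrogen
bonds, closest inter-group distance for salt bridges (real ARG/GLU atom
names, so the typing tables are exercised, not bypassed), centroid
separation and plane dihedral for ring stacks (ideal 1.39 Å hexagons),
and so on. `build_random_dimer()` grows two self-avoiding Cα walks
(3.8 Å steps) decorated with backbone and Cβ atoms in random local
frames, with a controllable interchain gap.

These fixtures emulate the *geometry* the detectors and the ASA engine
consume. They do not emulate real membrane proteins: no lipid
environment, no realistic side-chain rotamers beyond Cβ, no β-barrel or
helix topology, and residue types drawn uniformly rather than with TM
composition. Passing tests therefore demonstrate that the geometric
definitions are implemented correctly and behave invariantly — not that
any biological distribution is reproduced. Scale choices in the test
suite (random dimers of 3-8 residues per chain, 240-960 ASA points,
twenty-structure oracle comparisons) are the package's own balance
between coverage and a comfortably fast check; the oracle agreement is
resolution-limited, not size-limited, so small structures lose no
generality.

## Numerical choices and degenerate inputs

- Alternate locations: highest occupancy wins, ties break to the
  alphabetically first identifier — deterministic and conventional.
- Multi-model files: model 1 by default (`model_index` selects others).
- Fully coincident atoms contribute their surface exactly once.
- Residues with RSA > 1 (distorted conformations, chain termini of
  crude models) are reported, not clamped.
- Empty structures, single-chain dimer requests, unparseable PSSM rows
  and contradictory configuration values raise errors that name the
  offending entity; inapplicable TM annotations warn and keep the chain.
- Outputs use author numbering and preserve insertion codes, so rows
  can be matched back to the source structure.
- Batch runs are deterministic: identical manifest and configuration
  reproduce byte-identical CSVs.

## Known limitations

- PDB format only; no mmCIF, no symmetry-mate assembly generation, no
  repair of missing side chains (residues are flagged, not modelled).
- The ASA engine is a rolling-probe approximation, not the
  secondary-structure-assignment program used by some published
  pipelines; near the 0.20 RSA boundary the two can disagree for
  marginal residues.
- Interaction thresholds are geometric conventions, not energies;
  water-mediated bridges, halogen bonds and metal coordination are out
  of scope.
- The TM-annotation path consumes simple per-chain residue ranges; the
  curation of such ranges (and any visual inspection behind them) is the
  user's responsibility.
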