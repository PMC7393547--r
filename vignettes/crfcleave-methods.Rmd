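---
title: "Methods: CRF-based cleavage-site prediction from structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRF-based cleavage-site prediction from structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crfcleave)
```

This vignette is the package's own account of its model, its numerical
choices, and the design decisions taken where the method left genuine
freedom. No empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The model and its assumptions

A candidate cleavage site is the 8-residue window P4–P4′ around a
peptide bond; the bond sits between window positions 4 (P1) and 5
(P1′). The model is a linear-chain conditional random field over the
window,

$$ p(y \mid x) \;=\; \frac{1}{Z(x)}
   \exp\Big(\sum_{i=1}^{8}\sum_k \lambda_k\, f_k(y_i, y_{i-1}, x_i)\Big), $$

with binary labels and Boolean feature functions: one indicator per
(position-tagged observation attribute, label) pair, plus label-bigram
transitions with a distinguished start state. Position tagging means
the same residue identity at P1 and at P4 drives different weights,
which is essential — protease specificity is strongly
position-dependent. The assumptions this encodes: (i) the local window
carries the signal (no long-range interactions beyond P4/P4′); (ii)
labels of adjacent window positions are coupled (the chain term), which
lets the model express "the whole window looks cleavable" rather than
scoring P1 in isolation.

**Site labelling.** How to map per-site class labels onto the chain is
not dictated by the model. We label training chains homogeneously
(all-cleavage for positive sites, all-non-cleavage for negatives) and
read the prediction off the posterior marginal of the cleavage label at
the P1 position. This reproduces per-site classification while keeping
the chain coupling; the alternative reading (per-residue labelling of
whole substrates) is isolated behind `predict_site()` and could be
added without touching inference.

**Training.** Penalized maximum conditional likelihood,
$-\sum \log p(y|x) + \lVert\lambda\rVert^2 / (2\sigma^2)$, minimized
with L-BFGS-B from $\lambda_0 = 0$. The objective is convex, the
gradient is the model-minus-empirical feature expectation (verified
against central finite differences in the tests), and zero
initialization makes training fully deterministic. Defaults:
$\sigma = 1$, `max_iter` 120–300 depending on the entry point,
projected-gradient tolerance $10^{-5}$. Attributes never seen in
training contribute zero weight at prediction time.

## Structural descriptors

All descriptors are computed from raw ATOM coordinates; no external
programs are required. Defaults follow the tools that defined each
descriptor:

| descriptor | definition | default |
|---|---|---|
| SASA | Shrake–Rupley quadrature, golden-section sphere points | probe 1.4 Å, 960 points (240 in pipeline use) |
| accessibility categories | all / main / side / non-polar side / polar side; relative = % of extended-state reference | Gly Cα counts as side chain |
| secondary structure | Kabsch–Sander H-bond energy $E = 0.084(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) \cdot 332$, bond if $E < -0.5$; helices/bridges/turns/bends from the bond pattern; 8 → 3 class mapping H,G,I→H; E,B→E; rest→L | amide H imputed from the preceding carbonyl |
| torsions | IUPAC φ/ψ; `NA` at termini and across breaks (C–N ≥ 2.5 Å) | — |
| HSE | Cα neighbour counts split by half-sphere along the pseudo-Cβ (HSE-A) and Cβ (HSE-B) axes | radius 13 Å; ties count as "down"; hseau+hsead = cn exactly |
| DPX | distance to the nearest solvent-accessible atom | accessible ⇔ SASA > 0 |
| CX | (sphere volume − occupied) / occupied, occupied = atoms-in-sphere × mean atom volume | radius 10 Å, 20.1 Å³ |
| H-bonds | donor–acceptor < 3.9 Å, D–H⋯A > 90° where H imputable | name-table donors/acceptors |
| packing | heavy atoms within radius of the residue centroid / sphere volume | radius 8 Å |
| B-factor | mean over the residue's heavy atoms | — |

Decisions worth noting:

* **Packing** has no universally fixed formula; we define it as local
  heavy-atom density (count within 8 Å of the residue centroid over the
  sphere volume). It is one of several redundant burial descriptors.
* **Relative accessibility** for all five categories is normalized by
  the residue type's *all-atom* theoretical maximum (extended
  Ala-X-Ala-style reference). Per-category reference areas would change
  the scale of four columns but not their ordering, and bin edges are
  fitted on the data anyway, so the model is insensitive to this choice.
* **B-factor averaging** uses heavy atoms only (hydrogens are dropped at
  parse time).
* **Missing values** (chain termini, absent atoms, gap-padded window
  positions) are carried as an explicit `NA` category through
  encoding — never silently zero — so the model can learn terminus
  effects.
* The exact solvent-excluded (molecular) surface is not reimplemented;
  the solvent-accessible surface serves as the accessibility measure.

## LOWESS smoothing and discretization

Boolean feature functions force discretization; discretizing raw
descriptor profiles loses the window's shape. Each feature's 8-position
profile is therefore smoothed by locally weighted linear regression
before binning. For position $i$ with smoothing range $r$:

* interior ($i-r \ge 1$ and $i+r \le 8$): window $S=[i-r, i+r]$,
  weight normalizer $h = 2r+1$;
* left boundary: $S = [1, 2r]$, $h = 2r - i + 1$;
* right boundary: $S = [8-2r, 8]$, $h = i - 8 + 2r + 1$;

with tricube weights $w = (1 - (|i-j|/h)^3)^3$ clamped to $[0,1]$, and
the weighted least-squares line through $S$ evaluated at $i$. The
right-boundary normalizer is the mirror image of the left one; both
live in one small function (`lowess_weight_normalizer`) so an
alternative reading is a one-line change. Degenerate windows (zero
weighted variance) fall back to the weighted mean. Constants and exact
lines are reproduced unchanged — the smoother removes fluctuation, not
trend — and smoothing is shift-equivariant.

Bin edges are equal-width over the *training* range, fitted inside each
cross-validation training fold only and frozen into the model;
prediction-time values outside the training range are clipped into the
extreme bins, and boundary values go to the upper bin. `bins = 1`
yields a constant attribute, i.e. the feature is effectively disabled —
which is exactly what the grid search selects for uninformative
features, since ties resolve toward fewer bins then smaller range.
Categorical secondary structure enters as three 0/1 indicator profiles
so that it, too, can be smoothed numerically; this is a reconstruction
of an under-specified step, and `bins = 2` on an indicator recovers the
raw classes.

Smoothing ranges 1–5 and bin counts 1–10 (50 configurations per
feature) are searched sequentially — one feature at a time in a fixed
documented order, others held at the defaults (range 2, bins 5) — by
cross-validated AUC. A joint search over all features would be
$50^{25}$ configurations; the sequential pass mirrors how per-feature
optimization is described and costs $50 \times$ features CV runs. The
default entry point `cmd_train()` uses the defaults without searching;
`grid_search_smoothing()` is exported for explicit optimization runs.

## Dataset preparation

Annotations arrive as a MEROPS-style TSV (substrate id, protease,
1-based P1 position, substrate sequence, structure reference). Sites
are mapped onto chains by global pairwise alignment (BLOSUM62, gap
10/0.5), accepted only at ≥ 95% identity with both P1 and P1′ aligned
to real residues — the alignment-based stand-in for a
database-search-based mapping pipeline, keeping the same acceptance
rule without network dependence. Negatives are drawn uniformly without
replacement from the non-positive candidate windows of the same mapped
substrates (global pool, seed-controlled), equal in count to the
positives, excluding any window whose P1 lies within 7 residues of a
positive P1 and requiring full structural coverage. A greedy
longest-first redundancy filter over global-alignment identity stands
in for external clustering tools. Only X-ray structures pass the
experiment filter.

## The synthetic data generator

The generator emulates the statistical structure of real cleavage data
at desk scale: substrates are ideal-geometry backbones (N, Cα, C, O,
Cβ; bond lengths/angles from standard tables, ω = 180°) built from
helix/strand/coil segments, with helix (φ,ψ) = (−57°,−47°), strand
(−119°,113°), and coil torsions drawn per residue from an
extended-region window. B-factors are drawn per segment (core
N(15, 3²), loop N(40, 8²) Å², floored at 1) to mimic the elevated
mobility of loops. One positive site is planted per substrate: under
`sequence_only`/`both` a DEVD motif (a canonical caspase-style
recognition sequence) occupies P4..P1, with accidental off-site matches
mutated away; under `structure_only`/`both` the site sits at the centre
of a coil segment, the desk-scale analogue of the observation that
cleavage sites concentrate in exposed loops. Defaults: 40 substrates of
40 residues, ~30% coil.

What the fixtures do **not** model: side chains beyond Cβ (so
side-chain-dependent descriptors degrade to Cβ-level approximations),
realistic packing of a folded core, crystal contacts, missing density,
or sequence-structure correlation beyond the planted signal. Passing
tests therefore demonstrate that the machinery recovers signals of the
kind the method targets — not performance on real proteome data, which
requires real annotated structures.

## Evaluation machinery

Sn, Sp, precision, accuracy and MCC follow the standard confusion-table
formulas; zero denominators yield `NA` (MCC: 0 by convention). AUC is
trapezoidal over all distinct thresholds with midpoint tie handling,
which makes it equal to the Mann–Whitney rank statistic (asserted to
1e-12 in tests, and cross-checked against pROC). Cross-validation is
stratified, re-randomized per repeat from the seed; the per-repeat AUC
is the mean of fold AUCs, and *all* preprocessing state is fitted
inside training folds. The paired two-sided t-test across repeats
compares feature arms (paired, since the same fold assignments are
used; the degenerate zero-variance case reports p = 0 for a nonzero
shift, p = 1 otherwise). The operating threshold stored in each model
is the smallest score achieving 99% specificity on the training
scores; calls at or above it are flagged high-confidence.

Two statistical notes. First, the CV AUC of a *single* label
permutation is itself a noisy quantity (sd ≈ 0.09 at 80 windows,
≈ 0.045 at 160: the permutation, not the fold split, dominates the
variance, because one permutation's chance class structure affects all
folds); the label-permutation null is therefore estimated on the
160-window dataset as the mean over ten permutations rather than one
draw. Second, negatives are sampled once per dataset, not
re-sampled per repeat, so repeat-to-repeat variation reflects fold
assignment only.

## Problem sizes and numerical choices

Test and acceptance runs use 240 quadrature points per atom for
pipeline SASA (960 for the analytic checks; the isolated-sphere error
at 960 points is ~1e-14 relative because the golden-section point set
integrates a full sphere exactly up to weight placement), synthetic
datasets of 10–80 substrates of 40 residues, and CV layouts up to
10×5-fold. CRF training uses the vectorized forward–backward over all
instances simultaneously (sparse attribute incidence matrix), so a fold
trains in roughly a second at these sizes. Viterbi ties break toward
the non-cleavage label, then lexicographically; dihedrals of
(near-)collinear atoms return `NA` with a warning; alternate locations
resolve to highest occupancy (ties: first encountered).

## Known limitations

* The CRF chain is fixed at length 8; whole-substrate labelling modes
  are out of scope (see above).
* Per-category relative-accessibility references are approximated by
  the all-atom reference (see descriptors section).
* The secondary-structure assignment is a faithful but compact
  Kabsch–Sander implementation; rare edge classes (π-helix ends, bent
  ladders) may differ from full DSSP on real structures.
* The sequential grid search is greedy; feature interactions in the
  smoothing parameters are not explored.
* mmCIF input is not supported; NMR/EM structures are rejected rather
  than handled.
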