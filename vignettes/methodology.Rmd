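---
title: "Fuzzy FMEA with DEA cross-efficiency: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy FMEA with DEA cross-efficiency: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzydea)
```

`fuzzydea` prioritises drug-shortage failure modes in a pharmaceutical
supply network from expert Occurrence–Severity–Detection surveys. This
vignette records the models the package implements, the conventions it
fixes where several choices were defensible, and what its validation
does and does not establish.

## The rating model

Every failure mode in a firm's metric receives three ordinal ratings.
Occurrence and severity use ten anchored levels; detection only six
(1, 3, 5, 7, 9, 10), because the detection vocabulary — very high
effectiveness down to "no technology applies" — has no anchors at the
even levels. The package therefore *rejects* even detection ratings at
input rather than interpolating them: there is no inference rule for
them, and silently snapping a 4 to a 3 or 5 would alter the expert's
judgement. `fmea_scales()` returns the full instrument;
`validate_assessments()` applies these rules with row-level reasons.

## Fuzzification

Each factor has its own single-input, single-output Mamdani system
(`build_fis()`): a triangular membership function per admissible crisp
level, trapezoidal (or degenerate-triangular) output terms, and one
if-then rule per level. Inference (`infer()`) uses the canonical Mamdani
operators — rule strength by membership of the crisp value in the input
function, minimum implication (clipping), maximum aggregation. Severity
level 10 shares the VH consequent of levels 8–9, so its triple equals
theirs; the occurrence and detection scales end with a separate
plateau.

Defuzzification (`defuzzify()`) keeps only maximum-based summaries:
smallest of maximum (SOM), largest of maximum (LOM), and middle of
maximum (MOM). With the rating universe sampled on an equally spaced
grid, the maximisers form a contiguous plateau whose membership values
are exactly equal in double precision, so the three summaries are the
plateau's first point, last point and mean. Two MOM conventions exist —
the mean of all maximising grid points and the midpoint
(SOM + LOM) / 2 — and they coincide on contiguous plateaus; both are
exposed (`mom = "grid_mean"` is the default).

**Grid resolution.** The default is 101 points on [1, 10] (step 0.09),
the common default of FIS toolboxes. The characteristic score values it
produces (1.99, 3.07, 5.05, 8.02, …) are grid points adjacent to the
true plateau edges (2, 3, 5, 8): the discretisation overshoots each
edge by at most one step. Refining to 1001 points moves SOM/LOM by up
to 0.063 (bounded by the coarse step 0.09) and MOM by at most half a
step; the tests assert exactly these bounds. The grid count is
configurable everywhere, but note that the packaged case-study vectors
and any results compared against them are defined at 101 points.

## DEA cross-efficiency

Each (firm, failure mode) pair is a decision-making unit with the nine
fuzzified values (O, S, D) × (SOM, MOM, LOM) as inputs and the constant
output 1 shared by all units; FMEA has no natural DEA output, and a
constant output turns "uses small inputs" into "is efficient", so low
efficiency flags high risk. The package implements only the
input-oriented constant-returns (CCR) model — no VRS, output
orientation or super-efficiency — because the constant-output design
makes those variants meaningless or redundant here.

Self-appraisal solves, per unit k,
$\max \mu \;\text{s.t.}\; \nu^\top x_k = 1,\; \mu \le \nu^\top x_j\;
\forall j,\; \nu \ge 0$, and peer appraisal scores every unit with every
unit's weights, $E_{jk} = \mu_k / (\nu_k^\top x_j)$, averaged into
$CE_j$ over all appraisers. Two **anchor units** are appended per node
set: `Lower`, the fuzzified best rating (all inputs 1), and `Upper`, the
fuzzified worst (O = S = D = 10). They appraise and are appraised — so
the score scale is pinned to the instrument itself, not to the
happenstance of a node's worst respondent — but are excluded from
rankings and averages. `dea_self_efficiency()` additionally reports the
envelopment solution (reference intensities and slacks) with slacks
maximised at the optimal score, the two-phase treatment of the
non-Archimedean epsilon; a literal weight lower bound is available via
`epsilon`.

**Alternate optima.** Optimal multiplier weights are generally not
unique, and with many tied or degenerate units (identical rating
profiles are common in practice) the optimal face can be large. Which
vertex a solver returns is an artifact of its pivoting, yet it changes
individual $E_{jk}$ values. The package fixes three conventions:

* every solve is performed in *ratio units* — each input column divided
  by the appraiser's own input — which makes the chosen vertex, hence
  the whole E matrix, exactly invariant to rescaling any input column;
* the bundled simplex is deterministic (Dantzig pricing, lowest-index
  tie-breaks, Bland fallback against cycling), so identical inputs give
  identical reports;
* Doyle–Green `benevolent` and `aggressive` secondary goals are
  available to bound how much the vertex choice can matter in a given
  data set.

Under these conventions the packaged case study reproduces the original
firm averages, node averages and top-risk scores to within ±0.01 (the
tests assert this); individual low-risk cells can differ by up to about
0.02 from any other implementation's equally optimal basis, which is the
irreducible footprint of weight non-uniqueness.

The solver itself is a dense two-phase primal simplex written for these
programs (at most a few dozen rows once duplicate constraints are
dropped); it detects infeasible, unbounded and redundant systems and is
exercised against closed forms, vertex enumeration and a dense
weight-grid oracle in the tests.

## Classification and aggregation

Scores map to four linguistic levels: low [0.5, 1], moderate
[0.25, 0.5), high [0.125, 0.25), critical (0, 0.125). Boundaries belong
to the lower-risk side, following the "from 0.25 to less than 0.5"
phrasing of the moderate band; the other edges follow by partition.
Scores outside (0, 1] are rejected, not clamped — cross-efficiency is
provably inside that interval, so an out-of-range value signals a bug
upstream.

Firm scores are arithmetic means over the firm's failure modes; node
scores are means over the role's firms; the **chain score is the mean
over firms, not over nodes**. The two differ whenever roles have
unequal firm counts, and averaging firms keeps each surveyed expert
equally weighted. The report records the convention.

## The synthetic generator

`generate_assessments()` emulates the survey: per firm and per failure
mode in the role's metric, independent categorical draws of O, S and D
over the admissible levels. Defaults are the case-study network size
(3 manufacturers, 1 distributor, 2 pharmacies) and uniform rating
distributions — uniform because the instrument gives no prior reason to
favour levels, and skewed scenarios are one `probs` argument away.
Draws run under an isolated RNG state, so a seed fully determines the
survey without disturbing the session.

What the generator does *not* emulate: correlation between factors
(severe events are often also rare), correlation across failure modes
within a firm, multi-respondent disagreement, and missing answers.
Passing tests on synthetic surveys therefore demonstrate pipeline
correctness — determinism, admissibility, aggregation identities — not
that real surveys look like these draws.

## Problem sizes and runtime

The validation suite runs the full case study (50-, 11- and 18-unit
DEA sets, one LP per appraiser) in a couple of seconds on one CPU;
property tests use 2–5-unit instances where brute-force oracles
(closed forms, vertex enumeration, dense weight grids) are exact or
near-exact. These sizes were chosen so every oracle is computed rather
than assumed; the pipeline itself scales comfortably to a few hundred
units per node set.

## Known limitations

* One respondent per firm: the instrument has no aggregation rule for
  panels; pooling multiple experts is left to the caller.
* The crisp-to-fuzzy map is non-injective (O 3/4, O 5/6, D 9/10 share
  triples), so crisp ratings cannot always be recovered from fuzzy
  vectors; the case-study fixture therefore stores the fuzzified form.
* Cross-efficiency cell values are basis-dependent (see above); only
  quantities that average over appraisers should be compared across
  implementations at tight tolerances.
* The linguistic thresholds are fixed conventions, not estimated
  quantities; shifting a boundary relabels scores near it.
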