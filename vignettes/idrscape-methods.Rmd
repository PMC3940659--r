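---
title: "Methods: detecting and characterizing amyloidogenic and low-complexity regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterizing amyloidogenic and low-complexity regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrscape)
```

## The problem

Intrinsically disordered proteins (IDPs) carry two kinds of sequence
features that matter for aggregation biology. *Amyloidogenic regions*
(ARs) are short stretches — typically six to eight residues — that can
nucleate amyloid fibril formation. *Low-complexity regions* (LCRs) are
stretches of biased amino-acid composition, abundant in disordered
sequence, that modulate solubility and aggregation kinetics. idrscape
provides the full analysis chain for studying how these two region types
are distributed, how often they overlap, and how their content varies
with the degree of structural disorder: region detection engines,
interval statistics, disorder-class stratification, composition and
conformational-preference profiling, and distributional fits.

Because the curated disorder databases this kind of analysis draws on
are not bundled (and change between releases), the package ships a
synthetic-cohort generator that plants regions with known ground truth,
so every stage of the pipeline is testable offline.

## Coordinates and region algebra

All intervals are 1-based and inclusive at both ends: the interval
(97, 112) spans `112 - 97 + 1 = 16` residues. This matches the
convention of published per-protein region tables and is used for all
internal arithmetic; there is no half-open conversion anywhere.

Content percentages are defined as

$$\mathrm{content} = 100 \times \frac{\#\{\text{residues covered by the
merged regions}\}}{L},$$

where $L$ is the protein length. Same-kind regions are merged before
counting (only truly overlapping intervals; abutting intervals share no
residue and remain distinct regions for counting purposes), so no
residue is double-counted and contents can never exceed 100%. Core
operations return full precision; presentation rounding is a separate
half-up formatter (`format_pct()`), with 0 decimals for whole-cohort
tables and 2 decimals elsewhere. Half-up is used deliberately — R's
`round()` rounds half to even, which does not reproduce the printed
percentages of typical worked examples.

Terminal counts use window intersection: a region counts as N-terminal
when any of its residues falls within `margin` (default 15) residues of
the N-terminus, and symmetrically for the C-terminus. This is the most
inclusive reading of "within 15 residues of the terminal".

AR × LCR overlap is catalogued per (AR, LCR) pair with a non-empty
intersection; a protein "has overlap" when the catalog is non-empty.
Overlap regions are always derived objects, never inputs.

## The low-complexity detector

`detect_lcr()` is a SEG-style windowed-entropy segmentation. The
Shannon entropy of a window of width $W$ with residue counts $n_i$ is

$$H = -\sum_i \frac{n_i}{W}\log_2 \frac{n_i}{W} \quad\text{bits},$$

between 0 (homopolymer) and $\log_2\min(W, 20)$. The detector:

1. computes the sliding entropy profile (step 1);
2. seeds stretches at windows with $H \le$ `trigger_entropy`;
3. grows each seed through contiguous windows with $H \le$
   `extension_entropy`;
4. unions the residue spans of qualifying windows and merges
   overlapping or contiguous stretches;
5. refines each stretch to the contiguous sub-window of length
   $\ge W$ minimizing the *per-residue* multinomial composition
   probability, i.e. $\log(P)/W$ with
   $P = \frac{W!}{\prod_i n_i!}\,20^{-W}$, ties broken by longest then
   leftmost.

The defaults are the canonical triple $W = 12$, trigger 2.2 bits,
extension 2.5 bits; all three are exposed in `seg_params()`.

Two numerical choices deserve comment. First, the refinement objective
is normalized by window length. The unnormalized probability $P$ almost
always *decreases* when a duplicated flank residue is absorbed (each
repeat contributes a $1/n_i!$ factor), so minimizing raw $P$
systematically inflates boundaries by several residues around a planted
homopolymer; the per-residue rate leaves pure-stretch boundaries exact
and trims mixed edges. Second, the refinement is a single-pass
reduction of each raw stretch, not the original recursive
optimal-segmentation search; it is an approximation, and it can be
switched off (`refine = FALSE`) to obtain the raw window-union
stretches. Windows containing ambiguity letters (X, B, Z, U, O) are
skipped: they can neither seed nor extend a region.

On synthetic cohorts with planted homopolymeric stretches at least
twice the window long amid uniform-random flanks, the detector achieves
per-residue recall above 0.95 and precision above 0.99 at the defaults
(60-protein seeded cohorts; see `tests/testthat/test-acceptance.R`).
Detection of *weakly* biased composition stretches is threshold-limited:
a stretch sampled from a Ser/Pro/Gly/Ala-enriched distribution can have
window entropies above 2.5 bits and will then legitimately not be
called. The detector makes no attempt to reproduce any particular
SEG build bit-for-bit, and published per-protein LCR coordinates are
treated as input annotations, not as detector targets.

## The amyloidogenic-region scanner

`scan_sequence()` scores every hexapeptide window with an additive
position-specific scoring matrix (PSSM): 6 positions × 20 residues,
score $= \sum_{p=1}^{6} w_{p,\,s_p}$. Windows with score $\ge$ threshold
(closed bound) qualify; qualifying windows are unioned residue-wise and
each maximal run becomes one AR interval, so ARs are always at least 6
residues long and multi-hexamer ARs merge into a single region. The
per-region peak window score is retained as metadata.

No trained amyloid matrix is bundled: published trained matrices are
not freely redistributable in numeric form, and the scanner is
deliberately matrix-pluggable (TSV, 6 rows × 20 named columns). The
package ships an *indicator fixture matrix* built from a motif list
(`pssm_from_motifs()`): weight 1 wherever some motif has that residue at
that position. With threshold 6 it accepts exactly the position-wise
chimeras of the motif list, which makes planted-motif recovery on
synthetic cohorts essentially exact while false windows in uniform
background occur at rate $\approx (k/20)^6$ for $k$ distinct motif
residues per position. Named threshold presets can be stored on a
matrix; the numeric cutoff of any trained matrix remains a required
user input.

## Disorder classes and cohort aggregation

The disorder fraction of a protein is 100 × (annotated disordered
residues) / length, with merged intervals. Proteins are stratified as

* PDP (partially disordered): disorder ≤ 30%,
* MDP (moderately disordered): 30% < disorder ≤ 70%,
* LDP (largely disordered): disorder > 70%.

Published class definitions are given as integer ranges (0–30, 31–70,
71–100), which leaves real-valued fractions such as 30.5% formally
unassigned; the half-open convention above pins every value in [0, 100]
to exactly one class and agrees with the integer ranges on integers.
A protein is *amyloidogenic* when it carries at least one AR.
`summarize_class()` aggregates per-protein summaries into one row per
class plus a Total row (counts, amyloidogenic percentage, total region
counts, mean contents, overlap counts).

## Composition and conformational preference

`composition_profile()` reports residue frequencies (percent, summing
to 100) over a context — whole proteins, or the residues inside AR/LCR
regions. Ambiguity letters are excluded from numerator and denominator.

`ss_preference()` tallies per-residue secondary-structure labels
(H/E/C) over a context. The primary mode is per-residue; a secondary
`mode = "region"` assigns each region its majority label and reports
the percentage of regions preferring each conformation — both readings
of "percentage of AR/LCR sequence with a preference" are available and
reported separately. External per-residue annotations are the intended
input; `chou_fasman_baseline()` is a bundled deterministic stand-in
(single-residue propensity argmax, helix/sheet propensity > 1 required,
coil otherwise) for pipelines with no predictor output at hand. It
ignores all nucleation and neighbour context and should not be read as
a serious secondary-structure prediction.

## Stable-law fits

Region lengths and contents are heavy-tailed; the package fits the
four-parameter alpha-stable family with index of stability
$\alpha \in (0, 2]$, skewness $\beta \in [-1, 1]$, location $\mu$ and
scale $\sigma > 0$. Three numerical decisions:

* **Parameterization.** The S0 (location-scale continuous in $\alpha$)
  form is used throughout. Published fits of this kind frequently sit
  near $\beta \approx 1$; in the S1 form the location parameter
  diverges as $\alpha \to 1$ at fixed $\beta \ne 0$, which makes S0 the
  numerically safer choice for likelihood optimization.
* **Density.** `stable_pdf()` inverts the characteristic function
  numerically — composite Simpson on a uniform $t$ grid sized to the
  fastest phase oscillation, with the Pareto tail series taking over
  for standardized $|z| > 35$. The density matches its closed-form
  Gaussian ($\alpha = 2$, variance $2\sigma^2$) and Cauchy
  ($\alpha = 1, \beta = 0$) limits to $10^{-5}$ and integrates to 1
  within $10^{-3}$ across a lattice of shapes.
* **Fitting.** `fit_stable()` is maximum likelihood over the numeric
  density (grid + spline interpolation of the standardized log-density
  per parameter evaluation), with box constraints
  $\alpha \in [0.55, 2]$, $\beta \in [-0.999, 0.999]$ — the clipping
  keeps near-boundary skew fits stable. Starting values come from
  empirical-characteristic-function estimates of $\alpha$ and $\sigma$
  (two-point log–log regression of $-\log|\hat\varphi(t)|$), a
  quantile-skew estimate of $\beta$ and the sample median for $\mu$;
  these are computable directly from the data without tabulated
  look-ups and land close enough for the L-BFGS-B refinement in all
  tested regimes. Simulation uses the Chambers–Mallows–Stuck
  construction shifted to S0, and the simulator and density are
  cross-checked against each other in the tests.

On 5000 simulated variates at the set-point
$(\alpha, \beta, \mu, \sigma) = (1.34, 0.99, 9.73, 2.24)$ — the scale
of fitted AR-content distributions — the MLE recovers $\alpha$ within
±0.15 and $\mu$ within ±0.5, and Gaussian input drives
$\hat\alpha \ge 1.9$. Pooled region lengths across proteins (not
per-protein means) are the fitted quantity in the pipeline.

## Hyperbolic regression and kernel density

The length–content relation is summarized by the negative hyperbolic
model $y = a + b/x$, fitted by ordinary least squares in $u = 1/x$
(`fit_hyperbolic()`); $a$ is the asymptotic content at large protein
length and $b$ the curvature in percent·residues. $R^2$ is computed
from the residual and total sums of squares. Constant responses return
$b = 0$, $R^2 = 0$; a single distinct length is rank-deficient and an
error.

`kde2d_surface()` is a product-Gaussian bivariate kernel density on a
regular grid with Silverman's rule-of-thumb bandwidth per dimension —
both the kernel and the bandwidth rule are exposed because neither is
canonical for this application. Bandwidths are plain kernel standard
deviations (the MASS backend's internal /4 convention is pre-scaled
away). A zero-variance dimension is an error suggesting explicit
bandwidths.

Group contrasts use Welch's unequal-variance t test by default, with
the pooled Student variant behind a flag; the unequal-variance form is
the defensible default when class sizes and spreads differ strongly.
Discrete summaries report min/max/mean/median and a mode defined as the
midpoint of the most populated unit-width histogram bin (first bin on
ties) — a binned mode is the only meaningful one for continuous
percentages.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with full ground truth:

* **Lengths**: lognormal, median 400 residues (`sdlog` 0.55), clamped
  to [120, 2500] — disordered-protein cohorts are populated around
  ~400 aa, and the clamp keeps planted regions placeable.
* **Class mix**: (PDP, MDP, LDP) = (0.48, 0.26, 0.26), echoing the
  proportions of curated human disorder sets. Disorder intervals are
  sized so the realized fraction lands in the requested class (the
  residue budget is drawn inside the exact class band, then split into
  up to three disjoint intervals), so generator and classifier close
  the loop exactly.
* **LCR plants**: per-protein count Poisson (mean 2.9), lengths drawn
  from the stable law $(0.92, 0.99, 14.99, 4.67)$ — the scale of
  fitted LCR length distributions — truncated to [6, L/2] and rounded
  to integers (untruncated heavy tails would produce absurd lengths);
  composition Ser/Pro/Gly/Ala-enriched (18/16/13/12%), or single-residue
  homopolymers in `"homopolymer"` mode.
* **AR plants**: per-protein count Poisson (mean 4.0); hexapeptide
  motifs (defaults KLVFFA, GGVVIA, EGVLYV, KVQIIN — amyloid hexamers
  of well-studied disordered proteins) copied verbatim at recorded
  positions, disjoint from LCR plants with a 12-residue clearance.
* **Background**: uniform over the 20 residues by default — maximally
  distinguishable from the planted composition bias; any composition
  can be supplied.
* **Determinism**: one global seed drives a per-protein derived stream,
  so cohorts are byte-stable and prefix-stable under `n_proteins`
  changes.

What the generator does *not* emulate: real domain architecture,
evolutionary correlation between neighbouring residues, prion-like Q/N
tract grammar beyond composition bias, or the correlation between
disorder and composition. Passing recovery tests on these cohorts
therefore shows the *engines* are correct (the scanner recovers what
its matrix defines; the entropy detector recovers entropy-detectable
stretches), not that any particular biological cohort would be
annotated identically.

## Problem sizes in the test-suite

The suite checks each interval/statistical operation against an
independent brute-force oracle on 200 random small instances; stable
fits are validated on 5000-variate simulations (plus a 500 vs 5000
consistency comparison); planted-region recovery uses 200-protein
cohorts for the scanner and 60-protein homopolymer cohorts for the
detector. These sizes give stable verdicts for every stochastic check
at fixed seeds while keeping the default run light.

## Known limitations

* The SEG-style detector approximates the classical recursive optimal
  segmentation by a single refinement pass; deeply nested
  low-complexity structure may be reported as one region.
* `fit_stable()` constrains $\alpha \ge 0.55$; samples from much
  heavier-tailed laws will pile at the boundary.
* The hexapeptide scanner models only the additive PSSM term; physical
  property corrections used by trained web predictors are out of
  scope, so trained-predictor outputs should be supplied as annotation
  TSVs when exact reproduction matters.
* Stable fits pool regions across proteins; per-protein hierarchical
  structure is ignored.
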