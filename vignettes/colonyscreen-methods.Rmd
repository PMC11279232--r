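---
title: "Methods: growth-curve fitness and pairwise interaction classification on colony arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-curve fitness and pairwise interaction classification on colony arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonyscreen)
```

This vignette documents the statistical model behind `colonyscreen`, the
tunable parameters and their defaults, the design choices made where the
methodology was genuinely open, what the synthetic-data generator does and
does not emulate, and the package's known limitations. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The experimental design being modelled

A robotic platform arrays microbial isolates as spots on agar. Four distinct
96-array preculture plates are condensed, interleaved quadrant-wise, into one
384-array **main source plate** (MSP). Separately, each single 96-array plate
is replicated into all four quadrants of a 384-array **replicate source
plate** (RSP) — four replicate spots per isolate. Replicating an RSP on top
of the MSP produces an **interaction plate** on which every position carries
two isolates. With four RSPs per medium, each isolate is paired with three
other isolates and itself, and each unordered pair occurs twice at different
positions. Antifungal activity is read qualitatively (halo / no halo) from
spot-on-lawn assays against target yeasts; growth is quantified on control
plates without a lawn, imaged every two hours during the day over four days.

Two features of this design carry the entire analysis:

* **Same-position pairing.** The individual reference values for a pair at
  position x are read from position x of the MSP and the RSP. Any effect
  that attaches to a *position* (edge proximity, local agar thickness,
  neighborhood) cancels in the pair-vs-individual comparison.
* **Replicate spots at different positions.** The four RSP replicates of an
  isolate sit at four different positions, so their IF spread *includes*
  positional variance. The replicate-noise scale estimated from them (the
  MSD, below) is therefore deliberately conservative relative to the
  comparison it thresholds.

## 2. Growth model

Biomass per spot and timepoint is `log2(max(size × opacity, 1))`. The floor
at 1 maps an undetected or empty spot to biomass 0; how zero measurements
were handled upstream is not specified by image-analysis conventions, and the
floor is the choice that keeps the transform defined and monotone.

Growth curves are fit with the standard three-parameter Gompertz,
`y(t) = A·exp(−exp(−k(t − t_i)))`, in the parameters practitioners report
(asymptote, growth rate, inflection time); `y(t_i) = A/e`. Series with fewer
than 5 defined points are excluded (`rejected_qc`); series longer than 20
points are truncated to the first 20.

**Fitting.** Nonlinear least squares (`nls`, port algorithm) with
data-driven starts: `A₀ = max(biomass)`, `t_i₀` at the steepest observed
increase, `k₀ = max slope · e / A₀` (the Gompertz slope at `t_i` is `A·k/e`).
On nonconvergence two deterministically jittered starts are tried
(fixed factors — no RNG involved, so fitting never touches global random
state). Nonconvergence after all starts yields a rejected fit, never an
error.

**Acceptance screen.** Each parameter gets a two-sided Wald test
(estimate / SE against the standard normal; the squared z is chi-square with
1 df, which is what point-and-click statistics packages label a "Chi-square"
parameter probability). A fit is accepted iff all three p-values are
strictly below `alpha` (default 0.05), `A > 0`, `k > 0`. A numerically
perfect fit (residual sigma 0 to machine precision, as with noiseless
synthetic data) is treated as exactly determined (p = 0) rather than
undefined. In place of manual curation of aberrant curves — which is not
reproducible — fits with max |standardized residual| > 4 are rejected
(`rejected_visual`).

*Limitation discovered during validation and worth knowing about:* a spot
whose entire growth transition falls into unobserved hours (e.g. all
rise-phase images dropped; the overnight gap makes fast growers susceptible)
can have an ill-conditioned fit whose IF error is many times the typical
noise while all three parameter p-values remain tiny. The parameter-wise
significance screen does not catch this; only replicate disagreement does.

## 3. Integrated fitness, plate normalization, MSD

**IF** is the area under the fitted curve on [0, 72 h] (adaptive quadrature,
absolute tolerance 1e-8; lower limit 0 = inoculation). IF is exactly linear
in `A`.

**Plate normalization.** Plate-to-plate offsets (agar volume, humidity,
inoculum) are removed by subtracting a robust location per plate; the robust
location is a Huber M-estimate (tuning constant 1.345, MAD scale, iterated
to 1e-8), with plain median centering available via `center_method`.

Independent per-plate centering, however, subtracts each plate's
*population* location, not its technical offset. The plates of this design
have systematically different populations: an interaction plate is populated
by pairs (whose fitness distribution sits above the individual distribution
whenever pairs track their stronger partner — by roughly
`E[max(IF₁,IF₂)] − E[IF]`, i.e. ~0.56 sd of the isolate IF distribution),
and each RSP carries only a quarter of the isolates. Centering those plates
independently injects the population-median differences straight into every
cross-plate comparison, which can exceed the classification band by an order
of magnitude. `center_by_design()` therefore chains technical offsets onto
the MSP scale using anchors the design itself provides: RSP offsets from
same-isolate IF differences against the MSP, and interaction-plate offsets
from **self pairs** — spots biologically identical to the RSP individual at
the very same position, so the positional term cancels exactly. Plates
without usable anchors (non-design data) fall back to plain per-plate
centering. The spec-level `center_plate()` operation is exported and tested
on its own contract.

**MSD.** For each isolate, the sample SD (n−1) of IF over its non-border
replicates (≥2 required); the MSD is the median of those SDs over the whole
dataset. Border spots — the outermost ring of the array — are excluded
because edge spots grow atypically. The MSD is computed on centered IF, but
SD is translation-invariant, so raw IF gives the same value.

## 4. Interaction classification

With MSD `m`, a pair instance with individual references `I₁`, `I₂` and pair
value `P` is

* **cooperation** iff `P > max(I₁, I₂) + 2m`,
* **competition** iff `P < min(I₁, I₂) − 2m`,
* **neutral** otherwise — inequalities strict, so a value exactly on the
  boundary is neutral.

The rule is symmetric in the partners and measures only the *net* outcome;
per-partner directional effects are not identifiable in this design. Self
pairs have a degenerate two-sided rule (one individual reference) and are
excluded from ecological tallies by default (`include_self_pairs` to
override); they serve instead as normalization controls (§3).

Functionally, for each target yeast: **induction** iff the pair forms a halo
and neither individual does; **suppression** iff the pair forms no halo while
at least one individual does; **neutral** otherwise. The wording "one of the
isolates displayed an effect" is ambiguous when *both* partners are active
and the pair is not; the default counts that as suppression (the functional
loss is identical), and `strict_one_sided = TRUE` restricts suppression to
exactly one active partner.

Higher-level labels: **behavior profiles** count cooperative/competitive
outcomes over an isolate's three partner pairs (taken from its MSP-side
instances, which give exactly one instance per partner); **spectrum classes**
call an isolate *intrafamily* if active against both K. lactis and
S. cerevisiae but not C. boidinii, *interfamily* if active against
C. boidinii plus at least one of the other two, otherwise *none*; the
**stability matrix** tabulates per-pair class transitions between two media,
its diagonal the percentage of outcomes scored the same.

## 5. Statistics and reporting

The "log-likelihood chi-square" used for contingency tables is the G-test of
independence: `G = 2·Σ O·ln(O/E)`, df `(r−1)(c−1)`, upper-tail chi-square
p-value; zero cells contribute 0, zero margins are an error. Fisher's exact
test on 2×2 tables is computed from the hypergeometric distribution with
fixed margins; right-sided p sums tables at least as extreme in the [1,1]
cell, two-sided p sums all tables no more probable than the observed one.
Percentages are rounded half-up at the printed precision (2 decimals for
isolate-level rates, 1 elsewhere); base R's banker's rounding is not used.
No multiple-testing correction is applied anywhere, deliberately matching
screening practice; readers should treat reported p-values accordingly.

## 6. The synthetic experiment generator

`simulate_experiment()` produces a complete bundle (layouts, per-timepoint
quantification tables, halo scores, ground truth) that exercises every
pipeline stage. Its defaults state the emulated world:

| parameter | default | meaning |
|---|---|---|
| `timepoints` | 20 h-points: days 0–3, hours 8–16 every 2 h | daytime imaging over four days; ≤20 usable points per spot |
| `A_range`, `k_range`, `ti_range` | U(8,12), U(0.15,0.35) 1/h, U(8,20) h | isolate Gompertz parameters |
| `sigma` | 0.05 log2 units | per-timepoint replicate noise |
| `position_sigma` | 0.05 log2 units | per-(medium, position) bias shared across plates |
| `plate_sigma` | 0.25 log2 units | per-plate technical offset |
| `dropout` | 0.05 | per-(spot, timepoint) detection failure |
| `p_cooperation`, `p_competition` | 0.15, 0.12 | injected pair-effect fractions |
| `delta_msd` | 6 | injected effect magnitude, in expected-MSD multiples (must exceed the 2-MSD threshold) |
| `antifungal_prevalence` | LM17 0.111, PCA 0.019, SALN 0.007 | per-medium isolate activity rates (rich media select and express activity far more often than minimal media) |
| `p_suppression`, `p_induction` | 0.6, 0.006 | halo loss given an active partner / halo gain given none |

A dense every-2-h grid over the full four days would give ~49 points; with
the fitting contract capped at the *first* 20 points that would discard all
late-time data and cripple asymptote estimation, so the generator encodes
the daytime schedule that actually yields ≤20 points spanning all four days.

The **position effect** is the generator's expression of positional bias: it
is shared by all plates of a medium at the same position, so it inflates
replicate-to-replicate IF spread (replicates sit at different positions —
making the MSD conservative) while cancelling exactly in the same-position
pair-vs-individual comparison. This is precisely the structure the
experimental design assumes; omitting it would make the ±2·MSD band only
~1.4 comparison-sigmas wide and the generator's own null unrecoverable.

**Pair growth.** No generative model of co-culture biomass is established
for this assay, so the generator must choose one. The pair spot grows as a
Gompertz with the *dominant* partner's shape (the partner with the larger
individual IF) and its asymptote rescaled so the pair's true IF equals the
class target: `max(IF₁,IF₂) + δ` for cooperation, `min(IF₁,IF₂) − δ` for
competition (`δ = delta_msd ×` expected MSD), and dominant ± at most half an
expected MSD for neutral pairs. Two alternatives were examined and rejected
during implementation: (a) the pointwise *maximum* of the two partner curves
is not a Gompertz (kinked or double-sigmoid), and measuring it through a
Gompertz fit produced IF errors an order of magnitude larger than the
classification band — the injected classes would be unrecoverable by any
correct pipeline; (b) placing neutral pairs uniformly across the full ±2·MSD
neutral band puts mass on the band edges, where any noise flips the label,
contradicting the requirement that the generator's null be recoverable.
Placement well inside the band (±0.5 MSD) makes "neutral" a property of the
world rather than a coin flip at the boundary. The injected-effect
calibration `expected_msd()` pushes Monte-Carlo replicate sets through the
*actual* QC + fitting + integration path (deterministic given the config
seed), so δ is expressed in the units the classifier will actually see.

**Halo generation** is deterministic given the isolate flags and the
per-pair suppression/induction draws; scored classes therefore recover the
functional ground truth exactly wherever the spots are scored. Partial
source plates are filled interior-first, so every isolate keeps four usable
(non-border) replicates for MSD estimation even in small simulations.

**What the generator does not emulate** — and what a green test therefore
does not establish: volatile-mediated and higher-order neighbor effects;
quantitative halo sizes (scores are presence/absence); colony morphology and
image-level artifacts; growth models other than Gompertz (a real co-culture
spot may be bi-phasic — the generator deliberately stays inside the fitted
model family); correlated (non-i.i.d.) dropout; medium-specific growth
parameter distributions (media differ only in antifungal prevalence).

## 7. Numerical choices

* IF quadrature: `stats::integrate`, abs. tol 1e-8 (validated against a
  Δt = 0.001 trapezoid oracle to 1e-6).
* Huber location: fixed MAD scale, IRLS to 1e-8; zero MAD falls back to the
  median.
* Ties at the ±2·MSD boundary: neutral (strict inequalities).
* Rounding: half away from zero at the caller's precision, with a 1e-9
  guard against binary representation artifacts.
* Gompertz fit bounds: `A ∈ [1e-8, 1e4]`, `k ∈ [1e-4, 20]`,
  `t_i ∈ [min(t)−200, max(t)+500]`; flat series are rejected before fitting
  (a constant is fit perfectly by degenerate parameters).
* All generator randomness flows from one seeded local RNG; the session's
  `.Random.seed` is saved and restored, and `expected_msd()` derives its own
  fixed sub-seed, so bundles are byte-reproducible.

## 8. Known limitations

* Net-outcome classification only; directional partner effects are out of
  reach of this design.
* The MSD is a single global noise scale; spot-level IF uncertainty is
  heteroscedastic (see the ill-conditioned-fit caveat in §2), so
  borderline calls near ±2·MSD should be read with that in mind.
* Additive log2-biomass offsets transmit into IF with a gain that depends
  on curve shape (≈50–65× across the default parameter ranges); design-aware
  centering removes the mean transmission per plate but a shape-dependent
  residual (~0.3 MSD at default noise) remains in cross-plate comparisons.
* Suppression/induction rates are lower bounds in spirit: qualitative
  scoring cannot see quantitative halo changes.
* The G-test and Fisher helpers expect complete tables of counts; they do
  not model the pairing structure of instances (two instances per unordered
  pair are counted separately, as the screening design intends).
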