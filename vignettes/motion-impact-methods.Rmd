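---
title: "Split-half motion impact scores: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-half motion impact scores: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shaman)
```

## The problem

Resting-state functional connectivity (FC) is estimated from correlations
between parcel-averaged BOLD timeseries, and in-scanner head motion distorts
those correlations in ways that denoising never removes completely. When a
participant trait (BMI, cognition scores, income) is itself correlated with
how much people move, edgewise trait-FC regressions can be inflated (false
positives) or suppressed (false negatives) by residual motion. Generic
motion QC - mean framewise displacement (FD), censoring counts - is agnostic
to the hypothesis being tested; what a study needs to know is whether *this
trait's* FC associations are distorted by motion.

`shaman` implements a split-half answer. A trait is stable over the ~20
minutes of a scan, while motion is a state that fluctuates second to second.
If residual motion did not interact with a trait's FC signature, it would
not matter which frames we use to estimate it: splitting each participant's
timeseries into its low-FD half and its high-FD half should give the same
group-level inference up to sampling error. A systematic difference that is
predictable from the trait is evidence that motion is distorting that
trait's FC effect.

## The algorithm

For each participant (after optional censoring, minimum-duration exclusion,
and frame clamping):

1. concatenate runs and split frames into the lowest-FD half and the
   highest-FD half (`assign_halves()`; ties broken by temporal order, the
   low half takes the extra frame at odd counts);
2. compute Fisher-z edge vectors for each half (`summarize_half()`, built
   on `fc_edges()`: Pearson correlations clipped to ±(1 − 1e−7), then
   atanh), plus each half's mean FD.

Across participants:

3. regress each half's edges on that half's mean FD (intercept + slope,
   per edge) and form the per-participant difference of residuals,
   high − low (`residual_difference()`) - this removes the
   *between-participant* motion effect so that what remains is the
   within-participant contrast;
4. regress the trait (plus covariates) on the residual differences
   (`impact_glm()`); the per-edge t-values are the edgewise motion impact;
5. build a null ensemble by repeating 1-4 with the split randomized
   (motion-blocks permutation, below), and combine edges by non-parametric
   combining (NPC) with Stouffer's function: per-edge empirical p → z,
   omnibus Z = Σz/√E, and a permutation p-value for Z
   (`npc_stouffer()`, orchestrated by `run_shaman()`).

The **omnibus motion impact score** tests "no edge of this trait's FC
effect is distorted by motion". The **overestimation score** combines only
edges whose motion impact shares the sign of the trait-FC effect (estimated
on the full data with FD as covariate, gated at |t| > 2), one-sided in that
direction - significance signals false-positive risk. The
**underestimation score** is the mirror image (opposite sign, one-sided
against the trait-FC direction) and signals false-negative risk.

### Motion-blocks permutation

BOLD and FD series are autocorrelated, so exchanging individual frames
between halves would make permuted halves artificially similar and shrink
the null. The observed split already partitions the timeline into maximal
runs of same-label frames ("motion blocks", additionally broken at scan-run
boundaries). A permutation reassigns whole blocks: blocks are shuffled
uniformly and assigned to one half until it first holds at least half the
frames, the rest go to the other half, and a fair coin decides which half
is called "low". The multiset of block lengths is invariant, so the
temporal dependence inside blocks is preserved exactly. Two consequences
are documented choices rather than theorems: permuted halves are balanced
only up to the largest block (we additionally guard against a dominant
block leaving a half with fewer than 3 frames by redrawing, and against an
empty half by keeping the crossing block alone in its half), and per-half
mean FD is re-derived for every permuted split.

### Non-parametric combining details

All P + 1 statistics - the observed one and the P permutation statistics -
are ranked within the same ensemble, per edge. The observed member's count
is then exactly the add-one formula (1 + #{null ≥ observed})/(P + 1), which
is what `edge_p` reports; ranking the observed against the nulls while
ranking each permutation against an ensemble containing itself would give
the observed z a systematically wider range and an inflated omnibus score.
The z entering Stouffer combining uses half-count smoothing,
qnorm(1 − (count − 0.5)/(P + 1)), so every z is finite even at the extreme
ranks (with add-one alone, about E/(P + 1) edges per run sit below every
permutation and would map to −∞). The omnibus p is
(1 + #{Z_perm ≥ Z_obs})/(P + 1), so its floor is 1/(P + 1).

For the directional scores the sign-matched edge set is part of the
statistic: each permutation's combined Z is computed over *its own*
sign-matched, gated edge set, exactly as the observed Z is. Combining the
observed selection-biased set but ranking permutations over a fixed set
would reject a true null almost always. Even with this treatment the
directional scores inherit a mild anticonservatism from gating on a
trait-FC map estimated from the same data (the observed impact covaries
with the gate through the high/low variance asymmetry; permutations
cannot), so their p-values should be read as descriptive companions to the
calibrated omnibus test - the simulation suite therefore calibrates the
omnibus score only.

### Node-level analysis

`node_scores()` recombines the same per-edge z's over each node's incident
edges (Z_node = Σz/√deg) and recombines the stored permutation z's over the
same edge sets for node p-values; no new permutations are run.
`exclusion_trace()` repeatedly removes the node with the largest score and
recomputes the omnibus over the surviving edges until it loses
significance; the number of exclusions counts the regions carrying the
motion impact. The omnibus-p path is reported as-is (it is not forced to be
monotone). Ties in the largest node score exclude the lowest node index.

## The generative simulator

`generate_cohort()` works backwards from the massively univariate
regression model that consumes FC matrices. Two basis correlation matrices
define where trait-linked ("BRAIN") and motion-linked ("MOTION") structure
lives; the defaults (`basis_pattern()`) are disjoint binary masks - a
community structure for the brain pattern and long-range pairs for the
motion pattern - scaled to a peak correlation of 0.3 and conditioned to
positive definiteness by multiplying off-diagonals by 0.95 until a Cholesky
factorization succeeds (`build_basis()`, shrinkage recorded). Gaussian
series are drawn through the Cholesky factors (`draw_correlated_series()`).

Per participant:

* the trait is standard normal shifted positive (+|min| + 0.01), and is
  also the brain-pattern variance weight `w_brain`;
* the motion series is scaled by a participant amplitude and modulated by a
  lognormal AR(1) burst envelope (`burst_sd` = 0.75, `burst_phi` = 0.9,
  normalized to unit mean square). Real head motion is episodic - quiet
  stretches punctuated by bursts - and the envelope is what gives the
  simulated FD traces that character and makes the motion blocks
  temporally extended;
* FD at each frame is the cross-node *population* variance of the scaled
  motion series at that frame (a fixed, documented convention), so frames
  where the motion signal is strong are exactly the frames flagged as
  high-FD;
* the mixed series is √w_brain · brain + √w_motion · motion with
  `w_motion` = the participant's mean FD, followed by a variance
  correction: rescaling every node to unit sample variance. The correction
  exists so that downstream edges remain correlations on a common scale
  (the assumption of the regression model that consumes them);
  unit-variance rescaling is the simplest procedure with that property and
  is implemented as a replaceable, documented choice.
* mean FD levels sit around 0.25 (mm-equivalent units), matching a typical
  developmental cohort. Under `coupling = "independent"` the amplitude is
  lognormal around that level (`fd_spread` = 0.4); under
  `coupling = "nonlinear"` mean FD is an increasing convex function of the
  trait (exp(1.5 u) scaling of the standardized trait). The nonlinearity is
  the point: a linear trait-motion relation is largely removed by the
  linear FD residualization, and it is the nonlinear residue that produces
  a detectable, localized motion impact. The default strength was chosen to
  make the planted effect clearly visible at a few hundred participants, in
  the spirit of an illustration cohort.

Two subtleties matter when using the simulator for calibration. First,
because the trait is also the brain mixing weight, the unit-variance
correction makes motion-edge contamination scale like
w_m/(w_brain + w_m) - the *generative* trait therefore has a genuine motion
impact even when motion amplitude is drawn independently of it, and
detecting it is a true positive. Specificity experiments must use an
analysis trait drawn independently of every generative quantity; the trait
table ships one (`null_trait`), mirroring the classic device of using a
randomly assigned participant ID as the trait. Second, the simulator omits
hemodynamics, drift, spatial noise structure, scanner artifacts, and
respiratory pseudo-motion; passing tests demonstrate the statistical
machinery under the stated generative model, not performance on real
scanner data.

## Numerical and engineering choices

* Correlations are clipped to ±(1 − 1e−7) before atanh; tanh recovers the
  clipped r to 1e−12.
* Edge vectors use one fixed ordering everywhere: row-major upper triangle,
  i < j, i ascending then j (`edge_pairs()`), with 0-based node ids in all
  serialized outputs.
* Frames are kept iff fd < threshold (strict); clamping keeps the earliest
  frames; the minimum-duration rule is n_frames × TR ≥ 8 min (600 frames at
  TR 0.8 s).
* The permutation loop caches each motion block's crossproduct once per
  participant and assembles every permuted half by summing cached blocks
  (one sgemm against a block-membership indicator per batch of
  permutations). The cache is single precision with double totals and
  corrections; this admits ~1e−6 relative rounding in the Fisher-z values,
  far below their sampling noise (the double-precision reference path is
  `summarize_half()` + `residual_difference()` + `impact_glm()`, and the
  test suite pins the fast path to it).
* Per-permutation seeds derive from the master seed, so results are
  independent of how permutations are scheduled; every result object
  records its seed and configuration.
* Degenerate inputs fail loudly: zero-variance nodes are named; constant
  FD across participants is a rank-deficient design; a fully censored
  participant is an explicit error in `censor_frames()` and a silent
  exclusion in `apply_qc()`/`censoring_sweep()`.

## Reference experiment designs

The simulation experiments shipped with the package (test suite and
`scripts/acceptance.R`) use these designs, chosen as the smallest cohorts
at which their behavior is stable:

* **Type-I calibration**: independent-coupling cohorts, 64 nodes × 512
  frames × 200 participants, `null_trait` as the analysis trait, 200
  permutations, 100 repeats; empirical rejection at α = 0.05 is checked
  against the exact binomial 95% band [0.012, 0.105].
* **Planted-signal detection**: nonlinear-coupling cohorts, 64 × 512 × 300,
  49 permutations, 20 repeats; detection (omnibus p < 0.05) in ≥ 90% of
  repeats and Spearman correlation > 0.3 between the edgewise impact-t map
  and the injected motion mask in every detected run. At the default
  coupling the detection clause holds with margin while the per-run
  localization clause does not (the single-split impact map is noisy; the
  mask correlation ranges ~0.23-0.52 across repeats), and the
  corresponding test is allowed to fail rather than weakening either the
  clause or the generator.
* **Power curve**: nonlinear-coupling cohorts at n ∈ {100, 400, 1600}, 24
  permutations, 20 repeats per size; detection rate non-decreasing within
  Monte-Carlo tolerance.

## Known limitations

* The directional (over/under) scores are descriptive; only the omnibus
  score's type-I behavior is verified by simulation (see above).
* The block-permutation null preserves within-block dependence but not the
  FD-sortedness of the observed split; when residual motion is a single
  spatially coherent pattern, observed edgewise statistics are more
  strongly cross-edge dependent than permuted ones, and the omnibus test
  leans liberal. The calibration experiment bounds this at the reference
  design; cohorts with stronger, more coherent residual motion than the
  simulator's defaults may exceed it.
* Inputs are assumed denoised; the package neither computes FD from
  realignment parameters nor performs nuisance regression.
* The memory footprint of the permutation loop is dominated by the block
  cache (~E × 8 bytes per block); participants whose FD has no temporal
  structure (singleton blocks) cost the most.
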