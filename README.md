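# shaman

Split-Half Analysis of Motion-Associated Networks: trait-specific motion
impact scores for resting-state functional connectivity (FC).

## The problem

Head motion corrupts resting-state FC in ways denoising does not fully
remove, and traits that correlate with motion (body habitus, cognition,
psychiatric symptoms) can acquire spurious - or lose genuine - FC
associations as a result. Conventional motion QC (mean framewise
displacement, censoring rates) is agnostic to the hypothesis under test.
`shaman` assigns a **motion impact score to a specific trait-FC analysis**:
a permutation-calibrated omnibus statistic telling you whether residual
motion significantly distorts that trait's edgewise FC effects, plus
directional variants separating overestimation (false-positive risk) from
underestimation (false-negative risk).

It is written for neuroimaging statisticians and BWAS practitioners who
have parcellated, denoised BOLD timeseries with aligned FD traces and a
participant trait table.

## The statistic

A trait is stable over a scan; motion is a state. Each participant's
timeseries is split into its low-FD and high-FD halves, and Fisher-z edge
vectors `z_low`, `z_high` (E = n(n−1)/2 edges) are computed per half.
Across participants, each half is residualized on its mean FD, and for each
edge the difference of residuals is regressed on the trait:

    Δ_i = resid(z_high,i ~ 1 + FD_high) − resid(z_low,i ~ 1 + FD_low)
    Δ_e ~ β0 + β1 · trait (+ covariates)          (per edge e)

Under "motion does not interact with this trait's FC", β1 = 0 at every
edge. The per-edge t-values are ranked against a null ensemble built by
**motion-blocks permutation** (contiguous same-label frame runs are
reassigned to halves whole, preserving temporal autocorrelation), and
combined by non-parametric combining with Stouffer's function:

    z_e = Φ⁻¹(1 − p_e),   Z = Σ_e z_e / √E,   p = (1 + #{Z_perm ≥ Z}) / (1 + P)

`Z` is the **motion impact score**. Overestimation/underestimation scores
combine only edges whose impact is aligned/anti-aligned with the trait-FC
effect (gated at |t| > 2), one-sided.

The package also ships the generative simulator used to validate the
machinery (correlated Gaussian node series mixing a trait-weighted "brain"
pattern with an FD-weighted "motion" pattern, FD defined as the per-frame
cross-node variance of the motion series), node-level scores with iterative
region exclusion, and the companion QC analyses (frame censoring sweeps,
trait-FD correlations, trait-FC/motion-FC effect matrices, the log-log
variance-vs-motion denoising benchmark).

## Worked example

```r
library(shaman)

# a simulated cohort with a nonlinear trait-motion coupling (the failure
# mode that linear FD residualization cannot fix)
cohort <- generate_cohort(n_nodes = 64, n_frames = 512,
                          n_participants = 300,
                          coupling = "nonlinear", seed = 7)

res <- run_shaman(cohort, trait = "trait", n_perm = 199, seed = 11)
res
#> <motion_impact> 64 nodes, 2016 edges, 199 permutations (seed 11)
#>   omnibus Z = 21.555 (p = 0.005)
#>   overestimation Z = 53.289 (p = 0.005), 567 edges
#>   underestimation Z = 1.692 (p = 1), 13 edges

# where does the impact live?
ns <- node_scores(res)
head(ns[order(-ns$z), ], 3)
#>    node n_edges        z     p
#> 56   56      63 6.992998 0.005
#> 64   64      63 6.646696 0.005
#> 45   45      63 6.084267 0.005

tr <- exclusion_trace(res)
tr$n_contributing
#> [1] 33
```

The omnibus p of 0.005 (its floor at 199 permutations) says motion
significantly distorts this trait's FC effects; the overestimation score
carries the signal, i.e. the distortion *inflates* the trait-FC effect.
The node table localizes the impact (here: nodes inside the injected
long-range motion pattern), and the exclusion trace says 33 of 64 regions
must be removed before the whole-brain impact loses significance - the
distortion is spatially distributed, not a single bad parcel.

On a real cohort, replace the simulated object with
`read_cohort("dir/")` (delimited-text timeseries + FD + trait CSV, see
`?write_cohort` for the layout), apply `apply_qc()` (censoring at an FD
threshold in mm, the 8-minute minimum-data rule, optional 600-frame
clamp), and pass the trait column name. A thin command-line wrapper with
`simulate` / `shaman` / `trait-effects` / `node-analysis` / `qc`
subcommands lives at `inst/cli/shaman-cli.R`.

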