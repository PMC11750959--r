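---
title: "Methods: snapshot flux balance and methylome integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snapshot flux balance and methylome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmeth)
```

`fluxmeth` connects two measurements made on the same carbon-limited
heterotrophic cell culture: daily metabolite concentrations, turned into
reaction fluxes through a stoichiometric model, and whole-genome
bisulfite sequencing counts, turned into differentially methylated
cytosines (DMCs) and regions (DMRs) that are then joined to expression
changes. This vignette records the modeling assumptions and the
numerical choices behind each stage, so that defaults are not mysterious.

## 1. Snapshot flux balance analysis

A `reaction_network()` holds metabolites, reactions with flux bounds,
and the stoichiometric matrix `S`. Internal metabolites obey the
steady-state constraint `S_int v = 0`; boundary metabolites (medium
components, exported biomass fractions) do not accumulate constraints.

Each day of the culture is treated as an independent *snapshot*: the
culture is assumed to be in quasi-steady state over the day, and the
measured exchange fluxes for that day are imposed as constraints. Given
the measured set `M` with values `b`, the solver finds

  minimize ‖v‖²  subject to  S_int v = 0,  lb ≤ v ≤ ub,  v_M = b.

Choices worth stating:

* **Quadratic norm objective.** With equality-constrained measurements
  the feasible set can still be under-determined (internal cycles). The
  minimum-norm solution is the unique least-action representative and
  makes the solve a strictly convex quadratic program with a unique
  optimum, invariant to reaction ordering. Objectives like "maximize
  biomass" are inappropriate here because biomass production is itself a
  measured quantity.
* **Two-stage relaxation.** Measured values can be mutually
  inconsistent (they come from independently fitted curves). Stage one
  finds the minimum achievable residual ‖v_M − b‖ over the steady-state
  polytope; stage two minimizes ‖v‖² among the solutions attaining that
  residual. When measurements are consistent this reduces to exact
  constraint satisfaction; when not, the report carries per-constraint
  residuals instead of failing.
* **Hand-rolled active-set QP.** The solver
  (`fluxmeth:::qp_active_set`) is a dense primal active-set method for
  strictly convex objectives with equality constraints and box bounds.
  Equality consistency is checked by comparing the ranks of `A` and
  `[A | b]` (rank-revealing QR); singular working-set KKT systems fall
  back to an SVD pseudoinverse; working-set cycling is detected by
  signature and reported as infeasibility. It is validated in the test
  suite against directly assembled KKT systems.
* **Flux activity.** For an internal metabolite, the producing and
  consuming flux sums are equal at steady state; `flux_activity()`
  reports both as a turnover measure for cycle intermediates (for
  example S-adenosyl-methionine, whose turnover is the methylation
  donor flux).

## 2. Concentration time series to exchange fluxes

`fit_concentration_curve()` fits one smooth curve per component and
condition and differentiates it at the snapshot days. The fit is a
penalized truncated-power cubic spline with the penalty chosen by
generalized cross-validation over a `10^seq(-6, 6, 0.5)` grid. This
basis is exact for polynomials up to degree three, so simulated linear
accumulation is recovered to machine precision; with fewer than four
distinct days the fit degrades gracefully to a quadratic or straight
line. Derivatives are analytic, not finite differences. No
extrapolation is permitted: requesting a derivative outside the fitted
day range is an error rather than a guess.

Replicate standard errors of the derivative are obtained by refitting
each replicate separately (`estimate_exchange_flux()` attaches them as
an `se` attribute), which is what the noisy-recovery tests check
against.

Growth fold changes are reported with `round_half_up()` (half away from
zero, one decimal), matching how such ratios are conventionally printed;
`round()`'s banker's rounding would turn 197.6/160 into 1.2 as well but
differs on exact halves.

## 3. DMC calling

`call_dmcs()` implements a smoothed two-group Wald test on
beta-binomial counts:

* **Smoothing.** Group methylation at a locus is the pooled proportion
  over a ±250 bp window (500 bp total, configurable), computed per
  chromosome, context and group. Smoothing borrows strength exactly as
  the coverage suggests: windows pool *counts*, not per-locus ratios.
* **Dispersion.** Replicate overdispersion is estimated per locus by
  method of moments and shrunk toward the context-wide median with a
  weight proportional to coverage against a pseudo-coverage prior
  (default 100 reads, prior dispersion 0.05). Single-replicate groups
  fall back to the prior with a warning.
* **Variance of the smoothed estimator.** Because the estimator pools
  every (sample, locus) observation in the window, its beta-binomial
  variance sums `n_j (1 + (n_j − 1) ρ)` over those observations. Using
  the identity `n(1+(n−1)ρ) = n(1−ρ) + ρ n²`, both pieces come from
  windowed sums of `N` and `N²`; ignoring this (using single-locus
  coverage with a window-smoothed mean) would overstate the variance
  and destroy power.
* **Retention rule.** A locus is retained when `|Δm|` exceeds its
  context threshold (defaults 0.10 / 0.10 / 0.07 for CG / CHG / CHH)
  *and* the posterior probability `1 − 2Φ(−|stat|)` exceeds 0.9999.
  Proportions are clipped to `[1e-3, 1 − 1e-3]` before variance
  computation so zero-methylation contexts (CHH) do not produce
  degenerate statistics.

## 4. DMR segmentation

Significant same-sign loci at most 100 bp apart are clustered; a
cluster spans its first to last significant site and survives when the
span is ≥ 50 bp, contains ≥ 3 same-context sites, and ≥ 50 % of those
sites are individually significant. Surviving same-sign regions closer
than 100 bp are merged.

Smoothing makes neighbouring per-site tests strongly correlated: one
window-level fluctuation can light up several adjacent loci and imitate
a multi-site region. To control region-level type I error, every
candidate is **confirmed on its own raw pooled counts** — a Wald test
without smoothing, Bonferroni-corrected over all scanned testable loci.
On fully null simulations (200 000 loci, 3 vs 3 at 30×) this brings the
expected genome-wide false DMR count to essentially zero while leaving
planted effects (whose raw evidence is strong) untouched.

The region difference is the coverage-weighted mean of per-site
differences; regions are labeled `hyper` / `hypo` when it clears the
context direction cutoff (0.25 / 0.25 / 0.10), and kept as `weak`
otherwise so that tallies remain a partition.

## 5. Feature assignment and expression integration

Promoters are the 2 kb upstream of the TSS, strand-aware and clipped at
chromosome bounds. DMR categories follow the precedence
promoter > exon > intron > extragenic TE > intergenic, with ties at a
tier broken by larger overlap; promoter or intron DMRs that also touch
a transposable element are relabeled `TE-promoter` / `TE-intron`. The
assignment is a partition: category counts always sum to the number of
DMRs.

DEGs are the conjunction CPM > 10, padj < 0.05 and |log2FC| > 1;
adjusted p-values are consumed, never computed here. Genic-category
DMRs over DEGs give DMEG records; promoter-category DMRs (including
TE-promoter) give promDMEG records, one per (DMR, gene) pair.
`classify_quadrants()` crosses the signs of the methylation and
expression changes (Me±/Exp±); records with a zero difference are
flagged unclassifiable and excluded from tallies with a warning.

## 6. Metagene profiles

`metagene_profile()` averages pooled methylation into 10 upstream-flank
bins (2 kb), 20 proportionally scaled gene-body bins and 10
downstream-flank bins, per context and group, mirroring bins for minus
strand features. Flank bins that fall off the chromosome are missing
(`NA`), never zero. On a uniform binomial methylome the profile is flat
at the generating mean to within binomial noise, which the test suite
checks bin by bin.

## 7. Synthetic data

The simulators exist so that the full pipeline runs at desk scale with
known ground truth: a 13-reaction toy network whose true flux vector is
feasible by construction; concentration series whose slopes *are* the
exchange fluxes (optionally with multiplicative noise); a three-
chromosome annotated methylome with beta-binomial counts and planted
DMRs recorded in a truth table; and an expression table with calibrated
null adjusted p-values and planted fold changes, optionally
anticorrelated with planted promoter methylation. Every generator is a
pure function of its arguments and seed.

## 8. Running the pipeline

```{r, eval = FALSE}
cfg <- default_config()
run <- run_pipeline(cfg, out_dir = "run1")
print(run$report)
```

The configuration lists every analysis threshold in one place and can
be written to and read from YAML (`write_config()`, `load_config()`);
`run_pipeline()` logs the seed, a config hash and every assumed
parameter so a run can be reproduced from its log alone.
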