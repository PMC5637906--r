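---
title: "Methods: amino acid isotope paleodiet inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amino acid isotope paleodiet inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodiet)
```

This vignette documents the models implemented in `paleodiet`, the
assumptions behind them, the defaults and why they were chosen, the
numerical choices that affect results, and what the synthetic-data tests
do and do not demonstrate about real data.

## The inference problem

Bone collagen integrates dietary protein over years. Its bulk δ15N rises
both with trophic level and with the δ15N baseline of the local
ecosystem, so a human eating crops from 15N-enriched, anthropogenically
manipulated soils is indistinguishable — in bulk — from one eating large
amounts of fish. Compound-specific amino acid analysis breaks the
degeneracy: phenylalanine nitrogen passes from diet to consumer with
little fractionation ("source" amino acid), while glutamic acid is
enriched by a roughly constant Δ<sub>glu-phe</sub> per trophic transfer
("trophic" amino acid). The difference δ15N_glu − δ15N_phe within one
sample therefore measures trophic position independent of baseline, and
δ15N_phe itself measures the baseline mix the consumer fed on.

## Trophic position equations and constants

With β the producer glu−phe offset, the package computes

$$TP = \frac{\delta^{15}N_{glu} - \delta^{15}N_{phe} + \beta}{\Delta_{glu\text{-}phe}} + 1$$

using β<sub>marine</sub> = −3.4 ‰ for aquatic food webs and
β<sub>terrestrial</sub> = +8.4 ‰ for C3 vascular plant webs. Note the
sign convention: the terrestrial β is *added* with its positive value
(+8.4), which is the convention under which entirely herbivorous
terrestrial consumers with δ15N_glu − δ15N_phe = Δ − β land exactly on
TP = 2. Δ<sub>glu-phe</sub> defaults to 7.6 ‰, the accepted mammalian
value; recent work suggests marine consumers may be up to ~1.5 ‰ lower,
which is why the constant (and an uncertainty for it) is exposed in
`nitrogen_params()` rather than hard-wired. C4 plants have a
substantially lower β and are *not* covered by the terrestrial equation;
the package assumes C3-dominated terrestrial diets.

The mixed-diet equation interpolates the two βs linearly in the marine
protein fraction `f`. Three estimators of `f` are provided; their
agreement on the same data is the package's central cross-validation:

1. `f_marine_htl()` inverts the mixed equation at an assumed consumer
   trophic level. The default 2.21 (range 2.04–2.76) is the FAO
   food-supply-derived global human trophic level; it assumes modern
   subsistence-diet trophic ecology applies to prehistoric populations.
2. `f_marine_phe()` is a two-source mass balance on δ15N_phe between a
   terrestrial and a marine baseline end member. It assumes consumer
   phenylalanine reflects dietary phenylalanine with no fractionation
   and that two end members span the baseline space.
3. `f_marine_bulk()` is the classical bulk collagen δ13C mixing model;
   it needs an assumed diet-to-collagen enrichment (+5 ‰ for plant
   end members, `to_collagen_basis()`) and is biased toward protein
   sources.

Default phenylalanine end members: terrestrial 22.7 ± 0.9 ‰ (an
archaeologically preserved totora reed, the only measured plant
consistent with mass balance for the human data this methodology was
built around) and marine 0.4 ± 0.6 ‰ (the most 15N-depleted measured
fish) for the two-source estimator. The end-member inversion
(`infer_terrestrial_endmember()`) instead pairs with the *average* fish
value 1.0 ‰ — the two routes deliberately use the end member each
question calls for, and both are arguments, not constants. Published
human averages appear as 11.5 ‰ in one context and 11.6 ‰ in another
(rounding of the same data); the package takes whatever the caller
passes and the acceptance checks use each where its source table does.

Mass-balance violations (`f` outside [0, 1]) are returned as computed
and flagged `feasible = FALSE`, never clamped silently: an infeasible
`f` is diagnostic evidence that an end member is wrong, which is
precisely how unsuitable terrestrial end members (modern soils, palm
nut) are rejected.

## Error propagation

Uncertainties are first-order (delta-method) standard deviations
treating all inputs — the two measured δ values, the constants β and Δ,
the end members and the assumed trophic level — as independent
Gaussians. The partial derivatives are written out in the source next to
each estimator. Constant uncertainties default to zero (published
analyses include them but do not print their values); set
`sd_beta_*` / `sd_delta` in `nitrogen_params()` to include them.

The test suite pins every analytic sd to a 10⁶-draw Monte Carlo
simulation within 2 % relative. One honest caveat: the two-source ratio
`f = (x − t)/(m − t)` has no finite moments when the denominator is
Gaussian, so the Monte-Carlo comparison is meaningful only in the
linearization regime where the end-member gap is many standard
deviations wide (true of the phenylalanine end members: a 22.3 ‰ gap
with ~1 ‰ sds). With the wide bulk-δ13C end-member sds (±2.0 ‰ on a
9.2 ‰ gap) rare near-zero denominators inflate the empirical sd beyond
the first-order value; the reported analytic sd is then the standard
Phillips & Gregg two-source value, which is what practitioners quote,
and the Monte-Carlo equivalence tests use configurations inside the
valid regime.

## EAA fingerprinting and the Bayesian mixer

Essential amino acids cannot be synthesized by metazoans and reach
collagen with minimal carbon fractionation, so the *relative pattern* of
δ13C across Leu/Lys/Phe/Val is a fingerprint of protein sources.
`center_patterns()` removes each sample's mean over the included EAAs
(absolute values drop out); `pca_scores()` is ordinary PCA with a
deterministic sign convention (largest-magnitude loading element
positive). Source group membership is an explicit user input to
`build_source_groups()` — published groupings were made visually from
score plots and differ slightly between text and figure in the source
literature, so hard-coding them would be wrong.

`fit_mixture()` estimates source proportions under: flat Dirichlet prior
on the proportion vector; observed centered value for EAA *k* ~
Normal(Σᵢ pᵢ μᵢₖ, σₖ²) with σₖ² = consumer analytical variance +
Σᵢ pᵢ² sᵢₖ² + a model-error variance (default 0.4 ‰, the analytical
replicate scale). Lysine participates in centering and PCA but is
excluded from the likelihood by default (`use_eaas = Leu, Phe, Val`)
because it discriminates marine from terrestrial sources poorly; using a
different EAA set for centering and mixing is a hard error. The sampler
is random-walk Metropolis on additive log-ratio coordinates (the flat
Dirichlet contributes a Σ log pₖ Jacobian), 4 chains × 4000 kept
iterations by default, with Robbins–Monro step adaptation toward 30 %
acceptance during warmup only (so the kept chain is a valid fixed-kernel
MCMC). Convergence is monitored with split R-hat (flag threshold 1.05);
a non-converged fit warns and marks the result rather than failing
silently. A fixed seed gives bit-identical posteriors.

This Gaussian/Dirichlet model is this package's own specification: it is
*not* a clone of FRUITS/OpenBUGS, whose exact likelihood, offset and
concentration-dependence machinery are out of scope. Published
consumer-level posterior percentages that depend on unpublished
supplementary per-sample tables are consequently not reproducible here
and are not asserted anywhere in the tests.

## Radiocarbon calibration

`calibrate()` uses the standard single-date likelihood
exp(−(y − μ(θ))²/2(σ_y² + σ(θ)²)) evaluated on a 1-year grid (curves
resampled by linear interpolation), normalized to a discrete posterior.
Intervals are highest-posterior-density sets found by greedy mass
accumulation over grid years, merged into runs, reported in AD
(= 1950 − cal BP) at 95.4 % by default. Posterior mass > 0.1 % at a grid
edge sets a truncation flag. `mix_curves()` forms the diet-weighted
curve: the reservoir offset ΔR (default −83 ± 34 ¹⁴C yr) is applied to
the marine μ *before* mixing (the operational convention when the order
is unstated), means mix linearly in `f`, variances combine with (1−f)²
and f² weights plus an optional (μ_mar + ΔR − μ_atm)² f_sd² term for
uncertainty in `f` itself (f_sd defaults to 0, matching point-f
practice). Real calibration curve files are not bundled; tests run on
synthetic curves with known closed forms, and users supply IntCal
distribution files for calendar-date work.

## Synthetic data: what it shows and what it cannot

`simulate_nitrogen()` draws consumers by forward-running the mass
balance: the phenylalanine baseline is the convex end-member-mean mix at
`f_true`, glutamic acid is set so the mixed TP equation holds at
(`f_true`, `tp_true`), and independent Gaussian analytical noise
(0.41 ‰, the published replicate average) is added last. Synthetic human
`tp_true` defaults to uniform draws over the empirical global range
2.04–2.76. With zero noise every estimator inverts the generator exactly
— a self-consistency proof of the algebra, deliberately kept exact by
putting end-member scatter into the estimators' error budget rather
than the forward draw. `simulate_eaa()` builds four invented source
clusters (zero-sum centered means separated by ~3–6 ‰ in the
Leu/Phe/Val subspace, within-group scatter 0.38 ‰ = the published
carbon replicate average) and consumers as convex mixtures.

Passing tests on these simulations demonstrate internal consistency,
unbiasedness within propagated error (200-consumer recovery runs) and
frequentist coverage of the mixer's credible intervals (100 seeded
replicates, ≥ 90 % at the 95 % level). They cannot validate the
*constants* (β, Δ, end members) against nature, detect correlated
analytical errors (only per-AA replicate sds are published, so noise is
modeled independent), or certify that real food webs have only two
baseline end members. Problem sizes in the default suite (10⁶ Monte
Carlo draws, 200-consumer cohorts, 100 coverage replicates) were chosen
as the smallest that make the respective statistical bounds sharp.

## Degenerate inputs and tie-breaks

- Equal end-member means: degenerate-model error, never NaN.
- `f = 1` in the terrestrial end-member inversion: domain error (no
  terrestrial signal remains).
- C:N window [2.9, 3.6] is closed (boundary values pass); samples with
  no C:N (plants, soils) pass QC with a warning since collagen QC does
  not apply to them.
- Inter-laboratory δ13C offsets are applied at most once (provenance
  flag; second application errors). Their sign convention is
  configurable because the reference scale direction is ambiguous in
  the source literature.
- The sensitivity sweep evaluates mixed TP at `f` clipped into [0, 1]
  when a grid end member violates mass balance, flagging the row; rat
  solutions with mixed TP < 2.0 are flagged as incompatible with rat
  omnivory.
- Report tables round half-even to 2 decimals; full-precision CSVs are
  always written alongside.

## Known limitations

- Two-end-member baseline models; no 3+ source nitrogen mixing.
- No apatite/whole-diet carbon models and no caloric (non-protein)
  routing — all estimates concern dietary *protein*.
- No Bayesian sequence/phase modeling around calibration.
- Thr is accepted in input tables but never used in inference (its δ15N
  behaves anomalously with trophic level).
- The mixer's Gaussian likelihood treats source means as fixed at their
  group estimates; with ≤ 2 members per group the source sd is poorly
  determined and the model-error term dominates.
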