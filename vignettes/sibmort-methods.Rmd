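---
title: "Methods: adult mortality from full and summary sibling histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adult mortality from full and summary sibling histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibmort)
```

## Conventions

All dates are carried as century-month codes (CMC), months since January
1900 = 1, the convention of the large face-to-face survey programmes this
package interoperates with; ages are completed years. Every interval —
calendar windows, age groups, recency cutoffs — is half-open:
`[start, end)`. A death exactly at a window start is inside the window, a
death at the window end is not; "the last 3 years" is the 36 months before
the interview month; "since January 2019" is `[to_cmc(2019, 1), interview)`.

Converting a completed age to a birth date needs a within-year month
offset `j` in 0..11. The default is the deterministic mid-year value
`j = 6`, which is unbiased and reproducible; stochastic contexts
(imputation, simulation) draw `j` uniformly so that derived dates do not
pile up on one month. Either choice leaves the completed age implied by
the dates equal to the recorded age, which is the invariant the loaders
validate.

## Direct estimation

For each sibling and each month of the observation window in which the
sibling is alive (birth ≤ month < death), 1/12 of a person-year, scaled
by the respondent's weight, accrues to the 5-year age group containing
the sibling's completed age that month; a death inside the window adds
the respondent's weight to the deaths of its age-at-death group. Ages
outside 15–49 are ignored. Age is computed from exact CMCs rather than
the reported age at interview, so group boundaries are handled by the
same half-open rule as everything else. Respondents themselves are never
tabulated: they are alive by selection, and no survivor-bias reweighting
is attempted (the classical direct method, not the Gakidou–King
adjustment).

Rates are `m = D / PY`; conversion to probabilities uses the actuarial
mid-interval form `q = 5m / (1 + 2.5m)` — chosen over `1 − exp(−5m)`
because the method's tradition assumes deaths fall halfway through
5-year intervals — and the seven group probabilities are chained into
₃₅q₁₅. With the rates encountered in practice the two forms differ by
well under 0.1%.

Uncertainty comes from a delete-one jackknife at the *respondent* level:
the respondent is the independent sampling unit of a random-digit-dialled
phone survey (no PSU structure exists), and all of a respondent's
siblings enter or leave together. The variance formula is the standard
`(n−1)/n · Σ(θ₍ᵢ₎ − θ̄)²` with a normal-approximation interval truncated
to [0, 1]. A leave-one-out replicate that empties an age group is
skipped with a warning and the replicate count adjusted. The
implementation subtracts per-respondent deaths/person-year matrices from
the totals, so the n replicates cost one pass, not n.

## Weighting

Post-stratification weights are fitted by iterative proportional fitting
to target category shares, with a hard cap (default 2) on the final
mean-1 weights. The cap is applied after every full IPF cycle and
iteration then continues — rake, trim, re-rake — which keeps the margins
as close to target as the cap allows. The final normalisation solves
`mean(pmin(s·w, cap)) = 1` for the scale `s`, so both invariants
(mean 1, max ≤ cap) hold simultaneously. A binding cap can leave
residual margin deviations; these are reported (`max_dev`, flagged rows
in `composition_report()`) rather than silently absorbed, and
non-convergence raises a warning, not an error. Whether the original
analyses capped before or after convergence, or renormalised, is not
documented; the choices here are explicit and, without a binding cap,
coincide with any order. Stratified surveys are raked per stratum and
combined so each stratum's total weight share equals its population
share.

## Imputation

The reference tables are weighted empirical histograms from a full
reference survey, keyed by the respondent's 5-year age group and the
sibling's sex: the distribution of respondent−sibling age differences
(surviving siblings, differences clamped to ±40 years), and the joint
distribution of (age at death, time since death in completed years).
Empty keys resolve through a fallback chain — exact key, sex collapsed,
immediately adjacent respondent age group (sex-specific then collapsed),
finally the globally pooled table with a warning. Adjacency is limited
to one step: past that, the pooled table is a more honest donor than a
distant age group.

*Partial* mode imputes only what was not collected: each surviving
sibling's current age (respondent age minus a drawn difference, redrawn
up to 10 times if outside [0, 95], then clamped — rare, and it keeps
sibling counts conserved), missing fields of reported recent deaths
(a missing death month is drawn uniformly respecting the cutoff year; a
missing age at death is drawn conditionally on the reported time since
death, widening the conditioning band until populated), and the
schedules of deaths the respondent placed *before* the cutoff. Those
pre-cutoff draws are restricted to times-since-death of at least the
window length in completed years and the resulting date is clamped below
the cutoff: since times are integer years while the cutoff is a month,
requiring strictly greater would leave a 37–47-month gap no imputed
death could occupy.

*Complete* mode discards all reported death detail and draws (age at
death, time since death) jointly for every deceased sibling. Both modes
flag every filled field in `imputed_fields`, conserve `n_ever`,
`n_alive` and `n_dead` exactly, and derive birth dates with uniform
within-year jitter.

Draws use one RNG stream per call, seeded by the `seed` argument;
reproducibility is therefore at the call level (same seed, same input
order → identical output) rather than keyed per respondent.

## The synthetic world

The simulator is the package's oracle: a stationary demographic regime
whose truth is known in closed form. Hazards are piecewise-constant per
single year of age (0–95) per sex, with a Sahelian-like template —
elevated infant mortality, a trough near age 10, Gompertz-type adult
rise — whose adult segment (15–49) is rescaled so that
`1 − exp(−Σ h)` equals the target ₃₅q₁₅ exactly. Default targets
(0.15) and the published reference levels (0.178 men / 0.138 women) are
the magnitudes reported for high-mortality Sahelian settings. Sibship
sizes are negative-binomial with mean 6 (size 5), matching the 5–7
siblings per respondent such surveys report; respondent–sibling birth
gaps are discretised normal with SD 60 months. Respondents are alive by
construction and excluded from exposure.

Reporting-error injectors mirror the mechanisms hypothesised for phone
interviews: age heaping (round to the nearest multiple of 5),
backward displacement of death dates (geometric months, recorded age at
death preserved so only the period placement moves), and omission of
deceased siblings. A recent mortality shock
(`apply_mortality_shock()`) multiplies hazards during a calendar window
via an exact competing-exposure overlay, providing the non-stationary
setting in which complete imputation is expected to fail. Selection
thins respondents by a logistic model on covariates, emulating
phone-ownership bias.

What the generator does *not* emulate: mortality trends and HIV-type
bumps (beyond the single shock window), country-specific fertility
histories, correlation between sibship size and mortality, respondent
recall heterogeneity, and any causal link between phone ownership and
sibling survival. A green validation test therefore establishes that
the *methods* are implemented correctly and are unbiased under
stationarity — not that any particular field survey is unbiased.

## Validation experiment

`run_paired_experiment()` is the synthetic restatement of the paired
survey test of the two imputation modes: per replicate, an independent
reference and target survey are simulated from the same regime, the
target is collapsed to the summary instrument and reconstructed both
ways, and ₃₅q₁₅ over the 0–3-year window is compared between the direct
and imputed paths. The default scale — 20 replicates × 4000 respondents
— runs in seconds on a laptop; at that scale partial imputation shows
MAPE well under 2.5% per sex with a median ratio within 1±0.03, while
complete imputation shows an order-of-magnitude larger MAPE, and under a
recent mortality shock it is biased downward (the shock deaths are
re-dated according to the reference schedule).

## Diagnostics

Myers' blended index is computed on the halved 0–90 scale over a
decade-aligned range, default ages 10–89, from pooled single-year ages;
both age universes (current ages of the living, ages at death of the
dead) are supported because the appropriate universe depends on which
reports are being audited, and the range is returned with every result.
Note a distributional fact worth keeping in mind when reading
thresholds: ages fully rounded to multiples of 5 split the blended mass
between digits 0 and 5 and score 80, not the theoretical maximum 90,
which requires a single terminal digit. Recent-death proportions use
ratio-of-sums aggregation, so respondents reporting no deceased siblings
drop out of the denominator and weight rescaling cancels.

## Numerical choices and edge cases

* Raking: convergence on the maximum absolute share deviation,
  tolerance 1e-6, at most 100 cycles; initial weights are design weights
  when present.
* `q = 5m/(1+2.5m)` exceeds 1 for m > 0.4; probabilities are clamped at
  1 (an absorbing age group yields ₃₅q₁₅ = 1).
* Groups with zero person-years are unestimable: `estimate_35q15()`
  refuses rather than extrapolates; `annual_series()` flags the year.
* Out-of-range imputed ages: ≤10 redraws then clamp, keeping counts.
* Degenerate reference tables (single populated key) remain usable
  through the global fallback, with a warning.
* Weight cap below 1 is rejected (mean-1 weights cannot all sit under
  the cap).

## Known limitations

Pregnancy-related mortality, indirect sibling methods, model-life-table
smoothing and survivor-bias adjustments are out of scope. The imputation
is purely empirical hot-deck — no regression or EM — and inherits the
assumption that the reference survey's age-difference and death-schedule
distributions still apply at the target date; the validation experiment
quantifies exactly the failure of that assumption under a mortality
shock. Month-of-birth and month-of-death are never observed, only
reconstructed, so month-level analyses inherit the jitter conventions
described above.
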