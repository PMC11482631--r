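---
title: "Marker-based ileal digestibility of rapeseed cake: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based ileal digestibility of rapeseed cake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rscdigest)
```

## The measurement problem

Pigs absorb amino acids mainly before the distal ileum; whatever reaches a
T-cannula there is, for practical purposes, lost. Because total collection
at the ileum is infeasible, digestibility is inferred from an indigestible
marker: TiO₂ is mixed into the diet at 0.30% and the marker's concentration
shift between diet and digesta tells how much dry matter disappeared. For a
component with diet concentration $AA_r$ and digesta concentration $AA_d$
(both g/kg DM, marker $T_r$, $T_d$):

$$\mathrm{AID} = \left[1 - \frac{AA_d \, T_r}{AA_r \, T_d}\right] \times 100\%$$

AID conflates dietary losses with the animal's own secretions (mucus,
enzymes, sloughed cells). Feeding a nitrogen-free diet isolates that basal
endogenous flow per kg of DM intake,

$$IAA_{end} = AA_d \cdot T_r / T_d,$$

and the standardized digestibility corrects AID upward by it:

$$\mathrm{SID} = \mathrm{AID} + \frac{IAA_{end}}{AA_r} \times 100\%.$$

`compute_aid()`, `compute_endogenous()` and `compute_sid()` implement these
three steps; `estimate_digestibility()` chains them over a per-pig-period
digesta table.

**A notation decision made prominently.** In the source method's write-up
the SID correction is written with the symbol for the *digesta*
concentration in the denominator. Taken literally that reading does not
reproduce the published SID tables; dividing by the *dietary* concentration
(g/kg DM) does, exactly, for every lot (e.g. CP of lot RSC1:
$70.29 + 100 \times 21.24 / 194.94 = 81.19$). The package therefore
implements the dietary reading, and `compute_sid()`'s argument is named
`diet_conc_dm` so the choice is visible at every call site.

**Bases.** Ingredient and diet assays are reported per air-dry mass;
digesta assays per dry matter. Every quantity entering the marker equations
is first converted with `to_dm_basis()` (division by the DM fraction).
Mixing bases is the classic failure mode of this calculation, which is why
the conversion is an explicit, tested function rather than an inline
division.

## Treatment summaries

The replicate unit is the pig-period value; the two-square design yields 6
per diet. `summarize_treatments()` reports, per component:

- group means after a within-cell Z-score screen (default cutoff |Z| > 3;
  the screening rule was stated without a threshold, and 3 is the
  conventional choice — note that with only 6 replicates a single outlier
  cannot exceed |Z| ≈ 2.04, so the screen only bites on larger or multiply
  contaminated cells);
- one pooled SEM, $\sqrt{\mathrm{MSE}/n}$ with $n$ the per-group replicate
  count, matching the one-SEM-per-row convention of the published tables;
- the one-way ANOVA F-test p-value (the original analysis may have blocked
  on pig and period; the model behind its printed p-values is not stated,
  so the package defaults to the plain one-way layout);
- compact letter groups from all pairwise Tukey HSD comparisons at
  α = 0.05 (the multiple-comparison procedure was likewise unstated; Tukey
  is the standard for all-pairwise means separation). The insert-and-absorb
  letter algorithm is implemented in-package since no letter-display
  package is available in the dependency set.

Zero-residual cells (exact ties, noise-free simulations) would make the F
statistic degenerate; they are detected and handled by comparing means
directly, with no separation claimed between equal means.

Digestibility values are never clamped: negative AID and SID above 100%
are legitimate outcomes of the marker arithmetic (proline SID exceeds 100%
in the published data because the endogenous proline flow is large relative
to its dietary supply).

## Composition screening and prediction equations

`summarize_samples()` uses the sample (n − 1) standard deviation;
`flag_high_variation()` applies the strict CV > 10% rule. Report rounding
(2 decimals, half-up) is applied only at output; all internal computation
is unrounded.

`stepwise_select()` is classical p-value stepwise OLS: enter the candidate
with the smallest partial-F p-value while it is ≤ 0.05, then drop any
included predictor whose partial p-value reaches 0.10 — the entry/removal
defaults of the statistics package family in which this method is usually
run. Ties break by candidate input order, making the procedure
deterministic. Reported metrics follow the published table: R², adjusted
R², the F-test p-value, and "RSD", which reproduces the published values
only when read as the residual standard error
$\sqrt{SSE/(n-p-1)}$ — not a mean-scaled relative deviation. Both raw and
adjusted R² are always reported because the published equations mix the
two (the fiber and glucosinolate equations print raw R², the
heating-temperature equation prints the adjusted value).

The heating covariate `HT` is the midpoint of the reported temperature
range ("130 ± 10 °C" → 130; "40 ± 20 °C" → 40), and a duration range
("60~120 min") is likewise stored as its midpoint; the regressions were
reported against an undefined "HT", and the midpoint is the only symmetric
reading. The headline candidate pool is DM, GE, CP, EE, Ash, CF, NDF, ADF,
Ca, TP, TGS and HT.

## What the synthetic trial emulates

`build_design()` reproduces the experiment's structure: two 11 × 3
incomplete Latin squares over 22 pigs, 11 diets (ten test diets at 40% RSC
inclusion plus the nitrogen-free diet), three periods, hence six
pig-period replicates per diet. Construction is cyclic — within a square,
pig *i* gets diet $(i + o_j) \bmod 11$ in period *j* with distinct random
offsets $o_j$ — which guarantees once-per-square-period balance for every
seed; how the original squares were randomized is unknown, and any
balanced construction is equivalent for the estimators tested here.

`generate_trial()` then runs the marker model generatively. Defaults are
the stated trial conditions wherever those exist, and a single realistic
choice elsewhere:

| parameter | default | why |
|---|---|---|
| RSC inclusion | 0.40 | diet formulation of the trial |
| marker | 0.30% TiO₂, air-dry | diet formulation of the trial |
| diet DM | 91.3% (test), 90.3% (N-free) | mean/printed analyzed diet DM; the generator needs a DM the design table does not fix |
| DM digestibility | 0.75 (test), 0.90 (N-free) | typical for 40%-RSC vs starch/sucrose diets; sets marker concentration $T_d = T_r/(1-d_{DM})$ |
| assay noise | lognormal, CV 5% | multiplicative, strictly positive, roughly proportional error — the standard model for composition assays |
| N-free protein | zero | the carrier ingredients are protein-free by design; the small Cys/Pro artifacts seen in real N-free assays are ignored |

Noise is a mean-one lognormal factor drawn independently per
pig-period-component; the marker assay is treated as exact, so the
noise-free chain identity (estimated SID ≡ true SID, to machine precision)
is available as a structural test, and it is asserted in the test suite.
Implied negative digesta flows (a true SID above 100% without enough
endogenous supply) are floored at zero with a warning.

What the generator does *not* emulate — and what a green simulation test
therefore cannot establish: pig-to-pig and period effects (the real data
have them; the simulator's replicates differ only by assay noise),
correlated assay errors within a digesta sample, diet refusals, incomplete
digesta collection, and any physiological response such as
glucosinolate-induced depression of absorption. Parameter-recovery results
validate the estimation arithmetic, not the biology.

## Fixtures and their limits

The bundled tables transcribe the published multi-lot data: composition
and amino-acid profiles of ten lots, eleven analyzed diets, treatment-mean
AID/SID with pooled SEM, p-values and letter groups, and the
nitrogen-free endogenous losses. Pig-level replicates were never published,
so fixture-based checks operate on treatment means; replicate-level
behaviour is exercised only through the simulator.

Three printed summary values are knowingly irreproducible from the printed
per-lot rows: the CVs of EE (printed 32.79, recomputes ≈ 20.35), TGS
(printed 15.19, recomputes ≈ 7.56) and TP (printed 9.67, recomputes
≈ 9.88). The fixtures store the printed rows and the printed Mean/CV
columns separately and do not reconcile them; the recomputed-CV screen
consequently does not flag TGS even though the printed column would. The
published abstract also rounds some SID means differently from the tables
(73.34 vs 73.81 for CP); the tables are treated as authoritative
throughout.

## Numerical choices, in one place

- Sample SD (n − 1) everywhere a CV or SEM is formed.
- Correlation p-values from the t distribution on n − 2 df; zero-variance
  variables yield `NA` cells rather than errors.
- Stepwise entry/removal α: 0.05 / 0.10, configurable;
  `p_remove < p_enter` is rejected (cycling risk).
- Z-outlier cutoff 3, configurable; `Inf` disables the screen.
- No digestibility clamping; generation floors negative flows at 0.
- Degenerate ANOVA (zero residual SSE, detected at relative 1e-10) short-
  circuits to mean comparison.
- Seeds: `build_design()` and `trial_truth()` each take one integer seed;
  a trial is fully reproducible from the pair.
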