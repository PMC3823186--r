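---
title: "Quantifying habitual upper-limb use: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying habitual upper-limb use: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbuse)
```

## The problem

One-handed individuals — whether the hand is absent from birth or lost by
amputation — solve everyday tasks with very different strategies: some rely
almost exclusively on the intact hand, others incorporate the residual arm
extensively.  `limbuse` quantifies these strategies from data that can be
collected outside the lab:

* **bilateral accelerometry** — one tri-axial monitor on the intact wrist and
  one on the residual upper arm, worn during normal daily routines;
* a **modified 27-item Motor Activity Log** (MAL) rating how frequently the
  residual arm is incorporated in daily activities;
* a **chronic phantom-pain magnitude** combining intensity and frequency;

and then runs the cohort-level battery that relates these behavioural scores
to each other and to externally supplied sensorimotor activation estimates
(region-of-interest β values, consumed as plain numeric columns — the package
performs no image processing).

## Movement detection

The detector operates on raw acceleration in m/s², gravity included.  All of
its decisions are based on within-window *ranges* (max − min), which cancel
any constant offset, so no gravity removal or orientation estimation is
attempted anywhere.

The chain, per limb:

1. **Smoothing.** Each axis is replaced by its centred moving average over
   `smooth_ms` (default 500 ms; 50 samples at the devices' 100 Hz).  A boxcar
   is the simplest kernel that discards high-frequency noise; the kernel
   shape is otherwise unconstrained by the method, and the boxcar makes the
   impulse response exactly analysable (a 1/50 plateau), which the tests
   exploit.  At the trace edges the window shrinks symmetrically rather than
   padding — padding would fabricate stillness where nothing was recorded.
2. **Sliding-window ranges.** For every window start (stride of one sample —
   non-overlapping windows would undercount short movements), the max − min
   acceleration within `window_ms` (default 400 ms) is computed per axis.
   The rolling extrema use a doubling `pmax` scheme, O(n log w), so
   multi-hour recordings are cheap without compiled code.
3. **Threshold + quiescence.** A window position is *moving* when its range
   exceeds `threshold` (default 0.2 m/s²) on at least one axis, and *still*
   when its range is below the threshold on **all** axes.  A maximal run of
   consecutive moving positions is one candidate event; it is accepted only
   if the `quiescence_ms` of positions immediately before and after the run
   are all still.  The required quiescence duration is not fixed by the
   method; we default it to one full window (400 ms) per side and expose it
   as a parameter.  An event's sample span is the run plus the final window's
   span, making events disjoint and deterministically ordered.

Numerical conventions worth stating: *moving* uses a strict `>`, *still* a
strict `<`, so a range exactly at the threshold is neither — it breaks a
quiescence interval without extending a run.  Traces shorter than
`window + 2 × quiescence` cannot contain an acceptable event and return an
empty result with a warning.  Multi-day recordings are pooled per limb
before any ratio is formed, since the laterality ratio only cancels
recording-time differences if both limbs pool the same epochs.

## Behavioural scores

* **Laterality index**: `(n_intact − n_residual) / (n_intact + n_residual)`
  over detected counts; +1 is exclusive intact-hand use, 0 balanced, −1
  exclusive residual-arm use.  A ratio is used so whole-body co-movements
  and wear-time differences cancel.  Zero movements on both limbs is an
  error, not 0 — 0 means *balanced*, and silence should not impersonate it.
* **MAL score**: 27 items rated 0/1/2 (never/sometimes/very often), summed
  and divided by 54, giving a 0–1 scale of residual-arm incorporation.
  Incomplete questionnaires are rejected rather than prorated: the /54
  normalisation presumes 27 answered items.
* **Chronic pain magnitude**: intensity (0–10) divided by the frequency code
  (1 = all the time … 5 = once or less per month); because lower codes mean
  more frequent pain, the quotient grows with both intensity and frequency.

## The statistical battery

Every test returns a `stat_result` recording the test actually used, its
statistic, df, p, the α applied and the decision, so a full analysis is an
auditable table.

* **Normality gating.** Two-sample comparisons Shapiro–Wilk-test each group
  at 0.05; if both pass, a pooled-variance Student t (the plain reading of
  an unpaired t-test; Welch is an option), otherwise Mann–Whitney.  The
  branch is a pure function of the two Shapiro p-values, is recorded, and
  can be forced for testing.  Mann–Whitney p-values are exact for combined
  n ≤ 20 without ties and use the tie-corrected normal approximation
  otherwise — standard practice at these sample sizes.
* **Planned comparisons** run at α = 0.025 (two pre-specified contrasts per
  limb); everything else at 0.05.
* **Mixed ANOVA.** One between factor (group) × one two-level within factor
  (limb), via the classical univariate sums-of-squares decomposition
  (sphericity is trivial with two within levels).  Participants missing a
  limb value are an error listing who, not a silent drop.
* **Covariate-adjusted contrasts** fit `dv ~ group + covariates` and test
  the group term against the covariates-only model (F with 1 numerator df).
  Covariates are used unstandardised — the F is invariant to their scaling.
  An empty covariate set reproduces the unadjusted contrast exactly, which
  the tests assert.
* **Correlations.** Pearson r with t-based p at df = n − 2; partial
  correlations as the correlation of least-squares residuals at
  df = n − 2 − k.  Directional (one-tailed) partial tests must declare their
  direction in the plan; an undeclared direction falls back to two-tailed
  with a warning rather than guessing a sign.  Degrees of freedom are always
  computed from the records actually used — per-analysis exclusions (e.g.
  above-elbow deprivation excluded from residual-arm contrasts) are
  declarative `filter` expressions in the plan, and the resulting n is
  reported per test.
* **Fisher r-to-z** compares two independent correlations two-tailed.

## The synthetic-data generators

Neither raw recordings nor participant tables from the motivating study
design are publicly deposited, so the package ships generators that make
every stage verifiable against a known truth.

**Paired traces** (`generate_paired_accel`): per limb, Gaussian sensor noise
(σ = 0.02 m/s²) over a per-axis gravity offset, plus limb-specific bursts at
Poisson rates (defaults 6/min intact, 2/min residual) and whole-body bursts
(1/min) that share timing across limbs but pick their axis independently per
limb, as a trunk movement would.  A burst is a single-cycle sinusoid on one
axis, peak-to-peak 0.5 m/s² and 1000 ms long by default.  The duration
matters: a 500 ms boxcar attenuates a 1000 ms single cycle by sin(π/2)/(π/2)
≈ 0.64, leaving a worst-case 400 ms window range of ≈ 0.30 m/s² — comfortably
above the 0.2 m/s² threshold — whereas much shorter bursts would be largely
averaged away.  Candidate events closer than `min_gap_ms` (default 2000 ms)
to an already-placed event are discarded at draw time: separability requires
at least kernel + quiescence + window ≈ 1300 ms of clear gap, and 2000 ms
leaves margin.  The ground truth lists exactly the bursts that were placed,
which is what makes "detected = true in 100% of seeds" a meaningful
criterion.  Both generators draw from one explicitly seeded stream and
restore the ambient RNG state.

**Cohorts** (`generate_cohort`): group sizes default to the targeted study
design (11 congenital, 18 acquired, 22 controls).  Within the one-handed
groups, a standard-normal usage latent drives the MAL score
(means 0.55/0.35, sd 0.15), intact-hand activation (within-group correlation
−0.43 with usage) and the pain latent (correlation −0.40 with usage); the
laterality index is drawn per group (means 0.30/0.60, sd 0.20/0.17) with the
acquired group lateralised further towards the intact hand.  Activation cell
means give each group's over-used limb the larger β.  These defaults were
set once, from the direction and rough magnitude of the effects the battery
is meant to detect, with bounded scores kept ≥ ~2.3 sd inside their limits so
that fewer than 1% of draws are clipped (clipping is counted and reported).
Controls carry activation values only; their amputation, questionnaire,
pain and laterality fields are missing by construction, and validation
enforces that only controls may leave them missing.

Two structural notes.  First, deprivation age is generated independently of
the usage/activation residuals (0 for congenital, ~U(11, 48) for acquired),
so the generating *partial* usage–activation correlation given deprivation
age equals the marginal −0.43; recovery studies therefore use a
homogeneous-mean configuration (equal group means, n = 14 + 14) in which the
pooled generating correlation is well defined — under the default group
separations the pooled r additionally reflects between-group structure and
has no single generating value.  Second, the questionnaire–accelerometry
correlation arises in the simulation only through group separation (the
within-group draws are independent), so it is weaker than the within-sample
association a real cohort would show; a pooled negative r is still expected
and observed.

## What the simulations do and do not show

Passing the recovery and calibration suites shows the *implementation* is
faithful: the detector equals a literal brute-force statement of its rule on
randomized traces, counts match ground truth at high SNR, test statistics
match textbook formulas to 1e−10, null rejection rates sit at their nominal
α, and generating correlations are recovered without bias.  It does **not**
show that the defaults are optimal for real recordings: real sensor noise is
not white, movement durations and amplitudes are broad and skewed, non-wear
periods exist and are not modelled, posture changes masquerade as slow
movements, and real laterality distributions hug +1 rather than being
Gaussian.  Threshold and quiescence choices should be sanity-checked against
annotated data before substantive use.

## Validation problem sizes

The shipped suites use: 1000 randomized traces (2–8 s) for detector–oracle
equivalence; 200 seeded 300 s paired traces for count recovery; exhaustive
sweeps for the closed-form scores (all 3⁵ partial MAL patterns over five
varied items, all count pairs ≤ 50, all intensity × frequency combinations);
2000 null-cohort replicates for α calibration at 0.05 and 0.025; and 1000
replicates at n = 28 for correlation recovery at ρ = −0.43.  These sizes give
Monte-Carlo error comfortably below the assertion tolerances while keeping
the default check fast on a single CPU.

## Known limitations

* The detector has no non-wear or sleep segmentation; long still periods are
  simply event-free.
* The MAL item inventory is fixed at the 27 activities shipped in
  `mal_items()`; alternative inventories require re-deriving the
  normalisation constant.
* The mixed ANOVA is the classical univariate decomposition; with more than
  two within-limb conditions a sphericity correction would be needed.
* ROI activation values are trusted inputs; no imaging QC of any kind is
  performed.
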