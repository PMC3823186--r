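# limbuse

Quantifying habitual upper-limb use from bilateral accelerometry, with the
cohort statistics that relate usage strategies to questionnaire scores,
phantom-limb pain and sensorimotor activation estimates.

## What it is for

After hand loss or congenital hand absence, individuals differ in how much
they use the residual arm versus the intact hand in daily life.  `limbuse`
measures that strategy from wearable data and questionnaires and provides a
reproducible statistical battery for cohort studies in rehabilitation
neuroscience:

* **Movement detection** on tri-axial acceleration (one monitor per limb,
  100 Hz): each axis is smoothed with a centred 500 ms boxcar; within a
  400 ms sliding window (stride 1 sample) the range max − min is computed per
  axis; a maximal run of windows whose range exceeds 0.2 m/s² on ≥ 1 axis is
  a movement event, accepted only when immediately preceded and followed by
  400 ms of stillness (range < 0.2 m/s² on **all** axes).
* **Movement laterality index** over detected counts,
  LI = (n_intact − n_residual) / (n_intact + n_residual) ∈ [−1, 1];
  +1 = exclusive intact-hand use.  A ratio cancels whole-body co-movements
  and wear-time differences.
* **Modified Motor Activity Log** (27 items rated 0/1/2), scored
  Σ ratings / 54 ∈ [0, 1].
* **Chronic pain magnitude** = intensity (0–10) / frequency code (1–5).
* **Cohort battery**: Shapiro–Wilk-gated t / Mann–Whitney comparisons,
  one-sample t against zero, mixed group × limb ANOVA, planned comparisons
  at α = 0.025, covariate-adjusted group contrasts (univariate GLM), Pearson
  and one-tailed partial correlations, Fisher r-to-z comparison of
  correlations — all returning auditable `stat_result` records.
* **Synthetic generators** for paired traces with ground-truth events and
  for cohorts with a specified correlation structure, so every stage has a
  recovery target.

Imaging is strictly out of scope: region-of-interest activation estimates
(β) enter as plain numeric columns.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on synthetic
data.  Step 1 simulates six participants wearing both monitors for 10
minutes; step 2 detects movements and derives laterality indices:

```
$ Rscript analysis/01_simulate_accel.R
$ Rscript analysis/02_detect_usage.R
Per-participant usage (results/usage.csv):
 participant_id n_intact n_residual laterality_index wear_s_intact
            S01       55         30        0.2941176           600
            S02       50         33        0.2048193           600
            ...
Detection vs ground truth: 6/6 participants with exact counts; max |LI error| = 0.0000
```

Every detected count equals the generator's ground truth, and the laterality
indices (≈ 0.2–0.4: markedly more intact-hand movements) follow from the
simulated 6/min vs 2/min event rates plus 1/min shared whole-body events.

Steps 3–4 simulate a 51-participant cohort (11 congenital, 18 acquired, 22
controls) and run the shipped analysis plan:

```
$ Rscript analysis/03_simulate_cohort.R
$ Rscript analysis/04_cohort_analysis.R
                               label               test_name statistic   df  p_value alpha_used        decision n_used
               li_vs_zero_congenital            one_sample_t     6.967   10 3.87e-05      0.050     significant     11
                 li_vs_zero_acquired            one_sample_t    17.727   17 2.13e-12      0.050     significant     18
                 li_group_comparison               student_t     2.098   27 4.54e-02      0.050     significant     29
                mal_group_comparison               student_t     3.436   27 1.92e-03      0.050     significant     29
                  mal_group_adjusted    covariate_adjusted_F     8.404 1,24 7.88e-03      0.050     significant     29
                    beta_mixed_anova mixed_anova_interaction    10.447 2,48 1.71e-04      0.050     significant     51
    hand_beta_acquired_vs_congenital               student_t     3.627   27 1.18e-03      0.025     significant     29
     arm_beta_congenital_vs_acquired            mann_whitney    80.000   NA 7.83e-02      0.025 not_significant     21
                  usage_vs_hand_beta               pearson_r    -0.523   27 3.61e-03      0.050     significant     29
          usage_vs_hand_beta_partial               partial_r    -0.379   26 2.32e-02      0.050     significant     29
 ...
All 18 steps completed.
```

Reading the table: both one-handed groups lateralise towards the intact hand
(one-sample t against LI = 0), the acquired group more so; the congenital
group reports more residual-arm use on the questionnaire, surviving
adjustment for amputation level and prosthesis usage; the group × limb
interaction confirms each group over-represents its over-used limb; planned
limb contrasts are decided at α = 0.025 (note the arm contrast runs on
n = 21 after the declarative above-elbow exclusion and its normality gate
chose Mann–Whitney); and residual-arm usage correlates negatively with
intact-hand activation (r = −0.52), also when controlling for deprivation
age (one-tailed partial r = −0.38).  Step 5 draws summary figures.

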