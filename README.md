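# qtctbt

Heart-rate normalisation modelling and time-varying QT-interval correction
for patients treated for active tuberculosis.

## The problem

Active TB raises heart rate (HR); it normalises over the first months of
successful treatment. QT assessment relies on heart-rate-corrected QT,
`QTc = QT / RR^x` (RR in seconds), and any fixed exponent freezes one QT–RR
relationship: the pretreatment TB exponent 0.4081 over-corrects once HR has
recovered, while the Fridericia exponent 0.33 under-corrects at pretreatment
tachycardia. Since several second-line TB drugs and the bedaquiline
metabolite M2 prolong QT, both biases matter clinically — missed arrhythmic
risk on one side, unnecessary interruption of effective treatment on the
other.

`qtctbt` implements:

* a **composite nonlinear mixed-effects HR model** — asymptotic
  time-on-treatment recovery `TE(t) = (HR_rec − HR_base)(1 − e^(−ln2·t/T_prog))`,
  24 h + 12 h circadian cosine harmonics, an Emax effect of M2
  (`Emax·C/(EC50 + C)`), and power/conditional covariate effects — with
  log-normal (and Box–Cox) inter-individual variability and a two-level
  residual model (proportional per replicate, additive shared within a
  triplicate occasion);
* **Laplace marginal-likelihood estimation** (`hr_fit`), stepwise covariate
  selection (`scm_step`, ΔOFV 3.84 forward / 6.63 backward) and visual
  predictive checks (`vpc`);
* the **time-varying correction factor**
  `CF(t) = 0.4081 − 0.0781·(1 − e^(−ln2·t/7.74))`, applied as
  `QTcTBT = QT / RR^CF(t)`, alongside Bazett, Fridericia, Olliaro,
  Framingham and Van de Water corrections (`correct_qt`, `add_qtc`);
* the **two-step correction-quality evaluation**: per-time-bin OLS of QTc on
  HR with subject-cluster-robust CIs (`bin_regression`), then an
  SE-weighted regression of the bin slopes over time (`slope_trend`,
  `evaluate_corrections`);
* **standard QTc endpoints** (absolute, ΔQTc, placebo-corrected ΔΔQTc) over
  the eight prespecified time bins (`summarize_endpoints`);
* a **synthetic-cohort generator** emulating the pooled phase IIb MDR-TB
  trial design (440 adults, Day −1 to Week 24 triplicate ECGs, published
  covariate medians/ranges, week-2 mean M2 of 300 ng/mL), so the whole
  pipeline is testable without any patient data (`cohort_design`,
  `simulate_trial`).

## Worked example

Simulate a 200-subject virtual trial with the published model as truth,
correct QT with the time-varying factor and with Fridericia, and evaluate
both:

```r
library(qtctbt)
trial <- simulate_trial(cohort_design(n_subjects = 200), hr_model_spec(),
                        seed = 55)
ev <- evaluate_corrections(trial, methods = c("tbt", "fridericia"))
print(ev)
#> == tbt: slope CI covers 0 in 8/8 bins
#> slope at time 0 (intercept): 0.0103 ms/bpm (95% CI -0.2168, 0.2375)
#> trend over time: -0.0056 ms/bpm per week (95% CI -0.0171, 0.0060)
#> == fridericia: slope CI covers 0 in 3/8 bins
#> slope at time 0 (intercept): -0.3226 ms/bpm (95% CI -0.5430, -0.1021)
#> trend over time: 0.0094 ms/bpm per week (95% CI -0.0020, 0.0207)
```

The matched (time-varying) correction leaves no QTc–HR dependence in any
bin and no drift over treatment time. Fridericia shows the published
failure signature: a clearly negative slope at treatment start
(under-correction at elevated pretreatment HR; the real-data analysis
reports −0.383) that shrinks toward zero as HR normalises (positive trend).

The closed-form anchors:

```r
cf_tbt(c(0, 7.74, 1e4))
#> [1] 0.40810 0.36905 0.33000
predict_hr(spec = hr_model_spec(), t_weeks = c(0, 1e6), ctime_h = NULL, conc_m2 = 0)
#> [1] 78.2 73.1
round(100 * m2_effect(hr_model_spec(), 300))   # % HR decrease at week-2 mean M2
#> [1] 2
```

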