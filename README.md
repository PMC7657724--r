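# eprowatch

Electronic patient-reported outcome (ePRO) symptom monitoring for cancer
patients on anti-PD-(L)1 immune checkpoint inhibitor therapy.

Immune checkpoint inhibitors cause immune-related adverse events in any
organ, often weeks to months into therapy, so their safe use depends on
continuous symptom surveillance rather than visit-based assessment. This
package implements, as reusable and fully testable components, the engine
behind a weekly ePRO follow-up of such patients — for biostatisticians and
digital-health engineers who need to grade patient answers, trigger care
alerts, measure adherence, and analyze symptom/benefit structure without
access to a clinical ePRO product:

* **Severity grading** — an 18-symptom questionnaire (blood in stool,
  hematuria, blurred vision, chest pain, cough, loss of appetite, diarrhea,
  dizziness, fatigue, fever, headache, itching, nausea, pain in joints,
  rash, shortness of breath, stomach pain, vomiting) whose patient-friendly
  answers are mapped to NCI-CTCAE v4.03 grades *g* ∈ {0, 1, 2, 3, 4} by a
  declarative, clinically editable YAML rule file.
* **Urgency algorithm** — a questionnaire alerts on symptom *s* iff
  *g*<sub>s</sub> ≥ 3, or *g*<sub>s</sub> ≥ 2 while the patient's most
  recent prior grade was 0; alerts carry physician-annotated etiology
  (cancer / treatment / unclear).
* **Scheduling & compliance** — weekly email prompts with up to 6 daily
  reminders per unanswered cycle; compliance(w) = answered questionnaires
  in week *w* / patients whose follow-up window covers week *w*.
* **Analysis pipeline** — grade-bucket distributions {0, 1, 2, 3–4}, alert
  summaries, Pearson product-moment correlation heatmaps with effect-size
  classes (|r| ≥ 0.5 large, ≥ 0.3 medium, ≥ 0.1 small), benefit-stratified
  symptom trajectories (benefit = best RECIST 1.1 response CR/PR/SD,
  vs PD), per-arm prevalences, and experience-survey summaries.
* **Cohort simulator & reference fixture** — a seeded longitudinal
  generator (two-state weekly Markov presence chains, categorical severity,
  benefit-linked itching and chest-pain effects, prompt/reminder adherence)
  plus a deterministic 37-patient reference cohort encoding the published
  feasibility-study counts, so every stage is testable without patient
  data.

Everything is data-frame-first and pipe-friendly: tibbles in, tibbles out,
with `glance()`/`tidy()` methods and ggplot2 `autoplot()` for correlation
heatmaps.

## Worked example

```r
library(eprowatch)

co <- build_reference_cohort()
co
#> <epro_cohort>
#>   patients: 37
#>   graded questionnaires: 889
#>   survey records: 31
#>   evaluable: 34 (benefit 22, PD 12)

decisions <- evaluate_alerts(co$responses) |>
  annotate_etiology(co$etiologies)
s <- alert_summary(decisions, co, window = c(1, 12))
s
#> <epro_alert_summary> 67/391 questionnaires alerted (17.1%)
s$etiology
#>   etiology      n
#> 1 unclear      38
#> 2 treatment    21
#> 3 cancer        8
head(s$by_symptom, 5)
#>   symptom                 n
#> 1 loss_of_appetite       32
#> 2 shortness_of_breath    31
#> 3 pain_in_joints         21
#> 4 blurred_vision         17
#> 5 cough                  16

prevalence_by_arm(co, "itching")
#>   arm     n_reporting n_patients prevalence
#> 1 benefit          14         22      0.636
#> 2 PD                4         12      0.333

round(compliance_range(compute_compliance(co$responses, co$plans)), 3)
#>   min   max
#> 0.583 1.270
```

17.1% of the first-12-week questionnaires alerted, most often for loss of
appetite and shortness of breath, and most alerts had no clear etiology;
itching over the full follow-up was about twice as common under clinical
benefit (64% vs 33% of patients); weekly adherence stayed between 0.583 and
1.27 questionnaires per active patient. On a seeded 2000-patient
simulation the injected benefit effects surface with the expected signs:

```r
sim <- simulate_cohort(sim_params(n_patients = 2000, seed = 7))
benefit_correlation(sim, window = c(1, 12)) |>
  dplyr::filter(symptom %in% c("itching", "chest_pain"))
#>   symptom         r     n effect_size
#> 1 chest_pain -0.561  2000 large
#> 2 itching     0.400  2000 medium
```

Positive r: the symptom accompanies treatment benefit (itching); negative
r: it accompanies progression (chest pain).

A thin CLI covers the same flow
(`Rscript inst/cli/epro.R {simulate|fixture|grade|alerts|schedule|analyze}`),
and `run_pipeline()` writes the full CSV/JSON/heatmap bundle in one call.
See `vignettes/epro-monitoring.Rmd` for the model, parameter rationale and
encoding decisions.

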