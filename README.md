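# adta — automated digital TIL analysis for primary melanoma

Early-stage melanoma urgently needs prognostic biomarkers: depth and
ulceration alone leave clinicians guessing which stage II–III patients will
die of their disease, and pathologist grading of tumor-infiltrating
lymphocytes (TILs) as absent / non-brisk / brisk is notoriously
observer-dependent. **adta** implements a fully quantitative alternative:
automated digital TIL analysis over H&E whole-slide images, scored inside a
pathologist-annotated tumor region and validated against disease-specific
survival (DSS). It is written for computational pathology and biostatistics
groups who have patch-level lymphocyte probability maps from an upstream
detector and want a tested, reproducible pipeline from those maps to a
binary prognostic risk class.

## The score and the statistics

Each image arrives as a table of 100×100-px patches with the probability of
lymphocytic infiltration per patch. With tumor mask *M* and positivity
threshold τ (default 0.775):

    s(image)  =  #{patches in M with p ≥ τ} / #{patches in M}
    ADTA(patient) = median over the patient's images of s

On a training cohort, the ROC of patient scores against the
died-of-melanoma label (low score predicts death) yields an operating
cutoff *c* maximizing Youden's J = sensitivity + specificity − 1; patients
with ADTA ≥ *c* are **low risk** (high infiltrate, good prognosis).
Validation on an independent cohort uses Kaplan–Meier curves with at-risk
reporting, the log-rank (Mantel–Cox) test, and Cox proportional-hazards
models (Efron ties) — univariable and adjusted for Breslow depth,
ulceration, T stage, or derived overall stage (node/satellite-positive →
III, otherwise I/II by T band). Spearman rank correlation and a
Kruskal–Wallis comparison quantify agreement with ordinal pathologist TIL
grades. A synthetic-cohort generator with spatially clustered infiltration
and proportional-hazards survival makes every stage testable without
patient data.

## Worked example

Train a cutoff on one synthetic cohort, validate it on another:

```r
library(adta)

train <- gen_cohort(sim_config(seed = 1, n_patients = 80))
scored <- score_cohort(train$patch_sets, train$annotations, train$index)
m <- merge(scored$patients, train$clinical, by = "patient_id")
roc <- roc_curve(m$adta, m$dss_event)
roc
#> <roc_result> 44 died / 36 survived; AUC = 0.5306; max J = 0.205 at 0.0539
cutoff <- select_cutoff(roc)        # 0.0539

val <- gen_cohort(sim_config(seed = 1000001, n_patients = 145))
vs <- score_cohort(val$patch_sets, val$annotations, val$index)
d <- merge(vs$patients, val$clinical, by = "patient_id")
d$high_risk <- as.integer(classify_risk(d$adta, cutoff) == "high_risk")
d$time <- d$followup_months; d$event <- d$dss_event

logrank_test(d$time, d$event, d$high_risk)
#> <logrank_result> chi-square = 13.7234 (1 df), p = 0.0002118
cox_fit(d, c("high_risk", "depth_mm", "ulceration"))
#> <adta_cox> n = 145, events = 70, ties = efron
#>   high_risk    HR =   4.44 (1.89-10.41), p = 0.0006099
#>   depth_mm     HR =   1.18 (1.05-1.31), p = 0.003471
#>   ulceration   HR =   1.46 (0.90-2.36), p = 0.127
spearman_grade(d$adta, d$til_grade)
#> <spearman_result> rho = 0.617, p = 1.427e-16, n = 145
```

Read: the training ROC picks a cutoff of 0.054; applied to the independent
cohort it splits survival strongly (log-rank p ≈ 2×10⁻⁴), and the high-risk
class multiplies the death hazard by ≈ 4.4 after adjusting for depth and
ulceration — the true simulated effect is HR 4. The ADTA score also tracks
the (noisily) simulated pathologist TIL grades (ρ = 0.62). Because the
cutoff is estimated from only 80 patients, its transfer quality varies
across seeds; the methods vignette discusses this variance and when cutoff
recovery is well-posed.

File-based stages with run manifests are available as
`adta_simulate()` / `adta_score()` / `adta_cutoff()` / `adta_validate()`,
or from a shell via the bundled script:

```sh
Rscript inst/scripts/adta simulate --config run.yaml --set simulate.seed=7
```

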