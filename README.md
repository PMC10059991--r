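# gefed

Federated Grammatical Evolution for interpretable glucose forecasting.

People with type-1 diabetes steer their glucose with insulin doses and meal
planning, guided by a continuous glucose monitor (CGM) sampling every 5
minutes. A forecast 30 minutes ahead gives time to prevent a hypo- or
hyperglycemic event — but clinically it matters *which band* the glucose
will be in (very low … very high), not its exact value, and the models
that issue such warnings should be both **private** (trained without
pooling patient data) and **interpretable** (a formula a clinician can
read). `gefed` is built for researchers studying exactly that combination.

## What it does

Each patient ("slave") evolves, by Grammatical Evolution over a constrained
BNF grammar, an explicit forecasting expression

```
Ĝ(t + hΔt) = ( Γ(G(t), …, G(t−kΔt)) − Θ(I(t), …, I(t+hΔt)) + Ω(C(t), …, C(t+hΔt)) ) ◊ Φ(dG(t,t−Δt), …, dG(t,t−kΔt))
```

with `◊ ∈ {+, −, ·}`, where `G` are past CGM readings (mmol/L), `I` is the
plasma-insulin signal obtained from logged boluses and basal rates through
a two-compartment Hovorka-type absorption chain, `C` is the gut
carbohydrate absorption signal of logged meals, and `dG` are backward
glucose differences. Defaults `k = 12`, `h = 6` give a 30-minute forecast
from a 60-minute history. The forecast is banded into seven clinical
glycemic classes (two hypo, three normal, two hyper) and fitness is the
class-frequency-weighted F1 of those bands — the data are heavily
imbalanced, and the rare hypoglycemic classes are the ones that matter.

A master/slave federation (FLEA) periodically relays each patient's best
model to all other patients, who score it on *their own* data and keep it
if it beats their worst individuals. Only model expressions and scores
travel; raw CGM data never leave a slave. After evolution the per-patient
best models are cross-evaluated on every patient's test set and the one
with the best average becomes the global model. An identical run with
migration disabled (`non_fl`) is the baseline, and a Quade test with five
post-hoc procedures (Bonferroni–Dunn, Holm, Hochberg, Finner, Li) compares
the two arms across subjects.

Because the OhioT1DM CGM data set is access-restricted, the package ships
a synthetic cohort generator emulating its structure (5-minute grid,
glucose in [2, 25] mmol/L, Poisson meals with imperfect bolus dosing,
missing readings, hypo-rare class imbalance), plus an Ohio-style XML
reader for those with data access.

## Worked example

```r
library(gefed)
cohort <- simulate_cohort(cohort_config(n_patients = 3, days = 2, seed = 7))
fit <- flea_fit(cohort, flea_control(migration_interval = 10,
                                     ge = ge_control(population_size = 30,
                                                     generations = 30),
                                     seed = 42))
print(fit)
#> flea_fit (flea): 3 patients, 30 generations, 3 migration rounds
#>   global model: patient sim2  (cross-eval mean F1 0.8643)
#>   formula: (g2-plog((aq(psqrt((psqrt((aq(1.9,aq(i3,i2)) ... )+psqrt(c4))+dg2
print(fit$cross_eval)
#> Cross-evaluation weighted F1 (rows = models, cols = patients):
#>       evaluated_on
#> model    sim1   sim2 sim3
#>   sim1 0.7712 0.7432    1
#>   sim2 0.9341 0.6589    1
#>   sim3 0.9341 0.6589    1
score_model(fit$global_model, sample_split(build_samples(cohort[[2]]), "test"))
#> Weighted classification scores (67 samples)
#>   precision 0.6131  recall 0.7164  F1 0.6589  accuracy 0.7164
```

The printed formula is the model: a readable arithmetic expression over
named lags (`g2` = glucose 10 min ago), future absorption values (`i3`,
`c4`) and differences (`dg2`). Cross-evaluation cell (i, j) is model i's
weighted F1 on patient j's held-back test window; the global model is the
row with the best mean. The two-arm comparison at scale is run with
`flea_experiment()`, and `quade_test()` / `quade_posthoc()` compare the
arms across subjects.

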