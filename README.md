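# neolos

Gestation-stratified modelling of neonatal intensive care **length of
stay (LOS)** from daily deviations of nutrition and medication orders
against guideline recommendations — for biostatisticians and clinical
data scientists building or auditing LOS prediction pipelines on NICU
order streams.

## What it computes

For each patient and nutrient (enteral/parenteral energy in kcal/kg/day,
protein in g/kg/day), daily orders are scored against a table-driven
guideline recommendation (with the *highest-intake* rule on days of
combined EN+PN feeding) and summarised by the **deviation factor**

    D = sqrt( sum_i (x_i - x_i')^2 ) / n

— the L2 norm of the daily recommended-minus-ordered gaps over an n-day
stay, normalised by stay length. Within each gestation stratum
(26–32, 32–34, 34–37, ≥37 weeks) patients strictly above the nearest-rank
75th percentile of D form the top-quartile risk group `Q4`. Medication
orders deviate when dose per kg or daily frequency differs from the
reference by ≥10 % (vitamins/iron excluded); a patient's dose-deviation
days and category (`not_required` / `no_deviation` / `deviation`) feed
the model.

LOS is then modelled per stratum by OLS on a response transform selected
from {identity, log, sqrt, inverse} via repeated 80/20 splits (one per
patient) ranked by day-scale, Jacobian-corrected AIC; terms are screened
at p < 0.05 and refitted; each retained factor's contribution is
expressed in whole days via frequency-weighted (**ordinary**) marginal
means anchored at the grand marginal mean; and per-patient predictions,
validation RMSE/R², and a bedside JSON payload with change highlighting
are produced. A synthetic two-site cohort generator with fully known
multiplicative ground truth (`simulate_cohort()`) backs every test.

## Worked example

```r
library(neolos)

cohort <- simulate_cohort(sim_config(n_patients = 600), seed = 42)
cohort
#> <nicu_cohort> 600 patients, 4418 nutrition orders, 2493 medication orders
#>   G26_32   G32_34   G34_37 G37_plus
#>       68      134      190      208

run <- run_pipeline(cohort, seed = 42, n_iterations = 50)

run$rankings[["G32_34"]]          # transform comparison, 32-34 weeks
#>     family mean_aic mean_bic   mean_r2 mean_rmse_test rank
#> 1      log 356.2692 386.9885 0.6456914       2.728128    1
#> 2     sqrt 366.5003 397.2195 0.6747212       2.617769    2
#> 3  inverse 379.7300 410.4493 0.5253925      15.309057    3
#> 4 identity 398.9865 429.7058 0.6690628       2.637482    4

subset(run$models[["G32_34"]]$effects, select = -raw_effect_days)
#>                factor        level effect_days      p_value
#> 1              sepsis        FALSE           0 4.899862e-03
#> 2              sepsis         TRUE           9 4.899862e-03
#> 3     energy_quartile    remaining          -1 7.285994e-17
#> 4     energy_quartile           Q4           4 7.285994e-17
#> 5 medication_category not_required           0 4.366625e-09
#> 6 medication_category no_deviation          -1 4.366625e-09
#> 7 medication_category    deviation           5 4.366625e-09

run$validation[, c("gestation_category", "rmse", "r_squared", "n")]
#>   gestation_category      rmse r_squared  n
#> 1             G26_32 10.866360 0.8041447 14
#> 2             G32_34  2.192654 0.1556815 22
#> 3             G34_37  1.548450 0.5637454 48
#> 4           G37_plus  1.369114 0.5570589 52

run$payloads[[1]]
#> <bedside_payload> P00005 ( G34_37 ) predicted LOS: 6 days
```

Reading the output: the log transform wins the family comparison in the
32–34-week stratum (it is the generator's truth). The screened model
retains sepsis, the top-quartile energy deviation and the medication
category; the day-effect table says a top-quartile energy deviator is
expected to stay about 4 days longer than the stratum's weighted average
patient (the generator injects +5 days; whole-day rounding and sampling
noise account for the difference), and a patient with a ≥10 % dose
deviation about 5 days longer. Validation rows show per-stratum held-out
RMSE in days; the 26–32-week stratum has the largest errors because its
stays are an order of magnitude longer.

The bundled default guideline tables (`inst/extdata/`) are editable
placeholders with plausible neonatal ranges — swap in your unit's
references via `read_guidelines()` for real use. A thin command-line
wrapper over the same functions ships in `inst/scripts/nicu-los.R`
(subcommands `simulate`, `deviations`, `fit`, `report`).

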