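# geoanaemia

Bayesian geoadditive logistic models for mapping childhood anaemia (and
other binary child-health outcomes) across districts, from two-stage cluster
survey data.

## The problem

Childhood anaemia — altitude-adjusted haemoglobin below 11 g/dL in children
aged 6–59 months, by the WHO definition — varies strongly both with
measurable risk factors (malaria, maternal education, household wealth,
sanitation) and across space. Control programmes need to know how much of
the spatial variation follows district boundaries smoothly (shared
environment, factors that transcend boundaries) versus being district
specific. The class of model used for such questions is the **geoadditive
logistic regression**: for child *k* in household *j*, cluster *i* and
district *h*,

```
logit P(anaemic) = x'β + f_age(age) + f_str(district) + f_unstr(district)
```

with parametric fixed effects `β`, a penalised B-spline (P-spline) smooth of
age with a second-order random-walk prior, and a BYM-type spatial effect
split into a structured component (intrinsic CAR: each district's effect is
conditionally Gaussian around the average of its boundary-sharing
neighbours, precision `τ²_str`) and an unstructured iid component
(precision `τ²_unstr`). Priors are vague Gaussians N(0, 1000) on the fixed
effects and Gamma(1, 0.001) on every precision. Models of increasing
structure (GLM → GAM → geoadditive) are compared by DIC. Inference is a
Pólya-Gamma data-augmentation Gibbs sampler with exact handling of the
sum-to-zero identifiability constraints; see the methods vignette
(`vignettes/geoadditive-anaemia-mapping.Rmd`) for the full model, priors,
sampler and design choices.

Because the surveys this model is built for (DHS / MIS) are
access-restricted, the package includes a first-class synthetic survey
generator — the model run forwards over a nested
district/cluster/household/child design — so the entire pipeline is testable
end to end.

## Worked example

```r
library(geoanaemia)

# a synthetic survey: 60-district rook grid, ~7,800 children
survey   <- simulate_survey(synth_design(seed = 11))
children <- survey$children

weighted_prevalence(children, by = "malaria_rdt")
#>         group    level n_weighted prevalence    ci_lo    ci_hi
#> 1     overall            8551.153   51.64438 50.48068 52.80631
#> 2 malaria_rdt positive   2129.238   76.80451 74.78223 78.71078
#> 3 malaria_rdt negative   6421.915   43.30234 41.97591 44.63845

fit <- fit_geoadd(build_design(children, model_spec("m3"), survey$graph),
                  mcmc = mcmc_config(n_iter = 1600, burn_in = 500,
                                     thin = 2, seed = 1))
dic(fit)
#> DIC = 9798.75 (Dbar = 9728.84, pD = 69.90)

aor <- aor_table(fit)
aor[aor$column %in% c("gender_female", "malaria_rdt_positive", "wealth_index"),
    c("column", "level", "reference", "AOR", "ci_lo", "ci_hi", "significant")]
#>                  column    level reference   AOR ci_lo ci_hi significant
#> 1         gender_female   female      male 0.914 0.834  1.01       FALSE
#> 2  malaria_rdt_positive positive  negative 4.637 4.104  5.24        TRUE
#> 12         wealth_index                    0.866 0.822  0.91        TRUE

vt <- variance_table(fit)
vt
#>            effect     mean  ci_lo    ci_hi
#> 1 tau2_age_months 1057.609 73.948 3688.545
#> 2        tau2_str 1164.409 83.229 4245.791
#> 3      tau2_unstr    6.204  3.767    9.386
attr(vt, "dominance")
#> [1] "unstructured"

district_summary(fit)
#> Spatial effect summary over 60 districts
#>   structured: mean range [-0.0106, 0.0113]; 0 +, 0 -, 60 null
#>   unstructured: mean range [-0.8716, 0.8066]; 12 +, 13 -, 35 null
```

Reading the output: children testing malaria-positive have ~4.6 times the
adjusted odds of anaemia (the generating truth is 4.401); the structured
spatial precision is two orders of magnitude above the unstructured one, so
district-specific heterogeneity dominates — every district's structured
effect is statistically null while 25 of 60 districts carry a significant
unstructured effect, matching how the data were generated
(`τ²_str = 853.58`, `τ²_unstr = 3.84`). `smooth_summary(fit, "age_months")`
returns the centred non-linear age effect (peaking near 10 months) with a
95% band, and `export_district_summary()` writes the district
classifications to CSV/GeoJSON for mapping.

Screening utilities mirror the usual pre-modelling pipeline:
`classify_anaemia()` (strict 11 g/dL rule), `univariate_screen()` (10%-level
likelihood-ratio screen), `vif_table()` (collinearity, flag at VIF ≥ 4), and
`sensitivity_analysis()` refits under alternative Gamma hyper-parameters.

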