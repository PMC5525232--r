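# equicare

Tools for measuring **income-related inequality in health-care utilisation**
across repeated cross-sectional health surveys — for health economists and
biostatisticians who need to turn raw survey questionnaires (interval-censored
household income in wave-specific band dialects, recall-window contact counts,
last-contact ownership flags) into comparable annual public/private
utilisation counts, and then ask whether income groups use services
differently and whether that changed between waves.

## The model

Utilisation of a service is a zero-inflated count analysed as a **two-part
hurdle model**, estimated jointly:

- **Part 1 — any use** (patient-initiated): logistic,
  `logit(μ₁ᵢ) = X₁ᵢ'β₁`, with the structural Bernoulli variance
  `μ₁ᵢ(1 − μ₁ᵢ)` (no part-1 dispersion parameter — it is not identified).
- **Part 2 — frequency among users** (provider-driven): zero-truncated
  negative binomial with `μ₂ᵢ = exp(X₂ᵢ'β₂)` and NB1 dispersion
  `ψ₂ᵢ = μ₂ᵢ/φ`:

  ```
  f₂(y | y > 0) = [Γ(y+ψ)/(Γ(ψ)Γ(y+1)) · (μ/(μ+ψ))^y] / [((μ+ψ)/ψ)^ψ − 1]
  ```

The parts multiply in the likelihood; covariates may differ between parts.
Gaussian random intercepts `υⱼ ~ N(0, σ_υ²)` shared by both parts are
integrated by Gauss–Hermite quadrature, with a penalised-complexity-style
exponential penalty on `σ_υ` calibrated by `P(σ_υ > u) = α`.

Around this core the package implements the full construction pipeline:
per-wave **ordered-probit income harmonisation** onto a common latent scale
with within-wave quartiles (Q1 = poorest = reference); **ownership
imputation** of public/private contact splits from single-visit respondents
(`private = round(total·p̂)`, conservation `public + private = total` exact);
**annualisation** (×12 for 4-week services, model-based imputation of one
delayed contact for zero reporters with predicted delay probability > 0.5);
a **22-item medicine count** excluding contraceptives; and the quartile ×
wave **inequality report** (Wilcoxon/Fisher tests, percent changes, nested
Model 1→2→3 hurdle sequence). A seeded synthetic generator emulates the
whole two-wave survey structure so everything is testable without
restricted microdata.

## Worked example

```r
library(equicare)

d <- generate_survey(survey_config(n = c("2006" = 5000, "2011" = 5000)), seed = 1)
a <- build_analysis_dataset(d)           # quartiles, ownership split, annual counts

tab <- format_descriptive(descriptive_table(a))
tab[tab$variable == "emergency_public", c("quartile", "mean_pre", "mean_post",
                                          "pct_change", "p.value", "test")]
#>  quartile mean_pre mean_post pct_change p.value     test
#>         1    0.958     0.888       -7.3   0.286 wilcoxon
#>         2    0.718     0.808       12.5   0.036 wilcoxon
#>         3    0.703     0.666       -5.3   0.403 wilcoxon
#>         4    0.613     0.606       -1.3   0.355 wilcoxon
#>       all    0.748     0.742       -0.9   0.750 wilcoxon
```

Mean annual public emergency contacts fall from 0.96 (poorest quartile) to
0.61 (richest) in the pre-crisis wave — a pro-poor gradient — and the
per-quartile wave changes are small, as the generator's defaults encode.
The model-based version adjusts the gradient for need and double cover
(Model 3: quartiles + sex + age + private insurance + GHQ-12):

```r
ms <- run_model_sequence(a, "emergency", "public", models = 3)
subset(tidy(ms), wave == 2006 & part == "use")[, c("term", "estimate", "conf.low", "conf.high")]
#>        term estimate conf.low conf.high
#>  quartileq2    0.739    0.621     0.881
#>  quartileq3    0.760    0.637     0.908
#>  quartileq4    0.676    0.560     0.815
```

Respondents in the richest quartile have 0.68 times the odds of any public
emergency use relative to the poorest quartile, need held fixed — the
adjusted pro-poor gradient. `autoplot(ms)` draws the ratios across models
and waves; `glance(ms)` tabulates fit summaries.

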