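---
title: "Two-part hurdle models for income-related inequality in health-care use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part hurdle models for income-related inequality in health-care use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Repeated cross-sectional health surveys are the standard instrument for
asking whether an external shock — here, a financial crisis — changed how
income groups use publicly and privately funded health services. Answering
that question from survey microdata requires a chain of constructions
before any model can be fitted, because the raw questionnaires do not
deliver the analysis variables directly:

1. **Income is interval-censored and incomparable across waves.** One wave
   asks annual household income in 8 bands, the other monthly income in 10
   bands with different edges, so the band index itself carries no common
   meaning.
2. **Ownership of contacts is only observed for the last contact.** The
   surveys ask how many times a service was used, but whether the provider
   was public or private only for the most recent contact.
3. **Recall windows differ by service.** Primary-care and specialist
   contacts are asked over the last 4 weeks; hospitalisations and
   emergencies over the last 12 months.
4. **Utilisation is a zero-inflated count.** Most respondents have no
   contact with a given service in the window; users' counts are
   overdispersed.

`equicare` implements this chain end to end, together with a seeded
synthetic-data generator that emulates the whole structure so that every
stage is testable without restricted microdata.

```{r, eval = FALSE}
library(equicare)
d <- generate_survey(survey_config(n = c("2006" = 5000, "2011" = 5000)), seed = 1)
a <- build_analysis_dataset(d)
descriptive_table(a)
run_model_sequence(a, "emergency", "public")
```

## Income harmonisation

Per wave, an ordered probit regresses the observed band $k_i$ on sex, age
band, occupation, education and household size: with strictly increasing
thresholds $c_1 < \dots < c_{K-1}$,
$$\Pr(k_i = k) = \Phi(c_k - X_i'\gamma) - \Phi(c_{k-1} - X_i'\gamma).$$
Respondents are then scored by the fitted latent index $X_i'\hat\gamma$ and
assigned within-wave quartiles (quartile 1, the poorest, is the reference
everywhere).

*Which "probability" to score by is genuinely open* — an 8-category model
offers many per-respondent summaries. We score by the latent index because
every sensible alternative (expected band, $\Phi$ of the index,
$\Pr(\text{band} > \text{median})$) is a strictly monotone transform of it,
and quartiles — the only downstream use — are invariant under monotone
transforms. The test-suite asserts that invariance directly.

Quartile cut points are type-1 (inverted-CDF) sample quantiles and a score
exactly at a boundary goes to the lower quartile; this makes the labels a
reproducible, order-based function of the scores. The fit is a plain
ordered probit: with one income response per respondent an
individual-level random intercept is not identified, so none is included.
With only two observed bands the model degenerates to probit regression
and is fitted as such.

## Ownership imputation

For each service and wave, respondents who reported *exactly one* contact
identify the ownership of their entire utilisation, so a logistic model of
the last-contact ownership flag on sex, age band, self-perceived health
and chronic-condition count is fitted on that subsample only. Everyone
else's total is split by the predicted private probability $\hat p$:
single-visit users keep their observed flag; multi-visit users get
$\text{private} = \operatorname{round}(\text{total}\times\hat p)$ with
round-half-to-even and $\text{public} = \text{total} - \text{private}$;
non-users get zeros. Conservation ($\text{public} + \text{private} =
\text{total}$) is exact by construction and asserted for every respondent.

The rounding rule keeps counts integer-valued for the count model and is
deterministic. Its cost is a truncation bias when $\text{total}\times\hat
p < 0.5$ for most respondents — at a 5% private share, nearly all expected
private counts round to zero and the aggregate private share is
underestimated. This is a property of any deterministic integer split at
small shares; the recovery test therefore exercises the rule at a moderate
share, and results for low-share services (private hospitalisations,
private emergencies) should be read with this in mind.

## Annualisation and delayed contacts

Counts from the 4-week services are extrapolated by $\times 12$, but only
for respondents reporting at least one contact. A zero report does not
prove a year of non-use: the respondent may simply have waited longer than
4 weeks between perceiving a problem and contacting care. Among users, a
logistic model of the indicator "sought care more than 4 weeks after
perceiving a problem" (same covariates as the ownership model) is fitted
per wave; zero reporters with predicted probability strictly above 0.5 are
imputed **one** annual contact (not 12 — multiplying an imputed contact
would fabricate frequency), allocated to public/private by the ownership
model with the same rounding rule. A probability of exactly 0.5 imputes
nothing. Hence annualised 4-week counts are multiples of 12 *except* the
imputed singletons — an invariant the suite asserts exactly.

The medicine count sums 21 of the 22 binary medicine-use items, excluding
the contraceptive item, giving a 0–21 count analysed as total only.

## The two-part hurdle model

Any use and frequency of use are distinct decisions (contact is largely
patient-initiated; frequency largely provider-driven), so the count
$y_i$ is modelled in two parts estimated **simultaneously**:

* Part 1 (any use): $\mathrm{logit}(\mu_{1i}) = X_{1i}'\beta_1$ with
  $\operatorname{Var}(y_{1i}) = \mu_{1i}(1-\mu_{1i})$ — the Bernoulli
  variance is structural; no part-1 dispersion parameter exists in the
  code, because with a binary outcome it would not be identified.
* Part 2 (frequency among users): zero-truncated negative binomial
  $$f_2(y \mid y > 0) =
    \frac{\frac{\Gamma(y+\psi)}{\Gamma(\psi)\Gamma(y+1)}
          \left(\frac{\mu_2}{\mu_2+\psi}\right)^{y}}
         {\left(\frac{\mu_2+\psi}{\psi}\right)^{\psi} - 1},
    \qquad \mu_{2i} = \exp(X_{2i}'\beta_2),\; \psi_{2i} = \mu_{2i}/\phi.$$
  The dispersion is NB1-style ($\psi = \mu/\phi$, untruncated variance
  $\mu(1+\phi)$), taken exactly as written — not the more common NB2
  convention. Since $(\mu+\psi)/\psi = 1+\phi$, the pmf is computed on the
  log scale with $\log[(1+\phi)^\psi - 1] = \psi\log(1+\phi) +
  \log(1-e^{-\psi\log(1+\phi)})$, stable across the grid the tests cover
  ($\mu$ from 0.01 to 100, $\phi$ from 0.05 to 50); for very large $\psi$
  the gamma ratio is evaluated as an exact product to avoid cancellation.
  As $\phi \to 0$ the pmf converges to the zero-truncated Poisson, which
  the suite checks against the closed form.

The two parts multiply in the likelihood; the covariates of the two parts
may differ, and when they share no parameters the joint maximum coincides
with the two marginal maxima — asserted numerically as a correctness check
of the joint optimiser.

### Random effects and penalisation

All models can carry a Gaussian random intercept $\upsilon_j \sim N(0,
\sigma_\upsilon^2)$ shared by both parts. An *individual* effect is not
identified with one observation per respondent per part, so effects attach
to a declared grouping column — households in the synthetic data, which
average 2.5 respondents. Group likelihood contributions are integrated by
Gauss–Hermite quadrature (20 nodes by default, fixed nodes rather than
per-group adaptive centering — sufficient at household cluster sizes and
$\sigma_\upsilon \le 1$, as the recovery suite verifies). A full Bayesian
treatment is out of scope; instead the fit is penalised maximum
likelihood with an exponential penalty $\lambda\sigma_\upsilon$ emulating
a penalised-complexity prior, calibrated by $P(\sigma_\upsilon > u) =
\alpha$ with defaults $u = 1$, $\alpha = 0.01$ (so $\lambda =
-\log(0.01)$). No sampling-based mode is provided.

### Numerical choices

Optimisation is BFGS with analytic gradients for both objectives (the
random-effect gradient reuses the per-node posterior weights), at most 500
iterations, relative tolerance $10^{-12}$. Starting values: part 1 from a
plain logistic fit, part 2 from a Poisson fit on users, $\phi$ from the
method-of-moments excess variance floored at $10^{-3}$,
$\sigma_\upsilon$ at 0.3. A fit is flagged non-converged when the
optimiser reports failure or the gradient norm exceeds a sample-size-scaled
threshold; flagged fits warn and carry `converged = FALSE` rather than
failing silently. Standard errors come from the inverse observed
information (numerically differentiated at the optimum) on the working
scale ($\beta$, $\log\phi$, $\log\sigma_\upsilon$).

Two small-sample boundary cases are worth knowing. If a cell's users all
report exactly one contact, the ZTNB likelihood is maximised at
$\mu_2 \to 0$ (the distribution degenerates to a point mass at 1) and the
information matrix is singular; such fits are flagged, and the calibration
tests exclude and bound them. Complete separation in the logistic
components raises a structured fit error naming the service and wave.

## The inequality report

`descriptive_table()` reproduces the quartile × wave layout: per-cell n,
mean and SD, the percent change $(\bar y_{\text{post}} -
\bar y_{\text{pre}})/\bar y_{\text{pre}} \times 100$ (exactly $-100$ when
a positive pre-crisis mean vanishes; undefined, and reported as such, when
the pre-crisis mean is zero), and a p-value comparing waves within the
quartile — Wilcoxon rank-sum for counts, Fisher's exact test for binary
variables. Wave comparisons are made within quartile; an overall row
reproduces the unstratified layout. No multiple-testing adjustment is
applied — the report prints raw p-values, deliberately, and users should
adjust if they require familywise control. Both tests treat respondents as
independent; when observations cluster (e.g. household random effects) the
rank-sum test is mildly anti-conservative, a caveat that applies equally to
descriptive tests on real survey microdata. Printed rounding is 3 decimals
for means/SDs and 1 for percent changes.

`run_model_sequence()` fits the nested sequence per wave: Model 1 with
income quartiles only; Model 2 adding sex and age; Model 3 adding private
insurance and the GHQ-12 mental-health score (a 0–12 count used as a need
proxy). Medicines are fitted as total only. Quartile effects are reported
as odds ratios (part 1) and rate ratios (part 2) against quartile 1 with
delta-method intervals; a wave whose fit fails (e.g. no private users at
all) is flagged in the output rather than dropped.

## What the synthetic generator does and does not emulate

The generator (`survey_config()` defaults) draws, per wave: sex and
age-band composition matching the two waves' published margins; occupation,
education, household size, self-perceived health, chronic counts and a
beta-binomial GHQ-12 from realistic categorical distributions; a latent
log-income index with occupation/education gradients, discretised by the
wave's band dialect (8 annual bands vs 10 monthly bands × 12, half-open
intervals so a value at a cut point takes the upper band); two-part
utilisation per service with a shared household random intercept
($\sigma_\upsilon = 0.3$); per-contact ownership from a logistic model in
exactly the covariates the imputation fits; recall-window thinning of
annual primary/specialist contacts at 4/52 per contact, making the ×12
rule an approximate inverse (within 10% in the mean, asserted); delayed
indicators for users; and 22 medicine items with a shared frailty. Wave
sample sizes default to 29,712 and 19,935. Default income gradients are
pro-rich for specialist care and pro-poor for primary care, emergencies
and hospitalisations, with a crisis-wave shift down for primary care and
hospitalisations and up for specialist care.

It does **not** emulate: questionnaire skip patterns or item nonresponse
mechanisms beyond optional MCAR missingness; survey design weights;
panel linkage (the waves are independent cross-sections); seasonal
structure in the 4-week window; or ownership gradients by income (true
ownership depends only on the covariates the imputation models use, so
the imputation is correctly specified by construction — real data offer
no such guarantee). Passing tests therefore demonstrate that the
*procedures* recover what this structure encodes, not that any substantive
estimate transfers to real survey data.

Test problem sizes are the package's choices: parameter-recovery suites
use 200 replicates at n = 5,000 (fixed effects) and 100 replicates of 400
households × 10 (random-effect SD); null calibration uses 200 replicates
at n = 800 per wave; sign-recovery of opposite service gradients uses 100
replicates at n = 5,000.

## Known limitations

- The deterministic integer split biases aggregate private shares downward
  when shares are small (see above).
- The ×12 annualisation inflates the variance of annual counts and cannot
  recover within-year frequency for zero reporters beyond the single
  imputed contact; descriptive tables can be run on raw recall-window
  counts via `annualized = FALSE`.
- Wald intervals from the observed information are first-order; at small
  per-cell sample sizes the count part's intervals can be anti-conservative
  near the boundary.
- The PC-style penalty shrinks $\sigma_\upsilon$ toward zero; with few,
  small groups the posterior-mode analogue can sit noticeably below the
  simulation truth.
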