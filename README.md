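# critmix

Bayesian mixture modeling of **criterial** vs. **degree** vagueness in
repeated categorization data.

When people answer the same category membership questions twice
(sessions a few weeks apart), many answers change. `critmix` is for
cognitive scientists and psycholinguists who want to know *why*: did a
respondent merely shift the amount of evidence they require (a moved
threshold on a fixed ordering of items — degree vagueness), or did they
apply a different criterion altogether, re-ordering the items
(criterial vagueness)? The package fits a latent-group item-response
mixture to repeated yes/no/unknown membership decisions, assigns every
respondent-session to a criterion group by its posterior mode, and
counts within-person group changes between sessions — alongside the
plain descriptive inconsistency statistics.

## The model

Every respondent-session is an independent entry *p*. For item *i*,

```
x_ip ~ Bernoulli(r_ip)
r_ip = 1 / (1 + exp(-alpha_g (beta_gi - theta_p))),   g = z_p
```

* `z_p ~ Categorical(pi)` — latent criterion group (uniform Dirichlet
  prior on `pi`);
* `beta_gi ~ Normal(0, 1)` — item scale value under group *g*'s
  criterion;
* `theta_p ~ Normal(mu_g, 1)`, `mu_g ~ Normal(0, 1)` — respondent
  threshold and its group-specific mean (all "precision 1");
* `alpha_g ~ |Normal(0, 1)|` — steepness of the S-shaped response
  function, which equals .50 exactly where `beta_gi = theta_p`.

`unknown` responses are missing values: dropped from the likelihood,
never imputed. Fitting is Metropolis-within-Gibbs (exact Gibbs for `z`,
`pi`, `mu`, and a per-group location move; adaptive random-walk
Metropolis for `beta`, `theta`, and `log alpha`), followed by
relabeling to resolve label switching, split-R-hat/ESS convergence
diagnostics, and posterior-mode group assignment. A participant whose
two sessions land in different criterion groups is a detected
criterion change.

## Worked example

Simulate a two-session study with known ground truth (30 two-session
participants, 100 single-session archival respondents, 16 items, 20%
of participants switching criterion group between sessions), fit, and
ask which participants changed criteria:

```r
library(critmix)

cfg <- sim_config(n_participants = 30, n_archival = 100, n_items = 16,
                  switch_fraction = 0.2, seed = 2026)
truth <- generate_two_session_study(cfg)
m <- merge_sessions(truth$table, truth$archival_table, "synthetic")
m
#> merged_matrix: category 'synthetic', 160 entries x 16 items (56 missing cells)
#>   entries by provenance: archival=100, synthetic=60

build_consistency_report(truth$table, c(synthetic = "nominal"))
#> consistency_report: 480 pairs, overall inconsistency 25.00%

fit <- relabel(fit_mcmc(m, G = 2, n_chains = 2, n_iter = 1500,
                        n_burnin = 500, seed = 1))
summary(convergence_diagnostics(fit)$rhat)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9992  1.0010  1.0033  1.0049  1.0060  1.0470

asg <- assign_groups(fit)
pairs <- assign_sessions(asg, m)
pairs$category <- "synthetic"
cons <- build_consistency_report(truth$table, c(synthetic = "nominal"))
changes <- build_group_change_report(pairs, cons)
changes$per_category
#>    category n_participants n_changed n_with_inconsistency change_rate
#> 1 synthetic             30         6                   26         0.2
#>   change_rate_among_inconsistent
#> 1                      0.2307692

table(detected = pairs$changed,
      truth = pairs$participant %in% truth$switcher_ids)
#>         truth
#> detected FALSE TRUE
#>    FALSE    24    0
#>    TRUE      0    6
```

Reading the output: 25% of the repeated answers changed between
sessions, but only 6 of the 30 participants (23% of the 26 who showed
any inconsistency) were placed in different criterion groups — the
rest of the inconsistency is degree vagueness and response noise. Here
the detected changes recover the simulation's planted switchers
exactly (bottom table), and every R-hat is comfortably below 1.1.

Real data enter through `read_responses()` (CSV with columns
`participant,category,item,session,response`), and
`run_pipeline()`/`validate_config()` drive all stages per category
from a single JSON/YAML configuration, writing plain-text artifacts
plus a manifest.

## Package layout

* `R/response_table.R`, `R/merge.R` — response data model, CSV I/O,
  session merging into the model-ready matrix;
* `R/model.R`, `R/mcmc.R` — likelihood, priors, sampler;
* `R/relabel.R`, `R/assign.R` — label-switching resolution,
  diagnostics, posterior-mode assignment;
* `R/simulate.R` — the two-session synthetic-study generator (ground
  truth included);
* `R/consistency.R` — inconsistency and criterion-change reports;
* `R/pipeline.R` — config validation and the end-to-end driver;
* `vignettes/criterial-vagueness-model.Rmd` — the methods vignette:
  model assumptions, sampler design, calibration of the generator
  defaults, limitations.
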