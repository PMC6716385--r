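---
title: "Separating criterial and degree vagueness in repeated categorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating criterial and degree vagueness in repeated categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

When people answer the same category membership questions on two
occasions ("is a goldfish a fish?", "is a helicopter a means of
transport between Brussels and London?"), a sizable share of answers
change. Two mechanisms can produce such inconsistency:

* **degree vagueness** — the respondent applies the same *criterion*
  (the same latent ordering of items) on both occasions but demands a
  different *amount* of evidence: their threshold moved;
* **criterial vagueness** — the respondent orders the items differently
  on the two occasions: they switched to a different criterion
  altogether (fish-as-zoological-kind vs. fish-as-seafood, say).

These mechanisms are not distinguishable item by item, but they are
distinguishable at the level of a response *profile*: a threshold shift
moves a respondent along one item ordering, whereas a criterion switch
moves them between orderings. `critmix` implements the mixture model
that formalizes this distinction, an MCMC sampler for it, and the
bookkeeping that turns posterior group assignments into counts of
within-person criterion changes.

## The model

Each respondent-session is an independent **entry** `p` (a participant
who did the task twice contributes two entries; single-session archival
respondents contribute one). For entry `p` and item `i`, the observed
`yes`/`no` decision is Bernoulli,

    x_ip ~ Bernoulli(r_ip),
    r_ip = logistic(alpha_g * (beta_gi - theta_p)),   g = z_p,

where

* `z_p` in `1..G` is the entry's latent criterion group, categorically
  distributed with mixing probabilities `pi` (uniform Dirichlet prior);
* `beta_gi` is the item's scale value *under group g's criterion* — how
  strongly item `i` displays the property that group `g` uses to decide
  membership (independent standard normal priors per group and item);
* `theta_p` is the entry's threshold, drawn from the group-specific
  hyper-distribution `Normal(mu_g, 1)` ("precision 1" in
  inverse-variance terms), with `mu_g ~ Normal(0, 1)`;
* `alpha_g > 0` is the group's steepness: the response function is
  S-shaped, equals exactly .50 where `beta_gi = theta_p` (the point of
  subjective equality), and approaches 0/1 as the scale value falls
  short of / exceeds the threshold by a lot. Prior: half-normal with
  unit variance, i.e. `|Normal(0, 1)|`.

Only the shape properties of the response function are substantive
(monotone, .50 at equality, saturating); we fix the logistic form, the
standard choice in the Rasch/2PL item-response family that satisfies
all of them. `unknown` responses are treated as missing completely at
random and contribute nothing to the likelihood — they are dropped from
the Bernoulli product, never imputed.

`G` is fixed (default 2) rather than estimated; the two-group solution
is the configuration of interest throughout, and model selection over
`G` is out of scope.

## Sampling

`fit_mcmc()` runs a Metropolis-within-Gibbs scheme:

* `z_p`: exact Gibbs. The conditional is categorical with weights
  `pi_g * N(theta_p; mu_g, 1) * L(row p | beta_g, alpha_g)`, computable
  in closed form (the threshold hyper-density term matters: a group
  claims an entry partly through its threshold distribution).
* `pi`: conjugate `Dirichlet(1 + n_g)` given the group counts.
* `mu_g`: conjugate normal given the members' thresholds.
* `beta_gi` and `theta_p`: elementwise random-walk Metropolis. Given
  `z`, the likelihood factorizes over `(g, i)` cells for `beta` and over
  entries for `theta`, so a whole block of proposals is accepted or
  rejected independently in one vectorized pass.
* `alpha_g`: random-walk Metropolis on the log scale (with the
  log-normal proposal's Jacobian), since the parameter is positive.
* one **joint location move per group**: the likelihood depends on
  `beta - theta` only, so the direction "add a constant to a group's
  item scales, its members' thresholds, and its threshold mean" is a
  likelihood ridge pinned only by the priors. Componentwise updates
  traverse that ridge extremely slowly, which shows up as chains
  agreeing on every contrast but disagreeing on the common location
  (inflated split R-hat for `beta`, `mu`, `theta`). Along the ridge the
  conditional posterior of the shift is Gaussian
  (`delta ~ N(-(sum_i beta_gi + mu_g) / (I + 1), 1 / (I + 1))`), so the
  move is an exact Gibbs draw, not a proposal.

Random-walk step sizes adapt toward an acceptance rate of ~0.4 in
batches of 50 during burn-in only; after burn-in the kernel is fixed,
preserving detailed balance. Chains run sequentially with per-chain
seeds `seed + chain - 1`, so a fit is a pure function of (data,
protocol, seed).

The default protocol is 3 chains of 10,000 iterations with 4,000
burn-in. All package tests and the acceptance script use 2–3 chains of
up to 3,000 iterations with 1,000 burn-in at 370 entries x 24 items —
the package's standard demonstration size — which the convergence
diagnostics show to be ample for this model (split R-hat at or below
1.06 across all continuous parameters in the shipped checks).

Bernoulli log-likelihood terms are evaluated on the linear-predictor
scale via `plogis(eta, log.p = TRUE)`, which stays finite for saturated
probabilities; probability-scale `log(p)` would generate `0 * -Inf`
at steep `alpha`.

## Label switching, diagnostics, assignment

A mixture posterior is invariant under permutation of group labels, so
group-specific summaries require a common labeling. `relabel()` builds
a reference item-scale profile from the first chain (each draw's groups
provisionally ordered by `mu`, then averaged) and gives every draw of
every chain the permutation maximizing the summed Pearson correlation
of its `beta` rows with the reference. Ties and degenerate
(zero-variance) rows fall back to ordering by `mu`. The permutation is
applied jointly to `pi`, `beta`, `mu`, `alpha`, and `z`, so every
draw's likelihood and prior are unchanged; applying `relabel()` twice
is a no-op.

`convergence_diagnostics()` reports split R-hat (each chain halved
before the between/within comparison, so within-chain trends count
against convergence) and a multi-chain effective sample size with
Geyer initial-positive-sequence truncation, for every continuous scalar
parameter. Constant chains are reported as degenerate (`NA`) rather
than as a division by zero.

`assign_groups()` pools relabeled `z` draws across chains: an entry's
assignment probability for group `g` is the fraction of pooled draws
placing it there, and its group is the posterior mode. Exact ties are
flagged and broken toward the lower group index — a reproducible
convention; flagged ties should be inspected rather than trusted.
`assign_sessions()` then pairs each two-session participant's entries;
a participant whose modal group differs between sessions is a detected
criterion change. Pooling across chains (rather than using one chain)
uses all information and is well-defined once relabeling has aligned
the chains; this is the package's convention.

## The synthetic two-session study

`generate_two_session_study()` emulates the data-generating process the
model assumes, plus the two between-session mechanisms of interest:

* session 1: a population drawn from the model (groups, thresholds,
  responses);
* session 2: a controlled fraction of participants (`switch_fraction`,
  default 0.2) *switch* criterion group, their thresholds redrawn from
  the new group's hyper-distribution (a new criterion plausibly resets
  the threshold's frame of reference — the alternative, keeping the
  threshold, is available by setting `redraw_thresholds = FALSE`);
  non-switchers keep their group and undergo pure *degree drift*: a
  stationary autoregressive threshold step
  `theta_2 = mu + rho * (theta_1 - mu) + sqrt(1 - rho^2) * eps` with
  persistence `rho` (`theta_persistence`, default 0.95), which keeps
  thresholds marginally `Normal(mu_g, 1)` in both sessions so the
  fitted model remains correctly specified;
* every cell is independently replaced by `unknown` with probability
  `unknown_rate` (default 0.02) — missing completely at random,
  matching the model's ignorable treatment;
* optionally an independent archival population (default 250
  respondents) sharing the same item scales, mixing probabilities and
  hyper-parameters, contributing single-session entries, as archival
  data are merged in practice to stabilize the item-scale estimates.

Default dimensions mirror the study design the package targets: 60
two-session participants plus 250 archival respondents on 24 items
(370 entries; the ad hoc block variant, 254 archival respondents on 20
items, gives 374 x 20).

### Calibration of the defaults

The free generator parameters were set once, from generator-level
measurement, to make the synthetic study *look like* a real repeated
categorization study:

* `alpha = (6, 6)`. Steepness is not identified by any printed study
  quantity, but it governs pure response noise (`2p(1-p)` per cell).
  Small values (near the half-normal prior mean) make responding so
  noisy that two identical sessions already disagree on a third of
  answers, which no real study shows; steepness 6 brings clear members
  to near-deterministic endorsement, consistent with the observation
  that the clearest items draw perfectly consistent answers.
* `theta_persistence = 0.95`. A fully independent threshold redraw
  between sessions (persistence 0) flips roughly a third of answers by
  threshold crossing alone, again far above observed two-session
  inconsistency; month-scale threshold drift should be mild. With
  persistence 0.95 and steepness 6, the realized inconsistency
  proportion across seeds falls in the low twenties of percent —
  inside the 10–25% range bracketing what repeated categorization
  studies report — with the remainder contributed by the criterion
  switchers themselves and by `unknown` contamination.
* `beta_cor = 0.3`. Distinct criteria still order items similarly at a
  coarse grain (clear members are clear under both); the generated
  item-scale rows are rotated to this between-group correlation
  exactly.
* `mu = (-0.5, +0.5)`, `pi = (0.5, 0.5)`: two equally prevalent groups
  with modestly different response propensities.

What the generator does **not** emulate: item-content semantics (scale
values are exchangeable draws, not tied to real items), response-time
or typicality structure, non-random `unknown` usage (real respondents
reserve it for unfamiliar or ambiguous items), and any dependence of
switching on item content. Passing recovery tests therefore shows that
the estimation machinery works when the model's assumptions hold — not
that real categorization data satisfy those assumptions.

## Descriptive statistics

`classify_pair()` implements the inconsistency taxonomy: a pair of
repeated answers is inconsistent iff it changed (`yes/no`,
`yes/unknown`, `no/unknown`, in either order); `unknown/unknown` is
consistent, since the taxonomy lists changes only.
`build_consistency_report()` aggregates pair classifications per
participant, per item, per category and per block. Whether
`unknown`-both pairs belong in denominators is not settled by the
taxonomy; they stay in by default (an `unknown` given twice is an
answered, stable trial under a three-option task), and
`drop_unknown_pairs = TRUE` gives the other reading.

`build_group_change_report()` counts criterion changes with both
denominators: all participants, and participants with at least one
inconsistent answer in that category (the restricted denominator used
when asking what share of *observed* inconsistency reflects criterion
change). Its change counts depend only on whether the two sessions'
assignments differ, so they are invariant to group relabeling.

## Numerical conventions and degenerate inputs

* Items are ordered lexicographically at merge time, fixing the `beta`
  column indexing; entries are ordered participants-by-session, then
  archival.
* A matrix with every cell missing is rejected by default
  (`allow_all_missing = TRUE` opts in; the posterior is then the prior,
  which the test suite uses as a prior-recovery check).
* Merging requires completers: a participant present in only one
  session is an error, not silently dropped.
* An empty block in a prevalence summary yields an explicit `n = 0`
  row, never `NaN`.
* Assignment ties are flagged; the lower-index convention only breaks
  the tie for reporting.
* Serialized artifacts are plain text (CSV/JSON); missing cells are
  written as literal `NA`, distinct from `0`.

## Limitations

* `G` is fixed; the package deliberately offers no model selection over
  the number of criterion groups.
* The fitter treats the two sessions of a participant as independent
  entries — the very device that makes criterion changes detectable —
  so it does not model within-person threshold correlation across
  sessions, even though the generator can produce it.
* Criterion-change detection inherits the posterior mode's hard
  thresholding: a participant with genuinely mixed assignment
  probabilities contributes a single modal label per session. The
  assignment-probability profiles are reported alongside precisely so
  that borderline cases can be inspected.
* Inferential comparison of blocks (mixed-effects modeling of
  nominal vs. ad hoc prevalence) is left to general-purpose regression
  tools; the package reports the descriptive rates those models
  consume.
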