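---
title: "Similarity-conditioned social learning: model, simulator, and experiment pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-conditioned social learning: model, simulator, and experiment pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformsim)
```

## The decision problem

A naive *social learner* faces one of two environmental states; behavior 1 is
optimal in state 1 and behavior 0 in state 0. Before choosing she observes
three pieces of information:

* a private signal `s` about her own state (individual learning),
* the number `i` of `N` sampled *demonstrators* — experienced agents who have
  already chosen — exhibiting behavior 1 (social learning), and
* a binary similarity cue `a` indicating whether the demonstrators faced the
  same state she does.

The demonstrators' state differs from hers with probability `gamma`
(discordance); the cue is correct with probability `phi >= 0.5`; each
demonstrator exhibits the behavior optimal *for demonstrators* with
probability `q`. The learner does not know these quantities. She carries
heritable cognitive representations of them — `q_hat`, `gamma_hat`,
`phi_hat`, and a representation of her own signal reliability — which may be
accurate or wildly wrong, and she chooses as if performing a Bayesian
computation with the representations in place of the truth.

With binomial kernels `B1 = q_hat^i (1 - q_hat)^(N - i)` and
`B0 = (1 - q_hat)^i q_hat^(N - i)`, the social part of her evidence is the
posterior log-odds of her own state being 1, marginalized over the
demonstrators' state with a flat prior on her own:

```
L(same, i)      = log[ ((1-g) p B1 + g (1-p) B0) / (g (1-p) B1 + (1-g) p B0) ]
L(different, i) = the same expression with p replaced by 1 - p
```

for `g = gamma_hat`, `p = phi_hat`. She chooses behavior 1 exactly when
`2 s / sigma_hat^2 + L > 0`, with exact ties broken by a fair coin. This is
the expected-payoff-maximizing rule *under her representations*; it is optimal
in fact only if the representations are accurate.

Two structural facts drive everything downstream. First, `L(a, N - i) =
-L(a, i)`: relabeling the two behaviors flips the evidence exactly
(`social_log_odds` is antisymmetric, and the test suite checks it against a
brute-force enumeration of the joint distribution). Second, the cue enters
only through the posterior probability of concordance
(`similarity_posterior`). A biased prior (`gamma_hat < 0.5`) makes the two
posteriors asymmetric: a cue indicating *sameness* reinforces the prior,
while a cue indicating *difference* must first offset it. At
`gamma_hat = 0.1`, `phi_hat = 0.9` the offset is exact — after a "different"
cue the learner rationally ignores demonstrators altogether.

## Private-signal model and normalization

The signal family is a reconstruction choice: `s | z ~ Normal(2z - 1,
sigma^2)`, so individual-learning reliability is `alpha = pnorm(1 / sigma)`
and the decision rule is a threshold on `s`. Only the *combination* of signal
weight and social weight is identified by behavior (a fitness ridge), so the
package pins `sigma_hat` to the true `sigma` and lets `q_hat` carry the
evolvable social-weight degree of freedom. Probabilities are clipped `1e-12`
away from 0 and 1 before logs so that log-odds stay finite at the edges of
the open parameter intervals.

`learning_function()` summarizes a strategy the way the literature plots it:
the probability of choosing *one's own optimum* against the number of
demonstrators exhibiting it, conditional on the cue. The two state labelings
are averaged, making the curve exactly symmetric under relabeling. A curve
above the diagonal is positive (conformist-like) social influence; below is
negative.

```{r learning-function}
w <- world_params(gamma = 0.1, phi = 0.9, n_demo = 5, sigma = 2)
r <- cognitive_rep(q_hat = 0.75, gamma_hat = 0.1, phi_hat = 0.9, sigma_hat = 2)
learning_function(w, r, "same")
learning_function(w, r, "different")
```

## Measuring asymmetry

The headline qualitative prediction is that facultative adjustments are often
*asymmetric*: the tendency to follow the minority after a "different" cue is
weaker than the tendency to follow the majority after a "same" cue, because
the prior is biased toward concordance. `asymmetry_index()` quantifies this
as a difference in response strength: for a learning function `f` over counts
`0..N`, the strength is `mean |f(k) - f(N - k)| / 2`, and the index is the
strength under "same" minus the strength under "different".

This definition was a genuinely open design point. A naive contrast such as
`mean[f_same(k) - (1 - f_diff(N - k))]` fails a basic requirement: at
`gamma_hat = 0.5` the discordant response is the *exact mirror image* of the
concordant one (`f_diff(N - k) = f_same(k)`), which any reasonable index must
score as symmetric, yet that contrast reduces to `2 mean(f_same) - 1 != 0`.
The strength-difference index is zero in all three regimes where the
underlying posteriors are symmetric — an uninformative cue representation
(`phi_hat = 0.5`, where the two curves coincide), a flat prior
(`gamma_hat = 0.5`), and a perfectly reliable cue (`phi_hat -> 1`) — and
positive exactly when the concordant-cue response is the more extreme one.
Its one blind spot is direction: it measures extremity, not whether the
response is majority- or minority-oriented, which is why the regime tests
also assert the orientation of each curve separately.

## The gene-culture coevolutionary simulator

`run_evolution()` couples two inheritance systems. Culturally, each cohort's
realized choices become the next cohort's demonstrator pool. Genetically,
`(q_hat, gamma_hat, phi_hat)` are inherited under Wright-Fisher
payoff-proportional resampling with mutation. Each generation:

1. the cohort state flips from the demonstrator pool's state with probability
   `gamma` — a single cohort-level flip, because discordance is defined at
   the cohort level and a shared demonstrator pool requires a shared state;
2. every learner samples `N = 5` demonstrators uniformly with replacement,
   receives a cue (correct with probability `phi`) and a private signal, and
   chooses by the threshold rule;
3. payoff is `1 + 1 * [choice matches own state]`; the positive base keeps
   selection well-defined;
4. traits are resampled proportionally to payoff and mutated (probability
   0.01 per trait, Gaussian sd 0.1 on the logit scale, where `q_hat` lives on
   a logit mapped into (0.5, 1) and the other two into (0, 1)).

Demonstrator accuracy `q` is endogenous: it is whatever fraction of the
previous cohort chose its own optimum. Defaults are population 1000, 5000
generations with a 2000-generation burn-in, and founding traits drawn with sd
1 on the logit scale. The exact settings behind the original analysis are not
public; all of these are exposed in `evo_config()` and the reported values
here are reconstructions, not replications. The reported strategy is the
learning function of the *time-averaged population-mean genotype* (per-
individual averaging is available via `mean_of_functions = TRUE`; the two
differ in polymorphic populations).

Two regimes anchor the simulator's validity, each checked over five seeded
replicates in the acceptance suite with `sigma = 3` (individual-learning
reliability `alpha ~ 0.63`, making social learning valuable):

* `gamma = 0.1`, `phi = 0.9`: a strongly facultative system — learners follow
  the demonstrator majority after a "same" cue, the minority after a
  "different" cue, with a positive asymmetry index.
* `gamma = 0.01`, `phi = 0.5`: a non-facultative system with positive social
  influence; the two conditional curves should coincide.

A caveat on the second regime: when the cue is uninformative and discordance
is rare, `phi_hat` is selected only to second order. A drifted `phi_hat` can
be compensated by `gamma_hat` (both act through the average social weight),
so the population wanders along a near-neutral ridge with selection
differentials of order `1e-3` — comparable to drift at population 1000. Over
the default 3000 post-burn-in generations the time-averaged genotype
occasionally retains a facultative gap well above 0.05, though the response
stays positive-influence under both cues. Longer runs or larger populations
shrink these excursions; under the default problem size the strict
"curves coincide within 0.05" check holds in most but not all replicates,
and the test suite reports this honestly rather than enlarging the run.

## The synthetic urn experiment

`simulate_experiment()` emulates a laboratory paradigm that maps onto the
model: two urns, one with three winning balls of four (win probability 0.75
for the optimal urn), re-randomized each block. Each session has two
non-interacting groups; in each group five demonstrators learn individually
over 20 blocks of 5 trials, and 4–7 (or 5–11 in opaque treatments) social
learners each make one choice per block after seeing only the demonstrators'
fifth-trial choice distribution. Social learners get no per-block feedback,
so their strategies are static by design — one-shot social learning also
avoids the reflection problem that plagues mutual-observation designs.
Treatments cross discordant/concordant (opposite or shared optimal urn) with
within/between-subjects assignment (alternating blocks, counterbalanced
across a session's two groups, versus one all-discordant and one
all-concordant group), and with transparent versus opaque information
(concordance announced, or hidden with the uniform prior either revealed or
withheld).

The demonstrator model is deliberately minimal: a greedy Bayesian count
learner that knows the urn compositions and picks the urn with the higher
posterior probability of being the three-winning-ball urn (uniform prior over
the two assignments; the posterior comparison reduces exactly to comparing
wins-minus-losses per urn), with an optional exploration rate `epsilon`. At
`epsilon = 0` it reaches a final-trial majority-optimal rate near 0.96 —
better than human demonstrators, whose sessions show about 0.9. Analyses
that need demonstrator *failures* in every stratum (the optimum-model
interaction) therefore use `epsilon = 0.4`, which calibrates the
majority-optimal rate to roughly 0.9. The model is a stand-in for pipeline
testing, not a model of human demonstrators; nothing downstream depends on
its internals, only on the realized choice distributions.

Social learner strategies (`strategy_spec()`) include the deterministic
majority/minority/unconditional rules, a logistic response
`P(left) = plogis(beta * x5)` to the centered demonstrator proportion
`x5 = p5 - 0.5`, and a facultative variant with separate slopes for
concordant and discordant blocks. In the opaque uniform-prior design every
strategy has the same expected payoff — whatever rule maps the observed
distribution to an urn, that urn is the learner-optimal one with probability
one half — and `payoff_equivalence_check()` verifies this by Monte Carlo
(and that transparency breaks it).

## The analysis pipeline

`analyze_experiment()` reproduces the published analysis structure on any
trial-record table:

* `demonstrator_optimal_rate()`: share of group-blocks whose final-trial
  majority was demonstrator-optimal, plus the modal count.
* `fit_choice_model()`: logistic regression of choosing left on the block
  index (1–20, which affects the intercept but not the slope of interest)
  and `x5`, with a sandwich covariance clustered on social learner. The
  small-sample factor is `M / (M - 1)` for `M` clusters (switchable to none;
  the correction used originally is not stated, so coefficients — which are
  invariant to it — are the reproduction targets, and standard errors are
  expected to match only up to the correction convention).
* `fit_optimum_model()`: logistic regression of choosing one's own optimum on
  block, a left-optimal dummy, concordance, a majority-demonstrator-optimal
  dummy, and the concordance-by-majority interaction.
* `wald_combo()`: Wald tests of linear combinations under the clustered
  covariance, reported as F with `(1, M - 1)` degrees of freedom (a
  chi-squared convention is offered, again because the original convention is
  unstated).
* `classify_learner()`: per-learner strategy types — Min and Maj (always
  followed the minority/majority) are checked before U (always the same urn),
  then an intercept-free logistic slope `P(left) = plogis(beta * x5)` with a
  5% Wald flag; learners whose blocks show fewer than two distinct `x5`
  values are labeled `undefined` rather than force-fit.
* `bootstrap_curve()`: left-choice rates by demonstrator left-count with
  percentile intervals from resampling learners (clusters) with replacement —
  intervals are guaranteed to stay inside `[0, 1]`, and counts never observed
  are omitted, not imputed.

Separation and non-convergence are flagged with a warning and a `separation`
field, never silently regularized; aliased covariates (a dummy with no
variation in a subset) raise a descriptive error, and the bundle-level
`analyze_experiment()` records such failures per model instead of aborting.

```{r pipeline}
cfg <- experiment_config(n_sessions = 3, design = "within",
                         demonstrator_epsilon = 0.4,
                         strategies = strategy_spec("facultative",
                                                    beta_same = 8,
                                                    beta_diff = -8))
tab <- simulate_experiment(cfg, seed = 7)
demonstrator_optimal_rate(tab)$rate
fit_choice_model(tab, concordant = FALSE)
```

## Reading deposited raw data

`read_trial_records()` maps external delimited files onto the canonical
schema through a `raw_dialect()` — an explicit mapping of column names, role
codes, and urn codes. The shipped default is a best guess (tab-separated,
canonical names); the layout of any real deposited file must be inspected
and encoded in a dialect, and the reader validates totality and design
invariants instead of coercing silently. `reproduce_deposited_results()`
then recomputes the full set of published-style statistics from such a file.
The package does not ship the original deposited data; the corresponding
acceptance checks run only when a converted copy is placed at
`inst/extdata/s1_raw_data.txt`, and they are reported as failing, not
skipped, in its absence.

## Problem sizes and reproducibility

All stochastic entry points take explicit seeds (`run_evolution()`,
`simulate_experiment()`, `payoff_equivalence_check()`, and every CLI
subcommand record the seed in their manifests), and fixed seeds give
bit-identical trajectories. The shipped checks use: full-size coevolution
runs (population 1000, 5000 generations) for the regime suite, five
replicates per regime; six-session synthetic experiments (on the order of
40–50 social learners, 240 group-blocks) for effect recovery, comparable to
the scale of a real multi-session study; `1e5` Monte-Carlo blocks for payoff
equivalence; and `1e5` draws for the simulation check of the closed-form
choice probability. Smaller configurations are used in unit tests where only
mechanics, not regimes, are at stake.

## Known limitations

* Exactly two behaviors and two states; no continuous behavior spaces.
* The Gaussian signal family and the `sigma_hat = sigma` normalization are
  reconstructions; only the combined private/social weighting is identified.
* The coevolutionary parameterization (population size, mutation kernel,
  selection scheme, run length) is a reconstruction with all values exposed
  as configuration; regime claims are qualitative, never numeric curve
  matches.
* The demonstrator model is a pipeline stand-in; it does not try to fit
  human demonstrators' learning curves.
* Synthetic learners hold their strategy fixed within a session, so passing
  recovery tests says nothing about humans whose strategies drift — the real
  design discourages drift by withholding feedback, but cannot enforce it.
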