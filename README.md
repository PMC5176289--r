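# conformsim

Tools for studying **facultative conformist social learning conditioned on
perceived similarity**, for researchers in cultural evolution, gene–culture
coevolution, and experimental social learning.

Conformity — adopting the majority behavior disproportionately often — pays
when a naive learner and the experienced demonstrators she observes share an
optimum, and backfires when they do not. The question the package addresses
is whether, and how, cognition evolves to *condition* the use of
frequency-dependent social information on a cue of similarity.

## The model

A learner in one of two states (behavior 1 optimal in state 1) observes:

* a private signal `s | z ~ N(2z − 1, σ²)` about her own state `z`,
* the count `i` of `N` sampled demonstrators exhibiting behavior 1, and
* a binary similarity cue `a`, correct with probability `φ ≥ 0.5`, indicating
  whether demonstrators faced her state (they did not with probability `γ`).

She carries heritable *cognitive representations* `(q̂, γ̂, φ̂)` of
demonstrator accuracy, the discordance rate, and cue reliability, and
chooses behavior 1 iff

```
2s/σ̂² + L(a, i) > 0,
L(a=same, i) = log[((1−γ̂)φ̂B₁ + γ̂(1−φ̂)B₀) / (γ̂(1−φ̂)B₁ + (1−γ̂)φ̂B₀)]
```

with binomial kernels `B₁ = q̂ⁱ(1−q̂)^(N−i)`, `B₀ = (1−q̂)ⁱq̂^(N−i)`; a
`different` cue swaps `φ̂ ↔ 1−φ̂`. A gene–culture coevolutionary simulator
evolves these representations under Wright–Fisher selection while the
demonstrator behavior frequency evolves culturally. The package also ships a
synthetic generator for the matching two-urn laboratory paradigm
(demonstrators who learn individually; social learners who see only the
demonstrators' final-trial choice distribution) and the full analysis
pipeline: cluster-robust logistic regressions, Wald tests of linear
combinations, per-learner strategy classification, and cluster-bootstrap
learning curves.

## Worked example

Evolve a learning system where discordance is common (`γ = 0.1`) and the
similarity cue is informative (`φ = 0.9`), with weak individual learning:

```r
library(conformsim)
cfg <- evo_config(world_params(gamma = 0.1, phi = 0.9, n_demo = 5, sigma = 3))
run_evolution(cfg, seed = 42)
#> Gene-culture coevolution summary
#>   5000 generations (burn-in 2000), pop 1000; gamma = 0.1, phi = 0.9, sigma = 3
#>   realized demonstrator accuracy: 0.893
#>   mean representation: q_hat = 0.742, gamma_hat = 0.267, phi_hat = 0.781
#>   asymmetry index: 0.3439
#>   learning function, cue = different:
#>     0.764 0.756 0.699 0.558 0.490 0.478
#>   learning function, cue = same:
#>     0.001 0.005 0.179 0.943 0.999 1.000
```

Read the two curves as P(choose own optimum) against how many of the five
demonstrators exhibit it. Under a *same* cue the evolved strategy follows the
majority almost deterministically (0.001 → 1.000). Under a *different* cue it
follows the minority, but much more weakly (0.764 → 0.478): the positive
asymmetry index (0.34) is the signature of the inherited prior that
concordance is typical — a "different" cue must first offset that prior.

Simulate a transparent within-subjects urn experiment with facultative
learners (logistic slopes +8 in concordant, −8 in discordant blocks) and
recover the treatment effect:

```r
cfg <- experiment_config(n_sessions = 3, design = "within",
                         demonstrator_epsilon = 0.4,
                         strategies = strategy_spec("facultative",
                                                    beta_same = 8,
                                                    beta_diff = -8))
tab <- simulate_experiment(cfg, seed = 7)
demonstrator_optimal_rate(tab)$rate
#> [1] 0.825
fit_choice_model(tab, concordant = FALSE)
#> Cluster-robust logistic fit (n = 330, clusters = 33, logLik = -127.92)
#>                estimate    se      z     p
#> (Intercept)      -0.233 0.295 -0.792 0.429
#> learning_block    0.020 0.026  0.783 0.433
#> x5               -9.579 1.467 -6.532 0.000
```

The slope on `x5` (the centered proportion of demonstrators choosing left)
is strongly negative in discordant blocks — learners avoid the urn the
demonstrators favor — and the concordant-block fit recovers a slope of
+8.0. In the opaque uniform-prior design every social learning strategy is
payoff-equivalent, which `payoff_equivalence_check()` confirms by Monte
Carlo (all strategies ≈ 250 points per block, differences within sampling
error).

A command-line wrapper with `evolve`, `simulate-experiment`, `analyze`, and
`asymmetry` subcommands lives at `inst/cli/conformsim.R`:

```sh
Rscript inst/cli/conformsim.R evolve --gamma 0.1 --phi 0.9 --seed 1 --out runs/evo
```

Every run writes a `manifest.json` recording its configuration and seed.

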