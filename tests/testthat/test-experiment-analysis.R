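# Analysis pipeline: optimality rates, cluster-robust fits, Wald tests,
# classification, bootstrap curves.

test_that("demonstrator optimality is 1 for error-free demonstrators", {
  cfg <- experiment_config(win_prob_optimal = 1, learners_per_group = 4)
  tab <- simulate_experiment(cfg, seed = 30)
  d <- demonstrator_optimal_rate(tab)
  expect_equal(d$rate, 1)
  expect_equal(d$modal_count, 5L)
  expect_equal(d$n_blocks, 40L)
  expect_error(demonstrator_optimal_rate(tab[tab$role == "social_learner", ]),
               "demonstrator")
})

test_that("the choice model recovers a known logistic slope", {
  cfg <- experiment_config(n_sessions = 3, learners_per_group = 6,
                           strategies = strategy_spec("logistic", beta = 8))
  tab <- simulate_experiment(cfg, seed = 31)
  fit <- fit_choice_model(tab)
  b <- fit$coefficients["x5"]
  se <- fit$se["x5"]
  expect_gt(b + 1.96 * se, 8)
  expect_lt(b - 1.96 * se, 8)
})

test_that("the choice-model test has approximately nominal size under the null", {
  # random choosers: x5 has no effect, so the 5%-level slope test should
  # reject in roughly 5% of simulated experiments
  rejections <- 0L
  n_sim <- 100L
  set.seed(32)
  for (r in seq_len(n_sim)) {
    cfg <- experiment_config(learners_per_group = 10,
                             strategies = strategy_spec("random"))
    tab <- simulate_experiment(cfg)
    fit <- fit_choice_model(tab)
    if (fit$p_value["x5"] < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 10L)
})

test_that("coefficients are invariant to the cluster correction", {
  tab <- simulate_experiment(experiment_config(n_sessions = 2), seed = 33)
  f1 <- fit_choice_model(tab, concordant = TRUE, cluster_adjust = "CR1")
  f2 <- fit_choice_model(tab, concordant = TRUE, cluster_adjust = "none")
  expect_identical(f1$coefficients, f2$coefficients)
  expect_equal(unname(f1$se / f2$se),
               rep(sqrt(f1$n_clusters / (f1$n_clusters - 1)),
                   length(f1$se)))
})

test_that("demonstrator success raises optimal choices for conformists", {
  # strict majority-followers in concordant blocks choose optimally exactly
  # when the demonstrators' majority was optimal: a large positive effect
  # that also separates perfectly, which must be flagged rather than hidden
  cfg <- experiment_config(n_sessions = 3, learners_per_group = 6,
                           demonstrator_epsilon = 0.1,
                           strategies = strategy_spec("majority"))
  tab <- simulate_experiment(cfg, seed = 34)
  lt <- learner_block_table(tab)
  expect_warning(
    fit <- fit_cluster_logit(
      chose_optimal ~ learning_block + left_optimal_social + majority_demo_opt,
      lt[lt$concordant, ]
    ),
    "separation"
  )
  expect_true(fit$separation)
  expect_gt(fit$coefficients["majority_demo_optTRUE"], 1)
})

test_that("Wald combinations reduce to single-coefficient tests", {
  cfg <- experiment_config(n_sessions = 3, demonstrator_epsilon = 0.1)
  tab <- simulate_experiment(cfg, seed = 35)
  fit <- fit_optimum_model(tab)
  w <- wald_combo(fit, c(majority_demo_optTRUE = 1))
  expect_equal(w$statistic, unname(fit$z["majority_demo_optTRUE"]^2))
  expect_equal(w$df, c(1, fit$n_clusters - 1))
  w0 <- wald_combo(fit, rep(0, length(fit$coefficients)))
  expect_equal(w0$statistic, 0)
  wc <- wald_combo(fit, c(majority_demo_optTRUE = 1), type = "chisq")
  expect_equal(wc$statistic, w$statistic)
  expect_lte(wc$p_value, w$p_value)
  expect_error(wald_combo(fit, c(nonexistent = 1)), "unknown")
})

test_that("learners are classified by their revealed strategy", {
  n_left <- c(1, 4, 2, 5, 0, 3, 4, 1, 2, 5)
  maj <- n_left * 2 > 5
  lt_maj <- learner_block_table(tiny_trial_table(n_left, maj))
  expect_equal(classify_learner(lt_maj)$label, "Maj")
  lt_min <- learner_block_table(tiny_trial_table(n_left, !maj))
  expect_equal(classify_learner(lt_min)$label, "Min")
  lt_left <- learner_block_table(tiny_trial_table(n_left, rep(TRUE, 10)))
  expect_equal(classify_learner(lt_left)$label, "U")
  # Maj takes precedence over U when the majority always happened to be left
  lt_both <- learner_block_table(
    tiny_trial_table(c(3, 4, 5, 4, 3), rep(TRUE, 5))
  )
  expect_equal(classify_learner(lt_both)$label, "Maj")
  # mixed chooser with varying social information: slope fit
  set.seed(36)
  mixed <- runif(10) < plogis(6 * (n_left / 5 - 0.5))
  if (all(mixed == maj) || all(mixed != maj) ||
      all(mixed) || all(!mixed)) {
    mixed[1] <- !mixed[1]
    mixed[2] <- !mixed[2]
  }
  cls <- classify_learner(learner_block_table(tiny_trial_table(n_left, mixed)))
  expect_equal(cls$label, "slope")
  expect_true(is.finite(cls$beta))
  # constant social information: slope undefined
  lt_const <- learner_block_table(
    tiny_trial_table(rep(4, 6), c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  )
  expect_equal(classify_learner(lt_const)$label, "undefined")
})

test_that("classification recovers planted strategy mixtures", {
  cfg <- experiment_config(
    n_sessions = 1, information = "opaque_prior", learners_per_group = 8,
    strategies = list(strategy_spec("majority"), strategy_spec("minority"),
                      strategy_spec("unconditional_L"),
                      strategy_spec("random"))
  )
  tab <- simulate_experiment(cfg, seed = 37)
  types <- classify_learners(tab)
  expect_equal(nrow(types), 16L)
  expect_equal(sum(types$label == "Maj"), 4L)
  expect_equal(sum(types$label == "Min"), 4L)
  expect_equal(sum(types$label == "U"), 4L)
})

test_that("bootstrap curves stay in [0,1] and degenerate for one learner", {
  tab <- simulate_experiment(experiment_config(n_sessions = 2), seed = 38)
  bc <- bootstrap_curve(tab, concordant = TRUE, n_boot = 300)
  expect_true(all(bc$lower >= 0 & bc$upper <= 1))
  expect_true(all(bc$lower <= bc$rate & bc$rate <= bc$upper))
  expect_true(all(bc$n_left %in% 0:5))
  # one learner: resampling returns the same cluster every time
  lt <- learner_block_table(tab)
  one <- lt[lt$subject == lt$subject[1], ]
  bc1 <- bootstrap_curve(one, n_boot = 100)
  expect_equal(bc1$lower, bc1$rate)
  expect_equal(bc1$upper, bc1$rate)
})

test_that("bootstrap intervals cover a known choice rate at the nominal level", {
  # random choosers have a true left-choice rate of 0.5 at every count
  set.seed(39)
  covered <- 0L
  cells <- 0L
  for (r in 1:60) {
    cfg <- experiment_config(learners_per_group = 8,
                             strategies = strategy_spec("random"))
    tab <- simulate_session(cfg)
    bc <- bootstrap_curve(tab, n_boot = 400)
    keep <- bc$n_obs >= 20
    covered <- covered + sum(bc$lower[keep] <= 0.5 & bc$upper[keep] >= 0.5)
    cells <- cells + sum(keep)
  }
  coverage <- covered / cells
  expect_gt(coverage, 0.88)
  expect_lte(coverage, 1)
})

test_that("the full analysis bundle has the expected shape", {
  cfg <- experiment_config(n_sessions = 3, demonstrator_epsilon = 0.1)
  tab <- simulate_experiment(cfg, seed = 40)
  res <- analyze_experiment(tab, n_boot = 100)
  expect_named(res, c("demonstrator", "choice_models", "optimum_models",
                      "wald_majority_concordant", "learner_types", "curves"))
  expect_setequal(names(res$choice_models),
                  c("within_discordant", "within_concordant"))
  expect_s3_class(res$choice_models$within_discordant, "cluster_fit")
  expect_true(all(res$learner_types$label %in%
                    c("Maj", "Min", "U", "slope", "undefined")))
})

test_that("published-style reproduction runs end to end on synthetic data", {
  # exploration 0.4 puts the final-trial majority-optimal rate near the
  # ~0.9 observed in real sessions, so demonstrator failures are frequent
  # enough for the optimum model's interaction to be estimable
  cfg1 <- experiment_config(n_sessions = 3, design = "within",
                            demonstrator_epsilon = 0.4)
  tab1 <- simulate_experiment(cfg1, seed = 41)
  cfg2 <- experiment_config(
    n_sessions = 2, information = "opaque_prior", learners_per_group = 5:8,
    demonstrator_epsilon = 0.1,
    strategies = list(strategy_spec("majority"), strategy_spec("random"))
  )
  tab2 <- simulate_experiment(cfg2, seed = 42, sessions = 4:5)
  path <- tempfile(fileext = ".tsv")
  write_trial_records(rbind(tab1, tab2), path)
  res <- reproduce_deposited_results(path)
  expect_named(res, c("exp1", "exp2"))
  expect_gt(res$exp1$demonstrator$rate, 0.75)
  # facultative learners: negative discordant slope, positive concordant slope
  expect_lt(res$exp1$choice_models$within_discordant$coefficients["x5"], 0)
  expect_gt(res$exp1$choice_models$within_concordant$coefficients["x5"], 0)
  expect_gt(res$exp2$learner_types$opaque_prior$n_maj, 0)
})

test_that("aliased covariates raise a descriptive error", {
  # every block concordant: the concordance dummy has no variation
  tab <- tiny_trial_table(c(1, 4, 2, 5, 3, 0), c(FALSE, TRUE, FALSE, TRUE,
                                                 TRUE, FALSE))
  t2 <- tab
  t2$session <- 2L
  t2$subject[t2$role == "social_learner"] <- "SL2"
  lt <- learner_block_table(rbind(tab, t2))
  expect_error(
    suppressWarnings(
      fit_cluster_logit(chose_left ~ x5 + concordant, lt)
    ),
    "aliased"
  )
})
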