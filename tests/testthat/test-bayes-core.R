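# Closed-form decision model: likelihoods, posteriors, decision rule,
# learning functions, asymmetry.

test_that("demonstrator-count likelihood is binomial and normalized", {
  expect_equal(demo_count_likelihood(5, 5, 0.75, y = 1), 0.75^5)
  expect_equal(demo_count_likelihood(4, 5, 0.75, y = 1), 5 * 0.75^4 * 0.25)
  expect_equal(demo_count_likelihood(0, 5, 1, y = 1), 0)
  # state 0 flips the per-demonstrator probability
  expect_equal(demo_count_likelihood(2, 5, 0.75, y = 0),
               demo_count_likelihood(3, 5, 0.75, y = 1))
  for (q in c(0.5, 0.75, 0.9)) {
    expect_equal(sum(demo_count_likelihood(0:5, 5, q, y = 1)), 1)
  }
  expect_error(demo_count_likelihood(6, 5, 0.75, 1), "i")
  expect_error(demo_count_likelihood(2, 5, 1.2, 1), "q")
})

test_that("similarity posterior matches its closed forms", {
  # a discordant cue exactly offsets a gamma = 0.1 prior at phi = 0.9
  expect_equal(similarity_posterior(0.1, 0.9, "different"), 0.5)
  expect_equal(similarity_posterior(0.1, 0.9, "same"), 0.81 / 0.82)
  # uninformative cue returns the prior
  for (g in c(0.1, 0.3, 0.7)) {
    expect_equal(similarity_posterior(g, 0.5, "same"), 1 - g)
    expect_equal(similarity_posterior(g, 0.5, "different"), 1 - g)
  }
  # flat prior cancels, leaving the cue reliability
  expect_equal(similarity_posterior(0.5, 0.7, "same"), 0.7)
  expect_equal(similarity_posterior(0.5, 0.7, "different"), 0.3)
  # degenerate prior is a domain error, not NaN
  expect_error(similarity_posterior(1, 1, "same"))
  expect_error(similarity_posterior(0, 1, "different"))
})

test_that("social log-odds agree with brute-force enumeration", {
  grid <- expand.grid(
    n = c(1, 3, 5),
    q = c(0.6, 0.75, 0.9),
    g = c(0.05, 0.1, 0.5, 0.9),
    p = c(0.5, 0.7, 0.9),
    a = c("same", "different"),
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(grid))) {
    rep_ <- cognitive_rep(grid$q[r], grid$g[r], grid$p[r])
    for (i in 0:grid$n[r]) {
      expect_equal(
        social_log_odds(grid$a[r], i, grid$n[r], rep_),
        oracle_log_odds(grid$a[r], i, grid$n[r], grid$q[r], grid$g[r], grid$p[r]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("social log-odds reproduce the hand-worked regime values", {
  rep_ <- cognitive_rep(0.75, 0.1, 0.9)
  # strong majority pull after a concordant cue
  expect_equal(social_log_odds("same", 5, 5, rep_),
               log(((0.81) * 0.75^5 + 0.01 * 0.25^5) /
                   (0.01 * 0.75^5 + 0.81 * 0.25^5)))
  expect_equal(social_log_odds("same", 5, 5, rep_), 4.107, tolerance = 1e-3)
  # (1 - g)(1 - p) = g p: the cue neutralizes social information entirely
  for (i in 0:5) {
    expect_equal(social_log_odds("different", i, 5, rep_), 0,
                 tolerance = 1e-12)
  }
})

test_that("social log-odds are antisymmetric and normalized", {
  reps <- list(cognitive_rep(0.75, 0.1, 0.9),
               cognitive_rep(0.6, 0.45, 0.55),
               cognitive_rep(0.95, 0.8, 0.2))
  for (rep_ in reps) {
    for (a in c("same", "different")) {
      L <- social_log_odds(a, 0:5, 5, rep_)
      expect_equal(L, -rev(L), tolerance = 1e-12)
      # posterior from L and its complement sum to one by construction
      p1 <- stats::plogis(L)
      expect_equal(p1 + stats::plogis(-L), rep(1, 6), tolerance = 1e-12)
    }
  }
})

test_that("an uninformative cue representation collapses the two conditions", {
  rep_ <- cognitive_rep(0.8, 0.2, 0.5)
  expect_equal(social_log_odds("same", 0:5, 5, rep_),
               social_log_odds("different", 0:5, 5, rep_))
  w <- world_params(0.2, 0.5, 5, sigma = 2)
  expect_equal(learning_function(w, rep_, "same")$prob,
               learning_function(w, rep_, "different")$prob)
})

test_that("the choice rule thresholds on combined evidence and breaks ties fairly", {
  rep_ <- cognitive_rep(0.75, 0.1, 0.9)
  # social log-odds are 0 under a "different" cue for this representation
  expect_identical(choose_behavior(observation(3, 2, "different"), rep_), 1L)
  expect_identical(choose_behavior(observation(-3, 5, "different"), rep_), 0L)
  # weak contrary private signal overcome by L ~ 4.107
  expect_identical(choose_behavior(observation(-0.1, 5, "same"), rep_), 1L)
  # exact tie: fair coin
  set.seed(42)
  ties <- replicate(4000, choose_behavior(observation(0, 3, "different"), rep_))
  expect_gt(mean(ties), 0.5 - 3 * 0.5 / sqrt(4000))
  expect_lt(mean(ties), 0.5 + 3 * 0.5 / sqrt(4000))
})

test_that("closed-form choice probability matches the Normal CDF and simulation", {
  w <- world_params(0.1, 0.9, 5, sigma = 1)
  rep_ <- cognitive_rep(0.75, 0.1, 0.9)
  # L = 0 under the "different" cue: the private signal decides, so the
  # probability of a correct choice is pnorm(1 / sigma)
  expect_equal(choice_probability(1, "different", 3, w, rep_), pnorm(1))
  expect_equal(choice_probability(0, "different", 3, w, rep_), pnorm(-1))
  # overwhelming social information saturates the probability (the prior
  # gamma_hat must also be extreme: it caps |L| at log-odds of concordance)
  sharp <- cognitive_rep(1 - 1e-9, 1e-9, 0.9)
  expect_gt(choice_probability(0, "same", 5, w, sharp), 0.999)
  # Monte-Carlo agreement within 3 binomial standard errors
  set.seed(7)
  n_mc <- 1e5
  s <- rnorm(n_mc, mean = 1, sd = w$sigma)
  draws <- vapply(s, function(si) {
    choose_behavior(observation(si, 4, "same"), rep_)
  }, integer(1))
  p_hat <- mean(draws)
  p <- choice_probability(1, "same", 4, w, rep_)
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n_mc))
})

test_that("learning functions are flat at alpha when social info is ignored", {
  w <- world_params(0.1, 0.9, 5, sigma = 2)
  alpha <- signal_reliability(2)
  # this representation zeroes the social log-odds after a "different" cue
  lf <- learning_function(w, cognitive_rep(0.75, 0.1, 0.9, 2), "different")
  expect_equal(lf$prob, rep(alpha, 6), tolerance = 1e-12)
  expect_equal(attr(lf, "alpha"), alpha)
  expect_true(all(lf$prob >= 0 & lf$prob <= 1))
  expect_equal(lf$k, 0:5)
})

test_that("asymmetry vanishes exactly in the symmetric regimes", {
  mk <- function(g, p, s = 2) {
    list(w = world_params(g, max(p, 0.5), 5, sigma = s),
         r = cognitive_rep(0.75, g, p, s))
  }
  # non-facultative: uninformative cue representation
  x <- mk(0.1, 0.5)
  expect_equal(asymmetry_index(x$w, x$r), 0, tolerance = 1e-12)
  # flat discordance prior: mirror-symmetric adjustments
  x <- mk(0.5, 0.7)
  expect_equal(asymmetry_index(x$w, x$r), 0, tolerance = 1e-12)
  # biased prior with a moderately reliable cue: asymmetric
  x <- mk(0.25, 0.7)
  expect_gt(asymmetry_index(x$w, x$r), 0)
})

test_that("asymmetry fades as the prior flattens or the cue becomes perfect", {
  at <- function(g, p) {
    asymmetry_index(world_params(g, max(p, 0.5), 5, 2, 0.75),
                    cognitive_rep(0.75, g, p, 2))
  }
  base <- at(0.1, 0.9)
  expect_gt(base, 0)
  # gamma_hat -> 0.5
  gs <- c(0.2, 0.35, 0.45, 0.499)
  vals_g <- vapply(gs, at, numeric(1), p = 0.9)
  expect_true(all(diff(abs(vals_g)) < 0))
  expect_lt(abs(vals_g[length(vals_g)]), 1e-2)
  # phi_hat -> 1
  ps <- c(0.95, 0.99, 0.999, 0.9999)
  vals_p <- vapply(ps, at, numeric(1), g = 0.1)
  expect_true(all(diff(abs(vals_p)) < 0))
  expect_lt(abs(vals_p[length(vals_p)]), 1e-2)
})

test_that("constructors reject out-of-range parameters", {
  expect_error(world_params(-0.1, 0.9))
  expect_error(world_params(0.1, 0.4))
  expect_error(world_params(0.1, 0.9, sigma = 0))
  expect_error(cognitive_rep(0.5, 0.1, 0.9))
  expect_error(cognitive_rep(0.75, 0, 0.9))
  expect_error(observation(1, 6, "same", n_demo = 5))
  expect_error(observation(1, 2, "sideways"))
})
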