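# Independent oracles used across tests.

# Brute-force enumeration of the joint P(z, y, a, i): flat prior on the
# learner's state, y = z with probability 1 - gamma_hat, cue correct with
# probability phi_hat, count binomial given y. Returns the posterior log-odds
# of z = 1. Deliberately written with dbinom and an explicit sum over the
# 2 x 2 (z, y) table, independent of the package's log-kernel algebra.
oracle_log_odds <- function(a, i, n, q_hat, gamma_hat, phi_hat) {
  mass <- function(z) {
    sum(vapply(c(0, 1), function(y) {
      p_y <- if (y == z) 1 - gamma_hat else gamma_hat
      cue_correct <- (a == "same") == (y == z)
      p_a <- if (cue_correct) phi_hat else 1 - phi_hat
      p_i <- dbinom(i, n, if (y == 1) q_hat else 1 - q_hat)
      0.5 * p_y * p_a * p_i
    }, numeric(1)))
  }
  log(mass(1) / mass(0))
}

# A minimal, hand-assembled trial-record table: one group, `n_blocks` blocks,
# 5 demonstrators whose final-trial left-counts are given, and one social
# learner with the given choices. Demonstrator choices in trials 1-4 are
# arbitrary ("L").
tiny_trial_table <- function(n_left, learner_left,
                             demo_opt = rep("L", length(n_left)),
                             concordant = rep(TRUE, length(n_left)),
                             information = "transparent",
                             design = "within") {
  nb <- length(n_left)
  stopifnot(length(learner_left) == nb)
  social_opt <- ifelse(concordant, demo_opt, ifelse(demo_opt == "L", "R", "L"))
  demo <- do.call(rbind, lapply(seq_len(nb), function(b) {
    choices5 <- c(rep("L", n_left[b]), rep("R", 5 - n_left[b]))
    do.call(rbind, lapply(1:5, function(t) {
      data.frame(session = 1L, group = 1L, design = design,
                 information = information, role = "demonstrator",
                 subject = sprintf("D%d", 1:5), block = b, trial = t,
                 concordant = concordant[b],
                 urn_chosen = if (t == 5) choices5 else rep("L", 5),
                 demo_optimal_urn = demo_opt[b],
                 social_optimal_urn = social_opt[b],
                 wins = 0L, points = 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  soc <- data.frame(session = 1L, group = 1L, design = design,
                    information = information, role = "social_learner",
                    subject = "SL1", block = seq_len(nb), trial = NA_integer_,
                    concordant = concordant,
                    urn_chosen = ifelse(learner_left, "L", "R"),
                    demo_optimal_urn = demo_opt,
                    social_optimal_urn = social_opt,
                    wins = 0L, points = 0,
                    stringsAsFactors = FALSE)
  rbind(demo, soc)
}
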