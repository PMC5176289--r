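# Synthetic generator for two-urn social-learning sessions. A session has two
# groups; each group has 5 demonstrators who learn individually over 20 blocks
# of 5 trials (urns re-randomized each block, optimal urn pays with probability
# 0.75) and several social learners who each make one choice per block after
# seeing the demonstrators' fifth-trial choice distribution.

#' Specification of a social learner's strategy
#'
#' Static frequency-dependent strategies for synthetic social learners.
#' `"majority"` / `"minority"` follow or oppose the demonstrators' modal
#' choice; `"unconditional_L"` / `"unconditional_R"` always pick one urn;
#' `"random"` flips a coin; `"logistic"` chooses left with probability
#' `plogis(beta * x)` where `x` is the centered proportion of demonstrators
#' choosing left; `"facultative"` is logistic with slope `beta_same` in
#' concordant blocks and `beta_diff` in discordant blocks.
#'
#' @param kind One of `"majority"`, `"minority"`, `"unconditional_L"`,
#'   `"unconditional_R"`, `"random"`, `"logistic"`, `"facultative"`.
#' @param beta Slope for `"logistic"`.
#' @param beta_same,beta_diff Slopes for `"facultative"`.
#' @return An object of class `strategy_spec`.
#' @export
#' @examples
#' strategy_spec("facultative", beta_same = 8, beta_diff = -8)
strategy_spec <- function(kind, beta = NULL, beta_same = NULL, beta_diff = NULL) {
  kind <- match.arg(kind, c("majority", "minority", "unconditional_L",
                            "unconditional_R", "random", "logistic",
                            "facultative"))
  if (kind == "logistic" && (is.null(beta) || !is.finite(beta))) {
    stop("`logistic` strategy needs a finite `beta`", call. = FALSE)
  }
  if (kind == "facultative" &&
      (is.null(beta_same) || is.null(beta_diff) ||
       !is.finite(beta_same) || !is.finite(beta_diff))) {
    stop("`facultative` strategy needs finite `beta_same` and `beta_diff`",
         call. = FALSE)
  }
  structure(list(kind = kind, beta = beta, beta_same = beta_same,
                 beta_diff = beta_diff),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  extra <- switch(x$kind,
    logistic = sprintf(" (beta = %g)", x$beta),
    facultative = sprintf(" (beta_same = %g, beta_diff = %g)",
                          x$beta_same, x$beta_diff),
    "")
  cat(sprintf("Social learning strategy: %s%s\n", x$kind, extra))
  invisible(x)
}

# One choice from a strategy. n_left in 0..n_demo; concordant is the block's
# (possibly hidden) concordance label, used only by facultative strategies.
strategy_choose <- function(spec, n_left, n_demo, concordant) {
  coin <- function(p) if (stats::runif(1) < p) "L" else "R"
  switch(spec$kind,
    majority = if (n_left * 2 > n_demo) "L"
               else if (n_left * 2 < n_demo) "R" else coin(0.5),
    minority = if (n_left * 2 < n_demo) "L"
               else if (n_left * 2 > n_demo) "R" else coin(0.5),
    unconditional_L = "L",
    unconditional_R = "R",
    random = coin(0.5),
    logistic = coin(stats::plogis(spec$beta * (n_left / n_demo - 0.5))),
    facultative = coin(stats::plogis(
      (if (concordant) spec$beta_same else spec$beta_diff) *
        (n_left / n_demo - 0.5)))
  )
}

#' Configuration of a synthetic urn experiment
#'
#' @param n_sessions Number of sessions; each session contains two groups that
#'   never interact.
#' @param design `"within"` (every social learner alternates between 10
#'   discordant and 10 concordant blocks, initial block counterbalanced
#'   across the two groups of a session) or `"between"` (one all-discordant
#'   and one all-concordant group per session).
#' @param information `"transparent"` (learners are told each block's
#'   concordance), `"opaque_prior"` (concordance hidden, uniform prior
#'   revealed) or `"opaque_noprior"` (concordance hidden, no prior). Opaque
#'   treatments use the within-subjects alternation.
#' @param learners_per_group Integer vector of admissible social-learner
#'   counts per group; one value is drawn per group.
#' @param demonstrators_per_group Number of demonstrators per group.
#' @param n_blocks Learning blocks per session.
#' @param trials_per_block Demonstrator trials per block; the social
#'   information is the choice distribution in the final trial.
#' @param win_prob_optimal Probability the optimal urn pays (3 winning balls
#'   of 4).
#' @param points_win Points per winning draw.
#' @param draws_per_social_choice Payoff draws per social-learner choice.
#' @param demonstrator_epsilon Exploration rate of the demonstrator model: the
#'   probability of choosing an urn uniformly instead of greedily.
#' @param strategies A [strategy_spec()] applied to every social learner, or a
#'   list of specs assigned to learners cyclically.
#'
#' @return An object of class `experiment_config`.
#' @export
#' @examples
#' experiment_config(n_sessions = 2, design = "within",
#'                   strategies = strategy_spec("majority"))
experiment_config <- function(n_sessions = 1L,
                              design = c("within", "between"),
                              information = c("transparent", "opaque_prior",
                                              "opaque_noprior"),
                              learners_per_group = 4:7,
                              demonstrators_per_group = 5L,
                              n_blocks = 20L,
                              trials_per_block = 5L,
                              win_prob_optimal = 0.75,
                              points_win = 100,
                              draws_per_social_choice = 5L,
                              demonstrator_epsilon = 0,
                              strategies = strategy_spec("facultative",
                                                         beta_same = 8,
                                                         beta_diff = -8)) {
  design <- match.arg(design)
  information <- match.arg(information)
  if (inherits(strategies, "strategy_spec")) strategies <- list(strategies)
  stopifnot(
    n_sessions >= 1,
    all(learners_per_group >= 1),
    demonstrators_per_group >= 1,
    n_blocks >= 1, trials_per_block >= 1,
    win_prob_optimal > 0.5, win_prob_optimal <= 1,
    points_win > 0, draws_per_social_choice >= 1,
    demonstrator_epsilon >= 0, demonstrator_epsilon <= 1,
    length(strategies) >= 1,
    all(vapply(strategies, inherits, logical(1), "strategy_spec"))
  )
  if (information != "transparent" && design != "within") {
    stop("opaque treatments use the within-subjects alternation", call. = FALSE)
  }
  structure(
    list(n_sessions = as.integer(n_sessions), design = design,
         information = information,
         learners_per_group = as.integer(learners_per_group),
         demonstrators_per_group = as.integer(demonstrators_per_group),
         n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         win_prob_optimal = win_prob_optimal, points_win = points_win,
         draws_per_social_choice = as.integer(draws_per_social_choice),
         demonstrator_epsilon = demonstrator_epsilon,
         strategies = strategies),
    class = "experiment_config"
  )
}

# Vectorized demonstrator learning across `n_blocks` independent blocks of
# `n_demo` demonstrators each. Demonstrators know the urn compositions; after
# each draw they choose the urn with the greater posterior probability of
# holding three winning balls (uniform prior over the two assignments, known
# win probability). That posterior comparison reduces exactly to comparing
# net wins (wins minus losses) accumulated on each urn; ties are random.
# Returns choices["block", "demo", "trial"] as "L"/"R" and the win indicator.
simulate_demonstrator_choices <- function(n_blocks, n_demo, n_trials,
                                          optimal_urn, win_prob, epsilon = 0) {
  stopifnot(length(optimal_urn) == n_blocks)
  m <- n_blocks * n_demo
  # the length-m state vectors are laid out block-fastest, matching
  # matrix(..., nrow = n_blocks) below
  opt_left <- rep(optimal_urn == "L", times = n_demo)
  net_l <- numeric(m)
  net_r <- numeric(m)
  choices <- array(NA_character_, dim = c(n_blocks, n_demo, n_trials))
  wins <- array(NA_integer_, dim = c(n_blocks, n_demo, n_trials))
  for (t in seq_len(n_trials)) {
    d <- net_l - net_r
    choose_l <- ifelse(d > 0, TRUE, ifelse(d < 0, FALSE, stats::runif(m) < 0.5))
    if (epsilon > 0) {
      explore <- stats::runif(m) < epsilon
      choose_l[explore] <- stats::runif(sum(explore)) < 0.5
    }
    p_win <- ifelse(choose_l == opt_left, win_prob, 1 - win_prob)
    win <- stats::runif(m) < p_win
    net_l <- net_l + ifelse(choose_l, ifelse(win, 1, -1), 0)
    net_r <- net_r + ifelse(choose_l, 0, ifelse(win, 1, -1))
    choices[, , t] <- matrix(ifelse(choose_l, "L", "R"), nrow = n_blocks)
    wins[, , t] <- matrix(as.integer(win), nrow = n_blocks)
  }
  list(choices = choices, wins = wins)
}

#' Simulate one block of demonstrator learning
#'
#' Runs the demonstrator model for a single block: each demonstrator chooses
#' repeatedly, sees the drawn ball, and greedily picks the urn with the higher
#' posterior probability of being the optimal (three-winning-ball) urn.
#'
#' @param config An [experiment_config()].
#' @param demo_optimal_urn `"L"` or `"R"`, the demonstrators' optimal urn.
#' @return A data frame with one row per demonstrator-trial: `subject`,
#'   `trial`, `urn_chosen`, `win`, `points`.
#' @export
simulate_demonstrator_block <- function(config, demo_optimal_urn = "L") {
  stopifnot(inherits(config, "experiment_config"),
            demo_optimal_urn %in% c("L", "R"))
  nd <- config$demonstrators_per_group
  nt <- config$trials_per_block
  sim <- simulate_demonstrator_choices(1L, nd, nt, demo_optimal_urn,
                                       config$win_prob_optimal,
                                       config$demonstrator_epsilon)
  data.frame(
    subject = rep(seq_len(nd), times = nt),
    trial = rep(seq_len(nt), each = nd),
    urn_chosen = as.vector(sim$choices[1L, , ]),
    win = as.vector(sim$wins[1L, , ]),
    points = as.vector(sim$wins[1L, , ]) * config$points_win
  )
}

# Concordance labels for the blocks of one group.
block_concordance <- function(config, group_in_session) {
  nb <- config$n_blocks
  if (config$design == "between") {
    rep(group_in_session == 2L, nb)
  } else {
    # alternating, initial block counterbalanced across the session's groups
    start_concordant <- group_in_session == 2L
    base <- rep(c(TRUE, FALSE), length.out = nb)
    if (start_concordant) base else !base
  }
}

#' Simulate one experimental session
#'
#' A session holds two non-interacting groups. Within each group,
#' demonstrators learn individually for `n_blocks` blocks (urns re-randomized
#' each block) and each social learner makes one choice per block from the
#' demonstrators' final-trial choice distribution, according to her assigned
#' strategy. Strategies are static: learners receive no per-block feedback, so
#' nothing in the generator lets a learner's rule drift over the session.
#'
#' @param config An [experiment_config()].
#' @param session Integer session id used in subject labels.
#' @return A trial-record data frame; see [validate_trial_records()] for the
#'   schema.
#' @export
#' @examples
#' set.seed(1)
#' tab <- simulate_session(experiment_config())
#' head(tab)
simulate_session <- function(config, session = 1L) {
  stopifnot(inherits(config, "experiment_config"))
  nd <- config$demonstrators_per_group
  nb <- config$n_blocks
  nt <- config$trials_per_block
  out <- vector("list", 2L)

  for (g in 1:2) {
    concordant <- block_concordance(config, g)
    demo_opt <- ifelse(stats::runif(nb) < 0.5, "L", "R")
    social_opt <- ifelse(concordant, demo_opt,
                         ifelse(demo_opt == "L", "R", "L"))
    sim <- simulate_demonstrator_choices(nb, nd, nt, demo_opt,
                                         config$win_prob_optimal,
                                         config$demonstrator_epsilon)

    # as.vector() on the (block, demo, trial) array varies block fastest,
    # then demonstrator, then trial; the index columns must match that order
    demo_rows <- data.frame(
      session = session, group = g,
      design = config$design, information = config$information,
      role = "demonstrator",
      subject = sprintf("S%02dG%dD%d", session, g,
                        rep(rep(seq_len(nd), each = nb), times = nt)),
      block = rep(seq_len(nb), times = nd * nt),
      trial = rep(seq_len(nt), each = nd * nb),
      concordant = rep(concordant, times = nd * nt),
      urn_chosen = as.vector(sim$choices),
      demo_optimal_urn = rep(demo_opt, times = nd * nt),
      social_optimal_urn = rep(social_opt, times = nd * nt),
      wins = as.vector(sim$wins),
      points = as.vector(sim$wins) * config$points_win,
      stringsAsFactors = FALSE
    )

    n_learners <- if (length(config$learners_per_group) == 1L) {
      config$learners_per_group
    } else {
      sample(config$learners_per_group, 1L)
    }
    n_left5 <- rowSums(sim$choices[, , nt, drop = FALSE] == "L")
    learner_rows <- vector("list", n_learners)
    for (k in seq_len(n_learners)) {
      spec <- config$strategies[[(k - 1L) %% length(config$strategies) + 1L]]
      chosen <- character(nb)
      for (b in seq_len(nb)) {
        chosen[b] <- strategy_choose(spec, n_left5[b], nd, concordant[b])
      }
      p_win <- ifelse(chosen == social_opt, config$win_prob_optimal,
                      1 - config$win_prob_optimal)
      wins <- stats::rbinom(nb, config$draws_per_social_choice, p_win)
      learner_rows[[k]] <- data.frame(
        session = session, group = g,
        design = config$design, information = config$information,
        role = "social_learner",
        subject = sprintf("S%02dG%dL%d", session, g, k),
        block = seq_len(nb), trial = NA_integer_,
        concordant = concordant,
        urn_chosen = chosen,
        demo_optimal_urn = demo_opt,
        social_optimal_urn = social_opt,
        wins = wins,
        points = wins * config$points_win,
        stringsAsFactors = FALSE
      )
    }
    out[[g]] <- rbind(demo_rows, do.call(rbind, learner_rows))
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Simulate a multi-session experiment
#'
#' @param config An [experiment_config()].
#' @param seed Optional integer seed for exact reproducibility.
#' @param sessions Integer session ids, one per simulated session (defaults
#'   to `1:n_sessions`); distinct ids keep subjects distinguishable when
#'   several simulated experiments are combined into one table.
#' @return A trial-record data frame covering `n_sessions` sessions.
#' @export
simulate_experiment <- function(config, seed = NULL,
                                sessions = seq_len(config$n_sessions)) {
  stopifnot(inherits(config, "experiment_config"),
            length(sessions) == config$n_sessions)
  if (!is.null(seed)) set.seed(seed)
  tabs <- lapply(sessions, function(s) {
    simulate_session(config, session = s)
  })
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  tab
}

#' Expected-payoff equivalence of social learning strategies
#'
#' In the opaque design with a uniform prior over concordance and a uniform
#' urn assignment, every social learning strategy has the same expected payoff
#' (and indeed the same payoff distribution): whatever rule maps the observed
#' demonstrator distribution to an urn, the chosen urn is the learner-optimal
#' one with probability one half. This function checks that property by Monte
#' Carlo, simulating independent blocks and paying each strategy on the same
#' demonstrator information. Setting `concordant_only = TRUE` breaks the
#' symmetry (a transparent, always-concordant world) and majority-following
#' then strictly beats minority-following.
#'
#' @param config An [experiment_config()]; supplies the demonstrator model
#'   and payoff parameters.
#' @param strategies Named list of [strategy_spec()] objects to compare.
#' @param n_reps Number of simulated blocks.
#' @param concordant_only If `TRUE`, every block is concordant.
#' @param seed Optional integer seed.
#' @return A data frame with one row per strategy: `strategy`, `mean_payoff`
#'   (points per block), `se` (Monte-Carlo standard error), `n_reps`.
#' @export
#' @examples
#' payoff_equivalence_check(n_reps = 2000, seed = 1)
payoff_equivalence_check <- function(config = experiment_config(information = "opaque_prior"),
                                     strategies = list(
                                       majority = strategy_spec("majority"),
                                       minority = strategy_spec("minority"),
                                       random = strategy_spec("random"),
                                       unconditional_L = strategy_spec("unconditional_L")
                                     ),
                                     n_reps = 1e5,
                                     concordant_only = FALSE,
                                     seed = NULL) {
  stopifnot(inherits(config, "experiment_config"), n_reps >= 2)
  if (!is.null(seed)) set.seed(seed)
  nd <- config$demonstrators_per_group
  nt <- config$trials_per_block

  concordant <- if (concordant_only) rep(TRUE, n_reps) else stats::runif(n_reps) < 0.5
  demo_opt <- ifelse(stats::runif(n_reps) < 0.5, "L", "R")
  social_opt <- ifelse(concordant, demo_opt, ifelse(demo_opt == "L", "R", "L"))
  sim <- simulate_demonstrator_choices(n_reps, nd, nt, demo_opt,
                                       config$win_prob_optimal,
                                       config$demonstrator_epsilon)
  n_left5 <- rowSums(sim$choices[, , nt, drop = FALSE] == "L")

  res <- lapply(names(strategies), function(nm) {
    spec <- strategies[[nm]]
    chosen <- vapply(seq_len(n_reps), function(b) {
      strategy_choose(spec, n_left5[b], nd, concordant[b])
    }, character(1))
    p_win <- ifelse(chosen == social_opt, config$win_prob_optimal,
                    1 - config$win_prob_optimal)
    payoff <- stats::rbinom(n_reps, config$draws_per_social_choice, p_win) *
      config$points_win
    data.frame(strategy = nm, mean_payoff = mean(payoff),
               se = stats::sd(payoff) / sqrt(n_reps), n_reps = n_reps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
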