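# Gene-culture coevolutionary simulator. Each generation a cohort of learners
# inherits cognitive representations (q_hat, gamma_hat, phi_hat), observes the
# previous cohort's realized behaviors as demonstrators, chooses, is paid for
# matching its own state, and reproduces by payoff-proportional (Wright-Fisher)
# resampling with mutation. The behavior frequency evolves culturally while the
# representations evolve genetically.

# Traits live on an unconstrained transformed scale:
#   q_hat     = 0.5 + 0.5 * plogis(u1)  in (0.5, 1)
#   gamma_hat = plogis(u2)              in (0, 1)
#   phi_hat   = plogis(u3)              in (0, 1)
.traits_to_natural <- function(u) {
  cbind(q_hat = 0.5 + 0.5 * stats::plogis(u[, 1L]),
        gamma_hat = stats::plogis(u[, 2L]),
        phi_hat = stats::plogis(u[, 3L]))
}

#' Configuration for a coevolutionary run
#'
#' @param world A [world_params()] giving the true task structure: the
#'   cohort-level discordance rate `gamma`, cue reliability `phi`, private
#'   signal noise `sigma`, and the number of demonstrators each learner
#'   samples. The world's `q` slot is ignored: demonstrator accuracy is
#'   endogenous, it is whatever fraction of the previous cohort actually chose
#'   its optimum.
#' @param pop_size Number of learners per generation.
#' @param generations Total generations to simulate.
#' @param burn_in Generations discarded before summarizing; must be smaller
#'   than `generations`.
#' @param mutation_prob Per-trait mutation probability at reproduction.
#' @param mutation_sd Standard deviation of Gaussian mutations on the
#'   transformed (logit) trait scale.
#' @param payoff_base Baseline payoff, must be positive so that selection is
#'   always well defined.
#' @param payoff_bonus Additional payoff for choosing one's own optimum; set
#'   to 0 for a neutral (drift-only) run.
#' @param init_sd Standard deviation of the initial trait distribution on the
#'   transformed scale.
#'
#' @return An object of class `evo_config`.
#' @export
#' @examples
#' evo_config(world_params(gamma = 0.1, phi = 0.9, n_demo = 5, sigma = 3))
evo_config <- function(world,
                       pop_size = 1000L,
                       generations = 5000L,
                       burn_in = 2000L,
                       mutation_prob = 0.01,
                       mutation_sd = 0.1,
                       payoff_base = 1,
                       payoff_bonus = 1,
                       init_sd = 1) {
  stopifnot(
    inherits(world, "world_params"),
    pop_size >= world$n_demo,
    generations > burn_in, burn_in >= 0,
    mutation_prob >= 0, mutation_prob <= 1,
    mutation_sd > 0,
    payoff_base > 0, payoff_bonus >= 0,
    init_sd > 0
  )
  structure(
    list(world = world, pop_size = as.integer(pop_size),
         generations = as.integer(generations), burn_in = as.integer(burn_in),
         mutation_prob = mutation_prob, mutation_sd = mutation_sd,
         payoff_base = payoff_base, payoff_bonus = payoff_bonus,
         init_sd = init_sd),
    class = "evo_config"
  )
}

#' Initialize the coevolutionary state
#'
#' Draws the founding population's traits from a wide Gaussian on the
#' transformed scale, the founding demonstrator behaviors from a fair coin,
#' and a random initial state. Uses R's random stream; call [set.seed()]
#' first for a reproducible trajectory.
#'
#' @param config An [evo_config()].
#' @return An object of class `evo_state` with elements `generation`, `z`
#'   (current cohort state), `y` (demonstrator-pool state), `demo_behaviors`
#'   (previous cohort's realized choices), `traits` (pop_size x 3 matrix on
#'   the transformed scale), and `behavior_freq`.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "evo_config"))
  n <- config$pop_size
  traits <- matrix(stats::rnorm(3L * n, 0, config$init_sd), nrow = n, ncol = 3L,
                   dimnames = list(NULL, c("u_q", "u_gamma", "u_phi")))
  z <- as.integer(stats::runif(1) < 0.5)
  demo <- as.integer(stats::runif(n) < 0.5)
  structure(
    list(generation = 0L, z = z, y = z, demo_behaviors = demo,
         traits = traits, behavior_freq = mean(demo)),
    class = "evo_state"
  )
}

#' Advance the coevolutionary system by one generation
#'
#' One generation: (1) the cohort state flips from the demonstrator-pool state
#' with probability `gamma` (a single cohort-level flip, since discordance is
#' defined at the cohort level); (2) each learner independently samples
#' `n_demo` demonstrators uniformly with replacement from the previous
#' cohort's realized behaviors, receives a similarity cue that is correct with
#' probability `phi`, receives a private signal `s ~ Normal(2z - 1, sigma^2)`,
#' and chooses by the posterior-odds threshold rule; (3) payoff is
#' `payoff_base + payoff_bonus * [choice == own optimum]`; (4) the next
#' generation's traits are drawn by payoff-proportional resampling with
#' per-trait Gaussian mutation on the transformed scale; (5) this cohort's
#' realized choices become the next demonstrator pool.
#'
#' @param state An `evo_state`.
#' @param config An [evo_config()].
#' @return The next `evo_state`.
#' @export
generation_step <- function(state, config) {
  stopifnot(inherits(state, "evo_state"), inherits(config, "evo_config"))
  w <- config$world
  n <- config$pop_size

  # (1) environment: cohort state flips from the demonstrators' state w.p. gamma
  y <- state$z
  z <- if (stats::runif(1) < w$gamma) 1L - y else y
  concordant <- z == y

  # (2) observation and choice, vectorized across learners
  demo_idx <- sample.int(n, n * w$n_demo, replace = TRUE)
  i <- rowSums(matrix(state$demo_behaviors[demo_idx], nrow = n))
  cue_correct <- stats::runif(n) < w$phi
  a_same <- ifelse(cue_correct, concordant, !concordant)
  s <- stats::rnorm(n, mean = 2 * z - 1, sd = w$sigma)

  nat <- .traits_to_natural(state$traits)
  L <- .social_log_odds_vec(a_same, i, w$n_demo,
                            nat[, "q_hat"], nat[, "gamma_hat"], nat[, "phi_hat"])
  evidence <- 2 * s / w$sigma^2 + L   # sigma_hat pinned to sigma
  choice <- ifelse(evidence > 0, 1L,
                   ifelse(evidence < 0, 0L, as.integer(stats::runif(n) < 0.5)))

  # (3) selection on matching one's own state
  payoff <- config$payoff_base + config$payoff_bonus * (choice == z)

  # (4) Wright-Fisher resampling + mutation on the transformed scale
  parents <- sample.int(n, n, replace = TRUE, prob = payoff)
  traits <- state$traits[parents, , drop = FALSE]
  mutate <- matrix(stats::runif(3L * n) < config$mutation_prob, nrow = n)
  n_mut <- sum(mutate)
  if (n_mut > 0) {
    traits[mutate] <- traits[mutate] + stats::rnorm(n_mut, 0, config$mutation_sd)
  }

  structure(
    list(generation = state$generation + 1L, z = z, y = z,
         demo_behaviors = choice, traits = traits,
         behavior_freq = mean(choice),
         demo_accuracy = mean(state$demo_behaviors == y),
         learner_accuracy = mean(choice == z)),
    class = "evo_state"
  )
}

#' Run the gene-culture coevolutionary simulation
#'
#' Simulates `generations` generations, discards the burn-in, and summarizes
#' the evolved learning system: the time-averaged population-mean traits, the
#' mean observed demonstrator accuracy, the two conditional learning functions
#' of the mean genotype (evaluated at that observed accuracy), and the
#' asymmetry index. Per-generation summaries are returned as a data frame for
#' plotting or export.
#'
#' @param config An [evo_config()].
#' @param seed Optional integer seed; if supplied, `set.seed(seed)` is called
#'   so the run is exactly reproducible.
#' @param mean_of_functions If `TRUE`, additionally report learning functions
#'   averaged over individual genotypes (rather than the mean genotype's
#'   function) in elements `lf_same_indiv` / `lf_diff_indiv`. The two differ
#'   when the population is polymorphic.
#' @return An object of class `evo_summary`: a list with `mean_rep` (a
#'   [cognitive_rep()]), `world_realized` (a [world_params()] whose `q` is the
#'   mean post-burn-in demonstrator accuracy), `lf_same`, `lf_diff`,
#'   `asymmetry`, `trajectory` (per-generation data frame), and `config`.
#' @export
#' @examples
#' cfg <- evo_config(world_params(gamma = 0.1, phi = 0.9, n_demo = 5, sigma = 3),
#'                   pop_size = 200, generations = 300, burn_in = 100)
#' run_evolution(cfg, seed = 1)
run_evolution <- function(config, seed = NULL, mean_of_functions = FALSE) {
  stopifnot(inherits(config, "evo_config"))
  if (!is.null(seed)) set.seed(seed)
  state <- init_population(config)

  gens <- config$generations
  keep <- gens - config$burn_in
  traj <- data.frame(
    generation = seq_len(gens),
    behavior_freq = NA_real_, demo_accuracy = NA_real_,
    learner_accuracy = NA_real_,
    mean_q_hat = NA_real_, mean_gamma_hat = NA_real_, mean_phi_hat = NA_real_
  )
  trait_sum <- c(0, 0, 0)

  for (g in seq_len(gens)) {
    state <- generation_step(state, config)
    nat <- .traits_to_natural(state$traits)
    mu <- colMeans(nat)
    traj$behavior_freq[g] <- state$behavior_freq
    traj$demo_accuracy[g] <- state$demo_accuracy
    traj$learner_accuracy[g] <- state$learner_accuracy
    traj$mean_q_hat[g] <- mu["q_hat"]
    traj$mean_gamma_hat[g] <- mu["gamma_hat"]
    traj$mean_phi_hat[g] <- mu["phi_hat"]
    if (g > config$burn_in) trait_sum <- trait_sum + colMeans(state$traits)
  }

  u_mean <- matrix(trait_sum / keep, nrow = 1L)
  nat_mean <- .traits_to_natural(u_mean)
  mean_rep <- cognitive_rep(
    q_hat = nat_mean[1, "q_hat"],
    gamma_hat = nat_mean[1, "gamma_hat"],
    phi_hat = nat_mean[1, "phi_hat"],
    sigma_hat = config$world$sigma
  )
  q_real <- mean(traj$demo_accuracy[(config$burn_in + 1L):gens])
  world_real <- world_params(
    gamma = config$world$gamma, phi = config$world$phi,
    n_demo = config$world$n_demo, sigma = config$world$sigma,
    q = min(max(q_real, 0.5), 1)
  )

  out <- list(
    mean_rep = mean_rep,
    world_realized = world_real,
    lf_same = learning_function(world_real, mean_rep, "same"),
    lf_diff = learning_function(world_real, mean_rep, "different"),
    asymmetry = asymmetry_index(world_real, mean_rep),
    trajectory = traj,
    config = config,
    seed = seed
  )
  if (mean_of_functions) {
    nat <- .traits_to_natural(state$traits)
    lf_of <- function(j, a) {
      r <- cognitive_rep(nat[j, "q_hat"], nat[j, "gamma_hat"],
                         nat[j, "phi_hat"], config$world$sigma)
      learning_function(world_real, r, a)$prob
    }
    idx <- seq_len(min(nrow(nat), 200L))  # subsample for tractability
    out$lf_same_indiv <- rowMeans(vapply(idx, lf_of, numeric(config$world$n_demo + 1L), a = "same"))
    out$lf_diff_indiv <- rowMeans(vapply(idx, lf_of, numeric(config$world$n_demo + 1L), a = "different"))
  }
  class(out) <- "evo_summary"
  out
}

#' @export
print.evo_summary <- function(x, ...) {
  cfg <- x$config
  cat("Gene-culture coevolution summary\n")
  cat(sprintf("  %d generations (burn-in %d), pop %d; gamma = %.3g, phi = %.3g, sigma = %.3g\n",
              cfg$generations, cfg$burn_in, cfg$pop_size,
              cfg$world$gamma, cfg$world$phi, cfg$world$sigma))
  cat(sprintf("  realized demonstrator accuracy: %.3f\n", x$world_realized$q))
  cat(sprintf("  mean representation: q_hat = %.3f, gamma_hat = %.3f, phi_hat = %.3f\n",
              x$mean_rep$q_hat, x$mean_rep$gamma_hat, x$mean_rep$phi_hat))
  cat(sprintf("  asymmetry index: %.4f\n", x$asymmetry))
  cat("  learning function, cue = different:\n")
  cat("   ", paste(sprintf("%.3f", x$lf_diff$prob), collapse = " "), "\n")
  cat("  learning function, cue = same:\n")
  cat("   ", paste(sprintf("%.3f", x$lf_same$prob), collapse = " "), "\n")
  invisible(x)
}
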