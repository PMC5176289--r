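# Core decision model: a learner facing one of two environmental states chooses
# one of two behaviors after observing (i) a noisy private signal s about her
# own state, (ii) the number of sampled demonstrators exhibiting behavior 1,
# and (iii) a noisy binary cue of similarity indicating whether demonstrators
# faced the same state she does.

# Probabilities are clipped this far from {0, 1} before any log so that
# log-odds stay finite for representations at the edge of their open intervals.
.PROB_EPS <- 1e-12

.clip_prob <- function(p) pmin(pmax(p, .PROB_EPS), 1 - .PROB_EPS)

#' True task structure for the similarity-conditioned learning problem
#'
#' Bundles the parameters of the world a social learner faces: two states, two
#' behaviors (behavior 1 optimal in state 1), demonstrators who faced a state
#' that differs from the learner's with probability `gamma`, a binary
#' similarity cue that is correct with probability `phi`, a Gaussian private
#' signal with noise `sigma`, and demonstrators who exhibit their own optimal
#' behavior with probability `q`.
#'
#' @param gamma Probability in `[0, 1]` that learner and demonstrator states
#'   differ (discordance rate).
#' @param phi Probability in `[0.5, 1]` that the similarity cue is correct.
#' @param n_demo Positive integer, number of demonstrators sampled.
#' @param sigma Positive standard deviation of the private signal
#'   `s | z ~ Normal(2z - 1, sigma^2)`.
#' @param q Probability in `[0.5, 1]` that a demonstrator exhibits the
#'   behavior optimal in the demonstrators' state.
#'
#' @return An object of class `world_params`.
#' @seealso [cognitive_rep()], [learning_function()]
#' @export
#' @examples
#' world_params(gamma = 0.1, phi = 0.9, n_demo = 5, sigma = 2, q = 0.75)
world_params <- function(gamma, phi, n_demo = 5L, sigma = 1, q = 0.75) {
  stopifnot(
    is.numeric(gamma), length(gamma) == 1L, gamma >= 0, gamma <= 1,
    is.numeric(phi), length(phi) == 1L, phi >= 0.5, phi <= 1,
    is.numeric(n_demo), length(n_demo) == 1L, n_demo >= 1, n_demo == round(n_demo),
    is.numeric(sigma), length(sigma) == 1L, sigma > 0,
    is.numeric(q), length(q) == 1L, q >= 0.5, q <= 1
  )
  structure(
    list(gamma = gamma, phi = phi, n_demo = as.integer(n_demo),
         sigma = sigma, q = q),
    class = "world_params"
  )
}

#' @export
print.world_params <- function(x, ...) {
  cat("World parameters\n")
  cat(sprintf("  discordance rate gamma : %.4g\n", x$gamma))
  cat(sprintf("  cue reliability phi    : %.4g\n", x$phi))
  cat(sprintf("  demonstrators sampled  : %d\n", x$n_demo))
  cat(sprintf("  private-signal sd sigma: %.4g  (reliability alpha = %.4f)\n",
              x$sigma, signal_reliability(x$sigma)))
  cat(sprintf("  demonstrator accuracy q: %.4g\n", x$q))
  invisible(x)
}

#' Reliability of the Gaussian private signal
#'
#' Under the signal model `s | z ~ Normal(2z - 1, sigma^2)` the probability
#' that the sign of `s` matches the learner's state is `pnorm(1 / sigma)`.
#' It lies in `(0.5, 1)` and increases as `sigma` decreases.
#'
#' @param sigma Positive signal standard deviation (vectorized).
#' @return The probability that the signal sign identifies the state.
#' @export
#' @examples
#' signal_reliability(1)   # ~0.841
#' signal_reliability(10)  # barely better than chance
signal_reliability <- function(sigma) {
  stopifnot(is.numeric(sigma), all(sigma > 0))
  stats::pnorm(1 / sigma)
}

#' Heritable cognitive representation of the learning task
#'
#' The learner does not know the true task parameters; she carries inherited
#' internal stand-ins that enter her inference in place of the truth:
#' `q_hat` for demonstrator accuracy, `gamma_hat` for the discordance prior,
#' `phi_hat` for similarity-cue reliability, and `sigma_hat` for her own
#' signal noise. Only the combination of signal weight and social weight is
#' identified by behavior, so by convention `sigma_hat` is pinned to the true
#' `sigma` and `q_hat` carries the evolvable social-weight degree of freedom.
#'
#' @param q_hat Probability in `(0.5, 1)`, represented demonstrator accuracy.
#' @param gamma_hat Probability in `(0, 1)`, represented discordance prior.
#' @param phi_hat Probability in `(0, 1)`, represented cue reliability.
#' @param sigma_hat Positive real, represented private-signal noise.
#'
#' @return An object of class `cognitive_rep`.
#' @export
#' @examples
#' cognitive_rep(q_hat = 0.75, gamma_hat = 0.1, phi_hat = 0.9, sigma_hat = 1)
cognitive_rep <- function(q_hat, gamma_hat, phi_hat, sigma_hat = 1) {
  stopifnot(
    is.numeric(q_hat), length(q_hat) == 1L, q_hat > 0.5, q_hat < 1,
    is.numeric(gamma_hat), length(gamma_hat) == 1L, gamma_hat > 0, gamma_hat < 1,
    is.numeric(phi_hat), length(phi_hat) == 1L, phi_hat > 0, phi_hat < 1,
    is.numeric(sigma_hat), length(sigma_hat) == 1L, sigma_hat > 0
  )
  structure(
    list(q_hat = q_hat, gamma_hat = gamma_hat, phi_hat = phi_hat,
         sigma_hat = sigma_hat),
    class = "cognitive_rep"
  )
}

#' @export
print.cognitive_rep <- function(x, ...) {
  cat("Cognitive representation\n")
  cat(sprintf("  q_hat = %.4g, gamma_hat = %.4g, phi_hat = %.4g, sigma_hat = %.4g\n",
              x$q_hat, x$gamma_hat, x$phi_hat, x$sigma_hat))
  invisible(x)
}

#' One learner's observation
#'
#' @param s Real private signal.
#' @param i Integer in `[0, n_demo]`: demonstrators exhibiting behavior 1.
#' @param a Similarity cue, `"same"` or `"different"`.
#' @param n_demo Number of demonstrators sampled.
#'
#' @return An object of class `observation`.
#' @export
observation <- function(s, i, a, n_demo = 5L) {
  a <- match.arg(a, c("same", "different"))
  stopifnot(
    is.numeric(s), length(s) == 1L, is.finite(s),
    is.numeric(i), length(i) == 1L, i == round(i),
    is.numeric(n_demo), length(n_demo) == 1L, n_demo == round(n_demo),
    i >= 0, i <= n_demo
  )
  structure(list(s = s, i = as.integer(i), a = a, n_demo = as.integer(n_demo)),
            class = "observation")
}

#' Binomial likelihood of the observed demonstrator count
#'
#' Probability of observing `i` of `n_demo` demonstrators exhibiting behavior
#' 1 when each independently exhibits it with probability `q` if the
#' demonstrators' state is 1, and `1 - q` if it is 0.
#'
#' @param i Count of demonstrators exhibiting behavior 1 (vectorized).
#' @param n_demo Number of demonstrators sampled.
#' @param q Per-demonstrator probability of the demonstrator-optimal behavior.
#' @param y Demonstrators' state, 0 or 1.
#' @return Binomial probability of the count.
#' @export
#' @examples
#' demo_count_likelihood(5, 5, 0.75, y = 1)  # 0.75^5
demo_count_likelihood <- function(i, n_demo, q, y) {
  stopifnot(
    is.numeric(i), all(i == round(i)),
    is.numeric(n_demo), length(n_demo) == 1L, n_demo == round(n_demo),
    is.numeric(q), length(q) == 1L,
    length(y) == 1L, y %in% c(0, 1)
  )
  if (any(i < 0 | i > n_demo)) {
    stop("count `i` must lie in [0, n_demo]", call. = FALSE)
  }
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]", call. = FALSE)
  p1 <- if (y == 1) q else 1 - q
  stats::dbinom(i, size = n_demo, prob = p1)
}

#' Posterior probability of a shared optimum given the similarity cue
#'
#' Bayesian update of the discordance prior `gamma` by a binary cue correct
#' with probability `phi`. With a cue indicating the same optimum the
#' posterior probability of concordance is
#' `(1 - gamma) phi / ((1 - gamma) phi + gamma (1 - phi))`; a cue indicating
#' different optima swaps `phi` and `1 - phi`. A biased prior (`gamma < 0.5`)
#' makes the two posteriors asymmetric: a "different" cue must first offset
#' the prior before it can support a belief in different optima.
#'
#' @param gamma Discordance prior in `(0, 1)`.
#' @param phi Cue reliability in `[0.5, 1]`.
#' @param a Cue value, `"same"` or `"different"`.
#' @return Posterior probability that learner and demonstrators share an
#'   optimum.
#' @export
#' @examples
#' similarity_posterior(0.1, 0.9, "different")  # exactly 0.5
#' similarity_posterior(0.1, 0.9, "same")       # ~0.988
similarity_posterior <- function(gamma, phi, a) {
  a <- match.arg(a, c("same", "different"))
  stopifnot(
    is.numeric(gamma), length(gamma) == 1L, gamma > 0, gamma < 1,
    is.numeric(phi), length(phi) == 1L, phi >= 0.5, phi <= 1
  )
  p_correct <- if (a == "same") phi else 1 - phi
  num <- (1 - gamma) * p_correct
  den <- num + gamma * (1 - p_correct)
  if (den == 0) {
    stop("degenerate cue: prior and a perfectly reliable conflicting signal",
         call. = FALSE)
  }
  num / den
}

# Vectorized workhorse shared with the evolutionary simulator: log-odds of the
# learner's state being 1 given cue and count, for parallel learners with
# possibly different representations. `a_same` is logical.
.social_log_odds_vec <- function(a_same, i, n_demo, q_hat, gamma_hat, phi_hat) {
  q_hat <- .clip_prob(q_hat)
  gamma_hat <- .clip_prob(gamma_hat)
  phi_hat <- .clip_prob(phi_hat)
  # log-scale binomial kernels; the binomial coefficient cancels in the ratio
  lb1 <- i * log(q_hat) + (n_demo - i) * log1p(-q_hat)
  lb0 <- i * log1p(-q_hat) + (n_demo - i) * log(q_hat)
  p_cue <- ifelse(a_same, phi_hat, 1 - phi_hat)
  w_conc <- (1 - gamma_hat) * p_cue       # weight on y = z
  w_disc <- gamma_hat * (1 - p_cue)       # weight on y != z
  # stable log-sum-exp of w_conc * B1 + w_disc * B0 over the two kernels
  lse2 <- function(wa, la, wb, lb) {
    m <- pmax(la, lb)
    m + log(wa * exp(la - m) + wb * exp(lb - m))
  }
  lse2(w_conc, lb1, w_disc, lb0) - lse2(w_disc, lb1, w_conc, lb0)
}

#' Social log-odds of the learner's state from cue and demonstrator count
#'
#' The learner's posterior log-odds `log P(z = 1 | a, i) / P(z = 0 | a, i)`,
#' marginalized over the demonstrators' state with a flat prior on the
#' learner's state, computed with the learner's cognitive representation in
#' place of the true task parameters. With `B1 = q^i (1-q)^(n-i)` and
#' `B0 = (1-q)^i q^(n-i)`, a "same" cue gives
#' `log[((1-g) p B1 + g (1-p) B0) / (g (1-p) B1 + (1-g) p B0)]`
#' for `g = gamma_hat`, `p = phi_hat`; a "different" cue swaps `p` and `1-p`.
#'
#' @param a Similarity cue, `"same"` or `"different"`.
#' @param i Demonstrators exhibiting behavior 1 (vectorized over `i`).
#' @param n_demo Number of demonstrators sampled.
#' @param rep A [cognitive_rep()].
#' @return Log-odds, finite for representations inside their open intervals.
#' @export
#' @examples
#' rep <- cognitive_rep(0.75, 0.1, 0.9)
#' social_log_odds("same", 5, 5, rep)       # ~4.107: strong majority pull
#' social_log_odds("different", 5, 5, rep)  # 0: cue exactly offsets the prior
social_log_odds <- function(a, i, n_demo, rep) {
  a <- match.arg(a, c("same", "different"))
  stopifnot(inherits(rep, "cognitive_rep"),
            is.numeric(i), all(i == round(i)), all(i >= 0), all(i <= n_demo))
  .social_log_odds_vec(a == "same", i, n_demo,
                       rep$q_hat, rep$gamma_hat, rep$phi_hat)
}

#' Behavior choice by posterior-odds threshold
#'
#' The learner chooses behavior 1 when the combined evidence
#' `2 s / sigma_hat^2 + L` is positive, where `L` is the social log-odds from
#' [social_log_odds()]; exact ties are broken by a fair coin drawn from R's
#' random stream (seed with [set.seed()] for reproducibility).
#'
#' @param obs An [observation()].
#' @param rep A [cognitive_rep()].
#' @return `0` or `1`.
#' @export
choose_behavior <- function(obs, rep) {
  stopifnot(inherits(obs, "observation"), inherits(rep, "cognitive_rep"))
  evidence <- 2 * obs$s / rep$sigma_hat^2 +
    social_log_odds(obs$a, obs$i, obs$n_demo, rep)
  if (evidence > 0) 1L
  else if (evidence < 0) 0L
  else if (stats::runif(1) < 0.5) 1L else 0L
}

#' Closed-form probability of choosing behavior 1
#'
#' The decision rule chooses behavior 1 when `s` exceeds the threshold
#' `-(sigma_hat^2 / 2) L`. Under `s | z ~ Normal(2z - 1, sigma^2)` the choice
#' probability is a Normal tail probability; no simulation is involved.
#'
#' @param z Learner's state, 0 or 1.
#' @param a Similarity cue.
#' @param i Demonstrators exhibiting behavior 1 (vectorized).
#' @param world A [world_params()] (supplies the true `sigma`).
#' @param rep A [cognitive_rep()].
#' @return Probability that the learner chooses behavior 1.
#' @export
#' @examples
#' w <- world_params(0.1, 0.9, 5, sigma = 1)
#' r <- cognitive_rep(0.75, 0.1, 0.9)
#' choice_probability(1, "different", 3, w, r)  # pnorm(1): private signal only
choice_probability <- function(z, a, i, world, rep) {
  stopifnot(length(z) == 1L, z %in% c(0, 1),
            inherits(world, "world_params"), inherits(rep, "cognitive_rep"))
  a <- match.arg(a, c("same", "different"))
  L <- social_log_odds(a, i, world$n_demo, rep)
  threshold <- -(rep$sigma_hat^2 / 2) * L
  stats::pnorm(threshold, mean = 2 * z - 1, sd = world$sigma,
               lower.tail = FALSE)
}

#' Learning function: probability of choosing one's own optimum
#'
#' For each count `k` of demonstrators exhibiting the behavior that is optimal
#' for the learner, the probability that the learner chooses that optimum,
#' conditional on the similarity cue. The two state labelings are averaged,
#' which makes the function exactly symmetric under relabeling of the two
#' behaviors. Plotted against `k / n_demo`, a curve above the diagonal is
#' positive (conformist-like) social influence; below is negative.
#'
#' @param world A [world_params()].
#' @param rep A [cognitive_rep()].
#' @param a Similarity cue, `"same"` or `"different"`.
#' @return A data frame of class `learning_function` with columns `k`
#'   (demonstrators exhibiting the learner-optimal behavior) and `prob`;
#'   attributes `condition` (the cue) and `alpha` (individual-learning
#'   reliability, the level of the flat no-social-information line).
#' @export
#' @examples
#' w <- world_params(0.1, 0.9, 5, sigma = 2)
#' r <- cognitive_rep(0.75, 0.1, 0.9)
#' learning_function(w, r, "same")
learning_function <- function(world, rep, a) {
  stopifnot(inherits(world, "world_params"), inherits(rep, "cognitive_rep"))
  a <- match.arg(a, c("same", "different"))
  n <- world$n_demo
  k <- 0:n
  # optimum = 1: k demonstrators show behavior 1, learner in state 1
  p_opt1 <- choice_probability(1, a, k, world, rep)
  # optimum = 0: behavior-1 count is n - k, learner in state 0
  p_opt0 <- 1 - choice_probability(0, a, n - k, world, rep)
  out <- data.frame(k = k, prob = (p_opt1 + p_opt0) / 2)
  structure(out, condition = a, alpha = signal_reliability(world$sigma),
            class = c("learning_function", "data.frame"))
}

#' @export
print.learning_function <- function(x, ...) {
  cat(sprintf("Learning function (cue: %s; alpha = %.4f)\n",
              attr(x, "condition"), attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Plot a pair of conditional learning functions
#'
#' Draws the probability of choosing one's own optimum against the fraction of
#' demonstrators exhibiting it, for the "different" and "same" cue conditions,
#' with the unbiased diagonal and the individual-learning level as references.
#'
#' @param lf_diff,lf_same [learning_function()] objects for the two cues.
#' @param main Plot title.
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plot_learning_functions <- function(lf_diff, lf_same, main = "Learning functions") {
  stopifnot(inherits(lf_diff, "learning_function"),
            inherits(lf_same, "learning_function"))
  n <- max(lf_diff$k)
  graphics::plot(lf_diff$k / n, lf_diff$prob, type = "b", pch = 17,
                 col = "firebrick", ylim = c(0, 1),
                 xlab = "Fraction of demonstrators with the learner-optimal behavior",
                 ylab = "P(learner chooses her optimum)", main = main)
  graphics::lines(lf_same$k / n, lf_same$prob, type = "b", pch = 19,
                  col = "navy")
  graphics::abline(0, 1, lty = 2)
  graphics::abline(h = attr(lf_diff, "alpha"), lty = 3)
  graphics::legend("bottomright", legend = c("cue: different", "cue: same"),
                   col = c("firebrick", "navy"), pch = c(17, 19), bty = "n")
  invisible(NULL)
}

#' Asymmetry of the facultative response
#'
#' Compares the strength of the response to social information under the two
#' similarity cues. The strength of a learning function `f` over counts
#' `k = 0..n` is the mean absolute spread `|f(k) - f(n - k)| / 2`: how far the
#' probability of choosing one's optimum moves between a count and its mirror
#' image. The index is the strength under a "same" cue minus the strength
#' under a "different" cue. It is zero whenever the two conditional responses
#' are equally strong: for non-facultative strategies (`phi_hat = 0.5`, where
#' the two functions coincide), for a flat discordance prior
#' (`gamma_hat = 0.5`, where the discordant response is the exact mirror image
#' of the concordant one), and in the limit of a perfectly reliable cue
#' (`phi_hat` near 1). It is positive when the tendency to follow the
#' minority after a "different" cue is weaker than the tendency to follow the
#' majority after a "same" cue — the signature of a biased prior
#' (`gamma_hat < 0.5`) combined with a moderately reliable cue.
#'
#' @param world A [world_params()].
#' @param rep A [cognitive_rep()].
#' @return A single number; positive means the concordant-cue response is the
#'   more extreme one.
#' @export
#' @examples
#' w <- world_params(0.25, 0.7, 5, sigma = 2)
#' asymmetry_index(w, cognitive_rep(0.75, 0.25, 0.7))  # > 0
asymmetry_index <- function(world, rep) {
  f_same <- learning_function(world, rep, "same")$prob
  f_diff <- learning_function(world, rep, "different")$prob
  strength <- function(f) mean(abs(f - rev(f)) / 2)
  strength(f_same) - strength(f_diff)
}
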