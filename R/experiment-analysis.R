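# Statistical pipeline for trial-record tables: demonstrator optimality,
# cluster-robust logistic regressions of social-learner choices, Wald tests of
# linear combinations, per-learner strategy classification, and
# cluster-bootstrap learning curves.

#' Per-learner-block analysis table
#'
#' Collapses a trial-record table to one row per social learner and block,
#' joining on the demonstrators' final-trial choice distribution of the same
#' session, group, and block. Derived columns: `n_demo` (demonstrators
#' observed), `n_left` (demonstrators choosing left), `x5` (centered
#' proportion `n_left / n_demo - 0.5`), `n_demo_opt` (demonstrators choosing
#' the demonstrator-optimal urn), `majority_demo_opt`, `chose_left`,
#' `chose_optimal` (chose the social-learner optimum), `left_optimal_social`,
#' and `learning_block`.
#'
#' @param table A validated trial-record data frame.
#' @return A data frame with one row per social-learner choice.
#' @export
learner_block_table <- function(table) {
  stopifnot(is.data.frame(table))
  demo <- table[table$role == "demonstrator", ]
  soc <- table[table$role == "social_learner", ]
  if (nrow(demo) == 0 || nrow(soc) == 0) {
    stop("table needs both demonstrator and social-learner rows", call. = FALSE)
  }
  last_trial <- max(demo$trial, na.rm = TRUE)
  demo5 <- demo[demo$trial == last_trial, ]
  key5 <- paste(demo5$session, demo5$group, demo5$block, sep = ".")
  n_left <- tapply(demo5$urn_chosen == "L", key5, sum)
  n_demo <- tapply(demo5$urn_chosen, key5, length)
  n_opt <- tapply(demo5$urn_chosen == demo5$demo_optimal_urn, key5, sum)

  key <- paste(soc$session, soc$group, soc$block, sep = ".")
  if (anyNA(match(key, names(n_left)))) {
    stop("social-learner blocks without matching demonstrator final-trial rows",
         call. = FALSE)
  }
  out <- soc
  out$n_demo <- as.integer(n_demo[key])
  out$n_left <- as.integer(n_left[key])
  out$n_demo_opt <- as.integer(n_opt[key])
  out$x5 <- out$n_left / out$n_demo - 0.5
  out$majority_demo_opt <- out$n_demo_opt * 2 > out$n_demo
  out$chose_left <- out$urn_chosen == "L"
  out$chose_optimal <- out$urn_chosen == out$social_optimal_urn
  out$left_optimal_social <- out$social_optimal_urn == "L"
  out$learning_block <- out$block
  rownames(out) <- NULL
  out
}

#' Demonstrator optimality in the final trial of each block
#'
#' The proportion of group-blocks in which a majority of demonstrators chose
#' the demonstrator-optimal urn in the final trial, plus the modal number of
#' optimal choosers.
#'
#' @param table A trial-record data frame containing demonstrator rows.
#' @return A list with `rate` (proportion of blocks with a majority optimal),
#'   `modal_count` (most frequent number of optimal demonstrators),
#'   `n_blocks`, and `count_distribution` (a table over counts).
#' @export
demonstrator_optimal_rate <- function(table) {
  demo <- table[table$role == "demonstrator", ]
  if (nrow(demo) == 0) stop("no demonstrator rows", call. = FALSE)
  last_trial <- max(demo$trial, na.rm = TRUE)
  demo5 <- demo[demo$trial == last_trial, ]
  if (nrow(demo5) == 0) stop("no final-trial demonstrator rows", call. = FALSE)
  key <- paste(demo5$session, demo5$group, demo5$block, sep = ".")
  n_opt <- tapply(demo5$urn_chosen == demo5$demo_optimal_urn, key, sum)
  n_demo <- tapply(demo5$urn_chosen, key, length)
  dist <- table(n_opt)
  list(rate = mean(n_opt * 2 > n_demo),
       modal_count = as.integer(names(dist)[which.max(dist)]),
       n_blocks = length(n_opt),
       count_distribution = dist)
}

#' Logistic regression with cluster-robust standard errors
#'
#' Maximum-likelihood logistic fit with a sandwich covariance clustered on a
#' grouping variable, the workhorse behind [fit_choice_model()] and
#' [fit_optimum_model()]. The point estimates are the ordinary ML estimates;
#' clustering only affects the covariance. The default small-sample adjustment
#' multiplies the sandwich by `M / (M - 1)` for `M` clusters; set
#' `cluster_adjust = "none"` to drop it. Perfect separation is detected and
#' flagged, never silently regularized.
#'
#' @param formula Model formula with a binary response.
#' @param data Data frame.
#' @param cluster Name of the clustering column (one cluster per subject).
#' @param cluster_adjust `"CR1"` (multiply by `M / (M - 1)`) or `"none"`.
#' @return An object of class `cluster_fit`: a list with `coefficients`,
#'   `vcov` (clustered), `se`, `z`, `p_value`, `n`, `n_clusters`, `loglik`,
#'   `separation` (logical flag), and the underlying `glm` in `model`.
#' @export
fit_cluster_logit <- function(formula, data, cluster = "subject",
                              cluster_adjust = c("CR1", "none")) {
  cluster_adjust <- match.arg(cluster_adjust)
  stopifnot(is.data.frame(data), cluster %in% names(data))
  separation <- FALSE
  converged <- TRUE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("algorithm did not converge", msg)) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (anyNA(stats::coef(fit))) {
    stop("aliased (collinear) terms in fit: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "),
         "; a covariate or interaction has no variation in this subset",
         call. = FALSE)
  }
  if (!separation && any(abs(stats::coef(fit)) > 15)) separation <- TRUE
  if (separation || !converged) {
    warning("possible perfect separation or non-convergence; ",
            "coefficients reported as fitted", call. = FALSE)
  }
  cl <- data[[cluster]]
  if (!is.null(fit$na.action)) cl <- cl[-fit$na.action]
  M <- length(unique(cl))
  V <- sandwich::vcovCL(fit, cluster = cl, type = "HC0",
                        cadjust = cluster_adjust == "CR1")
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- b / se
  structure(
    list(coefficients = b, vcov = V, se = se, z = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         n = stats::nobs(fit), n_clusters = M,
         loglik = as.numeric(stats::logLik(fit)),
         separation = separation, converged = converged, cluster = cluster,
         cluster_adjust = cluster_adjust, model = fit),
    class = "cluster_fit"
  )
}

#' @export
print.cluster_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cluster-robust logistic fit (n = %d, clusters = %d, logLik = %.2f)\n",
              x$n, x$n_clusters, x$loglik))
  if (x$separation) cat("  [flagged: possible perfect separation]\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se, z = x$z,
                    p = x$p_value)
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.cluster_fit <- function(object, ...) object$coefficients

#' @export
vcov.cluster_fit <- function(object, ...) object$vcov

# Filter the learner-block table by treatment labels; NULL means no filter.
.filter_learners <- function(lt, design = NULL, information = NULL,
                             concordant = NULL) {
  if (!is.null(design)) lt <- lt[lt$design == design, ]
  if (!is.null(information)) lt <- lt[lt$information == information, ]
  if (!is.null(concordant)) lt <- lt[lt$concordant == concordant, ]
  if (nrow(lt) == 0) stop("no social-learner rows after filtering", call. = FALSE)
  lt
}

#' Treatment regression of left choices on the demonstrator distribution
#'
#' Logistic regression of a social learner choosing the left urn on the
#' learning-block index (1-20) and the centered proportion of demonstrators
#' choosing left in the final trial, `x5 = p5 - 0.5`, with standard errors
#' clustered on social learner.
#'
#' @param table A trial-record data frame (or a [learner_block_table()]).
#' @param design,information,concordant Optional treatment filters.
#' @param ... Passed to [fit_cluster_logit()].
#' @return A `cluster_fit`.
#' @export
#' @examples
#' set.seed(7)
#' tab <- simulate_experiment(experiment_config(n_sessions = 2))
#' fit_choice_model(tab, concordant = TRUE)
fit_choice_model <- function(table, design = NULL, information = NULL,
                             concordant = NULL, ...) {
  lt <- if ("n_left" %in% names(table)) table else learner_block_table(table)
  lt <- .filter_learners(lt, design, information, concordant)
  fit_cluster_logit(chose_left ~ learning_block + x5, lt, ...)
}

#' Treatment regression of optimal choices on demonstrator success
#'
#' Logistic regression of a social learner choosing her own optimal urn on
#' the learning-block index, a dummy for left being the social-learner
#' optimum, a concordance dummy, a dummy for a majority of demonstrators
#' choosing the demonstrator optimum, and the concordance-by-majority
#' interaction; standard errors clustered on social learner. The
#' majority-dummy main effect is the discordant-block effect of demonstrator
#' success; adding the interaction (see [wald_combo()]) gives the concordant
#' -block effect.
#'
#' @param table A trial-record data frame (or a [learner_block_table()]).
#' @param design,information Optional treatment filters.
#' @param ... Passed to [fit_cluster_logit()].
#' @return A `cluster_fit`.
#' @export
fit_optimum_model <- function(table, design = NULL, information = NULL, ...) {
  lt <- if ("n_left" %in% names(table)) table else learner_block_table(table)
  lt <- .filter_learners(lt, design, information)
  fit_cluster_logit(
    chose_optimal ~ learning_block + left_optimal_social + concordant +
      majority_demo_opt + concordant:majority_demo_opt,
    lt, ...
  )
}

#' Wald test of a linear combination of coefficients
#'
#' Tests `H0: w' beta = 0` under the cluster-robust covariance, reported as an
#' F statistic with 1 numerator and `M - 1` denominator degrees of freedom
#' (`M` clusters), or as a chi-squared statistic with 1 df.
#'
#' @param fit A `cluster_fit`.
#' @param weights Numeric weights, either a full-length vector aligned with
#'   the coefficients or a named vector naming a subset of them.
#' @param type `"F"` or `"chisq"`.
#' @return A list with `estimate`, `statistic`, `df`, `p_value`, `type`.
#' @export
#' @examples
#' set.seed(7)
#' tab <- simulate_experiment(experiment_config(n_sessions = 2))
#' fit <- fit_optimum_model(tab)
#' wald_combo(fit, c(majority_demo_optTRUE = 1,
#'                   "concordantTRUE:majority_demo_optTRUE" = 1))
wald_combo <- function(fit, weights, type = c("F", "chisq")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "cluster_fit"))
  b <- fit$coefficients
  w <- numeric(length(b))
  names(w) <- names(b)
  if (!is.null(names(weights))) {
    unknown <- setdiff(names(weights), names(b))
    if (length(unknown) > 0) {
      stop("weights name unknown coefficients: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    w[names(weights)] <- weights
  } else {
    stopifnot(length(weights) == length(b))
    w[] <- weights
  }
  est <- sum(w * b)
  v <- drop(t(w) %*% fit$vcov %*% w)
  if (all(w == 0)) {
    return(list(estimate = 0, statistic = 0,
                df = if (type == "F") c(1, fit$n_clusters - 1) else 1,
                p_value = 1, type = type))
  }
  if (!is.finite(v) || v <= 0) {
    stop("singular covariance for the requested combination", call. = FALSE)
  }
  stat <- est^2 / v
  if (type == "F") {
    df <- c(1, fit$n_clusters - 1)
    p <- stats::pf(stat, df[1], df[2], lower.tail = FALSE)
  } else {
    df <- 1
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  list(estimate = est, statistic = stat, df = df, p_value = p, type = type)
}

#' Classify one social learner's strategy
#'
#' Applies the classification used for disaggregated strategies: a learner who
#' followed the demonstrators' majority in every block is `"Maj"`; one who
#' always followed the minority is `"Min"`; one who always chose the same urn
#' is `"U"` (unconditional); otherwise an intercept-free logistic slope
#' `P(left) = plogis(beta * x5)` is fit by ML and reported with its Wald test.
#' Min/Maj are checked before U, so an unconditional learner who happened to
#' always agree with the majority counts as Maj.
#'
#' @param rows One learner's rows from [learner_block_table()].
#' @param alpha Significance level for flagging the slope.
#' @return A list with `label` (`"Min"`, `"Maj"`, `"U"`, `"slope"`, or
#'   `"undefined"` when the slope cannot be estimated), `beta`, `se`,
#'   `p_value`, `significant`, `n_blocks`.
#' @export
classify_learner <- function(rows, alpha = 0.05) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1,
            all(c("chose_left", "n_left", "n_demo", "x5") %in% names(rows)))
  res <- list(label = NA_character_, beta = NA_real_, se = NA_real_,
              p_value = NA_real_, significant = FALSE, n_blocks = nrow(rows))
  no_tie <- rows$n_left * 2 != rows$n_demo
  maj_left <- rows$n_left * 2 > rows$n_demo
  followed_maj <- rows$chose_left == maj_left
  if (any(no_tie) && all(followed_maj[no_tie])) {
    res$label <- "Maj"
    return(res)
  }
  if (any(no_tie) && all(!followed_maj[no_tie])) {
    res$label <- "Min"
    return(res)
  }
  if (all(rows$chose_left) || all(!rows$chose_left)) {
    res$label <- "U"
    return(res)
  }
  if (length(unique(rows$x5)) < 2) {
    res$label <- "undefined"
    return(res)
  }
  fit <- suppressWarnings(
    stats::glm(chose_left ~ 0 + x5, data = rows, family = stats::binomial())
  )
  sm <- summary(fit)$coefficients
  res$label <- "slope"
  res$beta <- sm["x5", "Estimate"]
  res$se <- sm["x5", "Std. Error"]
  res$p_value <- sm["x5", "Pr(>|z|)"]
  res$significant <- is.finite(res$p_value) && res$p_value < alpha
  res
}

#' Classify every social learner in a table
#'
#' @param table A trial-record data frame (or a [learner_block_table()]).
#' @param design,information Optional treatment filters.
#' @param alpha Significance level for the slope flag.
#' @return A data frame with one row per social learner: `subject`,
#'   `information`, `design`, `label`, `beta`, `se`, `p_value`,
#'   `significant`, `n_blocks`.
#' @export
classify_learners <- function(table, design = NULL, information = NULL,
                              alpha = 0.05) {
  lt <- if ("n_left" %in% names(table)) table else learner_block_table(table)
  lt <- .filter_learners(lt, design, information)
  subjects <- unique(lt$subject)
  rows <- lapply(subjects, function(s) {
    sub <- lt[lt$subject == s, ]
    cls <- classify_learner(sub, alpha = alpha)
    data.frame(subject = s, information = sub$information[1],
               design = sub$design[1], label = cls$label, beta = cls$beta,
               se = cls$se, p_value = cls$p_value,
               significant = cls$significant, n_blocks = cls$n_blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster-bootstrap learning curve
#'
#' Rates of choosing left by number of demonstrators choosing left, with
#' percentile confidence intervals from resampling social learners (clusters)
#' with replacement. Percentile intervals are guaranteed to stay in `[0, 1]`.
#' Counts never observed in the data are omitted, not imputed.
#'
#' @param table A trial-record data frame (or a [learner_block_table()]).
#' @param design,information,concordant Optional treatment filters.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param outcome Column to average: `"chose_left"` (learning curve) or
#'   `"chose_optimal"`.
#' @return A data frame of class `boot_curve`: `n_left`, `n_obs`, `rate`,
#'   `lower`, `upper`.
#' @export
#' @examples
#' set.seed(7)
#' tab <- simulate_experiment(experiment_config())
#' bootstrap_curve(tab, concordant = TRUE, n_boot = 200)
bootstrap_curve <- function(table, design = NULL, information = NULL,
                            concordant = NULL, n_boot = 2000, conf = 0.95,
                            outcome = "chose_left") {
  lt <- if ("n_left" %in% names(table)) table else learner_block_table(table)
  lt <- .filter_learners(lt, design, information, concordant)
  stopifnot(outcome %in% names(lt), n_boot >= 1)
  ks <- sort(unique(lt$n_left))
  subjects <- unique(lt$subject)
  m <- length(subjects)
  # per-learner, per-count sufficient statistics
  cnt <- matrix(0, nrow = m, ncol = length(ks),
                dimnames = list(subjects, ks))
  pos <- cnt
  for (j in seq_along(ks)) {
    sub <- lt[lt$n_left == ks[j], ]
    tc <- table(factor(sub$subject, levels = subjects))
    tp <- tapply(sub[[outcome]], factor(sub$subject, levels = subjects), sum)
    cnt[, j] <- as.numeric(tc)
    pos[, j] <- ifelse(is.na(tp), 0, tp)
  }
  rate <- colSums(pos) / colSums(cnt)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(ks))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(m, m, replace = TRUE)
    nb <- colSums(cnt[idx, , drop = FALSE])
    boot[b, ] <- ifelse(nb > 0, colSums(pos[idx, , drop = FALSE]) / nb, NA)
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  ci <- apply(boot, 2, stats::quantile, probs = probs, na.rm = TRUE)
  out <- data.frame(n_left = ks, n_obs = as.integer(colSums(cnt)),
                    rate = rate, lower = ci[1, ], upper = ci[2, ])
  rownames(out) <- NULL
  structure(out, conf = conf, n_boot = n_boot, outcome = outcome,
            class = c("boot_curve", "data.frame"))
}

# Capture a model-fitting error as a result object instead of aborting the
# whole analysis bundle (e.g. a treatment subset where a dummy never varies).
.try_fit <- function(expr) {
  tryCatch(expr, error = function(e) {
    structure(list(error = conditionMessage(e)), class = "failed_fit")
  })
}

#' @export
print.failed_fit <- function(x, ...) {
  cat("Model could not be fit:", x$error, "\n")
  invisible(x)
}

#' Full analysis of a trial-record table
#'
#' Runs the whole pipeline on one table: demonstrator optimality, the
#' left-choice regressions per treatment cell, the optimal-choice regressions
#' with the Wald linear combinations, per-learner classification, and
#' cluster-bootstrap curves.
#'
#' @param table A validated trial-record data frame.
#' @param n_boot Bootstrap resamples for the curves.
#' @return A list with elements `demonstrator`, `choice_models`,
#'   `optimum_models`, `wald_majority_concordant` (the "majority effect in
#'   concordant blocks" combination per optimum model), `learner_types`, and
#'   `curves`.
#' @export
analyze_experiment <- function(table, n_boot = 500) {
  validate_trial_records(table, n_blocks = NULL)
  lt <- learner_block_table(table)

  cells <- unique(lt[c("design", "information", "concordant")])
  transparent <- cells$information == "transparent"
  choice_models <- list()
  curves <- list()
  for (r in seq_len(nrow(cells))) {
    d <- cells$design[r]; inf <- cells$information[r]; cc <- cells$concordant[r]
    if (inf == "transparent") {
      nm <- sprintf("%s_%s", d, if (cc) "concordant" else "discordant")
      choice_models[[nm]] <- fit_choice_model(lt, design = d, information = inf,
                                              concordant = cc)
      curves[[nm]] <- bootstrap_curve(lt, design = d, information = inf,
                                      concordant = cc, n_boot = n_boot)
    }
  }
  # opaque treatments are analyzed pooled over (hidden) concordance
  for (inf in intersect(unique(lt$information),
                        c("opaque_prior", "opaque_noprior"))) {
    choice_models[[inf]] <- fit_choice_model(lt, information = inf)
    curves[[inf]] <- bootstrap_curve(lt, information = inf, n_boot = n_boot)
  }

  optimum_models <- list()
  wald <- list()
  combos <- c(majority_demo_optTRUE = 1,
              "concordantTRUE:majority_demo_optTRUE" = 1)
  if (any(transparent)) {
    for (d in unique(cells$design[transparent])) {
      fit <- .try_fit(fit_optimum_model(lt, design = d,
                                        information = "transparent"))
      optimum_models[[d]] <- fit
      wald[[d]] <- if (inherits(fit, "cluster_fit")) wald_combo(fit, combos)
    }
  }
  for (inf in intersect(unique(lt$information),
                        c("opaque_prior", "opaque_noprior"))) {
    fit <- .try_fit(fit_optimum_model(lt, information = inf))
    optimum_models[[inf]] <- fit
    wald[[inf]] <- if (inherits(fit, "cluster_fit")) wald_combo(fit, combos)
  }

  list(
    demonstrator = demonstrator_optimal_rate(table),
    choice_models = choice_models,
    optimum_models = optimum_models,
    wald_majority_concordant = wald,
    learner_types = classify_learners(lt),
    curves = curves
  )
}

#' Reproduce the published summary statistics from a deposited raw-data file
#'
#' Reads a deposited raw-data file through a [raw_dialect()], splits it into
#' the transparent (experiment 1) and opaque (experiment 2) treatments, and
#' recomputes the published quantities: demonstrator majority-optimality
#' rates, the left-choice slopes per treatment cell, the majority-dummy
#' coefficients from the optimal-choice models, the Wald F for the majority
#' effect in concordant blocks, and the counts of Maj/Min classified learners
#' in the opaque treatments.
#'
#' @param path Path to the raw data file.
#' @param dialect A [raw_dialect()] describing its layout.
#' @return A list with elements `exp1` and `exp2`, each containing the
#'   corresponding rates, fits, Wald tests, and type counts.
#' @export
reproduce_deposited_results <- function(path, dialect = raw_dialect()) {
  tab <- read_trial_records(path, dialect, n_blocks = NULL)
  lt <- learner_block_table(tab)
  out <- list()

  exp1 <- tab[tab$information == "transparent", ]
  if (nrow(exp1) > 0) {
    lt1 <- lt[lt$information == "transparent", ]
    slopes <- list()
    for (d in unique(lt1$design)) {
      for (cc in c(FALSE, TRUE)) {
        nm <- sprintf("%s_%s", d, if (cc) "concordant" else "discordant")
        slopes[[nm]] <- fit_choice_model(lt1, design = d, concordant = cc)
      }
    }
    opt <- lapply(stats::setNames(nm = unique(lt1$design)), function(d) {
      .try_fit(fit_optimum_model(lt1, design = d))
    })
    out$exp1 <- list(
      demonstrator = demonstrator_optimal_rate(exp1),
      choice_models = slopes,
      optimum_models = opt,
      wald = lapply(opt, function(f) {
        if (inherits(f, "cluster_fit")) {
          wald_combo(f, c(majority_demo_optTRUE = 1,
                          "concordantTRUE:majority_demo_optTRUE" = 1))
        }
      })
    )
  }

  exp2 <- tab[tab$information %in% c("opaque_prior", "opaque_noprior"), ]
  if (nrow(exp2) > 0) {
    lt2 <- lt[lt$information %in% c("opaque_prior", "opaque_noprior"), ]
    infs <- unique(lt2$information)
    out$exp2 <- list(
      demonstrator = demonstrator_optimal_rate(exp2),
      choice_models = lapply(stats::setNames(nm = infs), function(inf) {
        fit_choice_model(lt2, information = inf)
      }),
      optimum_models = lapply(stats::setNames(nm = infs), function(inf) {
        .try_fit(fit_optimum_model(lt2, information = inf))
      }),
      learner_types = lapply(stats::setNames(nm = infs), function(inf) {
        types <- classify_learners(lt2, information = inf)
        list(types = types, n_maj = sum(types$label == "Maj"),
             n_min = sum(types$label == "Min"))
      })
    )
  }
  out
}
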