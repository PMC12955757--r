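#' Parameter recovery for one model
#'
#' Simulates `n_datasets` single-subject datasets with parameters drawn from
#' the generator ranges and per-subject observation noise, refits the same
#' model by MAP, and reports the Pearson correlation between generating and
#' recovered values for every parameter. Recovered `sigma` is correlated
#' against the generating `obs_noise_sd`.
#'
#' @param model_id Generating (and fitted) model id, 1 to 5.
#' @param n_datasets Number of simulated datasets (>= 2; one subject each).
#' @param design A [task_design()].
#' @param theta_dist Named list of sampling ranges; defaults to
#'   [default_theta_ranges()].
#' @param obs_noise_sd Observation-noise value or range (default
#'   `c(0.3, 1.0)`, drawn per subject).
#' @param n_restarts Optimizer restarts per fit (default 10).
#' @param seed RNG seed.
#' @return An object of class `recovery_report`: list with `correlations`
#'   (tibble `term`, `r`, `n`), `draws` (tibble of true/recovered pairs),
#'   `model_id`, `n_datasets`, `theta_dist`.
#' @export
parameter_recovery <- function(model_id, n_datasets, design,
                               theta_dist = default_theta_ranges(model_id),
                               obs_noise_sd = c(0.3, 1.0),
                               n_restarts = 10, seed = 1) {
  if (n_datasets < 2) stop_invalid("`n_datasets` must be >= 2")
  set.seed(seed)
  par_names <- names(theta_dist)

  rows <- purrr::map(seq_len(n_datasets), function(j) {
    theta <- draw_theta(theta_dist)
    noise <- if (length(obs_noise_sd) == 2)
      runif(1, obs_noise_sd[1], obs_noise_sd[2]) else obs_noise_sd
    trials <- simulate_subject(design, model_id, theta, noise,
                               subject_id = j)
    fit <- fit_subject(trials, model_id, design, n_restarts = n_restarts)
    truth <- c(unlist(theta), sigma = noise)
    est <- fit$theta_map[names(truth)]
    tibble(dataset = j, term = names(truth),
           true = as.numeric(truth), recovered = as.numeric(est),
           converged = fit$converged)
  })
  draws <- purrr::list_rbind(rows)

  correlations <- draws |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      r = if (sd(.data$true) < 1e-12 || sd(.data$recovered) < 1e-12)
        NA_real_ else cor(.data$true, .data$recovered),
      n = dplyr::n(), .groups = "drop"
    )

  structure(
    list(correlations = correlations, draws = draws,
         model_id = as.integer(model_id), n_datasets = n_datasets,
         theta_dist = theta_dist),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> model %d (%s), %d datasets\n",
              x$model_id, model_label(x$model_id), x$n_datasets))
  print(as.data.frame(x$correlations), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
tidy.recovery_report <- function(x, ...) x$correlations

#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(title = sprintf("Parameter recovery, model %d",
                                  object$model_id),
                  x = "generating value", y = "recovered value") +
    ggplot2::theme_minimal()
}

#' Model-recovery confusion matrix
#'
#' For each generating model, simulates cohorts, runs the full hierarchical
#' comparison over all candidate models, and tallies which model attains the
#' highest protected exceedance probability. Exact PXP ties split the tally
#' equally among the tied models.
#'
#' @param design A [task_design()].
#' @param models Candidate (and generating) model ids (default `1:5`).
#' @param n_cohorts_per_model Cohorts simulated per generating model.
#' @param n_subjects Subjects per cohort.
#' @param obs_noise_sd Observation-noise value or range.
#' @param n_restarts Optimizer restarts for the first HBI pass.
#' @param xp_samples Monte-Carlo draws for exceedance probabilities.
#' @param seed RNG seed.
#' @return Object of class `confusion_matrix`: list with `matrix` (rows =
#'   generating model, columns = selected model, rows sum to 1), `n_cohorts`,
#'   `models`.
#' @export
model_recovery <- function(design, models = 1:5, n_cohorts_per_model = 10,
                           n_subjects = 20, obs_noise_sd = c(0.3, 1.0),
                           n_restarts = 10, xp_samples = 1e5, seed = 1) {
  if (n_cohorts_per_model < 1 || n_subjects < 2)
    stop_invalid("need >= 1 cohort and >= 2 subjects")
  K <- length(models)
  cm <- matrix(0, K, K, dimnames = list(paste0("gen_", models),
                                        paste0("sel_", models)))
  for (gi in seq_len(K)) {
    for (ci in seq_len(n_cohorts_per_model)) {
      cohort_seed <- seed + 1000L * gi + ci
      cs <- simulate_cohort(
        design,
        generator_config(n_subjects, model_id = models[gi],
                         seed = cohort_seed, obs_noise_sd = obs_noise_sd)
      )
      fit <- hbi_fit(cs$trials, design, models = models,
                     n_restarts = n_restarts, seed = cohort_seed,
                     xp_samples = xp_samples)
      win <- which(fit$pxp == max(fit$pxp))
      cm[gi, win] <- cm[gi, win] + 1 / length(win)
    }
  }
  structure(
    list(matrix = cm / n_cohorts_per_model,
         n_cohorts = n_cohorts_per_model, n_subjects = n_subjects,
         models = as.integer(models)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d cohorts x %d subjects per generating model\n",
              x$n_cohorts, x$n_subjects))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$matrix, responseName = "fraction")) |>
    dplyr::rename(generating = "Var1", selected = "Var2")
}

#' @export
autoplot.confusion_matrix <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$selected, y = .data$generating,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$fraction)),
                       colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = "Model recovery (fraction of cohorts, by PXP)") +
    ggplot2::theme_minimal()
}

#' Group-level posterior predictive check
#'
#' Draws parameter vectors from the fitted hierarchical Gaussian of the
#' winning model (unconstrained space, then transformed), simulates a full
#' cohort-mean rating trajectory per draw using each subject's own initial
#' beliefs, presentation order and feedback, and compares the 95% band of the
#' simulated per-position means against the empirical mean trajectory.
#'
#' @param data Cohort tibble (schema as in [hbi_fit()]).
#' @param fit An [hbi_fit()] result on the same cohort.
#' @param design A [task_design()].
#' @param model_id Model to simulate from (default: PXP winner).
#' @param n_draws Number of posterior draws (>= 100, default 200).
#' @param seed RNG seed.
#' @return Object of class `ppc_result`: list with `trajectory` (tibble:
#'   `position`, `empirical`, `predicted`, `lower`, `upper`, `covered`),
#'   `coverage` (fraction of positions covered), `model_id`, `n_draws`.
#' @export
posterior_predictive <- function(data, fit, design, model_id = NULL,
                                 n_draws = 200, seed = 1) {
  stopifnot(inherits(fit, "hbi_fit"))
  if (n_draws < 100) stop_invalid("`n_draws` must be >= 100")
  set.seed(seed)
  if (is.null(model_id)) model_id <- best_model(fit)[1]
  k <- match(model_id, fit$models)
  if (is.na(k)) stop_invalid("model %d was not among the candidates", model_id)
  space <- fit$spaces[[k]]
  mu <- fit$group_mu[[k]]
  sdv <- sqrt(fit$group_var[[k]])
  d <- length(mu)

  # canonical subject order: draws (and so coverage flags) depend only on
  # the set of subjects, not on row order
  subj_ids <- sort(unique(data$subject_id))
  subjects <- lapply(subj_ids, function(s)
    as_subject(data[data$subject_id == s, ], design))
  n_pos <- design$n_items

  sim_means <- matrix(NA_real_, n_draws, n_pos)
  for (b in seq_len(n_draws)) {
    acc <- matrix(NA_real_, length(subjects), n_pos)
    for (i in seq_along(subjects)) {
      x <- rnorm(d, mu, sdv)
      theta <- as.list(to_constrained(x, space))
      tr <- run_trial_loop(model_id, theta, subjects[[i]]$order,
                           subjects[[i]]$ib,
                           feedback = subjects[[i]]$feedback,
                           design = design)
      noisy <- tr$prediction + rnorm(n_pos, 0, theta$sigma)
      acc[i, ] <- clip(round_half_away(noisy),
                       design$scale_min, design$scale_max)
    }
    sim_means[b, ] <- colMeans(acc)
  }

  emp <- data |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(empirical = mean(.data$rating), .groups = "drop") |>
    dplyr::arrange(.data$position)

  trajectory <- tibble(
    position = seq_len(n_pos),
    empirical = emp$empirical,
    predicted = colMeans(sim_means),
    lower = apply(sim_means, 2, quantile, 0.025),
    upper = apply(sim_means, 2, quantile, 0.975)
  )
  trajectory$covered <- trajectory$empirical >= trajectory$lower &
    trajectory$empirical <= trajectory$upper

  structure(
    list(trajectory = trajectory, coverage = mean(trajectory$covered),
         model_id = as.integer(model_id), n_draws = n_draws),
    class = "ppc_result"
  )
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("<ppc_result> model %d, %d draws: %.0f%% of positions inside the 95%% band\n",
              x$model_id, x$n_draws, 100 * x$coverage))
  invisible(x)
}

#' @export
tidy.ppc_result <- function(x, ...) x$trajectory

#' @export
autoplot.ppc_result <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$empirical)) +
    ggplot2::labs(title = "Posterior predictive check",
                  y = "mean rating", x = "presentation position") +
    ggplot2::theme_minimal()
}

#' Trend of behavioral prediction errors across the task
#'
#' Model-free check for learning: the behavioral prediction error on each
#' trial is feedback minus the participant's own rating; a systematic decline
#' of its absolute mean over presentation positions indicates iterative
#' belief updating. Reports the least-squares slope of mean |PE| on position
#' and a permutation p-value obtained by shuffling positions within each
#' subject.
#'
#' @param data Cohort tibble with columns `subject_id`, `position`, `rating`,
#'   `feedback`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return Object of class `pe_trend`: list with `slope`, `p_value`
#'   (two-sided), `p_decline` (one-sided, H1: slope < 0), `by_position`
#'   (tibble `position`, `mean_abs_pe`), `n_perm`.
#' @export
pe_trend <- function(data, n_perm = 1000, seed = 1) {
  pos <- sort(unique(data$position))
  if (length(pos) < 2) stop_invalid("need at least 2 positions")
  set.seed(seed)

  abs_pe <- abs(data$feedback - data$rating)
  m <- tapply(abs_pe, list(data$subject_id, data$position), mean)
  m <- m[, order(as.numeric(colnames(m))), drop = FALSE]

  slope_of <- function(colmeans, x) {
    xc <- x - mean(x)
    sum(xc * (colmeans - mean(colmeans))) / sum(xc^2)
  }
  x <- as.numeric(colnames(m))
  obs <- slope_of(colMeans(m), x)

  perm <- vapply(seq_len(n_perm), function(b) {
    shuffled <- t(apply(m, 1, sample))
    slope_of(colMeans(shuffled), x)
  }, numeric(1))

  structure(
    list(slope = obs,
         p_value = (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1),
         p_decline = (1 + sum(perm <= obs)) / (n_perm + 1),
         by_position = tibble(position = x,
                              mean_abs_pe = unname(colMeans(m))),
         n_perm = n_perm),
    class = "pe_trend"
  )
}

#' @export
print.pe_trend <- function(x, ...) {
  cat(sprintf("<pe_trend> slope of mean |PE| per position: %.4f (two-sided p = %.3g, decline p = %.3g)\n",
              x$slope, x$p_value, x$p_decline))
  invisible(x)
}

#' @export
tidy.pe_trend <- function(x, ...) x$by_position

#' @export
glance.pe_trend <- function(x, ...) {
  tibble(slope = x$slope, p_value = x$p_value, p_decline = x$p_decline,
         n_perm = x$n_perm)
}

#' @export
autoplot.pe_trend <- function(object, ...) {
  ggplot2::ggplot(object$by_position,
                  ggplot2::aes(x = .data$position, y = .data$mean_abs_pe)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(title = "Mean |prediction error| by presentation position",
                  x = "position", y = "mean |PE|") +
    ggplot2::theme_minimal()
}
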