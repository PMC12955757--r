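#' Default parameter-sampling ranges for cohort simulation
#'
#' Uniform sampling ranges per parameter, used when simulating cohorts and in
#' the recovery analyses. Learning rates and the anchoring weight span almost
#' the full unit interval; the first-statement expectation spans most of the
#' rating scale; the no-learning regression coefficients cover regressions
#' from strong shrinkage to identity.
#'
#' @param model_id Integer model id, 1 to 5.
#' @return Named list of length-2 numeric ranges, one per free parameter
#'   (excluding `sigma`, whose simulation analogue is `obs_noise_sd`).
#' @export
default_theta_ranges <- function(model_id) {
  all <- list(
    beta0 = c(0, 2), beta1 = c(0.2, 1.0),
    alpha = c(0.05, 0.95), alpha_pos = c(0.05, 0.95),
    alpha_neg = c(0.05, 0.95), gamma = c(0.05, 0.95),
    e1 = c(1.5, 6.5)
  )
  all[setdiff(model_parameters(model_id), "sigma")]
}

#' Cohort-generator configuration
#'
#' Bundles everything needed to simulate a cohort of participants from one of
#' the five models: cohort size, generating model, per-parameter sampling
#' ranges, observation noise, latent-factor settings for the similarity
#' matrix, and a mandatory seed.
#'
#' @param n_subjects Number of simulated participants (>= 0).
#' @param model_id Generating model id, 1 to 5.
#' @param seed RNG seed (mandatory; every simulation is reproducible).
#' @param theta_dist Named list of length-2 ranges per parameter; defaults to
#'   [default_theta_ranges()] for `model_id`.
#' @param obs_noise_sd Observation noise SD in rating units: either a single
#'   positive value applied to every subject, or a length-2 range from which
#'   each subject's noise SD is drawn uniformly (default `c(0.3, 1.0)`).
#' @param n_factors,loading_range Latent-factor settings for
#'   [make_similarity()] when a design is generated from this config.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects, model_id, seed,
                             theta_dist = NULL,
                             obs_noise_sd = c(0.3, 1.0),
                             n_factors = 1, loading_range = c(0.4, 0.8)) {
  if (n_subjects < 0) stop_invalid("`n_subjects` must be >= 0")
  if (!model_id %in% 1:5) stop_invalid("`model_id` must be in 1..5")
  if (missing(seed) || is.null(seed)) stop_invalid("`seed` is mandatory")
  if (any(obs_noise_sd <= 0)) stop_invalid("`obs_noise_sd` must be > 0")
  if (!length(obs_noise_sd) %in% 1:2)
    stop_invalid("`obs_noise_sd` must be a value or a range")
  defaults <- default_theta_ranges(model_id)
  if (is.null(theta_dist)) {
    theta_dist <- defaults
  } else {
    unknown <- setdiff(names(theta_dist), names(defaults))
    if (length(unknown))
      stop_invalid("unknown parameters in `theta_dist`: %s",
                   paste(unknown, collapse = ", "))
    theta_dist <- utils::modifyList(defaults, theta_dist)
    bounds <- list(alpha = c(0, 1), alpha_pos = c(0, 1), alpha_neg = c(0, 1),
                   gamma = c(0, 1), e1 = c(1, 7))
    for (p in names(theta_dist)) {
      r <- theta_dist[[p]]
      if (length(r) != 2 || r[1] > r[2])
        stop_invalid("range for `%s` must be increasing", p)
      if (!is.null(bounds[[p]]) &&
          (r[1] < bounds[[p]][1] || r[2] > bounds[[p]][2]))
        stop_invalid("range for `%s` must lie inside [%g, %g]",
                     p, bounds[[p]][1], bounds[[p]][2])
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), model_id = as.integer(model_id),
         theta_dist = theta_dist, obs_noise_sd = obs_noise_sd,
         n_factors = n_factors, loading_range = loading_range,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

draw_theta <- function(theta_dist) {
  lapply(theta_dist, function(r) runif(1, r[1], r[2]))
}

# initial beliefs: discretized Gaussian centered on the scale midpoint,
# matching the heterogeneity of a general-population sample
draw_ib <- function(n_items, scale_min = 1, scale_max = 7,
                    mean = 4.0, sd = 1.0) {
  as.integer(clip(round_half_away(rnorm(n_items, mean, sd)),
                  scale_min, scale_max))
}

#' Simulate one participant under a given model
#'
#' Draws initial beliefs (discretized Gaussian, mean 4, SD 1, clipped to the
#' scale) and a random presentation order, runs the model's trial loop
#' against the design's normative feedback, and converts noiseless
#' predictions into integer Block-2 ratings by adding Gaussian observation
#' noise, rounding half away from zero, and clipping to the scale.
#'
#' @param design A [task_design()].
#' @param model_id Generating model id, 1 to 5.
#' @param theta Named list of constrained parameters (see
#'   [model_parameters()]; `sigma` not needed).
#' @param obs_noise_sd Observation noise SD (> 0) in rating units.
#' @param seed Optional RNG seed.
#' @param subject_id Identifier stored in the output (default 1).
#' @param ib,order Optional overrides for the initial beliefs (per item) and
#'   presentation order.
#' @param sum_bounds Propagation-sum convention, see [run_trial_loop()].
#' @return A tibble with one row per trial: `subject_id`, `item_id`,
#'   `position`, `ib`, `rating`, `feedback`, plus the noiseless model
#'   `prediction`.
#' @export
simulate_subject <- function(design, model_id, theta, obs_noise_sd,
                             seed = NULL, subject_id = 1L,
                             ib = NULL, order = NULL,
                             sum_bounds = "full") {
  if (obs_noise_sd <= 0) stop_invalid("`obs_noise_sd` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_items
  if (is.null(ib)) ib <- draw_ib(n, design$scale_min, design$scale_max)
  if (is.null(order)) order <- sample.int(n)
  check_order(order, n)

  tr <- run_trial_loop(model_id, theta, order, ib,
                       feedback = design$feedback[order],
                       design = design, sum_bounds = sum_bounds)
  rating <- as.integer(clip(
    round_half_away(tr$prediction + rnorm(n, 0, obs_noise_sd)),
    design$scale_min, design$scale_max
  ))
  tibble(
    subject_id = subject_id,
    item_id = tr$item_id,
    position = tr$position,
    ib = as.integer(ib[order]),
    rating = rating,
    feedback = design$feedback[order],
    prediction = tr$prediction
  )
}

#' Simulate a cohort of participants
#'
#' Simulates `config$n_subjects` independent participants from
#' `config$model_id`, with per-subject parameters drawn uniformly from
#' `config$theta_dist` and per-subject observation noise drawn from
#' `config$obs_noise_sd`. Presentation order is randomized per participant.
#'
#' @param design A [task_design()].
#' @param config A [generator_config()].
#' @return A list of class `cohort_sim` with elements `trials` (tibble, one
#'   row per subject x trial, schema as [simulate_subject()]) and `params`
#'   (tibble of generating parameters: `subject_id`, one column per model
#'   parameter, and `obs_noise_sd`).
#' @examples
#' d <- default_design(n_items = 6, seed = 1)
#' cs <- simulate_cohort(d, generator_config(3, model_id = 4, seed = 7))
#' cs$params
#' @export
simulate_cohort <- function(design, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  par_names <- names(config$theta_dist)

  if (config$n_subjects == 0) {
    trials <- simulate_subject(design, config$model_id,
                               lapply(config$theta_dist, mean),
                               obs_noise_sd = 0.5)[0, ]
    params <- tibble(subject_id = integer())
    for (p in par_names) params[[p]] <- numeric()
    params$obs_noise_sd <- numeric()
    return(structure(list(trials = trials, params = params,
                          model_id = config$model_id),
                     class = "cohort_sim"))
  }

  sims <- purrr::map(seq_len(config$n_subjects), function(s) {
    theta <- draw_theta(config$theta_dist)
    noise <- if (length(config$obs_noise_sd) == 2) {
      runif(1, config$obs_noise_sd[1], config$obs_noise_sd[2])
    } else {
      config$obs_noise_sd
    }
    trials <- simulate_subject(design, config$model_id, theta, noise,
                               subject_id = s)
    list(trials = trials,
         params = tibble(subject_id = s, !!!theta, obs_noise_sd = noise))
  })
  structure(
    list(trials = purrr::list_rbind(purrr::map(sims, "trials")),
         params = purrr::list_rbind(purrr::map(sims, "params")),
         model_id = config$model_id),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d subjects x %d trials, generating model %d (%s)\n",
              nrow(x$params), max(x$trials$position, 0), x$model_id,
              model_label(x$model_id)))
  invisible(x)
}
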