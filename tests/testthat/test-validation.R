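test_that("noiseless regression parameters recover almost perfectly", {
  # continuous ratings isolate the noiseless limit from Likert rounding
  d <- default_design(seed = 51)
  set.seed(52)
  pairs <- lapply(1:25, function(j) {
    theta <- list(beta0 = runif(1, 0, 2), beta1 = runif(1, 0.2, 1))
    ib <- beliefupdatr:::draw_ib(20)
    ord <- sample(20)
    ib_pos <- ib[ord]
    s <- tibble::tibble(
      subject_id = j, item_id = ord, position = 1:20, ib = ib_pos,
      rating = theta$beta0 + theta$beta1 * ib_pos + rnorm(20, 0, 1e-4),
      feedback = d$feedback[ord])
    f <- fit_subject(s, 1, d, n_restarts = 5)
    c(theta$beta0, theta$beta1, f$theta_map["beta0"], f$theta_map["beta1"])
  })
  m <- do.call(rbind, pairs)
  expect_gt(cor(m[, 1], m[, 3]), 0.999)
  expect_gt(cor(m[, 2], m[, 4]), 0.999)

  # the full generator pipeline (integer ratings) stays strongly recoverable
  rec <- parameter_recovery(1, 30, d, obs_noise_sd = 1e-4, n_restarts = 5,
                            seed = 52)
  r <- rec$correlations
  expect_gt(r$r[r$term == "beta1"], 0.8)
  expect_equal(unique(rec$draws$dataset), 1:30)
  expect_error(parameter_recovery(1, 1, d),
               class = "beliefupdatr_invalid_argument")
})

test_that("pure-noise data yield near-zero recovery correlations", {
  d <- default_design(seed = 53)
  set.seed(54)
  rows <- lapply(1:50, function(j) {
    theta <- list(beta0 = runif(1, 0, 2), beta1 = runif(1, 0.2, 1))
    s <- simulate_subject(d, 1, theta, obs_noise_sd = 0.5, subject_id = j)
    s$rating <- sample(1:7, 20, replace = TRUE) # sever the link to theta
    f <- fit_subject(s, 1, d, n_restarts = 5)
    c(theta$beta0, theta$beta1, f$theta_map["beta0"], f$theta_map["beta1"])
  })
  m <- do.call(rbind, rows)
  expect_lt(abs(cor(m[, 1], m[, 3])), 0.35)
  expect_lt(abs(cor(m[, 2], m[, 4])), 0.35)
})

test_that("recovery correlations are invariant to dataset order", {
  d <- toy_design(8)
  rec <- parameter_recovery(2, 20, d, n_restarts = 4, seed = 55)
  shuffled <- rec$draws[sample(nrow(rec$draws)), ]
  by_term <- dplyr::group_by(shuffled, term)
  r2 <- dplyr::summarise(by_term, r = cor(true, recovered))
  expect_equal(sort(r2$r), sort(rec$correlations$r), tolerance = 1e-12)
})

test_that("degenerate generating ranges give an undefined-marker correlation", {
  d <- toy_design(8)
  rec <- parameter_recovery(2, 10, d,
                            theta_dist = list(alpha = c(0.4, 0.4),
                                              e1 = c(3, 3)),
                            obs_noise_sd = 0.5, n_restarts = 3, seed = 56)
  r <- rec$correlations
  expect_true(is.na(r$r[r$term == "alpha"]))
  expect_true(is.na(r$r[r$term == "e1"]))
})

test_that("a single-candidate confusion matrix is the 1x1 identity", {
  d <- toy_design(8)
  mr <- model_recovery(d, models = 4, n_cohorts_per_model = 1,
                       n_subjects = 6, n_restarts = 4, xp_samples = 1e4,
                       seed = 57)
  expect_equal(unname(mr$matrix), matrix(1, 1, 1))
  expect_equal(rowSums(mr$matrix), c(gen_4 = 1))
})

test_that("posterior predictive covers a self-consistent cohort", {
  d <- default_design(seed = 58)
  cfg <- generator_config(15, model_id = 4, seed = 59,
                          theta_dist = list(alpha = c(0.1, 0.5),
                                            gamma = c(0.4, 0.8)))
  cs <- simulate_cohort(d, cfg)
  fit <- hbi_fit(cs$trials, d, models = c(2, 4), seed = 60,
                 xp_samples = 2e4)
  ppc <- posterior_predictive(cs$trials, fit, d, n_draws = 150, seed = 61)
  expect_gte(ppc$coverage, 0.9)
  expect_equal(nrow(ppc$trajectory), 20)
  expect_true(all(ppc$trajectory$lower <= ppc$trajectory$upper))

  # coverage flags are invariant to subject ordering
  shuffled <- dplyr::arrange(cs$trials, dplyr::desc(subject_id), position)
  ppc2 <- posterior_predictive(shuffled, fit, d, n_draws = 150, seed = 61)
  expect_equal(ppc2$trajectory$covered, ppc$trajectory$covered)
  expect_error(posterior_predictive(cs$trials, fit, d, n_draws = 10),
               class = "beliefupdatr_invalid_argument")
})

test_that("a degenerate hierarchy yields a collapsed predictive band", {
  d <- toy_design(8)
  sp <- param_space(4)
  # alpha = 0 and gamma = 0.4 keep predictions away from .5 rounding
  # boundaries, so the degenerate band collapses exactly
  x <- to_unconstrained(list(alpha = 1e-12, e1 = 5, gamma = 0.4,
                             sigma = 1e-6), sp)
  fake <- structure(
    list(models = 4L, spaces = list(sp),
         group_mu = list(as.numeric(x)),
         group_var = list(rep(1e-18, 4)),
         pxp = 1),
    class = "hbi_fit"
  )
  cs <- simulate_cohort(d, generator_config(5, model_id = 4, seed = 62))
  ppc <- posterior_predictive(cs$trials, fake, d, model_id = 4,
                              n_draws = 120, seed = 63)
  expect_equal(ppc$trajectory$upper, ppc$trajectory$lower, tolerance = 1e-9)
})

test_that("ratings equal to feedback give a flat zero PE profile", {
  d <- toy_design(8, feedback = rep(4, 8))
  cs <- simulate_cohort(d, generator_config(10, model_id = 1, seed = 64))
  flat <- cs$trials
  flat$rating <- flat$feedback
  tr <- pe_trend(flat, n_perm = 100, seed = 65)
  expect_equal(tr$slope, 0)
  expect_equal(tr$by_position$mean_abs_pe, rep(0, 8))
})

test_that("learning cohorts decline and no-learning cohorts do not", {
  d <- default_design(seed = 66)
  learn <- simulate_cohort(d, generator_config(
    100, model_id = 4, seed = 67,
    theta_dist = list(alpha = c(0.4, 0.4), gamma = c(0.2, 0.2))))
  tr <- pe_trend(learn$trials, n_perm = 500, seed = 68)
  expect_lt(tr$slope, 0)
  expect_lt(tr$p_decline, 0.05)

  none <- simulate_cohort(d, generator_config(100, model_id = 1, seed = 69))
  tr0 <- pe_trend(none$trials, n_perm = 500, seed = 70)
  expect_gt(tr0$p_value, 0.05)
})
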