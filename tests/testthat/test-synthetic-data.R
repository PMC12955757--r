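test_that("similarity from pure-noise loadings is near zero off the diagonal", {
  s <- make_similarity(2, loading_range = c(0, 0), n_respondents = 2000,
                       seed = 1)
  expect_equal(diag(s), c(1, 1))
  expect_lt(abs(s[1, 2]), 0.1) # sampling error of r at n = 2000 is ~0.02
})

test_that("unit loadings with zero uniqueness give perfect correlations", {
  s <- make_similarity(3, loading_range = c(1, 1), seed = 2)
  expect_equal(s, matrix(1, 3, 3))
})

test_that("similarity equals a hand-rolled Pearson r on the same response table", {
  n_items <- 20; n_resp <- 510; seed <- 7
  s <- make_similarity(n_items, n_factors = 1, loading_range = c(0.4, 0.8),
                       n_respondents = n_resp, seed = seed)
  # rebuild the simulated response table from the same seeded draws
  set.seed(seed)
  lambda <- runif(n_items, 0.4, 0.8)
  f <- matrix(rnorm(n_resp), n_resp, 1)
  eps <- matrix(rnorm(n_resp * n_items), n_resp, n_items)
  y <- f[, rep(1, n_items)] * rep(lambda, each = n_resp) +
    eps * rep(sqrt(1 - lambda^2), each = n_resp)
  pearson <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  manual <- sapply(1:n_items, function(i)
    sapply(1:n_items, function(j) pearson(y[, i], y[, j])))
  expect_equal(s, unname(manual), tolerance = 1e-12)
  expect_gt(mean(s[upper.tri(s)]), 0) # dominant common factor
})

test_that("similarity output is a valid correlation matrix", {
  for (seed in 1:3) {
    s <- make_similarity(12, n_factors = 2, seed = seed)
    expect_equal(s, t(s))
    expect_equal(diag(s), rep(1, 12))
    expect_true(all(abs(s) <= 1 + 1e-12))
    expect_true(all(eigen(s, symmetric = TRUE,
                          only.values = TRUE)$values >= -1e-8))
  }
  expect_error(make_similarity(1), class = "beliefupdatr_invalid_argument")
  expect_error(make_similarity(-3), class = "beliefupdatr_invalid_argument")
})

test_that("feedback generation respects scale, precision, and degenerate sd", {
  expect_equal(make_feedback(3, mean = 3.71, sd = 0), rep(3.71, 3))
  expect_equal(make_feedback(4, mean = 1, sd = 0), rep(1, 4))
  fb <- make_feedback(50, mean = 4, sd = 1, seed = 5)
  expect_true(all(fb >= 1 & fb <= 7))
  expect_equal(fb, round(fb, 2))
  set.seed(5)
  expect_equal(fb, round(pmin(pmax(rnorm(50, 4, 1), 1), 7), 2))
  expect_error(make_feedback(3, sd = -1),
               class = "beliefupdatr_invalid_argument")
  expect_error(make_feedback(3, mean = 8),
               class = "beliefupdatr_invalid_argument")
})

test_that("anchoring limit gamma = 1 reproduces initial beliefs before noise", {
  d <- toy_design()
  s <- simulate_subject(d, 4, list(alpha = 0.6, e1 = 2, gamma = 1),
                        obs_noise_sd = 0.4, seed = 3)
  expect_equal(s$prediction, as.numeric(s$ib))
})

test_that("no-learning limit alpha = 0 reproduces initial expectations", {
  d <- toy_design()
  s <- simulate_subject(d, 2, list(alpha = 0, e1 = 6), obs_noise_sd = 0.4,
                        seed = 4)
  ord <- s$item_id
  expect_equal(s$prediction, init_expectations(6, d, ord)[ord])
})

test_that("identity similarity stops propagation to other items", {
  d <- task_design(feedback = round(seq(1.5, 6.5, length.out = 5), 2),
                   sim = diag(5))
  s <- simulate_subject(d, 2, list(alpha = 0.3, e1 = 5), obs_noise_sd = 0.3,
                        seed = 5)
  e <- init_expectations(5, d, s$item_id)
  # with SIM = I the only nonzero term is an item's own (never-seen) PE
  expect_equal(s$prediction, e[s$item_id])
})

test_that("cohort simulation is reproducible, typed, and sized", {
  d <- toy_design()
  cfg <- generator_config(0, model_id = 4, seed = 1)
  empty <- simulate_cohort(d, cfg)
  expect_equal(nrow(empty$trials), 0)
  expect_equal(nrow(empty$params), 0)

  cfg2 <- generator_config(5, model_id = 4, seed = 99)
  a <- simulate_cohort(d, cfg2)
  b <- simulate_cohort(d, cfg2)
  expect_identical(a, b)

  big <- simulate_cohort(toy_design(20), generator_config(300, model_id = 4,
                                                          seed = 11))
  expect_equal(nrow(big$params), 300)
  expect_setequal(setdiff(names(big$params), c("subject_id", "obs_noise_sd")),
                  setdiff(model_parameters(4), "sigma"))
  expect_true(all(big$trials$rating %in% 1:7))
  expect_true(all(big$trials$ib %in% 1:7))
  expect_true(all(big$trials$rating == as.integer(big$trials$rating)))
})

test_that("learning cohorts show non-increasing mean |PE| across positions", {
  d <- default_design(seed = 21)
  cfg <- generator_config(100, model_id = 4, seed = 22,
                          theta_dist = list(alpha = c(0.3, 0.6),
                                            gamma = c(0.1, 0.4)))
  cs <- simulate_cohort(d, cfg)
  tr <- pe_trend(cs$trials, n_perm = 200, seed = 1)
  expect_lt(tr$slope, 0)
})

test_that("generator configuration validates its arguments", {
  expect_error(generator_config(5, model_id = 4, seed = NULL),
               class = "beliefupdatr_invalid_argument")
  expect_error(generator_config(5, model_id = 9, seed = 1),
               class = "beliefupdatr_invalid_argument")
  expect_error(generator_config(5, model_id = 4, seed = 1,
                                obs_noise_sd = 0),
               class = "beliefupdatr_invalid_argument")
  expect_error(generator_config(5, model_id = 4, seed = 1,
                                theta_dist = list(alpha = c(-0.2, 0.5))),
               class = "beliefupdatr_invalid_argument")
  expect_error(generator_config(5, model_id = 4, seed = 1,
                                theta_dist = list(zeta = c(0, 1))),
               class = "beliefupdatr_invalid_argument")
  expect_error(simulate_subject(toy_design(), 4,
                                list(alpha = .2, e1 = 4, gamma = .5),
                                obs_noise_sd = 0),
               class = "beliefupdatr_invalid_argument")
})
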