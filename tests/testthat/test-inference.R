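test_that("transforms round-trip to 1e-10 away from bounds", {
  for (m in 1:5) {
    sp <- param_space(m)
    theta <- c(alpha = 0.37, alpha_pos = 0.81, alpha_neg = 0.12,
               gamma = 0.55, e1 = 5.3, sigma = 0.8, beta0 = 1.4, beta1 = 0.6)
    x <- to_unconstrained(as.list(theta), sp)
    back <- to_constrained(x, sp)
    expect_equal(back, theta[sp$name], tolerance = 1e-10)
    # and the reverse direction
    x2 <- rnorm(nrow(sp))
    expect_equal(to_unconstrained(as.list(to_constrained(x2, sp)), sp),
                 setNames(x2, sp$name), tolerance = 1e-10)
  }
  expect_error(param_space(2, prior_var = 0),
               class = "beliefupdatr_invalid_argument")
})

test_that("zero-residual log-likelihood matches the closed form", {
  d <- default_design(seed = 6)
  s <- simulate_subject(d, 4, list(alpha = 0.3, e1 = 4.5, gamma = 0.4),
                        obs_noise_sd = 0.5, seed = 7)
  s$rating <- s$prediction # force residuals to zero (non-integer is fine)
  ll <- log_likelihood(s, 4, list(alpha = 0.3, e1 = 4.5, gamma = 0.4,
                                  sigma = 1), d)
  expect_equal(ll, 20 * log(1 / sqrt(2 * pi)), tolerance = 1e-10)
  expect_equal(ll, -18.3788, tolerance = 1e-4)
  expect_error(log_likelihood(s, 4, list(alpha = .3, e1 = 4.5, gamma = .4,
                                         sigma = 0), d),
               class = "beliefupdatr_invalid_argument")
})

test_that("likelihood is maximized over sigma at the RMS residual", {
  d <- toy_design()
  s <- simulate_subject(d, 2, list(alpha = 0.4, e1 = 5), obs_noise_sd = 0.8,
                        seed = 8)
  theta <- list(alpha = 0.4, e1 = 5)
  tr <- run_trial_loop(2, theta, s$item_id, {
    ib <- numeric(6); ib[s$item_id] <- s$ib; ib
  }, feedback = s$feedback, design = d)
  sig_hat <- sqrt(mean((s$rating - tr$prediction)^2))
  ll_at <- function(sg) log_likelihood(s, 2, c(theta, sigma = sg), d)
  expect_gt(ll_at(sig_hat), ll_at(sig_hat * 1.2))
  expect_gt(ll_at(sig_hat), ll_at(sig_hat * 0.8))
  opt <- optimize(ll_at, c(0.05, 5), maximum = TRUE)
  expect_equal(opt$maximum, sig_hat, tolerance = 1e-3)
})

test_that("three-trial toy log-likelihood equals the hand computation", {
  sim <- diag(3)
  sim[1, 2] <- sim[2, 1] <- 0.5
  sim[1, 3] <- sim[3, 1] <- 0.2
  sim[2, 3] <- sim[3, 2] <- 0.4
  d <- task_design(feedback = c(6, 4, 4), sim = sim)
  s <- tibble::tibble(subject_id = 1, item_id = 1:3, position = 1:3,
                      ib = rep(4L, 3), rating = c(4, 5, 4),
                      feedback = c(6, 4, 4))
  # predictions are (4, 4.5, 4.1) so residuals are (0, 0.5, -0.1)
  ll <- log_likelihood(s, 2, list(alpha = 0.5, e1 = 4, sigma = 1), d)
  expect_equal(ll, sum(dnorm(c(0, 0.5, -0.1), 0, 1, log = TRUE)),
               tolerance = 1e-12)
})

test_that("R likelihood agrees with the compiled objective minus the prior", {
  set.seed(12)
  d <- default_design(n_items = 8, seed = 9)
  s <- simulate_subject(d, 5, list(alpha_pos = .6, alpha_neg = .2, e1 = 3,
                                   gamma = .3), obs_noise_sd = .6, seed = 13)
  sp <- param_space(5)
  x <- rnorm(5)
  theta <- as.list(to_constrained(x, sp))
  subj <- beliefupdatr:::as_subject(s, d)
  fn <- beliefupdatr:::make_objective(subj, 5, d, sp, "full")
  log_prior <- sum(dnorm(x, sp$prior_mean, sqrt(sp$prior_var), log = TRUE))
  expect_equal(-fn(x), log_likelihood(s, 5, theta, d) + log_prior,
               tolerance = 1e-8)
})

test_that("noiseless identity regression is recovered to 1e-3", {
  d <- default_design(seed = 10)
  set.seed(14)
  ib <- beliefupdatr:::draw_ib(20)
  ord <- sample(20)
  ib_pos <- ib[ord] # avoid tibble self-reference to the ib column
  s <- tibble::tibble(subject_id = 1, item_id = ord, position = 1:20,
                      ib = ib_pos,
                      rating = ib_pos + rnorm(20, 0, 1e-4),
                      feedback = d$feedback[ord])
  f <- fit_subject(s, 1, d, seed = 15)
  expect_true(f$converged)
  expect_equal(unname(f$theta_map["beta1"]), 1, tolerance = 1e-3)
  expect_equal(unname(f$theta_map["beta0"]), 0, tolerance = 5e-3)
})

test_that("a frozen-belief subject yields gamma near the upper bound", {
  d <- default_design(seed = 11)
  s <- simulate_subject(d, 4, list(alpha = 0.5, e1 = 3, gamma = 1),
                        obs_noise_sd = 0.3, seed = 16)
  f <- fit_subject(s, 4, d, seed = 17)
  expect_gt(unname(f$theta_map["gamma"]), 0.9)
})

test_that("Laplace evidence is exact on a conjugate Gaussian-mean toy", {
  # y_i ~ N(mu, s2) with s known, mu ~ N(m0, v0): quadratic log posterior,
  # so the Laplace approximation equals the analytic marginal likelihood
  y <- c(4.2, 5.1, 3.8, 4.6, 4.9)
  s2 <- 0.49; m0 <- 4; v0 <- 6.25
  n <- length(y)
  log_joint <- function(mu) {
    sum(dnorm(y, mu, sqrt(s2), log = TRUE)) + dnorm(mu, m0, sqrt(v0),
                                                    log = TRUE)
  }
  # analytic marginal: y ~ N(m0 * 1, s2 * I + v0 * J)
  cov <- diag(s2, n) + v0
  dev <- y - m0
  log_marginal <- -0.5 * (n * log(2 * pi) +
                            determinant(cov)$modulus[1] +
                            drop(dev %*% solve(cov, dev)))
  post_prec <- n / s2 + 1 / v0
  mu_map <- (sum(y) / s2 + m0 / v0) / post_prec
  H <- beliefupdatr:::fd_hessian(function(x) -log_joint(x[1]), mu_map)
  lap <- beliefupdatr:::laplace_log_evidence(
    log_joint(mu_map), beliefupdatr:::ridged_logdet(H)$logdet, 1)
  expect_equal(lap, log_marginal, tolerance = 1e-6)
  # and against 1-D quadrature as a second, independent oracle
  quad <- log(integrate(function(m) exp(sapply(m, log_joint)),
                        mu_map - 20, mu_map + 20,
                        rel.tol = 1e-11)$value)
  expect_equal(lap, quad, tolerance = 1e-6)
})

test_that("subject fits are deterministic given a seed", {
  d <- toy_design()
  s <- simulate_subject(d, 4, list(alpha = .4, e1 = 4, gamma = .5),
                        obs_noise_sd = .5, seed = 18)
  f1 <- fit_subject(s, 4, d, n_restarts = 4, seed = 19)
  f2 <- fit_subject(s, 4, d, n_restarts = 4, seed = 19)
  expect_identical(f1, f2)
  expect_error(fit_subject(s, 4, d, n_restarts = 0),
               class = "beliefupdatr_invalid_argument")
})

test_that("laplace evidence field satisfies its defining identity", {
  d <- toy_design()
  s <- simulate_subject(d, 2, list(alpha = .3, e1 = 5), obs_noise_sd = .5,
                        seed = 20)
  f <- fit_subject(s, 2, d, seed = 21)
  expect_equal(f$laplace_log_evidence,
               f$log_posterior + (3 / 2) * log(2 * pi) -
                 0.5 * f$hessian_logdet,
               tolerance = 1e-12)
})
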