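# Deterministic small designs and an independent reference implementation of
# the trial loop, used as the oracle for the recursion tests.

# compound-symmetry similarity: every off-diagonal equals rho
toy_design <- function(n_items = 6, rho = 0.4, feedback = NULL) {
  sim <- matrix(rho, n_items, n_items)
  diag(sim) <- 1
  if (is.null(feedback))
    feedback <- round(seq(2, 5, length.out = n_items), 2)
  task_design(feedback = feedback, sim = sim)
}

# plain-R reference loop, written independently of the package internals
ref_trial_loop <- function(model_id, theta, order, ib, fb, sim,
                           scale_min = 1, scale_max = 7) {
  n <- length(order)
  anchor <- (scale_min + scale_max) / 2
  p <- pe <- numeric(n)
  if (model_id == 1) {
    for (t in 1:n) {
      p[t] <- theta$beta0 + theta$beta1 * ib[order[t]]
      pe[t] <- fb[t] - p[t]
    }
    return(list(p = p, pe = pe))
  }
  e <- numeric(n)
  i1 <- order[1]
  for (j in 1:n) {
    e[j] <- if (j == i1) theta$e1 else anchor + sim[i1, j] * (theta$e1 - anchor)
    e[j] <- min(max(e[j], scale_min), scale_max)
  }
  ap <- if (model_id %in% c(2, 4)) theta$alpha else theta$alpha_pos
  an <- if (model_id %in% c(2, 4)) theta$alpha else theta$alpha_neg
  g <- if (model_id %in% c(4, 5)) theta$gamma else 0
  for (t in 1:n) {
    item <- order[t]
    pm <- e[item]
    if (t > 1) for (i in 1:(t - 1)) {
      a <- if (pe[i] > 0) ap else an
      pm <- pm + a * pe[i] * sim[order[i], item]
    }
    p[t] <- if (model_id %in% c(4, 5)) g * ib[item] + (1 - g) * pm else pm
    pe[t] <- fb[t] - p[t]
  }
  list(p = p, pe = pe)
}

random_theta <- function(model_id) {
  th <- list(alpha = runif(1), alpha_pos = runif(1), alpha_neg = runif(1),
             gamma = runif(1), e1 = runif(1, 1, 7),
             beta0 = runif(1, -1, 2), beta1 = runif(1, -0.5, 1.5))
  th[setdiff(model_parameters(model_id), "sigma")]
}
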