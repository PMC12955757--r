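# responsibilities and Dirichlet counts consistent with a fixed evidence
# matrix: iterate r_nk ~ exp(L_nk + digamma(a_k) - digamma(sum a)),
# a_k = a0 + sum_n r_nk, to a fixed point (no refitting involved)
responsibility_fixed_point <- function(L, alpha0 = 1, max_iter = 200,
                                       tol = 1e-12) {
  n <- nrow(L); K <- ncol(L)
  alpha <- rep(alpha0 + n / K, K)
  r <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    w <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    m <- apply(w, 1, max)
    r_new <- exp(w - m)
    r_new <- r_new / rowSums(r_new)
    alpha <- alpha0 + colSums(r_new)
    if (max(abs(r_new - r)) < tol) { r <- r_new; break }
    r <- r_new
  }
  list(r = r, alpha = alpha)
}

#' Exceedance probability of Dirichlet-distributed model frequencies
#'
#' Monte-Carlo estimate of `xp_k = P(r_k > r_j for all j != k)` under
#' `r ~ Dirichlet(alpha)`: the posterior probability that model k is the most
#' frequent in the population. Ties (measure-zero for continuous draws) are
#' broken uniformly at random.
#'
#' @param dirichlet_alpha Positive Dirichlet concentration vector.
#' @param n_samples Number of Monte-Carlo draws (default 1e6).
#' @param seed Optional RNG seed.
#' @return Numeric vector summing to 1.
#' @examples
#' exceedance_probability(c(1, 1), n_samples = 1e5, seed = 1)
#' @export
exceedance_probability <- function(dirichlet_alpha, n_samples = 1e6,
                                   seed = NULL) {
  if (any(dirichlet_alpha <= 0)) stop_invalid("all alpha must be > 0")
  K <- length(dirichlet_alpha)
  if (K == 1) return(1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_samples)
  g <- matrix(rgamma(n * K, shape = rep(dirichlet_alpha, each = n)), n, K)
  idx <- max.col(g, ties.method = "random")
  tabulate(idx, K) / n
}

#' Bayes omnibus risk
#'
#' Posterior probability that the observed differences in model evidence
#' arose by chance, i.e. that all models are equally frequent in the
#' population (the "null" random-effects model), versus frequencies that
#' vary. Computed as `1 / (1 + exp(F1 - F0))` where `F0` is the log evidence
#' of the null model and `F1` the variational free energy of the
#' Dirichlet-multinomial frequency model.
#'
#' @param L n x K matrix of per-subject log model evidences.
#' @param dirichlet_alpha Optional Dirichlet counts; recomputed from `L` at
#'   the responsibility fixed point when omitted.
#' @param alpha0 Dirichlet prior count (default 1).
#' @return Scalar in `[0, 1]`.
#' @export
bayes_omnibus_risk <- function(L, dirichlet_alpha = NULL, alpha0 = 1) {
  L <- as.matrix(L)
  if (any(!is.finite(L))) stop_invalid("evidence matrix must be finite")
  n <- nrow(L); K <- ncol(L)
  fp <- responsibility_fixed_point(L, alpha0 = alpha0)
  r <- fp$r
  alpha <- if (is.null(dirichlet_alpha)) fp$alpha else dirichlet_alpha

  f0 <- sum(apply(L - log(K), 1, lse))
  rlogr <- r * log(r)
  rlogr[r == 0] <- 0
  f1 <- sum(r * L) - sum(rlogr) +
    lgamma(K * alpha0) - K * lgamma(alpha0) -
    lgamma(sum(alpha)) + sum(lgamma(alpha))
  1 / (1 + exp(f1 - f0))
}

#' Protected exceedance probability
#'
#' Exceedance probabilities shrunk towards uniform by the Bayes omnibus risk:
#' `pxp = (1 - bor) * xp + bor / K`.
#'
#' @param xp Exceedance-probability vector.
#' @param bor Bayes omnibus risk in `[0, 1]`.
#' @return Numeric vector summing to 1.
#' @export
protected_exceedance <- function(xp, bor) {
  (1 - bor) * xp + bor / length(xp)
}

#' Hierarchical Bayesian model comparison over a cohort
#'
#' Jointly estimates subject-level parameters, group-level parameter
#' distributions per model, and a per-subject model-assignment variable.
#' Iterates: (1) each subject is refit under the current group prior of each
#' candidate model (MAP + Laplace evidence); (2) responsibilities
#' `r_nk ~ exp(L_nk + digamma(alpha_k) - digamma(sum alpha))` are updated in
#' log space; (3) Dirichlet counts `alpha_k = alpha0 + sum_n r_nk`; (4) group
#' prior moments become responsibility-weighted means and second moments of
#' the subject posteriors in unconstrained space (spread of the modes plus
#' each subject's Laplace posterior variance, floored at 0.01 -- omitting the
#' posterior-variance term would collapse the hierarchy onto the group mean).
#' Convergence when the largest responsibility change drops below `tol`.
#' Afterwards, exceedance probabilities, the Bayes omnibus risk and protected
#' exceedance probabilities are computed from the final state.
#'
#' @param data Cohort tibble: one row per subject x trial with columns
#'   `subject_id`, `item_id`, `position`, `ib`, `rating`, `feedback`.
#' @param design A [task_design()].
#' @param models Integer vector of candidate model ids (default `1:5`).
#' @param max_iter Maximum outer iterations (default 50).
#' @param tol Convergence tolerance on responsibilities (default 1e-3).
#' @param n_restarts Optimizer restarts for the first pass; later passes warm
#'   start from the previous mode plus one fresh draw.
#' @param seed RNG seed (default 1).
#' @param xp_samples Monte-Carlo draws for the exceedance probability.
#' @param prior_var Wide prior variance in unconstrained space (default 6.25).
#' @param var_floor Group-variance floor in unconstrained space.
#' @param hyper_kappa0,hyper_a0,hyper_b0 Normal-inverse-gamma hyperprior on
#'   the group moments, centred on the wide prior (mean 0, prior-variance
#'   expectation `hyper_b0 / (hyper_a0 - 1)`); it regularizes the group
#'   prior of models with little responsibility back towards the wide prior.
#' @param sum_bounds Propagation-sum convention, see [run_trial_loop()].
#' @return An object of class `hbi_fit`: list with `responsibilities`,
#'   `dirichlet_alpha`, `model_frequency`, `xp`, `bor`, `pxp`, `group_mu`,
#'   `group_var` (lists indexed by model), `evidence` (n x K matrix),
#'   `subject_fits` (list of lists), `models`, `n_iterations`, `converged`.
#' @examples
#' \donttest{
#' d <- default_design(n_items = 8, seed = 2)
#' cs <- simulate_cohort(d, generator_config(6, model_id = 4, seed = 3))
#' fit <- hbi_fit(cs$trials, d, models = c(1, 4), seed = 1, xp_samples = 1e4)
#' tidy(fit)
#' }
#' @export
hbi_fit <- function(data, design, models = 1:5, max_iter = 50, tol = 1e-3,
                    n_restarts = 10, seed = 1, xp_samples = 1e6,
                    prior_var = 6.25, var_floor = 0.01,
                    hyper_kappa0 = 1, hyper_a0 = 2, hyper_b0 = prior_var,
                    sum_bounds = "full") {
  subj_ids <- sort(unique(data$subject_id)) # canonical processing order
  n <- length(subj_ids)
  K <- length(models)
  if (n < 2) stop_invalid("need at least 2 subjects")
  if (K < 1) stop_invalid("need at least 1 candidate model")
  set.seed(seed)
  alpha0 <- 1

  subj_data <- lapply(subj_ids, function(s)
    as_subject(data[data$subject_id == s, ], design))
  spaces <- lapply(models, function(m)
    param_space(m, prior_var = prior_var,
                scale_min = design$scale_min, scale_max = design$scale_max))
  group_mu <- lapply(spaces, function(sp) sp$prior_mean)
  group_var <- lapply(spaces, function(sp) sp$prior_var)

  fits <- vector("list", K)
  L <- matrix(NA_real_, n, K)
  r <- matrix(1 / K, n, K)
  alpha <- rep(alpha0 + n / K, K)
  converged <- FALSE
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    for (k in seq_len(K)) {
      sp <- spaces[[k]]
      sp$prior_mean <- group_mu[[k]]
      sp$prior_var <- group_var[[k]]
      prev <- fits[[k]]
      # full multistart on the first pass; afterwards the previous mode is a
      # warm start and the prior moves little, so restarts taper off
      n_rs <- if (is.null(prev)) n_restarts else if (iter == 2) 2 else 0
      fits[[k]] <- lapply(seq_len(n), function(i) {
        init <- if (!is.null(prev)) matrix(prev[[i]]$x_map, nrow = 1) else NULL
        fit_subject(subj_data[[i]], models[k], design, space = sp,
                    n_restarts = max(n_rs, if (is.null(init)) 1 else 0),
                    init = init, sum_bounds = sum_bounds)
      })
      L[, k] <- vapply(fits[[k]], function(f) {
        v <- f$laplace_log_evidence
        if (is.na(v)) -1e10 else v
      }, numeric(1))
    }

    fp <- responsibility_fixed_point(L, alpha0 = alpha0)
    r_new <- fp$r
    alpha <- fp$alpha

    for (k in seq_len(K)) {
      x <- do.call(rbind, lapply(fits[[k]], `[[`, "x_map"))
      pv <- do.call(rbind, lapply(fits[[k]], `[[`, "posterior_var"))
      pv[!is.finite(pv)] <- 0
      R <- sum(r_new[, k])
      xbar <- colSums(r_new[, k] * x) / R
      # scatter includes each subject's Laplace posterior variance; using
      # modes alone collapses the hierarchy onto the group mean
      S <- colSums(r_new[, k] * (sweep(x, 2, xbar)^2 + pv))
      # normal-inverse-gamma hyperprior centred on the wide prior: models
      # with little responsibility revert to it (keeping their Occam
      # penalty) instead of overfitting their group prior to a few subjects
      kap <- hyper_kappa0 + R
      mu <- (hyper_kappa0 * spaces[[k]]$prior_mean + R * xbar) / kap
      a_post <- hyper_a0 + R / 2
      b_post <- hyper_b0 + S / 2 +
        hyper_kappa0 * R * (xbar - spaces[[k]]$prior_mean)^2 / (2 * kap)
      group_mu[[k]] <- mu
      group_var[[k]] <- pmax(b_post / (a_post - 1), var_floor)
    }

    delta <- max(abs(r_new - r))
    r <- r_new
    if (iter >= 2 && delta < tol) { converged <- TRUE; break }
  }

  xp <- exceedance_probability(alpha, n_samples = xp_samples)
  bor <- bayes_omnibus_risk(L, dirichlet_alpha = alpha, alpha0 = alpha0)
  pxp <- protected_exceedance(xp, bor)

  structure(
    list(responsibilities = r, dirichlet_alpha = alpha,
         model_frequency = alpha / sum(alpha),
         xp = xp, bor = bor, pxp = pxp,
         group_mu = group_mu, group_var = group_var,
         evidence = L, subject_fits = fits,
         models = as.integer(models), subject_ids = subj_ids,
         spaces = spaces,
         n_iterations = iter, converged = converged),
    class = "hbi_fit"
  )
}

#' Which model wins under protected exceedance probability
#'
#' @param x An [hbi_fit()] result.
#' @return Integer vector of winning model ids; length > 1 signals an exact
#'   tie (ties are reported, never silently broken).
#' @export
best_model <- function(x) {
  stopifnot(inherits(x, "hbi_fit"))
  x$models[which(x$pxp == max(x$pxp))]
}

#' @export
print.hbi_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<hbi_fit> %d subjects, %d candidate models, %d iteration(s)%s\n",
              nrow(x$responsibilities), length(x$models), x$n_iterations,
              if (x$converged) "" else " [not converged]"))
  print(as.data.frame(tidy(x)), digits = digits, row.names = FALSE)
  cat(sprintf("Bayes omnibus risk: %.3g\n", x$bor))
  invisible(x)
}

#' @export
tidy.hbi_fit <- function(x, ...) {
  tibble(model_id = x$models, model = model_label(x$models),
         frequency = x$model_frequency, xp = x$xp, pxp = x$pxp,
         dirichlet_alpha = x$dirichlet_alpha)
}

#' @export
glance.hbi_fit <- function(x, ...) {
  win <- best_model(x)
  tibble(n_subjects = nrow(x$responsibilities), n_models = length(x$models),
         best_model = if (length(win) == 1) win else NA_integer_,
         tie = length(win) > 1, bor = x$bor,
         n_iterations = x$n_iterations, converged = x$converged)
}

#' Group-level parameter summary of the winning model
#'
#' Responsibility-weighted means and SDs of the subject-level MAP estimates,
#' reported in constrained (natural) space.
#'
#' @param x An [hbi_fit()] result.
#' @param model_id Model to summarize (default: PXP winner).
#' @return Tibble with columns `term`, `mean`, `sd`.
#' @export
group_parameters <- function(x, model_id = NULL) {
  stopifnot(inherits(x, "hbi_fit"))
  if (is.null(model_id)) model_id <- best_model(x)[1]
  k <- match(model_id, x$models)
  if (is.na(k)) stop_invalid("model %d was not among the candidates", model_id)
  theta <- do.call(rbind, lapply(x$subject_fits[[k]],
                                 function(f) f$theta_map))
  w <- x$responsibilities[, k]
  w <- w / sum(w)
  mu <- colSums(w * theta)
  sdv <- sqrt(colSums(w * sweep(theta, 2, mu)^2))
  tibble(term = colnames(theta), mean = as.numeric(mu), sd = as.numeric(sdv))
}

#' @export
autoplot.hbi_fit <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td, c("frequency", "pxp"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$model_id),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "model", y = NULL,
                  title = "Model frequency and protected exceedance probability") +
    ggplot2::theme_minimal()
}
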