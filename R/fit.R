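# internal canonical form of one subject's data for the C++ objective
as_subject <- function(data, design) {
  if (inherits(data, "bu_subject")) return(data)
  stopifnot(is.data.frame(data))
  data <- dplyr::arrange(data, .data$position)
  n <- design$n_items
  if (nrow(data) != n)
    stop_invalid("subject data must have one row per item (%d), got %d",
                 n, nrow(data))
  order <- as.integer(data$item_id)
  check_order(order, n)
  ib_items <- numeric(n)
  ib_items[order] <- data$ib
  structure(
    list(order = order, ib = ib_items,
         feedback = as.numeric(data$feedback),
         ratings = as.numeric(data$rating),
         subject_id = data$subject_id[1]),
    class = "bu_subject"
  )
}

#' Gaussian observation log-likelihood of one subject's ratings
#'
#' Evaluates `sum_t log Normal(rating(t) | P(t), sigma^2)` where `P(t)` comes
#' from the model's trial loop. The Gaussian density is evaluated at the
#' integer rating with no discretization correction.
#'
#' @param data One subject's trials: a data frame with columns `item_id`,
#'   `position`, `ib`, `rating`, `feedback`.
#' @param model_id Integer model id, 1 to 5.
#' @param theta Named constrained parameters including `sigma` (> 0).
#' @param design A [task_design()].
#' @param sum_bounds Propagation-sum convention, see [run_trial_loop()].
#' @return The log-likelihood (scalar).
#' @export
log_likelihood <- function(data, model_id, theta, design,
                           sum_bounds = "full") {
  sigma <- theta[["sigma"]]
  if (is.null(sigma) || sigma <= 0) stop_invalid("`sigma` must be > 0")
  subj <- as_subject(data, design)
  tr <- run_trial_loop(model_id, theta, subj$order, subj$ib,
                       feedback = subj$feedback, design = design,
                       sum_bounds = sum_bounds)
  sum(dnorm(subj$ratings, tr$prediction, sigma, log = TRUE))
}

# negative log posterior closure over one subject, in unconstrained space;
# everything is hoisted into locals so each call is one .Call
make_objective <- function(subj, model_id, design, space, sum_bounds) {
  anchor <- (design$scale_min + design$scale_max) / 2
  literal <- identical(sum_bounds, "literal")
  order0 <- as.integer(subj$order - 1L)
  model_id <- as.integer(model_id)
  ib <- subj$ib; feedback <- subj$feedback; ratings <- subj$ratings
  sim <- design$sim
  prior_mean <- as.numeric(space$prior_mean)
  prior_var <- as.numeric(space$prior_var)
  lo <- design$scale_min; hi <- design$scale_max
  function(x) {
    .neg_log_post_cpp(x, model_id, order0, ib, feedback, ratings, sim,
                      prior_mean, prior_var, anchor, lo, hi, literal)
  }
}

# central finite-difference Hessian; the objective is smooth and cheap so a
# fixed relative step is adequate
fd_hessian <- function(fn, x, eps = 1e-4) {
  d <- length(x)
  h <- eps * pmax(1, abs(x))
  f0 <- fn(x)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    ei <- rep(0, d); ei[i] <- h[i]
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- rep(0, d); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) -
           fn(x - ei + ej) + fn(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

# log-determinant via Cholesky with a doubling ridge for non-PD Hessians
ridged_logdet <- function(h, start = 1e-8) {
  d <- nrow(h)
  ridge <- 0
  ch <- tryCatch(chol(h), error = function(e) NULL)
  delta <- start
  while (is.null(ch) && delta < 1e8) {
    ch <- tryCatch(chol(h + delta * diag(d)), error = function(e) NULL)
    if (!is.null(ch)) ridge <- delta
    delta <- delta * 2
  }
  if (is.null(ch)) return(list(logdet = NA_real_, ridge = NA_real_))
  list(logdet = 2 * sum(log(diag(ch))), ridge = ridge)
}

# Laplace approximation to the log model evidence at a mode:
# log p(y) ~= log p(y, x_map) + (d/2) log(2*pi) - 0.5 * log det H,
# H the Hessian of the negative log joint at the mode.
laplace_log_evidence <- function(log_post, hessian_logdet, d) {
  log_post + (d / 2) * log(2 * pi) - 0.5 * hessian_logdet
}

#' Fit one subject by MAP with Laplace model evidence
#'
#' Maximizes log-likelihood plus log-prior in unconstrained space with
#' multi-restart BFGS (restart points drawn from the prior), computes the
#' Hessian of the negative log posterior at the best mode by finite
#' differences, and returns the Laplace approximation to the log model
#' evidence. A non-positive-definite Hessian is regularized by the smallest
#' ridge `delta * I` (doubling from 1e-8) that makes the Cholesky succeed.
#'
#' @param data One subject's trials (see [log_likelihood()]).
#' @param model_id Integer model id, 1 to 5.
#' @param design A [task_design()].
#' @param space A [param_space()]; supply a modified one to fit under
#'   non-default (e.g. hierarchical) priors.
#' @param n_restarts Number of optimizer restarts (>= 1, default 10).
#' @param seed Optional RNG seed for the restart draws.
#' @param init Optional matrix of additional starting points (rows =
#'   unconstrained parameter vectors), e.g. warm starts.
#' @param sum_bounds Propagation-sum convention, see [run_trial_loop()].
#' @return An object of class `subject_fit`: list with `model_id`,
#'   `theta_map` (constrained), `x_map` (unconstrained), `log_posterior`,
#'   `posterior_var` (diagonal of the Laplace posterior covariance),
#'   `hessian_logdet`, `laplace_log_evidence`, `n_restarts_used`,
#'   `converged`, `ridge`, `subject_id`.
#' @export
fit_subject <- function(data, model_id, design,
                        space = param_space(model_id,
                                            scale_min = design$scale_min,
                                            scale_max = design$scale_max),
                        n_restarts = 10, seed = NULL, init = NULL,
                        sum_bounds = "full") {
  if (n_restarts < 1 && is.null(init))
    stop_invalid("`n_restarts` must be >= 1 when no `init` is given")
  if (!is.null(seed)) set.seed(seed)
  subj <- as_subject(data, design)
  fn <- make_objective(subj, model_id, design, space, sum_bounds)
  d <- nrow(space)

  starts <- matrix(rnorm(n_restarts * d, space$prior_mean,
                         sqrt(space$prior_var)),
                   max(n_restarts, 0), d, byrow = TRUE)
  if (!is.null(init)) starts <- rbind(as.matrix(init), starts)

  best <- NULL
  converged <- FALSE
  for (k in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[k, ], fn, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    best <- list(par = starts[1, ], value = fn(starts[1, ]), convergence = 1)
  } else {
    # polish: a fresh BFGS from the incumbent resets the curvature estimate
    # and escapes stalls on badly scaled ridges (e.g. near-zero residuals)
    polish <- tryCatch(
      optim(best$par, fn, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(polish) && is.finite(polish$value) &&
        polish$value < best$value) {
      if (polish$convergence == 0) converged <- TRUE
      best <- polish
    }
  }

  h <- tryCatch(fd_hessian(fn, best$par), error = function(e) NULL)
  post_var <- rep(NA_real_, d)
  if (is.null(h)) {
    ld <- list(logdet = NA_real_, ridge = NA_real_)
  } else {
    ld <- ridged_logdet(h)
    if (!is.na(ld$logdet)) {
      hr <- h + ld$ridge * diag(d)
      post_var <- diag(chol2inv(chol(hr)))
    }
  }
  log_post <- -best$value
  lev <- if (is.na(ld$logdet)) NA_real_ else
    laplace_log_evidence(log_post, ld$logdet, d)

  structure(
    list(model_id = as.integer(model_id),
         theta_map = to_constrained(best$par, space),
         x_map = setNames(best$par, space$name),
         log_posterior = log_post,
         posterior_var = setNames(post_var, space$name),
         hessian_logdet = ld$logdet,
         laplace_log_evidence = lev,
         n_restarts_used = nrow(starts),
         converged = converged && !is.na(ld$logdet),
         ridge = ld$ridge,
         subject_id = subj$subject_id),
    class = "subject_fit"
  )
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf("<subject_fit> model %d (%s), log evidence %.2f%s\n",
              x$model_id, model_label(x$model_id), x$laplace_log_evidence,
              if (x$converged) "" else " [not converged]"))
  print(round(x$theta_map, 4))
  invisible(x)
}

#' @export
tidy.subject_fit <- function(x, ...) {
  tibble(term = names(x$theta_map), estimate = as.numeric(x$theta_map),
         unconstrained = as.numeric(x$x_map))
}

#' @export
glance.subject_fit <- function(x, ...) {
  tibble(model_id = x$model_id, log_posterior = x$log_posterior,
         laplace_log_evidence = x$laplace_log_evidence,
         converged = x$converged, n_restarts_used = x$n_restarts_used)
}
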