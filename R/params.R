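#' Parameter space: transforms and priors in unconstrained space
#'
#' Each model parameter is estimated on an unconstrained scale and mapped to
#' its natural range by a smooth bijection: logistic for unit-interval
#' parameters (`alpha`, `alpha_pos`, `alpha_neg`, `gamma`), a scaled logistic
#' onto the rating scale for `e1`, the exponential for `sigma`, and the
#' identity for the regression coefficients of the no-learning model. Priors
#' are independent wide Gaussians in unconstrained space.
#'
#' @param model_id Integer model id, 1 to 5.
#' @param prior_mean,prior_var Prior mean and variance applied to every
#'   unconstrained parameter (defaults 0 and 6.25, the conventional "wide"
#'   setting).
#' @param scale_min,scale_max Rating-scale bounds for the `e1` transform.
#' @return A tibble of class `param_space` with columns `name`, `transform`,
#'   `prior_mean`, `prior_var`.
#' @examples
#' param_space(4)
#' @export
param_space <- function(model_id, prior_mean = 0, prior_var = 6.25,
                        scale_min = 1, scale_max = 7) {
  if (any(prior_var <= 0)) stop_invalid("prior variances must be > 0")
  nm <- model_parameters(model_id)
  tf <- dplyr::case_when(
    nm %in% c("alpha", "alpha_pos", "alpha_neg", "gamma") ~ "logit01",
    nm == "e1" ~ "logit_scale",
    nm == "sigma" ~ "log",
    TRUE ~ "identity"
  )
  out <- tibble(
    name = nm, transform = tf,
    prior_mean = rep_len(prior_mean, length(nm)),
    prior_var = rep_len(prior_var, length(nm))
  )
  attr(out, "model_id") <- as.integer(model_id)
  attr(out, "scale") <- c(scale_min, scale_max)
  class(out) <- c("param_space", class(out))
  out
}

inv_logit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' Map unconstrained parameters to constrained space (and back)
#'
#' @param x Numeric vector in unconstrained space (order of `space$name`).
#' @param space A [param_space()].
#' @return `to_constrained()` returns a named numeric vector of natural-scale
#'   parameters; `to_unconstrained()` its inverse.
#' @examples
#' sp <- param_space(2)
#' to_constrained(c(0, 0, 0), sp)
#' @export
to_constrained <- function(x, space) {
  lo <- attr(space, "scale")[1]
  hi <- attr(space, "scale")[2]
  out <- vapply(seq_along(x), function(j) {
    switch(space$transform[j],
      logit01 = inv_logit(x[j]),
      logit_scale = lo + (hi - lo) * inv_logit(x[j]),
      log = exp(x[j]),
      identity = x[j]
    )
  }, numeric(1))
  setNames(out, space$name)
}

#' @rdname to_constrained
#' @param theta Named numeric vector/list in constrained space.
#' @export
to_unconstrained <- function(theta, space) {
  lo <- attr(space, "scale")[1]
  hi <- attr(space, "scale")[2]
  out <- vapply(seq_len(nrow(space)), function(j) {
    v <- as.numeric(theta[[space$name[j]]])
    switch(space$transform[j],
      logit01 = logit(v),
      logit_scale = logit((v - lo) / (hi - lo)),
      log = log(v),
      identity = v
    )
  }, numeric(1))
  setNames(out, space$name)
}
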