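#' The five candidate belief-updating models
#'
#' @description
#' The package implements five trial-by-trial models of how participants
#' revise their agreement with statements while receiving normative feedback:
#'
#' * **Model 1 (no learning):** final ratings are a linear function of
#'   initial beliefs, `P = beta0 + beta1 * IB`.
#' * **Model 2 (fine granularity):** a prediction error on one statement
#'   propagates to every other statement in proportion to their similarity,
#'   scaled by a learning rate `alpha`:
#'   `P(t) = E(item_t) + sum_{i < t} alpha * PE(i) * SIM(item_i, item_t)`.
#' * **Model 3:** as Model 2 with separate learning rates `alpha_pos` /
#'   `alpha_neg` for positive and negative prediction errors.
#' * **Model 4 (anchored fine granularity):** the Model-2 prediction `Pm` is
#'   mixed with the participant's initial belief,
#'   `P(t) = gamma * IB(item_t) + (1 - gamma) * Pm(t)`, with anchoring weight
#'   `gamma` in `[0, 1]`.
#' * **Model 5:** Model 4 with the dual learning rates of Model 3.
#'
#' The prediction error is always `PE(t) = F(t) - P(t)`: feedback minus the
#' model's prediction on that trial. Feedback never influences its own
#' trial's prediction. Predictions are not clipped to the scale; only
#' simulated integer ratings are.
#'
#' @param model_id Integer model id, 1 to 5.
#' @return `model_parameters()` returns the character vector of constrained
#'   parameter names for a model, in the canonical order used throughout the
#'   package (observation noise `sigma` always last).
#' @examples
#' model_parameters(4)
#' @export
model_parameters <- function(model_id) {
  switch(as.character(model_id),
    "1" = c("beta0", "beta1", "sigma"),
    "2" = c("alpha", "e1", "sigma"),
    "3" = c("alpha_pos", "alpha_neg", "e1", "sigma"),
    "4" = c("alpha", "e1", "gamma", "sigma"),
    "5" = c("alpha_pos", "alpha_neg", "e1", "gamma", "sigma"),
    stop_invalid("unknown model_id: %s", format(model_id))
  )
}

#' Model names for display
#' @param model_id Integer model id, 1 to 5 (vectorised).
#' @return Character vector of short model labels.
#' @export
model_label <- function(model_id) {
  labs <- c("no learning", "fine granularity", "fine granularity (dual rates)",
            "anchored fine granularity", "anchored (dual rates)")
  labs[model_id]
}

check_theta <- function(model_id, theta, design) {
  need <- setdiff(model_parameters(model_id), "sigma")
  missing <- setdiff(need, names(theta))
  if (length(missing))
    stop_invalid("theta for model %d is missing: %s", model_id,
                 paste(missing, collapse = ", "))
  for (p in intersect(c("alpha", "alpha_pos", "alpha_neg", "gamma"), need)) {
    v <- theta[[p]]
    if (v < 0 || v > 1) stop_invalid("`%s` must lie in [0, 1]", p)
  }
  if ("e1" %in% need) {
    if (theta[["e1"]] < design$scale_min || theta[["e1"]] > design$scale_max)
      stop_invalid("`e1` must lie in [%g, %g]", design$scale_min,
                   design$scale_max)
  }
  invisible(TRUE)
}

#' Initial feedback expectations from the first statement's expectation
#'
#' The expectation for the first-presented statement is a free parameter
#' `e1`; the expectation for every other statement j is obtained by linear
#' regression towards the scale midpoint, weighted by the similarity between
#' j and the first statement: `E(j) = c + SIM(i1, j) * (e1 - c)` with anchor
#' `c = (scale_min + scale_max) / 2`. Expectations are clipped to the rating
#' scale.
#'
#' @param e1 Expectation for the first-presented statement, in scale units.
#' @param design A [task_design()].
#' @param order Integer permutation of `1:n_items` giving presentation order.
#' @return Numeric vector of per-item expectations (indexed by item, not by
#'   position).
#' @examples
#' d <- task_design(feedback = c(3, 4, 5), sim = diag(3))
#' init_expectations(6, d, order = c(2, 1, 3))
#' @export
init_expectations <- function(e1, design, order) {
  check_order(order, design$n_items)
  if (e1 < design$scale_min || e1 > design$scale_max)
    stop_invalid("`e1` must lie in [%g, %g]", design$scale_min,
                 design$scale_max)
  anchor <- (design$scale_min + design$scale_max) / 2
  i1 <- order[1]
  e <- anchor + design$sim[i1, ] * (e1 - anchor)
  e[i1] <- e1
  clip(e, design$scale_min, design$scale_max)
}

check_order <- function(order, n_items) {
  if (length(order) != n_items || anyNA(order) ||
      !setequal(order, seq_len(n_items)))
    stop_invalid("`order` must be a permutation of 1..%d", n_items)
  invisible(TRUE)
}

#' Prediction error
#'
#' The learning signal of all models: feedback minus the model's prediction
#' on the same trial.
#'
#' @param feedback Feedback value(s) F(t).
#' @param prediction Model prediction(s) P(t).
#' @return `feedback - prediction`.
#' @examples
#' compute_pe(3.71, 5) # -1.29
#' @export
compute_pe <- function(feedback, prediction) feedback - prediction

#' No-learning predictions (Model 1)
#'
#' @param theta Named list/vector with `beta0` (intercept, rating units) and
#'   `beta1` (slope).
#' @param ib Numeric vector of initial beliefs.
#' @return Per-item predictions `beta0 + beta1 * ib`.
#' @examples
#' predict_model1(list(beta0 = 1, beta1 = 0.5), ib = 6)
#' @export
predict_model1 <- function(theta, ib) theta[["beta0"]] + theta[["beta1"]] * ib

#' Run a model's trial-by-trial prediction loop for one participant
#'
#' Computes, for each presentation position, the model prediction `P(t)`,
#' the pre-anchoring prediction `Pm(t)` (models 4/5; `NA` for model 1), and
#' the prediction error `PE(t) = F(t) - P(t)`. The propagation sum runs over
#' all completed trials `i = 1..t-1` by default; `sum_bounds = "literal"`
#' restricts it to `i = 2..t-2` (skipping the first trial and the
#' immediately preceding one).
#'
#' @param model_id Integer model id, 1 to 5.
#' @param theta Named list/vector of constrained parameters for the model
#'   (see [model_parameters()]; `sigma` is ignored here).
#' @param order Integer permutation of `1:n_items`: item presented at each
#'   position.
#' @param ib Integer vector of initial beliefs, indexed by item.
#' @param feedback Feedback value at each position (defaults to the design's
#'   normative feedback for the presented items).
#' @param design A [task_design()].
#' @param sum_bounds `"full"` (default) or `"literal"`; see Details.
#' @return A tibble with columns `position`, `item_id`, `expectation`
#'   (initial per-item expectation of the presented item; `NA` for model 1),
#'   `pm`, `prediction`, `pe`.
#' @examples
#' d <- default_design(n_items = 5, seed = 1)
#' run_trial_loop(4, list(alpha = 0.3, e1 = 4, gamma = 0.5),
#'                order = 1:5, ib = rep(4, 5), design = d)
#' @export
run_trial_loop <- function(model_id, theta, order, ib, feedback = NULL,
                           design, sum_bounds = c("full", "literal")) {
  sum_bounds <- match.arg(sum_bounds)
  check_order(order, design$n_items)
  if (length(ib) != design$n_items)
    stop_invalid("`ib` must have one entry per item")
  if (is.null(feedback)) feedback <- design$feedback[order]
  if (length(feedback) != design$n_items)
    stop_invalid("`feedback` must have one entry per position")
  check_theta(model_id, theta, design)

  par <- constrained_par_vector(model_id, theta)
  anchor <- (design$scale_min + design$scale_max) / 2
  tr <- .trial_trace_cpp(as.integer(model_id), par, as.integer(order - 1L),
                         as.numeric(ib), as.numeric(feedback), design$sim,
                         anchor, design$scale_min, design$scale_max,
                         sum_bounds == "literal")
  expectation <- if (model_id == 1) {
    rep(NA_real_, design$n_items)
  } else {
    init_expectations(theta[["e1"]], design, order)[order]
  }
  tibble(
    position = seq_len(design$n_items),
    item_id = as.integer(order),
    expectation = expectation,
    pm = tr[, "pm"],
    prediction = tr[, "prediction"],
    pe = tr[, "pe"]
  )
}

# constrained parameters in canonical order; missing sigma filled with 1
# (sigma does not affect predictions)
constrained_par_vector <- function(model_id, theta) {
  nm <- model_parameters(model_id)
  th <- as.list(theta)
  if (is.null(th[["sigma"]])) th[["sigma"]] <- 1
  as.numeric(unlist(th[nm]))
}
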