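#' Task design: items, scale, normative feedback and similarity structure
#'
#' A `task_design` bundles everything that is fixed across participants in a
#' belief-rating task with normative feedback: the number of statements, the
#' rating scale, the per-item normative feedback values (the reference
#' group's mean agreement on a 1-7 scale, shown to participants after each
#' rating), and the item-by-item similarity matrix used to propagate
#' prediction errors between statements.
#'
#' @param feedback Numeric vector of per-item normative feedback values, one
#'   per statement, each within `[scale_min, scale_max]`.
#' @param sim Square numeric similarity matrix (typically an inter-item
#'   correlation matrix from a reference sample): symmetric, unit diagonal,
#'   entries in `[-1, 1]`, dimension `length(feedback)`.
#' @param scale_min,scale_max Rating-scale bounds (default 1 and 7).
#'
#' @return An object of class `task_design`: a list with elements `n_items`,
#'   `scale_min`, `scale_max`, `feedback`, `sim`.
#' @examples
#' d <- task_design(feedback = c(3.71, 2.5, 4.2),
#'                  sim = diag(3))
#' d$n_items
#' @export
task_design <- function(feedback, sim, scale_min = 1, scale_max = 7) {
  n <- length(feedback)
  if (n < 2) stop_invalid("a task design needs at least 2 items, got %d", n)
  if (!is.matrix(sim) || nrow(sim) != n || ncol(sim) != n)
    stop_invalid("`sim` must be a %d x %d matrix", n, n)
  if (any(diag(sim) != 1))
    stop_invalid("`sim` must have a unit diagonal")
  if (!isTRUE(all.equal(sim, t(sim), tolerance = 1e-12)))
    stop_invalid("`sim` must be symmetric")
  if (any(abs(sim) > 1 + 1e-12))
    stop_invalid("similarity entries must lie in [-1, 1]")
  if (any(feedback < scale_min | feedback > scale_max))
    stop_invalid("feedback values must lie in [%g, %g]", scale_min, scale_max)
  structure(
    list(n_items = n, scale_min = scale_min, scale_max = scale_max,
         feedback = as.numeric(feedback), sim = unname(sim)),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  off <- x$sim[upper.tri(x$sim)]
  cat(sprintf("<task_design> %d items, scale [%g, %g]\n",
              x$n_items, x$scale_min, x$scale_max))
  cat(sprintf("  feedback: mean %.2f, range [%.2f, %.2f]\n",
              mean(x$feedback), min(x$feedback), max(x$feedback)))
  cat(sprintf("  similarity: mean off-diagonal %.3f\n", mean(off)))
  invisible(x)
}

#' Default 20-item task design
#'
#' Convenience constructor emulating the study conditions: 20 statements on a
#' 1-7 scale, normative feedback drawn around a below-midpoint mean (the
#' reference sample mostly leans towards disagreement with the statements),
#' and a similarity matrix computed as inter-item correlations of a simulated
#' reference sample with one dominant latent factor.
#'
#' @param n_items Number of statements (default 20).
#' @param seed RNG seed (required for reproducibility).
#' @param feedback_mean,feedback_sd Mean and SD of the normative feedback
#'   draws before clipping to the scale (defaults 3.5 and 1.0).
#' @param n_factors,loading_range,n_respondents Passed to [make_similarity()].
#' @return A [task_design()].
#' @export
default_design <- function(n_items = 20, seed = 1,
                           feedback_mean = 3.5, feedback_sd = 1.0,
                           n_factors = 1, loading_range = c(0.4, 0.8),
                           n_respondents = 510) {
  sim <- make_similarity(n_items, n_factors = n_factors,
                         loading_range = loading_range,
                         n_respondents = n_respondents, seed = seed)
  fb <- make_feedback(n_items, mean = feedback_mean, sd = feedback_sd,
                      seed = seed + 1L)
  task_design(feedback = fb, sim = sim)
}
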