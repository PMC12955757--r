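#' Synthetic inter-item similarity matrix from a latent-factor reference sample
#'
#' Simulates a reference sample of respondents whose item responses load on
#' one or more common latent factors, then returns the inter-item Pearson
#' correlation matrix. With a single dominant factor and positive loadings
#' this yields the structure typical of a belief scale measuring a common
#' construct: predominantly positive off-diagonal correlations.
#'
#' Items are assigned to factors round-robin; item j's response for
#' respondent i is `lambda_j * f[i, factor(j)] + sqrt(1 - lambda_j^2) * eps`,
#' so a loading of 1 gives zero uniqueness and a loading of 0 gives pure
#' noise.
#'
#' @param n_items Number of items (>= 2).
#' @param n_factors Number of latent factors (default 1).
#' @param loading_range Length-2 numeric, bounds for the uniform draw of each
#'   item's factor loading, inside `[0, 1]`.
#' @param n_respondents Size of the simulated reference sample (default 510).
#' @param seed Optional RNG seed.
#' @return An `n_items` x `n_items` correlation matrix.
#' @examples
#' s <- make_similarity(5, seed = 1)
#' all(diag(s) == 1)
#' @export
make_similarity <- function(n_items, n_factors = 1,
                            loading_range = c(0.4, 0.8),
                            n_respondents = 510, seed = NULL) {
  if (length(n_items) != 1 || is.na(n_items) || n_items < 2)
    stop_invalid("`n_items` must be a single count >= 2")
  if (n_factors < 1) stop_invalid("`n_factors` must be >= 1")
  if (length(loading_range) != 2 || any(loading_range < 0) ||
      any(loading_range > 1) || loading_range[1] > loading_range[2])
    stop_invalid("`loading_range` must be an increasing interval inside [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  fac_of <- rep_len(seq_len(n_factors), n_items)
  lambda <- runif(n_items, loading_range[1], loading_range[2])
  f <- matrix(rnorm(n_respondents * n_factors), n_respondents, n_factors)
  eps <- matrix(rnorm(n_respondents * n_items), n_respondents, n_items)
  y <- f[, fac_of, drop = FALSE] * rep(lambda, each = n_respondents) +
    eps * rep(sqrt(pmax(0, 1 - lambda^2)), each = n_respondents)

  s <- cor(y)
  # degenerate items (zero variance when loading = 1 and factor constant)
  # cannot occur here since factor scores are continuous, but guard anyway
  s[!is.finite(s)] <- 0
  diag(s) <- 1
  s <- (s + t(s)) / 2
  unname(s)
}

#' Per-item normative feedback values
#'
#' Draws one normative feedback value per item from a Gaussian, clips to the
#' rating scale and rounds to two decimals -- the precision at which feedback
#' is shown to participants.
#'
#' @param n_items Number of items.
#' @param mean Mean of the feedback draws, within `[1, 7]`.
#' @param sd Standard deviation of the draws (>= 0; `sd = 0` gives a
#'   constant vector).
#' @param seed Optional RNG seed.
#' @param scale_min,scale_max Rating-scale bounds.
#' @return Numeric vector of length `n_items`, values in
#'   `[scale_min, scale_max]` with at most two decimals.
#' @examples
#' make_feedback(3, mean = 3.71, sd = 0)
#' @export
make_feedback <- function(n_items, mean = 3.5, sd = 1.0, seed = NULL,
                          scale_min = 1, scale_max = 7) {
  if (sd < 0) stop_invalid("`sd` must be >= 0")
  if (mean < scale_min || mean > scale_max)
    stop_invalid("`mean` must lie in [%g, %g]", scale_min, scale_max)
  if (!is.null(seed)) set.seed(seed)
  draws <- rnorm(n_items, mean, sd)
  round(clip(draws, scale_min, scale_max), 2)
}
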