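#' Read and write cohort CSV files
#'
#' The cohort CSV has one row per subject x trial with columns `subject_id`,
#' `item_id` (1-based), `position`, `ib`, `rating`, `feedback`.
#' `read_cohort()` validates the schema and, when a design is supplied, the
#' consistency of the data with it: ratings and initial beliefs inside the
#' scale, per-subject presentation orders that are valid permutations, no
#' duplicate (subject, position) pairs, feedback within the scale, and item
#' ids within `1..n_items`. Violations raise errors naming the offending
#' rows.
#'
#' @param path File path.
#' @param design Optional [task_design()] to validate against.
#' @return A tibble with the cohort schema (extra columns are preserved).
#' @export
read_cohort <- function(path, design = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(df, design)
}

#' @rdname read_cohort
#' @param data Cohort tibble to validate or write.
#' @export
validate_cohort <- function(data, design = NULL) {
  required <- c("subject_id", "item_id", "position", "ib", "rating",
                "feedback")
  missing <- setdiff(required, names(data))
  if (length(missing))
    stop_invalid("cohort is missing columns: %s",
                 paste(missing, collapse = ", "))

  lo <- if (is.null(design)) 1 else design$scale_min
  hi <- if (is.null(design)) 7 else design$scale_max
  bad <- which(data$rating < lo | data$rating > hi)
  if (length(bad))
    stop_invalid("rating out of [%g, %g] at row(s): %s", lo, hi,
                 paste(head(bad, 5), collapse = ", "))
  bad <- which(data$ib < lo | data$ib > hi)
  if (length(bad))
    stop_invalid("ib out of [%g, %g] at row(s): %s", lo, hi,
                 paste(head(bad, 5), collapse = ", "))
  bad <- which(data$feedback < lo | data$feedback > hi)
  if (length(bad))
    stop_invalid("feedback out of [%g, %g] at row(s): %s", lo, hi,
                 paste(head(bad, 5), collapse = ", "))

  dup <- duplicated(data[, c("subject_id", "position")])
  if (any(dup))
    stop_invalid("duplicate (subject_id, position) at row(s): %s",
                 paste(head(which(dup), 5), collapse = ", "))

  if (!is.null(design)) {
    n <- design$n_items
    if (any(data$item_id < 1 | data$item_id > n))
      stop_invalid("item_id outside 1..%d", n)
    for (s in unique(data$subject_id)) {
      ord <- data$item_id[data$subject_id == s][
        order(data$position[data$subject_id == s])]
      if (length(ord) != n || !setequal(ord, seq_len(n)))
        stop_invalid("subject %s: presentation order is not a permutation of 1..%d",
                     format(s), n)
    }
  }
  as_tibble(data)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  validate_cohort(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Read and write similarity-matrix CSV files
#'
#' The similarity CSV is an `n x n` numeric table with a header row of item
#' ids. `read_similarity()` checks squareness, symmetry and the unit
#' diagonal; supply `n_items` to enforce a dimension (e.g. against a cohort).
#'
#' @param path File path.
#' @param n_items Optional expected dimension.
#' @return A numeric matrix.
#' @export
read_similarity <- function(path, n_items = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop_invalid("similarity file is not square: %d x %d", nrow(m), ncol(m))
  if (!is.null(n_items) && nrow(m) != n_items)
    stop_invalid("similarity is %d x %d but the cohort has %d items",
                 nrow(m), ncol(m), n_items)
  storage.mode(m) <- "double"
  if (max(abs(m - t(m))) > 1e-8) stop_invalid("similarity must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-12))
    stop_invalid("similarity must have a unit diagonal")
  unname(m)
}

#' @rdname read_similarity
#' @param sim Similarity matrix to write.
#' @export
write_similarity <- function(sim, path) {
  df <- as.data.frame(sim)
  names(df) <- paste0("item_", seq_len(ncol(sim)))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#'
#' Configurations drive reproducible simulation runs. A `seed` key is
#' mandatory; unknown keys are rejected so that typos fail loudly.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [generator_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("n_subjects", "model_id", "seed", "theta_dist",
               "obs_noise_sd", "n_factors", "loading_range")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop_invalid("unknown config keys: %s", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop_invalid("config must contain a `seed` key")
  if (!is.null(cfg$theta_dist)) cfg$theta_dist <- lapply(cfg$theta_dist, unlist)
  do.call(generator_config, cfg)
}

#' Write an hierarchical comparison result to JSON
#'
#' Serializes the group-level quantities of an [hbi_fit()] (frequencies, XP,
#' BOR, PXP, Dirichlet counts, responsibilities, group moments) together with
#' a schema version.
#'
#' @param x An [hbi_fit()] result.
#' @param path Output path.
#' @export
write_hbi_json <- function(x, path) {
  stopifnot(inherits(x, "hbi_fit"))
  out <- list(
    schema_version = "1.0",
    models = x$models,
    model_frequency = x$model_frequency,
    xp = x$xp, bor = x$bor, pxp = x$pxp,
    dirichlet_alpha = x$dirichlet_alpha,
    responsibilities = x$responsibilities,
    group_mu = x$group_mu, group_var = x$group_var,
    n_iterations = x$n_iterations, converged = x$converged
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
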