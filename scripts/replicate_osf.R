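#!/usr/bin/env Rscript
# Replication script for the human-cohort analysis. The study's trial-level
# ratings and the empirical 20-item similarity matrix are deposited on OSF
# (https://osf.io/68wrt/) and are NOT shipped here; download them and convert
# to the package's CSV schema first:
#
#   cohort CSV:     subject_id, item_id (1-based), position, ib, rating, feedback
#   similarity CSV: 20 x 20 numeric table with a header row of item ids
#
# Then:
#   Rscript scripts/replicate_osf.R --cohort data/cohort.csv \
#       --similarity data/similarity.csv --out results/replication
#
# The script runs the five-model hierarchical comparison and writes the
# comparison table (model frequency, XP, BOR, PXP) plus the winning model's
# group-level parameter means -- the quantities reported for the study cohort.

suppressPackageStartupMessages({
  library(optparse)
  library(beliefupdatr)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--cohort", type = "character"),
  make_option("--similarity", type = "character"),
  make_option("--out", type = "character", default = "results/replication"),
  make_option("--seed", type = "integer", default = 1L)
)))
if (is.null(opts$cohort) || is.null(opts$similarity))
  stop("--cohort and --similarity are required (see header comment)")

cohort <- read_cohort(opts$cohort)
sim <- read_similarity(opts$similarity,
                       n_items = length(unique(cohort$item_id)))
feedback <- vapply(split(cohort$feedback, cohort$item_id),
                   function(x) x[1], numeric(1))
design <- task_design(feedback = feedback, sim = sim)
cohort <- validate_cohort(cohort, design)

fit <- hbi_fit(cohort, design, models = 1:5, seed = opts$seed)
print(fit)

dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
readr::write_csv(tidy(fit), file.path(opts$out, "model_comparison.csv"))
readr::write_csv(group_parameters(fit),
                 file.path(opts$out, "group_parameters.csv"))
write_hbi_json(fit, file.path(opts$out, "hbi_fit.json"))
message("wrote ", opts$out)
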