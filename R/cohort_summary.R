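#' Recompute cohort composition percentages from counts
#'
#' Given a long table of clinical category counts (one row per cohort,
#' variable and level), recomputes each level's percentage of its
#' cohort-and-variable total. Used against the bundled clinical
#' composition of the published multi-study bladder-cancer meta-cohort
#' (see `inst/extdata/blca_cohort_counts.tsv`), whose printed
#' percentages the recomputation reproduces to the printed precision.
#'
#' @param counts Data frame with columns `cohort`, `variable`, `level`,
#'   `count` and optionally `printed_pct` (carried through).
#' @return The input with a `pct` column (100 * count / group total)
#'   and, when `printed_pct` is present, `pct_diff = pct - printed_pct`.
#' @export
cohort_percentages <- function(counts) {
  need <- c("cohort", "variable", "level", "count")
  stopifnot(all(need %in% names(counts)))
  key <- interaction(counts$cohort, counts$variable, drop = TRUE)
  totals <- tapply(counts$count, key, sum)
  counts$pct <- 100 * counts$count / as.vector(totals[key])
  if ("printed_pct" %in% names(counts))
    counts$pct_diff <- counts$pct - counts$printed_pct
  counts
}

#' Load the bundled bladder-cancer cohort composition table
#'
#' Stage, sex, grade and immunotherapy-response counts (with the
#' percentages as printed in the source clinical table) for the
#' 1135-sample discovery meta-cohort and the two RNA-Seq validation
#' cohorts the pipeline is designed around.
#'
#' @return Data frame with columns `cohort`, `variable`, `level`,
#'   `count`, `printed_pct`.
#' @export
load_cohort_counts <- function() {
  path <- system.file("extdata", "blca_cohort_counts.tsv",
                      package = "monostage", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
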