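# Published reference values from the Mt Wutai nested-plot moss survey
# that motivated this package.  They are shipped as plain CSV so that the
# scale-regression hand-checks and the acceptance report can use them as
# inputs; the full deposited site/occurrence tables are not redistributed
# here.

#' Reported relative-importance scores (Mt Wutai moss survey)
#'
#' Top-four permutation relative-importance percentages for each of the
#' eight driver analyses (c, z, and richness at six subplot areas).
#'
#' @return data.frame: `response` ("c", "z", "richness"), `area` (m2; NA
#'   for c and z), `predictor`, `ri` (percent).
#' @export
reported_importance <- function() {
  read.csv(system.file("extdata", "wutai_reported_importance.csv",
                       package = "mossar"),
           stringsAsFactors = FALSE)
}

#' Reported richness-pattern summary (Mt Wutai moss survey)
#'
#' Per-scale peak location and strength, GAM fit (R2, printed p of the
#' elevation smooth) and BRT performance (RMSE, MAE, R2).
#'
#' @return data.frame keyed by `area` (m2).
#' @export
reported_richness_summary <- function() {
  read.csv(system.file("extdata", "wutai_reported_richness_summary.csv",
                       package = "mossar"),
           stringsAsFactors = FALSE)
}
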