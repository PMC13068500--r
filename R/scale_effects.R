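#' Regress a per-scale quantity against log10 area
#'
#' Ordinary least squares of a quantity observed at each subplot scale
#' (e.g. a predictor's relative-importance score, or a model R2) on
#' log10(area in m2), with a two-sided t-test on the slope (df = n - 2).
#' Base-10 logs are used; a different base (or using side length instead
#' of area) rescales the slope but leaves its sign and p-value unchanged.
#'
#' @param values numeric vector, one value per scale.
#' @param areas subplot areas in m2 (>= 3 distinct values).
#' @param quantity optional label carried into the output.
#' @return one-row data.frame: `quantity`, `slope` (per log10 m2),
#'   `intercept`, `p_slope`, `r2`, `n`.
#' @export
regress_vs_scale <- function(values, areas, quantity = NA_character_) {
  stopifnot(length(values) == length(areas))
  if (length(unique(areas)) < 3L) stop("need >= 3 distinct areas")
  x <- log10(areas)
  if (stats::sd(values) == 0) {
    # constant response: zero slope, no evidence against it
    return(data.frame(quantity = quantity, slope = 0,
                      intercept = mean(values), p_slope = 1, r2 = 0,
                      n = length(values), stringsAsFactors = FALSE))
  }
  fit <- lm(values ~ x)
  sm <- summary(fit)$coefficients
  data.frame(quantity = quantity,
             slope = sm[2L, 1L], intercept = sm[1L, 1L],
             p_slope = sm[2L, 4L],
             r2 = summary(fit)$r.squared,
             n = length(values), stringsAsFactors = FALSE)
}

#' Scale regressions for a table of importance scores and model R2
#'
#' @param importance_by_scale data.frame with columns `area`, `predictor`,
#'   `ri`, one row per predictor per scale.
#' @param r2_by_scale optional data.frame with columns `area`, `r2`.
#' @return data.frame of [regress_vs_scale()] rows, one per predictor
#'   (labelled by predictor name) plus one for `R2` when supplied.
#' @export
scale_regressions <- function(importance_by_scale, r2_by_scale = NULL) {
  rows <- lapply(split(importance_by_scale, importance_by_scale$predictor),
                 function(d) {
                   d <- d[order(d$area), , drop = FALSE]
                   regress_vs_scale(d$ri, d$area, quantity = d$predictor[1L])
                 })
  out <- do.call(rbind, rows)
  if (!is.null(r2_by_scale)) {
    d <- r2_by_scale[order(r2_by_scale$area), , drop = FALSE]
    out <- rbind(out, regress_vs_scale(d$r2, d$area, quantity = "R2"))
  }
  rownames(out) <- NULL
  out
}
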