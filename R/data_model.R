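#' @useDynLib mossar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats as.formula coef cor lm median nls optimize p.adjust
#'   pnorm predict pt qnorm quantile residuals rnorm runif sd setNames
#'   t.test var vcov
#' @importFrom utils read.csv write.csv
NULL

# canonical predictor set, in display order
.predictors <- c("Bio1", "Bio6", "Bio7", "Bio12", "Bio14",
                 "WS", "NPP", "NDVI", "HD")

.environments <- c("grassland", "forest", "alpine meadow",
                   "alpine rocky meadow")

#' Canonical environmental predictor names
#'
#' The nine plot-level covariates used throughout the driver analyses:
#' Bio1 (mean annual temperature, deg C), Bio6 (coldest-month minimum,
#' deg C), Bio7 (annual temperature range, deg C), Bio12 (annual
#' precipitation, mm), Bio14 (driest-month precipitation, mm), WS (wind
#' speed, m/s), NPP (net primary productivity, kg C/m2/yr), NDVI
#' (unitless), and HD (habitat-type count, 0-4).
#'
#' @return character vector of length 9.
#' @export
predictor_names <- function() .predictors

#' Build and validate a plot environment table
#'
#' @param df data.frame with columns `plot_id`, `lon`, `lat`, `elevation`,
#'   `environment` and the nine predictors of [predictor_names()]
#'   (case-insensitive).
#' @return the validated data.frame with canonical column names, class
#'   `plot_table`.
#' @export
plot_table <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("plot_id", "lon", "lat", "elevation", "environment",
                .predictors)
  # case-insensitive canonicalization of column names
  idx <- match(tolower(required), tolower(names(df)))
  if (anyNA(idx)) {
    miss <- required[is.na(idx)]
    stop("environment table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  out <- df[, idx, drop = FALSE]
  names(out) <- required
  out$plot_id <- as.character(out$plot_id)
  if (anyDuplicated(out$plot_id))
    stop("duplicate plot_id: ",
         paste(unique(out$plot_id[duplicated(out$plot_id)]), collapse = ", "))
  num_cols <- c("lon", "lat", "elevation", .predictors)
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(out[[cl]]))
    if (anyNA(v))
      stop("column '", cl, "' contains missing or non-numeric values")
    out[[cl]] <- v
  }
  out$environment <- as.character(out$environment)
  if (!all(out$HD == round(out$HD)) || any(out$HD < 0) || any(out$HD > 4))
    warning("HD expected to be an integer habitat count in [0, 4]")
  rownames(out) <- NULL
  class(out) <- c("plot_table", "data.frame")
  out
}

#' Read a plot environment table from CSV
#'
#' One row per plot: id, WGS84 coordinates, elevation (m a.s.l.),
#' environment class, and the nine covariates.  Rows with missing
#' covariates are rejected with an explicit error.
#'
#' @param path CSV file path (comma-separated, header, "." decimal).
#' @return a `plot_table`.
#' @export
read_environment_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  plot_table(df)
}

#' Write a plot environment table to CSV
#'
#' @param plots a `plot_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_environment_table <- function(plots, path) {
  write.csv(as.data.frame(plots), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build and validate an occurrence matrix
#'
#' @param mat binary matrix, plots in rows (rownames = plot ids), species
#'   in columns.
#' @param area subplot area in m2.
#' @param plots optional `plot_table`; when given, rows are reordered to
#'   match it and unknown plot ids raise an error.
#' @return a binary integer matrix with attribute `area`, class
#'   `occurrence_matrix`.
#' @export
occurrence_matrix <- function(mat, area, plots = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("occurrence matrix needs plot ids as rownames")
  if (anyDuplicated(colnames(mat)))
    stop("duplicate species columns: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", "))
  bad <- which(!(mat %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(mat)) + 1
    j <- ((bad[1] - 1) %/% nrow(mat)) + 1
    stop(sprintf("occurrence cell [%s, %s] = %s is not in {0, 1}",
                 rownames(mat)[i], colnames(mat)[j], mat[bad[1]]))
  }
  storage.mode(mat) <- "integer"
  if (!is.null(plots)) {
    missing_ids <- setdiff(rownames(mat), plots$plot_id)
    if (length(missing_ids))
      stop("plot id(s) absent from the environment table: ",
           paste(missing_ids, collapse = ", "))
    mat <- mat[match(plots$plot_id, rownames(mat)), , drop = FALSE]
    if (anyNA(rownames(mat)))
      stop("occurrence matrix lacks rows for some plots in the environment table")
  }
  attr(mat, "area") <- as_area(area, "area")
  class(mat) <- c("occurrence_matrix", class(mat))
  mat
}

#' Read an occurrence matrix from CSV
#'
#' First column is the plot id, remaining columns are species with 0/1
#' cells.
#'
#' @param path CSV file path.
#' @param scale scale label (side length by default; see `what`).
#' @param plots optional `plot_table` used to align row order.
#' @param what is `scale` a "side" length or an "area"?
#' @return an `occurrence_matrix`.
#' @export
read_occurrence_matrix <- function(path, scale, plots = NULL,
                                   what = c("side", "area")) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("occurrence CSV needs a plot id column plus species")
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  if (anyNA(mat)) stop("non-numeric occurrence cell in ", path)
  rownames(mat) <- ids
  occurrence_matrix(mat, as_area(scale, match.arg(what)), plots = plots)
}

#' Write an occurrence matrix to CSV
#'
#' @param occ an `occurrence_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrence_matrix <- function(occ, path) {
  df <- data.frame(plot_id = rownames(occ), unclass(occ)[, , drop = FALSE],
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-plot species richness at one scale
#'
#' @param occ an `occurrence_matrix` (or any binary plots x species matrix).
#' @return named integer vector of row sums (one per plot).
#' @export
richness_by_scale <- function(occ) {
  r <- as.integer(rowSums(occ))
  names(r) <- rownames(occ)
  r
}

#' Check nestedness of richness across scales
#'
#' For nested subplots, per-plot richness must be non-decreasing with
#' area.  Field or transcription noise can break this in deposited tables,
#' so violations are reported as warnings, not errors.
#'
#' @param occ_by_scale list of `occurrence_matrix`, any order.
#' @return TRUE invisibly if nested; otherwise FALSE with a warning.
#' @export
check_nestedness <- function(occ_by_scale) {
  areas <- vapply(occ_by_scale, function(m) attr(m, "area"), numeric(1))
  ord <- order(areas)
  rich <- vapply(occ_by_scale[ord], richness_by_scale,
                 integer(nrow(occ_by_scale[[1L]])))
  ok <- all(apply(rich, 1L, function(x) all(diff(x) >= 0)))
  if (!ok)
    warning("per-plot richness decreases with area for some plots ",
            "(nestedness violated)")
  invisible(ok)
}
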