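#' Nested subplot scales
#'
#' The survey design uses square nested subplots sharing a corner, so each
#' larger area contains every smaller one (a "Type I" species accumulation
#' design).  Scales may be labelled either by side length in metres or by
#' area in square metres; the area is always `side^2` exactly.
#'
#' @param side numeric vector of side lengths in metres.  Defaults to the
#'   six canonical sides 0.01, 0.1, 0.5, 1, 5, 10 m (areas 0.0001 to
#'   100 m2).
#' @return a data.frame with columns `side` (m) and `area` (m2), ordered by
#'   increasing area.
#' @export
subplot_scales <- function(side = c(0.01, 0.1, 0.5, 1, 5, 10)) {
  side <- sort(unique(as.numeric(side)))
  if (any(!is.finite(side)) || any(side <= 0))
    stop("subplot side lengths must be positive and finite")
  data.frame(side = side, area = side^2)
}

#' Canonicalize a scale label to an area in m2
#'
#' Deposited occurrence tables label scales by subplot side length while the
#' analysis works in areas; this helper accepts either and returns the area.
#'
#' @param x a single number: a side length (when `what = "side"`) or an
#'   area (when `what = "area"`).
#' @param what one of "side" or "area".
#' @return the area in m2.
#' @export
as_area <- function(x, what = c("side", "area")) {
  what <- match.arg(what)
  x <- as.numeric(x)
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop("scale label must be a single positive number")
  if (what == "side") x^2 else x
}
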