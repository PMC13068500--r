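#' Fit the power-law species-area relationship for one plot
#'
#' Fits `S = c * A^z` to the richness of one set of nested subplots by
#' nonlinear least squares on the untransformed scale (Gaussian error),
#' with starting values from a log-log ordinary least squares fit over the
#' points with `S > 0`.  When NLS fails to converge the log-log OLS fit is
#' returned instead with `converged = FALSE`; the two backends are never
#' silently mixed.  Standard errors come from the asymptotic covariance at
#' the optimum (delta method for `c` on the log-log fallback), and
#' `weight_c = 1/se_c`, `weight_z = 1/se_z` are carried forward so that
#' noisy fits are down-weighted in later trend and driver models.
#'
#' @param areas vector of subplot areas in m2 (>= 3 distinct values).
#' @param richness non-negative integer richness per area; expected
#'   non-decreasing with area (Type I accumulation; violations warn).
#' @return one-row data.frame: `c`, `se_c`, `z`, `se_z`, `r2`,
#'   `converged`, `z_flagged` (TRUE when z falls outside [0, 1]).
#' @export
fit_power_sar <- function(areas, richness) {
  areas <- as.numeric(areas); richness <- as.numeric(richness)
  keep <- is.finite(areas) & is.finite(richness)
  areas <- areas[keep]; richness <- richness[keep]
  if (length(unique(areas)) < 3L)
    stop("need >= 3 distinct areas to fit a SAR")
  if (all(richness == 0)) stop("all-zero richness: no SAR to fit")
  if (any(richness < 0)) stop("negative richness")
  ord <- order(areas)
  if (any(diff(richness[ord]) < 0))
    warning("richness decreases with area: not a Type I accumulation curve")
  pos <- richness > 0
  # log-log OLS start (and fallback)
  if (sum(pos) >= 2L) {
    ll <- lm(log(richness[pos]) ~ log(areas[pos]))
    c0 <- exp(coef(ll)[[1L]]); z0 <- coef(ll)[[2L]]
  } else stop("fewer than 2 positive-richness points: no SAR to fit")
  if (!is.finite(c0) || c0 <= 0) c0 <- mean(richness[pos])
  # noiseless data breaks nls (zero-residual "singular gradient"); the
  # log-log start is then already the exact optimum
  pred0 <- c0 * areas^z0
  tss <- sum((richness - mean(richness))^2)
  if (sum((richness - pred0)^2) <= 1e-12 * max(tss, 1)) {
    n <- length(areas)
    jac <- cbind(areas^z0, c0 * areas^z0 * log(areas))
    sigma2 <- sum((richness - pred0)^2) / max(1L, n - 2L)
    vc <- tryCatch(sigma2 * solve(crossprod(jac)),
                   error = function(e) matrix(0, 2, 2))
    se <- pmax(sqrt(pmax(diag(vc), 0)), .Machine$double.eps)
    out <- data.frame(c = c0, se_c = se[[1L]], z = z0, se_z = se[[2L]],
                      r2 = 1, converged = TRUE)
    out$z_flagged <- out$z < 0 | out$z > 1
    return(out)
  }
  fit <- tryCatch(
    nls(richness ~ c * areas^z,
        start = list(c = c0, z = z0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- coef(fit)
    vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
    se <- sqrt(pmax(diag(vc), 0))
    pred <- est[["c"]] * areas^est[["z"]]
    r2 <- 1 - sum((richness - pred)^2) / sum((richness - mean(richness))^2)
    out <- data.frame(c = est[["c"]], se_c = se[[1L]],
                      z = est[["z"]], se_z = se[[2L]],
                      r2 = r2, converged = TRUE)
  } else {
    # log-log fallback over positive points only
    sm <- summary(ll)$coefficients
    if (nrow(sm) < 2L || !all(is.finite(sm[, 2L]))) {
      # degenerate (e.g. flat curve nls already handles); use z = 0
      out <- data.frame(c = mean(richness[pos]),
                        se_c = stats::sd(richness[pos]) /
                          sqrt(max(1, sum(pos))),
                        z = 0, se_z = NA_real_, r2 = 0, converged = FALSE)
    } else {
      c_hat <- exp(sm[1L, 1L]); z_hat <- sm[2L, 1L]
      pred <- c_hat * areas^z_hat
      r2 <- 1 - sum((richness - pred)^2) / sum((richness - mean(richness))^2)
      out <- data.frame(c = c_hat, se_c = c_hat * sm[1L, 2L],
                        z = z_hat, se_z = sm[2L, 2L],
                        r2 = r2, converged = FALSE)
    }
  }
  out$z_flagged <- out$z < 0 | out$z > 1
  rownames(out) <- NULL
  out
}

#' Fit SARs for every plot across the nested scales
#'
#' @param occ_by_scale list of `occurrence_matrix` covering all scales,
#'   rows aligned to `plots`.
#' @param plots a `plot_table`.
#' @return data.frame with one row per plot: `plot_id`, `elevation`,
#'   `environment`, `c`, `se_c`, `z`, `se_z`, `r2`, `converged`,
#'   `z_flagged`.  Plots whose fit fails are dropped with a warning.
#' @export
fit_all_plots <- function(occ_by_scale, plots) {
  areas <- vapply(occ_by_scale, function(m) attr(m, "area"), numeric(1))
  ord <- order(areas)
  occ_by_scale <- occ_by_scale[ord]; areas <- areas[ord]
  rich <- vapply(occ_by_scale, richness_by_scale,
                 integer(nrow(plots)))
  if (nrow(plots) == 1L) rich <- matrix(rich, nrow = 1L)
  rows <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    fit <- tryCatch(fit_power_sar(areas, rich[i, ]), error = function(e) {
      warning("plot ", plots$plot_id[i], ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(fit)) {
      rows[[i]] <- cbind(data.frame(plot_id = plots$plot_id[i],
                                    elevation = plots$elevation[i],
                                    environment = plots$environment[i],
                                    stringsAsFactors = FALSE),
                         fit)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Pairwise comparisons of c- and z-values across environments
#'
#' Welch two-sample t-tests for every unordered pair of environment
#' classes, for c and z separately.  The original analysis does not state
#' a multiplicity correction, so Holm-adjusted p-values are reported
#' alongside the raw ones.
#'
#' @param fits output of [fit_all_plots()].
#' @param plots a `plot_table` (used only when `fits` lacks an
#'   `environment` column).
#' @return data.frame: `parameter` (c or z), `group1`, `group2`, `t`,
#'   `df`, `p`, `p_holm`.  Groups with fewer than 2 members are excluded
#'   with a warning.
#' @export
compare_environments <- function(fits, plots = NULL) {
  if (!"environment" %in% names(fits)) {
    fits$environment <- plots$environment[match(fits$plot_id, plots$plot_id)]
  }
  counts <- table(fits$environment)
  drop <- names(counts)[counts < 2L]
  if (length(drop))
    warning("excluding group(s) with < 2 members: ",
            paste(drop, collapse = ", "))
  groups <- setdiff(names(counts), drop)
  if (length(groups) < 2L) stop("need >= 2 environment groups with >= 2 members")
  pairs <- utils::combn(sort(groups), 2L)
  res <- list()
  for (param in c("c", "z")) {
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- fits[[param]][fits$environment == pairs[1L, j]]
      g2 <- fits[[param]][fits$environment == pairs[2L, j]]
      if (stats::sd(g1) == 0 && stats::sd(g2) == 0 && mean(g1) == mean(g2)) {
        tt <- list(statistic = c(t = 0), parameter = c(df = length(g1) +
                                                         length(g2) - 2),
                   p.value = 1)
      } else tt <- t.test(g1, g2)
      data.frame(parameter = param,
                 group1 = pairs[1L, j], group2 = pairs[2L, j],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    block$p_holm <- p.adjust(block$p, method = "holm")
    res[[param]] <- block
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
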