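# Full-study orchestration: (load | synthesize) -> SAR fits -> MDE ->
# trends -> BRT drivers -> scale regressions -> sensitivity, with seeded
# stages and a JSON run-metadata sidecar.

# small FNV-1a hash so every output can carry a config fingerprint
# without external dependencies
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = 10)
  bytes <- utf8ToInt(as.character(s))
  h <- 216613626  # kept below 2^31 so bitwXor stays in integer range
  for (b in bytes) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483648
  }
  sprintf("%08x", as.integer(h))
}

#' Build a pipeline run configuration
#'
#' Either point at deposited CSV tables (`env_path` + `occ_paths`, the
#' latter a named vector keyed by subplot side length in metres) or leave
#' them NULL to synthesize data from `truth`.
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param env_path,occ_paths input CSVs (NULL = synthetic).
#' @param truth a [synthetic_truth()] (used when inputs are NULL).
#' @param n_plots plots to synthesize.
#' @param mde_n_sims MDE Monte Carlo simulations (design value 100000).
#' @param gam_k spline basis dimension (design value 5).
#' @param moran_k,moran_n_perm Moran's I neighbours and permutations
#'   (design values 5 and 999).
#' @param brt_grid meta-parameter grid (design default the 360-point
#'   grid; pass `default_brt_grid(reduced = TRUE)` for smoke runs).
#' @param max_trees,step_size boosting schedule.
#' @param sensitivity_n_iter perturbation iterations (design value 1000).
#' @param noise_frac perturbation noise fraction (design value 0.05).
#' @param run_sensitivity responses to run sensitivity checks on
#'   (subset of `c("c", "z")` and `"richness_<area>"`; NULL = none).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, env_path = NULL, occ_paths = NULL,
                       truth = synthetic_truth(seed = seed), n_plots = 56L,
                       mde_n_sims = 100000L, gam_k = 5L, moran_k = 5L,
                       moran_n_perm = 999L, brt_grid = default_brt_grid(),
                       max_trees = 10000L, step_size = 50L,
                       sensitivity_n_iter = 1000L, noise_frac = 0.05,
                       run_sensitivity = c("c", "z")) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              env_path = env_path, occ_paths = occ_paths, truth = truth,
              n_plots = as.integer(n_plots),
              mde_n_sims = as.integer(mde_n_sims), gam_k = as.integer(gam_k),
              moran_k = as.integer(moran_k),
              moran_n_perm = as.integer(moran_n_perm),
              brt_grid = brt_grid, max_trees = as.integer(max_trees),
              step_size = as.integer(step_size),
              sensitivity_n_iter = as.integer(sensitivity_n_iter),
              noise_frac = noise_frac, run_sensitivity = run_sensitivity)
  cfg$hash <- .config_hash(cfg[setdiff(names(cfg), c("out_dir", "truth"))])
  class(cfg) <- "run_config"
  cfg
}

.stage_seed <- function(cfg, stage) {
  # deterministic per-stage sub-seed, kept below 2^31
  (cfg$seed * 1000L + match(stage, c("data", "sar", "mde", "trends",
                                     "brt", "scaling", "sensitivity"))) %%
    2147483647L
}

.write_stage <- function(df, cfg, name) {
  path <- file.path(cfg$out_dir, paste0(name, ".csv"))
  df$config_hash <- cfg$hash
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Emits per-stage tidy CSVs under `config$out_dir`: `sar_fits`,
#' `environment_tests`, `mde_<area>`, `trends` (8 responses: c, z, and
#' richness at each scale), `brt_summary`, `importance`, `scaling`
#' (importance and R2 vs log10 area for the richness models), optional
#' `sensitivity_*`, plus a Table-1-shaped `richness_summary` and a
#' `run_metadata.json` sidecar.  Every CSV row carries the config hash.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with all stage results, invisibly.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[mossar] ", ...)
  scales <- subplot_scales()

  # -- data ----------------------------------------------------------
  if (!is.null(config$env_path)) {
    say("loading deposited tables")
    plots <- read_environment_table(config$env_path)
    occ <- lapply(names(config$occ_paths), function(sd)
      read_occurrence_matrix(config$occ_paths[[sd]], as.numeric(sd),
                             plots = plots, what = "side"))
    names(occ) <- vapply(occ, function(m) as.character(attr(m, "area")),
                         character(1))
    occ <- occ[order(as.numeric(names(occ)))]
  } else {
    say("synthesizing data (seed ", config$seed, ")")
    plots <- generate_environment(n_plots = config$n_plots,
                                  seed = .stage_seed(config, "data"))
    occ <- generate_community(plots, config$truth,
                              seed = .stage_seed(config, "data"))
  }
  check_nestedness(occ)
  areas <- as.numeric(names(occ))

  # -- SAR fits ------------------------------------------------------
  say("fitting per-plot SARs")
  sar <- fit_all_plots(occ, plots)
  .write_stage(sar, config, "sar_fits")
  env_tests <- tryCatch(compare_environments(sar), error = function(e) NULL)
  if (!is.null(env_tests)) .write_stage(env_tests, config, "environment_tests")

  # -- MDE -----------------------------------------------------------
  say("MDE null model (", config$mde_n_sims, " sims/scale)")
  mde <- mde_by_scale(occ, plots, n_sims = config$mde_n_sims,
                      seed = .stage_seed(config, "mde"))
  for (a in names(mde))
    .write_stage(as.data.frame(mde[[a]]), config, paste0("mde_", a))

  # -- responses ------------------------------------------------------
  idx <- match(sar$plot_id, plots$plot_id)
  responses <- list(
    c = list(y = sar$c, w = 1 / sar$se_c, rows = idx, mde = FALSE),
    z = list(y = sar$z, w = 1 / sar$se_z, rows = idx, mde = FALSE))
  for (a in names(occ))
    responses[[paste0("richness_", a)]] <-
      list(y = as.numeric(richness_by_scale(occ[[a]])),
           w = NULL, rows = seq_len(nrow(plots)), mde = TRUE, area = a)

  # -- trends --------------------------------------------------------
  say("elevational trends (GAM + Moran + model choice)")
  trend_rows <- list()
  for (nm in names(responses)) {
    r <- responses[[nm]]
    pl <- plots[r$rows, , drop = FALSE]
    w <- r$w
    if (!is.null(w) && any(!is.finite(w))) w <- pmin(w, max(w[is.finite(w)]))
    ch <- spatial_decision(r$y, pl$elevation, pl$lon, pl$lat, weights = w,
                           k = config$gam_k, k_neighbors = config$moran_k,
                           n_perm = config$moran_n_perm,
                           seed = .stage_seed(config, "trends"))
    trend_rows[[nm]] <- data.frame(
      response = nm, r2 = ch$m1$r2, dev_expl = ch$m1$dev_expl,
      p_smooth = ch$m1$p_smooth,
      peak_elevation = ch$m1$peak_elevation,
      peak_strength = ch$m1$peak_strength,
      moran_I = ch$moran_on_m1$I, moran_p = ch$moran_on_m1$p_perm,
      r2_m2 = ch$r2_m2, r2_m3 = ch$r2_m3, decision = ch$decision,
      stringsAsFactors = FALSE)
  }
  trends <- do.call(rbind, trend_rows)
  rownames(trends) <- NULL
  .write_stage(trends, config, "trends")

  # -- BRT drivers ---------------------------------------------------
  say("BRT driver models (", nrow(config$brt_grid), "-point grid)")
  brt_rows <- list(); imp_rows <- list(); models <- list()
  for (nm in names(responses)) {
    r <- responses[[nm]]
    pl <- plots[r$rows, , drop = FALSE]
    X <- as.data.frame(pl)[, predictor_names()]
    if (r$mde) X$MDE <- mde[[r$area]]$expected[r$rows]
    w <- r$w
    if (!is.null(w) && any(!is.finite(w))) w <- pmin(w, max(w[is.finite(w)]))
    model <- tune_brt(X, r$y, weights = w, grid = config$brt_grid,
                      strata = pl$elevation, max_trees = config$max_trees,
                      step_size = config$step_size,
                      seed = .stage_seed(config, "brt"))
    imp <- conditional_importance(model, X, r$y,
                                  seed = .stage_seed(config, "brt"))
    mor <- residual_spatial_check(model, X, r$y, pl$lon, pl$lat,
                                  k_neighbors = config$moran_k,
                                  n_perm = config$moran_n_perm,
                                  seed = .stage_seed(config, "brt"))
    brt_rows[[nm]] <- data.frame(
      response = nm,
      tree_complexity = model$config$tree_complexity,
      learning_rate = model$config$learning_rate,
      bag_fraction = model$config$bag_fraction,
      n_trees_opt = model$n_trees_opt, cv_deviance = model$cv_deviance,
      cv_correlation = model$cv_correlation, pseudo_r2 = model$pseudo_r2,
      rmse = unname(model$rmse), mae = unname(model$mae),
      r2 = unname(model$r2),
      resid_moran_I = mor$I, resid_moran_p = mor$p_perm,
      stringsAsFactors = FALSE)
    imp$response <- nm
    imp_rows[[nm]] <- imp
    models[[nm]] <- model
  }
  brt_summary <- do.call(rbind, brt_rows)
  rownames(brt_summary) <- NULL
  importance <- do.call(rbind, imp_rows)
  rownames(importance) <- NULL
  .write_stage(brt_summary, config, "brt_summary")
  .write_stage(importance, config, "importance")

  # -- scale regressions ---------------------------------------------
  say("scale regressions")
  rich_names <- paste0("richness_", names(occ))
  imp_rich <- importance[importance$response %in% rich_names, , drop = FALSE]
  imp_rich$area <- as.numeric(sub("richness_", "", imp_rich$response))
  r2_rich <- data.frame(
    area = as.numeric(sub("richness_", "", rich_names)),
    r2 = brt_summary$r2[match(rich_names, brt_summary$response)])
  scaling <- scale_regressions(imp_rich, r2_rich)
  .write_stage(scaling, config, "scaling")

  # -- sensitivity ---------------------------------------------------
  sens <- list()
  for (nm in intersect(config$run_sensitivity, names(responses))) {
    say("sensitivity checks: ", nm)
    r <- responses[[nm]]
    pl <- plots[r$rows, , drop = FALSE]
    X <- as.data.frame(pl)[, predictor_names()]
    if (r$mde) X$MDE <- mde[[r$area]]$expected[r$rows]
    d1 <- drop_one_analysis(models[[nm]], X, r$y,
                            seed = .stage_seed(config, "sensitivity"))
    pert <- perturbation_analysis(models[[nm]], X, r$y,
                                  noise_frac = config$noise_frac,
                                  n_iter = config$sensitivity_n_iter,
                                  seed = .stage_seed(config, "sensitivity"))
    .write_stage(d1, config, paste0("sensitivity_drop_one_", nm))
    .write_stage(data.frame(t(pert$summary), baseline_r2 = pert$baseline_r2),
                 config, paste0("sensitivity_perturbation_", nm))
    sens[[nm]] <- list(drop_one = d1, perturbation = pert)
  }

  # -- Table-1-shaped richness summary -------------------------------
  rich_trends <- trends[trends$response %in% rich_names, , drop = FALSE]
  summary_tbl <- data.frame(
    area = as.numeric(sub("richness_", "", rich_trends$response)),
    peak_elevation = rich_trends$peak_elevation,
    peak_strength = rich_trends$peak_strength,
    gam_r2 = rich_trends$r2, gam_p_smooth = rich_trends$p_smooth,
    brt_rmse = brt_summary$rmse[match(rich_trends$response,
                                      brt_summary$response)],
    brt_mae = brt_summary$mae[match(rich_trends$response,
                                    brt_summary$response)],
    brt_r2 = brt_summary$r2[match(rich_trends$response,
                                  brt_summary$response)])
  .write_stage(summary_tbl, config, "richness_summary")

  meta <- list(seed = config$seed, config_hash = config$hash,
               n_plots = nrow(plots), n_scales = length(occ),
               mde_n_sims = config$mde_n_sims,
               brt_grid_size = nrow(config$brt_grid),
               package_version = as.character(utils::packageVersion("mossar")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(plots = plots, occ = occ, sar = sar, env_tests = env_tests,
                 mde = mde, trends = trends, brt_summary = brt_summary,
                 importance = importance, models = models,
                 scaling = scaling, sensitivity = sens,
                 richness_summary = summary_tbl, config = config))
}
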