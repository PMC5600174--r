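#' Pipeline configuration
#'
#' One validated, serializable object holds every stage's parameters.
#' Defaults follow the study protocol: 20 BCT runs, 59 nests, 100 transect
#' units of 229 m, 5% right truncation (125 m), three-filter-style SEVM
#' selection at alpha 0.05, quantiles 0.1/0.5/0.9, 1,000 population
#' bootstraps. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see [pipeline_defaults()])
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$mode %in% c("synthetic", "real"),
            cfg$n_runs >= 1, cfg$n_nests >= 1, cfg$n_units >= 3,
            cfg$alpha > 0, cfg$alpha <= 1,
            all(cfg$taus > 0 & cfg$taus < 1),
            cfg$n_boot_pop >= 2, cfg$master_seed == round(cfg$master_seed))
  if (cfg$mode == "real") {
    need <- c("stack_dir", "nests_csv", "contacts_csv", "units_csv")
    missing_paths <- need[vapply(need, function(k) is.null(cfg[[k]]),
                                 logical(1))]
    if (length(missing_paths))
      stop("real mode requires path(s): ",
           paste(missing_paths, collapse = ", "))
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(
    mode = "synthetic",
    # synthetic world
    grid_nrow = 100L, grid_ncol = 100L, cell_size = 50,
    cor_range = 8, cross_cor = 0.5, lapse_weight = 0.7,
    ranges = list(),
    truth_terms = NULL,      # NULL = truth_params() defaults
    lambda1 = 1.4, sigma_true = 60,
    n_nests = 59L, n_units = 100L, unit_length = 229,
    years = 15L, w_max = 125,
    # real-mode paths
    stack_dir = NULL, nests_csv = NULL, contacts_csv = NULL,
    units_csv = NULL, transect_length_km = 22.9,
    # suitability stage
    n_runs = 20L, hp = list(), exclude_presence = TRUE,
    # detection stage
    truncate_pct = 5, fixed_w = NULL,
    # abundance link stage
    alpha = 0.05, taus = c(0.1, 0.5, 0.9), n_perm = 999, n_boot_qr = 999,
    # population stage
    n_boot_pop = 1000L, area_scale = 1,
    master_seed = 1L)
}

config_hp <- function(cfg) do.call(bct_hyperparams, cfg$hp)

config_truth <- function(cfg) {
  if (is.null(cfg$truth_terms)) truth_params(lambda1 = cfg$lambda1,
                                             sigma_true = cfg$sigma_true)
  else truth_params(terms = cfg$truth_terms, lambda1 = cfg$lambda1,
                    sigma_true = cfg$sigma_true)
}

#' Read / write a pipeline configuration (JSON or YAML by extension)
#'
#' @param cfg a [pipeline_config()]
#' @param path file ending in `.json`, `.yaml` or `.yml`
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.json$", path))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  else if (grepl("\\.ya?ml$", path))
    yaml::write_yaml(x, path)
  else stop("config path must end in .json or .yaml/.yml")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else stop("config path must end in .json or .yaml/.yml")
  x <- x[!vapply(x, is.null, logical(1))]
  do.call(pipeline_config, x)
}

load_real_inputs <- function(cfg) {
  # fail fast on every path before any computation
  for (k in c("nests_csv", "contacts_csv", "units_csv"))
    if (!file.exists(cfg[[k]]))
      stop("input file not found: ", cfg[[k]], " (", k, ")")
  if (!dir.exists(cfg$stack_dir))
    stop("stack directory not found: ", cfg$stack_dir)
  layers <- lapply(predictor_names(), function(nm) {
    p <- file.path(cfg$stack_dir, paste0(nm, ".asc"))
    if (!file.exists(p)) stop("missing raster layer file: ", p)
    read_raster(p)
  })
  names(layers) <- predictor_names()
  contacts <- read.csv(cfg$contacts_csv)
  for (col in c("unit_id", "year", "distance_m"))
    if (!col %in% names(contacts))
      stop("contacts CSV is missing column `", col, "`")
  units <- read_points_csv(cfg$units_csv)
  if (!"unit_id" %in% names(units)) stop("units CSV is missing `unit_id`")
  list(stack = env_stack(layers), nests = read_points_csv(cfg$nests_csv),
       contacts = contacts, units = units)
}

#' Run the full pipeline
#'
#' Executes the stages in order -- generate/ingest, suitability ensemble,
#' detection fit, abundance link, population estimate -- and, if `out_dir`
#' is given, writes every stage output (JSON/CSV/ASCII grid) together with
#' the archived configuration, its hash, and a provenance log.
#'
#' @param cfg a [pipeline_config()]
#' @param out_dir output directory (created); `NULL` = return only
#' @return list of class `pipeline_result` with `stack`, `nests`, `ensemble`,
#'   `suitability` (map), `areas`, `detection`, `link`, `population`,
#'   `config`, `truth` (synthetic mode only)
#' @export
run_full <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("finchsdm %s", as.character(utils::packageVersion("finchsdm"))),
                 sprintf("config hash %s", digest::digest(unclass(cfg))),
                 sprintf("master seed %d", cfg$master_seed))
  seed_of <- function(stage) derive_seed(cfg$master_seed, stage)

  truth <- NULL
  if (cfg$mode == "synthetic") {
    lc <- landscape_config(nrow = cfg$grid_nrow, ncol = cfg$grid_ncol,
                           cell_size = cfg$cell_size,
                           ranges = cfg$ranges,
                           cor_range = cfg$cor_range,
                           cross_cor = cfg$cross_cor,
                           lapse_weight = cfg$lapse_weight,
                           seed = seed_of("landscape"))
    stack <- generate_landscape(lc)
    tp <- config_truth(cfg)
    suit_true <- true_suitability(stack, tp)
    nests <- simulate_nests(suit_true, n = cfg$n_nests,
                            seed = seed_of("nests"))
    units <- make_transect_units(suit_true, n_units = cfg$n_units,
                                 unit_length = cfg$unit_length)
    sim <- simulate_transects(suit_true, units, tp,
                              years = seq_len(cfg$years),
                              w_max = cfg$w_max,
                              seed = seed_of("transects"))
    contacts <- sim$distances
    counts <- sim$counts
    truth <- list(params = tp, suitability = suit_true,
                  true_population = tp$lambda1 *
                    sum(cells_200m(suit_true)$values, na.rm = TRUE))
    presence_cells <- nests$cell
  } else {
    inputs <- load_real_inputs(cfg)
    stack <- inputs$stack
    nests <- inputs$nests
    contacts <- inputs$contacts
    units <- inputs$units
    counts <- contacts  # counts reconstructed below from contacts
    presence_cells <- cells_at_points(stack$layers[[1]], nests)$cell
  }
  log_lines <- c(log_lines, sprintf("stage ingest done at +%.1fs",
                                    as.numeric(Sys.time() - t0, "secs")))

  ens <- run_ensemble(stack, presence_cells, hp = config_hp(cfg),
                      n_runs = cfg$n_runs, master_seed = seed_of("ensemble"),
                      exclude_presence = cfg$exclude_presence)
  suit_map <- ens$prediction
  areas <- area_by_suitability(suit_map)
  log_lines <- c(log_lines, sprintf("stage suitability done at +%.1fs",
                                    as.numeric(Sys.time() - t0, "secs")))

  det <- fit_detection(contacts$distance_m, pct = cfg$truncate_pct,
                       w = cfg$fixed_w,
                       L_km = if (cfg$mode == "synthetic")
                         cfg$n_units * cfg$unit_length / 1000
                       else cfg$transect_length_km,
                       n_surveys = if (cfg$mode == "synthetic") cfg$years
                       else length(unique(contacts$year)),
                       seed = seed_of("detection"))
  log_lines <- c(log_lines, sprintf("stage detection done at +%.1fs",
                                    as.numeric(Sys.time() - t0, "secs")))

  # mean detected count per unit across years
  if (cfg$mode == "synthetic") {
    mean_count <- tapply(counts$n_detected,
                         factor(counts$unit_id, levels = units$unit_id),
                         mean)
  } else {
    yrs <- length(unique(contacts$year))
    tab <- table(factor(contacts$unit_id, levels = units$unit_id))
    mean_count <- as.numeric(tab) / yrs
  }
  units_df <- data.frame(unit_id = units$unit_id, x = units$x, y = units$y,
                         mean_count = as.numeric(mean_count))
  link <- link_abundance(units_df, suit_map, alpha = cfg$alpha,
                         taus = cfg$taus, n_perm = cfg$n_perm,
                         n_boot = cfg$n_boot_qr, seed = seed_of("link"))
  log_lines <- c(log_lines, sprintf("stage link done at +%.1fs",
                                    as.numeric(Sys.time() - t0, "secs")))

  pop <- population_from_map(suit_map,
                             intercept = link$ols$coefficients["intercept"],
                             slope = link$ols$coefficients["suitability"],
                             pdet = det$pdet, n_boot = cfg$n_boot_pop,
                             seed = seed_of("population"),
                             area_scale = cfg$area_scale)
  log_lines <- c(log_lines, sprintf("stage population done at +%.1fs",
                                    as.numeric(Sys.time() - t0, "secs")))

  res <- structure(list(stack = stack, nests = nests, units = units_df,
                        ensemble = ens, suitability = suit_map,
                        areas = areas, detection = det, link = link,
                        population = pop, config = cfg, truth = truth,
                        log = log_lines),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- res$config
  write_config(cfg, file.path(out_dir, "config.json"))
  jsonlite::write_json(
    list(config_hash = digest::digest(unclass(cfg)),
         metrics = res$ensemble$metrics), file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(predictor = names(res$ensemble$importance),
                       importance_pct = as.numeric(res$ensemble$importance)),
            file.path(out_dir, "importance.csv"), row.names = FALSE)
  pd <- do.call(rbind, lapply(names(res$ensemble$partial_dependence),
                              function(v) cbind(variable = v,
                                                res$ensemble$partial_dependence[[v]])))
  write.csv(pd, file.path(out_dir, "partial_dependence.csv"),
            row.names = FALSE)
  write_raster(res$suitability, file.path(out_dir, "suitability.asc"))
  write.csv(res$areas$classes, file.path(out_dir, "area_by_class.csv"),
            row.names = FALSE)
  jsonlite::write_json(unclass(res$detection),
                       file.path(out_dir, "detection.json"),
                       auto_unbox = TRUE, digits = NA)
  lk <- res$link
  jsonlite::write_json(
    list(r_squared = lk$ols$r_squared,
         coefficients = as.list(lk$ols$coefficients),
         hc4m_se = as.list(lk$ols$se), p = as.list(lk$ols$p),
         n_filters = lk$n_filters,
         residual_moran_I = lk$selection$residual_I,
         residual_moran_p = lk$selection$residual_p,
         partition = lk$partition, quantiles = lk$quantiles),
    file.path(out_dir, "link.json"), auto_unbox = TRUE, digits = NA)
  pp <- res$population
  jsonlite::write_json(
    list(total = pp$total, ci_low = pp$ci[1], ci_high = pp$ci[2],
         n_cells = pp$n_cells, pdet = pp$pdet,
         intercept = unname(pp$intercept), slope = unname(pp$slope)),
    file.path(out_dir, "population.json"), auto_unbox = TRUE, digits = NA)
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$ensemble)
  print(x$detection)
  print(x$link)
  print(x$population)
  invisible(x)
}

#' Synthetic recovery experiment across many worlds
#'
#' Generates `n_worlds` independent synthetic landscapes with known truth,
#' runs the pipeline on each, and reports per-world recovery diagnostics:
#' the ensemble CV-AUC, whether the truth-driving predictors rank top-2 in
#' importance, the sign and p-value of the suitability slope, and whether
#' the bootstrap 95% CI covers the true simulated population. With
#' `use_bct = FALSE` the true suitability surface stands in for the fitted
#' map (isolating the detection/link/population stages).
#'
#' @param n_worlds number of worlds (>= 1)
#' @param cfg a [pipeline_config()] (synthetic mode)
#' @param seed integer master seed; world `i` uses a seed derived from it
#' @param use_bct fit the BCT ensemble per world (default TRUE)
#' @return list: `worlds` (data.frame, one row per world) and `summary`
#' @export
recovery_experiment <- function(n_worlds, cfg = pipeline_config(),
                                seed = 1L, use_bct = TRUE) {
  stopifnot(n_worlds >= 1, inherits(cfg, "pipeline_config"),
            cfg$mode == "synthetic")
  tp <- config_truth(cfg)
  drivers <- names(tp$terms)
  rows <- vector("list", n_worlds)
  for (wi in seq_len(n_worlds)) {
    sw <- derive_seed(seed, paste0("world-", wi))
    lc <- landscape_config(nrow = cfg$grid_nrow, ncol = cfg$grid_ncol,
                           cell_size = cfg$cell_size,
                           ranges = cfg$ranges,
                           cor_range = cfg$cor_range,
                           cross_cor = cfg$cross_cor,
                           lapse_weight = cfg$lapse_weight,
                           seed = derive_seed(sw, "landscape"))
    stack <- generate_landscape(lc)
    suit_true <- true_suitability(stack, tp)
    true_pop <- tp$lambda1 * sum(cells_200m(suit_true)$values, na.rm = TRUE)
    auc <- NA_real_; top2 <- NA
    if (use_bct) {
      nests <- simulate_nests(suit_true, n = cfg$n_nests,
                              seed = derive_seed(sw, "nests"))
      ens <- run_ensemble(stack, nests$cell, hp = config_hp(cfg),
                          n_runs = cfg$n_runs,
                          master_seed = derive_seed(sw, "ensemble"),
                          exclude_presence = cfg$exclude_presence,
                          predict_stack = TRUE, pd_grid_n = 25L)
      auc <- ens$metrics$mean[ens$metrics$metric == "cv_auc"]
      ranked <- names(sort(ens$importance, decreasing = TRUE))
      top2 <- all(head(ranked, 2) %in% drivers)
      suit_map <- ens$prediction
    } else {
      suit_map <- suit_true
    }
    units <- make_transect_units(suit_true, n_units = cfg$n_units,
                                 unit_length = cfg$unit_length)
    sim <- simulate_transects(suit_true, units, tp,
                              years = seq_len(cfg$years), w_max = cfg$w_max,
                              seed = derive_seed(sw, "transects"))
    det <- fit_detection(sim$distances$distance_m, w = cfg$w_max,
                         seed = derive_seed(sw, "detection"))
    mean_count <- tapply(sim$counts$n_detected,
                         factor(sim$counts$unit_id, levels = units$unit_id),
                         mean)
    units_df <- data.frame(unit_id = units$unit_id, x = units$x,
                           y = units$y,
                           mean_count = as.numeric(mean_count))
    suit_u <- suitability_at_units(suit_map, units_df)
    ols <- ols_hc4m(units_df$mean_count,
                    cbind(intercept = 1, suitability = suit_u))
    pop <- population_from_map(suit_map,
                               intercept = ols$coefficients["intercept"],
                               slope = ols$coefficients["suitability"],
                               pdet = det$pdet, n_boot = cfg$n_boot_pop,
                               seed = derive_seed(sw, "population"),
                               area_scale = cfg$area_scale)
    rows[[wi]] <- data.frame(
      world = wi, cv_auc = auc, top2_importance = top2,
      slope = unname(ols$coefficients["suitability"]),
      slope_p = unname(ols$p["suitability"]),
      pdet = det$pdet, true_population = true_pop,
      est_population = pop$total, ci_low = pop$ci[1], ci_high = pop$ci[2],
      covered = pop$ci[1] <= true_pop && true_pop <= pop$ci[2])
  }
  worlds <- do.call(rbind, rows)
  list(worlds = worlds,
       summary = list(
         mean_auc = mean(worlds$cv_auc),
         top2_rate = mean(worlds$top2_importance),
         slope_positive_rate = mean(worlds$slope > 0),
         slope_significant_rate = mean(worlds$slope_p < 0.05),
         coverage = mean(worlds$covered)))
}
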