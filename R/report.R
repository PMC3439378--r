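ANALYSIS_CONFIG_KEYS <- c("input", "synthetic", "schema", "grid",
                          "covariates", "interactions", "stratify_by",
                          "level", "out_dir", "seed", "currency",
                          "report_scale")

#' Load an analysis configuration
#'
#' Reads a YAML configuration describing one full analysis run. Exactly one
#' of `input` (path to a CSV dataset) and `synthetic` must be given;
#' `synthetic: default` (or `true`) selects the calibrated Nouna
#' configuration, and a mapping under `synthetic` overrides its fields.
#' Unknown keys and invalid values are rejected by name. Remaining keys
#' receive defaults: the 0–2,500,000 by 100,000 ceiling grid, confidence
#' level 0.95, currency `"XOF"`, seed 1, per-unit report scale.
#'
#' @param path path to a YAML file.
#' @return object of class `analysis_config` (a named list).
#' @export
load_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), ANALYSIS_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  analysis_config(raw)
}

analysis_config <- function(opts) {
  has_input <- !is.null(opts$input)
  has_syn <- !is.null(opts$synthetic) && !identical(opts$synthetic, FALSE)
  if (has_input == has_syn)
    stop("exactly one of 'input' and 'synthetic' must be set", call. = FALSE)
  level <- opts$level %||% 0.95
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("invalid value for key 'level': must lie strictly in (0, 1)",
         call. = FALSE)
  grid <- opts$grid
  grid <- if (is.null(grid)) ceiling_grid()
          else if (is.list(grid))
            ceiling_grid(grid$start %||% 0, grid$stop %||% 2.5e6,
                         grid$step %||% 1e5, values = grid$values)
          else ceiling_grid(values = grid)
  seed <- as.integer(opts$seed %||% 1L)
  syn <- NULL
  if (has_syn) {
    syn <- default_nouna_config(seed = seed)
    if (is.list(opts$synthetic)) {
      bad <- setdiff(names(opts$synthetic), names(unclass(syn)))
      if (length(bad))
        stop("unknown synthetic key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      for (k in names(opts$synthetic)) syn[[k]] <- opts$synthetic[[k]]
      syn <- do.call(synthetic_config, unclass(syn))
    }
    syn$seed <- seed
  }
  structure(list(input = opts$input, synthetic = syn,
                 schema = opts$schema, grid = grid,
                 covariates = opts$covariates %||% character(),
                 interactions = isTRUE(opts$interactions),
                 stratify_by = opts$stratify_by,
                 level = level,
                 out_dir = opts$out_dir %||% "nbcea-results",
                 seed = seed,
                 currency = opts$currency %||% "XOF",
                 report_scale = match.arg(opts$report_scale %||% "unit",
                                          c("unit", "percentage_point"))),
            class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full net-benefit cost-effectiveness analysis
#'
#' Executes the complete pipeline described by an [analysis
#' config][load_analysis_config()]: load or generate the dataset, validate
#' it, compute arm summaries and increments/ICER (overall and, when
#' requested, stratified), fit the net-benefit regression over the ceiling
#' grid, and build overall, subgroup and adjusted acceptability curves.
#' Tables are written as CSV, curves additionally as a PNG figure, and a
#' plain-text log records the seed, record counts and complete-case drops.
#' Every number in the bundle is reproducible by calling the underlying
#' functions directly with the same configuration.
#'
#' @param config an `analysis_config` (or path to a YAML file).
#' @return invisibly, a list with the in-memory results (`dataset`,
#'   `summaries`, `incremental`, `fits`, `ceac`, and when configured
#'   `subgroups`, `adjusted`) plus `files`, the paths written.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- load_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("nbcea run: %s", format(Sys.time())),
                 sprintf("seed: %d", config$seed))

  dataset <- if (!is.null(config$input)) {
    read_cea_dataset(config$input, schema = config$schema,
                     currency = config$currency)
  } else generate_cea(config$synthetic)
  if (nrow(dataset) == 0) stop("dataset is empty", call. = FALSE)
  violations <- validate_cea_dataset(dataset)
  if (nrow(violations))
    stop(sprintf("dataset fails validation (%d violation(s)); first: %s/%s: %s",
                 nrow(violations), violations$household_id[1],
                 violations$field[1], violations$rule[1]), call. = FALSE)
  log_lines <- c(log_lines,
                 sprintf("records: %d (%d intervention, %d comparison)",
                         nrow(dataset), sum(dataset$treated == 1),
                         sum(dataset$treated == 0)))

  out <- function(name) file.path(config$out_dir, name)
  files <- character()

  summaries <- summarize_groups(dataset)
  utils::write.csv(as.data.frame(summaries), out("group_summary.csv"),
                   row.names = FALSE, na = "")
  files <- c(files, out("group_summary.csv"))

  inc <- incremental(summaries)
  inc_df <- data.frame(stratum = "overall", delta_cost = inc$delta_cost,
                       se_delta_cost = inc$se_delta_cost,
                       delta_effect = inc$delta_effect,
                       icer = inc$icer, icer_per_point = inc$icer_per_point,
                       quadrant = inc$quadrant)
  if (!is.null(config$stratify_by)) {
    lv <- sort(unique(dataset[[config$stratify_by]]))
    for (l in lv[!is.na(lv)]) {
      si <- incremental(summarize_groups(dataset, by = config$stratify_by,
                                         level = l))
      inc_df <- rbind(inc_df, data.frame(
        stratum = sprintf("%s=%s", config$stratify_by, format(l)),
        delta_cost = si$delta_cost, se_delta_cost = si$se_delta_cost,
        delta_effect = si$delta_effect, icer = si$icer,
        icer_per_point = si$icer_per_point, quadrant = si$quadrant))
    }
  }
  utils::write.csv(inc_df, out("increments.csv"), row.names = FALSE, na = "")
  files <- c(files, out("increments.csv"))

  fits <- lapply(as.numeric(config$grid), function(lam)
    fit_nb_simple(dataset, lam))
  fit_df <- do.call(rbind, lapply(fits, function(f)
    data.frame(lambda = f$lambda, delta = f$delta, se = f$delta_se,
               p_value = f$delta_p, adj_r_squared = f$adj_r_squared,
               f_statistic = f$f_statistic)))
  utils::write.csv(fit_df, out("nb_regression.csv"), row.names = FALSE,
                   na = "")
  files <- c(files, out("nb_regression.csv"))

  curves <- list(overall = build_ceac(dataset, config$grid))
  results <- list(dataset = dataset, summaries = summaries,
                  incremental = inc, fits = fits, ceac = curves$overall)
  if (!is.null(config$stratify_by)) {
    results$subgroups <- subgroup_ceacs(dataset, config$grid,
                                        config$stratify_by)
    curves <- c(curves, results$subgroups)
  }
  if (length(config$covariates)) {
    results$adjusted <- adjusted_ceac(dataset, config$grid,
                                      config$covariates,
                                      interactions = config$interactions)
    curves$adjusted <- results$adjusted
    n_drop <- fit_nb_adjusted(dataset, 0, config$covariates)$n_dropped
    log_lines <- c(log_lines,
                   sprintf("complete-case drops (adjusted model): %d", n_drop))
  }
  write_ceac(curves, out("ceac.csv"))
  files <- c(files, out("ceac.csv"))
  gg <- plot_ceac(curves, currency = config$currency)
  ggplot2::ggsave(out("ceac.png"), gg, width = 7, height = 5, dpi = 150)
  files <- c(files, out("ceac.png"))

  crossing <- icer_from_ceac(curves$overall)
  ci <- ci_from_ceac(curves$overall, config$level)
  log_lines <- c(log_lines,
                 sprintf("CEAC 50%% crossing (overall): %s",
                         format(crossing, big.mark = ",")),
                 sprintf("CEAC %g%% interval: [%s, %s]", 100 * config$level,
                         format(ci[["lower"]], big.mark = ","),
                         format(ci[["upper"]], big.mark = ",")))
  writeLines(log_lines, out("run_log.txt"))
  files <- c(files, out("run_log.txt"))

  results$files <- files
  invisible(results)
}
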