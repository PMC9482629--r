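## cli_runner module: orchestration of the scenario grid, the systematic
## sensitivity sweep, reporting and provenance manifests.

#' Run one policy scenario end to end
#'
#' Builds the compliance map, splits the accounts, calibrates, solves the
#' no-restriction baseline and the frozen counterfactual, and assembles the
#' land-change, leakage and emissions reports.
#'
#' @param world a `"soy_world"`.
#' @param spec a [scenario_spec()].
#' @param drivers a `"soy_shocks"`; defaults to [default_drivers()].
#' @param control solver control list.
#' @param prep optional pre-computed list (compliance/split/model/baseline)
#'   as produced by [prepare_scenario()], reused across forest definitions.
#' @return list with the reports and intermediate objects.
#' @export
run_scenario <- function(world, spec, drivers = NULL, control = list(),
                         prep = NULL) {
  if (is.null(drivers)) drivers <- default_drivers(world$config)
  if (is.null(prep)) prep <- prepare_scenario(world, spec, drivers, control)
  covered <- prep$split$cells$cell_id[!is.na(prep$split$cells$compliant) &
                                        prep$split$cells$compliant]
  cf <- if (length(covered) == 0) prep$baseline else
    run_counterfactual(prep$model, drivers, covered,
                       spec$forest_definition, control)
  lct <- diff_land(prep$baseline, cf, covered, world$config$roles$policy)
  rep <- build_report(lct, frontier_regions = world$config$roles$frontier)
  ef <- build_ef_matrix(default_carbon_stocks(prep$split$cells))
  em <- emissions_from_deltas(lct, ef)
  list(spec = spec, compliance = prep$compliance, coverage = prep$coverage,
       model = prep$model, baseline = prep$baseline, counterfactual = cf,
       land_change = lct, leakage = rep, emissions = em,
       covered_cells = covered)
}

#' Prepare the scenario database and baseline
#'
#' The compliance split and its baseline depend only on scenario and
#' threshold, so they are shared between the two forest definitions.
#'
#' @inheritParams run_scenario
#' @return list(compliance, split, model, baseline, coverage).
#' @export
prepare_scenario <- function(world, spec, drivers = NULL, control = list()) {
  if (is.null(drivers)) drivers <- default_drivers(world$config)
  cm <- build_compliance_map(world$municipalities, world$trader_exports,
                             world$companies, spec)
  split <- split_accounts(world, cm)
  model <- calibrate(split, world$config)
  baseline <- run_baseline(model, drivers, control)
  list(compliance = cm, split = split, model = model, baseline = baseline,
       coverage = coverage_stats(world$municipalities, cm,
                                 spec$forest_definition))
}

#' Provenance manifest of a run
#' @param world the world; @param extra named list merged in.
#' @return list with config hash, seed and software version.
#' @export
run_manifest <- function(world, extra = list()) {
  c(list(config_hash = config_hash(world$config),
         world_seed = world$config$seed,
         package_version = tryCatch(
           as.character(utils::packageVersion("soyshift")),
           error = function(e) "dev"),
         timestamp = format(Sys.time(), tz = "UTC")),
    extra)
}

#' Run the full scenario grid
#'
#' All 30 scenario x threshold x forest-definition combinations against one
#' shared driver set, each differenced against the matching no-restriction
#' baseline. Solver failures do not abort the grid; they are recorded in the
#' summary and the manifest.
#'
#' @param world a `"soy_world"`.
#' @param drivers a `"soy_shocks"`; defaults to [default_drivers()].
#' @param grid subset of [scenario_grid()] rows to run.
#' @param control solver control.
#' @param quiet suppress progress messages.
#' @return list with `summary` (one row per run), `runs` (reports) and
#'   `manifest`, class `"soy_grid"`.
#' @export
run_grid <- function(world, drivers = NULL, grid = scenario_grid(),
                     control = list(), quiet = TRUE) {
  if (is.null(drivers)) drivers <- default_drivers(world$config)
  preps <- list()
  rows <- list(); runs <- list(); failures <- list()
  for (k in seq_len(nrow(grid))) {
    g <- grid[k, ]
    spec <- scenario_spec(g$scenario, g$threshold, g$forest_definition)
    key <- paste(g$scenario, g$threshold)
    run_id <- paste(g$scenario, g$threshold, g$forest_definition, sep = "_")
    if (!quiet) message("running ", run_id)
    res <- tryCatch({
      if (is.null(preps[[key]]))
        preps[[key]] <- prepare_scenario(world, spec, drivers, control)
      run_scenario(world, spec, drivers, control, prep = preps[[key]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[run_id]] <- conditionMessage(res)
      rows[[run_id]] <- data.frame(
        scenario = g$scenario, threshold = g$threshold,
        forest_definition = g$forest_definition, converged = FALSE,
        gross_avoided_kha = NA, displaced_domestic_kha = NA,
        displaced_crossborder_kha = NA, net_country_kha = NA,
        net_global_kha = NA, domestic_leakage_rate_pct = NA,
        crossborder_leakage_rate_pct = NA, ghg_delta_kt = NA,
        stringsAsFactors = FALSE)
      next
    }
    runs[[run_id]] <- res
    lr <- res$leakage
    rows[[run_id]] <- data.frame(
      scenario = g$scenario, threshold = g$threshold,
      forest_definition = g$forest_definition, converged = TRUE,
      gross_avoided_kha = lr$gross_avoided_kha,
      displaced_domestic_kha = lr$displaced_domestic_kha,
      displaced_crossborder_kha = lr$displaced_crossborder_kha,
      net_country_kha = lr$net_country_kha,
      net_global_kha = lr$net_global_kha,
      domestic_leakage_rate_pct = lr$domestic_leakage_rate_pct,
      crossborder_leakage_rate_pct = lr$crossborder_leakage_rate_pct,
      ghg_delta_kt = res$emissions$global_kt,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, runs = runs,
                 manifest = run_manifest(world, list(
                   n_runs = nrow(grid), failures = failures))),
            class = "soy_grid")
}

#' @export
print.soy_grid <- function(x, ...) {
  cat("<soy_grid> ", nrow(x$summary), " runs, ",
      sum(x$summary$converged), " converged\n", sep = "")
  print(x$summary[, c("scenario", "threshold", "forest_definition",
                      "gross_avoided_kha", "net_global_kha",
                      "domestic_leakage_rate_pct")], digits = 3)
  invisible(x)
}

#' Specify a sensitivity sweep
#'
#' Independent uniform multiplicative draws on the key land-supply and trade
#' elasticities (transformation elasticities of the three land nests and the
#' Armington elasticities).
#'
#' @param n number of draws (>= 1).
#' @param seed integer seed.
#' @param ranges named list of length-2 multiplier ranges.
#' @return class `"sweep_spec"`.
#' @export
sweep_spec <- function(n = 50L, seed = 1L,
                       ranges = list(sigma_nat = c(0.5, 2),
                                     sigma_agpast = c(0.5, 2),
                                     sigma_crop = c(0.5, 2),
                                     armington = c(0.5, 2))) {
  abort_if(!is_count(n, 1L), "n must be a count >= 1")
  for (r in ranges)
    abort_if(length(r) != 2 || any(r <= 0) || r[1] > r[2],
             "invalid multiplier range")
  structure(list(n = as.integer(n), seed = as.integer(seed), ranges = ranges),
            class = "sweep_spec")
}

#' Systematic sensitivity sweep
#'
#' Monte-Carlo re-solves of one scenario under draws of the key elasticities,
#' reporting the distribution of leakage rates and the sign stability of net
#' global avoided deforestation.
#'
#' @param world a `"soy_world"`.
#' @param drivers a `"soy_shocks"`.
#' @param sw a [sweep_spec()].
#' @param spec the scenario to perturb (default: ASM at the ge50 threshold).
#' @param control solver control.
#' @return list with `draws` (one row per draw), `summary` (means and 5-95%
#'   intervals) and `sign_stability`, class `"soy_sweep"`.
#' @export
sensitivity_sweep <- function(world, drivers = NULL, sw = sweep_spec(),
                              spec = scenario_spec("ASM", "ge50", "A"),
                              control = list()) {
  if (is.null(drivers)) drivers <- default_drivers(world$config)
  cm <- build_compliance_map(world$municipalities, world$trader_exports,
                             world$companies, spec)
  split <- split_accounts(world, cm)
  mult <- with_seed(sw$seed, {
    m <- lapply(sw$ranges, function(r) stats::runif(sw$n, r[1], r[2]))
    as.data.frame(m)
  })
  rows <- vector("list", sw$n)
  for (d in seq_len(sw$n)) {
    el <- world$config$elasticities
    if (!is.null(mult$sigma_nat)) el$sigma_nat <- el$sigma_nat * mult$sigma_nat[d]
    if (!is.null(mult$sigma_agpast))
      el$sigma_agpast <- el$sigma_agpast * mult$sigma_agpast[d]
    if (!is.null(mult$sigma_crop))
      el$sigma_crop <- el$sigma_crop * mult$sigma_crop[d]
    if (!is.null(mult$armington)) {
      el$armington1 <- el$armington1 * mult$armington[d]
      el$armington2 <- el$armington2 * mult$armington[d]
    }
    model <- calibrate(split, world$config, elasticities = el)
    base <- run_baseline(model, drivers, control)
    covered <- split$cells$cell_id[!is.na(split$cells$compliant) &
                                     split$cells$compliant]
    cf <- run_counterfactual(model, drivers, covered, spec$forest_definition,
                             control)
    lct <- diff_land(base, cf, covered, world$config$roles$policy)
    lr <- build_report(lct, world$config$roles$frontier)
    rows[[d]] <- data.frame(
      draw = d, gross_avoided_kha = lr$gross_avoided_kha,
      net_global_kha = lr$net_global_kha,
      domestic_leakage_rate_pct = lr$domestic_leakage_rate_pct,
      crossborder_leakage_rate_pct = lr$crossborder_leakage_rate_pct)
  }
  draws <- do.call(rbind, rows)
  qs <- function(x) c(mean = mean(x), q05 = unname(stats::quantile(x, 0.05)),
                      q95 = unname(stats::quantile(x, 0.95)))
  structure(list(
    draws = draws, multipliers = mult,
    summary = rbind(domestic_leakage_rate_pct =
                      qs(draws$domestic_leakage_rate_pct),
                    crossborder_leakage_rate_pct =
                      qs(draws$crossborder_leakage_rate_pct),
                    net_global_kha = qs(draws$net_global_kha)),
    sign_stability = mean(draws$net_global_kha > 0),
    spec = spec, sweep = sw), class = "soy_sweep")
}

#' @export
print.soy_sweep <- function(x, ...) {
  cat("<soy_sweep> ", nrow(x$draws), " draws; sign stability ",
      format(x$sign_stability, digits = 3), "\n", sep = "")
  print(round(x$summary, 2))
  invisible(x)
}

#' Write grid results, summary tables and figures
#'
#' Writes `summary.csv`, `manifest.json` and a bar-with-range figure in the
#' style of the headline results (bars at the ge50 threshold, vertical lines
#' spanning gt0 to ge75), with integer-percent rounding in the printed table.
#'
#' @param grid_result a `"soy_grid"`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written summary data.frame.
#' @export
report_runs <- function(grid_result, out_dir) {
  abort_if(!inherits(grid_result, "soy_grid") ||
             is.null(grid_result$summary) || nrow(grid_result$summary) == 0,
           "no completed runs to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- grid_result$summary
  utils::write.csv(s, file.path(out_dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(grid_result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pres <- s[s$converged, ]
  pres$domestic_leakage_rate_pct <- round(pres$domestic_leakage_rate_pct)
  pres$crossborder_leakage_rate_pct <-
    round(pres$crossborder_leakage_rate_pct)
  utils::write.csv(pres, file.path(out_dir, "summary_rounded.csv"),
                   row.names = FALSE)
  wide <- stats::reshape(
    s[s$converged, c("scenario", "threshold", "forest_definition",
                     "net_global_kha")],
    direction = "wide", idvar = c("scenario", "forest_definition"),
    timevar = "threshold")
  p <- ggplot2::ggplot(wide, ggplot2::aes(x = scenario)) +
    ggplot2::geom_col(ggplot2::aes(y = net_global_kha.ge50),
                      fill = "forestgreen", width = 0.6) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = net_global_kha.ge75,
                                         ymax = net_global_kha.gt0)) +
    ggplot2::facet_wrap(~forest_definition, labeller = ggplot2::label_both) +
    ggplot2::labs(y = "net global avoided deforestation (kha)", x = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "net_global_by_scenario.pdf"), p,
                  width = 8, height = 4)
  invisible(s)
}
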