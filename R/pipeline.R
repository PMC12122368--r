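# Orchestration: one configuration object and one entry point running the
# whole audit -- simulate, collinearity screen, site selection, success
# scoring and modelling, exposure, future DHW and costs -- with a single
# seed fanned out deterministically to every stage.

#' Configuration for the full audit pipeline
#'
#' @param sim A [sim_config()] for the synthetic inputs.
#' @param site A [site_config()]; `NULL` skips the site-selection stage.
#' @param success A [success_config()]; `NULL` skips the success stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "screen", "select_sites", "success", "exposure",
#'   "future", "costs")`. Stages other than "simulate" require "simulate".
#' @param dhw_threshold Exceedance threshold in C-weeks (20).
#' @param restore_fraction_of_degraded Fraction of the degraded reef area
#'   costed (0.10).
#' @param degraded_area_km2 Global degraded reef area (11,700 km^2).
#' @param seed Single integer seed fanned out to all stages.
#' @param out_dir Optional directory: stage outputs are written as CSV and
#'   a machine-readable JSON summary.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            site = site_config(),
                            success = success_config(),
                            stages = c("simulate", "screen", "select_sites",
                                       "success", "exposure", "future", "costs"),
                            dhw_threshold = 20,
                            restore_fraction_of_degraded = 0.10,
                            degraded_area_km2 = 11700,
                            seed = 1L, out_dir = NULL) {
  known <- c("simulate", "screen", "select_sites", "success", "exposure",
             "future", "costs")
  if (length(stages) && !all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  if (length(setdiff(stages, "simulate")) && !"simulate" %in% stages)
    stop("all analysis stages require the simulate stage", call. = FALSE)
  assert_number(dhw_threshold, "dhw_threshold", 0)
  assert_number(restore_fraction_of_degraded, "restore_fraction_of_degraded", 0, 1)
  structure(list(sim = sim, site = site, success = success, stages = stages,
                 dhw_threshold = dhw_threshold,
                 restore_fraction_of_degraded = restore_fraction_of_degraded,
                 degraded_area_km2 = degraded_area_km2,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full restoration audit
#'
#' Executes the enabled stages in order on a synthetic reef grid and
#' returns a report bundle; every stage's seed and headline numbers are
#' echoed into the summary. A stage failure halts the run naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return List of class `audit_report` with per-stage results and a flat
#'   `summary` list of the headline quantities.
#' @export
run_all <- function(config = pipeline_config()) {
  stages <- config$stages
  report <- list(config_echo = list(seed = config$seed, stages = stages))
  summary <- list(seed = config$seed)
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  grid <- NULL; records <- NULL
  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      cfg <- config$sim
      cfg$seed <- derive_seed(config$seed, "sim")
      grid <<- generate_grid(cfg)
      records <<- generate_records(grid)
    })
    report$grid <- grid; report$records <- records
    summary$n_localities <- nrow(grid$localities)
    summary$n_restored <- sum(grid$localities$restored)
    summary$n_records <- nrow(records)
  }
  if ("screen" %in% stages) {
    run_stage("screen", function() {
      tab <- build_site_table(grid, records)
      report$collinearity <<- collinearity_screen(tab[, SITE_PREDICTORS])
    })
    summary$max_pairwise_r2 <- {
      r2 <- report$collinearity$r2; diag(r2) <- NA
      max(r2, na.rm = TRUE)
    }
  }
  if ("select_sites" %in% stages) {
    run_stage("select_sites", function() {
      report$site_selection <<- run_site_selection(
        grid, records, config$site, seed = derive_seed(config$seed, "site"))
    })
    s <- report$site_selection$summary
    summary$tss_mean <- s$tss_mean; summary$tss_sd <- s$tss_sd
    summary$false_positive_mean <- s$false_positive_mean
    summary$false_negative_mean <- s$false_negative_mean
    summary$top_influence <- report$site_selection$influence$variable[1]
  }
  if ("success" %in% stages) {
    run_stage("success", function() {
      tab <- build_success_table(records, grid)
      report$success_table <<- tab
      report$success <<- run_success_model(
        tab, config$success, seed = derive_seed(config$seed, "success"))
    })
    s <- report$success$summary
    summary$success_r2_mean <- s$r2_mean
    summary$success_r2_sd <- s$r2_sd
    summary$success_suppressed <- report$success$suppressed
  }
  if ("exposure" %in% stages) {
    run_stage("exposure", function() {
      report$exposure <<- restored_vs_control_fractions(grid, records)
    })
  }
  if ("future" %in% stages) {
    run_stage("future", function() {
      report$future <<- dhw_exceedance(grid, config$dhw_threshold)
    })
    g <- report$future$groups
    summary$dhw_fraction_restored <- g$fraction_exceeding[g$group == "restored"]
    summary$dhw_fraction_control <- g$fraction_exceeding[g$group == "control"]
    summary$first_exceedance_restored_mean <- g$first_year_mean[g$group == "restored"]
  }
  if ("costs" %in% stages) {
    run_stage("costs", function() {
      area <- area_for_fraction(config$degraded_area_km2,
                                config$restore_fraction_of_degraded)
      report$costs <<- cost_curve(default_cost_table(), area)
      report$costs_area_ha <<- area
    })
    cc <- report$costs
    summary$restored_area_ha <- report$costs_area_ha
    summary$cost_low_usd <- min(cc$low_usd)
    summary$cost_high_usd <- max(cc$high_usd)
    summary$cost_gardening_median_usd <-
      cc$median_usd[cc$technique == "coral_gardening"]
  }
  report$summary <- summary
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  structure(report, class = "audit_report")
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$grid))
    write_grid_csv(report$grid, dir, records = report$records)
  if (!is.null(report$site_selection)) {
    write.csv(report$site_selection$replicates,
              file.path(dir, "site_selection_replicates.csv"), row.names = FALSE)
    write.csv(report$site_selection$influence,
              file.path(dir, "site_selection_influence.csv"), row.names = FALSE)
  }
  if (!is.null(report$success))
    write.csv(report$success$replicates,
              file.path(dir, "success_replicates.csv"), row.names = FALSE)
  if (!is.null(report$future))
    write.csv(report$future$per_locality,
              file.path(dir, "dhw_exceedance.csv"), row.names = FALSE)
  if (!is.null(report$costs))
    write.csv(report$costs, file.path(dir, "cost_curves.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Coral-restoration audit report\n")
  s <- x$summary
  for (nm in names(s))
    cat(sprintf("  %-32s %s\n", nm, format(s[[nm]], digits = 5)))
  invisible(x)
}
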