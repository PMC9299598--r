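# End-to-end orchestration: estimates, classifiers, recrediting, Monte Carlo,
# diagnostics and report files, with a run log of every seed, fallback and
# floor event.

#' Assemble a pipeline run configuration
#'
#' @param inventory Condition tibble or path to an inventory CSV.
#' @param projects Project tibble or path to a project JSON file.
#' @param assessment_map Forest-type to assessment-area map (tibble or CSV
#'   path with columns `supersection`, `forest_type`, `assessment_area`).
#' @param out_dir Optional output directory; created if absent.
#' @param price Offset price, $/tCO2e (> 0, default 13.67).
#' @param mc A [mc_config()].
#' @param radius_grid,n_folds,classifier_seed Classifier settings.
#' @param baseline_mode,alt_method,perturb_reference Recrediting settings (see
#'   [recompute_credits()], [portfolio_scaled_cp()], [propagate()]).
#' @param buffer_pool Optional buffer-pool size, tCO2e, for the depletion
#'   figure in the program summary.
#' @return A `run_config` list.
#' @export
run_config <- function(inventory, projects, assessment_map, out_dir = NULL,
                       price = 13.67, mc = mc_config(),
                       radius_grid = default_radius_grid(), n_folds = 5,
                       classifier_seed = 1L,
                       baseline_mode = "preserve-margin",
                       alt_method = "posterior",
                       perturb_reference = TRUE,
                       buffer_pool = NULL) {
  if (!is.numeric(price) || price <= 0) abort("`price` must be positive")
  structure(list(inventory = inventory, projects = projects,
                 assessment_map = assessment_map, out_dir = out_dir,
                 price = price, mc = mc, radius_grid = radius_grid,
                 n_folds = n_folds, classifier_seed = classifier_seed,
                 baseline_mode = baseline_mode, alt_method = alt_method,
                 perturb_reference = perturb_reference,
                 buffer_pool = buffer_pool),
            class = "run_config")
}

read_if_path <- function(x, reader) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) abort(sprintf("input file not found: %s", x))
    reader(x)
  } else {
    x
  }
}

#' Run the full recrediting pipeline
#'
#' Stages: validate inventory; estimate regulator-style (assessment-area) and
#' species-specific (forest-type) common practice; fit per-supersection
#' forest-type classifiers; classify every project; rescale each project's
#' reported common practice; recompute credits; propagate inventory
#' uncertainty by Monte Carlo; verify issuance replication; compute the
#' ecosection aggregation diagnostic. Deterministic given the configured
#' seeds. If `out_dir` is set, writes `outcomes.csv`, `figure5.csv`,
#' `program_summary.json`, `ecosection_diagnostic.csv`,
#' `issuance_replication.csv` and `run_log.txt`.
#'
#' @param config A [run_config()].
#' @return A `recredit_run` list: `estimates` (assessment-area and
#'   forest-type), `classifiers`, `classifications`, `outcomes`, `figure5`,
#'   `program`, `replication`, `ecosection_diagnostic`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, recredit_log = function(m) {
      log_lines <<- c(log_lines, paste0("[", name, "] ",
                                        trimws(conditionMessage(m))))
      invokeRestart("muffleMessage")
    }), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  inventory <- stage("read", read_if_path(config$inventory, read_inventory_csv))
  projects <- stage("read", read_if_path(config$projects, read_projects_json))
  amap <- stage("read", read_if_path(config$assessment_map, function(p) {
    as_tibble(read.csv(p, stringsAsFactors = FALSE))
  }))
  stage("validate", validate_inventory(inventory))
  if (nrow(projects) == 0) abort("stage 'read' failed: empty project table")

  aa_est <- stage("common-practice", carb_common_practice(inventory, amap))
  type_est <- stage("common-practice",
                    species_specific_common_practice(inventory))
  note("common practice: %d assessment-area and %d forest-type strata",
       nrow(aa_est), nrow(type_est))

  note("classifier seed: %d; monte carlo seed: %d; draws: %d",
       config$classifier_seed, config$mc$seed, config$mc$n_draws)
  store <- stage("classify", fit_classifiers(inventory, config$radius_grid,
                                             config$n_folds,
                                             config$classifier_seed))
  for (m in store) {
    note("classifier %s: radius %.4f, CV weighted F1 %.4f",
         m$supersection, m$radius, m$selected_score)
  }
  cls <- stage("classify", classify_projects(store, projects))
  note("classifier nearest-neighbor fallbacks: %d", sum(cls$fallback))

  repl <- stage("recredit", replicate_issuance(projects))
  prop <- stage("recredit", propagate(
    projects, cls, type_est, amap, config$mc,
    baseline_mode = config$baseline_mode,
    perturb_reference = config$perturb_reference,
    alt_method = config$alt_method, price = config$price))
  note("negative common-practice values floored at credit step: %d",
       prop$n_floored)

  program <- prop$program
  if (!is.null(config$buffer_pool)) {
    program$buffer_pool <- config$buffer_pool
    program$buffer_depletion_percent <-
      buffer_depletion(program$net_error, config$buffer_pool)
  }

  eco <- stage("diagnostic", {
    joined <- left_join(inventory, amap, by = c("supersection", "forest_type"))
    bind_rows(lapply(split(joined, paste(joined$supersection,
                                         joined$assessment_area, sep = "\r")),
                     function(g) {
                       d <- ecosection_diagnostic(g)
                       d$assessment_area <- g$assessment_area[1]
                       d
                     }))
  })

  fig5 <- figure5_table(prop$outcomes)
  run <- structure(
    list(estimates = list(assessment_area = aa_est, forest_type = type_est),
         classifiers = store, classifications = cls,
         outcomes = prop$outcomes, figure5 = fig5, program = program,
         program_draws = prop$program_draws, replication = repl,
         ecosection_diagnostic = eco, log = log_lines, config = config),
    class = "recredit_run")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$out_dir, f)
    write.csv(run$outcomes, p("outcomes.csv"), row.names = FALSE)
    write.csv(fig5, p("figure5.csv"), row.names = FALSE)
    write.csv(eco, p("ecosection_diagnostic.csv"), row.names = FALSE)
    write.csv(repl$comparison, p("issuance_replication.csv"), row.names = FALSE)
    summary_json <- list(
      net_error_tco2e = program$net_error,
      percent_of_analyzed = program$percent_of_analyzed,
      value_usd = program$value_usd,
      total_analyzed_credits = program$total_analyzed_credits,
      price_usd_per_tco2e = program$price,
      issuance_r_squared = repl$r_squared,
      percentiles = program$percentiles,
      buffer_pool = program$buffer_pool,
      buffer_depletion_percent = program$buffer_depletion_percent)
    jsonlite::write_json(summary_json, p("program_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log_lines, p("run_log.txt"))
  }
  run
}

#' @export
print.recredit_run <- function(x, ...) {
  cat(sprintf("<recredit_run> %d projects, %d forest-type strata\n",
              nrow(x$outcomes), nrow(x$estimates$forest_type)))
  print(x$program)
  invisible(x)
}

#' Per-project crediting-error table (median and quartiles)
#'
#' One row per project with the crediting error as a percentage of issued
#' credits at the 25th, 50th and 75th percentiles, alongside the common
#' practice the project used and the rescaled value, sorted by median error
#' descending (worst over-crediting first).
#'
#' @param outcomes Outcome tibble from [propagate()] (needs `p25`/`p50`/`p75`
#'   percentile columns).
#' @return Sorted tibble.
#' @export
figure5_table <- function(outcomes) {
  needed <- c("p25_percent", "p50_percent", "p75_percent", "reported_cp",
              "scaled_cp")
  missing <- setdiff(needed, names(outcomes))
  if (length(missing)) {
    abort(paste("outcomes lack percentile summaries:",
                paste(missing, collapse = ", ")))
  }
  outcomes |>
    select("project_id", "credits_issued",
           error_percent_p25 = "p25_percent",
           error_percent_p50 = "p50_percent",
           error_percent_p75 = "p75_percent",
           cp_used = "reported_cp", cp_recalculated = "scaled_cp") |>
    arrange(desc(.data$error_percent_p50))
}
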