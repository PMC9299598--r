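# Upfront credit issuance and recrediting under species-specific common
# practice.
#
# Upfront credits for an IFM project are (initial onsite carbon plus
# project-scenario wood products) minus (the 100-year baseline average onsite
# carbon plus baseline wood products), adjusted for secondary effects and a
# confidence deduction, floored at zero:
#
#   credits = [ (IFM1+IFM3 + WP_proj)
#               - (baseline_avg_density * acreage + WP_base)
#               + secondary_effects ] * (1 - confidence_deduction)
#
# This is a reconstruction of the protocol's issuance equation from its
# documented components; the placement of the confidence deduction is isolated
# here for auditability.

required_credit_fields <- c(
  "acreage", "initial_onsite_carbon", "wood_products_project",
  "wood_products_baseline", "baseline_avg_density", "secondary_effects",
  "confidence_deduction")

#' Replicate upfront credit issuance for project records
#'
#' @param projects Project tibble (one row per project) with the crediting
#'   fields: `acreage`, `initial_onsite_carbon`, `wood_products_project`,
#'   `wood_products_baseline`, `baseline_avg_density`, `secondary_effects`,
#'   `confidence_deduction`.
#' @param baseline_avg_density Optional vector overriding the recorded
#'   100-year baseline average density (tCO2e/acre), used when recrediting
#'   under a new common-practice constraint.
#' @return Numeric vector of upfront credits (tCO2e), floored at 0.
#' @export
compute_upfront_credits <- function(projects,
                                    baseline_avg_density = projects$baseline_avg_density) {
  missing <- setdiff(required_credit_fields, names(projects))
  if (length(missing)) {
    abort(paste("project record(s) missing crediting fields:",
                paste(missing, collapse = ", ")))
  }
  if (any(projects$acreage <= 0)) abort("acreage must be > 0")
  if (any(is.na(unlist(projects[required_credit_fields])))) {
    abort("crediting fields contain missing values")
  }
  delta <- (projects$initial_onsite_carbon + projects$wood_products_project) -
    (baseline_avg_density * projects$acreage + projects$wood_products_baseline) +
    projects$secondary_effects
  pmax(0, delta * (1 - projects$confidence_deduction))
}

#' Verify issuance replication against recorded credits
#'
#' Recomputes every project's upfront credits from its components and compares
#' them with the credits actually recorded, summarized by the coefficient of
#' determination. On records generated by [generate_projects()] the
#' replication is exact (R^2 = 1).
#'
#' @param projects Project tibble with a `credits_issued` column.
#' @return List with `comparison` (tibble `project_id`, `computed`,
#'   `recorded`) and `r_squared` (NA with fewer than two projects or constant
#'   recorded credits).
#' @export
replicate_issuance <- function(projects) {
  if (!"credits_issued" %in% names(projects)) {
    abort("projects lack recorded `credits_issued`")
  }
  computed <- compute_upfront_credits(projects)
  r2 <- r_squared(projects$credits_issued, computed)
  if (is.na(r2)) {
    inform("issuance R^2 undefined (fewer than 2 projects or constant credits)",
           class = "recredit_log")
  }
  list(comparison = tibble(project_id = projects$project_id,
                           computed = computed,
                           recorded = projects$credits_issued),
       r_squared = r2)
}

#' Project-level reported common practice
#'
#' The acreage-weighted mean of the per-assessment-area reported common
#' practice values in each project's `areas` list-column.
#'
#' @param projects Project tibble.
#' @return Numeric vector, tCO2e/acre.
#' @export
project_reported_cp <- function(projects) {
  vapply(projects$areas, function(a) {
    w <- a$acres / sum(a$acres)
    sum(w * a$reported_cp)
  }, numeric(1))
}

#' Scale a project's reported common practice by the alternative/recomputed ratio
#'
#' Rather than replacing the reported common practice outright, it is scaled
#' by the assessment-area-acreage-weighted ratio of the alternative
#' (species-specific) common practice to the re-calculated assessment-area
#' estimate, so that the change reflects only the change in how inventory data
#' are aggregated:
#' `scaled = reported_cp * sum_a w_a * (alt_a / recomputed_a)`.
#'
#' @param project One project record (single-row tibble or list).
#' @param alt_cp Named numeric: alternative common practice per assessment
#'   area of the project (tCO2e/acre).
#' @param recomputed_cp Named numeric: re-calculated assessment-area common
#'   practice (tCO2e/acre); must be positive.
#' @return Scaled common practice, tCO2e/acre (scalar).
#' @export
scale_common_practice <- function(project, alt_cp, recomputed_cp) {
  areas <- project$areas[[1]]
  aa <- areas$assessment_area
  if (!all(aa %in% names(alt_cp)) || !all(aa %in% names(recomputed_cp))) {
    abort(sprintf("missing common-practice estimates for project '%s'",
                  project$project_id[[1]]))
  }
  if (any(recomputed_cp[aa] <= 0)) {
    abort(sprintf("recomputed common practice is zero for project '%s': ratio undefined",
                  project$project_id[[1]]))
  }
  w <- areas$acres / sum(areas$acres)
  reported <- sum(w * areas$reported_cp)
  reported * sum(w * (alt_cp[aa] / recomputed_cp[aa]))
}

#' Recompute credits under a new common-practice constraint
#'
#' Projects are assumed to re-select baseline scenarios against the new
#' constraint: a project whose original baseline sat at (or below) its
#' reported common practice snaps to the scaled value, while a project whose
#' baseline exceeded the constraint keeps its absolute margin above the new
#' one (`baseline_mode = "preserve-margin"`, the default;
#' `"snap-to-cp"` forces every baseline to the scaled value). A project whose
#' scaled common practice reaches its initial onsite density earns nothing
#' (100% over-credited).
#'
#' @param projects Project tibble.
#' @param scaled_cp Numeric vector of scaled common practice per project,
#'   tCO2e/acre (negative values are floored at 0, counted via attribute
#'   `n_floored`).
#' @param baseline_mode `"preserve-margin"` or `"snap-to-cp"`.
#' @return Numeric vector of recomputed credits (tCO2e) with attribute
#'   `n_floored`.
#' @export
recompute_credits <- function(projects, scaled_cp,
                              baseline_mode = c("preserve-margin", "snap-to-cp")) {
  baseline_mode <- match.arg(baseline_mode)
  n_floored <- sum(scaled_cp < 0)
  scaled_cp <- pmax(0, scaled_cp)
  reported <- project_reported_cp(projects)
  margin <- pmax(0, projects$baseline_avg_density - reported)
  new_baseline <- if (baseline_mode == "preserve-margin") {
    scaled_cp + margin
  } else {
    scaled_cp
  }
  credits <- compute_upfront_credits(projects, baseline_avg_density = new_baseline)
  credits[scaled_cp >= projects$initial_onsite_carbon / projects$acreage] <- 0
  attr(credits, "n_floored") <- n_floored
  credits
}

#' Assemble per-project crediting outcomes
#'
#' @param projects Project tibble with `credits_issued`.
#' @param credits_recomputed Numeric vector from [recompute_credits()].
#' @return Tibble: `project_id`, `credits_issued`, `credits_recomputed`,
#'   `crediting_error` (issued minus recomputed; positive = over-credited),
#'   `error_percent` (100 * error / issued, NA where issuance is 0).
#' @export
crediting_outcomes <- function(projects, credits_recomputed) {
  err <- projects$credits_issued - as.numeric(credits_recomputed)
  tibble(
    project_id = projects$project_id,
    credits_issued = projects$credits_issued,
    credits_recomputed = as.numeric(credits_recomputed),
    crediting_error = err,
    error_percent = ifelse(projects$credits_issued > 0,
                           100 * err / projects$credits_issued, NA_real_)
  )
}

#' Program-wide crediting summary
#'
#' Net crediting error summed over projects, expressed as a percentage of the
#' credits analyzed and as a dollar value at the given price; the same
#' transforms applied to per-draw program totals yield percentile summaries.
#'
#' @param outcomes Outcome tibble from [crediting_outcomes()].
#' @param total_analyzed_credits Total upfront credits analyzed, tCO2e
#'   (default: sum of issued credits in `outcomes`).
#' @param price Offset price, $/tCO2e (default 13.67, a recent market price).
#' @param program_draws Optional numeric vector of per-draw program net errors
#'   (tCO2e) from [propagate()].
#' @param percentiles Percentiles to report when `program_draws` is given.
#' @return List of class `program_summary`: `net_error` (tCO2e),
#'   `percent_of_analyzed`, `value_usd`, `total_analyzed_credits`, `price`,
#'   and (with draws) a `percentiles` tibble.
#' @export
aggregate_program <- function(outcomes,
                              total_analyzed_credits = sum(outcomes$credits_issued),
                              price = 13.67, program_draws = NULL,
                              percentiles = c(5, 50, 95)) {
  if (nrow(outcomes) == 0) {
    return(structure(list(net_error = 0, percent_of_analyzed = NA_real_,
                          value_usd = 0, total_analyzed_credits = 0,
                          price = price, percentiles = NULL),
                     class = "program_summary"))
  }
  if (!is.numeric(total_analyzed_credits) || total_analyzed_credits <= 0) {
    abort("`total_analyzed_credits` must be positive for a nonempty portfolio")
  }
  net <- sum(outcomes$crediting_error)
  out <- list(net_error = net,
              percent_of_analyzed = 100 * net / total_analyzed_credits,
              value_usd = net * price,
              total_analyzed_credits = total_analyzed_credits,
              price = price, percentiles = NULL)
  if (!is.null(program_draws)) {
    q <- quantile(program_draws, percentiles / 100, names = FALSE, type = 7)
    out$percentiles <- tibble(
      percentile = percentiles,
      net_error = q,
      percent_of_analyzed = 100 * q / total_analyzed_credits,
      value_usd = q * price)
  }
  structure(out, class = "program_summary")
}

#' @export
print.program_summary <- function(x, ...) {
  cat(sprintf(
    "<program_summary> net error %.3g tCO2e (%.1f%% of %.3g analyzed), $%.3g at $%.2f/tCO2e\n",
    x$net_error, x$percent_of_analyzed, x$total_analyzed_credits,
    x$value_usd, x$price))
  if (!is.null(x$percentiles)) {
    for (i in seq_len(nrow(x$percentiles))) {
      cat(sprintf("  p%g: %.3g tCO2e (%.1f%%)\n", x$percentiles$percentile[i],
                  x$percentiles$net_error[i],
                  x$percentiles$percent_of_analyzed[i]))
    }
  }
  invisible(x)
}

#' Buffer-pool depletion from a crediting error
#'
#' @param error Crediting error, tCO2e.
#' @param buffer_pool Buffer-pool size, tCO2e (> 0).
#' @param digits Rounding for reporting (default integer percent).
#' @return Percent of the buffer pool the error would deplete.
#' @export
buffer_depletion <- function(error, buffer_pool, digits = 0) {
  if (!is.numeric(buffer_pool) || buffer_pool <= 0) {
    abort("`buffer_pool` must be positive")
  }
  round(100 * error / buffer_pool, digits)
}

#' Dollar value of a quantity of credits
#'
#' @param credits tCO2e.
#' @param price $/tCO2e (default 13.67).
#' @return Dollar value.
#' @export
credit_value <- function(credits, price = 13.67) {
  if (!is.numeric(price) || price <= 0) abort("`price` must be positive")
  credits * price
}
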