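# Design-based common-practice estimation.
#
# "Common practice" is the average standing-live aboveground carbon density
# (tCO2e/acre) of a forest stratum. Following design-based inventory practice,
# carbon and acreage are summed separately over condition records (each scaled
# by its expansion factor) before taking the ratio. Variances use the standard
# delta-method ratio-estimator formula with conditions as sampling units.

#' Validate an inventory condition table
#'
#' Checks the schema invariants: species fractions in `[0, 1]` summing to 1
#' within 1e-6, carbon density non-negative, expansion acreage positive.
#'
#' @param conditions Inventory tibble as produced by [generate_inventory()] or
#'   [read_inventory_csv()].
#' @return The table, invisibly; aborts with the first violated invariant.
#' @export
validate_inventory <- function(conditions) {
  needed <- c("supersection", "ecosection", "forest_type", "species_fractions",
              "carbon_density", "expansion_acres")
  missing <- setdiff(needed, names(conditions))
  if (length(missing)) {
    abort(paste("inventory table is missing columns:",
                paste(missing, collapse = ", ")))
  }
  if (any(conditions$carbon_density < 0)) abort("carbon_density must be >= 0")
  if (any(conditions$expansion_acres <= 0)) abort("expansion_acres must be > 0")
  sums <- vapply(conditions$species_fractions, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-6)) {
    abort("species fractions must sum to 1 within 1e-6")
  }
  bad <- vapply(conditions$species_fractions,
                function(f) any(f < 0 | f > 1), logical(1))
  if (any(bad)) abort("species fractions must lie in [0, 1]")
  invisible(conditions)
}

ratio_estimate <- function(carbon_density, expansion_acres) {
  x <- expansion_acres
  y <- carbon_density * expansion_acres
  tx <- sum(x)
  if (tx <= 0) abort("zero total acreage in stratum: ratio undefined")
  r <- sum(y) / tx
  n <- length(x)
  v <- if (n < 2) 0 else n * sum((y - r * x)^2) / ((n - 1) * tx^2)
  list(mean_density = r, variance = v, n_conditions = n, total_acres = tx)
}

#' Estimate common practice by stratum (ratio of expansion-weighted sums)
#'
#' For each group defined by `by`, computes
#' `sum(carbon_density * expansion_acres) / sum(expansion_acres)` together with
#' the delta-method ratio-estimator variance (conditions as sampling units,
#' expansion acreage as size weights). Single-condition strata get variance 0
#' and are reported in a log message (no within-stratum variance is estimable).
#'
#' @param conditions Inventory condition table.
#' @param by Character vector of grouping columns; must include
#'   `"supersection"` so that no group spans supersections.
#' @return Tibble with the grouping columns plus `mean_density` (tCO2e/acre),
#'   `variance` ((tCO2e/acre)^2), `n_conditions`, `total_acres`.
#' @export
estimate_common_practice <- function(conditions, by = c("supersection", "forest_type")) {
  if (!"supersection" %in% by) {
    abort("`by` must include \"supersection\": strata never span supersections")
  }
  missing <- setdiff(by, names(conditions))
  if (length(missing)) {
    abort(paste("grouping columns absent from table:",
                paste(missing, collapse = ", ")))
  }
  if (nrow(conditions) == 0) abort("empty condition table")
  out <- conditions |>
    group_by(dplyr::across(dplyr::all_of(by))) |>
    summarise(est = list(ratio_estimate(.data$carbon_density,
                                        .data$expansion_acres)),
              .groups = "drop") |>
    tidyr::unnest_wider("est")
  singletons <- sum(out$n_conditions == 1)
  if (singletons > 0) {
    inform(sprintf(
      "%d stratum/strata with a single condition: variance set to 0", singletons),
      class = "recredit_log")
  }
  out
}

#' Regulator-style common practice by assessment area
#'
#' Pools all forest types of each assessment area across the whole
#' supersection, the aggregation the offsets protocol uses, by delegating to
#' [estimate_common_practice()] after joining the forest-type to
#' assessment-area map.
#'
#' @param conditions Inventory condition table.
#' @param assessment_map Tibble with columns `supersection`, `forest_type`,
#'   `assessment_area` (see [assessment_map()]); every forest type present in
#'   `conditions` must be mapped.
#' @return Estimates keyed by (`supersection`, `assessment_area`).
#' @export
carb_common_practice <- function(conditions, assessment_map) {
  joined <- left_join(conditions, assessment_map,
                      by = c("supersection", "forest_type"))
  if (anyNA(joined$assessment_area)) {
    orphans <- unique(joined$forest_type[is.na(joined$assessment_area)])
    abort(paste("forest type(s) missing from assessment map:",
                paste(orphans, collapse = ", ")))
  }
  estimate_common_practice(joined, by = c("supersection", "assessment_area"))
}

#' Species-specific common practice by forest type
#'
#' The alternative stratification: conditions grouped by forest-type code
#' within each supersection, so that a project is compared only against plots
#' whose species composition resembles its own.
#'
#' @param conditions Inventory condition table.
#' @param expected_types Optional tibble (`supersection`, `forest_type`) of
#'   strata that should exist; strata with zero conditions are reported in a
#'   log message and are absent from the output.
#' @return Estimates keyed by (`supersection`, `forest_type`).
#' @export
species_specific_common_practice <- function(conditions, expected_types = NULL) {
  est <- estimate_common_practice(conditions, by = c("supersection", "forest_type"))
  if (!is.null(expected_types)) {
    missing <- dplyr::anti_join(expected_types, est,
                                by = c("supersection", "forest_type"))
    if (nrow(missing) > 0) {
      inform(paste("forest-type strata with no conditions (absent from output):",
                   paste(missing$supersection, missing$forest_type,
                         sep = "/", collapse = ", ")),
             class = "recredit_log")
    }
  }
  est
}

#' Ecosection aggregation diagnostic
#'
#' Compares the supersection-wide common practice against each ecosection's
#' own estimate for the same stratum, exposing the distortion introduced when
#' ecologically distinct ecosections are pooled into one supersection. The
#' reported change is `100 * (CP_super - CP_eco) / CP_eco`: a negative value
#' means pooling pulled the regional average below the ecosection's.
#'
#' @param conditions Inventory condition table, pre-filtered to the stratum of
#'   interest (e.g. one assessment area's forest types).
#' @return Tibble with one row per (`supersection`, `ecosection`):
#'   `cp_ecosection`, `cp_supersection`, `n_conditions`, and `pct_change`
#'   (missing where the ecosection estimate is zero).
#' @export
ecosection_diagnostic <- function(conditions) {
  if (nrow(conditions) == 0) abort("empty condition table")
  super <- estimate_common_practice(conditions, by = "supersection") |>
    select("supersection", cp_supersection = "mean_density")
  eco <- estimate_common_practice(conditions, by = c("supersection", "ecosection")) |>
    select("supersection", "ecosection", cp_ecosection = "mean_density",
           "n_conditions")
  out <- left_join(eco, super, by = "supersection")
  out$pct_change <- ifelse(out$cp_ecosection == 0, NA_real_,
                           100 * (out$cp_supersection - out$cp_ecosection) /
                             out$cp_ecosection)
  out
}
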