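#' Specify a forest type for a synthetic landscape
#'
#' A forest type is a canonical species grouping: inventory conditions of this
#' type draw their carbon density from a Normal distribution (censored at zero)
#' and their species mixture from a Dirichlet centred on `species_centroid`.
#'
#' @param code Forest-type code (character scalar), unique within a
#'   supersection.
#' @param mean_carbon Mean aboveground standing-live carbon density,
#'   tCO2e/acre (>= 0).
#' @param sd_carbon Standard deviation of carbon density, tCO2e/acre (>= 0).
#' @param species_centroid Named numeric vector of fractional basal area by
#'   species; must sum to 1 within 1e-9.
#' @param dirichlet_concentration Positive concentration multiplier; larger
#'   values give species mixtures tighter around the centroid.
#' @return A `forest_type_spec` list.
#' @export
forest_type_spec <- function(code, mean_carbon, sd_carbon, species_centroid,
                             dirichlet_concentration = 50) {
  stopifnot(is.character(code), length(code) == 1, nzchar(code))
  assert_scalar_number(mean_carbon, "mean_carbon", lower = 0)
  assert_scalar_number(sd_carbon, "sd_carbon", lower = 0)
  if (!is.numeric(dirichlet_concentration) || dirichlet_concentration <= 0) {
    abort("`dirichlet_concentration` must be a positive number")
  }
  if (is.null(names(species_centroid)) || any(!nzchar(names(species_centroid)))) {
    abort("`species_centroid` must be a named numeric vector")
  }
  if (any(species_centroid < 0) || abs(sum(species_centroid) - 1) > 1e-9) {
    abort(sprintf("species_centroid fractions for type '%s' must be >= 0 and sum to 1",
                  code))
  }
  structure(
    list(code = code, mean_carbon = mean_carbon, sd_carbon = sd_carbon,
         species_centroid = species_centroid,
         dirichlet_concentration = dirichlet_concentration),
    class = "forest_type_spec"
  )
}

#' Specify one supersection of a synthetic landscape
#'
#' A supersection is a geographic region built from ecosections; its forest
#' types are partitioned into named assessment areas (the strata regulators use
#' for common practice).
#'
#' @param name Supersection identifier.
#' @param ecosections Data frame (or tibble) with columns `ecosection`,
#'   `weight` (relative land area, > 0) and `offset` (additive carbon-density
#'   shift, tCO2e/acre).
#' @param forest_types List of [forest_type_spec()] objects.
#' @param assessment_areas Named list: assessment-area name -> character vector
#'   of forest-type codes. Must partition the forest-type codes exactly.
#' @return A `supersection_spec` list.
#' @export
supersection_spec <- function(name, ecosections, forest_types, assessment_areas) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  ecosections <- as_tibble(ecosections)
  if (!all(c("ecosection", "weight", "offset") %in% names(ecosections))) {
    abort("`ecosections` needs columns ecosection, weight, offset")
  }
  if (nrow(ecosections) < 1 || any(ecosections$weight <= 0)) {
    abort("ecosection area weights must be positive")
  }
  if (length(forest_types) == 0) {
    abort(sprintf("supersection '%s' has an empty forest-type list", name))
  }
  ok <- vapply(forest_types, inherits, logical(1), what = "forest_type_spec")
  if (!all(ok)) abort("`forest_types` must be a list of forest_type_spec objects")
  codes <- vapply(forest_types, `[[`, character(1), "code")
  if (anyDuplicated(codes)) abort("duplicate forest-type codes in one supersection")
  grouped <- unlist(assessment_areas, use.names = FALSE)
  if (is.null(names(assessment_areas)) || any(!nzchar(names(assessment_areas)))) {
    abort("`assessment_areas` must be a named list")
  }
  if (anyDuplicated(grouped) || !setequal(grouped, codes)) {
    abort(sprintf(
      "assessment areas of supersection '%s' must partition its forest-type codes",
      name))
  }
  structure(
    list(name = name, ecosections = ecosections, forest_types = forest_types,
         assessment_areas = assessment_areas),
    class = "supersection_spec"
  )
}

#' Configure a synthetic inventory landscape
#'
#' @param supersections List of [supersection_spec()] objects.
#' @param n_conditions_per_supersection Number of inventory conditions to
#'   generate per supersection (>= 0).
#' @param expansion_meanlog,expansion_sdlog Parameters of the lognormal
#'   distribution of per-condition acreage expansion factors; defaults give a
#'   median of about 5000 acres per condition, independent of strata.
#' @param seed Integer seed controlling all generation from this landscape.
#' @return A `landscape_config` object.
#' @export
landscape_config <- function(supersections, n_conditions_per_supersection,
                             expansion_meanlog = log(5000),
                             expansion_sdlog = 0.5, seed = 1L) {
  ok <- vapply(supersections, inherits, logical(1), what = "supersection_spec")
  if (length(supersections) == 0 || !all(ok)) {
    abort("`supersections` must be a non-empty list of supersection_spec objects")
  }
  nm <- vapply(supersections, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("duplicate supersection names")
  assert_scalar_number(n_conditions_per_supersection, "n_conditions_per_supersection",
                       lower = 0)
  structure(
    list(supersections = setNames(supersections, nm),
         n_conditions_per_supersection = as.integer(n_conditions_per_supersection),
         expansion_meanlog = expansion_meanlog,
         expansion_sdlog = expansion_sdlog,
         seed = as.integer(seed)),
    class = "landscape_config"
  )
}

#' @export
print.landscape_config <- function(x, ...) {
  cat("<landscape_config>\n")
  for (ss in x$supersections) {
    cat(sprintf("  %s: %d ecosections, %d forest types, %d assessment areas\n",
                ss$name, nrow(ss$ecosections), length(ss$forest_types),
                length(ss$assessment_areas)))
  }
  cat(sprintf("  conditions per supersection: %d (seed %d)\n",
              x$n_conditions_per_supersection, x$seed))
  invisible(x)
}

#' Forest-type to assessment-area lookup for a landscape
#'
#' @param landscape A [landscape_config()].
#' @return Tibble with columns `supersection`, `forest_type`,
#'   `assessment_area`.
#' @export
assessment_map <- function(landscape) {
  stopifnot(inherits(landscape, "landscape_config"))
  rows <- lapply(landscape$supersections, function(ss) {
    bind_rows(lapply(names(ss$assessment_areas), function(aa) {
      tibble(supersection = ss$name, forest_type = ss$assessment_areas[[aa]],
             assessment_area = aa)
    }))
  })
  bind_rows(rows)
}

#' Closed-form ground-truth common practice of a synthetic landscape
#'
#' True expected carbon density per (supersection, forest type) and per
#' (supersection, assessment area). Type truth is the ecosection-area-weighted
#' mean of the censored-Normal expectation `E[max(0, N(mean + offset, sd))]`;
#' assessment-area truth pools member types with equal weight, matching the
#' generator's uniform type sampling and strata-independent expansion acreage.
#'
#' @param landscape A [landscape_config()].
#' @return List with tibbles `forest_type` (`supersection`, `forest_type`,
#'   `assessment_area`, `true_cp`) and `assessment_area` (`supersection`,
#'   `assessment_area`, `true_cp`), densities in tCO2e/acre.
#' @export
ground_truth <- function(landscape) {
  stopifnot(inherits(landscape, "landscape_config"))
  ft <- bind_rows(lapply(landscape$supersections, function(ss) {
    w <- ss$ecosections$weight / sum(ss$ecosections$weight)
    bind_rows(lapply(ss$forest_types, function(ty) {
      mu_e <- ty$mean_carbon + ss$ecosections$offset
      tibble(supersection = ss$name, forest_type = ty$code,
             true_cp = sum(w * censored_normal_mean(mu_e, ty$sd_carbon)))
    }))
  }))
  ft <- left_join(ft, assessment_map(landscape),
                  by = c("supersection", "forest_type"))
  aa <- ft |>
    group_by(.data$supersection, .data$assessment_area) |>
    summarise(true_cp = mean(.data$true_cp), .groups = "drop")
  list(forest_type = select(ft, "supersection", "forest_type",
                            "assessment_area", "true_cp"),
       assessment_area = aa)
}

#' Configure synthetic offset-project generation
#'
#' @param n_projects Number of candidate projects drawn (the emitted table may
#'   be shorter: only candidates whose initial carbon density exceeds their
#'   reported common practice become projects).
#' @param adverse_selection_strength Non-negative tilt `gamma`: enrollment
#'   probability is proportional to `expansion_acres * exp(gamma * z)` where
#'   `z` is the condition's standardized carbon density. 0 means enrollment
#'   uniform over land area; large values enroll only carbon-dense parcels.
#' @param baseline_at_cp_fraction Fraction of projects whose 100-year baseline
#'   average equals reported common practice exactly (in `[0, 1]`).
#' @param baseline_noise_sd Half-Normal sd, tCO2e/acre, of the margin above
#'   common practice for the remaining projects.
#' @param acreage_range Length-2 numeric, min/max project acreage (min > 0).
#' @param confidence_deduction_range Length-2 numeric in `[0, 1)`.
#' @param secondary_effects_range Length-2 numeric, tCO2e, both <= 0.
#' @param species_report_level `"per-assessment-area"` or `"project-wide"`,
#'   mirroring the two reporting granularities found in project filings.
#' @param require_above_cp Emit only projects whose initial density exceeds
#'   reported common practice (the analysis scope rule); default `TRUE`.
#' @param seed Integer seed.
#' @return A `project_sim_config` object.
#' @export
project_sim_config <- function(n_projects,
                               adverse_selection_strength = 0,
                               baseline_at_cp_fraction = 0.89,
                               baseline_noise_sd = 20,
                               acreage_range = c(1000, 30000),
                               confidence_deduction_range = c(0, 0.05),
                               secondary_effects_range = c(-20000, 0),
                               species_report_level = c("per-assessment-area",
                                                        "project-wide"),
                               require_above_cp = TRUE,
                               seed = 1L) {
  assert_scalar_number(n_projects, "n_projects", lower = 0)
  assert_scalar_number(adverse_selection_strength, "adverse_selection_strength",
                       lower = 0)
  assert_scalar_number(baseline_at_cp_fraction, "baseline_at_cp_fraction",
                       lower = 0, upper = 1)
  assert_scalar_number(baseline_noise_sd, "baseline_noise_sd", lower = 0)
  stopifnot(length(acreage_range) == 2, acreage_range[1] > 0,
            diff(acreage_range) >= 0)
  stopifnot(length(confidence_deduction_range) == 2,
            confidence_deduction_range[1] >= 0,
            confidence_deduction_range[2] < 1,
            diff(confidence_deduction_range) >= 0)
  stopifnot(length(secondary_effects_range) == 2,
            all(secondary_effects_range <= 0),
            diff(secondary_effects_range) >= 0)
  species_report_level <- match.arg(species_report_level)
  structure(
    list(n_projects = as.integer(n_projects),
         adverse_selection_strength = adverse_selection_strength,
         baseline_at_cp_fraction = baseline_at_cp_fraction,
         baseline_noise_sd = baseline_noise_sd,
         acreage_range = acreage_range,
         confidence_deduction_range = confidence_deduction_range,
         secondary_effects_range = secondary_effects_range,
         species_report_level = species_report_level,
         require_above_cp = isTRUE(require_above_cp),
         seed = as.integer(seed)),
    class = "project_sim_config"
  )
}

#' @export
print.project_sim_config <- function(x, ...) {
  cat(sprintf(
    "<project_sim_config> %d candidates, gamma = %.2f, %.0f%% baselines at CP, seed %d\n",
    x$n_projects, x$adverse_selection_strength,
    100 * x$baseline_at_cp_fraction, x$seed))
  invisible(x)
}

#' Example two-supersection landscape
#'
#' A compact landscape modelled on the published regional averages that
#' motivate species-specific common practice: a "Southern Cascades"-like
#' supersection whose single mixed-conifer assessment area pools carbon-dense
#' Douglas-fir (122.5 tCO2e/acre) and tanoak (192.4) with arid ponderosa pine
#' (60.4) across three ecosections of unequal wetness, and a "Coastal
#' Alaska"-like supersection pooling Sitka spruce (121.1) and western hemlock
#' (143.0) with cottonwood (41.4) and paper birch (38.3).
#'
#' @param n_conditions Conditions per supersection (default 400).
#' @param seed Integer seed.
#' @return A [landscape_config()].
#' @export
example_landscape <- function(n_conditions = 400, seed = 1L) {
  sc <- supersection_spec(
    name = "Southern Cascades",
    ecosections = tibble(
      ecosection = c("M261A", "M261B", "M261D"),
      weight = c(0.35, 0.40, 0.25),
      offset = c(-5, 15, -15)
    ),
    forest_types = list(
      forest_type_spec("douglas_fir", 122.5, 35, c(
        douglas_fir = 0.65, tanoak = 0.10, white_fir = 0.15,
        ponderosa_pine = 0.10), 60),
      forest_type_spec("tanoak", 192.4, 45, c(
        tanoak = 0.60, douglas_fir = 0.30, madrone = 0.10), 60),
      forest_type_spec("ponderosa_pine", 60.4, 20, c(
        ponderosa_pine = 0.75, white_fir = 0.15, incense_cedar = 0.10), 60)
    ),
    assessment_areas = list(
      `Mixed Conifer` = c("douglas_fir", "tanoak", "ponderosa_pine")
    )
  )
  ak <- supersection_spec(
    name = "Coastal Alaska",
    ecosections = tibble(
      ecosection = c("AK-coast", "AK-inland"),
      weight = c(0.6, 0.4),
      offset = c(8, -12)
    ),
    forest_types = list(
      forest_type_spec("sitka_spruce", 121.1, 40, c(
        sitka_spruce = 0.80, western_hemlock = 0.20), 60),
      forest_type_spec("western_hemlock", 143.0, 40, c(
        western_hemlock = 0.70, sitka_spruce = 0.30), 60),
      forest_type_spec("cottonwood", 41.4, 15, c(
        cottonwood = 0.80, paper_birch = 0.20), 60),
      forest_type_spec("paper_birch", 38.3, 15, c(
        paper_birch = 0.75, cottonwood = 0.25), 60)
    ),
    assessment_areas = list(
      `Spruce-Hemlock` = c("sitka_spruce", "western_hemlock"),
      `Hardwoods` = c("cottonwood", "paper_birch")
    )
  )
  landscape_config(list(sc, ak), n_conditions_per_supersection = n_conditions,
                   seed = seed)
}
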