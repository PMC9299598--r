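# Shared fixtures: small landscapes built in code, hand-built project records,
# and independent oracles used across test files.

# One supersection, two forest types with disjoint species and well-separated
# carbon densities: classifiable exactly, heterogeneous means.
two_type_landscape <- function(n = 200, seed = 1L, sd_carbon = c(20, 20),
                               mean_carbon = c(150, 60), concentration = 60) {
  ss <- supersection_spec(
    name = "SS1",
    ecosections = tibble::tibble(ecosection = c("E1", "E2"),
                                 weight = c(0.6, 0.4), offset = c(5, -7.5)),
    forest_types = list(
      forest_type_spec("wet_conifer", mean_carbon[1], sd_carbon[1],
                       c(douglas_fir = 0.7, hemlock = 0.3), concentration),
      forest_type_spec("dry_pine", mean_carbon[2], sd_carbon[2],
                       c(ponderosa = 0.8, juniper = 0.2), concentration)
    ),
    assessment_areas = list(Mixed = c("wet_conifer", "dry_pine"))
  )
  landscape_config(list(ss), n_conditions_per_supersection = n, seed = seed)
}

# Equal expected carbon in every pooled type (species differ, carbon law does
# not): assessment-area pooling is ecologically neutral, so recrediting is
# unbiased even under the above-common-practice eligibility rule.
equal_mean_landscape <- function(n = 400, seed = 1L) {
  two_type_landscape(n = n, seed = seed, mean_carbon = c(100, 100),
                     sd_carbon = c(25, 25))
}

# Same species support for both types, low Dirichlet concentration: species
# mixtures overlap heavily, so held-out classification cannot be perfect.
overlapping_landscape <- function(n = 150, seed = 1L, concentration = 2) {
  ss <- supersection_spec(
    name = "SS1",
    ecosections = tibble::tibble(ecosection = "E1", weight = 1, offset = 0),
    forest_types = list(
      forest_type_spec("type_a", 120, 20,
                       c(douglas_fir = 0.55, hemlock = 0.45), concentration),
      forest_type_spec("type_b", 80, 20,
                       c(douglas_fir = 0.45, hemlock = 0.55), concentration)
    ),
    assessment_areas = list(All = c("type_a", "type_b"))
  )
  landscape_config(list(ss), n_conditions_per_supersection = n, seed = seed)
}

# A fully specified project record with arbitrary crediting components.
make_project <- function(project_id = "P1", supersection = "SS1",
                         acreage = 1000, initial_density = 170,
                         baseline_density = 130, reported_cp = 130,
                         wood_project = 0, wood_baseline = 0,
                         secondary = 0, deduction = 0,
                         assessment_area = "Mixed",
                         species = c(douglas_fir = 0.7, hemlock = 0.3),
                         species_level = "per-assessment-area",
                         area_acres = NULL, area_cp = NULL) {
  areas <- tibble::tibble(
    assessment_area = assessment_area,
    acres = area_acres %||% rep(acreage / length(assessment_area),
                                length(assessment_area)),
    reported_cp = area_cp %||% rep(reported_cp, length(assessment_area)))
  sp <- if (identical(species_level, "per-assessment-area")) {
    if (is.list(species)) {
      stats::setNames(species, assessment_area)
    } else {
      stats::setNames(rep(list(species), length(assessment_area)),
                      assessment_area)
    }
  } else {
    species
  }
  prj <- tibble::tibble(
    project_id = project_id, supersection = supersection, acreage = acreage,
    initial_onsite_carbon = initial_density * acreage,
    wood_products_project = wood_project,
    wood_products_baseline = wood_baseline,
    baseline_avg_density = baseline_density,
    secondary_effects = secondary, confidence_deduction = deduction,
    species_level = species_level,
    areas = list(areas), species = list(sp))
  prj$credits_issued <- compute_upfront_credits(prj)
  prj
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force loop oracle for the ratio-of-sums estimator.
oracle_ratio <- function(density, acres) {
  num <- 0
  den <- 0
  for (i in seq_along(density)) {
    num <- num + density[i] * acres[i]
    den <- den + acres[i]
  }
  num / den
}

# Point-estimate recrediting of a synthetic portfolio on its own landscape:
# species-specific estimates, per-supersection classifiers, rescaled common
# practice, recomputed credits. Returns the outcome tibble.
point_recredit <- function(landscape, inventory, projects,
                           classifier_seed = 1L) {
  amap <- assessment_map(landscape)
  ty <- suppressMessages(species_specific_common_practice(inventory))
  store <- suppressMessages(fit_classifiers(inventory, seed = classifier_seed))
  cls <- suppressMessages(classify_projects(store, projects))
  scaled <- portfolio_scaled_cp(projects, cls, ty, amap)
  crediting_outcomes(projects, recompute_credits(projects, scaled))
}
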