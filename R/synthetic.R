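# Synthetic inventory-condition and offset-project generation.
#
# The generator emulates the statistical structure the analysis assumes:
# supersections subdivided into ecosections of unequal land area and carbon
# density, forest types with characteristic species mixtures (Dirichlet around
# a centroid), design-based expansion acreage per condition, and projects that
# enroll preferentially in carbon-dense conditions and report baselines pinned
# at (or just above) regional common practice.

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) {
    # all-zero gamma draws are only possible for degenerate tiny alphas;
    # fall back to the centroid proportions
    g <- alpha
  }
  g / sum(g)
}

#' Generate a synthetic forest-inventory condition table
#'
#' Draws `n_conditions_per_supersection` condition records per supersection:
#' the ecosection is sampled by area weight, the forest type uniformly, the
#' species fractions from Dirichlet(centroid x concentration), the carbon
#' density from Normal(mean + ecosection offset, sd) censored at zero, and the
#' acreage expansion factor from the configured lognormal. Deterministic given
#' the landscape seed.
#'
#' @param landscape A [landscape_config()].
#' @param seed Optional seed overriding `landscape$seed`.
#' @return Tibble with columns `supersection`, `ecosection`, `forest_type`,
#'   `species_fractions` (list-column of named numeric vectors summing to 1),
#'   `carbon_density` (tCO2e/acre), `expansion_acres`.
#' @export
generate_inventory <- function(landscape, seed = landscape$seed) {
  stopifnot(inherits(landscape, "landscape_config"))
  n <- landscape$n_conditions_per_supersection
  if (n == 0) {
    return(tibble(supersection = character(), ecosection = character(),
                  forest_type = character(), species_fractions = list(),
                  carbon_density = numeric(), expansion_acres = numeric()))
  }
  with_seed(seed, {
    bind_rows(lapply(landscape$supersections, function(ss) {
      eco <- ss$ecosections
      e_idx <- sample.int(nrow(eco), n, replace = TRUE,
                          prob = eco$weight / sum(eco$weight))
      t_idx <- sample.int(length(ss$forest_types), n, replace = TRUE)
      fractions <- vector("list", n)
      carbon <- numeric(n)
      for (i in seq_len(n)) {
        ty <- ss$forest_types[[t_idx[i]]]
        fr <- rdirichlet_one(ty$species_centroid * ty$dirichlet_concentration)
        names(fr) <- names(ty$species_centroid)
        fractions[[i]] <- fr
        carbon[i] <- max(0, rnorm(1, ty$mean_carbon + eco$offset[e_idx[i]],
                                  ty$sd_carbon))
      }
      tibble(
        supersection = ss$name,
        ecosection = eco$ecosection[e_idx],
        forest_type = vapply(ss$forest_types, `[[`, character(1), "code")[t_idx],
        species_fractions = fractions,
        carbon_density = carbon,
        expansion_acres = rlnorm(n, landscape$expansion_meanlog,
                                 landscape$expansion_sdlog)
      )
    }))
  })
}

threshold_species <- function(fractions, threshold = 0.05) {
  keep <- fractions > threshold
  if (!any(keep)) keep <- seq_along(fractions) == which.max(fractions)
  out <- fractions[keep]
  out / sum(out)
}

#' Generate synthetic offset-project records
#'
#' Each candidate project enrolls one inventory condition, sampled with
#' probability proportional to `expansion_acres * exp(gamma * z)` where `z` is
#' the condition's carbon density standardized against the expansion-weighted
#' inventory moments (`gamma = 0` is enrollment uniform over land area).
#' Initial onsite carbon is the enrolled density times a drawn acreage; the
#' reported common practice is the landscape's ground-truth assessment-area
#' value; the 100-year baseline average sits exactly at common practice for
#' `baseline_at_cp_fraction` of candidates and at common practice plus a
#' half-Normal margin otherwise. Species composition is the enrolled
#' condition's, thresholded at 5% fractional basal area and renormalized.
#' Credits issued are computed with [compute_upfront_credits()]. Only
#' candidates whose initial carbon density exceeds their reported common
#' practice are emitted (the program's analysis scope); deterministic given the
#' config seed.
#'
#' @param config A [project_sim_config()].
#' @param landscape The [landscape_config()] that produced `inventory`.
#' @param inventory Condition table from [generate_inventory()].
#' @return Tibble of project records; one row per emitted project, with
#'   scalar crediting fields, an `areas` list-column (per-assessment-area
#'   acreage and reported common practice) and a `species` list-column.
#' @export
generate_projects <- function(config, landscape, inventory) {
  stopifnot(inherits(config, "project_sim_config"),
            inherits(landscape, "landscape_config"))
  if (nrow(inventory) == 0) abort("`inventory` is empty")
  gt <- ground_truth(landscape)
  amap <- assessment_map(landscape)
  cond <- left_join(inventory, amap, by = c("supersection", "forest_type"))
  if (anyNA(cond$assessment_area)) {
    abort("inventory contains forest types absent from the landscape's assessment areas")
  }
  aa_cp <- setNames(gt$assessment_area$true_cp,
                    paste(gt$assessment_area$supersection,
                          gt$assessment_area$assessment_area, sep = "\r"))

  with_seed(config$seed, {
    a <- cond$expansion_acres
    d <- cond$carbon_density
    wm <- sum(d * a) / sum(a)
    wsd <- sqrt(sum(a * (d - wm)^2) / sum(a))
    z <- if (wsd > 0) (d - wm) / wsd else rep(0, length(d))
    w <- a * exp(config$adverse_selection_strength * z)
    idx <- sample.int(nrow(cond), config$n_projects, replace = TRUE,
                      prob = w / sum(w))

    np <- config$n_projects
    acreage <- runif(np, config$acreage_range[1], config$acreage_range[2])
    deduction <- runif(np, config$confidence_deduction_range[1],
                       config$confidence_deduction_range[2])
    secondary <- runif(np, config$secondary_effects_range[1],
                       config$secondary_effects_range[2])
    at_cp <- runif(np) < config$baseline_at_cp_fraction
    margin <- ifelse(at_cp, 0, abs(rnorm(np, 0, config$baseline_noise_sd)))

    enrolled <- cond[idx, ]
    reported_cp <- unname(aa_cp[paste(enrolled$supersection,
                                      enrolled$assessment_area, sep = "\r")])
    projects <- tibble(
      project_id = sprintf("SYN%04d", seq_len(np)),
      supersection = enrolled$supersection,
      acreage = acreage,
      initial_onsite_carbon = enrolled$carbon_density * acreage,
      wood_products_project = 0,
      wood_products_baseline = 0,
      baseline_avg_density = reported_cp + margin,
      secondary_effects = secondary,
      confidence_deduction = deduction,
      reported_cp = reported_cp,
      true_forest_type = enrolled$forest_type,
      species_level = config$species_report_level,
      areas = lapply(seq_len(np), function(i) {
        tibble(assessment_area = enrolled$assessment_area[i],
               acres = acreage[i], reported_cp = reported_cp[i])
      }),
      species = lapply(seq_len(np), function(i) {
        comp <- threshold_species(enrolled$species_fractions[[i]])
        if (config$species_report_level == "per-assessment-area") {
          setNames(list(comp), enrolled$assessment_area[i])
        } else {
          comp
        }
      })
    )
    projects$credits_issued <- compute_upfront_credits(projects)
    if (config$require_above_cp) {
      projects <- projects[projects$initial_onsite_carbon / projects$acreage >
                             projects$reported_cp, ]
    }
    projects
  })
}
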