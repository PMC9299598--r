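# Monte Carlo propagation of inventory sampling uncertainty into crediting
# errors.
#
# Forest-type mean densities are perturbed with Gaussian noise (sd = sqrt of
# the ratio-estimator variance). Each forest type owns a keyed random-number
# stream, so one draw of a type's density is reused consistently everywhere
# that type enters an iteration — in the species-specific (alternative) common
# practice and in the rebuilt assessment-area reference — preserving the
# correlation implied by both being computed from the same inventory. Draws
# are not truncated at zero (the Gaussian assumption is kept); negative common
# practice values are floored at zero only at the credit-computation step,
# with a count kept for the run log.

#' Monte Carlo configuration
#'
#' @param n_draws Number of draws (default 1000).
#' @param seed Integer seed; every forest type derives its own substream from
#'   it, so adding strata or projects never changes existing draws.
#' @param percentiles Program-level percentiles to report, strictly increasing
#'   in (0, 100); default the 5th, 50th and 95th.
#' @return A `mc_config` object.
#' @export
mc_config <- function(n_draws = 1000, seed = 1L, percentiles = c(5, 50, 95)) {
  assert_scalar_number(n_draws, "n_draws", lower = 1)
  if (any(percentiles <= 0 | percentiles >= 100) || is.unsorted(percentiles, strictly = TRUE)) {
    abort("`percentiles` must be strictly increasing within (0, 100)")
  }
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 percentiles = percentiles),
            class = "mc_config")
}

type_stream_seed <- function(config_seed, supersection, forest_type) {
  key <- paste(supersection, forest_type, sep = "\r")
  as.integer((config_seed + 7919 * as.double(string_seed(key))) %% 2147483647)
}

check_type_estimates <- function(type_estimates) {
  needed <- c("supersection", "forest_type", "mean_density", "variance",
              "total_acres")
  missing <- setdiff(needed, names(type_estimates))
  if (length(missing)) {
    abort(paste("type estimates missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(type_estimates$variance < 0)) abort("negative variance in estimates")
  invisible(type_estimates)
}

# Matrix of Gaussian density draws: one row per forest-type stratum, one
# column per draw. Row i's stream depends only on (seed, supersection, type),
# and column j is identical however many total draws are requested.
type_draw_matrix <- function(type_estimates, config, n_draws = config$n_draws) {
  check_type_estimates(type_estimates)
  sd <- sqrt(type_estimates$variance)
  m <- matrix(NA_real_, nrow(type_estimates), n_draws)
  for (i in seq_len(nrow(type_estimates))) {
    s <- type_stream_seed(config$seed, type_estimates$supersection[i],
                          type_estimates$forest_type[i])
    m[i, ] <- with_seed(s, rnorm(n_draws, type_estimates$mean_density[i], sd[i]))
  }
  rownames(m) <- paste(type_estimates$supersection, type_estimates$forest_type,
                       sep = "\r")
  m
}

#' One Monte Carlo draw of the forest-type carbon estimates
#'
#' Replaces each stratum's mean density with a Gaussian draw
#' `Normal(mean_density, sqrt(variance))` from that stratum's keyed stream.
#' Deterministic given the config seed and `draw_index`, and independent of
#' how many other draws or strata exist.
#'
#' @param type_estimates Estimates from [species_specific_common_practice()].
#' @param config A [mc_config()].
#' @param draw_index Which draw to return (1-based).
#' @return `type_estimates` with `mean_density` perturbed.
#' @export
draw_carbon_estimates <- function(type_estimates, config, draw_index) {
  stopifnot(inherits(config, "mc_config"))
  assert_scalar_number(draw_index, "draw_index", lower = 1)
  m <- type_draw_matrix(type_estimates, config, n_draws = draw_index)
  out <- type_estimates
  out$mean_density <- unname(m[, draw_index])
  out
}

# Internal geometry shared by the point estimate and every draw: maps a named
# vector/matrix of forest-type densities to per-project scaled common practice.
build_scaling_geometry <- function(projects, classifications, type_estimates,
                                   assessment_map,
                                   alt_method = c("posterior", "argmax")) {
  alt_method <- match.arg(alt_method)
  check_type_estimates(type_estimates)
  type_key <- paste(type_estimates$supersection, type_estimates$forest_type,
                    sep = "\r")

  # assessment-area reference: acreage-weighted combination of member types,
  # identical to the pooled ratio estimate at the point values
  aa_members <- left_join(type_estimates, assessment_map,
                          by = c("supersection", "forest_type"))
  if (anyNA(aa_members$assessment_area)) {
    abort("forest type(s) in estimates missing from the assessment map")
  }
  aa_key <- unique(paste(aa_members$supersection, aa_members$assessment_area,
                         sep = "\r"))
  bmat <- matrix(0, length(aa_key), length(type_key),
                 dimnames = list(aa_key, type_key))
  for (i in seq_len(nrow(aa_members))) {
    k <- paste(aa_members$supersection[i], aa_members$assessment_area[i],
               sep = "\r")
    bmat[k, type_key[i]] <- aa_members$total_acres[i]
  }
  bmat <- bmat / rowSums(bmat)

  # project-area rows: classifier probabilities over types, plus the project
  # acreage weight of each area
  pa <- left_join(classifications,
                  tibble(project_id = projects$project_id,
                         supersection = projects$supersection),
                  by = "project_id")
  if (nrow(pa) == 0) abort("no classifications supplied")
  amat <- matrix(0, nrow(pa), length(type_key),
                 dimnames = list(NULL, type_key))
  for (i in seq_len(nrow(pa))) {
    p <- pa$probs[[i]]
    if (alt_method == "argmax") {
      hard <- names(p)[which.max(p)]
      p <- setNames(1, hard)
    }
    keys <- paste(pa$supersection[i], names(p), sep = "\r")
    if (!all(keys %in% type_key)) {
      abort(sprintf("no common-practice estimate for forest type(s) %s",
                    paste(names(p)[!keys %in% type_key], collapse = ", ")))
    }
    amat[i, keys] <- p
  }
  aa_of_pa <- match(paste(pa$supersection, pa$assessment_area, sep = "\r"),
                    aa_key)
  if (anyNA(aa_of_pa)) {
    abort("project assessment area(s) absent from the estimates")
  }
  proj_of_pa <- match(pa$project_id, projects$project_id)
  w_pa <- vapply(seq_len(nrow(pa)), function(i) {
    a <- projects$areas[[proj_of_pa[i]]]
    a$acres[a$assessment_area == pa$assessment_area[i]][1] / sum(a$acres)
  }, numeric(1))
  list(amat = amat, bmat = bmat, aa_of_pa = aa_of_pa,
       proj_of_pa = proj_of_pa, w_pa = w_pa,
       reported = project_reported_cp(projects))
}

# Scaled common practice (projects x draws) from type-density draw matrix m
# (types x draws, rows keyed like the geometry) and reference matrix m_ref.
scaled_cp_matrix <- function(geom, projects, m, m_ref = m) {
  alt <- geom$amat %*% m
  ref <- geom$bmat %*% m_ref
  if (any(!is.finite(ref)) || any(ref == 0)) {
    abort("recomputed assessment-area common practice hit zero: ratio undefined")
  }
  ratio <- alt / ref[geom$aa_of_pa, , drop = FALSE]
  grp <- factor(geom$proj_of_pa, levels = seq_len(nrow(projects)))
  scaled <- rowsum(ratio * geom$w_pa, grp)
  scaled * geom$reported
}

#' Point-estimate scaled common practice for a portfolio
#'
#' The alternative common practice of each project assessment area is the
#' classifier-probability-weighted mean of the per-forest-type estimates
#' (`alt_method = "posterior"`; `"argmax"` pools on the most probable type
#' instead), and the reference is the acreage-weighted recombination of the
#' same per-type estimates into assessment areas. See
#' [scale_common_practice()] for the single-project arithmetic.
#'
#' @param projects Project tibble.
#' @param classifications Tibble from [classify_projects()].
#' @param type_estimates Estimates from [species_specific_common_practice()].
#' @param assessment_map Forest-type to assessment-area map.
#' @param alt_method `"posterior"` or `"argmax"`.
#' @return Numeric vector of scaled common practice per project, tCO2e/acre.
#' @export
portfolio_scaled_cp <- function(projects, classifications, type_estimates,
                                assessment_map,
                                alt_method = c("posterior", "argmax")) {
  geom <- build_scaling_geometry(projects, classifications, type_estimates,
                                 assessment_map, alt_method)
  m <- matrix(type_estimates$mean_density, ncol = 1,
              dimnames = list(paste(type_estimates$supersection,
                                    type_estimates$forest_type, sep = "\r"),
                              NULL))
  scaled_cp_matrix(geom, projects, m)[, 1]
}

#' Propagate inventory uncertainty into crediting-error distributions
#'
#' For each Monte Carlo draw, perturbs the forest-type mean densities with
#' Gaussian noise, rebuilds both the alternative common practice and (by
#' default) the assessment-area reference from the same draw, rescales each
#' project's common practice, recomputes credits and crediting errors, and
#' totals the program-wide error. Summaries are empirical percentiles over
#' draws; program percentiles are taken on per-draw program totals, never by
#' summing per-project percentiles.
#'
#' @inheritParams portfolio_scaled_cp
#' @param config A [mc_config()].
#' @param baseline_mode Passed to [recompute_credits()].
#' @param perturb_reference Rebuild the assessment-area reference from the
#'   same perturbed draw (default `TRUE`, preserving numerator/denominator
#'   correlation); `FALSE` holds the reference at its point value.
#' @return List with `outcomes` (per-project tibble: point estimates plus
#'   `p<q>` error percentiles and matching `p<q>_percent` columns),
#'   `program` ([aggregate_program()] summary with percentiles),
#'   `program_draws` (per-draw net program error, tCO2e), and `n_floored`
#'   (count of negative common-practice values floored at credit time).
#' @export
propagate <- function(projects, classifications, type_estimates, assessment_map,
                      config = mc_config(),
                      baseline_mode = c("preserve-margin", "snap-to-cp"),
                      perturb_reference = TRUE,
                      alt_method = c("posterior", "argmax"),
                      price = 13.67) {
  stopifnot(inherits(config, "mc_config"))
  baseline_mode <- match.arg(baseline_mode)
  if (config$n_draws < 20 && any(config$percentiles <= 5 | config$percentiles >= 95)) {
    warn("fewer than 20 draws: extreme percentiles will be unstable")
  }
  geom <- build_scaling_geometry(projects, classifications, type_estimates,
                                 assessment_map, alt_method)
  point_m <- matrix(type_estimates$mean_density, ncol = 1,
                    dimnames = list(paste(type_estimates$supersection,
                                          type_estimates$forest_type,
                                          sep = "\r"), NULL))
  draws <- type_draw_matrix(type_estimates, config)

  scaled_point <- scaled_cp_matrix(geom, projects, point_m)[, 1]
  scaled_draws <- scaled_cp_matrix(geom, projects, draws,
                                   m_ref = if (perturb_reference) draws else
                                     point_m[, rep(1, config$n_draws), drop = FALSE])

  n_floored <- 0L
  recomputed_point <- recompute_credits(projects, scaled_point, baseline_mode)
  n_floored <- n_floored + attr(recomputed_point, "n_floored")
  err <- matrix(NA_real_, nrow(projects), config$n_draws)
  for (j in seq_len(config$n_draws)) {
    cr <- recompute_credits(projects, scaled_draws[, j], baseline_mode)
    n_floored <- n_floored + attr(cr, "n_floored")
    err[, j] <- projects$credits_issued - as.numeric(cr)
  }

  project_pcts <- sort(unique(c(config$percentiles, 25, 75)))
  qmat <- t(apply(err, 1, quantile, probs = project_pcts / 100,
                  names = FALSE, type = 7))
  outcomes <- crediting_outcomes(projects, recomputed_point)
  for (k in seq_along(project_pcts)) {
    outcomes[[sprintf("p%g", project_pcts[k])]] <- qmat[, k]
    outcomes[[sprintf("p%g_percent", project_pcts[k])]] <-
      ifelse(outcomes$credits_issued > 0,
             100 * qmat[, k] / outcomes$credits_issued, NA_real_)
  }
  outcomes$scaled_cp <- scaled_point
  outcomes$reported_cp <- project_reported_cp(projects)

  program_draws <- colSums(err)
  program <- aggregate_program(outcomes, price = price,
                               program_draws = program_draws,
                               percentiles = config$percentiles)
  list(outcomes = outcomes, program = program, program_draws = program_draws,
       n_floored = n_floored)
}
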