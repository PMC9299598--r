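# Synthetic inventory and project generation.

test_that("generated conditions respect construction invariants and empty case", {
  empty <- generate_inventory(two_type_landscape(n = 0))
  expect_equal(nrow(empty), 0)

  inv <- generate_inventory(two_type_landscape(n = 150, seed = 4))
  expect_equal(nrow(inv), 150)
  sums <- vapply(inv$species_fractions, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(inv$carbon_density >= 0))
  expect_true(all(inv$expansion_acres > 0))
  expect_true(all(inv$forest_type %in% c("wet_conifer", "dry_pine")))
  expect_true(all(inv$ecosection %in% c("E1", "E2")))
})

test_that("generation is deterministic given config and seed", {
  ls1 <- two_type_landscape(n = 60, seed = 9)
  expect_identical(generate_inventory(ls1), generate_inventory(ls1))
  inv <- generate_inventory(ls1)
  cfg <- project_sim_config(n_projects = 25, adverse_selection_strength = 1,
                            seed = 5)
  expect_identical(generate_projects(cfg, ls1, inv),
                   generate_projects(cfg, ls1, inv))
  # a different seed produces different draws
  ls2 <- two_type_landscape(n = 60, seed = 10)
  expect_false(identical(generate_inventory(ls1)$carbon_density,
                         generate_inventory(ls2)$carbon_density))
})

test_that("expansion-weighted mean carbon falls in its analytic 99% interval", {
  # single type, single ecosection: densities iid Normal(100, 10), censoring
  # negligible ten sds from zero
  ss <- supersection_spec(
    "S", tibble::tibble(ecosection = "E", weight = 1, offset = 0),
    list(forest_type_spec("only", 100, 10, c(fir = 1), 50)),
    list(AA = "only"))
  ls1 <- landscape_config(list(ss), n_conditions_per_supersection = 500,
                          seed = 21)
  inv <- generate_inventory(ls1)
  w <- inv$expansion_acres / sum(inv$expansion_acres)
  wmean <- sum(w * inv$carbon_density)
  # SE of a weighted mean of iid draws: sigma * sqrt(sum(w^2))
  half_width <- 2.576 * 10 * sqrt(sum(w^2))
  expect_lt(abs(wmean - 100), half_width)
})

test_that("configuration errors are rejected", {
  expect_error(project_sim_config(10, adverse_selection_strength = -1))
  expect_error(forest_type_spec("x", 100, 10, c(a = 1), -2),
               "dirichlet_concentration")
  expect_error(forest_type_spec("x", 100, 10, c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(supersection_spec(
    "S", tibble::tibble(ecosection = "E", weight = 1, offset = 0),
    list(), list()), "empty forest-type")
  ls1 <- two_type_landscape(n = 10)
  cfg <- project_sim_config(5)
  expect_error(generate_projects(cfg, ls1, generate_inventory(two_type_landscape(n = 0))),
               "empty")
})

test_that("uniform enrollment matches an area-weighted resampling oracle", {
  ls1 <- two_type_landscape(n = 400, seed = 2)
  inv <- generate_inventory(ls1)
  cfg <- project_sim_config(n_projects = 600, adverse_selection_strength = 0,
                            seed = 31)
  prj <- generate_projects(cfg, ls1, inv)
  enrolled_mean <- mean(prj$initial_onsite_carbon / prj$acreage)

  # oracle: resample conditions proportional to acreage, apply the same
  # above-common-practice eligibility rule, average the densities
  gt <- ground_truth(ls1)
  amap <- assessment_map(ls1)
  cond <- dplyr::left_join(inv, amap, by = c("supersection", "forest_type"))
  cond <- dplyr::left_join(cond, gt$assessment_area,
                           by = c("supersection", "assessment_area"))
  oracle_draws <- withr::with_seed(99, {
    idx <- sample.int(nrow(cond), 20000, replace = TRUE,
                      prob = cond$expansion_acres)
    d <- cond$carbon_density[idx]
    d[d > cond$true_cp[idx]]
  })
  se <- stats::sd(oracle_draws) *
    sqrt(1 / length(oracle_draws) + 1 / nrow(prj))
  expect_lt(abs(enrolled_mean - mean(oracle_draws)), 4 * se)
})

test_that("strong adverse selection tilts enrollment toward carbon-dense conditions", {
  ls1 <- two_type_landscape(n = 300, seed = 2)
  inv <- generate_inventory(ls1)
  landscape_mean <- sum(inv$carbon_density * inv$expansion_acres) /
    sum(inv$expansion_acres)
  prj <- generate_projects(
    project_sim_config(n_projects = 200, adverse_selection_strength = 5,
                       seed = 8), ls1, inv)
  expect_gt(mean(prj$initial_onsite_carbon / prj$acreage), landscape_mean)
})

test_that("mean enrolled carbon density is nondecreasing in the selection tilt", {
  ls1 <- two_type_landscape(n = 300, seed = 2)
  inv <- generate_inventory(ls1)
  means <- vapply(c(0, 1, 5), function(g) {
    prj <- generate_projects(
      project_sim_config(n_projects = 200, adverse_selection_strength = g,
                         seed = 8), ls1, inv)
    mean(prj$initial_onsite_carbon / prj$acreage)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("baselines and eligibility follow the configured rules", {
  ls1 <- two_type_landscape(n = 200, seed = 3)
  inv <- generate_inventory(ls1)
  at_cp <- generate_projects(
    project_sim_config(n_projects = 60, baseline_at_cp_fraction = 1, seed = 4),
    ls1, inv)
  expect_equal(at_cp$baseline_avg_density, at_cp$reported_cp)

  noisy <- generate_projects(
    project_sim_config(n_projects = 60, baseline_at_cp_fraction = 0,
                       baseline_noise_sd = 15, seed = 4), ls1, inv)
  expect_true(all(noisy$baseline_avg_density >= noisy$reported_cp))
  expect_true(any(noisy$baseline_avg_density > noisy$reported_cp))
  # analysis scope: initial density strictly above reported common practice
  expect_true(all(noisy$initial_onsite_carbon / noisy$acreage >
                    noisy$reported_cp))
  # issuance is replicable from components by construction
  expect_equal(compute_upfront_credits(noisy), noisy$credits_issued)
})

test_that("species compositions are thresholded at 5% and renormalized", {
  ls1 <- two_type_landscape(n = 120, seed = 6)
  inv <- generate_inventory(ls1)
  prj <- generate_projects(project_sim_config(n_projects = 40, seed = 7),
                           ls1, inv)
  for (sp in prj$species) {
    comp <- sp[[1]]
    # renormalization only scales retained fractions up, so all stay above 5%
    expect_true(all(comp > 0.05))
    expect_equal(sum(comp), 1, tolerance = 1e-12)
  }
  pw <- generate_projects(
    project_sim_config(n_projects = 10, species_report_level = "project-wide",
                       seed = 7), ls1, inv)
  expect_true(is.numeric(pw$species[[1]]))
})

test_that("estimates recover generator ground truth within three standard errors", {
  ls1 <- example_landscape(n_conditions = 500, seed = 12)
  inv <- generate_inventory(ls1)
  gt <- ground_truth(ls1)

  ty <- suppressMessages(species_specific_common_practice(inv))
  chk <- dplyr::left_join(ty, gt$forest_type,
                          by = c("supersection", "forest_type"))
  expect_true(all(abs(chk$mean_density - chk$true_cp) <=
                    3 * sqrt(chk$variance)))

  aa <- suppressMessages(carb_common_practice(inv, assessment_map(ls1)))
  chk2 <- dplyr::left_join(aa, gt$assessment_area,
                           by = c("supersection", "assessment_area"))
  expect_true(all(abs(chk2$mean_density - chk2$true_cp) <=
                     3 * sqrt(chk2$variance)))
})
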