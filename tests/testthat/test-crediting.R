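# Upfront credit issuance, rescaled common practice, recrediting, and program
# aggregation.

test_that("upfront credits reproduce hand-computed protocol arithmetic", {
  # no delta between project and baseline -> zero credits
  flat <- make_project(initial_density = 130, baseline_density = 130)
  expect_equal(flat$credits_issued, 0)

  # initial 170 tCO2e/acre on 1000 acres, baseline 130, secondary -5000,
  # 5% confidence deduction: (40000 - 5000) * 0.95
  p <- make_project(initial_density = 170, baseline_density = 130,
                    secondary = -5000, deduction = 0.05)
  expect_equal(p$credits_issued, 33250)

  # full confidence deduction wipes out issuance
  full <- make_project(initial_density = 170, baseline_density = 130,
                       deduction = 1)
  expect_equal(full$credits_issued, 0)

  # wood products enter with opposite signs for project and baseline
  wp <- make_project(initial_density = 170, baseline_density = 130,
                     wood_project = 2000, wood_baseline = 500)
  expect_equal(wp$credits_issued, 40000 + 2000 - 500)

  # credits floor at zero rather than going negative
  under <- make_project(initial_density = 120, baseline_density = 130)
  expect_equal(under$credits_issued, 0)

  expect_error(compute_upfront_credits(tibble::tibble(acreage = 10)),
               "missing crediting fields")
})

test_that("issuance replication is exact on generated records and sensitive to perturbation", {
  ls1 <- two_type_landscape(n = 150, seed = 2)
  prj <- generate_projects(project_sim_config(n_projects = 30, seed = 3),
                           ls1, generate_inventory(ls1))
  expect_equal(replicate_issuance(prj)$r_squared, 1)

  perturbed <- prj
  perturbed$credits_issued[1] <- perturbed$credits_issued[1] * 1.2 + 1000
  expect_lt(replicate_issuance(perturbed)$r_squared, 1)

  constant <- prj[1:3, ]
  constant$credits_issued <- 5000
  expect_message(r <- replicate_issuance(constant)$r_squared, "undefined")
  expect_true(is.na(r))
  expect_true(is.na(suppressMessages(replicate_issuance(prj[1, ])$r_squared)))
})

test_that("common-practice scaling follows the weighted-ratio arithmetic", {
  p1 <- make_project(reported_cp = 100, baseline_density = 100)
  # identical alternative and recomputed estimates leave CP unchanged
  expect_equal(scale_common_practice(p1, c(Mixed = 120), c(Mixed = 120)), 100)
  # single area, ratio 1.2
  expect_equal(scale_common_practice(p1, c(Mixed = 120), c(Mixed = 100)), 120)

  # two areas, weights 0.25/0.75, ratios 0.9/1.1 -> 100 * 1.05
  p2 <- make_project(reported_cp = 100, baseline_density = 100,
                     assessment_area = c("A1", "A2"),
                     area_acres = c(250, 750), area_cp = c(100, 100),
                     species = list(c(a = 1), c(b = 1)))
  expect_equal(
    scale_common_practice(p2, c(A1 = 90, A2 = 110), c(A1 = 100, A2 = 100)),
    105)

  expect_error(scale_common_practice(p1, c(Mixed = 120), c(Mixed = 0)),
               "ratio undefined")
  expect_error(scale_common_practice(p1, c(Other = 120), c(Other = 100)),
               "missing")
})

test_that("recrediting responds linearly to the new baseline and caps at full issuance", {
  # scaled CP equal to the original baseline: nothing changes
  p <- make_project(initial_density = 170, baseline_density = 100,
                    reported_cp = 100)
  expect_equal(as.numeric(recompute_credits(p, 100)), p$credits_issued)

  # baseline at CP 100, scaled CP 110, 1000 acres: credits fall by 10000
  r <- as.numeric(recompute_credits(p, 110))
  expect_equal(p$credits_issued - r, 10000)

  # scaled CP at/above initial onsite density: project earns nothing
  r0 <- as.numeric(recompute_credits(p, 170))
  expect_equal(r0, 0)
  out <- crediting_outcomes(p, r0)
  expect_equal(out$error_percent, 100)
})

test_that("baseline margin above common practice is preserved or snapped by mode", {
  # baseline 20 above its reported CP
  p <- make_project(initial_density = 200, baseline_density = 120,
                    reported_cp = 100)
  preserved <- as.numeric(recompute_credits(p, 110, "preserve-margin"))
  expect_equal(p$credits_issued - preserved, 10 * 1000) # margin kept, CP +10
  snapped <- as.numeric(recompute_credits(p, 110, "snap-to-cp"))
  expect_equal(snapped, (200 - 110) * 1000) # margin forfeited

  # negative scaled CP floors at zero and is counted
  fl <- recompute_credits(p, -5)
  expect_equal(attr(fl, "n_floored"), 1L)
  expect_equal(as.numeric(fl), (200 - 20) * 1000) # baseline = 0 + margin 20
})

test_that("doubling acreage at fixed densities doubles every crediting error", {
  ls1 <- two_type_landscape(n = 200, seed = 2)
  inv <- generate_inventory(ls1)
  prj <- generate_projects(project_sim_config(n_projects = 30,
                                              adverse_selection_strength = 1,
                                              seed = 3), ls1, inv)
  scaled <- withr::with_seed(5, runif(nrow(prj), 80, 130))
  base_err <- crediting_outcomes(prj, recompute_credits(prj, scaled))$crediting_error

  doubled <- prj
  doubled$acreage <- prj$acreage * 2
  doubled$initial_onsite_carbon <- prj$initial_onsite_carbon * 2
  doubled$secondary_effects <- prj$secondary_effects * 2
  doubled$areas <- lapply(prj$areas, function(a) {
    a$acres <- a$acres * 2
    a
  })
  doubled$credits_issued <- compute_upfront_credits(doubled)
  dbl_err <- crediting_outcomes(doubled,
                                recompute_credits(doubled, scaled))$crediting_error
  expect_equal(dbl_err, 2 * base_err)
})

test_that("projects with species-specific CP below their area CP are under-credited", {
  # means close enough that both types produce eligible (above-CP) conditions
  ls1 <- two_type_landscape(n = 300, seed = 2, mean_carbon = c(140, 100),
                            sd_carbon = c(20, 20))
  inv <- generate_inventory(ls1)
  prj <- generate_projects(project_sim_config(n_projects = 120, seed = 3),
                           ls1, inv)
  out <- point_recredit(ls1, inv, prj)
  ty <- suppressMessages(species_specific_common_practice(inv))
  merged <- dplyr::left_join(
    tibble::tibble(project_id = prj$project_id,
                   forest_type = prj$true_forest_type,
                   supersection = prj$supersection),
    ty, by = c("supersection", "forest_type"))
  merged <- dplyr::left_join(merged, out, by = "project_id")
  aa <- suppressMessages(carb_common_practice(inv, assessment_map(ls1)))
  # dry-pine projects: type CP far below the pooled assessment-area CP
  dry <- merged[merged$forest_type == "dry_pine" & merged$credits_issued > 0, ]
  expect_gt(nrow(dry), 0)
  expect_true(all(dry$crediting_error < 0))
  wet <- merged[merged$forest_type == "wet_conifer" & merged$credits_issued > 0, ]
  expect_true(all(wet$crediting_error > 0))
})

test_that("program aggregation applies the percent and dollar transforms", {
  outcomes <- tibble::tibble(
    project_id = c("a", "b"), credits_issued = c(60e6, 42.1e6),
    credits_recomputed = c(40e6, 32.1e6),
    crediting_error = c(20e6, 10e6),
    error_percent = c(100 * 20 / 60, 100 * 10 / 42.1))
  summary <- aggregate_program(outcomes, total_analyzed_credits = 102.1e6,
                               price = 13.67)
  expect_equal(summary$net_error, 30e6)
  expect_equal(round(summary$percent_of_analyzed, 1), 29.4)
  expect_equal(round(summary$value_usd / 1e6), 410)

  empty <- aggregate_program(outcomes[0, ])
  expect_equal(empty$net_error, 0)
  expect_true(is.na(empty$percent_of_analyzed))

  expect_error(aggregate_program(outcomes, total_analyzed_credits = 0),
               "positive")

  draws <- c(25e6, 30e6, 35e6)
  with_ci <- aggregate_program(outcomes, total_analyzed_credits = 102.1e6,
                               program_draws = draws, percentiles = c(5, 50, 95))
  expect_equal(with_ci$percentiles$net_error[2], 30e6)
  expect_true(all(diff(with_ci$percentiles$net_error) >= 0))
})

test_that("buffer depletion and credit valuation are simple audited ratios", {
  expect_equal(buffer_depletion(20.5e6, 24.6e6), 83)
  expect_equal(buffer_depletion(0, 24.6e6), 0)
  expect_equal(buffer_depletion(24.6e6, 24.6e6), 100)
  expect_error(buffer_depletion(1e6, 0), "positive")
  expect_equal(credit_value(193e6, 13.67) / 1e9, 2.638, tolerance = 1e-3)
  expect_error(credit_value(1, price = -1), "positive")
})
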