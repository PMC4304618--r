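test_that("sugar-free scenario neither grows nor expresses", {
  ct <- default_constants()
  sc <- scenario(strains = c("lacZ", ct$background_strain),
                 sugar_mix = numeric(0), duration = 5)
  tr <- simulate_batch(sc, ct)
  expect_true(all(tr$od == sc$inoculum_od))
  # GFP accumulates at the shared autofluorescence (baseline) rate only
  expect_equal(tr$gfp[, "lacZ"], tr$gfp[, ct$background_strain])
  expect_equal(max(tr$gfp[, "lacZ"]),
               ct$autofluor_rate * sc$inoculum_od * 5)
})

test_that("single-sugar depletion time matches the closed form", {
  ct <- default_constants()
  ct$sugars$yield <- rep(1, 6)
  sc <- scenario(strains = ct$background_strain,
                 sugar_mix = c(lactose = 0.09), inoculum_od = 0.01)
  ct$sugars$max_growth_rate[ct$sugars$name == "lactose"] <- 0.5
  tr <- simulate_batch(sc, ct)
  # S(t) = S0 - (OD - OD0)/Y with exponential OD: depletion at ln(10)/0.5
  t_dep <- log(10) / 0.5
  expect_equal(tr$phases[[1]]$t1, t_dep, tolerance = 1e-9)
  s_traj <- tr$sugars[, "lactose"]
  expect_true(all(s_traj[tr$times > t_dep + 0.1] == 0))
  expect_true(all(s_traj[tr$times < t_dep - 0.1] > 0))
})

test_that("sugar mass balance holds along the trajectory", {
  ct <- default_constants()
  sc <- scenario(strains = ct$background_strain,
                 sugar_mix = c(xylose = 0.1), inoculum_od = 0.008)
  tr <- simulate_batch(sc, ct)
  y <- ct$sugars$yield[ct$sugars$name == "xylose"]
  growing <- tr$sugars[, "xylose"] > 0
  expect_equal(y * (0.1 - tr$sugars[growing, "xylose"]) + sc$inoculum_od,
               tr$od[growing], tolerance = 1e-9)
})

test_that("mixture growth follows the higher sugar, with optional ribose boost", {
  ct <- default_constants()
  sc <- scenario_pair("lactose", "ribose", ct)
  tr <- simulate_batch(sc, ct)
  expect_equal(tr$phases[[1]]$mu_eff, 0.53)
  ct2 <- ct
  ct2$ribose_boost <- 1.10
  tr2 <- simulate_batch(sc, ct2)
  expect_equal(tr2$phases[[1]]$mu_eff, 0.53 * 1.10)
  # boost applies only while both sugars are present
  last <- tr2$phases[[length(tr2$phases) - 1]]
  expect_equal(last$mu_reg, 0.29)
})

test_that("sequential mode consumes the higher-ranked sugar first", {
  ct <- default_constants()
  sc <- scenario_pair("arabinose", "rhamnose", ct)
  tr <- simulate_batch(sc, ct)
  expect_identical(tr$phases[[1]]$active, "arabinose")
  expect_identical(tr$phases[[2]]$active, "rhamnose")
  expect_lt(tr$phases[[2]]$mu_eff, tr$phases[[1]]$mu_eff)
})

test_that("co-consumption depletes sugars in proportion, together", {
  ct <- default_constants()
  sc <- scenario(
    strains = ct$background_strain,
    sugar_mix = c(arabinose = 0.005, xylose = 0.2),
    consumption_mode = "co"
  )
  tr <- simulate_batch(sc, ct)
  grow <- tr$sugars[, "xylose"] > 0 & tr$times > 0
  ratio <- tr$sugars[grow, "arabinose"] / tr$sugars[grow, "xylose"]
  expect_equal(ratio, rep(0.005 / 0.2, sum(grow)), tolerance = 1e-9)
})

test_that("invalid scenarios are rejected", {
  ct <- default_constants()
  expect_error(scenario(strains = "lacZ", inoculum_od = 0))
  expect_error(
    simulate_batch(scenario(strains = "lacZ", sugar_mix = c(glucose = 0.2)), ct),
    "unknown sugar"
  )
  expect_error(promoter_for_strain("notastrain", ct), "unknown strain")
})

test_that("external cAMP pins the CRP level seen by promoters", {
  ct <- default_constants()
  sc <- scenario(strains = c("lacZ", "crp", ct$background_strain),
                 sugar_mix = c(lactose = 0.2), camp = 0.5)
  tr <- simulate_batch(sc, ct)
  growing <- tr$mu > 0
  expect_true(all(tr$crp[growing] == 0.5))
  prom <- promoter_for_strain("lacZ", ct)
  expect_equal(unique(tr$pa[growing, "lacZ"]),
               true_promoter_activity(prom, 0.5, induced = TRUE))
})
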