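# a shallow column entirely inside the 5 cm penetration depth: every
# individual is fully exposed no matter where it moves, which makes the
# population-side survival exactly comparable to the standalone TKTD curve
shallow_column <- function() soil_column(n_layers = 4, layer_thickness = 1)

test_that("individual exposure is masked below the penetration depth", {
  prof <- verification_profile(5, 20)
  # layers 1-5 are within 5 cm (tops 0-4 cm); layer 6 top = 5 cm is below
  conc_day3 <- prof$concentration[4]
  x <- individual_exposure(c(1L, 5L, 6L, 10L), 1, list(prof), day = 3)
  expect_equal(as.numeric(x), c(conc_day3, conc_day3, 0, 0))

  # an alternating trajectory sees the profile masked on alternate days
  layers <- rep(c(2L, 10L), 10)
  seen <- vapply(0:19, function(d)
    individual_exposure(layers[d + 1], 1, list(prof), d)[1], 0)
  expect_equal(seen, prof$concentration[1:20] * rep(c(1, 0), 10))
})

test_that("toxicant death follows the fate draw with the refugium exception", {
  # fate 0.5: survives at mortality 0.4, dies at 0.6 (companion adult
  # present so the refugium rule does not interfere)
  expect_identical(decide_toxicant_deaths(c(0.5, 0.9), c(0.4, 0.1),
                                          c(3L, 3L), c(TRUE, TRUE)),
                   c(FALSE, FALSE))
  expect_identical(decide_toxicant_deaths(c(0.5, 0.9), c(0.6, 0.1),
                                          c(3L, 3L), c(TRUE, TRUE)),
                   c(TRUE, FALSE))
  # eggs never die of toxicity; juveniles only when enabled
  expect_false(decide_toxicant_deaths(0.1, 0.9, 1L, TRUE))
  expect_false(decide_toxicant_deaths(0.1, 0.9, 2L, TRUE,
                                      include_juvenile_mortality = FALSE))
  expect_true(decide_toxicant_deaths(0.1, 0.9, 2L, TRUE,
                                     include_juvenile_mortality = TRUE))
  # the last alive adult survives even certain death
  expect_false(decide_toxicant_deaths(0.5, 1.0, 3L, TRUE))
  # with several adults, exactly one is spared
  dies <- decide_toxicant_deaths(rep(0.1, 4), rep(1, 4), rep(3L, 4),
                                 rep(TRUE, 4))
  expect_identical(sum(dies), 3L)
})

test_that("runs are deterministic and iteration seeds are stable", {
  subs <- list(a = demo_substance())
  apps <- data.frame(substance_id = "substance_a", day = 0, rate = 0.6)
  scn1 <- scenario("det", apps, subs, verification_soil(), horizon = 40,
                   iterations = 1, master_seed = 99)
  scn3 <- scenario("det", apps, subs, verification_soil(), horizon = 40,
                   iterations = 3, master_seed = 99)
  r1a <- run_simulation(scn1)
  r1b <- run_simulation(scn1)
  expect_identical(r1a$records, r1b$records)
  r3 <- run_simulation(scn3)
  # iteration 1 unchanged when more iterations are requested
  expect_identical(r3$records[[1]], r1a$records[[1]])
  # different iterations differ
  expect_false(identical(r3$records[[1]]$daily, r3$records[[2]]$daily))
})

test_that("no applications means no toxicant mortality, ever", {
  subs <- list(a = demo_substance())
  no_apps <- data.frame(substance_id = character(0), day = numeric(0),
                        rate = numeric(0))
  scn <- scenario("clean", no_apps, subs, verification_soil(), horizon = 80,
                  master_seed = 5)
  rec <- run_simulation(scn, record_depth = FALSE)$records[[1]]
  expect_identical(sum(rec$daily$toxicant_deaths), 0L)
  expect_identical(as.integer(rec$death_causes[["toxicant"]]), 0L)
})

test_that("a lone adult surviving 10 days contributes 10 to the occurrence total", {
  subs <- list(a = demo_substance())
  no_apps <- data.frame(substance_id = character(0), day = numeric(0),
                        rate = numeric(0))
  scn <- scenario("lone", no_apps, subs, verification_soil(), horizon = 10,
                  master_seed = 1, life_history = cohort_life_history(),
                  init = c(adults = 1, juveniles = 0, eggs = 0))
  rec <- run_simulation(scn)$records[[1]]
  expect_identical(as.numeric(rec$occurrence[["adults"]]), 10)
  expect_identical(as.numeric(rec$occurrence[["juveniles"]]), 0)
})

test_that("engine survival matches the standalone TKTD chain when fully exposed", {
  # single substance: the engine's per-individual mixture survival must
  # equal predict_guts on the raw profile for every day
  subs <- list(a = demo_substance())
  apps <- data.frame(substance_id = "substance_a", day = 0, rate = 0.6)
  for (assumption in c("SD", "IT")) {
    scn <- scenario("pin", apps, subs, verification_soil(),
                    guts_assumption = assumption, horizon = 50,
                    master_seed = 13, column = shallow_column(),
                    life_history = cohort_life_history(),
                    init = c(adults = 30, juveniles = 0, eggs = 0))
    rec <- run_simulation(scn, record_depth = FALSE)$records[[1]]
    prof <- verification_profile(5, 50)
    params <- if (assumption == "SD") demo_params_sd() else demo_params_it()
    pred <- predict_guts(prof, params)
    expect_equal(rec$daily$toxicant_mortality_mean, 1 - pred$survival,
                 tolerance = 1e-9)
    expect_equal(rec$daily$toxicant_mortality_max,
                 rec$daily$toxicant_mortality_mean, tolerance = 1e-12)
  }
})

test_that("engine IA mixture equals the product of per-substance predictions", {
  sub_a <- demo_substance("a")
  sub_b <- substance_properties(
    "b", dt50 = 30, guts_sd = guts_params_sd(0.5, 0.2, 0.3),
    guts_it = guts_params_it(0.5, 0.9, 3))
  subs <- list(a = sub_a, b = sub_b)
  apps <- data.frame(substance_id = c("a", "b"), day = c(0, 5),
                     rate = c(0.6, 0.8))
  soil <- verification_soil()
  scn <- scenario("ia", apps, subs, soil, guts_assumption = "SD",
                  mixture_rule = "IA", horizon = 40, master_seed = 17,
                  column = shallow_column(),
                  life_history = cohort_life_history(),
                  init = c(adults = 20, juveniles = 0, eggs = 0))
  rec <- run_simulation(scn, record_depth = FALSE)$records[[1]]
  prof_a <- build_exposure_profile(apps[1, ], sub_a, soil, 40)
  prof_b <- build_exposure_profile(apps[2, ], sub_b, soil, 40)
  mix <- predict_guts_mixture(list(prof_a, prof_b),
                              list(sub_a$guts_sd, sub_b$guts_sd), rule = "IA")
  expect_equal(rec$daily$toxicant_mortality_mean, 1 - mix$survival,
               tolerance = 1e-9)
})

test_that("engine CA mixture equals the damage-addition prediction", {
  sub_a <- demo_substance("a")
  sub_b <- substance_properties(
    "b", dt50 = 30, guts_sd = guts_params_sd(0.5, 0.2, 0.3),
    guts_it = guts_params_it(0.5, 0.9, 3))
  subs <- list(a = sub_a, b = sub_b)
  apps <- data.frame(substance_id = c("a", "b"), day = c(0, 5),
                     rate = c(0.6, 0.8))
  soil <- verification_soil()
  scn <- scenario("ca", apps, subs, soil, guts_assumption = "IT",
                  mixture_rule = "CA", horizon = 40, master_seed = 18,
                  column = shallow_column(),
                  life_history = cohort_life_history(),
                  init = c(adults = 20, juveniles = 0, eggs = 0))
  rec <- run_simulation(scn, record_depth = FALSE)$records[[1]]
  prof_a <- build_exposure_profile(apps[1, ], sub_a, soil, 40)
  prof_b <- build_exposure_profile(apps[2, ], sub_b, soil, 40)
  mix <- predict_guts_mixture(list(prof_a, prof_b),
                              list(sub_a$guts_it, sub_b$guts_it), rule = "CA")
  expect_equal(rec$daily$toxicant_mortality_mean, 1 - mix$survival,
               tolerance = 1e-9)
})

test_that("the refugium rule preserves one adult under overwhelming exposure", {
  lethal <- substance_properties(
    "l", dt50 = 92.1, guts_sd = guts_params_sd(k_e = 2, k_k = 50, z = 0.01))
  subs <- list(l = lethal)
  apps <- data.frame(substance_id = "l", day = 0, rate = 5)
  scn <- scenario("refuge", apps, subs, verification_soil(),
                  horizon = 30, master_seed = 8, column = shallow_column(),
                  life_history = cohort_life_history(),
                  init = c(adults = 6, juveniles = 0, eggs = 0))
  rec <- run_simulation(scn, record_depth = FALSE)$records[[1]]
  expect_identical(as.integer(tail(rec$daily$n_adults, 1)), 1L)
  expect_identical(as.integer(rec$death_causes[["toxicant"]]), 5L)
})

test_that("scenario validation catches configuration problems before day 0", {
  soil <- verification_soil()
  apps <- data.frame(substance_id = "ghost", day = 0, rate = 0.6)
  expect_error(scenario("bad", apps, list(a = demo_substance()), soil),
               "ghost")
  no_guts <- list(x = substance_properties("x", dt50 = 10))
  apps_x <- data.frame(substance_id = "x", day = 0, rate = 0.6)
  expect_error(scenario("bad", apps_x, no_guts, soil), "missing GUTS-SD")
  expect_error(scenario("bad", apps_x, list(x = demo_substance("x")), soil,
                        horizon = 0), "horizon")
})
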