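test_that("habitat suitability combines trapezoid memberships and food saturation", {
  lh <- life_history_params(food_half_saturation = NULL)
  # all variables at optimum, food term off -> exactly 1
  env <- data.frame(temperature = 20, moisture = 0.5, food = 1)
  expect_identical(habitat_suitability(env, lh), 1)
  # any variable outside its tolerance zeroes the product
  cold <- data.frame(temperature = -5, moisture = 0.5, food = 1)
  expect_identical(habitat_suitability(cold, lh), 0)
  dry <- data.frame(temperature = 20, moisture = 0.01, food = 1)
  expect_identical(habitat_suitability(dry, lh), 0)
  # midpoint of the lower temperature ramp (0 -> 15) scores 0.5
  ramp <- data.frame(temperature = 7.5, moisture = 0.5, food = 1)
  expect_equal(habitat_suitability(ramp, lh), 0.5)
  # food term halves the score at the half-saturation constant
  lh_food <- life_history_params(food_half_saturation = 0.2)
  fed <- data.frame(temperature = 20, moisture = 0.5, food = 0.2)
  expect_equal(habitat_suitability(fed, lh_food), 0.5)
})

test_that("density-dependent mortality is zero below capacity and linear above", {
  lh <- life_history_params(carrying_capacity = 200,
                            density_mortality_coefficient = 0.1)
  expect_identical(density_mortality(0, lh), 0)
  expect_identical(density_mortality(200, lh), 0)
  expect_equal(density_mortality(400, lh), 0.1)
  expect_identical(density_mortality(1e6, lh), 0.99)
})

test_that("movement follows suitability weights and respects boundaries", {
  # equal suitabilities: each neighbour chosen about 1/3 of the time
  suit <- rep(1, 10)
  set.seed(21)
  draws <- move_layers(rep(5L, 1e5), suit)
  freq <- table(draws) / 1e5
  se <- sqrt((1 / 3) * (2 / 3) / 1e5)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))

  # only one candidate with positive suitability is always chosen
  suit2 <- c(0, 0, 1, 0, 0)
  expect_true(all(move_layers(rep(2L, 500), suit2) == 3L))

  # zero suitability everywhere: uniform over valid candidates, clipped at
  # the surface
  suit3 <- rep(0, 5)
  set.seed(22)
  top <- move_layers(rep(1L, 2000), suit3)
  expect_true(all(top %in% c(1L, 2L)))
  expect_gt(mean(top == 1L), 0.4)
})

test_that("life-cycle thresholds trigger the documented events", {
  lh <- life_history_params()
  # columns: egg about to hatch, fresh egg, juvenile maturing, adult at
  # clutch day, adult mid-interval, adult at max age
  stage <- c(1L, 1L, 2L, 3L, 3L, 3L)
  age <- c(10, 3, 31, 60, 61, 240)
  stage_age <- c(10, 3, 21, 3, 4, 100)
  ev <- step_life_cycle(stage, age, stage_age, lh)
  expect_identical(ev, c("hatch", "none", "mature", "reproduce", "none",
                         "die_age"))
})

test_that("a pesticide-free population settles near the carrying capacity", {
  subs <- list(a = demo_substance())
  no_apps <- data.frame(substance_id = character(0), day = numeric(0),
                        rate = numeric(0))
  for (seed in c(7, 20)) {
    scn <- scenario("baseline", no_apps, subs, verification_soil(),
                    horizon = 250, master_seed = seed)
    d <- run_simulation(scn, record_depth = FALSE)$records[[1]]$daily
    expect_identical(sum(d$toxicant_deaths), 0L)
    n_mobile <- d$n_adults + d$n_juveniles
    long_run <- mean(n_mobile[101:251])
    k <- scn$life_history$carrying_capacity
    expect_gt(long_run, 0.8 * k)
    expect_lt(long_run, 1.2 * k)
  }
})

test_that("depth and stage bookkeeping stay consistent through a run", {
  subs <- list(a = demo_substance())
  scn <- scenario("book", data.frame(substance_id = "substance_a", day = 0,
                                     rate = 0.6),
                  subs, verification_soil(), horizon = 60, master_seed = 3)
  res <- run_simulation(scn)
  rec <- res$records[[1]]
  # the depth histogram must re-sum to the daily stage counts, every day
  agg <- aggregate(count ~ day + stage, rec$depth, sum)
  for (dy in c(0, 10, 30, 60)) {
    row <- rec$daily[rec$daily$day == dy, ]
    for (stg in c("adult", "juvenile", "egg")) {
      got <- agg$count[agg$day == dy & agg$stage == stg]
      want <- switch(stg, adult = row$n_adults, juvenile = row$n_juveniles,
                     egg = row$n_eggs)
      expect_identical(if (length(got)) got else 0L, as.integer(want))
    }
  }
  # daily toxicant deaths reconcile with the per-individual causes
  expect_identical(sum(rec$daily$toxicant_deaths),
                   as.integer(rec$death_causes[["toxicant"]]))
})

test_that("individuals accumulate in the most suitable layers", {
  # static column with a surface-biased food gradient: the modal layer of
  # the mobile population should be the argmax-suitability layer
  subs <- list(a = demo_substance())
  no_apps <- data.frame(substance_id = character(0), day = numeric(0),
                        rate = numeric(0))
  # pronounced interior suitability peak (food maximum at layer 5, e.g. an
  # organic-matter band); away from the column boundaries the movement
  # kernel concentrates the population exactly on the best layer
  steep <- soil_column(n_layers = 15,
                       food = exp(-(((1:15) - 5) / 1.2)^2))
  hits <- 0
  for (seed in 1:8) {
    scn <- scenario("depth", no_apps, subs, verification_soil(),
                    horizon = 60, master_seed = seed, column = steep,
                    life_history = cohort_life_history(),
                    init = c(adults = 150, juveniles = 0, eggs = 0))
    rec <- run_simulation(scn)$records[[1]]
    suit <- habitat_suitability(scn$column, scn$life_history)
    # pool the last 20 days to smooth single-day sampling noise
    late <- rec$depth[rec$depth$day > 40 & rec$depth$stage == "adult", ]
    by_layer <- tapply(late$count, late$layer, sum)
    modal <- as.integer(names(by_layer)[which.max(by_layer)])
    if (modal == which.max(suit)) hits <- hits + 1
  }
  expect_gte(hits, 7)
})
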