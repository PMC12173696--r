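test_that("survival datasets are validated", {
  good <- data.frame(replicate_id = "a", concentration = 1,
                     time = c(0, 7, 14), n_alive = c(10, 8, 8))
  expect_s3_class(survival_dataset(good), "survival_dataset")
  no_zero <- good; no_zero$time <- c(1, 7, 14)
  expect_error(survival_dataset(no_zero), "time-0")
  rising <- good; rising$n_alive <- c(10, 8, 9)
  expect_error(survival_dataset(rising), "increase")
})

test_that("log-likelihood evaluates the conditional binomial terms", {
  # params that predict no mortality give probability one to all-survive data
  p_safe <- guts_params_sd(k_e = 0.5, k_k = 1, z = 10)
  dat <- data.frame(replicate_id = rep(c("a", "b"), each = 3),
                    concentration = rep(c(1, 2), each = 3),
                    time = rep(c(0, 7, 14), 2),
                    n_alive = rep(10, 6))
  expect_identical(guts_log_likelihood(dat, p_safe), 0)

  # single interval with predicted mortality exactly 0.5:
  # pick a constant concentration whose damage reaches alpha at the
  # observation time, so S(t1) = 0.5
  ke <- 0.4; t1 <- 7
  p_it <- guts_params_it(k_e = ke, alpha = 1, beta = 3)
  conc <- 1 / (1 - exp(-ke * t1))
  dat1 <- data.frame(replicate_id = "a", concentration = conc,
                     time = c(0, t1), n_alive = c(10, 5))
  expect_equal(guts_log_likelihood(dat1, p_it),
               lchoose(10, 5) + 10 * log(0.5))

  # observed deaths where the model predicts none: impossible data
  dat_dead <- data.frame(replicate_id = "a", concentration = 1,
                         time = c(0, 7), n_alive = c(10, 5))
  expect_identical(guts_log_likelihood(dat_dead, p_safe), -Inf)
})

test_that("log-likelihood is invariant to replicate order and matches the fast path", {
  p <- guts_params_sd(k_e = 0.3, k_k = 0.3, z = 0.3)
  dat <- simulate_survival_experiment(p, c(0, 0.5, 1.5), 2, 15, c(0, 3, 7, 14),
                                      seed = 5)
  shuffled <- dat[sample(nrow(dat)), ]
  expect_equal(guts_log_likelihood(shuffled, p), guts_log_likelihood(dat, p))
  prep <- collempop:::group_entries(collempop:::replicate_entries(
    survival_dataset(dat)))
  expect_equal(collempop:::ll_grouped(prep, p), guts_log_likelihood(dat, p))
})

test_that("log-likelihood matches brute-force path enumeration on a toy dataset", {
  # 3 individuals observed over 2 intervals: enumerate all 3^3 fate
  # assignments (die in interval 1, die in interval 2, survive) and sum
  # the probabilities of assignments consistent with the observed counts
  p <- guts_params_it(k_e = 0.5, alpha = 0.6, beta = 2)
  conc <- 1.2
  times <- c(0, 4, 9)
  s <- guts_survival_constant(conc, times, p)
  fate_prob <- c(1 - s[2], s[2] - s[3], s[3])
  counts <- c(3, 2, 1)  # n_alive at the three times -> deaths 1 then 1
  total <- 0
  for (f1 in 1:3) for (f2 in 1:3) for (f3 in 1:3) {
    fates <- c(f1, f2, f3)
    n_path <- c(3, sum(fates >= 2), sum(fates == 3))
    if (all(n_path == counts))
      total <- total + prod(fate_prob[fates])
  }
  dat <- data.frame(replicate_id = "a", concentration = conc,
                    time = times, n_alive = counts)
  expect_equal(guts_log_likelihood(dat, p), log(total))
})

test_that("simulated experiments honour the generating survival curve", {
  # threshold above every tested concentration: nobody can die under SD
  p_safe <- guts_params_sd(k_e = 0.5, k_k = 1, z = 5)
  dat <- simulate_survival_experiment(p_safe, c(0, 0.5, 1, 2), 3, 20, 0:14,
                                      seed = 3)
  expect_true(all(dat$n_alive == 20))

  # Monte-Carlo frequencies converge to the closed-form curve
  p_it <- guts_params_it(k_e = 0.4, alpha = 0.8, beta = 3)
  big <- simulate_survival_experiment(p_it, 1.6, 1, 5000, c(0, 2, 5, 10, 21),
                                      seed = 9)
  s_hat <- big$n_alive / 5000
  s_true <- guts_survival_constant(1.6, c(0, 2, 5, 10, 21), p_it)
  se <- sqrt(s_true * (1 - s_true) / 5000)
  expect_true(all(abs(s_hat - s_true) <= 3 * se + 1e-12))

  # long-duration top concentration approaches the IT plateau
  plateau <- 1 - 1 / (1 + (1.6 / 0.8)^(-3))
  expect_equal(s_hat[5], plateau, tolerance = 0.05)
})

test_that("maximum-likelihood fitting is deterministic and recovers parameters", {
  true_p <- guts_params_sd(k_e = 0.3, k_k = 0.2, z = 0.5)
  dat <- simulate_survival_experiment(true_p, c(0, 0.3, 1, 3), 3, 20, 0:21,
                                      seed = 11)
  fit1 <- fit_guts(dat, "SD", seed = 11)
  fit2 <- fit_guts(dat, "SD", seed = 11)
  expect_identical(fit1$params, fit2$params)
  expect_lt(abs(fit1$params$k_e - true_p$k_e) / true_p$k_e, 0.5)
  expect_lt(abs(fit1$params$z - true_p$z) / true_p$z, 0.5)
  # the optimum cannot beat the truth by much on its own data, and the
  # fitted likelihood can never be worse
  expect_gte(fit1$log_likelihood, guts_log_likelihood(dat, true_p))
})

test_that("degenerate calibration inputs raise informative errors", {
  control_only <- data.frame(replicate_id = "a", concentration = 0,
                             time = c(0, 7, 14), n_alive = c(10, 10, 10))
  expect_error(fit_guts(control_only, "SD"), "non-identifiable")
  no_deaths <- simulate_survival_experiment(
    guts_params_sd(0.5, 1, 50), c(0, 0.5, 1), 2, 10, 0:7, seed = 1)
  expect_error(fit_guts(no_deaths, "SD"), "no deaths")
})
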