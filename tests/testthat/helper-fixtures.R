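# shared builders for the test suite; everything is generated in code

# the exposure verification setting: single 0.6 kg/ha application,
# DT50 92.1 d, bulk density 1.3 g/cm3, constant 20 degC
verification_substance <- function(...) {
  substance_properties("teflubenzuron", dt50 = 92.1, ...)
}

verification_soil <- function(mixing_depth = 5) {
  soil_scenario(mixing_depth = mixing_depth, bulk_density = 1.3,
                temperature = 20)
}

verification_profile <- function(mixing_depth = 5, horizon = 100) {
  build_exposure_profile(data.frame(day = 0, rate = 0.6),
                         verification_substance(),
                         verification_soil(mixing_depth), horizon)
}

# published PEC verification table: day -> mg/kg at 5 cm and 20 cm mixing
pec_reference_table <- function() {
  data.frame(
    day = c(0, 1, 2, 4, 7, 14, 21, 28, 42, 50, 100),
    pec_5cm = c(0.9231, 0.9162, 0.9093, 0.8957, 0.8757, 0.8308, 0.7881,
                0.7477, 0.6729, 0.6336, 0.4349),
    pec_20cm = c(0.2308, 0.2290, 0.2273, 0.2239, 0.2189, 0.2077, 0.1970,
                 0.1869, 0.1682, 0.1584, 0.1087)
  )
}

demo_params_sd <- function() guts_params_sd(k_e = 0.3, k_k = 0.4, z = 0.2)
demo_params_it <- function() guts_params_it(k_e = 0.3, alpha = 0.5, beta = 2.5)

demo_substance <- function(id = "substance_a") {
  substance_properties(id, dt50 = 92.1, guts_sd = demo_params_sd(),
                       guts_it = demo_params_it())
}

# fine-grid explicit-Euler integration of dCi*/dt = ke (Cs - Ci*), the
# brute-force oracle for the analytic toxicokinetic step; uses the linear
# recurrence C[n+1] = C[n](1 - ke dt) + ke dt Cs(t_n). The raw scheme is
# first-order, so the oracle Richardson-extrapolates dt and dt/2 to cancel
# the leading error term (still pure brute force, no model knowledge).
euler_once <- function(c0, c_ext0, k, ke, t_end, dt) {
  n <- round(t_end / dt)
  cs <- c_ext0 * exp(-k * (0:(n - 1)) * dt)
  as.numeric(stats::filter(ke * dt * cs, 1 - ke * dt,
                           method = "recursive", init = c0)[n])
}

euler_internal_concentration <- function(c0, c_ext0, k, ke, t_end,
                                         dt = 1e-4) {
  coarse <- euler_once(c0, c_ext0, k, ke, t_end, dt)
  fine <- euler_once(c0, c_ext0, k, ke, t_end, dt / 2)
  2 * fine - coarse
}

# cohort scenario: mobile individuals only, no reproduction, no ageing or
# crowding deaths - isolates toxicant mortality for envelope checks
cohort_life_history <- function(...) {
  life_history_params(clutch_size = 0, max_age_days = 1e6,
                      carrying_capacity = 1e6, ...)
}
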