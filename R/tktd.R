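#' GUTS-RED stochastic-death parameters
#'
#' Parameter set for the stochastic-death (SD) toxicodynamic assumption:
#' all individuals share one damage threshold `z`; above it the hazard rate
#' grows linearly with the killing rate constant `k_k`.
#'
#' @param k_e dominant rate constant, per day (> 0).
#' @param k_k killing rate constant, per day per (mg/kg) (>= 0).
#' @param z threshold concentration, mg/kg (>= 0).
#' @param h_b background hazard rate, per day (default 0; the population
#'   model carries its own density-dependent background mortality, so a
#'   non-zero h_b there would double-count natural deaths).
#' @return Object of class `guts_params_sd`.
#' @export
guts_params_sd <- function(k_e, k_k, z, h_b = 0) {
  if (!is.numeric(k_e) || k_e <= 0)
    stop("invalid parameter: k_e must be > 0", call. = FALSE)
  stopifnot(k_k >= 0, z >= 0, h_b >= 0)
  structure(list(k_e = k_e, k_k = k_k, z = z, h_b = h_b),
            class = c("guts_params_sd", "guts_params"))
}

#' GUTS-RED individual-tolerance parameters
#'
#' Parameter set for the individual-tolerance (IT) assumption: thresholds
#' vary between individuals following a log-logistic distribution with
#' median `alpha` and shape `beta`; an individual dies once the scaled
#' internal concentration exceeds its personal threshold.
#'
#' @param k_e dominant rate constant, per day (> 0).
#' @param alpha median of the threshold distribution, mg/kg (> 0).
#' @param beta shape parameter (> 0).
#' @param h_b background hazard rate, per day (default 0).
#' @return Object of class `guts_params_it`.
#' @export
guts_params_it <- function(k_e, alpha, beta, h_b = 0) {
  if (!is.numeric(k_e) || k_e <= 0)
    stop("invalid parameter: k_e must be > 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0)
    stop("invalid parameter: alpha and beta must be > 0", call. = FALSE)
  stopifnot(h_b >= 0)
  structure(list(k_e = k_e, alpha = alpha, beta = beta, h_b = h_b),
            class = c("guts_params_it", "guts_params"))
}

#' Advance the scaled internal concentration over one interval
#'
#' Integrates the one-compartment scaled-damage toxicokinetics
#' \deqn{dC_i^*/dt = k_e (C_s(t) - C_i^*(t))}
#' exactly over a step of length `dt`, with the external soil concentration
#' decaying exponentially within the step,
#' \eqn{C_s(\tau) = C_{s,0} e^{-k \tau}}:
#' \deqn{C_i^*(t + dt) = C_i^*(t) e^{-k_e dt} +
#'   C_{s,0} \frac{k_e}{k_e - k} (e^{-k\,dt} - e^{-k_e dt})}
#' with the analytic limit \eqn{C_{s,0} k_e\,dt\,e^{-k_e dt}} when
#' \eqn{k_e \approx k}. All arguments are vectorised.
#'
#' @param c_internal scaled internal concentration at step start, mg/kg.
#' @param c_external_start external soil concentration at step start, mg/kg.
#' @param decay_rate_k within-step external decay rate, per day (>= 0).
#' @param k_e dominant rate constant, per day (> 0).
#' @param dt step length in days (> 0).
#' @return Scaled internal concentration at step end, mg/kg.
#' @examples
#' step_internal_concentration(0, 1, 0, k_e = 0.5, dt = 1000)  # steady state 1
#' @export
step_internal_concentration <- function(c_internal, c_external_start,
                                        decay_rate_k, k_e, dt) {
  if (any(k_e <= 0)) stop("invalid parameter: k_e must be > 0", call. = FALSE)
  stopifnot(all(dt > 0))
  e_ke <- exp(-k_e * dt)
  regular <- k_e / (k_e - decay_rate_k) * (exp(-decay_rate_k * dt) - e_ke)
  limit <- k_e * dt * e_ke
  near <- rep_len(abs(k_e - decay_rate_k) < 1e-10 * k_e, length(regular))
  forcing <- ifelse(near, rep_len(limit, length(regular)), regular)
  c_internal * e_ke + c_external_start * forcing
}

#' SD hazard rate
#'
#' Instantaneous mortality hazard under stochastic death:
#' \eqn{h_z = k_k \max(0, C_i^* - z) + h_b}. Vectorised over `c_internal`.
#'
#' @param c_internal scaled internal concentration, mg/kg (>= 0).
#' @param params a [guts_params_sd()] object.
#' @return Hazard rate, per day.
#' @export
hazard_sd <- function(c_internal, params) {
  stopifnot(inherits(params, "guts_params_sd"))
  params$k_k * pmax(0, c_internal - params$z) + params$h_b
}

#' SD survival from a hazard series
#'
#' Cumulative-hazard integration by the trapezoidal rule on an evenly
#' spaced grid: \eqn{S(t) = e^{-\int_0^t h_z\,d\tau}}.
#'
#' @param hazard_series hazard values on the grid (first value at t = 0).
#' @param dt grid spacing in days.
#' @return Survival probabilities at every grid point (same length as
#'   `hazard_series`, first value 1).
#' @examples
#' survival_sd(rep(0.1, 11), dt = 1)[11]  # exp(-1) at day 10
#' @export
survival_sd <- function(hazard_series, dt = 1) {
  if (any(hazard_series < 0) || anyNA(hazard_series))
    stop("invalid state: negative hazard", call. = FALSE)
  n <- length(hazard_series)
  if (n == 1L) return(1)
  increments <- (hazard_series[-n] + hazard_series[-1L]) / 2 * dt
  exp(-c(0, cumsum(increments)))
}

#' IT survival from the running damage maximum
#'
#' \deqn{S_{IT}(t) = \left(1 - \frac{1}{1 + (\max_{0 \le \tau \le t}
#'   C_i^*(\tau) / \alpha)^{-\beta}}\right) e^{-h_b t}}
#' The log-logistic tolerance CDF is 0 at 0, so an unexposed individual has
#' survival \eqn{e^{-h_b t}}. Vectorised over `c_internal_max` and `t`.
#'
#' @param c_internal_max running maximum of the scaled internal
#'   concentration up to time `t`, mg/kg (>= 0).
#' @param params a [guts_params_it()] object.
#' @param t time in days (only used for the background-hazard term).
#' @return Survival probability in \[0, 1\].
#' @examples
#' survival_it(2, guts_params_it(0.5, alpha = 2, beta = 3))  # 0.5 at the median
#' @export
survival_it <- function(c_internal_max, params, t = 0) {
  stopifnot(inherits(params, "guts_params_it"))
  stopifnot(all(c_internal_max >= 0), all(t >= 0))
  cdf <- ifelse(c_internal_max == 0, 0,
                1 / (1 + (c_internal_max / params$alpha)^(-params$beta)))
  (1 - cdf) * exp(-params$h_b * t)
}

#' Conditional daily mortality from consecutive survival values
#'
#' Converts a cumulative survival curve into the probability of dying
#' within one day given survival up to its start:
#' \eqn{1 - S(t)/S(t-1)}. By convention the result is 1 when survival had
#' already reached 0.
#'
#' @param survival_today cumulative survival at day end.
#' @param survival_yesterday cumulative survival at day start.
#' @return Conditional mortality probability in \[0, 1\].
#' @export
conditional_daily_mortality <- function(survival_today, survival_yesterday) {
  stopifnot(all(survival_today <= survival_yesterday + 1e-12))
  ifelse(survival_yesterday <= 0, 1,
         pmin(1, pmax(0, 1 - survival_today / survival_yesterday)))
}

#' Predict a GUTS-RED survival curve for an exposure profile
#'
#' Runs the full toxicokinetic-toxicodynamic chain on a daily soil
#' concentration series: the scaled internal concentration is advanced
#' analytically within each day (the external concentration decays
#' exponentially at the profile's degradation rate within the day), and the
#' toxicodynamics are integrated on a sub-daily grid — trapezoidal
#' cumulative hazard for SD, running damage maximum for IT.
#'
#' @param profile an [build_exposure_profile()] object, or a numeric vector
#'   of daily concentrations (mg/kg, day 0 first; decay rate then taken
#'   from `decay_rate`).
#' @param params a [guts_params_sd()] or [guts_params_it()] object.
#' @param assumption `"SD"` or `"IT"`; defaults to the class of `params`.
#' @param substeps sub-daily integration steps (default 10).
#' @param decay_rate within-day external decay rate when `profile` is a
#'   bare numeric vector (default 0, i.e. piecewise-constant exposure).
#' @return `data.frame` with columns `day`, `c_external`, `c_internal`,
#'   `survival`.
#' @examples
#' p <- guts_params_sd(k_e = 0.7, k_k = 0.3, z = 0.2)
#' predict_guts(rep(1, 22), p)[c(1, 11, 22), ]
#' @export
predict_guts <- function(profile, params, assumption = NULL, substeps = 10,
                         decay_rate = 0) {
  if (inherits(profile, "exposure_profile")) {
    conc <- profile$concentration
    k <- profile$decay_rate
  } else {
    conc <- as.numeric(profile)
    k <- decay_rate
  }
  n_days <- length(conc) - 1L
  if (length(k) == 1L) k <- rep(k, n_days + 1L)
  if (is.null(assumption))
    assumption <- if (inherits(params, "guts_params_sd")) "SD" else "IT"
  assumption <- match.arg(assumption, c("SD", "IT"))

  tau <- seq_len(substeps) / substeps        # within-day grid, excl. day start
  c_int <- 0
  c_max <- 0
  h_cum <- 0
  surv <- numeric(n_days + 1L)
  surv[1L] <- 1
  ci <- numeric(n_days + 1L)

  for (d in seq_len(n_days)) {
    sub <- step_internal_concentration(c_int, conc[d], k[d], params$k_e, tau)
    grid <- c(c_int, sub)                    # substeps + 1 points incl. start
    if (assumption == "SD") {
      haz <- hazard_sd(grid, params)
      h_cum <- h_cum + sum((haz[-1L] + haz[-length(haz)]) / 2) / substeps
      surv[d + 1L] <- exp(-h_cum)
    } else {
      c_max <- max(c_max, grid)
      surv[d + 1L] <- survival_it(c_max, params, t = d)
    }
    c_int <- sub[substeps]
    ci[d + 1L] <- c_int
  }
  data.frame(day = 0:n_days, c_external = conc, c_internal = ci,
             survival = surv)
}

#' Closed-form GUTS-RED survival under constant exposure
#'
#' Exact survival at arbitrary times for a constant external concentration
#' — the design of standard laboratory survival tests. Used by the
#' calibration likelihood; also a convenient oracle for the numerical
#' integrator. For SD, with \eqn{C_i^*(t) = C(1 - e^{-k_e t})}, the hazard
#' integral has the closed form given in the methods vignette; for IT the
#' running maximum is simply \eqn{C(1 - e^{-k_e t})}.
#'
#' @param concentration constant external concentration, mg/kg.
#' @param times times in days (>= 0) at which to evaluate survival.
#' @param params [guts_params_sd()] or [guts_params_it()] object.
#' @return Survival probabilities at `times`.
#' @export
guts_survival_constant <- function(concentration, times, params) {
  stopifnot(concentration >= 0, all(times >= 0))
  ke <- params$k_e
  if (inherits(params, "guts_params_sd")) {
    z <- params$z; kk <- params$k_k
    if (concentration <= z || kk == 0) {
      h <- rep(0, length(times))
    } else {
      # first crossing time of C(1 - e^{-ke t}) = z
      t_z <- -log(1 - z / concentration) / ke
      h <- numeric(length(times))
      over <- times > t_z
      tt <- times[over]
      h[over] <- kk * ((concentration - z) * (tt - t_z) +
                         concentration / ke * (exp(-ke * tt) - exp(-ke * t_z)))
    }
    exp(-h) * exp(-params$h_b * times)
  } else {
    cmax <- concentration * (1 - exp(-ke * times))
    survival_it(cmax, params, t = times)
  }
}
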