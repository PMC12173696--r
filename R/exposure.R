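#' Substance properties
#'
#' Bundle the environmental-fate and toxicity parameters of one active
#' substance: the soil half-life (DT50), an optional degradation-rate
#' reduction factor, and GUTS-RED parameter sets for one or both
#' toxicodynamic assumptions.
#'
#' The reduction factor *multiplies* DT50, i.e. a factor of 2 halves the
#' degradation rate constant (effective DT50 = 2 * DT50). This convention is
#' stated here prominently because "reduction factor for the degradation
#' rate" is ambiguous; see the methods vignette.
#'
#' @param substance_id character identifier.
#' @param dt50 soil half-life in days (> 0), at the reference temperature.
#' @param reduction_factor dimensionless multiplier >= 1 applied to DT50.
#' @param guts_sd optional [guts_params_sd()] set.
#' @param guts_it optional [guts_params_it()] set.
#' @return An object of class `substance_properties`.
#' @examples
#' teflubenzuron <- substance_properties("teflubenzuron", dt50 = 92.1)
#' @export
substance_properties <- function(substance_id, dt50, reduction_factor = 1,
                                 guts_sd = NULL, guts_it = NULL) {
  stopifnot(is.character(substance_id), length(substance_id) == 1L)
  if (!is.numeric(dt50) || length(dt50) != 1L || !is.finite(dt50) || dt50 <= 0)
    stop("invalid substance: dt50 must be a single positive number", call. = FALSE)
  if (!is.numeric(reduction_factor) || reduction_factor < 1)
    stop("invalid substance: reduction_factor must be >= 1", call. = FALSE)
  if (!is.null(guts_sd) && !inherits(guts_sd, "guts_params_sd"))
    stop("guts_sd must be created by guts_params_sd()", call. = FALSE)
  if (!is.null(guts_it) && !inherits(guts_it, "guts_params_it"))
    stop("guts_it must be created by guts_params_it()", call. = FALSE)
  structure(list(substance_id = substance_id, dt50 = dt50,
                 reduction_factor = reduction_factor,
                 guts_sd = guts_sd, guts_it = guts_it),
            class = "substance_properties")
}

#' Soil scenario
#'
#' Physical description of the ploughed/mixed soil layer used for the PEC
#' calculation: mixing depth, dry bulk density and a daily temperature
#' series. The soil column is assumed horizontally homogeneous.
#'
#' @param mixing_depth mixing depth in cm (> 0).
#' @param bulk_density dry bulk density in g/cm^3 (> 0).
#' @param temperature daily temperature in deg C; either a single value
#'   (held constant) or a vector covering the simulation horizon.
#' @param crop optional crop identifier used for canopy interception.
#' @return An object of class `soil_scenario`.
#' @examples
#' soil_scenario(mixing_depth = 5, bulk_density = 1.3, temperature = 20)
#' @export
soil_scenario <- function(mixing_depth, bulk_density, temperature = 20,
                          crop = NULL) {
  if (!is.numeric(mixing_depth) || length(mixing_depth) != 1L || mixing_depth <= 0)
    stop("invalid scenario: mixing_depth must be > 0 cm", call. = FALSE)
  if (!is.numeric(bulk_density) || length(bulk_density) != 1L || bulk_density <= 0)
    stop("invalid scenario: bulk_density must be > 0 g/cm^3", call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) < 1L)
    stop("invalid scenario: temperature series required", call. = FALSE)
  structure(list(mixing_depth = mixing_depth, bulk_density = bulk_density,
                 temperature = temperature, crop = crop),
            class = "soil_scenario")
}

#' Initial PEC in soil after one application
#'
#' Converts an application rate (kg active substance per hectare) into the
#' concentration in the homogeneously mixed soil layer:
#' \deqn{PEC_0 = \frac{100 \cdot A (1 - f_{int})}{d \cdot \rho}}
#' with the mixing depth \eqn{d} in m and bulk density \eqn{\rho} in kg/m^3;
#' the factor 100 carries the kg/ha -> mg/kg unit conversion.
#'
#' @param rate application rate in kg a.s./ha (>= 0).
#' @param interception_fraction fraction intercepted by the crop canopy,
#'   in \[0, 1\]; see [interception_fraction()].
#' @param mixing_depth soil mixing depth in cm (> 0).
#' @param bulk_density dry bulk density in g/cm^3 (> 0).
#' @return Initial soil concentration in mg a.s./kg dry soil.
#' @examples
#' initial_pec(0.6, 0, mixing_depth = 5, bulk_density = 1.3)  # 0.9231 mg/kg
#' @export
initial_pec <- function(rate, interception_fraction = 0, mixing_depth,
                        bulk_density) {
  if (mixing_depth <= 0 || bulk_density <= 0)
    stop("invalid scenario: mixing depth and bulk density must be positive",
         call. = FALSE)
  stopifnot(rate >= 0, interception_fraction >= 0, interception_fraction <= 1)
  depth_m <- mixing_depth / 100
  density_kg_m3 <- bulk_density * 1000
  100 * rate * (1 - interception_fraction) / (depth_m * density_kg_m3)
}

#' Crop canopy interception fraction
#'
#' Fraction of the sprayed dose intercepted by the crop canopy, looked up
#' from a user-configurable table keyed by crop and BBCH growth-stage
#' interval. With no crop, no stage, or BBCH 0 (pre-emergence) the fraction
#' is 0 — bare-soil application, the conservative default.
#'
#' @param crop crop identifier or `NULL`.
#' @param bbch_stage BBCH phenology code (integer 0-99) or `NULL`.
#' @param table optional `data.frame` with columns `crop`, `bbch_min`,
#'   `bbch_max`, `fraction`; defaults to an empty table (0 everywhere).
#' @return Interception fraction in \[0, 1\].
#' @export
interception_fraction <- function(crop = NULL, bbch_stage = NULL, table = NULL) {
  if (is.null(crop) || is.null(bbch_stage) || is.na(bbch_stage)) return(0)
  stopifnot(bbch_stage >= 0, bbch_stage <= 99)
  if (bbch_stage == 0) return(0)
  if (is.null(table) || nrow(table) == 0L) return(0)
  hit <- table$crop == crop & table$bbch_min <= bbch_stage &
    bbch_stage <= table$bbch_max
  if (!any(hit)) {
    if (!any(table$crop == crop))
      warning("no interception values configured for crop '", crop,
              "'; assuming bare soil (0)", call. = FALSE)
    return(0)
  }
  frac <- table$fraction[which(hit)[1L]]
  stopifnot(frac >= 0, frac <= 1)
  frac
}

#' First-order degradation rate constant with temperature correction
#'
#' \deqn{k(T) = \frac{\ln 2}{DT50 \cdot f_{red}} \cdot Q_{10}^{(T - T_{ref})/10}}
#' At the 20 deg C reference the correction is identity. Below 0 deg C the
#' soil is treated as frozen and degradation stops (k = 0).
#'
#' @param dt50 half-life in days (> 0).
#' @param reduction_factor multiplier >= 1 applied to DT50 (slows degradation).
#' @param temperature soil temperature in deg C (vectorised).
#' @param q10 temperature coefficient (default 2.58, the FOCUS value
#'   corresponding to an Arrhenius activation energy of 65.4 kJ/mol).
#' @param t_ref reference temperature in deg C (default 20).
#' @return Degradation rate constant(s), per day.
#' @examples
#' degradation_rate(92.1, 1, 20)  # ln(2)/92.1 = 0.007526 per day
#' @export
degradation_rate <- function(dt50, reduction_factor = 1, temperature = 20,
                             q10 = 2.58, t_ref = 20) {
  if (!is.numeric(dt50) || dt50 <= 0)
    stop("invalid substance: dt50 must be > 0", call. = FALSE)
  stopifnot(reduction_factor >= 1)
  f_t <- ifelse(temperature <= 0, 0, q10^((temperature - t_ref) / 10))
  log(2) / (dt50 * reduction_factor) * f_t
}

#' Build a time-dependent soil exposure profile for one substance
#'
#' Computes the daily PEC series (mg/kg dry soil) over the simulation
#' horizon from one or more applications of the same substance, combining
#' them by superposition, with single-first-order degradation at a
#' temperature-corrected rate. The series is evaluated at day start: the
#' application day carries the full, undegraded initial PEC.
#'
#' @param applications `data.frame` with columns `day` (integer >= 0, the
#'   relative simulation day of application), `rate` (kg a.s./ha) and
#'   optionally `bbch` (growth stage for canopy interception).
#' @param props a [substance_properties()] object.
#' @param scenario a [soil_scenario()] object.
#' @param horizon last simulation day; profile covers days `0:horizon`.
#' @param interception_table optional lookup passed to
#'   [interception_fraction()].
#' @param penetration_depth depth (cm) below which the substance is absent;
#'   defaults to the mixing depth.
#' @return An object of class `exposure_profile`: list with `substance_id`,
#'   `concentration` (numeric, length `horizon + 1`, mg/kg),
#'   `penetration_depth` (cm) and `decay_rate` (per-day series used).
#' @examples
#' tef <- substance_properties("teflubenzuron", dt50 = 92.1)
#' soil <- soil_scenario(mixing_depth = 5, bulk_density = 1.3, temperature = 20)
#' prof <- build_exposure_profile(data.frame(day = 0, rate = 0.6), tef, soil, 100)
#' round(prof$concentration[c(1, 15, 101)], 4)  # days 0, 14, 100
#' @export
build_exposure_profile <- function(applications, props, scenario, horizon,
                                   interception_table = NULL,
                                   penetration_depth = NULL) {
  stopifnot(inherits(props, "substance_properties"),
            inherits(scenario, "soil_scenario"))
  stopifnot(is.data.frame(applications), all(c("day", "rate") %in% names(applications)))
  if (nrow(applications) > 0 && any(applications$day > horizon))
    stop("configuration error: application day beyond simulation horizon",
         call. = FALSE)
  if (any(applications$rate < 0))
    stop("configuration error: negative application rate", call. = FALSE)

  temp <- scenario$temperature
  if (length(temp) == 1L) temp <- rep(temp, horizon + 1L)
  if (length(temp) < horizon + 1L)
    stop("invalid scenario: temperature series shorter than horizon", call. = FALSE)
  k_daily <- degradation_rate(props$dt50, props$reduction_factor, temp[seq_len(horizon + 1L)])

  # cumulative degradation from day 0 to start of day t: sum of k over days 0..t-1
  cum_k <- c(0, cumsum(k_daily[seq_len(horizon)]))
  conc <- numeric(horizon + 1L)
  for (i in seq_len(nrow(applications))) {
    d0 <- applications$day[i]
    bbch <- if ("bbch" %in% names(applications)) applications$bbch[i] else NULL
    if (!is.null(bbch) && is.na(bbch)) bbch <- NULL
    f_int <- interception_fraction(scenario$crop, bbch, interception_table)
    pec0 <- initial_pec(applications$rate[i], f_int,
                        scenario$mixing_depth, scenario$bulk_density)
    t_idx <- (d0:horizon) + 1L
    conc[t_idx] <- conc[t_idx] + pec0 * exp(-(cum_k[t_idx] - cum_k[d0 + 1L]))
  }
  structure(list(
    substance_id = props$substance_id,
    concentration = conc,
    penetration_depth = if (is.null(penetration_depth)) scenario$mixing_depth
                        else penetration_depth,
    decay_rate = k_daily
  ), class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat("<exposure_profile> ", x$substance_id, ": ",
      length(x$concentration) - 1L, " days, peak ",
      format(max(x$concentration), digits = 4), " mg/kg, penetration ",
      x$penetration_depth, " cm\n", sep = "")
  invisible(x)
}
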