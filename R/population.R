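#' Vertical soil column environment
#'
#' Discretises the soil profile into horizontal layers; the column is
#' horizontally homogeneous and vertically heterogeneous, so only a
#' vertical profile of each environmental variable is stored. Layer `i`
#' spans depths `[(i-1), i) * layer_thickness` cm (depth positive
#' downward).
#'
#' The default profile holds temperature and moisture constant and lets
#' food decline exponentially with depth (organic matter concentrates near
#' the surface), which gives the column a realistic surface-biased habitat
#' quality gradient.
#'
#' @param n_layers number of layers (> 0; default 30).
#' @param layer_thickness thickness of each layer in cm (default 1).
#' @param temperature per-layer temperature, deg C (recycled).
#' @param moisture per-layer moisture as a fraction in \[0, 1\] (recycled).
#' @param food per-layer food availability, arbitrary units >= 0; default
#'   `exp(-(depth - 0.5) / 10)` at layer midpoints.
#' @return Object of class `soil_column`: data.frame with one row per
#'   layer (`layer`, `depth_top`, `temperature`, `moisture`, `food`) and
#'   attribute `layer_thickness`.
#' @export
soil_column <- function(n_layers = 30, layer_thickness = 1,
                        temperature = 20, moisture = 0.5, food = NULL) {
  stopifnot(n_layers > 0, layer_thickness > 0)
  mid <- (seq_len(n_layers) - 0.5) * layer_thickness
  if (is.null(food)) food <- exp(-mid / 10)
  col <- data.frame(
    layer = seq_len(n_layers),
    depth_top = (seq_len(n_layers) - 1) * layer_thickness,
    temperature = rep_len(temperature, n_layers),
    moisture = rep_len(moisture, n_layers),
    food = rep_len(food, n_layers)
  )
  stopifnot(all(col$food >= 0))
  structure(col, layer_thickness = layer_thickness,
            class = c("soil_column", "data.frame"))
}

#' Life-history and population parameters for Folsomia candida
#'
#' Stage durations, fecundity, longevity, density regulation and habitat
#' preference ranges. The numeric defaults are uncalibrated placeholders
#' in the right order of magnitude for *F. candida* at 20 deg C; every
#' structural test in the package depends only on the rules, not on these
#' magnitudes, and users should replace them with calibrated values for
#' quantitative work.
#'
#' Preference ranges are trapezoids `c(min, opt_low, opt_high, max)`:
#' suitability is 0 outside `[min, max]`, 1 inside `[opt_low, opt_high]`,
#' with linear ramps between.
#'
#' @param egg_development_days days from laying to hatch (default 10).
#' @param juvenile_maturation_days days from hatch to maturity (default 21).
#' @param reproduction_interval_days days between clutches (default 3).
#' @param clutch_size eggs per clutch (default 10).
#' @param max_age_days maximum lifespan (default 240).
#' @param carrying_capacity supportable juveniles + adults (default 200).
#' @param density_mortality_coefficient slope of the density-dependent
#'   daily mortality above capacity (default 0.7, which balances the default
#'   fecundity so the demographic equilibrium sits near the nominal capacity).
#' @param temperature_range,moisture_range trapezoid preference ranges.
#' @param food_half_saturation food level at which the food suitability
#'   term is 0.5; `NULL` disables the food term (default 0.2).
#' @return Object of class `life_history_params`.
#' @export
life_history_params <- function(egg_development_days = 10,
                                juvenile_maturation_days = 21,
                                reproduction_interval_days = 3,
                                clutch_size = 10,
                                max_age_days = 240,
                                carrying_capacity = 200,
                                density_mortality_coefficient = 0.7,
                                temperature_range = c(0, 15, 25, 35),
                                moisture_range = c(0.05, 0.3, 0.8, 1),
                                food_half_saturation = 0.2) {
  stopifnot(egg_development_days > 0, juvenile_maturation_days > 0,
            reproduction_interval_days > 0, clutch_size >= 0,
            max_age_days > 0, carrying_capacity > 0,
            density_mortality_coefficient >= 0)
  check_range <- function(r) stopifnot(length(r) == 4, !is.unsorted(r))
  check_range(temperature_range); check_range(moisture_range)
  structure(list(
    egg_development_days = egg_development_days,
    juvenile_maturation_days = juvenile_maturation_days,
    reproduction_interval_days = reproduction_interval_days,
    clutch_size = clutch_size,
    max_age_days = max_age_days,
    carrying_capacity = carrying_capacity,
    density_mortality_coefficient = density_mortality_coefficient,
    temperature_range = temperature_range,
    moisture_range = moisture_range,
    food_half_saturation = food_half_saturation
  ), class = "life_history_params")
}

# trapezoidal membership: 0 outside [r1, r4], 1 in [r2, r3], linear ramps
trapezoid_membership <- function(x, r) {
  up <- ifelse(r[2] > r[1], (x - r[1]) / (r[2] - r[1]), as.numeric(x >= r[2]))
  down <- ifelse(r[4] > r[3], (r[4] - x) / (r[4] - r[3]), as.numeric(x <= r[3]))
  pmax(0, pmin(1, up, down))
}

#' Habitat suitability of soil layers
#'
#' Combines trapezoidal preference memberships for temperature and
#' moisture by product, optionally multiplied by a saturating food term
#' `food / (food + half_saturation)`. Values in \[0, 1\]; 1 requires every
#' variable inside its optimum and the food term disabled (the saturating
#' term only reaches 1 asymptotically).
#'
#' @param column a [soil_column()] (or data.frame with `temperature`,
#'   `moisture`, `food` columns).
#' @param params a [life_history_params()] holding the preference ranges.
#' @return Numeric vector of suitability scores, one per layer.
#' @export
habitat_suitability <- function(column, params) {
  s <- trapezoid_membership(column$temperature, params$temperature_range) *
    trapezoid_membership(column$moisture, params$moisture_range)
  if (!is.null(params$food_half_saturation))
    s <- s * column$food / (column$food + params$food_half_saturation)
  s
}

#' Density-dependent daily background mortality
#'
#' Zero at or below carrying capacity, rising linearly with relative
#' overshoot above it: `p = c * max(0, n/K - 1)`, clipped to \[0, 0.99\].
#' Applied to juveniles and adults (the mobile, feeding stages).
#'
#' @param n_alive current number of alive juveniles plus adults.
#' @param params a [life_history_params()].
#' @return Daily mortality probability in \[0, 0.99\].
#' @examples
#' lh <- life_history_params(carrying_capacity = 200,
#'                           density_mortality_coefficient = 0.1)
#' density_mortality(400, lh)  # 0.1
#' @export
density_mortality <- function(n_alive, params) {
  stopifnot(n_alive >= 0)
  p <- params$density_mortality_coefficient *
    pmax(0, n_alive / params$carrying_capacity - 1)
  pmin(p, 0.99)
}

#' Sample movement between adjacent soil layers
#'
#' Each mobile individual considers staying or moving one layer up or
#' down (clipped at the column boundaries) and picks a candidate with
#' probability proportional to the candidates' habitat suitability; when
#' all three candidates have zero suitability the choice is uniform.
#' Eggs never move (handled by the caller). Vectorised over individuals;
#' consumes one uniform draw per individual.
#'
#' @param layers integer vector of current layer indices.
#' @param suitability per-layer suitability scores (see
#'   [habitat_suitability()]).
#' @return Integer vector of new layer indices.
#' @export
move_layers <- function(layers, suitability) {
  n_layers <- length(suitability)
  if (length(layers) == 0L) return(layers)
  cand <- cbind(layers - 1L, layers, layers + 1L)
  valid <- cand >= 1L & cand <= n_layers
  w <- matrix(0, nrow(cand), 3L)
  w[valid] <- suitability[cand[valid]]
  zero <- rowSums(w) == 0
  if (any(zero)) w[zero, ] <- as.numeric(valid[zero, , drop = FALSE])
  w <- w / rowSums(w)
  u <- runif(length(layers))
  pick <- 1L + (u >= w[, 1L]) + (u >= w[, 1L] + w[, 2L])
  new_layer <- cand[cbind(seq_along(layers), pick)]
  as.integer(new_layer)
}

#' Daily life-cycle events for one individual state vector
#'
#' Applies the threshold rules of the three-stage life cycle (egg ->
#' juvenile -> adult) to vectors of individual states and returns the
#' event each individual undergoes today: eggs hatch once they reach the
#' egg development time, juveniles mature after the maturation time
#' (counted from hatch), adults lay a clutch every reproduction interval
#' (counted from maturation), and any individual at the maximum age dies.
#' Background density mortality is drawn separately (see
#' [density_mortality()]).
#'
#' @param stage integer vector: 1 = egg, 2 = juvenile, 3 = adult.
#' @param age days since the egg was laid.
#' @param stage_age days since entering the current stage.
#' @param params a [life_history_params()].
#' @return Character vector of events: `"hatch"`, `"mature"`,
#'   `"reproduce"`, `"die_age"` or `"none"`.
#' @export
step_life_cycle <- function(stage, age, stage_age, params) {
  ev <- rep("none", length(stage))
  ev[age >= params$max_age_days] <- "die_age"
  none <- ev == "none"
  ev[none & stage == 1L & stage_age >= params$egg_development_days] <- "hatch"
  ev[none & stage == 2L & stage_age >= params$juvenile_maturation_days] <- "mature"
  repro <- none & stage == 3L & stage_age > 0 &
    stage_age %% params$reproduction_interval_days == 0
  ev[repro] <- "reproduce"
  ev
}
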