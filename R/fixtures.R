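#' Generate self-contained demonstration scenarios
#'
#' Writes a ready-to-run `scenario.csv` + `substances.csv` pair into
#' `out_dir` so every part of the package can be exercised without any
#' external data:
#'
#' * `"table1"` — the exposure verification scenario: a single 0.6 kg/ha
#'   teflubenzuron application on bare soil, DT50 92.1 d, bulk density
#'   1.3 g/cm^3, constant 20 deg C, 5 cm mixing depth, 100-day horizon.
#'   The GUTS parameters attached to the substance are synthetic
#'   placeholders (the scenario is meant for the PEC calculation).
#' * `"guts_demo"` — one substance with synthetic SD and IT parameter
#'   sets, two applications.
#' * `"mixture_demo"` — two substances with synthetic parameters, applied
#'   together (defaults to IA; switch the `mixture_assumption` key for CA).
#' * `"population_demo"` — pesticide-free run of the population model.
#'
#' All numeric toxicity parameters in these files are synthetic: chosen
#' for demonstration, not derived from any laboratory dataset.
#'
#' @param kind one of `"table1"`, `"guts_demo"`, `"mixture_demo"`,
#'   `"population_demo"`.
#' @param out_dir output directory (created if absent).
#' @param seed seed recorded as the scenario's master seed.
#' @return Named character vector with the `scenario` and `substances`
#'   file paths, invisibly.
#' @export
make_fixtures <- function(kind = c("table1", "guts_demo", "mixture_demo",
                                   "population_demo"),
                          out_dir, seed = 1) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # synthetic GUTS parameter sets (demonstration magnitudes)
  sub_a <- substance_properties(
    "substance_a", dt50 = 92.1,
    guts_sd = guts_params_sd(k_e = 0.3, k_k = 0.4, z = 0.2),
    guts_it = guts_params_it(k_e = 0.3, alpha = 0.5, beta = 2.5))
  sub_b <- substance_properties(
    "substance_b", dt50 = 30,
    guts_sd = guts_params_sd(k_e = 0.5, k_k = 0.2, z = 0.4),
    guts_it = guts_params_it(k_e = 0.5, alpha = 1.0, beta = 3))

  cfg <- switch(kind,
    table1 = list(
      substances = list(substance_properties(
        "teflubenzuron", dt50 = 92.1,
        guts_sd = sub_a$guts_sd, guts_it = sub_a$guts_it)),
      applications = data.frame(substance_id = "teflubenzuron", day = 0,
                                rate = 0.6, bbch = NA_real_),
      mixing_depth = 5, horizon = 100, assumption = "SD", rule = "IA",
      iterations = 1),
    guts_demo = list(
      substances = list(sub_a),
      applications = data.frame(substance_id = "substance_a",
                                day = c(0, 30), rate = c(0.6, 0.6),
                                bbch = c(NA_real_, NA_real_)),
      mixing_depth = 5, horizon = 120, assumption = "SD", rule = "IA",
      iterations = 3),
    mixture_demo = list(
      substances = list(sub_a, sub_b),
      applications = data.frame(
        substance_id = c("substance_a", "substance_b"), day = c(0, 7),
        rate = c(0.6, 0.8), bbch = c(NA_real_, NA_real_)),
      mixing_depth = 5, horizon = 120, assumption = "SD", rule = "IA",
      iterations = 3),
    population_demo = list(
      substances = list(sub_a),
      applications = data.frame(substance_id = character(0), day = numeric(0),
                                rate = numeric(0), bbch = numeric(0)),
      mixing_depth = 5, horizon = 150, assumption = "SD", rule = "IA",
      iterations = 1)
  )

  names(cfg$substances) <- vapply(cfg$substances, `[[`, "", "substance_id")
  scn <- scenario(
    name = kind, applications = cfg$applications,
    substances = cfg$substances,
    soil = soil_scenario(cfg$mixing_depth, 1.3, 20),
    guts_assumption = cfg$assumption, mixture_rule = cfg$rule,
    horizon = cfg$horizon, iterations = cfg$iterations,
    master_seed = seed)

  paths <- c(scenario = file.path(out_dir, "scenario.csv"),
             substances = file.path(out_dir, "substances.csv"))
  write_scenario(scn, paths[["scenario"]])
  write_substances(cfg$substances, paths[["substances"]])
  invisible(paths)
}
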