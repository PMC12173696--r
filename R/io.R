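# CSV dialect is pinned throughout: comma-delimited, '.' decimal separator,
# UTF-8, header row — avoids the ';' / ',' locale ambiguity of spreadsheet
# exports.

#' Read a substance-properties table
#'
#' Columns: `substance_id`, `dt50_days`, optional `reduction_factor`
#' (default 1) and GUTS-RED parameter columns `sd_ke`, `sd_kk`, `sd_z`,
#' `it_ke`, `it_alpha`, `it_beta` (leave NA when a parameter set is not
#' available).
#'
#' @param path CSV file path (or a data.frame already in that layout).
#' @return Named list of [substance_properties()] objects.
#' @export
read_substances <- function(path) {
  tab <- if (is.data.frame(path)) path
         else read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("substance_id", "dt50_days") %in% names(tab)))
  get <- function(row, col) {
    if (!col %in% names(tab)) return(NA_real_)
    as.numeric(tab[row, col])
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    rf <- get(i, "reduction_factor")
    sd_par <- if (!is.na(get(i, "sd_ke")))
      guts_params_sd(get(i, "sd_ke"), get(i, "sd_kk"), get(i, "sd_z")) else NULL
    it_par <- if (!is.na(get(i, "it_ke")))
      guts_params_it(get(i, "it_ke"), get(i, "it_alpha"), get(i, "it_beta")) else NULL
    substance_properties(tab$substance_id[i], tab$dt50_days[i],
                         reduction_factor = if (is.na(rf)) 1 else rf,
                         guts_sd = sd_par, guts_it = it_par)
  })
  names(out) <- tab$substance_id
  out
}

#' Write fitted GUTS parameters as a substance-properties row
#'
#' Serialises a [fit_guts()] result so that it can be fed straight back
#' into [read_substances()] (together with the substance's environmental
#' fate parameters).
#'
#' @param fit a `guts_fit` object.
#' @param substance_id identifier for the substance.
#' @param dt50 soil half-life in days to record alongside the fit.
#' @param path output CSV path.
#' @param reduction_factor degradation-rate reduction factor (default 1).
#' @return The written data.frame, invisibly.
#' @export
write_fitted_params <- function(fit, substance_id, dt50, path,
                                reduction_factor = 1) {
  stopifnot(inherits(fit, "guts_fit"))
  p <- fit$params
  row <- data.frame(substance_id = substance_id, dt50_days = dt50,
                    reduction_factor = reduction_factor,
                    sd_ke = NA_real_, sd_kk = NA_real_, sd_z = NA_real_,
                    it_ke = NA_real_, it_alpha = NA_real_, it_beta = NA_real_)
  if (fit$assumption == "SD") {
    row$sd_ke <- p$k_e; row$sd_kk <- p$k_k; row$sd_z <- p$z
  } else {
    row$it_ke <- p$k_e; row$it_alpha <- p$alpha; row$it_beta <- p$beta
  }
  write.csv(row, path, row.names = FALSE, quote = FALSE)
  invisible(row)
}

#' Read survival-test data from CSV
#'
#' Long format with columns `replicate_id`, `concentration`, `time`,
#' `n_alive` (see [survival_dataset()]).
#'
#' @param path CSV file path.
#' @return A [survival_dataset()].
#' @export
read_survival_data <- function(path) {
  survival_dataset(read.csv(path, stringsAsFactors = FALSE))
}

# recognised scenario keys with defaults (NA = mandatory)
scenario_key_table <- function() {
  list(
    name = NA_character_,
    mixing_depth_cm = NA_real_,
    horizon_days = NA_real_,
    guts_assumption = NA_character_,
    bulk_density_g_cm3 = 1.3,
    temperature_c = 20,
    crop = "",
    iterations = 1,
    mixture_assumption = "IA",
    include_juvenile_mortality = TRUE,
    master_seed = 1,
    movement_enabled = TRUE,
    penetration_depth_cm = NA_real_   # optional; defaults to mixing depth
  )
}

#' Load a simulation scenario from CSV files
#'
#' The scenario file is a two-column CSV (`key`, `value`). One row per
#' setting; applications are given as repeated `application` keys with the
#' value `substance_id|day|rate_kg_ha|bbch` (bbch may be omitted or NA).
#' Unknown keys are rejected; missing optional keys fall back to
#' documented defaults with a warning. All validation problems are
#' collected and reported together.
#'
#' @param path scenario CSV path.
#' @param substances path to the substance-properties CSV (see
#'   [read_substances()]) or an already-loaded list.
#' @param ... further arguments (e.g. `column`, `life_history`, `init`,
#'   `substeps`) passed to [scenario()].
#' @return A validated [scenario()].
#' @export
load_scenario <- function(path, substances, ...) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("key", "value") %in% names(raw)))
    stop("scenario file must be a CSV with columns 'key' and 'value'",
         call. = FALSE)
  keys <- scenario_key_table()
  unknown <- setdiff(unique(raw$key), c(names(keys), "application"))
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  problems <- character()
  val <- function(key) {
    hit <- raw$value[raw$key == key]
    if (length(hit) >= 1L) return(hit[1L])
    default <- keys[[key]]
    if (is.na(default) && key != "penetration_depth_cm") {
      problems <<- c(problems, paste0("missing mandatory field '", key, "'"))
      return(NA)
    }
    if (key != "penetration_depth_cm")
      warning("scenario key '", key, "' missing; using default ",
              deparse(default), call. = FALSE)
    default
  }

  name <- as.character(val("name"))
  mixing_depth <- as.numeric(val("mixing_depth_cm"))
  horizon <- as.numeric(val("horizon_days"))
  guts_assumption <- toupper(as.character(val("guts_assumption")))
  bulk_density <- as.numeric(val("bulk_density_g_cm3"))
  temperature <- as.numeric(strsplit(as.character(val("temperature_c")), ";")[[1L]])
  crop <- as.character(val("crop"))
  iterations <- as.numeric(val("iterations"))
  mixture_rule <- toupper(as.character(val("mixture_assumption")))
  juv <- as.logical(val("include_juvenile_mortality"))
  seed <- as.numeric(val("master_seed"))
  movement <- as.logical(val("movement_enabled"))
  pen_raw <- raw$value[raw$key == "penetration_depth_cm"]
  penetration <- if (length(pen_raw)) as.numeric(pen_raw[1L]) else NULL

  app_rows <- raw$value[raw$key == "application"]
  applications <- if (length(app_rows)) {
    parts <- strsplit(app_rows, "|", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
      problems <- c(problems,
                    "application rows need 'substance_id|day|rate_kg_ha[|bbch]'")
    ok <- parts[!bad]
    data.frame(
      substance_id = vapply(ok, `[`, "", 1L),
      day = as.numeric(vapply(ok, `[`, "", 2L)),
      rate = as.numeric(vapply(ok, `[`, "", 3L)),
      bbch = vapply(ok, function(p) if (length(p) >= 4L)
        suppressWarnings(as.numeric(p[4L])) else NA_real_, 0)
    )
  } else data.frame(substance_id = character(0), day = numeric(0),
                    rate = numeric(0), bbch = numeric(0))

  if (!guts_assumption %in% c("SD", "IT"))
    problems <- c(problems,
                  paste0("guts_assumption must be SD or IT, got '",
                         guts_assumption, "'"))
  if (!mixture_rule %in% c("IA", "CA"))
    problems <- c(problems,
                  paste0("mixture_assumption must be IA or CA, got '",
                         mixture_rule, "'"))
  if (!is.na(mixing_depth) && mixing_depth <= 0)
    problems <- c(problems, "mixing_depth_cm must be > 0")
  if (length(unique(applications$substance_id)) < 2L &&
      !any(raw$key == "mixture_assumption"))
    message("single substance applied; mixture assumption is irrelevant")
  if (length(problems))
    stop("invalid scenario file:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)

  subs <- if (is.list(substances) && !is.data.frame(substances)) substances
          else read_substances(substances)
  scenario(
    name = name, applications = applications, substances = subs,
    soil = soil_scenario(mixing_depth, bulk_density, temperature,
                         crop = if (nzchar(crop)) crop else NULL),
    guts_assumption = guts_assumption, mixture_rule = mixture_rule,
    horizon = horizon, iterations = iterations,
    include_juvenile_mortality = juv, master_seed = seed,
    movement_enabled = movement, penetration_depth = penetration,
    ...
  )
}

#' Write a scenario back to its CSV representation
#'
#' Inverse of [load_scenario()] for the CSV-representable settings
#' (application schedule and scalar configuration; the soil column and
#' life-history parameters live in R configuration, not the file).
#'
#' @param scn a [scenario()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "collempop_scenario"))
  rows <- data.frame(key = character(0), value = character(0))
  add <- function(key, value) rows <<- rbind(rows, data.frame(key = key,
                                                              value = as.character(value)))
  add("name", scn$name)
  add("mixing_depth_cm", scn$soil$mixing_depth)
  add("bulk_density_g_cm3", scn$soil$bulk_density)
  add("temperature_c", paste(scn$soil$temperature, collapse = ";"))
  add("crop", if (is.null(scn$soil$crop)) "" else scn$soil$crop)
  add("horizon_days", scn$horizon)
  add("guts_assumption", scn$guts_assumption)
  add("iterations", scn$iterations)
  add("mixture_assumption", scn$mixture_rule)
  add("include_juvenile_mortality", scn$include_juvenile_mortality)
  add("master_seed", scn$master_seed)
  add("movement_enabled", scn$movement_enabled)
  if (!is.null(scn$penetration_depth))
    add("penetration_depth_cm", scn$penetration_depth)
  apps <- scn$applications
  for (i in seq_len(nrow(apps))) {
    bbch <- if ("bbch" %in% names(apps) && !is.na(apps$bbch[i]))
      paste0("|", apps$bbch[i]) else ""
    add("application", paste0(apps$substance_id[i], "|", apps$day[i], "|",
                              apps$rate[i], bbch))
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a substance list to CSV
#'
#' @param substances named list of [substance_properties()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_substances <- function(substances, path) {
  rows <- lapply(substances, function(s) {
    data.frame(
      substance_id = s$substance_id, dt50_days = s$dt50,
      reduction_factor = s$reduction_factor,
      sd_ke = if (is.null(s$guts_sd)) NA_real_ else s$guts_sd$k_e,
      sd_kk = if (is.null(s$guts_sd)) NA_real_ else s$guts_sd$k_k,
      sd_z = if (is.null(s$guts_sd)) NA_real_ else s$guts_sd$z,
      it_ke = if (is.null(s$guts_it)) NA_real_ else s$guts_it$k_e,
      it_alpha = if (is.null(s$guts_it)) NA_real_ else s$guts_it$alpha,
      it_beta = if (is.null(s$guts_it)) NA_real_ else s$guts_it$beta
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation results as tidy CSV files plus metadata
#'
#' Writes four tidy files into `out_dir` — `population_counts.csv`
#' (iteration, day, metric, value), `toxicant_deaths.csv` (iteration, day,
#' deaths), `depth_distribution.csv` (iteration, day, stage, layer, count)
#' and `occurrence.csv` (iteration, stage, occurrence) — plus
#' `metadata.json` echoing the configuration and seeds. Output is
#' byte-stable for identical results.
#'
#' @param results a [run_simulation()] result.
#' @param out_dir output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "collempop_results"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)

  counts <- do.call(rbind, lapply(results$records, function(r) {
    d <- r$daily
    do.call(rbind, lapply(c("n_adults", "n_juveniles", "n_eggs"), function(mt)
      data.frame(iteration = r$iteration, day = d$day, metric = mt,
                 value = d[[mt]])))
  }))
  deaths <- do.call(rbind, lapply(results$records, function(r)
    data.frame(iteration = r$iteration, day = r$daily$day,
               deaths = r$daily$toxicant_deaths)))
  depth <- do.call(rbind, lapply(results$records, function(r) {
    if (is.null(r$depth)) return(NULL)
    cbind(iteration = r$iteration, r$depth)
  }))
  occ <- do.call(rbind, lapply(results$records, function(r)
    data.frame(iteration = r$iteration,
               stage = c("adults", "juveniles", "eggs"),
               occurrence = as.numeric(r$occurrence))))

  scn <- results$scenario
  meta <- list(
    scenario_name = scn$name,
    guts_assumption = scn$guts_assumption,
    mixture_rule = scn$mixture_rule,
    horizon_days = scn$horizon,
    iterations = scn$iterations,
    master_seed = scn$master_seed,
    iteration_seeds = vapply(results$records, `[[`, 0L, "seed"),
    substances = names(scn$substances),
    include_juvenile_mortality = scn$include_juvenile_mortality,
    movement_enabled = scn$movement_enabled,
    package_version = as.character(utils::packageVersion("collempop"))
  )

  paths <- file.path(out_dir, c("population_counts.csv", "toxicant_deaths.csv",
                                "depth_distribution.csv", "occurrence.csv",
                                "metadata.json"))
  write.csv(counts, paths[1L], row.names = FALSE, quote = FALSE)
  write.csv(deaths, paths[2L], row.names = FALSE, quote = FALSE)
  if (!is.null(depth))
    write.csv(depth, paths[3L], row.names = FALSE, quote = FALSE)
  write.csv(occ, paths[4L], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(meta, paths[5L], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Export an exposure profile as tidy CSV
#'
#' @param profiles list of (or single) [build_exposure_profile()] objects.
#' @param path output CSV path with columns `day`, `substance_id`,
#'   `pec_mg_kg`.
#' @return `path`, invisibly.
#' @export
write_exposure_profiles <- function(profiles, path) {
  if (inherits(profiles, "exposure_profile")) profiles <- list(profiles)
  tidy <- do.call(rbind, lapply(profiles, function(p)
    data.frame(day = seq_along(p$concentration) - 1L,
               substance_id = p$substance_id,
               pec_mg_kg = p$concentration)))
  write.csv(tidy, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
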