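#' Survival-test dataset
#'
#' Validate and normalise raw survival-test data in long format, the
#' standard design of laboratory toxicity tests under constant exposure:
#' replicated vessels at several concentrations, observed counts of
#' survivors at successive time points (time 0 carries the initial count).
#'
#' @param data `data.frame` with columns `replicate_id`, `concentration`
#'   (mg/kg), `time` (days) and `n_alive` (integer >= 0).
#' @return The validated `data.frame` with class `survival_dataset`,
#'   ordered by replicate and time.
#' @export
survival_dataset <- function(data) {
  req <- c("replicate_id", "concentration", "time", "n_alive")
  stopifnot(is.data.frame(data), all(req %in% names(data)))
  data <- data[order(data$replicate_id, data$time), req]
  stopifnot(all(data$n_alive >= 0), all(data$time >= 0),
            all(data$concentration >= 0))
  for (r in unique(data$replicate_id)) {
    sub <- data[data$replicate_id == r, ]
    if (sub$time[1L] != 0)
      stop("invalid dataset: replicate '", r, "' lacks a time-0 count",
           call. = FALSE)
    if (any(diff(sub$n_alive) > 0))
      stop("invalid dataset: survivors increase over time in replicate '",
           r, "'", call. = FALSE)
  }
  class(data) <- c("survival_dataset", "data.frame")
  data
}

#' Conditional-binomial log-likelihood of GUTS-RED parameters
#'
#' Standard GUTS survival likelihood: within each replicate, the deaths in
#' each observation interval \eqn{(t_{j-1}, t_j]} are binomial with the
#' conditional mortality probability \eqn{1 - S(t_j)/S(t_{j-1})} predicted
#' under constant exposure (closed form, [guts_survival_constant()]).
#' Intervals whose predicted probability is 0 while deaths were observed
#' contribute `-Inf`.
#'
#' @param data a [survival_dataset()] (or coercible `data.frame`).
#' @param params [guts_params_sd()] or [guts_params_it()] object.
#' @param assumption `"SD"` or `"IT"`; defaults to the class of `params`.
#' @return Log-likelihood (sum over replicates and intervals, including the
#'   binomial coefficients).
#' @export
guts_log_likelihood <- function(data, params, assumption = NULL) {
  if (!inherits(data, "survival_dataset")) data <- survival_dataset(data)
  if (is.null(assumption))
    assumption <- if (inherits(params, "guts_params_sd")) "SD" else "IT"
  ll <- 0
  for (r in unique(data$replicate_id)) {
    sub <- data[data$replicate_id == r, ]
    sub <- sub[order(sub$time), ]
    s_pred <- guts_survival_constant(sub$concentration[1L], sub$time, params)
    n <- sub$n_alive
    for (j in seq_len(nrow(sub) - 1L)) {
      d <- n[j] - n[j + 1L]
      p <- if (s_pred[j] <= 0) 1 else 1 - s_pred[j + 1L] / s_pred[j]
      p <- min(max(p, 0), 1)
      if (p == 0 && d > 0) return(-Inf)
      if (p == 1 && n[j + 1L] > 0) return(-Inf)
      ll <- ll + lchoose(n[j], d) +
        (if (d > 0) d * log(p) else 0) +
        (if (n[j + 1L] > 0) n[j + 1L] * log(1 - p) else 0)
    }
  }
  ll
}

# --- fast likelihood path used by the optimizer -----------------------------
# replicates sharing (concentration, observation times) also share the
# predicted survival curve, so group them and evaluate the closed form once
replicate_entries <- function(data) {
  lapply(split(data, data$replicate_id), function(r) {
    r <- r[order(r$time), ]
    list(conc = r$concentration[1L], times = r$time, n = r$n_alive)
  })
}

group_entries <- function(entries) {
  key <- vapply(entries, function(e)
    paste0(e$conc, "|", paste(e$times, collapse = ",")), "")
  lapply(split(entries, key), function(g)
    list(conc = g[[1L]]$conc, times = g[[1L]]$times,
         n = do.call(rbind, lapply(g, `[[`, "n"))))
}

ll_grouped <- function(prep, params) {
  total <- 0
  for (g in prep) {
    s <- guts_survival_constant(g$conc, g$times, params)
    nt <- length(g$times)
    sj <- s[-nt]
    p <- ifelse(sj <= 0, 1, 1 - s[-1L] / sj)
    p <- pmin(pmax(p, 0), 1)
    n0 <- g$n[, -nt, drop = FALSE]
    n1 <- g$n[, -1L, drop = FALSE]
    d <- n0 - n1
    logp <- matrix(log(p), nrow(n0), nt - 1L, byrow = TRUE)
    log1mp <- matrix(log1p(-p), nrow(n0), nt - 1L, byrow = TRUE)
    term <- lchoose(n0, d) + ifelse(d > 0, d * logp, 0) +
      ifelse(n1 > 0, n1 * log1mp, 0)
    if (any(!is.finite(term))) return(-Inf)
    total <- total + sum(term)
  }
  total
}

# parameter vector <-> object mapping on the log scale used by the optimizer
guts_par_to_vec <- function(params) {
  if (inherits(params, "guts_params_sd"))
    log(c(k_e = params$k_e, k_k = max(params$k_k, 1e-12), z = max(params$z, 1e-12)))
  else
    log(c(k_e = params$k_e, alpha = params$alpha, beta = params$beta))
}

guts_vec_to_par <- function(vec, assumption, h_b = 0) {
  v <- exp(vec)
  if (assumption == "SD") guts_params_sd(v[1L], v[2L], v[3L], h_b = h_b)
  else guts_params_it(v[1L], v[2L], v[3L], h_b = h_b)
}

# Latin-hypercube-style stratified starting points in log space within bounds
guts_start_points <- function(n_restarts, lower, upper) {
  k <- length(lower)
  pts <- matrix(0, n_restarts, k)
  for (j in seq_len(k)) {
    strata <- (sample.int(n_restarts) - runif(n_restarts)) / n_restarts
    pts[, j] <- log(lower[j]) + strata * (log(upper[j]) - log(lower[j]))
  }
  pts
}

#' Fit GUTS-RED parameters to survival-test data by maximum likelihood
#'
#' Maximises the conditional-binomial likelihood over log-transformed
#' parameters using multi-start Nelder-Mead from stratified (Latin
#' hypercube) starting points, optionally followed by a nonparametric
#' bootstrap (resampling replicates with replacement) for percentile
#' confidence intervals. Deterministic for a fixed seed. The background
#' hazard is fixed (default 0); control mortality beyond it is better
#' handled by the population model's density-dependent mortality.
#'
#' @param data a [survival_dataset()] (or coercible `data.frame`) with at
#'   least two concentrations including a control and two post-zero times.
#' @param assumption `"SD"` or `"IT"`.
#' @param n_restarts number of optimizer starts (default 8).
#' @param seed integer seed controlling starts and bootstrap.
#' @param n_boot bootstrap replicates for confidence intervals (default 0,
#'   i.e. no bootstrap).
#' @param conf_level confidence level for percentile intervals.
#' @param h_b fixed background hazard, per day.
#' @param bounds named list `lower`/`upper` of positive parameter bounds on
#'   the natural scale, in the order (k_e, k_k, z) for SD or
#'   (k_e, alpha, beta) for IT.
#' @return An object of class `guts_fit`: list with `params`,
#'   `log_likelihood`, `assumption`, `convergence` (0 = success),
#'   `n_restarts_converged`, and when bootstrapped a `ci` matrix
#'   (rows lower/upper) and `boot` matrix of resampled estimates.
#' @export
fit_guts <- function(data, assumption = c("SD", "IT"), n_restarts = 8,
                     seed = 1, n_boot = 0, conf_level = 0.9, h_b = 0,
                     bounds = NULL) {
  assumption <- match.arg(assumption)
  if (!inherits(data, "survival_dataset")) data <- survival_dataset(data)
  concs <- unique(data$concentration)
  if (length(concs) < 2L || min(concs) > 0)
    stop("non-identifiable: need >= 2 concentrations including a control",
         call. = FALSE)
  if (length(setdiff(unique(data$time), 0)) < 2L)
    stop("non-identifiable: need >= 2 post-zero observation times", call. = FALSE)
  total_deaths <- sum(vapply(split(data$n_alive, data$replicate_id),
                             function(n) n[1L] - n[length(n)], 0))
  if (total_deaths == 0)
    stop(paste("non-identifiable: no deaths observed at any concentration;",
               "toxicity parameters cannot be estimated - widen the tested",
               "concentration range or extend the test duration"), call. = FALSE)

  cmax <- max(concs)
  tmax <- max(data$time)
  if (is.null(bounds)) {
    bounds <- if (assumption == "SD")
      list(lower = c(1e-3, 1e-4, 1e-4 * cmax), upper = c(50, 100 / cmax, 2 * cmax))
    else
      list(lower = c(1e-3, 1e-3 * cmax, 0.2), upper = c(50, 5 * cmax, 30))
  }

  one_fit <- function(prep, starts) {
    best <- NULL
    n_conv <- 0L
    nll <- function(v) {
      if (any(v < log(bounds$lower) - 1e-9) || any(v > log(bounds$upper) + 1e-9))
        return(1e10)
      p <- guts_vec_to_par(v, assumption, h_b = h_b)
      ll <- ll_grouped(prep, p)
      if (!is.finite(ll)) 1e10 else -ll
    }
    for (i in seq_len(nrow(starts))) {
      res <- tryCatch(
        optim(starts[i, ], nll, method = "Nelder-Mead",
              control = list(maxit = 600, reltol = 1e-9)),
        error = function(e) NULL)
      if (is.null(res) || res$value >= 1e10) next
      n_conv <- n_conv + 1L
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best))
      stop("fit failed: no optimizer start converged to a finite likelihood; ",
           "check data scale against the parameter bounds", call. = FALSE)
    list(res = best, n_conv = n_conv)
  }

  set.seed(seed)
  entries <- replicate_entries(data)
  starts <- guts_start_points(n_restarts, bounds$lower, bounds$upper)
  main <- one_fit(group_entries(entries), starts)
  est <- guts_vec_to_par(main$res$par, assumption, h_b = h_b)

  fit <- structure(list(
    params = est,
    log_likelihood = -main$res$value,
    assumption = assumption,
    convergence = main$res$convergence,
    n_restarts_converged = main$n_conv,
    seed = seed
  ), class = "guts_fit")

  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_boot, 3L,
                   dimnames = list(NULL, names(guts_par_to_vec(est))))
    start_boot <- rbind(main$res$par,
                        guts_start_points(2L, bounds$lower, bounds$upper))
    for (b in seq_len(n_boot)) {
      pick <- sample.int(length(entries), length(entries), replace = TRUE)
      prep_b <- group_entries(entries[pick])
      fit_b <- tryCatch(one_fit(prep_b, start_boot), error = function(e) NULL)
      if (!is.null(fit_b)) boot[b, ] <- exp(fit_b$res$par)
    }
    a <- (1 - conf_level) / 2
    fit$boot <- boot
    fit$ci <- apply(boot, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE)
    fit$conf_level <- conf_level
  }
  fit
}

#' @export
print.guts_fit <- function(x, ...) {
  cat("GUTS-RED-", x$assumption, " maximum-likelihood fit\n", sep = "")
  p <- x$params
  vals <- if (x$assumption == "SD") c(k_e = p$k_e, k_k = p$k_k, z = p$z)
          else c(k_e = p$k_e, alpha = p$alpha, beta = p$beta)
  print(signif(vals, 4))
  cat("log-likelihood:", format(x$log_likelihood, digits = 6), "\n")
  if (!is.null(x$ci)) {
    cat(100 * x$conf_level, "% bootstrap percentile intervals:\n", sep = "")
    print(signif(x$ci, 4))
  }
  invisible(x)
}

#' Simulate a constant-exposure survival experiment
#'
#' Draws individual death times by inverse-CDF sampling from the model
#' survival curve \eqn{S(t)} under constant exposure (each individual gets
#' one uniform draw; it dies in the first observation interval where
#' \eqn{1 - S(t)} exceeds the draw) and aggregates them to survivor counts
#' — the synthetic counterpart of a laboratory survival test, used for
#' parameter-recovery testing.
#'
#' @param params [guts_params_sd()] or [guts_params_it()] object.
#' @param concentrations tested concentrations, mg/kg (include 0 for a
#'   control).
#' @param n_replicates replicates per concentration.
#' @param n_individuals individuals per replicate at time 0.
#' @param times observation days (0 is added if absent).
#' @param seed integer seed.
#' @return A [survival_dataset()].
#' @export
simulate_survival_experiment <- function(params, concentrations,
                                         n_replicates = 3, n_individuals = 20,
                                         times = 0:21, seed = 1) {
  times <- sort(unique(c(0, times)))
  set.seed(seed)
  rows <- list()
  for (conc in concentrations) {
    s_t <- guts_survival_constant(conc, times, params)
    for (r in seq_len(n_replicates)) {
      u <- runif(n_individuals)
      # individual i is alive at time j iff u_i < S(t_j)  (P = S(t_j))
      n_alive <- vapply(s_t, function(s) sum(u < s), 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = sprintf("c%g_r%d", conc, r),
        concentration = conc, time = times, n_alive = n_alive)
    }
  }
  survival_dataset(do.call(rbind, rows))
}
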