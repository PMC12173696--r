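#' Plot simulation results
#'
#' Writes three diagnostic figures into `out_dir`: population time series
#' (adults/juveniles/eggs, one trace per iteration plus the across-
#' iteration mean), daily toxicant deaths, and stage-resolved depth
#' distribution over time (depth axis inverted, increasing downward).
#' Plot failures are logged, never fatal — figures are conveniences, the
#' CSV output is the interface.
#'
#' @param results a [run_simulation()] result.
#' @param out_dir output directory (created if absent).
#' @param width,height figure size in inches.
#' @return Character vector of the figure files written, invisibly.
#' @export
plot_results <- function(results, out_dir, width = 8, height = 5) {
  stopifnot(inherits(results, "collempop_results"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_quietly <- function(plot, file) {
    path <- file.path(out_dir, file)
    ok <- tryCatch({
      ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
      TRUE
    }, error = function(e) {
      message("plot '", file, "' failed: ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }

  counts <- do.call(rbind, lapply(results$records, function(r) {
    d <- r$daily
    do.call(rbind, lapply(c(adults = "n_adults", juveniles = "n_juveniles",
                            eggs = "n_eggs"), function(mt)
      data.frame(iteration = r$iteration, day = d$day,
                 stage = sub("n_", "", mt), value = d[[mt]])))
  }))
  mean_counts <- aggregate(value ~ day + stage, counts, mean)

  p1 <- ggplot2::ggplot(counts,
                        ggplot2::aes(.data$day, .data$value,
                                     group = .data$iteration)) +
    ggplot2::geom_line(alpha = 0.35, colour = "grey40") +
    ggplot2::geom_line(data = mean_counts,
                       ggplot2::aes(.data$day, .data$value, group = NULL),
                       colour = "red", linewidth = 0.7) +
    ggplot2::facet_wrap(~stage, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "day", y = "individuals",
                  title = paste("Population —", results$scenario$name)) +
    ggplot2::theme_minimal()
  save_quietly(p1, "population_trends.png")

  deaths <- do.call(rbind, lapply(results$records, function(r)
    data.frame(iteration = r$iteration, day = r$daily$day,
               deaths = r$daily$toxicant_deaths)))
  mean_deaths <- aggregate(deaths ~ day, deaths, mean)
  p2 <- ggplot2::ggplot(deaths, ggplot2::aes(.data$day, .data$deaths,
                                             group = .data$iteration)) +
    ggplot2::geom_line(alpha = 0.35, colour = "grey40") +
    ggplot2::geom_line(data = mean_deaths,
                       ggplot2::aes(.data$day, .data$deaths, group = NULL),
                       colour = "red", linewidth = 0.7) +
    ggplot2::labs(x = "day", y = "toxicant deaths",
                  title = "Daily deaths attributed to the applied substances") +
    ggplot2::theme_minimal()
  save_quietly(p2, "toxicant_deaths.png")

  depth <- do.call(rbind, lapply(results$records, function(r) {
    if (is.null(r$depth)) return(NULL)
    cbind(iteration = r$iteration, r$depth)
  }))
  if (!is.null(depth) && nrow(depth)) {
    depth_sum <- aggregate(count ~ day + layer + stage, depth, mean)
    p3 <- ggplot2::ggplot(depth_sum,
                          ggplot2::aes(.data$day, .data$layer,
                                       fill = .data$count)) +
      ggplot2::geom_tile() +
      ggplot2::scale_y_reverse() +   # depth increases downward
      ggplot2::facet_wrap(~stage, ncol = 1) +
      ggplot2::labs(x = "day", y = "soil layer (depth ->)",
                    fill = "mean count",
                    title = "Vertical distribution over time") +
      ggplot2::theme_minimal()
    save_quietly(p3, "depth_distribution.png")
  }
  invisible(written)
}
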