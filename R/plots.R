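#' Daily technique frequencies in a log
#'
#' Raw daily proportions of each technique per group, the descriptive view
#' of a diffusion curve.
#'
#' @param log An [ewa_log].
#' @return A ggplot object.
#' @export
plot_diffusion <- function(log) {
  stopifnot(inherits(log, "ewa_log"))
  ev <- log$events
  ev <- dplyr::left_join(ev, log$individuals[, c("id", "group")],
                         by = c(actor_id = "id"))
  daily <- ev |>
    dplyr::count(.data$group, .data$date, .data$technique) |>
    dplyr::group_by(.data$group, .data$date) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(daily, ggplot2::aes(.data$date, .data$freq,
                                      colour = .data$technique)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "experimental day", y = "daily technique frequency",
                  colour = "technique", size = "events") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ewa_prediction <- function(object, ...) {
  res <- attr(object, "resolution")
  xvar <- if (res == "per-bout") "time_min" else "date"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data[[xvar]], .data$mean,
                                    colour = .data$technique,
                                    fill = .data$technique)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw, size = .data$n_events),
                        shape = 1) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(y = "probability of technique",
                  size = "events (raw)") +
    ggplot2::theme_minimal()
  if ("group" %in% names(object) && res == "population-daily") {
    p <- p + ggplot2::facet_wrap(~group)
  }
  if ("actor_id" %in% names(object) && res != "population-daily") {
    p <- p + ggplot2::facet_wrap(~actor_id)
  }
  p
}

#' @export
autoplot.ewa_fit <- function(object, by = "age_sex", ...) {
  td <- tidy(object, by = by)
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$selector)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "posterior mean and 89% HPDI", y = NULL,
                  title = paste0("EWA '", object$spec$name,
                                 "' model: natural-scale parameters")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ewa_comparison <- function(object, ...) {
  object$model <- factor(object$model, levels = rev(object$model))
  ggplot2::ggplot(object, ggplot2::aes(.data$waic, .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$waic - .data$se,
                                          xmax = .data$waic + .data$se)) +
    ggplot2::labs(x = "WAIC (deviance scale, ± SE)", y = NULL) +
    ggplot2::theme_minimal()
}
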