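#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL

#' Tidiers for detection, evaluation and parameter objects
#'
#' `tidy()` returns the per-event / per-match table; `glance()` returns a
#' one-row summary.
#'
#' @param x A `uc_detection`, `uc_evaluation` or `uc_parameters` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name ehgdetect_tidiers
NULL

#' @rdname ehgdetect_tidiers
#' @export
tidy.uc_detection <- function(x, ...) x$events

#' @rdname ehgdetect_tidiers
#' @export
glance.uc_detection <- function(x, ...) {
  tibble::tibble(
    n_ehg = sum(x$events$source == "EHG"),
    n_toco = sum(x$events$source == "TOCO"),
    duration_s = x$duration_s,
    fs = x$fs
  )
}

#' @rdname ehgdetect_tidiers
#' @export
tidy.uc_evaluation <- function(x, ...) {
  tibble::tibble(
    metric = c("sensitivity", "ppv"),
    estimate = c(x$sensitivity, x$ppv),
    undefined = c("sensitivity", "ppv") %in% x$undefined
  )
}

#' @rdname ehgdetect_tidiers
#' @export
glance.uc_evaluation <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 sensitivity = x$sensitivity, ppv = x$ppv,
                 score = (x$sensitivity + x$ppv) / 2)
}

#' @rdname ehgdetect_tidiers
#' @export
tidy.uc_parameters <- function(x, ...) {
  tibble::tibble(
    count = x$count,
    freq_per_10min = x$freq_per_10min,
    mean_duration_s = x$mean_duration_s,
    sd_duration_s = x$sd_duration_s,
    mean_interval_s = x$mean_interval_s,
    sd_interval_s = x$sd_interval_s
  )
}

#' Plot a detection result
#'
#' Shows the EHG envelope (and the smoothed TOCO when present) with the
#' detected events marked: shaded onset-to-end spans and dotted peak lines.
#' The recording must have been detected with `keep_signals = TRUE`.
#'
#' @param object A `uc_detection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uc_detection <- function(object, ...) {
  if (is.null(object$envelopes))
    stop("detection was run with keep_signals = FALSE; nothing to plot",
         call. = FALSE)
  env_long <- tidyr::pivot_longer(
    object$envelopes, -"time_s",
    names_to = "source", values_to = "envelope")
  env_long$source <- toupper(sub("_envelope$", "", env_long$source))
  ev <- object$events

  ggplot2::ggplot(env_long, ggplot2::aes(x = .data$time_s / 60)) +
    ggplot2::geom_rect(
      data = ev,
      ggplot2::aes(xmin = .data$onset_s / 60, xmax = .data$end_s / 60,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$envelope),
                       colour = "steelblue4") +
    ggplot2::geom_vline(
      data = ev, ggplot2::aes(xintercept = .data$peak_s / 60),
      linetype = "dotted", colour = "grey30"
    ) +
    ggplot2::facet_wrap(~source, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "envelope amplitude",
                  title = "Detected uterine contractions") +
    ggplot2::theme_minimal()
}

#' Plot a parameter sweep
#'
#' Sensitivity, PPV and their average (the score) as a function of the swept
#' ZCR parameter.
#'
#' @param object A `uc_sweep` tibble from [sweep_parameter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.uc_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("param_value", "sensitivity", "ppv", "score")],
    -"param_value", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$param_value, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$param[1], y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
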