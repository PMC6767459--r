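#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_rect
#'   geom_point geom_vline labs theme_minimal scale_fill_viridis_c coord_fixed
#' @importFrom rlang .data
NULL

#' Plot an ECG record
#'
#' Voltage trace against time; samples masked by the large-amplitude-noise
#' stage are shaded.
#'
#' @param object An `ecg_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_tbl <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$time, y = .data$voltage)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "voltage (mV)") +
    theme_minimal()
  if (any(!object$valid)) {
    fs <- ecg_fs(object)
    r <- rle(!object$valid)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    bad <- tibble::tibble(xmin = (starts[r$values] - 1) / fs,
                          xmax = ends[r$values] / fs)
    p <- p + geom_rect(data = bad,
                       aes(xmin = .data$xmin, xmax = .data$xmax,
                           ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "red", alpha = 0.15)
  }
  p
}

#' Plot beat detections over the filtered ECG
#'
#' @param beats A `beat_tbl` from [detect_beats()].
#' @param signal Optional `ecg_tbl` to draw under the beat markers; defaults
#'   to the filtered record attached by [detect_beats()].
#' @return A ggplot object.
#' @export
plot_beats <- function(beats, signal = attr(beats, "filtered")) {
  p <- if (!is.null(signal)) autoplot(signal) else
    ggplot() + theme_minimal() + labs(x = "time (s)", y = "voltage (mV)")
  p + geom_vline(data = beats, aes(xintercept = .data$time),
                 colour = "steelblue", alpha = 0.5, linetype = 2)
}

#' Plot a discretized Lorenz-Poincare diagram
#'
#' Occupied bins of the RR-versus-dRR grid, coloured by point count. A tight
#' cluster indicates an organised rhythm; a scattered cloud is the
#' atrial-fibrillation signature the disorganization index quantifies.
#'
#' @param object A `poincare_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poincare_grid <- function(object, ...) {
  rr_range <- attr(object, "rr_range", exact = TRUE)
  drr_range <- attr(object, "drr_range", exact = TRUE)
  nb <- attr(object, "bins_per_axis", exact = TRUE)
  ggplot(object, aes(x = .data$rr_mid, y = .data$drr_mid,
                     fill = .data$count)) +
    geom_tile(width = diff(rr_range) / nb, height = diff(drr_range) / nb) +
    scale_fill_viridis_c() +
    labs(x = "RR (s)", y = "dRR (s)", fill = "points") +
    theme_minimal()
}

#' Plot an averaged beat template
#'
#' @param object A `beat_template`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beat_template <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$voltage)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    labs(x = "time relative to R wave (s)", y = "voltage (mV)",
         subtitle = sprintf("%d contributing beats",
                            attr(object, "n_contributing", exact = TRUE))) +
    theme_minimal()
}

#' @export
ggplot2::autoplot
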