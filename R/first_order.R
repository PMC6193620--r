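# First-order gray-scale statistics of ROI pixels and the per-patient mean
# intensity score.

#' First-order statistics of a set of gray values
#'
#' @param pixels integer vector of gray values in 0..255 (e.g. from
#'   [extract_pixels()])
#' @return list of class `first_order_stats`: `histogram` (256 counts, gray
#'   levels 0..255), `mean`, `variance` (population variance, divide by n),
#'   `n`
#' @export
first_order_stats <- function(pixels) {
  stop_if_not(length(pixels) > 0, "empty pixel set")
  stop_if_not(all(is.finite(pixels)) && all(pixels >= 0 & pixels <= 255),
              "pixel values must lie in [0, 255]")
  h <- tabulate(as.integer(pixels) + 1L, nbins = 256L)
  m <- mean(pixels)
  v <- mean((pixels - m)^2)
  structure(list(histogram = h, mean = m, variance = v, n = length(pixels)),
            class = "first_order_stats")
}

#' @export
print.first_order_stats <- function(x, ...) {
  cat(sprintf("<first_order_stats> n = %d, mean = %.2f, variance = %.2f\n",
              x$n, x$mean, x$variance))
  invisible(x)
}

#' Per-patient gray-scale mean intensity score
#'
#' The per-frame ROI mean intensities of one patient's standard views are
#' pooled into a single average — the gray-scale mean intensity score used
#' for correlation against the oxygenation indices.
#'
#' @param frame_means numeric vector of per-frame ROI means
#' @param views_per_patient required number of frames (default 8)
#' @return the arithmetic mean, in gray units
#' @export
patient_mean_intensity_score <- function(frame_means, views_per_patient = 8) {
  stop_if_not(length(frame_means) == views_per_patient,
              "expected ", views_per_patient, " frame means, got ", length(frame_means))
  stop_if_not(all(is.finite(frame_means)), "non-finite frame means")
  mean(frame_means)
}
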