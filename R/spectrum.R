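#' Construct a 1D spectrum table
#'
#' A spectrum is a tibble with columns `frequency_hz` (strictly increasing)
#' and `intensity`, carrying an optional `noise_sigma` attribute (baseline
#' noise standard deviation, same units as `intensity`).
#'
#' @param frequency_hz Strictly increasing frequency grid, Hz.
#' @param intensity Real amplitudes, arbitrary units; same length as the grid.
#' @param noise_sigma Optional known baseline noise standard deviation.
#' @return A tibble of class `nmr_spectrum`.
#' @export
new_spectrum <- function(frequency_hz, intensity, noise_sigma = NA_real_) {
  stopifnot(length(frequency_hz) == length(intensity))
  if (any(diff(frequency_hz) <= 0)) {
    stop("`frequency_hz` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(frequency_hz = as.numeric(frequency_hz),
                        intensity = as.numeric(intensity))
  attr(out, "noise_sigma") <- noise_sigma
  class(out) <- c("nmr_spectrum", class(out))
  out
}

#' @rdname new_spectrum
#' @param x Object to query.
#' @export
noise_sigma <- function(x) attr(x, "noise_sigma")

#' Read a two-column spectrum text file
#'
#' Accepts whitespace- or comma-separated text with columns
#' frequency (Hz) and intensity, and an optional third noise column
#' (a single noise level; the first value is used).
#'
#' @param path File path.
#' @return An `nmr_spectrum` tibble.
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  df <- if (grepl(",", first, fixed = TRUE)) {
    utils::read.csv(path, header = grepl("[A-Za-z]", first))
  } else {
    utils::read.table(path, header = grepl("[A-Za-z]", first))
  }
  ns <- if (ncol(df) >= 3) as.numeric(df[[3]][1]) else NA_real_
  new_spectrum(df[[1]], df[[2]], noise_sigma = ns)
}

#' Write a spectrum as two-column text
#'
#' @param spectrum An `nmr_spectrum` (or two-column data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(frequency_hz = spectrum$frequency_hz,
                   intensity = spectrum$intensity)
  ns <- noise_sigma(spectrum)
  if (!is.null(ns) && is.finite(ns)) df$noise_sigma <- ns
  utils::write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subtract an identically sampled reference spectrum
#'
#' Pointwise difference used to remove enzyme-only background signals from a
#' peptide + enzyme spectrum. The two spectra must share the identical
#' frequency axis; no silent interpolation is performed. Noise levels combine
#' in quadrature when both are known.
#'
#' @param sample,reference `nmr_spectrum` tibbles on the same axis.
#' @return The difference as an `nmr_spectrum`.
#' @export
subtract_reference <- function(sample, reference) {
  if (nrow(sample) != nrow(reference) ||
      !isTRUE(all.equal(sample$frequency_hz, reference$frequency_hz,
                        tolerance = 1e-12))) {
    stop("sample and reference must share an identical frequency axis",
         call. = FALSE)
  }
  ns_s <- noise_sigma(sample)
  ns_r <- noise_sigma(reference)
  ns <- if (is.finite(ns_s) && is.finite(ns_r)) sqrt(ns_s^2 + ns_r^2) else ns_s
  new_spectrum(sample$frequency_hz, sample$intensity - reference$intensity,
               noise_sigma = ns)
}

#' Estimate baseline noise in a signal-free window
#'
#' @param spectrum An `nmr_spectrum`.
#' @param window Length-2 numeric, Hz; region assumed free of signal.
#' @return Standard deviation of the (detrended) intensities in the window.
#' @export
estimate_noise <- function(spectrum, window) {
  stopifnot(length(window) == 2L)
  sel <- spectrum$frequency_hz >= min(window) &
    spectrum$frequency_hz <= max(window)
  if (sum(sel) < 8) stop("noise window contains fewer than 8 points",
                         call. = FALSE)
  y <- spectrum$intensity[sel]
  stats::sd(y - stats::median(y))
}

#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$frequency_hz, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "intensity") +
    ggplot2::theme_minimal()
}
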