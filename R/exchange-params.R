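#' Two-site chemical-exchange parameters
#'
#' Container for the parameters of a spin exchanging between a cis and a trans
#' chemical environment: equilibrium populations, resonance positions,
#' intrinsic transverse relaxation rates and the total exchange rate
#' `k_ex = k_ct + k_tc`. Detailed balance ties the microscopic rates to the
#' populations: `k_ct = p_trans * k_ex` (cis -> trans) and
#' `k_tc = p_cis * k_ex` (trans -> cis), so that `k_ct * p_cis = k_tc * p_trans`.
#'
#' @param p_cis Equilibrium fraction of the cis conformer, in `[0, 1]`.
#'   `p_trans` is `1 - p_cis`.
#' @param nu_cis,nu_trans Resonance positions of the cis and trans lines, Hz.
#' @param r2_cis,r2_trans Intrinsic transverse relaxation rates, s^-1.
#'   The full width at half maximum of an isolated line is `r2 / pi` Hz.
#' @param k_ex Total exchange rate `k_ct + k_tc`, s^-1. Must be >= 0.
#'
#' @return An object of class `exchange_params` (a validated named list with
#'   elements `p_cis`, `p_trans`, `nu_cis`, `nu_trans`, `r2_cis`, `r2_trans`,
#'   `k_ex`, `k_ct`, `k_tc`).
#'
#' @examples
#' pars <- exchange_params(p_cis = 0.25, nu_cis = -10, nu_trans = 10,
#'                         r2_cis = 8, r2_trans = 8, k_ex = 30)
#' tidy(pars)
#' @export
exchange_params <- function(p_cis, nu_cis, nu_trans, r2_cis, r2_trans, k_ex) {
  stopifnot(is.numeric(p_cis), length(p_cis) == 1L)
  if (p_cis < 0 || p_cis > 1) {
    stop("`p_cis` must lie in [0, 1], got ", p_cis, call. = FALSE)
  }
  rates <- c(r2_cis = r2_cis, r2_trans = r2_trans, k_ex = k_ex)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("relaxation and exchange rates must be finite and >= 0", call. = FALSE)
  }
  if (!all(is.finite(c(nu_cis, nu_trans)))) {
    stop("resonance positions must be finite", call. = FALSE)
  }
  structure(
    list(
      p_cis = p_cis, p_trans = 1 - p_cis,
      nu_cis = nu_cis, nu_trans = nu_trans,
      r2_cis = r2_cis, r2_trans = r2_trans,
      k_ex = k_ex,
      k_ct = (1 - p_cis) * k_ex,  # cis -> trans
      k_tc = p_cis * k_ex         # trans -> cis
    ),
    class = "exchange_params"
  )
}

#' @export
print.exchange_params <- function(x, ...) {
  cat("<exchange_params>\n")
  cat(sprintf("  p_cis/p_trans: %.3f / %.3f\n", x$p_cis, x$p_trans))
  cat(sprintf("  nu_cis/nu_trans: %.2f / %.2f Hz (delta-nu %.2f Hz)\n",
              x$nu_cis, x$nu_trans, abs(x$nu_trans - x$nu_cis)))
  cat(sprintf("  r2_cis/r2_trans: %.2f / %.2f s^-1\n", x$r2_cis, x$r2_trans))
  cat(sprintf("  k_ex: %.2f s^-1 (k_ct %.2f, k_tc %.2f)\n",
              x$k_ex, x$k_ct, x$k_tc))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.exchange_params <- function(x, ...) {
  tibble::tibble(
    term = c("p_cis", "p_trans", "nu_cis", "nu_trans",
             "r2_cis", "r2_trans", "k_ex", "k_ct", "k_tc"),
    estimate = unlist(x, use.names = FALSE)
  )
}

#' Spectrometer frequency helpers
#'
#' Convert between a chemical-shift axis in ppm and the Hz axis used
#' internally, given the spectrometer proton frequency.
#'
#' @param ppm,hz Values to convert.
#' @param spectrometer_mhz Spectrometer frequency in MHz (default 600).
#' @return Numeric vector in the other unit.
#' @export
ppm_to_hz <- function(ppm, spectrometer_mhz = 600) ppm * spectrometer_mhz

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, spectrometer_mhz = 600) hz / spectrometer_mhz
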