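#' Simulate a two-site chemical-exchange absorption lineshape
#'
#' Computes the real part of the steady-state two-site exchange (Bloch--
#' McConnell) absorption lineshape. Magnetization evolves under
#' `dM/dt = (i * Omega - R + K) M` with `Omega = 2 * pi * diag(nu_cis, nu_trans)`,
#' `R = diag(r2_cis, r2_trans)` and the detailed-balance exchange matrix `K`;
#' the spectrum at frequency `nu` is
#' `Re(1' (i * 2 * pi * nu * I - i * Omega + R - K)^-1 p)`, evaluated in closed
#' form from the 2x2 complex inverse. The total integral over frequency equals
#' `amplitude` and is independent of `k_ex`.
#'
#' In the no-exchange limit the spectrum is two Lorentzians with areas
#' `p_cis`/`p_trans` and FWHM `r2 / pi` Hz; in fast exchange a single line
#' appears at the population-weighted mean frequency.
#'
#' @param params An [exchange_params()] object.
#' @param frequency_hz Strictly increasing frequency grid, Hz. Should span both
#'   resonances by at least 5 linewidths (a warning is issued otherwise).
#' @param amplitude Total integrated intensity.
#' @return An `nmr_spectrum` tibble.
#' @examples
#' pars <- exchange_params(0.3, -10, 10, 10, 10, 50)
#' sp <- simulate_two_site_spectrum(pars, seq(-100, 100, length.out = 1024))
#' @export
simulate_two_site_spectrum <- function(params, frequency_hz, amplitude = 1) {
  stopifnot(inherits(params, "exchange_params"))
  fwhm <- max(params$r2_cis, params$r2_trans) / pi
  lo <- min(params$nu_cis, params$nu_trans) - 5 * fwhm
  hi <- max(params$nu_cis, params$nu_trans) + 5 * fwhm
  if (min(frequency_hz) > lo || max(frequency_hz) < hi) {
    warning("frequency axis does not cover both resonances by >= 5 linewidths",
            call. = FALSE)
  }
  y <- two_site_shape(params, frequency_hz)
  new_spectrum(frequency_hz, amplitude * y, noise_sigma = 0)
}

# Closed-form evaluation of the 2x2 complex inverse, vectorized over
# frequency. Normalized so the integral over nu (Hz) is 1.
two_site_shape <- function(params, nu) {
  w <- 2 * pi * nu
  a11 <- complex(real = params$r2_cis + params$k_ct,
                 imaginary = w - 2 * pi * params$nu_cis)
  a22 <- complex(real = params$r2_trans + params$k_tc,
                 imaginary = w - 2 * pi * params$nu_trans)
  a12 <- -params$k_tc
  a21 <- -params$k_ct
  det <- a11 * a22 - a12 * a21
  x1 <- (a22 * params$p_cis - a12 * params$p_trans) / det
  x2 <- (a11 * params$p_trans - a21 * params$p_cis) / det
  2 * Re(x1 + x2)
}

#' Fit the intrinsic linewidth of a single non-exchanging resonance
#'
#' Least-squares fit of a single Lorentzian (position, height, `r2`, constant
#' baseline) inside a frequency window containing one resonance, as used to
#' calibrate the exchange-free transverse relaxation rate from the second
#' leucine methyl group. The FWHM of the line is `r2 / pi` Hz.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param window Length-2 numeric (Hz) delimiting the fit region; must contain
#'   a single resolved maximum, otherwise an error is raised.
#' @return A list of class `linewidth_fit` with elements `r2`, `r2_se`,
#'   `nu0`, `height`, `baseline`, `residual_rms`.
#' @export
fit_intrinsic_linewidth <- function(spectrum, window) {
  stopifnot(length(window) == 2L)
  sel <- spectrum$frequency_hz >= min(window) &
    spectrum$frequency_hz <= max(window)
  nu <- spectrum$frequency_hz[sel]
  y <- spectrum$intensity[sel]
  if (length(nu) < 10) stop("fit window contains fewer than 10 points",
                            call. = FALSE)
  if (count_resolved_maxima(y) > 1) {
    stop("fit window contains more than one resolved maximum; ",
         "intrinsic linewidth requires a single resonance", call. = FALSE)
  }
  base0 <- stats::median(c(utils::head(y, 5), utils::tail(y, 5)))
  h0 <- max(y) - base0
  nu0 <- nu[which.max(y)]
  half <- which(y - base0 > h0 / 2)
  fwhm0 <- max(nu[max(half)] - nu[min(half)], 2 * mean(diff(nu)))
  fit <- minpack.lm::nlsLM(
    y ~ h * r2^2 / (r2^2 + (2 * pi * (nu - n0))^2) + b,
    start = list(h = h0, r2 = pi * fwhm0, n0 = nu0, b = base0),
    lower = c(0, 1e-6, min(nu), -Inf),
    upper = c(Inf, Inf, max(nu), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 4))
  structure(
    list(r2 = unname(cf["r2"]), r2_se = unname(se[2]),
         nu0 = unname(cf["n0"]), height = unname(cf["h"]),
         baseline = unname(cf["b"]),
         residual_rms = sqrt(mean(stats::resid(fit)^2))),
    class = "linewidth_fit"
  )
}

# Count maxima that are resolved above the baseline spread: local maxima of a
# lightly smoothed trace whose prominence exceeds 20% of the signal range.
count_resolved_maxima <- function(y, k = 5L) {
  if (length(y) < 2 * k + 3) k <- max(1L, (length(y) - 3L) %/% 2L)
  ys <- stats::filter(y, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  ys <- as.numeric(ys)
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  rng <- diff(range(ys))
  if (rng <= 0) return(1L)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (ys[i] >= ys[i - 1] && ys[i] > ys[i + 1]) peaks <- c(peaks, i)
  }
  if (length(peaks) < 2) return(length(peaks))
  # prominence: drop to the highest minimum separating consecutive peaks
  keep <- peaks[order(ys[peaks], decreasing = TRUE)]
  resolved <- 1L
  for (j in 2:length(keep)) {
    p <- keep[j]
    higher <- keep[seq_len(j - 1)]
    sep <- vapply(higher, function(q) min(ys[seq(min(p, q), max(p, q))]),
                  numeric(1))
    prom <- ys[p] - max(sep)
    if (prom > 0.2 * rng) resolved <- resolved + 1L
  }
  resolved
}

#' Fit two Lorentzians to an exchange-free doublet
#'
#' Estimates cis/trans populations, resonance positions and intrinsic widths
#' from a zero-enzyme spectrum in which the two conformers give two resolved
#' Lorentzian lines. Populations are the fractional integrated areas.
#'
#' @param spectrum An `nmr_spectrum` containing the doublet.
#' @param window Optional length-2 numeric restricting the fit region, Hz.
#' @param cis Which line is the cis conformer: `"minor"` (smaller area,
#'   default), `"lower"` (lower frequency) or `"upper"`.
#' @return A list of class `doublet_fit` with elements `p_cis`, `nu_cis`,
#'   `nu_trans`, `r2_cis`, `r2_trans`, `baseline`, `residual_rms`.
#' @export
fit_reference_doublet <- function(spectrum, window = NULL,
                                  cis = c("minor", "lower", "upper")) {
  cis <- match.arg(cis)
  nu <- spectrum$frequency_hz
  y <- spectrum$intensity
  if (!is.null(window)) {
    sel <- nu >= min(window) & nu <= max(window)
    nu <- nu[sel]; y <- y[sel]
  }
  base0 <- stats::median(c(utils::head(y, 5), utils::tail(y, 5)))
  i1 <- which.max(y)
  n1 <- nu[i1]
  h0 <- max(y) - base0
  # half-height width of the tallest line, then start the second line at the
  # highest point outside a 3-FWHM mask around the first
  above <- which(y - base0 > h0 / 2)
  run <- above[cumsum(c(1, diff(above) != 1)) ==
                 cumsum(c(1, diff(above) != 1))[match(i1, above)]]
  fwhm1 <- max(nu[max(run)] - nu[min(run)], 2 * mean(diff(nu)))
  outside <- which(abs(nu - n1) > 3 * fwhm1)
  n2 <- if (length(outside) > 0) nu[outside[which.max(y[outside])]] else
    n1 + 10 * mean(diff(nu))
  fit <- minpack.lm::nlsLM(
    y ~ h1 * r1^2 / (r1^2 + (2 * pi * (nu - m1))^2) +
      h2 * r2^2 / (r2^2 + (2 * pi * (nu - m2))^2) + b,
    start = list(h1 = h0, r1 = 8, m1 = n1, h2 = h0 / 2, r2 = 8, m2 = n2,
                 b = base0),
    lower = c(0, 1e-6, min(nu), 0, 1e-6, min(nu), -Inf),
    upper = c(Inf, Inf, max(nu), Inf, Inf, max(nu), Inf),
    control = minpack.lm::nls.lm.control(maxiter = 400)
  )
  cf <- as.list(stats::coef(fit))
  # Lorentzian area over nu: height * r2 / 2 (integral of h r^2/(r^2+(2pi x)^2))
  area <- c(cf$h1 * cf$r1 / 2, cf$h2 * cf$r2 / 2)
  pos <- c(cf$m1, cf$m2)
  wid <- c(cf$r1, cf$r2)
  i_cis <- switch(cis,
                  minor = which.min(area),
                  lower = which.min(pos),
                  upper = which.max(pos))
  i_trn <- 3L - i_cis
  structure(
    list(p_cis = area[i_cis] / sum(area),
         nu_cis = pos[i_cis], nu_trans = pos[i_trn],
         r2_cis = wid[i_cis], r2_trans = wid[i_trn],
         baseline = cf$b,
         residual_rms = sqrt(mean(stats::resid(fit)^2))),
    class = "doublet_fit"
  )
}

#' Fit the apparent exchange rate of a two-site lineshape
#'
#' Fits the exchange-broadened cis/trans doublet with the two-site lineshape
#' model, holding the populations, resonance positions and intrinsic
#' relaxation rates fixed (taken from the enzyme-free spectrum and the
#' non-exchanging reference methyl). The only shape parameter floated is the
#' apparent exchange rate `k_app >= 0`; for each candidate rate the amplitude
#' and constant baseline are solved by linear least squares, and the rate is
#' profiled over a coarse grid followed by golden-section refinement.
#'
#' @param spectrum An `nmr_spectrum` of the exchanging doublet.
#' @param p_cis,nu_cis,nu_trans,r2_cis,r2_trans Fixed shape parameters.
#' @param window Optional length-2 numeric restricting the fit region, Hz.
#' @param k_max Upper bound for the rate search, s^-1 (default 2000).
#' @param init Optional initial rate; by default inferred from a log-spaced
#'   profile grid.
#' @return A list of class `lineshape_fit` with elements `k_app`, `k_app_sd`
#'   (`NA` until [monte_carlo_uncertainty()] is applied), `amplitude`,
#'   `baseline`, `fixed` (the fixed parameter list), `residual_rms`,
#'   `converged`, `at_bound`.
#' @export
fit_apparent_exchange <- function(spectrum, p_cis, nu_cis, nu_trans,
                                  r2_cis, r2_trans, window = NULL,
                                  k_max = 2000, init = NULL) {
  nu <- spectrum$frequency_hz
  y <- spectrum$intensity
  if (!is.null(window)) {
    sel <- nu >= min(window) & nu <= max(window)
    nu <- nu[sel]; y <- y[sel]
  }
  pars_at <- function(k) exchange_params(p_cis, nu_cis, nu_trans,
                                         r2_cis, r2_trans, k)
  # residual sum of squares at rate k, amplitude/baseline profiled out
  rss_at <- function(k) {
    s <- two_site_shape(pars_at(k), nu)
    X <- cbind(s, 1)
    beta <- tryCatch(stats::lm.fit(X, y)$coefficients,
                     error = function(e) c(NA_real_, NA_real_))
    if (anyNA(beta)) return(list(rss = Inf, a = NA_real_, b = NA_real_))
    r <- y - X %*% beta
    list(rss = sum(r^2), a = beta[1], b = beta[2])
  }
  grid <- c(0, exp(seq(log(0.1), log(k_max), length.out = 60)))
  if (!is.null(init)) grid <- sort(unique(c(grid, init)))
  rss_grid <- vapply(grid, function(k) rss_at(k)$rss, numeric(1))
  i0 <- which.min(rss_grid)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(function(k) rss_at(k)$rss, c(lo, hi), tol = 1e-6)
  # accept the grid point if refinement did not improve on it
  k_hat <- if (opt$objective <= rss_grid[i0]) opt$minimum else grid[i0]
  if (rss_at(0)$rss <= rss_at(k_hat)$rss) k_hat <- 0
  sol <- rss_at(k_hat)
  at_bound <- k_hat >= k_max * (1 - 1e-6)
  if (at_bound) {
    warning("fitted rate hit the search bound k_max = ", k_max, call. = FALSE)
  }
  structure(
    list(k_app = k_hat, k_app_sd = NA_real_,
         amplitude = unname(sol$a), baseline = unname(sol$b),
         fixed = list(p_cis = p_cis, nu_cis = nu_cis, nu_trans = nu_trans,
                      r2_cis = r2_cis, r2_trans = r2_trans),
         window = if (is.null(window)) range(spectrum$frequency_hz) else window,
         residual_rms = sqrt(sol$rss / length(y)),
         n_points = length(y),
         converged = is.finite(sol$rss), at_bound = at_bound),
    class = "lineshape_fit"
  )
}

#' @export
print.lineshape_fit <- function(x, ...) {
  cat("<lineshape_fit>\n")
  cat(sprintf("  k_app: %.3f s^-1", x$k_app))
  if (is.finite(x$k_app_sd)) cat(sprintf(" +/- %.3f (MC)", x$k_app_sd))
  cat("\n")
  cat(sprintf("  residual rms: %.4g over %d points\n",
              x$residual_rms, x$n_points))
  if (x$at_bound) cat("  WARNING: rate at search bound\n")
  invisible(x)
}

#' @export
tidy.lineshape_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_app", "amplitude", "baseline"),
    estimate = c(x$k_app, x$amplitude, x$baseline),
    std.error = c(x$k_app_sd, NA_real_, NA_real_)
  )
}

#' @export
glance.lineshape_fit <- function(x, ...) {
  tibble::tibble(k_app = x$k_app, k_app_sd = x$k_app_sd,
                 residual_rms = x$residual_rms, n_points = x$n_points,
                 converged = x$converged, at_bound = x$at_bound)
}

#' Monte-Carlo uncertainty of a fitted exchange rate
#'
#' Generates `n_replicates` synthetic spectra from the best-fit model plus
#' Gaussian noise at the estimated noise level, refits each, and reports the
#' standard deviation of the refitted rates (one standard deviation). The
#' global RNG state is left untouched; results are reproducible given `seed`.
#'
#' @param fit A converged [fit_apparent_exchange()] result.
#' @param spectrum The spectrum that was fitted (used for the axis, window and
#'   noise level).
#' @param n_replicates Number of noise replicates (default 500; fewer than 50
#'   triggers a warning).
#' @param seed Integer seed.
#' @return The `lineshape_fit` with `k_app_sd` filled in and the replicate
#'   rates attached as attribute `"replicates"`.
#' @export
monte_carlo_uncertainty <- function(fit, spectrum, n_replicates = 500,
                                    seed = 1L) {
  stopifnot(inherits(fit, "lineshape_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge", call. = FALSE)
  if (n_replicates < 50) {
    warning("n_replicates < 50 gives an unreliable error estimate",
            call. = FALSE)
  }
  sel <- spectrum$frequency_hz >= min(fit$window) &
    spectrum$frequency_hz <= max(fit$window)
  nu <- spectrum$frequency_hz[sel]
  y <- spectrum$intensity[sel]
  pars <- do.call(exchange_params, c(fit$fixed, list(k_ex = fit$k_app)))
  model <- fit$amplitude * two_site_shape(pars, nu) + fit$baseline
  sigma <- noise_sigma(spectrum)
  if (is.null(sigma) || !is.finite(sigma) || sigma <= 0) {
    sigma <- sqrt(mean((y - model)^2))
  }
  ks <- with_local_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      pert <- new_spectrum(nu, model + stats::rnorm(length(nu), 0, sigma))
      f <- fit_apparent_exchange(pert, fit$fixed$p_cis, fit$fixed$nu_cis,
                                 fit$fixed$nu_trans, fit$fixed$r2_cis,
                                 fit$fixed$r2_trans)
      f$k_app
    }, numeric(1))
  })
  fit$k_app_sd <- stats::sd(ks)
  attr(fit, "replicates") <- ks
  fit
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
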