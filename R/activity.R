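#' Catalytic efficiency from an enzyme titration of exchange rates
#'
#' Under substrate concentrations well below `K_M`, the apparent cis/trans
#' exchange rate grows linearly with enzyme concentration,
#' `k_app([E]) = k0 + (kcat/KM) * [E]`, so the catalytic efficiency is the
#' slope of a straight-line fit of `k_app` against `[E]`. When per-point
#' uncertainties are supplied the fit is weighted by `1 / sd^2`; the weighted
#' fit is invariant to a uniform rescaling of all uncertainties.
#'
#' @param data Data frame with one row per titration point.
#' @param enzyme,k,sd Tidy-select columns holding the enzyme concentration
#'   (micromolar), the apparent exchange rate (s^-1) and (optionally) its
#'   standard deviation. Defaults match the generator/CLI column names.
#' @param weighted Use `1/sd^2` weights when `sd` is available (default TRUE).
#' @return An object of class `activity_fit` wrapping the underlying `lm`,
#'   with elements `kcat_over_km` (micromolar^-1 s^-1), `kcat_over_km_sd`,
#'   `intercept_k0`, `intercept_k0_sd`, `n`, `negative_slope` flag.
#' @examples
#' d <- tibble::tibble(enzyme_um = c(0, 2, 4, 6),
#'                     k_app = c(100, 110, 120, 130))
#' fit_activity_slope(d)
#' @export
fit_activity_slope <- function(data, enzyme = "enzyme_um", k = "k_app",
                               sd = "k_app_sd", weighted = TRUE) {
  e <- pull_col(data, enzyme)
  y <- pull_col(data, k)
  s <- if (sd %in% names(data)) pull_col(data, sd) else NULL
  keep <- is.finite(e) & is.finite(y)
  e <- e[keep]; y <- y[keep]
  if (!is.null(s)) s <- s[keep]
  if (length(unique(e)) < 3) {
    stop("at least 3 distinct enzyme concentrations are required",
         call. = FALSE)
  }
  if (any(e < 0)) stop("enzyme concentrations must be >= 0", call. = FALSE)
  w <- NULL
  if (weighted && !is.null(s) && all(is.finite(s)) && all(s > 0)) {
    w <- 1 / s^2
  }
  df <- data.frame(e = e, y = y)
  fit <- if (is.null(w)) stats::lm(y ~ e, data = df)
  else stats::lm(y ~ e, data = df, weights = w)
  cf <- summary(fit)$coefficients
  slope <- cf["e", "Estimate"]
  if (slope < 0) {
    warning("fitted activity slope is negative", call. = FALSE)
  }
  structure(
    list(kcat_over_km = slope,
         kcat_over_km_sd = cf["e", "Std. Error"],
         intercept_k0 = cf["(Intercept)", "Estimate"],
         intercept_k0_sd = cf["(Intercept)", "Std. Error"],
         n = length(e), weighted = !is.null(w),
         negative_slope = slope < 0,
         lm = fit, data = tibble::tibble(enzyme_um = e, k_app = y,
                                         k_app_sd = s %||% NA_real_)),
    class = "activity_fit"
  )
}

#' @export
print.activity_fit <- function(x, ...) {
  cat("<activity_fit>\n")
  cat(sprintf("  kcat/KM: %.4g +/- %.2g uM^-1 s^-1 (%s fit, n = %d)\n",
              x$kcat_over_km, x$kcat_over_km_sd,
              if (x$weighted) "weighted" else "ordinary", x$n))
  cat(sprintf("  uncatalysed intercept k0: %.4g +/- %.2g s^-1\n",
              x$intercept_k0, x$intercept_k0_sd))
  invisible(x)
}

#' @export
tidy.activity_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kcat_over_km", "intercept_k0"),
    estimate = c(x$kcat_over_km, x$intercept_k0),
    std.error = c(x$kcat_over_km_sd, x$intercept_k0_sd)
  )
}

#' @export
glance.activity_fit <- function(x, ...) {
  tibble::tibble(kcat_over_km = x$kcat_over_km,
                 kcat_over_km_sd = x$kcat_over_km_sd,
                 intercept_k0 = x$intercept_k0, n = x$n,
                 weighted = x$weighted, negative_slope = x$negative_slope,
                 r.squared = summary(x$lm)$r.squared)
}

#' @export
autoplot.activity_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$enzyme_um, y = .data$k_app)) +
    ggplot2::geom_abline(intercept = object$intercept_k0,
                         slope = object$kcat_over_km, colour = "grey40") +
    ggplot2::geom_point() +
    {if (all(is.finite(d$k_app_sd)))
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$k_app - .data$k_app_sd,
                                          ymax = .data$k_app + .data$k_app_sd),
                             width = 0)} +
    ggplot2::labs(x = "enzyme (uM)", y = expression(k[app] ~ (s^-1))) +
    ggplot2::theme_minimal()
}

#' Michaelis-Menten catalytic efficiency and limiting regime
#'
#' For the scheme `E + S <-> ES -> E + P` with rate constants `k_on`, `k_off`
#' and `k_cat`, the catalytic efficiency is
#' `kcat/KM = k_on * k_cat / (k_off + k_cat)` with
#' `K_M = (k_off + k_cat)/k_on` and `K_D = k_off/k_on`. Two limits are
#' labelled by analogy with amide hydrogen-exchange regimes:
#' when `k_off >> k_cat` the efficiency tends to `k_cat / K_D` (binding-
#' equilibrated, "EX2-like"), and when `k_cat >> k_off` it tends to `k_on`
#' (association-limited, "EX1-like"). Rate ratios of at least
#' `ratio_threshold` (default 100, where the limits hold to 1%) earn the
#' limit label, otherwise the regime is "intermediate".
#'
#' @param k_on Association rate constant, M^-1 s^-1.
#' @param k_off Dissociation rate constant, s^-1.
#' @param k_cat Catalytic rate constant, s^-1.
#' @param ratio_threshold Ratio above which a limit label is assigned.
#' @return A tibble with columns `kcat_over_km` (M^-1 s^-1), `K_M` (M),
#'   `K_D` (M), `regime`.
#' @examples
#' efficiency_regimes(k_on = 1e8, k_off = 1e6, k_cat = 1e2)  # EX2-like
#' efficiency_regimes(k_on = 1e8, k_off = 1e2, k_cat = 1e6)  # EX1-like
#' @export
efficiency_regimes <- function(k_on, k_off, k_cat, ratio_threshold = 100) {
  stopifnot(all(c(k_on, k_off, k_cat) >= 0))
  denom <- k_off + k_cat
  if (any(denom == 0)) stop("k_off + k_cat must be > 0", call. = FALSE)
  eff <- k_on * k_cat / denom
  regime <- dplyr::case_when(
    k_off / pmax(k_cat, .Machine$double.xmin) >= ratio_threshold ~ "EX2-like",
    k_cat / pmax(k_off, .Machine$double.xmin) >= ratio_threshold ~ "EX1-like",
    TRUE ~ "intermediate"
  )
  tibble::tibble(kcat_over_km = eff, K_M = denom / k_on, K_D = k_off / k_on,
                 regime = regime)
}

#' Upper bound on the dissociation rate from an assumed association rate
#'
#' For diffusion-limited association (`k_on` about 1e8 M^-1 s^-1) and a
#' measured dissociation constant, `k_off = k_on * K_D` bounds the
#' dissociation rate from above.
#'
#' @param k_on_assumed Assumed association rate constant, M^-1 s^-1.
#' @param kd_um Dissociation constant, micromolar.
#' @return Dissociation rate bound, s^-1.
#' @examples
#' koff_upper_bound(1e8, 50)  # 5000 s^-1
#' koff_upper_bound(1e8, 1)   # 100 s^-1
#' @export
koff_upper_bound <- function(k_on_assumed, kd_um) {
  stopifnot(all(k_on_assumed > 0), all(kd_um >= 0))
  k_on_assumed * kd_um * 1e-6
}

#' Convert catalytic efficiency between micromolar and molar units
#'
#' @param x Value(s) in micromolar^-1 s^-1 (or M^-1 s^-1 for the inverse).
#' @return Converted value(s).
#' @export
per_um_s_to_per_m_s <- function(x) x * 1e6

#' @rdname per_um_s_to_per_m_s
#' @export
per_m_s_to_per_um_s <- function(x) x * 1e-6

# internal: pull a column by bare name string
pull_col <- function(data, col) {
  if (!col %in% names(data)) {
    stop("column `", col, "` not found in data", call. = FALSE)
  }
  as.numeric(data[[col]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
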