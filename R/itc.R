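#' ITC injection protocol
#'
#' Describes a perfusion-cell titration: cell volume and concentration,
#' syringe (titrant) concentration and the per-injection volumes. The default
#' reproduces the study protocol: a 3 ul pre-injection followed by 42
#' injections of 6.5 ul of 1.2 mM peptide into a cell containing 50 uM
#' protein at 25 C (VP-ITC cell volume 1.43 ml).
#'
#' @param cell_volume_ul Active cell volume, microliters.
#' @param cell_conc_um Macromolecule concentration in the cell, micromolar.
#' @param syringe_conc_um Titrant concentration in the syringe, micromolar.
#' @param injection_volumes_ul Per-injection volumes, microliters. The first
#'   injection may differ from the rest.
#' @param temperature_c Temperature, Celsius.
#' @return A list of class `itc_protocol`.
#' @export
itc_protocol <- function(cell_volume_ul = 1430,
                         cell_conc_um = 50,
                         syringe_conc_um = 1200,
                         injection_volumes_ul = c(3, rep(6.5, 42)),
                         temperature_c = 25) {
  stopifnot(cell_volume_ul > 0, cell_conc_um > 0, syringe_conc_um > 0,
            all(injection_volumes_ul > 0))
  structure(
    list(cell_volume_ul = cell_volume_ul, cell_conc_um = cell_conc_um,
         syringe_conc_um = syringe_conc_um,
         injection_volumes_ul = injection_volumes_ul,
         temperature_c = temperature_c),
    class = "itc_protocol"
  )
}

#' Binding model with one or two independent site classes
#'
#' Each site class `j` has a stoichiometry `n_j` (sites per macromolecule), a
#' dissociation constant `K_D,j` and a molar binding enthalpy `dH_j`. The
#' two-site model treats the classes as thermodynamically independent; the
#' one-site model is its exact restriction with a single class.
#'
#' @param n Stoichiometries, one per site class (> 0).
#' @param kd_um Dissociation constants, micromolar (> 0).
#' @param dh_kcal Binding enthalpies, kcal/mol of sites.
#' @return A list of class `binding_model`.
#' @examples
#' binding_model(n = c(1, 1), kd_um = c(0.22, 3.5), dh_kcal = c(-15.4, -6.4))
#' @export
binding_model <- function(n, kd_um, dh_kcal) {
  stopifnot(length(n) == length(kd_um), length(n) == length(dh_kcal),
            length(n) %in% 1:2, all(n > 0), all(kd_um > 0),
            all(is.finite(dh_kcal)))
  structure(list(n = as.numeric(n), kd_um = as.numeric(kd_um),
                 dh_kcal = as.numeric(dh_kcal)),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("<binding_model> ", length(x$n), " site class(es)\n", sep = "")
  for (j in seq_along(x$n)) {
    cat(sprintf("  site %d: n = %.3f, K_D = %.4g uM, dH = %.4g kcal/mol\n",
                j, x$n[j], x$kd_um[j], x$dh_kcal[j]))
  }
  invisible(x)
}

#' @export
tidy.binding_model <- function(x, ...) {
  tibble::tibble(site = seq_along(x$n), n = x$n, kd_um = x$kd_um,
                 dh_kcal = x$dh_kcal)
}

#' Free titrant concentration by mass balance
#'
#' Solves `X_t = [X] + M_t * sum_j n_j [X] / (K_D,j + [X])` for the free
#' titrant concentration `[X]` by bracketed root-finding on `[0, X_t]`,
#' to a residual below `1e-10 * X_t`.
#'
#' @param x_total Total titrant concentration(s), micromolar.
#' @param m_total Total macromolecule concentration(s), micromolar.
#' @param model A [binding_model()].
#' @return Free titrant concentration(s), micromolar.
#' @export
free_ligand_conc <- function(x_total, m_total, model) {
  stopifnot(inherits(model, "binding_model"),
            all(x_total >= 0), all(m_total >= 0))
  m_total <- rep_len(m_total, length(x_total))
  vapply(seq_along(x_total), function(i) {
    xt <- x_total[i]; mt <- m_total[i]
    if (xt == 0) return(0)
    f <- function(x) xt - x - mt * sum(model$n * x / (model$kd_um + x))
    # f(0) = xt > 0, f(xt) <= 0: bracket guaranteed for valid inputs
    stopifnot(f(xt) <= 0)
    stats::uniroot(f, c(0, xt), tol = min(1e-12 * xt, 1e-12))$root
  }, numeric(1))
}

# cumulative heat content of the cell (kcal) for given totals (uM)
cell_heat_kcal <- function(x_total, m_total, model, v0_ul) {
  x_free <- free_ligand_conc(x_total, m_total, model)
  bound_terms <- vapply(seq_along(x_total), function(i) {
    sum(model$n * model$dh_kcal * x_free[i] / (model$kd_um + x_free[i]))
  }, numeric(1))
  # V0 [l] * Mt [mol/l] * sum(...) [kcal/mol] -> kcal
  (v0_ul * 1e-6) * (m_total * 1e-6) * bound_terms
}

# Totals in the cell after cumulative injected volume.
# "perfusion": standard overfilled-cell instrument convention, where each
# injection displaces an equal volume of mixed content out of the active
# volume. "exact": all content is retained and the working volume grows;
# under this convention total moles (and hence total heat) are conserved.
cell_totals <- function(protocol, cum_volume_ul,
                        dilution = c("perfusion", "exact")) {
  dilution <- match.arg(dilution)
  v0 <- protocol$cell_volume_ul
  f <- cum_volume_ul / v0
  if (dilution == "perfusion") {
    list(
      m_total = protocol$cell_conc_um * (1 - f / 2) / (1 + f / 2),
      x_total = protocol$syringe_conc_um * f / (1 + f / 2),
      volume_ul = rep(v0, length(f))
    )
  } else {
    list(
      m_total = protocol$cell_conc_um / (1 + f),
      x_total = protocol$syringe_conc_um * f / (1 + f),
      volume_ul = v0 * (1 + f)
    )
  }
}

#' Simulate a titration isotherm
#'
#' For each injection the cell totals are updated with the standard
#' displacement-dilution bookkeeping, the cumulative heat content
#' `Q_i = V0 * M_t * sum_j n_j dH_j [X] / (K_D,j + [X])` is evaluated, and the
#' differential heat is returned with the displaced-volume correction,
#' normalized per mole of injectant. Optional Gaussian noise (kcal/mol) is
#' seeded and leaves the global RNG untouched.
#'
#' @param model A [binding_model()].
#' @param protocol An [itc_protocol()].
#' @param noise_sd Gaussian noise on the normalized heats, kcal/mol.
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param dilution Dilution bookkeeping: `"perfusion"` (default; the
#'   overfilled-cell instrument convention with displaced-volume heat
#'   correction) or `"exact"` (growing working volume, total heat exactly
#'   conserved).
#' @return A tibble of class `itc_isotherm` with columns `injection`,
#'   `volume_ul`, `molar_ratio`, `ndh_kcal_per_mol`; the protocol is attached
#'   as attribute `"protocol"`.
#' @export
simulate_isotherm <- function(model, protocol = itc_protocol(),
                              noise_sd = 0, seed = 1L,
                              dilution = c("perfusion", "exact")) {
  stopifnot(inherits(model, "binding_model"),
            inherits(protocol, "itc_protocol"), noise_sd >= 0)
  dilution <- match.arg(dilution)
  dv <- protocol$injection_volumes_ul
  v0 <- protocol$cell_volume_ul
  cum <- cumsum(dv)
  tot <- cell_totals(protocol, cum, dilution)
  q <- cell_heat_kcal(tot$x_total, tot$m_total, model, tot$volume_ul)
  q_prev <- c(0, q[-length(q)])
  dq <- if (dilution == "perfusion") {
    # heat of injection i incl. heat carried out in the displaced volume
    q - q_prev + (dv / v0) * (q + q_prev) / 2
  } else {
    q - q_prev
  }
  injected_mol <- protocol$syringe_conc_um * 1e-6 * dv * 1e-6
  ndh <- dq / injected_mol
  if (noise_sd > 0) {
    ndh <- ndh + with_local_seed(seed, stats::rnorm(length(ndh), 0, noise_sd))
  }
  out <- tibble::tibble(
    injection = seq_along(dv),
    volume_ul = dv,
    molar_ratio = tot$x_total / tot$m_total,
    ndh_kcal_per_mol = ndh
  )
  attr(out, "protocol") <- protocol
  class(out) <- c("itc_isotherm", class(out))
  out
}

#' Read / write isotherm CSV
#'
#' Columns: `injection`, `volume_ul`, `ndh_kcal_per_mol` (a `molar_ratio`
#' column is recomputed from the protocol if absent).
#'
#' @param path CSV file path.
#' @param protocol An [itc_protocol()] describing the experiment.
#' @return An `itc_isotherm` tibble.
#' @export
read_isotherm <- function(path, protocol = itc_protocol()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("injection", "volume_ul", "ndh_kcal_per_mol") %in% names(df)))
  tot <- cell_totals(protocol, cumsum(df$volume_ul))
  df$molar_ratio <- tot$x_total / tot$m_total
  out <- tibble::as_tibble(df)
  attr(out, "protocol") <- protocol
  class(out) <- c("itc_isotherm", class(out))
  out
}

#' @rdname read_isotherm
#' @param isotherm An `itc_isotherm` tibble.
#' @export
write_isotherm <- function(isotherm, path) {
  readr::write_csv(
    tibble::tibble(injection = isotherm$injection,
                   volume_ul = isotherm$volume_ul,
                   ndh_kcal_per_mol = isotherm$ndh_kcal_per_mol),
    path)
  invisible(path)
}

#' Fit a binding model to an isotherm
#'
#' Least-squares fit of `(n_j, K_D,j, dH_j)` for one or two independent site
#' classes using the same heat model as [simulate_isotherm()]. Site classes in
#' a two-site fit are reported ordered by ascending `K_D`. The first
#' (pre-)injection is excluded by default. A warning is issued when a fitted
#' c-value (`M_t * n / K_D`) falls outside `[1, 1000]`, where `K_D` is weakly
#' determined.
#'
#' @param data An `itc_isotherm` (or data frame with `injection`, `volume_ul`,
#'   `ndh_kcal_per_mol`).
#' @param n_sites 1 or 2 site classes.
#' @param protocol Protocol; defaults to the one attached to `data`.
#' @param init Optional [binding_model()] with starting values.
#' @param fix_n Optional numeric vector: fix stoichiometries at these values.
#' @param exclude_first Drop the first injection from the fit (default TRUE).
#' @param dilution Dilution convention, as in [simulate_isotherm()].
#' @return A list of class `itc_fit` with elements `model` (fitted
#'   [binding_model()]), `se` (tibble of standard errors), `residual_rms`,
#'   `c_values`, `converged`, `flags`.
#' @export
fit_isotherm <- function(data, n_sites = 1, protocol = NULL, init = NULL,
                         fix_n = NULL, exclude_first = TRUE,
                         dilution = c("perfusion", "exact")) {
  stopifnot(n_sites %in% 1:2)
  dilution <- match.arg(dilution)
  protocol <- protocol %||% attr(data, "protocol")
  if (is.null(protocol)) {
    stop("no protocol supplied or attached to the isotherm", call. = FALSE)
  }
  dv <- data$volume_ul
  cum <- cumsum(dv)
  keep <- if (exclude_first) seq_along(dv)[-1] else seq_along(dv)
  y <- data$ndh_kcal_per_mol[keep]
  if (length(y) < 10) stop("at least 10 informative injections required",
                           call. = FALSE)
  if (all(abs(y) < 1e-8)) {
    stop("all heats are zero; nothing to fit", call. = FALSE)
  }

  predict_ndh <- function(model) {
    sim <- simulate_isotherm(model, protocol, noise_sd = 0,
                             dilution = dilution)
    sim$ndh_kcal_per_mol[keep]
  }

  init <- init %||% default_itc_init(y, n_sites, protocol)
  fixed_n <- !is.null(fix_n)
  if (fixed_n) stopifnot(length(fix_n) == n_sites)

  # parameter packing: per site (log kd, dh) and, unless fixed, log n
  pack <- function(m) {
    p <- c(rbind(log(m$kd_um), m$dh_kcal))
    if (!fixed_n) p <- c(p, log(m$n))
    p
  }
  unpack <- function(p) {
    kd <- exp(p[seq(1, 2 * n_sites, by = 2)])
    dh <- p[seq(2, 2 * n_sites, by = 2)]
    n <- if (fixed_n) fix_n else exp(p[(2 * n_sites + 1):(3 * n_sites)])
    binding_model(n = n, kd_um = kd, dh_kcal = dh)
  }
  resid_fun <- function(p) {
    m <- tryCatch(unpack(p), error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, length(y)))
    r <- y - predict_ndh(m)
    r[!is.finite(r)] <- 1e6
    r
  }
  nls_out <- minpack.lm::nls.lm(
    par = pack(init), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, maxfev = 10000,
                                         ftol = 1e-12, ptol = 1e-12)
  )
  # Levenberg-Marquardt termination codes 1-4 and 6-8 all indicate a
  # converged (possibly tolerance-limited) solution; 5 is maxiter, 0 invalid
  converged <- nls_out$info %in% c(1:4, 6:8)
  model <- unpack(nls_out$par)

  # order site classes by ascending K_D
  ord <- order(model$kd_um)
  model <- binding_model(model$n[ord], model$kd_um[ord], model$dh_kcal[ord])

  # delta-method standard errors on the natural scale
  se_tab <- itc_fit_se(nls_out, n_sites, fixed_n, ord, model)

  c_values <- protocol$cell_conc_um * model$n / model$kd_um
  flags <- character(0)
  if (!converged) flags <- c(flags, "non-convergence")
  if (any(c_values < 1 | c_values > 1000)) {
    flags <- c(flags, "c-value outside [1, 1000]: K_D weakly determined")
    warning("c-value outside [1, 1000]; K_D is weakly determined",
            call. = FALSE)
  }
  structure(
    list(model = model, se = se_tab,
         residual_rms = sqrt(mean(nls_out$fvec^2)),
         c_values = c_values, converged = converged, flags = flags,
         protocol = protocol, data = data, excluded_first = exclude_first,
         dilution = dilution),
    class = "itc_fit"
  )
}

# rough starting values: dH from early heats, K_D from c ~ 20, n = 1
default_itc_init <- function(y, n_sites, protocol) {
  dh0 <- stats::median(utils::head(y, 4))
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -5
  if (n_sites == 1) {
    binding_model(1, protocol$cell_conc_um / 20, dh0)
  } else {
    binding_model(c(1, 1),
                  c(protocol$cell_conc_um / 100, protocol$cell_conc_um / 10),
                  c(dh0 * 0.6, dh0 * 0.4))
  }
}

itc_fit_se <- function(nls_out, n_sites, fixed_n, ord, model) {
  se_raw <- tryCatch({
    dof <- length(nls_out$fvec) - length(nls_out$par)
    s2 <- sum(nls_out$fvec^2) / max(dof, 1)
    sqrt(diag(s2 * solve(nls_out$hessian)))
  }, error = function(e) rep(NA_real_, length(nls_out$par)))
  kd_se_log <- se_raw[seq(1, 2 * n_sites, by = 2)]
  dh_se <- se_raw[seq(2, 2 * n_sites, by = 2)]
  n_se_log <- if (fixed_n) rep(0, n_sites) else
    se_raw[(2 * n_sites + 1):(3 * n_sites)]
  # reorder raw (unsorted) SEs to the K_D-ascending site order, then map the
  # log-scale SEs for kd and n to the natural scale by the delta method
  tibble::tibble(
    site = seq_len(n_sites),
    n_se = n_se_log[ord] * model$n,
    kd_um_se = kd_se_log[ord] * model$kd_um,
    dh_kcal_se = dh_se[ord]
  )
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("<itc_fit> ", if (x$converged) "converged" else "NOT converged", "\n",
      sep = "")
  print(x$model)
  cat(sprintf("  residual rms: %.4g kcal/mol; c-values: %s\n",
              x$residual_rms, paste(signif(x$c_values, 3), collapse = ", ")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.itc_fit <- function(x, ...) {
  dplyr::bind_cols(tidy(x$model),
                   x$se[, c("kd_um_se", "dh_kcal_se"), drop = FALSE])
}

#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(n_sites = length(x$model$n),
                 residual_rms = x$residual_rms,
                 converged = x$converged,
                 n_flags = length(x$flags))
}

#' @export
autoplot.itc_fit <- function(object, ...) {
  d <- object$data
  pred <- simulate_isotherm(object$model, object$protocol, noise_sd = 0,
                            dilution = object$dilution)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$molar_ratio,
                                  y = .data$ndh_kcal_per_mol)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "grey40") +
    ggplot2::labs(x = "molar ratio (titrant / macromolecule)",
                  y = "kcal per mol of injectant") +
    ggplot2::theme_minimal()
}
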