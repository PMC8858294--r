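#' Configuration for the synthetic fixture generators
#'
#' Collects the study conditions emulated by the generators: 100 uM peptide
#' substrate titrated with 0-6 uM enzyme for the NMR activity assay, and the
#' calorimetry protocol (3 ul pre-injection + 42 x 6.5 ul of 1.2 mM peptide
#' into 50 uM protein). The exchange spectral parameters default to a minor
#' cis population of 0.25 (a plausible placeholder for an Xaa-Pro bond; the
#' true value for the substrate panel is not tabulated), a cis/trans shift
#' difference of 20 Hz and intrinsic relaxation of 8 s^-1.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param substrate_um Substrate concentration, micromolar (fixed, below K_M).
#' @param enzyme_um Enzyme concentrations, micromolar.
#' @param kcat_over_km True catalytic efficiency, micromolar^-1 s^-1.
#' @param k0 Baseline (uncatalysed) exchange rate, s^-1.
#' @param p_cis Cis population of the substrate.
#' @param nu_cis,nu_trans Cis/trans resonance positions of methyl I, Hz.
#' @param nu_ref Position of the non-exchanging reference methyl II, Hz.
#' @param r2 Intrinsic transverse relaxation rate of all lines, s^-1.
#' @param snr Signal-to-noise ratio (peak height over baseline noise SD) of
#'   the zero-enzyme spectrum.
#' @param n_replicates Technical replicates per enzyme concentration
#'   (default 3, as the activity assays are run in technical triplicates).
#' @param frequency_hz Frequency grid covering methyl I and methyl II, Hz.
#' @param itc_model [binding_model()] used by [generate_isotherm_data()];
#'   defaults to the two-site psWT panel values (K_D 0.22 and 3.5 uM, dH
#'   -15.4 and -6.4 kcal/mol).
#' @param itc_protocol [itc_protocol()] for the isotherm generator.
#' @param itc_noise_sd Gaussian noise on normalized heats, kcal/mol.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           substrate_um = 100,
                           enzyme_um = c(0, 1, 2, 4, 6),
                           kcat_over_km = 3,
                           k0 = 0.05,
                           p_cis = 0.25,
                           nu_cis = -10, nu_trans = 10,
                           nu_ref = 180,
                           r2 = 8,
                           snr = 100,
                           n_replicates = 3,
                           frequency_hz = seq(-120, 260, length.out = 2048),
                           itc_model = binding_model(c(1, 1), c(0.22, 3.5),
                                                     c(-15.4, -6.4)),
                           itc_protocol = prolylkin::itc_protocol(),
                           itc_noise_sd = 0.1) {
  stopifnot(substrate_um > 0, all(enzyme_um >= 0),
            length(enzyme_um) >= 3, kcat_over_km >= 0, k0 >= 0,
            p_cis > 0, p_cis < 1, r2 > 0, snr > 0, n_replicates >= 1,
            itc_noise_sd >= 0)
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a titration series of exchange-broadened spectra
#'
#' For each enzyme concentration the true exchange rate is
#' `k_ex = k0 + kcat_over_km * [E]`, and a spectrum containing the cis/trans
#' methyl-I doublet plus the non-exchanging methyl-II reference singlet is
#' simulated with seeded Gaussian noise at the configured signal-to-noise
#' ratio (`n_replicates` technical replicates per concentration). The
#' reference singlet carries the same integrated area as the exchanging
#' doublet, as for the two methyl groups of a single leucine. Identical
#' seeds give bit-identical fixtures.
#'
#' @param config A [fixture_config()].
#' @return A list with `spectra` (named list of `nmr_spectrum`, one per
#'   concentration and replicate), `truth` (tibble: `enzyme_um`, `replicate`,
#'   `k_ex_true`, `noise_sigma`) and `config`.
#' @export
generate_titration_spectra <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  nu <- config$frequency_hz
  shape_at <- function(k_ex) {
    pars <- exchange_params(config$p_cis, config$nu_cis, config$nu_trans,
                            config$r2, config$r2, k_ex)
    doublet <- two_site_shape(pars, nu)
    # unit-area Lorentzian: the non-exchanging methyl matches the doublet area
    singlet <- 2 * config$r2 /
      (config$r2^2 + (2 * pi * (nu - config$nu_ref))^2)
    doublet + singlet
  }
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      enzyme_um = config$enzyme_um)
  grid <- grid[order(grid$replicate, grid$enzyme_um), ]
  k_true <- config$k0 + config$kcat_over_km * grid$enzyme_um
  clean0 <- shape_at(config$k0)
  sigma <- max(clean0) / config$snr
  spectra <- with_local_seed(config$seed, {
    lapply(seq_along(k_true), function(i) {
      y <- shape_at(k_true[i]) + stats::rnorm(length(nu), 0, sigma)
      new_spectrum(nu, y, noise_sigma = sigma)
    })
  })
  names(spectra) <- sprintf("E_%g_uM_r%d", grid$enzyme_um, grid$replicate)
  list(
    spectra = spectra,
    truth = tibble::tibble(enzyme_um = grid$enzyme_um,
                           replicate = grid$replicate,
                           k_ex_true = k_true, noise_sigma = sigma),
    config = config
  )
}

#' Recover a titration series and catalytic efficiency from spectra
#'
#' The analysis pipeline applied to a set of titration spectra sharing one
#' frequency axis: the intrinsic linewidth is calibrated on the
#' non-exchanging reference singlet, the populations and positions of the
#' cis/trans doublet are fixed from the zero-enzyme spectrum, each spectrum
#' is fitted for its apparent exchange rate (with Monte-Carlo uncertainties),
#' and the catalytic efficiency is the weighted slope of rate versus enzyme
#' concentration.
#'
#' @param spectra Named list of `nmr_spectrum`, one per enzyme concentration
#'   and technical replicate.
#' @param enzyme_um Enzyme concentrations, micromolar, one per spectrum
#'   (repeated concentrations are replicate measurements; calibration uses
#'   all zero-enzyme entries).
#' @param doublet_window,reference_window Length-2 frequency windows (Hz)
#'   containing the exchanging doublet and the reference singlet.
#' @param mc_replicates Monte-Carlo replicates per spectrum (default 100;
#'   0 disables uncertainties and the slope fit is unweighted).
#' @param seed Seed for the Monte-Carlo resampling.
#' @return A list with `series` (tibble: `enzyme_um`, `k_app`, `k_app_sd`),
#'   `activity` (an `activity_fit`), `reference` (the doublet calibration)
#'   and `r2_intrinsic`.
#' @export
titration_pipeline <- function(spectra, enzyme_um,
                               doublet_window = c(-60, 60),
                               reference_window = c(140, 220),
                               mc_replicates = 100, seed = 1L) {
  stopifnot(length(spectra) == length(enzyme_um),
            any(enzyme_um == 0))
  zero <- which(enzyme_um == 0)
  # calibration from all enzyme-free spectra: average the fitted linewidth
  # and doublet parameters over replicates
  lws <- lapply(zero, function(i) {
    fit_intrinsic_linewidth(spectra[[i]], reference_window)
  })
  lw <- list(r2 = mean(vapply(lws, function(l) l$r2, numeric(1))))
  refs <- lapply(zero, function(i) {
    fit_reference_doublet(spectra[[i]], window = doublet_window)
  })
  ref <- list(
    p_cis = mean(vapply(refs, function(r) r$p_cis, numeric(1))),
    nu_cis = mean(vapply(refs, function(r) r$nu_cis, numeric(1))),
    nu_trans = mean(vapply(refs, function(r) r$nu_trans, numeric(1)))
  )
  fits <- lapply(seq_along(spectra), function(i) {
    f <- fit_apparent_exchange(spectra[[i]],
                               p_cis = ref$p_cis,
                               nu_cis = ref$nu_cis, nu_trans = ref$nu_trans,
                               r2_cis = lw$r2, r2_trans = lw$r2,
                               window = doublet_window)
    if (mc_replicates > 0) {
      f <- monte_carlo_uncertainty(f, spectra[[i]],
                                   n_replicates = mc_replicates,
                                   seed = seed + i)
    }
    f
  })
  series <- tibble::tibble(
    enzyme_um = enzyme_um,
    k_app = vapply(fits, function(f) f$k_app, numeric(1)),
    k_app_sd = vapply(fits, function(f) f$k_app_sd, numeric(1))
  )
  act <- fit_activity_slope(series, weighted = mc_replicates > 0)
  list(series = series, activity = act, reference = ref,
       r2_intrinsic = lw$r2, fits = fits)
}

#' Generate a synthetic calorimetry isotherm with known truth
#'
#' @param config A [fixture_config()]; uses its `itc_model`, `itc_protocol`,
#'   `itc_noise_sd` and `seed`.
#' @return A list with `isotherm` (an `itc_isotherm` tibble) and `truth`
#'   (tidy tibble of the generating model).
#' @export
generate_isotherm_data <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  iso <- simulate_isotherm(config$itc_model, config$itc_protocol,
                           noise_sd = config$itc_noise_sd,
                           seed = config$seed)
  list(isotherm = iso, truth = tidy(config$itc_model))
}

#' Generate toy two-domain structures with prescribed geometry
#'
#' Builds C-alpha-only models of a two-domain protein (chain A, residues
#' 1-150) with a bound 15-residue peptide (chain B). The PPIase-domain
#' scaffold is a fixed template shared by all models; the chaperone-domain
#' anchor residues are placed so that [interdomain_metrics()] returns exactly
#' the prescribed `(d, delta)` per model. The peptide's central positions
#' 5-11 are conformationally conserved (scatter `core_sd`) while the termini
#' are scattered with `term_sd`, emulating a binding mode in which only the
#' residues around the proline are positionally restrained.
#'
#' @param d,delta Prescribed inter-domain distances (Angstrom) and angles
#'   (degrees), one per model.
#' @param ids Model identifiers (default `toy_1`, ...).
#' @param core_sd,term_sd Peptide coordinate scatter (Angstrom) for the
#'   conserved core (positions 5-11) and the termini.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, each model is also written
#'   as a C-alpha-only PDB file.
#' @return A list with `models` (named list of `structure_model`), `truth`
#'   (tibble: `id`, `d`, `delta`) and `files` (paths or `NULL`).
#' @export
generate_toy_structures <- function(d = c(12, 16, 22, 30),
                                    delta = c(33, 42, 51, 65),
                                    ids = paste0("toy_", seq_along(d)),
                                    core_sd = 0.3, term_sd = 3,
                                    seed = 1L, out_dir = NULL) {
  stopifnot(length(d) == length(delta), all(d > 0),
            all(delta >= 0), all(delta <= 180),
            core_sd >= 0, term_sd >= 0)
  n_models <- length(d)
  # fixed protein template: a gentle helix for the scaffold residues
  scaffold_resno <- setdiff(1:150, c(95, 99))
  tmpl <- cbind(9 * cos(scaffold_resno / 4),
                9 * sin(scaffold_resno / 4),
                1.6 * scaffold_resno)
  # anchor residues of the metric definition get fixed template positions
  fix <- function(m, rn, xyz) { m[match(rn, scaffold_resno), ] <- xyz; m }
  tmpl <- fix(tmpl, 19, c(0, 0, 0))
  tmpl <- fix(tmpl, 145, c(10, 0, 0))
  tmpl <- fix(tmpl, 146, c(12, 0, 0))
  # peptide template: an extended strand near the domain interface
  pep_tmpl <- cbind(3 * (1:15) - 24, rep(6, 15), rep(4, 15))
  models <- with_local_seed(seed, {
    lapply(seq_len(n_models), function(m) {
      th <- delta[m] * pi / 180
      ca95 <- 20 * c(cos(th), sin(th), 0)
      ca99 <- c(12, 0, 0) + d[m] * c(cos(th), sin(th), 0)
      prot <- tibble::tibble(
        chain = "A",
        resno = c(scaffold_resno, 95L, 99L),
        x = c(tmpl[, 1], ca95[1], ca99[1]),
        y = c(tmpl[, 2], ca95[2], ca99[2]),
        z = c(tmpl[, 3], ca95[3], ca99[3])
      )
      sds <- ifelse(1:15 %in% 5:11, core_sd, term_sd)
      pep <- tibble::tibble(
        chain = "B",
        resno = 1:15,
        x = pep_tmpl[, 1] + stats::rnorm(15, 0, sds),
        y = pep_tmpl[, 2] + stats::rnorm(15, 0, sds),
        z = pep_tmpl[, 3] + stats::rnorm(15, 0, sds)
      )
      out <- dplyr::bind_rows(prot, pep)
      out <- out[order(out$chain, out$resno), ]
      as_structure_model(out, id = ids[m])
    })
  })
  names(models) <- ids
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- vapply(seq_len(n_models), function(m) {
      path <- file.path(out_dir, paste0(ids[m], ".pdb"))
      write_ca_pdb(models[[m]], path)
      path
    }, character(1))
  }
  list(models = models,
       truth = tibble::tibble(id = ids, d = d, delta = delta),
       files = files)
}

#' Write a C-alpha model as a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(model, path) {
  xyz <- as.vector(t(coords_matrix(model)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = model$resno, chain = model$chain,
                   resid = model$resid %||% rep("ALA", nrow(model)),
                   elety = rep("CA", nrow(model)))
  invisible(path)
}
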