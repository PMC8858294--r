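#' Thermodynamic and activity table for the SlyD substrate-variant panel
#'
#' Loads the packaged table of per-variant binding and activity constants for
#' the 15-residue S2-derived peptide panel (psWT and its point mutants):
#' ITC-derived dissociation constants and binding enthalpies of the
#' chaperone (IF) and PPIase (FKBP) sites of full-length SlyD, the single
#' FKBP site of the SlyDdeltaIF construct, and the NMR-derived catalytic
#' efficiencies (kcat/KM, micromolar^-1 s^-1) of both constructs. Entries not
#' determined experimentally are `NA` and drop the corresponding pair from
#' any analysis.
#'
#' @return A tibble with one row per peptide variant; value columns
#'   `kd_if_um`, `dh_if_kcal`, `kd_fkbp_um`, `dh_fkbp_kcal`, `act_wt`,
#'   `kd_dif_um`, `dh_dif_kcal`, `act_dif` plus matching `*_se` columns and
#'   the derived `dh_sum_kcal = dh_if_kcal + dh_fkbp_kcal`.
#' @examples
#' tab <- slyd_variant_table()
#' correlate_robust(tab, "kd_fkbp_um", "kd_dif_um", labels = "variant")
#' @export
slyd_variant_table <- function() {
  path <- system.file("extdata", "slyd_variant_panel.csv", package = "prolylkin",
                      mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tab$dh_sum_kcal <- tab$dh_if_kcal + tab$dh_fkbp_kcal
  tab
}

#' Standard robust-correlation analyses of the variant panel
#'
#' Runs the three headline comparisons on [slyd_variant_table()]:
#' full-length FKBP-site affinity vs truncated-construct affinity
#' (`kd_wt_vs_dif`), truncated-construct affinity vs its activity
#' (`kd_dif_vs_act`), and the summed binding enthalpy of both full-length
#' sites vs full-length activity (`dh_sum_vs_act_wt`). The affinity
#' comparisons use bagplot outlier exclusion on standardized coordinates;
#' the enthalpy comparison uses all complete pairs.
#'
#' @param table The variant table (default [slyd_variant_table()]).
#' @return Named list of [correlate_robust()] results.
#' @export
slyd_panel_correlations <- function(table = slyd_variant_table()) {
  list(
    kd_wt_vs_dif = correlate_robust(table, "kd_fkbp_um", "kd_dif_um",
                                    labels = "variant"),
    kd_dif_vs_act = correlate_robust(table, "kd_dif_um", "act_dif",
                                     labels = "variant"),
    dh_sum_vs_act_wt = correlate_robust(table, "dh_sum_kcal", "act_wt",
                                        labels = "variant", bagplot = FALSE)
  )
}
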