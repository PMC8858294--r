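#' SlyD domain residue selections
#'
#' Author-numbering residue ranges of the SlyD domains: the FKBP (PPIase)
#' domain (residues 1-66 + 125-150), the IF (insert-in-flap) chaperone domain
#' (residues 70-117) and the core FKBP selection used for cross-construct
#' RMSD comparisons (residues 1-57 + 126-150).
#'
#' @return Named list of integer residue-number vectors:
#'   `fkbp`, `if_domain`, `fkbp_core`.
#' @export
slyd_domains <- function() {
  list(
    fkbp = c(1:66, 125:150),
    if_domain = 70:117,
    fkbp_core = c(1:57, 126:150)
  )
}

#' Load C-alpha coordinates from a PDB or mmCIF file
#'
#' Parses the file with bio3d, keeps C-alpha atoms, resolves alternate
#' locations by highest occupancy, and returns a coordinate table. Missing
#' residues are simply absent from the table, never fabricated.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param chain Optional chain identifier(s) to keep; by default all chains
#'   are kept. An error is raised when a requested chain is absent.
#' @return A tibble of class `structure_model` with columns `chain`, `resno`,
#'   `insert`, `resid`, `x`, `y`, `z` and attribute `id` (file stem).
#' @export
read_ca_coords <- function(path, chain = NULL) {
  ext <- tolower(tools::file_ext(path))
  # keep all altloc records; the highest-occupancy one is selected below
  pdb <- if (ext == "cif") bio3d::read.cif(path) else
    bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$elety == "CA" & !is.na(at$x), , drop = FALSE]
  if (!is.null(chain)) {
    missing <- setdiff(chain, unique(at$chain))
    if (length(missing) > 0) {
      stop("chain(s) not present in ", basename(path), ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    at <- at[at$chain %in% chain, , drop = FALSE]
  }
  at$insert[is.na(at$insert)] <- ""
  # altlocs: keep the highest-occupancy record per (chain, resno, insert)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert)
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert)), , drop = FALSE]
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  out <- tibble::tibble(
    chain = at$chain, resno = as.integer(at$resno), insert = at$insert,
    resid = at$resid, x = at$x, y = at$y, z = at$z
  )
  attr(out, "id") <- sub("\\.(pdb|cif)$", "", basename(path),
                         ignore.case = TRUE)
  class(out) <- c("structure_model", class(out))
  out
}

as_structure_model <- function(df, id = "model") {
  out <- tibble::as_tibble(df)
  if (!"insert" %in% names(out)) out$insert <- ""
  if (!"resid" %in% names(out)) out$resid <- "ALA"
  stopifnot(all(c("chain", "resno", "x", "y", "z") %in% names(out)))
  stopifnot(!anyDuplicated(paste(out$chain, out$resno, out$insert)),
            all(is.finite(out$x)), all(is.finite(out$y)), all(is.finite(out$z)))
  attr(out, "id") <- id
  if (!inherits(out, "structure_model")) {
    class(out) <- c("structure_model", class(out))
  }
  out
}

coords_matrix <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

# rows of `model` matching a residue-number selection within a chain
select_residues <- function(model, resno, chain = NULL) {
  chain <- chain %||% model$chain[1]
  sel <- model$chain == chain & model$resno %in% resno
  model[sel, , drop = FALSE]
}

#' Kabsch superposition of two coordinate sets
#'
#' Finds the least-squares optimal rigid transform (proper rotation,
#' `det(R) = +1`, plus translation) aligning the mobile structure onto the
#' target over a residue selection, matching residues by `(resno, insert)`
#' within the chosen chain. The whole mobile model is transformed.
#'
#' @param mobile,target `structure_model` tibbles.
#' @param selection Integer residue numbers used for the superposition;
#'   default all residues common to both.
#' @param mobile_chain,target_chain Chains to match (default: each model's
#'   first chain).
#' @return A list of class `superposition` with elements `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (over the selection, Angstrom),
#'   `n_atoms`, and `mobile_transformed` (the full transformed mobile model).
#' @export
kabsch_superpose <- function(mobile, target, selection = NULL,
                             mobile_chain = NULL, target_chain = NULL) {
  mobile_chain <- mobile_chain %||% mobile$chain[1]
  target_chain <- target_chain %||% target$chain[1]
  m_sub <- mobile[mobile$chain == mobile_chain, , drop = FALSE]
  t_sub <- target[target$chain == target_chain, , drop = FALSE]
  if (!is.null(selection)) {
    m_sub <- m_sub[m_sub$resno %in% selection, , drop = FALSE]
    t_sub <- t_sub[t_sub$resno %in% selection, , drop = FALSE]
  }
  key_m <- paste(m_sub$resno, m_sub$insert)
  key_t <- paste(t_sub$resno, t_sub$insert)
  common <- intersect(key_m, key_t)
  if (length(common) < 3) {
    stop("fewer than 3 common C-alpha atoms in the selection", call. = FALSE)
  }
  P <- coords_matrix(m_sub[match(common, key_m), ])
  Q <- coords_matrix(t_sub[match(common, key_t), ])
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  rmsd <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  all_xyz <- coords_matrix(mobile)
  new_xyz <- sweep(sweep(all_xyz, 2, cp) %*% R, 2, cq, FUN = "+")
  moved <- mobile
  moved$x <- new_xyz[, 1]; moved$y <- new_xyz[, 2]; moved$z <- new_xyz[, 3]
  structure(
    list(rotation = R, translation = as.numeric(cq - cp %*% R),
         rmsd = rmsd, n_atoms = length(common),
         mobile_transformed = moved),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.4f A over %d C-alpha\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Core C-alpha RMSD between two structures
#'
#' Superposes structure `a` onto structure `b` over the core selection and
#' returns the C-alpha RMSD over that selection. The default core is the FKBP
#' core (residues 1-57 + 126-150) used to compare the PPIase fold across
#' constructs with and without the chaperone domain.
#'
#' @param a,b `structure_model` tibbles.
#' @param core Integer residue numbers of the core selection.
#' @param ... Passed to [kabsch_superpose()] (chain choices).
#' @return RMSD in Angstrom.
#' @export
core_rmsd <- function(a, b, core = slyd_domains()$fkbp_core, ...) {
  kabsch_superpose(a, b, selection = core, ...)$rmsd
}

#' Per-residue C-alpha RMSD of bound peptides across structures
#'
#' All models are first superposed onto the first model by the protein-chain
#' alignment selection (by default the FKBP domain), then for every substrate
#' position the C-alpha distances over all unordered model pairs are
#' collected. Positions missing in a model are skipped for that pair;
#' positions resolved in fewer than two models are reported as `NA`, not 0.
#'
#' @param models Named list of `structure_model` tibbles.
#' @param positions Substrate residue positions (default 1:15).
#' @param peptide_chain,protein_chain Chain IDs of the peptide and protein
#'   in every model.
#' @param align_selection Protein residues used for superposition.
#' @return A tibble with columns `position`, `mean_rmsd`, `sd_rmsd`,
#'   `n_pairs`, and a list-column `pair_distances`.
#' @export
per_residue_peptide_rmsd <- function(models, positions = 1:15,
                                     peptide_chain = "B",
                                     protein_chain = "A",
                                     align_selection = slyd_domains()$fkbp) {
  stopifnot(length(models) >= 2)
  ref <- models[[1]]
  aligned <- lapply(models, function(m) {
    if (identical(m, ref)) return(m)
    kabsch_superpose(m, ref, selection = align_selection,
                     mobile_chain = protein_chain,
                     target_chain = protein_chain)$mobile_transformed
  })
  pep <- lapply(aligned, function(m) select_residues(m, positions,
                                                     chain = peptide_chain))
  pairs <- utils::combn(length(models), 2, simplify = FALSE)
  purrr::map_dfr(positions, function(pos) {
    dists <- purrr::map_dbl(pairs, function(pr) {
      a <- pep[[pr[1]]]; b <- pep[[pr[2]]]
      ia <- match(pos, a$resno); ib <- match(pos, b$resno)
      if (is.na(ia) || is.na(ib)) return(NA_real_)
      sqrt(sum((c(a$x[ia], a$y[ia], a$z[ia]) -
                  c(b$x[ib], b$y[ib], b$z[ib]))^2))
    })
    dists <- dists[!is.na(dists)]
    tibble::tibble(
      position = pos,
      mean_rmsd = if (length(dists) >= 1) mean(dists) else NA_real_,
      sd_rmsd = if (length(dists) >= 2) stats::sd(dists) else NA_real_,
      n_pairs = length(dists),
      pair_distances = list(dists)
    )
  })
}

#' Inter-domain distance and angle of a SlyD model
#'
#' Computes the two scalar coordinates summarizing the relative position of
#' the chaperone (IF) and PPIase (FKBP) domains: the distance `d` between the
#' C-alpha atoms of residues 99 (IF domain) and 146 (FKBP domain), and the
#' angle `delta` at the residue-19 C-alpha subtended by the C-alpha atoms of
#' residues 145 and 95, in degrees.
#'
#' @param model A `structure_model`.
#' @param chain Protein chain (default: first chain).
#' @return A one-row tibble with columns `id`, `d`, `delta`.
#' @export
interdomain_metrics <- function(model, chain = NULL) {
  chain <- chain %||% model$chain[1]
  need <- c(19, 95, 99, 145, 146)
  sub <- select_residues(model, need, chain = chain)
  missing <- setdiff(need, sub$resno)
  if (length(missing) > 0) {
    stop("residue(s) required for inter-domain metrics missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- function(rn) {
    i <- match(rn, sub$resno)
    c(sub$x[i], sub$y[i], sub$z[i])
  }
  d <- sqrt(sum((p(99) - p(146))^2))
  v1 <- p(145) - p(19)
  v2 <- p(95) - p(19)
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  delta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  tibble::tibble(id = attr(model, "id") %||% "model", d = d, delta = delta)
}

#' Reference (d, delta) table for conformational classification
#'
#' Loads the packaged reference table of labelled inter-domain coordinates
#' used by [classify_conformation()]. The packaged values are a synthetic
#' stand-in (see the file name): representative centroids chosen to reproduce
#' the qualitative closed < tight < loose < open ordering of the inter-domain
#' distance, not values measured on deposited structures. Users comparing
#' real deposited entries should build their own reference table with
#' [interdomain_metrics()] and pass it in.
#'
#' @return A tibble with columns `id`, `state`, `d`, `delta`.
#' @export
conformation_references <- function() {
  path <- system.file("extdata", "synthetic_conformation_references.csv",
                      package = "prolylkin", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Classify a SlyD conformation from inter-domain metrics
#'
#' Nearest-centroid classification in standardized `(d, delta)` space.
#' Reference points are standardized (z-scored using the reference mean and
#' SD per coordinate), centroids are the per-state means, and a query further
#' than `cutoff` standardized units from every centroid is labelled
#' `"intermediate"` (as for structures with a partially occupied chaperone
#' site that sit between the loose and tight groups).
#'
#' @param metrics A data frame with columns `d` and `delta` (one or more
#'   rows), e.g. from [interdomain_metrics()].
#' @param references Labelled reference table with columns `state`, `d`,
#'   `delta` (default [conformation_references()]).
#' @param cutoff Standardized distance beyond which the label is
#'   `"intermediate"` (default 2).
#' @return `metrics` with added columns `state` and `centroid_distance`.
#' @export
classify_conformation <- function(metrics,
                                  references = conformation_references(),
                                  cutoff = 2) {
  stopifnot(nrow(references) > 0,
            all(c("state", "d", "delta") %in% names(references)))
  mu <- c(d = mean(references$d), delta = mean(references$delta))
  sg <- c(d = stats::sd(references$d), delta = stats::sd(references$delta))
  sg[sg == 0 | is.na(sg)] <- 1
  zref <- cbind((references$d - mu["d"]) / sg["d"],
                (references$delta - mu["delta"]) / sg["delta"])
  centroids <- rowsum(zref, references$state) /
    as.vector(table(references$state)[sort(unique(references$state))])
  zq <- cbind((metrics$d - mu["d"]) / sg["d"],
              (metrics$delta - mu["delta"]) / sg["delta"])
  res <- purrr::map_dfr(seq_len(nrow(zq)), function(i) {
    dd <- sqrt(rowSums(sweep(centroids, 2, zq[i, ])^2))
    j <- which.min(dd)
    tibble::tibble(
      state = if (dd[j] > cutoff) "intermediate" else rownames(centroids)[j],
      centroid_distance = unname(dd[j])
    )
  })
  dplyr::bind_cols(tibble::as_tibble(metrics), res)
}

#' Inter-domain metrics and classification for a set of models
#'
#' @param models Named list of `structure_model` tibbles, or a character
#'   vector of file paths (read with [read_ca_coords()]).
#' @param ... Passed to [classify_conformation()].
#' @return A tibble with one row per model: `id`, `d`, `delta`, `state`,
#'   `centroid_distance`.
#' @export
conformation_table <- function(models, ...) {
  if (is.character(models)) {
    models <- stats::setNames(lapply(models, read_ca_coords),
                              sub("\\.(pdb|cif)$", "", basename(models)))
  }
  purrr::map_dfr(models, interdomain_metrics) |>
    classify_conformation(...)
}
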