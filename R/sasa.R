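# Shrake-Rupley solvent-accessible surface area.
#
# Surface and occluding atoms are heavy atoms only; hydrogens never contribute,
# so results are identical for inputs with or without explicit hydrogens.

#' Default van der Waals radii (Bondi)
#'
#' C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Angstrom; unknown elements fall back
#' to `default`. Hydrogens are excluded from SASA altogether.
#'
#' @param overrides Named numeric vector of per-element radii to override.
#' @param default Radius for elements not in the table.
#' @return A list of class `radii_table` with elements `radii` and `default`.
#' @export
default_radii <- function(overrides = NULL, default = 1.70) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  if (!is.null(overrides)) radii[names(overrides)] <- as.numeric(overrides)
  if (any(radii <= 0.5) || any(radii >= 3.0) || default <= 0.5 || default >= 3.0) {
    abort("van der Waals radii must lie in (0.5, 3.0) Angstrom")
  }
  structure(list(radii = radii, default = default), class = "radii_table")
}

atom_radii <- function(elements, radii) {
  r <- radii$radii[elements]
  r[is.na(r)] <- radii$default
  unname(r)
}

#' Near-uniform points on the unit sphere (golden spiral)
#'
#' Deterministic golden-spiral lattice used as the Shrake-Rupley test-point
#' set.
#'
#' @param n Number of points, at least 12.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  if (n < 12) abort("sphere_points: need at least 12 points")
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (i - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Shrake-Rupley per-atom solvent-accessible surface area
#'
#' For each heavy atom a lattice of `n_points` is placed on its expanded
#' sphere of radius `r_atom + probe`; the SASA is the exposed-point fraction
#' times the expanded-sphere area. A point is exposed if it lies outside every
#' neighbouring expanded sphere; neighbours are occluding atoms within
#' `r_i + r_j + 2 * probe`. Exactly coincident atoms are counted once (the
#' later atom in order is treated as fully buried).
#'
#' @param frame A `cv_frame`.
#' @param radii A `radii_table` (see [default_radii()]).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Lattice points per atom.
#' @param atom_subset Indices of atoms whose SASA is wanted (default: all
#'   heavy atoms). Hydrogens in the subset are ignored.
#' @param occluders Indices of atoms that occlude (default: all heavy atoms
#'   of the frame). Hydrogens never occlude.
#' @return Numeric vector of length `n_atoms(frame)`: SASA in square Angstrom
#'   for computed atoms, `NA` elsewhere. Attributes `probe` and `n_points`
#'   record the parameters.
#' @export
shrake_rupley <- function(frame, radii = default_radii(), probe = 1.4,
                          n_points = 960, atom_subset = NULL, occluders = NULL) {
  stopifnot(inherits(frame, "cv_frame"))
  heavy <- which(frame$atoms$element != "H")
  if (is.null(occluders)) occluders <- heavy else
    occluders <- intersect(occluders, heavy)
  if (is.null(atom_subset)) atom_subset <- heavy else
    atom_subset <- intersect(atom_subset, heavy)
  if (length(atom_subset) == 0) abort("shrake_rupley: empty atom subset")

  S <- sphere_points(n_points)
  xyz <- frame$xyz
  r_all <- atom_radii(frame$atoms$element, radii)
  out <- rep(NA_real_, nrow(xyz))
  occ_xyz <- xyz[occluders, , drop = FALSE]
  occ_r <- r_all[occluders]

  for (i in atom_subset) {
    Ri <- r_all[i] + probe
    d2 <- (occ_xyz[, 1] - xyz[i, 1])^2 + (occ_xyz[, 2] - xyz[i, 2])^2 +
      (occ_xyz[, 3] - xyz[i, 3])^2
    cut2 <- (occ_r + r_all[i] + 2 * probe)^2
    nb <- which(d2 < cut2 & occluders != i)
    # coincident-atom rule: the earlier atom keeps the area
    co <- nb[d2[nb] < 1e-12]
    if (any(occluders[co] < i)) { out[i] <- 0; next }
    nb <- nb[d2[nb] >= 1e-12]
    P <- S * Ri
    P[, 1] <- P[, 1] + xyz[i, 1]
    P[, 2] <- P[, 2] + xyz[i, 2]
    P[, 3] <- P[, 3] + xyz[i, 3]
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      Rj2 <- (occ_r[j] + probe)^2
      dd <- (P[, 1] - occ_xyz[j, 1])^2 + (P[, 2] - occ_xyz[j, 2])^2 +
        (P[, 3] - occ_xyz[j, 3])^2
      exposed <- exposed & (dd >= Rj2)
      if (!any(exposed)) break
    }
    out[i] <- sum(exposed) / n_points * 4 * pi * Ri^2
  }
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  out
}

#' Total SASA of a configured residue set
#'
#' Sums per-atom Shrake-Rupley areas over the atoms of a residue set, either
#' whole residues or side chains only. Occluders are the heavy atoms of the
#' chosen context: `"monomer"` uses all atoms (protein and HETATM) of the
#' chains spanned by the set, so a dimer partner on another chain does not
#' occlude; `"full_frame"` uses every heavy atom.
#'
#' @param frame A `cv_frame`.
#' @param residue_set Tibble/data frame with columns `chain` and `resno`.
#' @param mode `"whole_residue"` or `"sidechain"`.
#' @param context `"monomer"` or `"full_frame"`.
#' @inheritParams shrake_rupley
#' @return Total area in square Angstrom.
#' @export
residue_set_sasa <- function(frame, residue_set,
                             mode = c("whole_residue", "sidechain"),
                             context = c("monomer", "full_frame"),
                             radii = default_radii(), probe = 1.4,
                             n_points = 960) {
  mode <- match.arg(mode)
  context <- match.arg(context)
  residue_set <- tibble::as_tibble(residue_set)
  a <- frame$atoms
  present <- paste(a$chain, a$resno)
  wanted <- paste(residue_set$chain, residue_set$resno)
  missing_res <- setdiff(wanted, present)
  if (length(missing_res) > 0) {
    abort(paste0("residue(s) absent from frame: ",
                 paste(missing_res, collapse = ", ")))
  }
  in_set <- present %in% wanted
  cls <- if (mode == "sidechain") "SIDECHAIN" else "HEAVY"
  sel_idx <- resolve_selection(frame, selection(class = cls), quiet = TRUE)
  set_idx <- intersect(which(in_set), sel_idx)
  occ <- if (context == "monomer") {
    which(a$chain %in% unique(residue_set$chain) & a$element != "H")
  } else {
    which(a$element != "H")
  }
  per_atom <- shrake_rupley(frame, radii = radii, probe = probe,
                            n_points = n_points, atom_subset = set_idx,
                            occluders = occ)
  sum(per_atom[set_idx])
}

#' Per-frame residue-set SASA series
#'
#' @param traj A `cv_trajectory`.
#' @inheritParams residue_set_sasa
#' @return Tibble with columns `frame` and `value` (square Angstrom).
#' @export
sasa_series <- function(traj, residue_set,
                        mode = c("whole_residue", "sidechain"),
                        context = c("monomer", "full_frame"),
                        radii = default_radii(), probe = 1.4, n_points = 960) {
  mode <- match.arg(mode)
  context <- match.arg(context)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    residue_set_sasa(get_frame(traj, k), residue_set, mode = mode,
                     context = context, radii = radii, probe = probe,
                     n_points = n_points)
  }, numeric(1))
  metric_series(vals, metric = "sasa", units = "A^2")
}
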