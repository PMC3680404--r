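# Scaffold-bundle collective variables, gate distances, ion displacement and
# ligand contact occupancy.

#' Terminal residues of a helix
#'
#' Returns the k-th residues from a helix end, counting the terminal residue
#' as k = 1. The default offsets `c(3, 4)` select the third and fourth
#' residues from the end, avoiding helix-terminal unwinding artefacts.
#'
#' @param helix One-row tibble/list with `first` and `last` residue numbers.
#' @param end `"N_terminal"` or `"C_terminal"`.
#' @param offsets Integer offsets (k values).
#' @return Integer vector of residue numbers.
#' @export
terminal_residues <- function(helix, end = c("N_terminal", "C_terminal"),
                              offsets = c(3L, 4L)) {
  end <- match.arg(end)
  first <- as.integer(helix$first); last <- as.integer(helix$last)
  if ((last - first + 1L) < max(offsets)) {
    abort(paste0("helix ", first, "-", last, " shorter than max offset ",
                 max(offsets)))
  }
  if (end == "C_terminal") last - (as.integer(offsets) - 1L)
  else first + (as.integer(offsets) - 1L)
}

# C-alpha indices of a group's terminal residues (all members pooled).
group_ca_indices <- function(frame, topo, side, body) {
  g <- tibble::as_tibble(topo$groups[[side]][[body]])
  idx <- integer(0)
  for (i in seq_len(nrow(g))) {
    h <- topo$helices[topo$helices$tm == g$tm[i], , drop = FALSE]
    if (nrow(h) != 1) abort(paste0("helix ", g$tm[i], " not defined exactly once"))
    resnos <- terminal_residues(h, g$end[i], topo$offsets)
    ii <- resolve_selection(frame, selection(chain = h$chain, resno = resnos,
                                             class = "CA_ONLY"), quiet = TRUE)
    if (length(ii) != length(resnos)) {
      abort(paste0("missing C-alpha for residue(s) ",
                   paste(setdiff(resnos, frame$atoms$resno[ii]), collapse = ", "),
                   " of ", g$tm[i]))
    }
    idx <- c(idx, ii)
  }
  idx
}

#' Scaffold-bundle centre-of-mass distance
#'
#' The collective variable of the alternating-access transition: the distance
#' between the centre of mass of the C-alpha atoms of the scaffold group's
#' helix-terminal residues and that of the bundle group, on the chosen
#' membrane face. Internal to the frame, hence invariant under global rigid
#' motion.
#'
#' @param frame A `cv_frame`.
#' @param topo A `cv_topology` with scaffold/bundle groups.
#' @param side `"extracellular"` or `"intracellular"`.
#' @return Distance in Angstrom.
#' @export
scaffold_bundle_distance <- function(frame, topo,
                                     side = c("extracellular", "intracellular")) {
  side <- match.arg(side)
  if (is.null(topo$groups[[side]])) {
    abort(paste0("topology defines no ", side, " groups"))
  }
  com_s <- center_of_mass(frame, group_ca_indices(frame, topo, side, "scaffold"))
  com_b <- center_of_mass(frame, group_ca_indices(frame, topo, side, "bundle"))
  sqrt(sum((com_s - com_b)^2))
}

#' Per-frame scaffold-bundle distance series
#'
#' @param traj A `cv_trajectory`.
#' @inheritParams scaffold_bundle_distance
#' @return Tibble with columns `frame` and `value` (Angstrom).
#' @export
scaffold_bundle_series <- function(traj, topo,
                                   side = c("extracellular", "intracellular")) {
  side <- match.arg(side)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    scaffold_bundle_distance(get_frame(traj, k), topo, side)
  }, numeric(1))
  metric_series(vals, metric = paste0(side, "_scaffold_bundle"), units = "A")
}

#' Gate distance in one frame
#' @param frame A `cv_frame`.
#' @param g A `cv_gate`.
#' @return Minimum distance between the gate's atom sets (Angstrom).
#' @export
gate_distance <- function(frame, g) {
  stopifnot(inherits(g, "cv_gate"))
  ia <- resolve_selection(frame, g$selA, quiet = TRUE)
  ib <- resolve_selection(frame, g$selB, quiet = TRUE)
  if (length(ia) == 0 || length(ib) == 0) {
    abort(paste0("gate '", g$label, "': unresolvable atoms"))
  }
  min_pair_distance(frame, ia, ib)
}

#' Per-frame gate-distance series
#' @param traj A `cv_trajectory`.
#' @param g A `cv_gate`.
#' @return Tibble with columns `frame` and `value` (Angstrom).
#' @export
gate_distance_series <- function(traj, g) {
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    gate_distance(get_frame(traj, k), g)
  }, numeric(1))
  metric_series(vals, metric = g$label, units = "A")
}

#' Fraction of frames inside a distance band
#'
#' The 2.5-4.0 Angstrom default brackets hydrogen bonds and salt bridges, the
#' band conventionally highlighted on gate-distance traces.
#'
#' @param series Numeric vector, or a metric tibble with a `value` column.
#' @param low,high Band edges in Angstrom (`low <= high`).
#' @return Fraction in `[0, 1]`.
#' @export
in_band_fraction <- function(series, low = 2.5, high = 4.0) {
  if (low > high) abort("in_band_fraction: low > high")
  x <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (length(x) == 0) abort("in_band_fraction: empty series")
  mean(x >= low & x <= high)
}

#' Ion displacement along the membrane normal
#'
#' Each frame is superposed onto the first frame using `align_sel` (protein
#' C-alpha atoms), and the ion's z displacement from its initial position is
#' reported, multiplied by the membrane-normal sign so that negative values
#' always mean movement towards the intracellular side.
#'
#' @param traj A `cv_trajectory`.
#' @param ion_sel Selection resolving to exactly one atom.
#' @param align_sel Selection used for the superposition.
#' @param membrane_normal `+1` if +z points extracellular.
#' @return Tibble with columns `frame` and `value` (Angstrom).
#' @export
ion_z_displacement <- function(traj, ion_sel, align_sel, membrane_normal = 1) {
  f1 <- get_frame(traj, 1)
  ion <- resolve_selection(f1, ion_sel, quiet = TRUE)
  if (length(ion) != 1) {
    abort(paste0("ion selection resolves to ", length(ion),
                 " atoms (need exactly 1)"))
  }
  ai <- resolve_selection(f1, align_sel, quiet = TRUE)
  if (length(ai) == 0) abort("ion_z_displacement: empty alignment selection")
  ref <- f1$xyz[ai, , drop = FALSE]
  z0 <- f1$xyz[ion, 3]
  s <- sign(membrane_normal)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- traj$coords[, , k, drop = TRUE]
    tf <- kabsch_superpose(xyz[ai, , drop = FALSE], ref)
    zi <- apply_transform(tf, xyz[ion, , drop = FALSE])[1, 3]
    s * (zi - z0)
  }, numeric(1))
  metric_series(vals, metric = "ion_dz", units = "A")
}

#' Ligand contact occupancy per partner residue
#'
#' For each partner residue, the fraction of frames in which the minimum
#' heavy-atom distance between the ligand and the residue is within `cutoff`.
#' Occupancies at or above `stable_threshold` are flagged as stable
#' interactions.
#'
#' @param traj A `cv_trajectory`.
#' @param ligand_sel Non-empty selection of ligand atoms.
#' @param partners Tibble/data frame with columns `chain` and `resno`.
#' @param cutoff Polar-contact cutoff in Angstrom.
#' @param stable_threshold Occupancy above which a contact counts as stable.
#' @return Tibble with columns `chain`, `resno`, `occupancy`, `stable`.
#' @export
contact_occupancy <- function(traj, ligand_sel, partners, cutoff = 3.5,
                              stable_threshold = 0.7) {
  partners <- tibble::as_tibble(partners)
  if (nrow(partners) == 0) abort("contact_occupancy: empty partner set")
  f1 <- get_frame(traj, 1)
  lig <- resolve_selection(f1, ligand_sel, quiet = TRUE)
  lig <- lig[f1$atoms$element[lig] != "H"]
  if (length(lig) == 0) abort("contact_occupancy: empty ligand selection")
  a <- f1$atoms
  res_idx <- lapply(seq_len(nrow(partners)), function(i) {
    ii <- which(a$chain == partners$chain[i] & a$resno == partners$resno[i] &
                  a$element != "H")
    ii <- setdiff(ii, lig)
    if (length(ii) == 0) {
      abort(paste0("partner residue ", partners$chain[i], " ",
                   partners$resno[i], " has no heavy atoms"))
    }
    ii
  })
  nf <- n_frames(traj)
  hits <- matrix(FALSE, nrow = nrow(partners), ncol = nf)
  for (k in seq_len(nf)) {
    fr <- get_frame(traj, k)
    for (i in seq_along(res_idx)) {
      hits[i, k] <- min_pair_distance(fr, lig, res_idx[[i]]) <= cutoff
    }
  }
  occ <- rowMeans(hits)
  tibble::tibble(chain = partners$chain, resno = partners$resno,
                 occupancy = occ, stable = occ >= stable_threshold)
}

#' Standard NSS-fold scaffold/bundle group memberships
#'
#' The published membership of the two collective-variable groups for the
#' NSS fold: the extracellular scaffold anchor pools the C-terminal ends of
#' TM3, TM5 and TM9 with the N-terminal ends of TM4, TM8 and TM10; the
#' extracellular bundle anchor pools the C-terminal ends of TM1b and TM7 with
#' the N-terminal ends of TM2 and TM6a; the intracellular side mirrors both.
#'
#' @return List with `extracellular` and `intracellular` elements, each
#'   holding `scaffold` and `bundle` membership tibbles, ready for
#'   [topology()].
#' @export
nss_groups <- function() {
  list(
    extracellular = list(
      scaffold = tibble::tibble(
        tm = c("TM3", "TM5", "TM9", "TM4", "TM8", "TM10"),
        end = c(rep("C_terminal", 3), rep("N_terminal", 3))),
      bundle = tibble::tibble(
        tm = c("TM1b", "TM7", "TM2", "TM6a"),
        end = c("C_terminal", "C_terminal", "N_terminal", "N_terminal"))
    ),
    intracellular = list(
      scaffold = tibble::tibble(
        tm = c("TM3", "TM5", "TM9", "TM4", "TM8", "TM10"),
        end = c(rep("N_terminal", 3), rep("C_terminal", 3))),
      bundle = tibble::tibble(
        tm = c("TM1a", "TM7", "TM2", "TM6b"),
        end = c("N_terminal", "N_terminal", "C_terminal", "C_terminal"))
    )
  )
}

#' Gating-network presets for hSERT
#'
#' The four canonical gate distances of the serotonin transporter, hSERT
#' author numbering: the intracellular Tyr350(OH)-Glu444(OE1/OE2) pair, the
#' Glu136(OE1/OE2)-Gly340(backbone N) pair, the extracellular
#' Arg104(NE/NH1/NH2)-Glu493(OE1/OE2) salt bridge, and
#' Glu136(OE1/OE2)-Glu508(OE1/OE2).
#'
#' @param chain Chain identifier of the monomer to analyse.
#' @return Named list of `cv_gate` objects.
#' @export
hsert_gates <- function(chain = "A") {
  list(
    tyr350_glu444 = gate("Tyr350-Glu444",
      selection(chain = chain, resno = 350, atoms = "OH"),
      selection(chain = chain, resno = 444, atoms = c("OE1", "OE2"))),
    glu136_gly340 = gate("Glu136-Gly340",
      selection(chain = chain, resno = 136, atoms = c("OE1", "OE2")),
      selection(chain = chain, resno = 340, atoms = "N")),
    arg104_glu493 = gate("Arg104-Glu493",
      selection(chain = chain, resno = 104, atoms = c("NE", "NH1", "NH2")),
      selection(chain = chain, resno = 493, atoms = c("OE1", "OE2"))),
    glu136_glu508 = gate("Glu136-Glu508",
      selection(chain = chain, resno = 136, atoms = c("OE1", "OE2")),
      selection(chain = chain, resno = 508, atoms = c("OE1", "OE2")))
  )
}
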