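# Synthetic toy-transporter generator.
#
# A 12-helix bundle/scaffold toy with NSS topology: four bundle helices
# (TM1, TM2, TM6, TM7) on an inner ring offset from a six-helix scaffold ring
# (TM3-5, TM8-10), TM11/TM12 peripheral. TM1 and TM6 are split at mid-helix;
# TM1a swings outward about its split-point pivot by the hinge angle theta,
# the dominant motion of the inward-facing transition, while the whole bundle
# rocks by a small coupled angle. Ground truth (per-frame hinge and rocking
# angles) is emitted so every downstream metric has an oracle.

.helix_rise <- 1.5      # A per residue along the axis
.helix_radius <- 2.3    # A, C-alpha radius of an ideal alpha-helix
.helix_twist <- 100     # degrees per residue

# Fixed toy layout (membrane normal +z = extracellular; distances in A).
.toy_scaffold_radius <- 10
.toy_bundle_radius <- 5
.toy_bundle_center <- c(6, 0)
.toy_peripheral_radius <- 14
.toy_sidechain_offset <- 1.5
.toy_ion_dz_per_deg <- -0.2   # A of intracellular ion travel per degree of hinge

#' Parameters of the synthetic toy transporter
#'
#' @param n_res_per_helix Residues per helix (even, at least 8).
#' @param hinge_angle_max Maximal TM1a hinge angle in degrees, in `[0, 60]`.
#' @param rocking_angle Bundle rocking amplitude in degrees, reached at
#'   `hinge_angle_max`.
#' @param noise_sigma Gaussian coordinate noise, A (i.i.d. per coordinate).
#' @param n_frames Number of frames.
#' @param seed RNG seed (recorded in the emitted provenance).
#' @param schedule Hinge-angle schedule: `"linear_open"`, `"hold_closed"`,
#'   `"hold_open"` or `"two_state"`.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_res_per_helix = 20, hinge_angle_max = 30,
                             rocking_angle = 5, noise_sigma = 0.1,
                             n_frames = 50, seed = 1,
                             schedule = c("linear_open", "hold_closed",
                                          "hold_open", "two_state")) {
  schedule <- match.arg(schedule)
  if (n_res_per_helix < 8 || n_res_per_helix %% 2 != 0) {
    abort("n_res_per_helix must be an even number >= 8")
  }
  if (hinge_angle_max < 0 || hinge_angle_max > 60) {
    abort("hinge_angle_max must lie in [0, 60] degrees")
  }
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  if (n_frames < 1) abort("n_frames must be >= 1")
  structure(list(n_res_per_helix = as.integer(n_res_per_helix),
                 hinge_angle_max = hinge_angle_max,
                 rocking_angle = rocking_angle,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), schedule = schedule),
            class = "synthetic_params")
}

#' C-alpha trace of an ideal alpha-helix
#'
#' C-alpha atoms at 2.3 A radius, 100 degrees of twist and 1.5 A of rise per
#' residue along the given axis.
#'
#' @param n_res Number of residues (at least 4).
#' @param origin 3-vector: position of the first residue's axis point.
#' @param axis Direction of propagation (normalised internally).
#' @param phase Phase of the first residue in degrees.
#' @return `n_res x 3` matrix of C-alpha coordinates.
#' @export
build_ideal_helix <- function(n_res, origin = c(0, 0, 0), axis = c(0, 0, 1),
                              phase = 0) {
  if (n_res < 4) abort("build_ideal_helix: need at least 4 residues")
  a <- axis / sqrt(sum(axis^2))
  e <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- e - sum(e * a) * a; u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  i <- seq_len(n_res) - 1
  phi <- (phase + .helix_twist * i) * pi / 180
  t(vapply(seq_len(n_res), function(k) {
    origin + a * .helix_rise * i[k] +
      .helix_radius * (cos(phi[k]) * u + sin(phi[k]) * v)
  }, numeric(3)))
}

# Static layout of the 12 physical helices: position in the membrane plane,
# vertical direction (odd TMs run intracellular -> extracellular) and the ring
# centre its side chains point towards.
toy_layout <- function() {
  cx <- .toy_bundle_center[1]
  ang_s <- c(TM5 = 55, TM3 = 105, TM4 = 155, TM9 = 205, TM10 = 255, TM8 = 305)
  pos <- rbind(
    # TM1 sits closer to the bundle centre than the other bundle helices so
    # that, in the closed state, TM1a packs against TM6b across the
    # intracellular pathway; its outward hinge swing then uncovers the
    # pathway residues.
    TM1 = c(cx + 2, 0),
    TM2 = c(cx, .toy_bundle_radius),
    TM6 = c(cx - .toy_bundle_radius, 0),
    TM7 = c(cx, -.toy_bundle_radius),
    t(vapply(names(ang_s), function(nm) {
      .toy_scaffold_radius * c(cos(ang_s[nm] * pi / 180),
                               sin(ang_s[nm] * pi / 180))
    }, numeric(2))),
    TM11 = .toy_peripheral_radius * c(cos(45 * pi / 180), sin(45 * pi / 180)),
    TM12 = .toy_peripheral_radius * c(cos(-45 * pi / 180), sin(-45 * pi / 180))
  )
  hnum <- as.integer(sub("TM", "", rownames(pos)))
  tibble::tibble(
    tm = rownames(pos), helix_number = hnum,
    x = pos[, 1], y = pos[, 2],
    up = hnum %% 2 == 1,                       # odd TMs ascend (+z)
    ring_cx = ifelse(hnum %in% c(1, 2, 6, 7), cx, 0),
    ring_cy = 0,
    bundle = hnum %in% c(1, 2, 6, 7)
  ) |> dplyr::arrange(.data$helix_number)
}

# Residue bookkeeping: helix h covers residues (h-1)*n+1 .. h*n.
toy_resno <- function(h, n) (h - 1L) * n + seq_len(n)

# Residues with non-default names/side-chain atoms (gate and lid analogues).
toy_special_residues <- function(n) {
  m <- n %/% 2L
  f <- function(h) (h - 1L) * n + 1L
  l <- function(h) h * n
  tibble::tribble(
    ~resno,            ~resname, ~sc_name, ~sc_element,
    f(1) + 4L,         "TYR",    "OH",     "O",   # IC gate, TM1a
    l(8) - 2L,         "GLU",    "OE1",    "O",   # IC gate, TM8 (pathway)
    l(1) - 2L,         "ARG",    "NH1",    "N",   # EC gate, TM1b
    f(10) + 2L,        "GLU",    "OE2",    "O",   # EC gate, TM10
    l(3) - 2L,         "TYR",    "CB",     "C",   # aromatic-lid analogue, TM3
    f(6) + 2L,         "PHE",    "CB",     "C"    # aromatic-lid analogue, TM6a
  )
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
}
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Build one toy-transporter conformation
#'
#' Constructs the 12-helix toy at hinge angle `theta`: the whole bundle is
#' rocked about the membrane-parallel axis through its centre (aligned with
#' the scaffold-to-bundle direction, so the rock sways the bundle sideways)
#' by `rocking_angle * theta / hinge_angle_max`, then TM1a is rigidly rotated
#' outward about the pivot at its split-point C-alpha by `theta`. Each residue
#' carries a C-alpha and one pseudo side-chain heavy atom 1.5 A radially
#' inward; a pseudo-ligand atom sits at the bundle centre and a pseudo-ion
#' (Na2 analogue) descends 0.2 A per degree of hinge.
#'
#' @param params A `synthetic_params`.
#' @param theta Hinge angle in degrees, in `[0, hinge_angle_max]`.
#' @return A `cv_frame` (deterministic; noise is added only by
#'   [generate_trajectory()]).
#' @export
build_toy_transporter <- function(params, theta = 0) {
  stopifnot(inherits(params, "synthetic_params"))
  if (theta < 0 || theta > params$hinge_angle_max) {
    abort("theta outside [0, hinge_angle_max]")
  }
  n <- params$n_res_per_helix
  m <- n %/% 2L
  lay <- toy_layout()
  span <- (n - 1) * .helix_rise
  special <- toy_special_residues(n)

  res_rows <- list()
  for (i in seq_len(nrow(lay))) {
    h <- lay$helix_number[i]
    resnos <- toy_resno(h, n)
    axis <- if (lay$up[i]) c(0, 0, 1) else c(0, 0, -1)
    origin <- c(lay$x[i], lay$y[i], if (lay$up[i]) -span / 2 else span / 2)
    ca <- build_ideal_helix(n, origin = origin, axis = axis,
                            phase = 40 * (h - 1))
    inward <- c(lay$ring_cx[i] - lay$x[i], lay$ring_cy[i] - lay$y[i], 0)
    inward <- inward / sqrt(sum(inward^2))
    sc <- sweep(ca, 2, .toy_sidechain_offset * inward, `+`)
    res_rows[[i]] <- list(resnos = resnos, ca = ca, sc = sc,
                          bundle = lay$bundle[i], helix_number = h)
  }

  # bundle rocking about the x-axis through the bundle centre
  psi <- if (params$hinge_angle_max > 0)
    params$rocking_angle * theta / params$hinge_angle_max else 0
  if (psi != 0) {
    Rx <- rot_x(psi)
    pivot_b <- c(.toy_bundle_center, 0)
    for (i in seq_along(res_rows)) {
      if (!res_rows[[i]]$bundle) next
      res_rows[[i]]$ca <- sweep(sweep(res_rows[[i]]$ca, 2, pivot_b) %*% t(Rx),
                                2, pivot_b, `+`)
      res_rows[[i]]$sc <- sweep(sweep(res_rows[[i]]$sc, 2, pivot_b) %*% t(Rx),
                                2, pivot_b, `+`)
    }
  }

  # TM1a hinge: rigid rotation of residues 1..m of TM1 about the split-point
  # C-alpha, swinging the intracellular tip outward (+x)
  if (theta != 0) {
    i1 <- which(vapply(res_rows, function(r) r$helix_number == 1L, logical(1)))
    pivot <- res_rows[[i1]]$ca[m, ]
    Ry <- rot_y(theta)
    sel <- seq_len(m)
    res_rows[[i1]]$ca[sel, ] <-
      sweep(sweep(res_rows[[i1]]$ca[sel, , drop = FALSE], 2, pivot) %*% t(Ry),
            2, pivot, `+`)
    res_rows[[i1]]$sc[sel, ] <-
      sweep(sweep(res_rows[[i1]]$sc[sel, , drop = FALSE], 2, pivot) %*% t(Ry),
            2, pivot, `+`)
  }

  # assemble atoms in residue order: CA then the pseudo side-chain atom
  resno_all <- unlist(lapply(res_rows, `[[`, "resnos"))
  n_res_tot <- length(resno_all)
  ca_all <- do.call(rbind, lapply(res_rows, `[[`, "ca"))
  sc_all <- do.call(rbind, lapply(res_rows, `[[`, "sc"))
  sp_idx <- match(resno_all, special$resno)
  resname_res <- ifelse(is.na(sp_idx), "ALA", special$resname[sp_idx])
  sc_name_res <- ifelse(is.na(sp_idx), "CB", special$sc_name[sp_idx])
  sc_elem_res <- ifelse(is.na(sp_idx), "C", special$sc_element[sp_idx])

  ord <- rep(seq_len(n_res_tot), each = 2)
  is_sc <- rep(c(FALSE, TRUE), n_res_tot)
  xyz <- matrix(NA_real_, nrow = 2 * n_res_tot + 2, ncol = 3)
  xyz[c(!is_sc, FALSE, FALSE), ] <- ca_all
  xyz[c(is_sc, FALSE, FALSE), ] <- sc_all
  # pseudo-ligand at the bundle centre and Na2-analogue ion
  xyz[2 * n_res_tot + 1, ] <- c(.toy_bundle_center, 0)
  xyz[2 * n_res_tot + 2, ] <- c(.toy_bundle_center[1] - 1.5, 0,
                                .toy_ion_dz_per_deg * theta)
  at <- tibble::tibble(
    serial = seq_len(2 * n_res_tot + 2),
    name = c(ifelse(is_sc, sc_name_res[ord], "CA"), "C1", "NA"),
    resname = c(resname_res[ord], "LIG", "NA"),
    chain = "A",
    resno = c(resno_all[ord], 900L, 901L),
    insert = " ",
    element = c(ifelse(is_sc, sc_elem_res[ord], "C"), "C", "NA"),
    is_hetero = c(rep(FALSE, 2 * n_res_tot), TRUE, TRUE))
  new_frame(at, xyz)
}

#' Helix table of the toy transporter
#'
#' The 14 helix segments (TM1a/TM1b, TM2-TM5, TM6a/TM6b, TM7-TM12) with their
#' residue ranges, matching [build_toy_transporter()].
#'
#' @param params A `synthetic_params`.
#' @return Tibble with columns `tm`, `chain`, `first`, `last`.
#' @export
toy_helix_table <- function(params) {
  n <- params$n_res_per_helix
  m <- n %/% 2L
  f <- function(h) (h - 1L) * n + 1L
  l <- function(h) h * n
  segs <- list(
    c("TM1a", f(1), f(1) + m - 1L), c("TM1b", f(1) + m, l(1)),
    c("TM2", f(2), l(2)), c("TM3", f(3), l(3)), c("TM4", f(4), l(4)),
    c("TM5", f(5), l(5)),
    c("TM6a", f(6), f(6) + m - 1L), c("TM6b", f(6) + m, l(6)),
    c("TM7", f(7), l(7)), c("TM8", f(8), l(8)), c("TM9", f(9), l(9)),
    c("TM10", f(10), l(10)), c("TM11", f(11), l(11)), c("TM12", f(12), l(12))
  )
  tibble::tibble(tm = vapply(segs, `[[`, character(1), 1), chain = "A",
                 first = as.integer(vapply(segs, `[[`, character(1), 2)),
                 last = as.integer(vapply(segs, `[[`, character(1), 3)))
}

#' Topology configuration of the toy transporter
#'
#' Names the helices, the intracellular pathway and aromatic-lid residue sets,
#' the intracellular/extracellular gates, scaffold/bundle group memberships,
#' and the ion/ligand selections, all consistent with
#' [build_toy_transporter()].
#'
#' @param params A `synthetic_params`.
#' @return A `cv_topology`.
#' @export
toy_topology <- function(params) {
  n <- params$n_res_per_helix
  f <- function(h) (h - 1L) * n + 1L
  l <- function(h) h * n
  pathway <- tibble::tibble(chain = "A", resno = c(
    f(1) + 1:4,            # TM1a, intracellular inner face
    f(5) + 1:3,            # TM5 intracellular end
    l(6) - 3:1,            # TM6b intracellular end
    l(8) - 3:1))           # TM8 intracellular end
  lid <- tibble::tibble(chain = "A", resno = c(l(3) - 2L, f(6) + 2L))
  gates <- list(
    gate("ic_tyr_glu",
         selection(chain = "A", resno = f(1) + 4L, atoms = "OH"),
         selection(chain = "A", resno = l(8) - 2L, atoms = "OE1")),
    gate("ec_arg_glu",
         selection(chain = "A", resno = l(1) - 2L, atoms = "NH1"),
         selection(chain = "A", resno = f(10) + 2L, atoms = "OE2"))
  )
  groups <- nss_groups()
  topology(chains = "A", helices = toy_helix_table(params),
           residue_sets = list(
             pathway = list(mode = "whole_residue", residues = pathway),
             lid = list(mode = "sidechain", residues = lid)),
           gates = gates, groups = groups,
           ion = selection(chain = "A", resno = 901L, atoms = "NA",
                           hetero = TRUE),
           ligand = selection(chain = "A", resno = 900L, hetero = TRUE),
           membrane_normal = 1)
}

toy_schedule <- function(params) {
  n <- params$n_frames
  th <- switch(params$schedule,
    hold_closed = rep(0, n),
    hold_open = rep(params$hinge_angle_max, n),
    linear_open = if (n == 1) 0 else
      params$hinge_angle_max * (seq_len(n) - 1) / (n - 1),
    two_state = ifelse(seq_len(n) <= n / 2, 0, params$hinge_angle_max)
  )
  rock <- if (params$hinge_angle_max > 0)
    params$rocking_angle * th / params$hinge_angle_max else rep(0, n)
  tibble::tibble(frame = seq_len(n), theta_deg = th, rocking_deg = rock)
}

#' Generate a synthetic opening trajectory with ground truth
#'
#' Builds one toy-transporter frame per scheduled hinge angle, adds i.i.d.
#' Gaussian coordinate noise from a single seeded generator, and returns the
#' trajectory together with its ground truth and matching topology.
#'
#' @param params A `synthetic_params`.
#' @return List with elements `trajectory` (a `cv_trajectory`),
#'   `ground_truth` (tibble: `frame`, `theta_deg`, `rocking_deg`) and
#'   `topology` (a `cv_topology`).
#' @export
generate_trajectory <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  sched <- toy_schedule(params)
  frames <- lapply(seq_len(params$n_frames), function(k) {
    fr <- build_toy_transporter(params, sched$theta_deg[k])
    if (params$noise_sigma > 0) {
      fr$xyz <- fr$xyz + matrix(stats::rnorm(length(fr$xyz),
                                             sd = params$noise_sigma),
                                ncol = 3)
    }
    fr$frame_index <- k - 1L
    fr
  })
  list(trajectory = new_trajectory(frames),
       ground_truth = sched,
       topology = toy_topology(params))
}

#' Anchor structures for classifying synthetic trajectories
#'
#' Noise-free toy conformations at chosen hinge angles, packaged for
#' [reference_points()].
#'
#' @param params A `synthetic_params`.
#' @param thetas Named numeric vector of hinge angles; names become state
#'   labels. Defaults to closed (0) and open (`hinge_angle_max`).
#' @return List of structures, each `list(label, frame, topo, source)`.
#' @export
toy_anchor_structures <- function(params,
                                  thetas = c(closed = 0,
                                             open = params$hinge_angle_max)) {
  topo <- toy_topology(params)
  lapply(seq_along(thetas), function(i) {
    list(label = names(thetas)[i],
         frame = build_toy_transporter(params, thetas[[i]]),
         topo = topo,
         source = sprintf("synthetic toy, theta = %g deg", thetas[[i]]))
  })
}
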