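# Rigid-body superposition, RMSD/RMSF, centres of mass, minimum inter-set
# distances, helix axes and kink angles.

# Atomic masses for mass weighting (u). Unknown elements fall back to carbon.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                     P = 30.974, NA. = 22.990, CL = 35.45, K = 39.098,
                     MG = 24.305, ZN = 65.38, FE = 55.845)

element_mass <- function(element) {
  key <- ifelse(element == "NA", "NA.", element)
  m <- .element_masses[key]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Centre of mass of an atom set
#'
#' @param frame A `cv_frame`.
#' @param indices Non-empty integer vector of atom indices.
#' @param weighting `"uniform"` (the default, appropriate for C-alpha groups)
#'   or `"mass"`.
#' @return Numeric 3-vector (Angstrom).
#' @export
center_of_mass <- function(frame, indices, weighting = c("uniform", "mass")) {
  weighting <- match.arg(weighting)
  if (length(indices) == 0) abort("center_of_mass: empty atom set")
  xyz <- frame$xyz[indices, , drop = FALSE]
  w <- if (weighting == "uniform") rep(1, nrow(xyz)) else
    element_mass(frame$atoms$element[indices])
  colSums(xyz * w) / sum(w)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, by SVD of the cross-covariance with a determinant
#' correction that forbids reflections.
#'
#' @param mobile,reference Numeric `n x 3` matrices with `n >= 3` paired
#'   points, not all collinear.
#' @return A list of class `rigid_transform` with elements `rotation` (3x3,
#'   determinant +1), `translation` (3-vector) and `rmsd` (Angstrom). The
#'   transform maps `x` to `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    abort("kabsch_superpose: point sets differ in length")
  }
  if (nrow(mobile) < 3) abort("kabsch_superpose: need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  s <- svd(H)
  # Degenerate (collinear) sets leave the rotation about the line undetermined
  # and can demand a reflection; refuse them.
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    abort("kabsch_superpose: degenerate (collinear) point set")
  }
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param tf A `rigid_transform`.
#' @param xyz Numeric `n x 3` matrix.
#' @return Transformed `n x 3` matrix.
#' @export
apply_transform <- function(tf, xyz) {
  stopifnot(inherits(tf, "rigid_transform"))
  sweep(as.matrix(xyz) %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Per-frame RMSD against a reference structure
#'
#' Each frame is superposed on the reference using `align_sel`; the RMSD is
#' then reported over `measure_sel` without re-fitting, as is standard for
#' e.g. ligand RMSD after C-alpha alignment.
#'
#' @param traj A `cv_trajectory`.
#' @param reference A `cv_frame`; defaults to the first frame.
#' @param align_sel,measure_sel `cv_selection` objects.
#' @return Tibble with columns `frame` and `value` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, align_sel, measure_sel) {
  if (is.null(reference)) reference <- get_frame(traj, 1)
  f1 <- get_frame(traj, 1)
  ai <- resolve_selection(f1, align_sel, quiet = TRUE)
  mi <- resolve_selection(f1, measure_sel, quiet = TRUE)
  ra <- resolve_selection(reference, align_sel, quiet = TRUE)
  rm_ <- resolve_selection(reference, measure_sel, quiet = TRUE)
  if (length(ai) == 0 || length(mi) == 0 || length(ra) == 0 || length(rm_) == 0) {
    abort("rmsd_series: empty selection")
  }
  if (length(ai) != length(ra) || length(mi) != length(rm_)) {
    abort("rmsd_series: selections resolve to different sizes in trajectory and reference")
  }
  ref_align <- reference$xyz[ra, , drop = FALSE]
  ref_meas <- reference$xyz[rm_, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- traj$coords[, , k, drop = TRUE]
    tf <- kabsch_superpose(xyz[ai, , drop = FALSE], ref_align)
    moved <- apply_transform(tf, xyz[mi, , drop = FALSE])
    sqrt(mean(rowSums((moved - ref_meas)^2)))
  }, numeric(1))
  metric_series(vals, metric = "rmsd", units = "A")
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are first aligned to the first frame on `align_sel`, the mean
#' structure is formed, and a single re-alignment pass onto that mean is made;
#' the RMSF of each selected atom is the root-mean-square deviation from its
#' mean position.
#'
#' @param traj A `cv_trajectory` with at least two frames.
#' @param align_sel Selection used for the superpositions.
#' @param sel Selection of atoms to report (default C-alpha atoms).
#' @return Tibble with columns `chain`, `resno`, `name`, `value` (Angstrom).
#' @export
rmsf <- function(traj, align_sel, sel = selection(class = "CA_ONLY")) {
  if (n_frames(traj) < 2) abort("rmsf: need at least two frames")
  f1 <- get_frame(traj, 1)
  ai <- resolve_selection(f1, align_sel, quiet = TRUE)
  si <- resolve_selection(f1, sel, quiet = TRUE)
  if (length(ai) == 0 || length(si) == 0) abort("rmsf: empty selection")
  nf <- n_frames(traj)
  aligned <- array(NA_real_, dim = dim(traj$coords))
  ref <- traj$coords[ai, , 1, drop = TRUE]
  for (k in seq_len(nf)) {
    xyz <- traj$coords[, , k, drop = TRUE]
    tf <- kabsch_superpose(xyz[ai, , drop = FALSE], ref)
    aligned[, , k] <- apply_transform(tf, xyz)
  }
  mean_xyz <- apply(aligned, c(1, 2), mean)
  for (k in seq_len(nf)) {
    xyz <- aligned[, , k, drop = TRUE]
    tf <- kabsch_superpose(xyz[ai, , drop = FALSE],
                           mean_xyz[ai, , drop = FALSE])
    aligned[, , k] <- apply_transform(tf, xyz)
  }
  mean_xyz <- apply(aligned, c(1, 2), mean)
  dev2 <- matrix(0, nrow = length(si), ncol = nf)
  for (k in seq_len(nf)) {
    xk <- aligned[, , k, drop = TRUE]
    d <- xk[si, , drop = FALSE] - mean_xyz[si, , drop = FALSE]
    dev2[, k] <- rowSums(d^2)
  }
  tibble::tibble(chain = f1$atoms$chain[si], resno = f1$atoms$resno[si],
                 name = f1$atoms$name[si], value = sqrt(rowMeans(dev2)))
}

#' Minimum distance between two atom sets
#'
#' @param frame A `cv_frame`.
#' @param setA,setB Non-empty, disjoint integer vectors of atom indices.
#' @return Minimum Euclidean distance over the Cartesian product (Angstrom).
#' @export
min_pair_distance <- function(frame, setA, setB) {
  if (length(setA) == 0 || length(setB) == 0) {
    abort("min_pair_distance: empty atom set")
  }
  if (length(intersect(setA, setB)) > 0) {
    abort("min_pair_distance: atom sets overlap")
  }
  A <- frame$xyz[setA, , drop = FALSE]
  B <- frame$xyz[setB, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

#' Principal axis of a helix
#'
#' The axis is the principal eigenvector of the covariance of the C-alpha
#' coordinates, with its sign fixed to point from the first to the last
#' supplied atom (N- to C-terminal when indices follow sequence order).
#'
#' @param frame A `cv_frame`.
#' @param ca_indices At least 4 atom indices in sequence order.
#' @return A list of class `helix_axis` with unit `direction` and `centroid`.
#' @export
helix_axis <- function(frame, ca_indices) {
  if (length(ca_indices) < 4) abort("helix_axis: need at least 4 atoms")
  X <- frame$xyz[ca_indices, , drop = FALSE]
  centroid <- colMeans(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  v <- ev$vectors[, 1]
  span <- X[nrow(X), ] - X[1, ]
  if (sum(span * v) < 0) v <- -v
  structure(list(direction = v / sqrt(sum(v^2)), centroid = centroid),
            class = "helix_axis")
}

#' Kink angle of a helix segment against a reference axis
#'
#' The absolute angle between the segment's principal axis and a fixed
#' reference axis (for TM1a: the scaffold principal axis of the first frame),
#' in degrees on `[0, 90]`.
#'
#' @param frame A `cv_frame`.
#' @param segment_sel Selection resolving to the segment's C-alpha atoms.
#' @param reference_axis Unit 3-vector.
#' @return Angle in degrees.
#' @export
kink_angle <- function(frame, segment_sel, reference_axis) {
  idx <- resolve_selection(frame, segment_sel, quiet = TRUE)
  if (length(idx) < 4) abort("kink_angle: degenerate segment")
  ax <- helix_axis(frame, idx)
  ref <- reference_axis / sqrt(sum(reference_axis^2))
  cosang <- min(abs(sum(ax$direction * ref)), 1)
  acos(cosang) * 180 / pi
}

#' Principal axis of the scaffold helices
#'
#' Convenience wrapper: the principal eigenvector of all scaffold-helix
#' C-alpha atoms of a frame, used as the fixed reference for TM1a kink angles.
#'
#' @param frame A `cv_frame`.
#' @param topo A topology (see [topology()]).
#' @return Unit 3-vector.
#' @export
scaffold_axis <- function(frame, topo) {
  tms <- scaffold_tm_ids(topo)
  h <- topo$helices[topo$helices$tm %in% tms, , drop = FALSE]
  resnos <- unlist(mapply(seq, h$first, h$last, SIMPLIFY = FALSE))
  idx <- resolve_selection(frame, selection(chain = unique(h$chain),
                                            resno = resnos,
                                            class = "CA_ONLY"), quiet = TRUE)
  if (length(idx) < 4) abort("scaffold_axis: too few scaffold C-alpha atoms")
  X <- frame$xyz[idx, , drop = FALSE]
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  v <- ev$vectors[, 1]
  v / sqrt(sum(v^2))
}

# Internal: a metric series tibble with metadata attributes.
metric_series <- function(values, metric, units, frame = seq_along(values)) {
  out <- tibble::tibble(frame = as.integer(frame), value = as.numeric(values))
  attr(out, "metric") <- metric
  attr(out, "units") <- units
  out
}
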