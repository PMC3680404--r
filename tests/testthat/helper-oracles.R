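# Test helpers: quick frame construction and independent oracles.

# Minimal frame from bare coordinates.
mk_frame <- function(xyz, element = "C", name = NULL, resno = NULL,
                     chain = "A", resname = "UNK", is_hetero = FALSE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(name)) name <- paste0("X", seq_len(n))
  if (is.null(resno)) resno <- seq_len(n)
  new_frame(tibble::tibble(
    serial = seq_len(n), name = name, resname = rep_len(resname, n),
    chain = rep_len(chain, n), resno = as.integer(rep_len(resno, n)),
    insert = " ", element = rep_len(element, n),
    is_hetero = rep_len(is_hetero, n)), xyz)
}

# A frame holding one "residue" per atom with standard protein atom names.
mk_residue_frame <- function(residues) {
  # residues: list of list(resno, resname, atoms = named list name -> xyz,
  #                        elements = named character)
  rows <- list(); xyz <- list()
  for (r in residues) {
    for (nm in names(r$atoms)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        name = nm, resname = r$resname, chain = if (is.null(r$chain)) "A" else r$chain,
        resno = as.integer(r$resno), insert = " ",
        element = r$elements[[nm]], is_hetero = FALSE)
      xyz[[length(xyz) + 1]] <- r$atoms[[nm]]
    }
  }
  at <- dplyr::bind_rows(rows)
  at$serial <- seq_len(nrow(at))
  new_frame(at, do.call(rbind, xyz))
}

# Random compact atom cluster for SASA property tests.
random_cluster <- function(n, sd = 2.5, elements = c("C", "N", "O")) {
  mk_frame(matrix(rnorm(n * 3, sd = sd), ncol = 3),
           element = sample(elements, n, replace = TRUE))
}

# Monte-Carlo SASA oracle: uniform random points on each expanded sphere,
# independent of the golden-spiral lattice used by the implementation.
mc_sasa <- function(fr, probe = 1.4, n_mc = 1e5) {
  rt <- default_radii()
  r <- unname(ifelse(fr$atoms$element %in% names(rt$radii),
                     rt$radii[fr$atoms$element], rt$default)) + probe
  n <- nrow(fr$xyz)
  vapply(seq_len(n), function(i) {
    P <- matrix(rnorm(n_mc * 3), ncol = 3)
    P <- P / sqrt(rowSums(P^2)) * r[i]
    P <- sweep(P, 2, fr$xyz[i, ], `+`)
    exposed <- rep(TRUE, n_mc)
    for (j in setdiff(seq_len(n), i)) {
      dd <- (P[, 1] - fr$xyz[j, 1])^2 + (P[, 2] - fr$xyz[j, 2])^2 +
        (P[, 3] - fr$xyz[j, 3])^2
      exposed <- exposed & dd >= r[j]^2
    }
    mean(exposed) * 4 * pi * r[i]^2
  }, numeric(1))
}

# Exhaustive-rotation RMSD oracle for planar point sets (z = 0). Proper 3D
# rotations acting within the plane are in-plane rotations and in-plane
# reflections (pi-rotations about in-plane axes); both families are searched.
brute_rmsd_planar <- function(A, B) {
  Ac <- sweep(as.matrix(A), 2, colMeans(A))
  Bc <- sweep(as.matrix(B), 2, colMeans(B))
  flip <- diag(c(1, -1, -1))  # proper rotation: pi about the x-axis
  obj <- function(ang, M) {
    Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                 3, 3)
    sqrt(mean(rowSums((M %*% t(Rz) - Bc)^2)))
  }
  best <- Inf
  for (M in list(Ac, Ac %*% t(flip))) {
    for (w in seq(0, 2 * pi, length.out = 73)[-73]) {
      o <- optimize(obj, c(w - 0.1, w + 0.1 + 2 * pi / 72), M = M, tol = 1e-12)
      best <- min(best, o$objective)
    }
  }
  best
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Apply a global rigid motion to a frame.
transform_frame <- function(fr, R = diag(3), t = c(0, 0, 0)) {
  fr$xyz <- sweep(fr$xyz %*% t(R), 2, t, `+`)
  fr
}

# Hand-authored fixed-column PDB ATOM line.
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM  ", altloc = " ", element = "C") {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else
    paste0(" ", sprintf("%-3s", name))
  sprintf("%6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altloc, resname, chain, resno, x, y, z,
          1, 0, sprintf("%2s", element))
}
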