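# Multi-model PDB input/output and atom selections.
#
# Conventions used throughout the package:
#  * author-assigned PDB residue numbers, 1-based, used verbatim (no renumbering);
#  * alternate locations other than blank/'A' are dropped on read;
#  * hydrogens are kept on read but excluded from every measurement through the
#    HEAVY / CA_ONLY selection classes.

#' Construct a frame from an atom table and coordinates
#'
#' A frame is one structural snapshot: a tibble of atom metadata plus an
#' `n_atoms x 3` coordinate matrix in Angstrom.
#'
#' @param atoms Tibble with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `insert`, `element`, `is_hetero`.
#' @param xyz Numeric matrix, `nrow(atoms)` rows and 3 columns, Angstrom.
#' @param frame_index Integer frame index (0-based; metadata only).
#' @return An object of class `cv_frame`.
#' @export
new_frame <- function(atoms, xyz, frame_index = 0L) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("serial", "name", "resname", "chain", "resno", "insert",
                "element", "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3) {
    abort("xyz must be an n_atoms x 3 matrix")
  }
  if (!all(is.finite(xyz))) abort("coordinates must be finite")
  if (any(!nzchar(atoms$name))) abort("atom names must be non-empty")
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate (chain, residue, atom) triple within frame: ",
                 key[which(duplicated(key))[1]]))
  }
  structure(list(atoms = atoms, xyz = xyz, frame_index = as.integer(frame_index)),
            class = "cv_frame")
}

#' Construct a trajectory from a list of frames
#'
#' All frames must share an identical atom ordering (same names, residues and
#' chains in the same order); only the coordinates vary.
#'
#' @param frames List of `cv_frame` objects (at least one).
#' @param frame_spacing Time per frame in ns; metadata only.
#' @return An object of class `cv_trajectory` holding the shared atom table and
#'   a coordinate array of dimension `n_atoms x 3 x n_frames`.
#' @export
new_trajectory <- function(frames, frame_spacing = NA_real_) {
  if (length(frames) < 1) abort("a trajectory needs at least one frame")
  ref_key <- atom_identity(frames[[1]]$atoms)
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]$atoms) != length(ref_key)) {
      abort(paste0("frame ", k, " has ", nrow(frames[[k]]$atoms),
                   " atoms; expected ", length(ref_key)))
    }
    if (!identical(atom_identity(frames[[k]]$atoms), ref_key)) {
      abort(paste0("frame ", k, " atom ordering differs from frame 1"))
    }
  }
  coords <- array(NA_real_, dim = c(length(ref_key), 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]$xyz
  structure(list(atoms = frames[[1]]$atoms, coords = coords,
                 frame_spacing = frame_spacing),
            class = "cv_trajectory")
}

atom_identity <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
}

#' Number of frames in a trajectory
#' @param traj A `cv_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "cv_trajectory"))
  dim(traj$coords)[3]
}

#' Number of atoms in a frame or trajectory
#' @param x A `cv_frame` or `cv_trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "cv_frame")) return(nrow(x$atoms))
  if (inherits(x, "cv_trajectory")) return(dim(x$coords)[1])
  abort("n_atoms expects a cv_frame or cv_trajectory")
}

#' Extract one frame from a trajectory
#' @param traj A `cv_trajectory`.
#' @param i Frame number (1-based).
#' @return A `cv_frame`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(inherits(traj, "cv_trajectory"))
  i <- as.integer(i)
  if (i < 1 || i > n_frames(traj)) abort("frame index out of range")
  new_frame(traj$atoms, traj$coords[, , i, drop = TRUE], frame_index = i - 1L)
}

#' @export
print.cv_frame <- function(x, ...) {
  cat("<cv_frame> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat("<cv_trajectory> ", dim(x$coords)[3], " frame(s) x ",
      dim(x$coords)[1], " atoms\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# PDB reading

#' Read a (multi-model) PDB file as a trajectory
#'
#' Fixed-column PDB v3 ATOM/HETATM records are parsed; MODEL/ENDMDL delimit
#' frames (a file without MODEL records yields a single frame). Alternate
#' location indicators other than blank or 'A' are dropped. All models must
#' contain the same atoms in the same order.
#'
#' @param path Path to a PDB file.
#' @param frame_spacing Time per frame in ns (metadata only).
#' @return A `cv_trajectory`.
#' @export
read_pdb <- function(path, frame_spacing = NA_real_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(rec, "MODEL")
  if (!any(is_atom)) abort(paste0("no ATOM/HETATM records in ", path))

  model_starts <- which(is_model)
  atom_lines <- which(is_atom)
  if (length(model_starts) == 0) {
    model_of <- rep(1L, length(atom_lines))
    n_models <- 1L
  } else {
    model_of <- findInterval(atom_lines, model_starts)
    keep <- model_of >= 1L  # ignore stray records before the first MODEL
    atom_lines <- atom_lines[keep]
    model_of <- model_of[keep]
    n_models <- max(model_of)
  }

  txt <- lines[atom_lines]
  altloc <- substr(txt, 17, 17)
  keep <- altloc == " " | altloc == "A"
  txt <- txt[keep]
  atom_lines <- atom_lines[keep]
  model_of <- model_of[keep]

  xs <- suppressWarnings(as.numeric(substr(txt, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(txt, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(txt, 47, 54)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs))
  if (length(bad) > 0) {
    abort(paste0("malformed coordinate field at line ", atom_lines[bad[1]],
                 " of ", path))
  }
  resno <- suppressWarnings(as.integer(substr(txt, 23, 26)))
  bad <- which(is.na(resno))
  if (length(bad) > 0) {
    abort(paste0("malformed residue number at line ", atom_lines[bad[1]],
                 " of ", path))
  }

  name <- trimws(substr(txt, 13, 16))
  resname <- trimws(substr(txt, 18, 20))
  chain <- substr(txt, 22, 22)
  insert <- substr(txt, 27, 27)
  element <- trimws(substr(txt, 77, 78))
  serial <- suppressWarnings(as.integer(substr(txt, 7, 11)))
  is_het <- substr(txt, 1, 6) == "HETATM"
  element <- ifelse(nzchar(element), element, guess_element(name, resname))

  atoms_all <- tibble::tibble(
    serial = serial, name = name, resname = resname, chain = chain,
    resno = resno, insert = insert, element = toupper(element),
    is_hetero = is_het
  )

  idx_split <- split(seq_along(model_of), model_of)
  counts <- lengths(idx_split)
  if (length(unique(counts)) > 1) {
    abort(paste0("models of ", path, " differ in atom count (",
                 paste(unique(counts), collapse = ", "),
                 "); not a valid trajectory"))
  }
  frames <- lapply(seq_along(idx_split), function(k) {
    ii <- idx_split[[k]]
    new_frame(atoms_all[ii, ], cbind(xs[ii], ys[ii], zs[ii]),
              frame_index = k - 1L)
  })
  new_trajectory(frames, frame_spacing = frame_spacing)
}

# Element from atom name when columns 77-78 are blank. Digits are stripped;
# two-letter ion symbols are recognised via the residue name.
guess_element <- function(name, resname) {
  two_letter <- c("NA", "CL", "MG", "ZN", "FE", "CA", "K", "BR", "MN")
  out <- character(length(name))
  stripped <- gsub("[0-9']", "", name)
  for (i in seq_along(name)) {
    if (toupper(resname[i]) %in% two_letter &&
        toupper(stripped[i]) == toupper(resname[i])) {
      out[i] <- toupper(stripped[i])
    } else {
      out[i] <- toupper(substr(stripped[i], 1, 1))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# PDB writing

#' Write a trajectory as a (multi-model) PDB file
#'
#' Multi-frame trajectories are written with MODEL/ENDMDL blocks. A round trip
#' through [read_pdb()] reproduces names, numbering and coordinates to the PDB
#' precision of 0.001 Angstrom.
#'
#' @param traj A `cv_trajectory` (or single `cv_frame`).
#' @param path Output path.
#' @param header_lines Optional character vector written before the first
#'   model (e.g. HELIX records).
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(traj, path, header_lines = NULL) {
  if (inherits(traj, "cv_frame")) traj <- new_trajectory(list(traj))
  stopifnot(inherits(traj, "cv_trajectory"))
  nf <- n_frames(traj)
  if (nf < 1 || n_atoms(traj) < 1) abort("refusing to write an empty trajectory")
  atoms <- traj$atoms
  if (any(atoms$resno > 9999L) || any(atoms$resno < -999L)) {
    abort("residue numbers outside the 4-column PDB field")
  }
  serial <- seq_len(nrow(atoms)) %% 100000L
  rec <- ifelse(atoms$is_hetero, "HETATM", "ATOM  ")
  name4 <- vapply(atoms$name, function(nm) {
    if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf("%-3s", nm)
  }, character(1))
  name4 <- ifelse(nchar(atoms$name) >= 4, name4, paste0(" ", name4))
  elem <- sprintf("%2s", substr(atoms$element, 1, 2))

  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(header_lines, con)
  multi <- nf > 1
  for (k in seq_len(nf)) {
    xyz <- traj$coords[, , k, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    recs <- sprintf("%6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rec, serial, name4, " ", atoms$resname, atoms$chain,
                    atoms$resno, atoms$insert, xyz[, 1], xyz[, 2], xyz[, 3],
                    1, 0, elem)
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(recs, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Selections

#' Describe a set of atoms
#'
#' A selection combines an optional chain, optional residue numbers, an
#' optional explicit atom-name set and a symbolic class. The class and the
#' explicit name set compose by intersection.
#'
#' Classes: `ALL` (no class filter), `CA_ONLY` (protein C-alpha atoms),
#' `BACKBONE` (N, CA, C, O), `SIDECHAIN` (heavy atoms not in the backbone set),
#' `HEAVY` (element != H). `CA_ONLY`, `BACKBONE` and `SIDECHAIN` exclude
#' HETATM records.
#'
#' @param chain Chain identifier, or `NULL` for any chain.
#' @param resno Integer vector of residue numbers, or `NULL` for any.
#' @param atoms Character vector of atom names, or `NULL` for any.
#' @param class One of `"ALL"`, `"CA_ONLY"`, `"SIDECHAIN"`, `"BACKBONE"`,
#'   `"HEAVY"`.
#' @param hetero `NA` to allow both ATOM and HETATM, `TRUE`/`FALSE` to
#'   restrict.
#' @return An object of class `cv_selection`.
#' @export
selection <- function(chain = NULL, resno = NULL, atoms = NULL,
                      class = c("ALL", "CA_ONLY", "SIDECHAIN", "BACKBONE", "HEAVY"),
                      hetero = NA) {
  class <- match.arg(class)
  structure(list(chain = chain,
                 resno = if (is.null(resno)) NULL else as.integer(resno),
                 atoms = atoms, class = class, hetero = hetero),
            class = "cv_selection")
}

#' Resolve a selection to atom indices
#'
#' @param frame A `cv_frame`.
#' @param spec A `cv_selection`.
#' @param quiet Suppress the empty-selection warning.
#' @return Integer vector of atom indices in atom order (possibly empty, with
#'   a warning).
#' @export
resolve_selection <- function(frame, spec, quiet = FALSE) {
  stopifnot(inherits(frame, "cv_frame"), inherits(spec, "cv_selection"))
  a <- frame$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(spec$chain)) keep <- keep & a$chain %in% spec$chain
  if (!is.null(spec$resno)) keep <- keep & a$resno %in% spec$resno
  if (!is.null(spec$atoms)) keep <- keep & a$name %in% spec$atoms
  backbone <- c("N", "CA", "C", "O")
  keep <- keep & switch(spec$class,
    ALL = TRUE,
    HEAVY = a$element != "H",
    CA_ONLY = a$name == "CA" & !a$is_hetero,
    BACKBONE = a$name %in% backbone & !a$is_hetero,
    SIDECHAIN = !(a$name %in% backbone) & a$element != "H" & !a$is_hetero
  )
  if (!is.na(spec$hetero)) keep <- keep & (a$is_hetero == spec$hetero)
  idx <- which(keep)
  if (length(idx) == 0 && !quiet) warn("selection resolved to zero atoms")
  idx
}
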