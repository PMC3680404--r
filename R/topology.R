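# Topology configuration: TM helix ranges, residue sets, gates,
# scaffold/bundle group membership, ion/ligand selections and analysis
# parameters. Everything tunable lives here, nothing is hidden in code.

#' Build a topology configuration
#'
#' @param chains Character vector of chains to analyse.
#' @param helices Tibble with columns `tm` (e.g. "TM1a", "TM1b", "TM2", ...),
#'   `chain`, `first`, `last` (author PDB numbering).
#' @param residue_sets Named list; each element is
#'   `list(mode = "whole_residue"|"sidechain", residues = tibble(chain, resno))`.
#'   The set named `"pathway"` feeds the conformational-state coordinate; a
#'   set named `"lid"` is reported when present.
#' @param gates List of gates built with [gate()].
#' @param groups List with elements `extracellular` and `intracellular`, each
#'   `list(scaffold = tibble(tm, end), bundle = tibble(tm, end))` where `end`
#'   is `"N_terminal"` or `"C_terminal"`.
#' @param ion Optional `cv_selection` resolving to a single ion atom.
#' @param ligand Optional `cv_selection` for the bound ligand.
#' @param membrane_normal `+1` if the +z axis points extracellular (the
#'   convention for oriented inputs), `-1` otherwise.
#' @param sasa List of SASA parameters: `probe`, `n_points`, `radii`
#'   (named overrides), `default_radius`.
#' @param offsets Integer offsets selecting helix-terminal residues for the
#'   scaffold/bundle centres of mass (default `c(3, 4)`, counting the
#'   terminal residue as 1).
#' @param classification Optional list with `scales` (length-2 numeric) for
#'   state classification.
#' @return An object of class `cv_topology`.
#' @export
topology <- function(chains, helices, residue_sets = list(), gates = list(),
                     groups = NULL, ion = NULL, ligand = NULL,
                     membrane_normal = 1,
                     sasa = list(probe = 1.4, n_points = 960, radii = NULL,
                                 default_radius = 1.70),
                     offsets = c(3L, 4L),
                     classification = list(scales = NULL)) {
  helices <- tibble::as_tibble(helices)
  stopifnot(all(c("tm", "chain", "first", "last") %in% names(helices)))
  helices$first <- as.integer(helices$first)
  helices$last <- as.integer(helices$last)
  topo <- structure(list(chains = chains, helices = helices,
                         residue_sets = residue_sets, gates = gates,
                         groups = groups, ion = ion, ligand = ligand,
                         membrane_normal = sign(membrane_normal),
                         sasa = utils::modifyList(
                           list(probe = 1.4, n_points = 960, radii = NULL,
                                default_radius = 1.70), sasa),
                         offsets = as.integer(offsets),
                         classification = classification),
                    class = "cv_topology")
  errs <- topology_errors(topo)
  if (length(errs) > 0) {
    abort(paste0("invalid topology:\n", paste0("  - ", errs, collapse = "\n")))
  }
  topo
}

#' @export
print.cv_topology <- function(x, ...) {
  cat("<cv_topology> ", nrow(x$helices), " helix segments, ",
      length(x$residue_sets), " residue set(s), ",
      length(x$gates), " gate(s)\n", sep = "")
  invisible(x)
}

#' Define a gating-network distance
#'
#' A gate is a labelled pair of disjoint atom selections; the gate distance is
#' the per-frame minimum heavy-atom distance between them.
#'
#' @param label Gate name.
#' @param selA,selB `cv_selection` objects resolving to disjoint atom sets.
#' @return An object of class `cv_gate`.
#' @export
gate <- function(label, selA, selB) {
  stopifnot(inherits(selA, "cv_selection"), inherits(selB, "cv_selection"))
  structure(list(label = label, selA = selA, selB = selB), class = "cv_gate")
}

# Structural consistency checks that need no coordinates.
topology_errors <- function(topo) {
  errs <- character(0)
  h <- topo$helices
  if (anyDuplicated(h$tm)) {
    errs <- c(errs, paste0("duplicated helix id(s): ",
                           paste(unique(h$tm[duplicated(h$tm)]), collapse = ", ")))
  }
  bad <- h$first > h$last
  if (any(bad)) {
    errs <- c(errs, paste0("helix with first > last: ",
                           paste(h$tm[bad], collapse = ", ")))
  }
  for (pair in list(c("TM1a", "TM1b"), c("TM6a", "TM6b"))) {
    if (all(pair %in% h$tm)) {
      a <- h[h$tm == pair[1], ]; b <- h[h$tm == pair[2], ]
      if (a$last >= b$first) {
        errs <- c(errs, paste0(pair[1], "/", pair[2], " overlap"))
      }
    }
  }
  for (nm in names(topo$residue_sets)) {
    rs <- topo$residue_sets[[nm]]
    if (is.null(rs$residues) || nrow(tibble::as_tibble(rs$residues)) == 0) {
      errs <- c(errs, paste0("residue set '", nm, "' is empty"))
    }
  }
  if (!is.null(topo$groups)) {
    for (side in names(topo$groups)) {
      for (body in names(topo$groups[[side]])) {
        g <- tibble::as_tibble(topo$groups[[side]][[body]])
        if (nrow(g) == 0) {
          errs <- c(errs, paste0(side, " ", body, " group is empty"))
          next
        }
        unknown <- setdiff(g$tm, h$tm)
        if (length(unknown) > 0) {
          errs <- c(errs, paste0(side, " ", body,
                                 " group references undefined helix: ",
                                 paste(unknown, collapse = ", ")))
        }
        if (anyDuplicated(paste(g$tm, g$end))) {
          errs <- c(errs, paste0(side, " ", body, " group has duplicate members"))
        }
        if (!all(g$end %in% c("N_terminal", "C_terminal"))) {
          errs <- c(errs, paste0(side, " ", body,
                                 " group has invalid end labels"))
        }
      }
    }
  }
  errs
}

#' Validate a topology against a frame
#'
#' Collects every problem (unresolvable helices, missing residues, empty or
#' overlapping gate selections, ambiguous ion) and aborts with an itemised
#' message, so a bad configuration fails before any computation.
#'
#' @param topo A `cv_topology`.
#' @param frame A `cv_frame` to validate against.
#' @return Invisibly `TRUE`.
#' @export
validate_topology <- function(topo, frame) {
  errs <- topology_errors(topo)
  h <- topo$helices
  for (i in seq_len(nrow(h))) {
    idx <- resolve_selection(frame, selection(chain = h$chain[i],
                                              resno = h$first[i]:h$last[i],
                                              class = "CA_ONLY"), quiet = TRUE)
    if (length(idx) < (h$last[i] - h$first[i] + 1)) {
      errs <- c(errs, paste0("helix ", h$tm[i],
                             ": missing C-alpha atoms in frame"))
    }
  }
  present <- paste(frame$atoms$chain, frame$atoms$resno)
  for (nm in names(topo$residue_sets)) {
    rs <- tibble::as_tibble(topo$residue_sets[[nm]]$residues)
    miss <- setdiff(paste(rs$chain, rs$resno), present)
    if (length(miss) > 0) {
      errs <- c(errs, paste0("residue set '", nm, "' missing residue(s): ",
                             paste(miss, collapse = ", ")))
    }
  }
  for (g in topo$gates) {
    ia <- resolve_selection(frame, g$selA, quiet = TRUE)
    ib <- resolve_selection(frame, g$selB, quiet = TRUE)
    if (length(ia) == 0 || length(ib) == 0) {
      errs <- c(errs, paste0("gate '", g$label, "' has an empty selection"))
    } else if (length(intersect(ia, ib)) > 0) {
      errs <- c(errs, paste0("gate '", g$label, "' selections overlap"))
    }
  }
  if (!is.null(topo$ion)) {
    ii <- resolve_selection(frame, topo$ion, quiet = TRUE)
    if (length(ii) != 1) {
      errs <- c(errs, paste0("ion selection resolves to ", length(ii),
                             " atoms (need exactly 1)"))
    }
  }
  if (length(errs) > 0) {
    abort(paste0("topology validation failed:\n",
                 paste0("  - ", errs, collapse = "\n")))
  }
  invisible(TRUE)
}

# TM ids appearing in scaffold groups on either side.
scaffold_tm_ids <- function(topo) {
  if (is.null(topo$groups)) abort("topology has no scaffold/bundle groups")
  unique(unlist(lapply(topo$groups, function(side) {
    tibble::as_tibble(side$scaffold)$tm
  })))
}

# ---------------------------------------------------------------------------
# YAML serialisation

sel_to_list <- function(s) {
  if (is.null(s)) return(NULL)
  list(chain = s$chain, resno = s$resno, atoms = s$atoms, class = s$class,
       hetero = if (is.na(s$hetero)) NULL else s$hetero)
}

sel_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  selection(chain = l$chain, resno = unlist(l$resno), atoms = unlist(l$atoms),
            class = if (is.null(l$class)) "ALL" else l$class,
            hetero = if (is.null(l$hetero)) NA else l$hetero)
}

#' Write a topology configuration to YAML
#' @param topo A `cv_topology`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_topology <- function(topo, path) {
  stopifnot(inherits(topo, "cv_topology"))
  obj <- list(
    chains = topo$chains,
    membrane_normal = topo$membrane_normal,
    offsets = topo$offsets,
    helices = lapply(seq_len(nrow(topo$helices)), function(i) {
      as.list(topo$helices[i, ])
    }),
    residue_sets = lapply(topo$residue_sets, function(rs) {
      r <- tibble::as_tibble(rs$residues)
      list(mode = rs$mode,
           residues = lapply(seq_len(nrow(r)), function(i) as.list(r[i, ])))
    }),
    gates = lapply(topo$gates, function(g) {
      list(label = g$label, selA = sel_to_list(g$selA), selB = sel_to_list(g$selB))
    }),
    groups = if (is.null(topo$groups)) NULL else lapply(topo$groups, function(side) {
      lapply(side, function(body) {
        b <- tibble::as_tibble(body)
        lapply(seq_len(nrow(b)), function(i) as.list(b[i, ]))
      })
    }),
    ion = sel_to_list(topo$ion),
    ligand = sel_to_list(topo$ligand),
    sasa = topo$sasa[!vapply(topo$sasa, is.null, logical(1))],
    classification = topo$classification[!vapply(topo$classification, is.null,
                                                 logical(1))]
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a topology configuration from YAML
#' @param path Path written by [write_topology()] (or hand-authored in the
#'   same schema).
#' @return A `cv_topology`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  obj <- yaml::read_yaml(path)
  helices <- dplyr::bind_rows(lapply(obj$helices, tibble::as_tibble))
  residue_sets <- lapply(obj$residue_sets, function(rs) {
    list(mode = rs$mode,
         residues = dplyr::bind_rows(lapply(rs$residues, tibble::as_tibble)))
  })
  gates <- lapply(obj$gates, function(g) {
    gate(g$label, sel_from_list(g$selA), sel_from_list(g$selB))
  })
  groups <- if (is.null(obj$groups)) NULL else lapply(obj$groups, function(side) {
    lapply(side, function(body) dplyr::bind_rows(lapply(body, tibble::as_tibble)))
  })
  topology(chains = unlist(obj$chains), helices = helices,
           residue_sets = residue_sets, gates = gates, groups = groups,
           ion = sel_from_list(obj$ion), ligand = sel_from_list(obj$ligand),
           membrane_normal = if (is.null(obj$membrane_normal)) 1 else obj$membrane_normal,
           sasa = if (is.null(obj$sasa)) list() else obj$sasa,
           offsets = if (is.null(obj$offsets)) c(3L, 4L) else unlist(obj$offsets),
           classification = if (is.null(obj$classification)) list(scales = NULL)
                            else list(scales = unlist(obj$classification$scales)))
}

# ---------------------------------------------------------------------------
# Helix ranges from PDB HELIX records

#' Extract HELIX records from a PDB file
#'
#' @param path Path to a PDB file with HELIX records.
#' @return Tibble with columns `serial`, `helix_id`, `chain`, `first`,
#'   `last`, `length`.
#' @export
helix_records <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  hx <- lines[startsWith(lines, "HELIX")]
  if (length(hx) == 0) abort(paste0("no HELIX records in ", path))
  tibble::tibble(
    serial = as.integer(substr(hx, 8, 10)),
    helix_id = trimws(substr(hx, 12, 14)),
    chain = substr(hx, 20, 20),
    first = as.integer(substr(hx, 22, 25)),
    last = as.integer(substr(hx, 34, 37)),
    length = suppressWarnings(as.integer(substr(hx, 72, 76)))
  )
}

#' Map HELIX records to TM helix ranges
#'
#' Transmembrane assignments cannot be inferred automatically: you must say
#' which HELIX record is which TM (`tm_map`), and where TM1 and TM6 split at
#' their unwound centres (`splits`). The function refuses to guess.
#'
#' @param records Tibble from [helix_records()].
#' @param tm_map Named character vector mapping TM names to `helix_id` values
#'   (e.g. `c(TM1 = "1", TM2 = "2", ...)`). When a chain is repeated in the
#'   records, `chain` restricts the lookup.
#' @param splits Named integer vector: last residue of the intracellular half,
#'   e.g. `c(TM1 = 22, TM6 = 251)`; required for TM1 and TM6 if present in
#'   `tm_map`. TM1 splits into TM1a (first..split) and TM1b (split+1..last);
#'   TM6 into TM6a (first..split) and TM6b (split+1..last), `a` naming the
#'   half nearer the start of the record.
#' @param chain Optional chain filter applied to `records`.
#' @return Tibble of helix definitions with columns `tm`, `chain`, `first`,
#'   `last`, suitable for [topology()].
#' @export
assign_tm_ranges <- function(records, tm_map, splits = NULL, chain = NULL) {
  if (!is.null(chain)) records <- records[records$chain %in% chain, , drop = FALSE]
  rows <- list()
  for (tm in names(tm_map)) {
    rec <- records[records$helix_id == tm_map[[tm]], , drop = FALSE]
    if (nrow(rec) == 0) {
      abort(paste0("no HELIX record with id '", tm_map[[tm]], "' for ", tm))
    }
    if (nrow(rec) > 1) {
      abort(paste0("HELIX id '", tm_map[[tm]], "' is ambiguous; filter by chain"))
    }
    if (tm %in% c("TM1", "TM6")) {
      if (is.null(splits) || is.na(splits[tm])) {
        abort(paste0(tm, " must be split at its unwound centre; supply splits[\"",
                     tm, "\"]"))
      }
      sp <- as.integer(splits[tm])
      if (sp < rec$first || sp >= rec$last) {
        abort(paste0("split point for ", tm, " outside its range"))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        tm = paste0(tm, c("a", "b")), chain = rec$chain,
        first = c(rec$first, sp + 1L), last = c(sp, rec$last))
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        tm = tm, chain = rec$chain, first = rec$first, last = rec$last)
    }
  }
  dplyr::bind_rows(rows)
}

#' Format HELIX records for [write_pdb()]
#'
#' @param helices Tibble with columns `tm`, `chain`, `first`, `last`.
#' @param resname Residue name written into the record (cosmetic).
#' @return Character vector of fixed-column HELIX lines whose `helix_id`
#'   equals the `tm` value stripped of its "TM" prefix (e.g. "1A" for TM1a).
#' @export
format_helix_records <- function(helices, resname = "ALA") {
  helices <- tibble::as_tibble(helices)
  ids <- toupper(sub("^TM", "", helices$tm))
  if (any(nchar(ids) > 3)) abort("helix id too long for HELIX record")
  sprintf("HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d  1%30s %5d",
          seq_len(nrow(helices)), ids, resname, helices$chain, helices$first,
          resname, helices$chain, helices$last, "",
          helices$last - helices$first + 1L)
}
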