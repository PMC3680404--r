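# Two-dimensional conformational-state coordinate (intracellular-pathway SASA
# x intracellular scaffold-bundle distance), reference-structure placement,
# per-frame classification and series summaries.

# The (pathway SASA, intracellular distance) pair for one frame.
state_coordinate <- function(frame, topo) {
  rs <- topo$residue_sets[["pathway"]]
  if (is.null(rs)) abort("topology defines no 'pathway' residue set")
  radii <- default_radii(overrides = topo$sasa$radii,
                         default = topo$sasa$default_radius)
  sasa <- residue_set_sasa(frame, rs$residues, mode = "whole_residue",
                           context = "monomer", radii = radii,
                           probe = topo$sasa$probe,
                           n_points = topo$sasa$n_points)
  dist <- scaffold_bundle_distance(frame, topo, "intracellular")
  c(pathway_sasa_A2 = sasa, ic_distance_A = dist)
}

#' Place reference structures on the conformational plane
#'
#' Computes, for each labelled reference structure, the intracellular-pathway
#' SASA (whole residues, monomer context) and the intracellular
#' scaffold-bundle distance, giving the anchor points against which frames are
#' classified.
#'
#' @param structures List of entries, each a list with elements `label`,
#'   `frame` (a `cv_frame`) and `topo` (a `cv_topology`), plus an optional
#'   `source` identifier.
#' @return Tibble with columns `label`, `pathway_sasa_A2`, `ic_distance_A`,
#'   `source`.
#' @export
reference_points <- function(structures) {
  labels <- vapply(structures, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    abort(paste0("duplicate reference labels: ",
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  rows <- lapply(structures, function(s) {
    co <- state_coordinate(s$frame, s$topo)
    tibble::tibble(label = s$label,
                   pathway_sasa_A2 = co[["pathway_sasa_A2"]],
                   ic_distance_A = co[["ic_distance_A"]],
                   source = if (is.null(s$source)) NA_character_ else s$source)
  })
  dplyr::bind_rows(rows)
}

#' Classify one conformational coordinate against reference points
#'
#' Nearest reference after dividing each axis by its scale. Default scales are
#' the per-axis ranges of the references, preventing the square-Angstrom SASA
#' axis from swamping the Angstrom distance axis. Ties break to the reference
#' earliest in list order.
#'
#' @param coord Numeric length-2: `(pathway SASA, intracellular distance)`.
#' @param refs Tibble as returned by [reference_points()] (at least 2 rows).
#' @param scales Positive length-2 numeric, or `NULL` for reference ranges.
#' @return The winning reference's `label`.
#' @export
classify_frame <- function(coord, refs, scales = NULL) {
  refs <- tibble::as_tibble(refs)
  if (nrow(refs) < 2) abort("classify_frame: need at least 2 references")
  M <- cbind(refs$pathway_sasa_A2, refs$ic_distance_A)
  if (is.null(scales)) {
    scales <- c(diff(range(M[, 1])), diff(range(M[, 2])))
    scales[scales == 0] <- 1
  }
  if (length(scales) != 2 || any(scales <= 0)) {
    abort("classify_frame: scales must be two positive numbers")
  }
  Ms <- sweep(M, 2, scales, `/`)
  key <- paste(signif(Ms[, 1], 12), signif(Ms[, 2], 12))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup) && length(unique(refs$label[dup])) > 1) {
    abort("classify_frame: coincident scaled references with different labels")
  }
  cs <- as.numeric(coord)[1:2] / scales
  d2 <- (Ms[, 1] - cs[1])^2 + (Ms[, 2] - cs[2])^2
  refs$label[which.min(d2)]  # which.min takes the earliest on ties
}

#' Classify every frame of a trajectory
#'
#' Computes the per-frame conformational coordinate and assigns each frame to
#' its nearest reference state.
#'
#' @param traj A `cv_trajectory`.
#' @param topo A `cv_topology` with a `pathway` residue set and intracellular
#'   groups.
#' @param refs Reference tibble from [reference_points()].
#' @param scales Optional classification scales (see [classify_frame()]);
#'   falls back to `topo$classification$scales`, then to reference ranges.
#' @return An object of class `cv_state_series`; see [tidy.cv_state_series()]
#'   and [glance.cv_state_series()].
#' @export
classify_trajectory <- function(traj, topo, refs, scales = NULL) {
  if (is.null(scales)) scales <- topo$classification$scales
  coords <- t(vapply(seq_len(n_frames(traj)), function(k) {
    state_coordinate(get_frame(traj, k), topo)
  }, numeric(2)))
  labels <- vapply(seq_len(nrow(coords)), function(k) {
    classify_frame(coords[k, ], refs, scales)
  }, character(1))
  data <- tibble::tibble(frame = seq_len(nrow(coords)),
                         pathway_sasa_A2 = coords[, 1],
                         ic_distance_A = coords[, 2],
                         label = labels)
  occupancy <- data |>
    dplyr::count(.data$label, name = "n_frames") |>
    dplyr::mutate(fraction = .data$n_frames / sum(.data$n_frames))
  structure(list(data = data, occupancy = occupancy, refs = refs,
                 scales = scales),
            class = "cv_state_series")
}

#' @export
print.cv_state_series <- function(x, ...) {
  cat("<cv_state_series> ", nrow(x$data), " frames, ",
      nrow(x$occupancy), " occupied state(s)\n", sep = "")
  print(x$occupancy)
  invisible(x)
}

#' Tidy a classified state series
#'
#' @param x A `cv_state_series`.
#' @param ... Unused.
#' @return Per-frame tibble: `frame`, `pathway_sasa_A2`, `ic_distance_A`,
#'   `label`.
#' @export
tidy.cv_state_series <- function(x, ...) x$data

#' One-row summary of a classified state series
#'
#' @param x A `cv_state_series`.
#' @param ... Unused.
#' @return Tibble with `n_frames`, `n_states`, `modal_state`,
#'   `modal_fraction`.
#' @export
glance.cv_state_series <- function(x, ...) {
  top <- x$occupancy[which.max(x$occupancy$fraction), ]
  tibble::tibble(n_frames = nrow(x$data), n_states = nrow(x$occupancy),
                 modal_state = top$label, modal_fraction = top$fraction)
}

#' Plot a classified state series on the conformational plane
#'
#' @param object A `cv_state_series`.
#' @param ... Unused.
#' @return A ggplot: frames coloured by state label, references as labelled
#'   crosses.
#' @export
autoplot.cv_state_series <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pathway_sasa_A2,
                               y = .data$ic_distance_A,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = object$refs, shape = 4, size = 4,
                        colour = "black") +
    ggplot2::geom_text(data = object$refs,
                       ggplot2::aes(label = .data$label), colour = "black",
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "intracellular pathway SASA (Å²)",
                  y = "intracellular scaffold-bundle distance (Å)",
                  colour = "state")
}

#' Classify precomputed conformational coordinates
#'
#' Labels rows of an existing metrics table (as written by [run_analysis()])
#' against reference points, without re-reading the trajectory.
#'
#' @param metrics Data frame with columns `pathway_sasa_A2` and `ic_dist_A`
#'   (or `ic_distance_A`).
#' @param refs Reference tibble from [reference_points()].
#' @param scales Optional classification scales (see [classify_frame()]).
#' @return The input with a `label` column appended.
#' @export
classify_metrics <- function(metrics, refs, scales = NULL) {
  metrics <- tibble::as_tibble(metrics)
  dist_col <- intersect(c("ic_dist_A", "ic_distance_A"), names(metrics))[1]
  if (!("pathway_sasa_A2" %in% names(metrics)) || is.na(dist_col)) {
    abort("metrics must contain pathway_sasa_A2 and ic_dist_A columns")
  }
  metrics$label <- vapply(seq_len(nrow(metrics)), function(i) {
    classify_frame(c(metrics$pathway_sasa_A2[i], metrics[[dist_col]][i]),
                   refs, scales)
  }, character(1))
  metrics
}

#' Five-number summary of a metric series
#'
#' Minimum, lower quartile, median, upper quartile and maximum with
#' linear-interpolation (type 7) quantiles, matching whisker-to-extreme
#' boxplots.
#'
#' @param series Numeric vector or metric tibble with a `value` column.
#' @return One-row tibble: `minimum`, `q1`, `median`, `q3`, `maximum`.
#' @export
boxplot_stats <- function(series) {
  x <- if (is.data.frame(series)) series$value else as.numeric(series)
  if (length(x) == 0) abort("boxplot_stats: empty series")
  q <- quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  tibble::tibble(minimum = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 maximum = q[5])
}

#' Plot a per-frame metric series
#'
#' @param series Metric tibble with `frame` and `value` columns (attributes
#'   `metric`/`units` are used for labels when present).
#' @return A ggplot line plot.
#' @export
plot_metric_series <- function(series) {
  lab <- attr(series, "metric"); un <- attr(series, "units")
  ylab <- if (!is.null(lab)) paste0(lab, if (!is.null(un)) paste0(" (", un, ")"))
          else "value"
  ggplot2::ggplot(series, ggplot2::aes(x = .data$frame, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = ylab)
}
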