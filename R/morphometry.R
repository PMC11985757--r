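#' Construct a process trace
#'
#' One oligodendrocyte process as a polyline in micrometres, with its class
#' (primary = emerging from the soma, secondary = emerging from a primary,
#' blind = ending abruptly without myelinating), optional width samples
#' along the arc, and a myelination flag.
#'
#' @param trace_id Identifier, unique within the cell.
#' @param kind "primary", "secondary" or "blind".
#' @param polyline Two-column matrix of at least 2 points (x, y) in um.
#' @param parent_id For secondary processes, the `trace_id` of the primary
#'   they emerge from; `NA` for soma-attached processes.
#' @param width_samples Optional data frame with columns `position`
#'   (arc-length fraction in [0, 1]) and `width_um` (> 0, or `NA` where the
#'   process could not be distinguished from an overlapping neighbor).
#' @param myelinating Logical flag (from [detect_myelin()] on image chips).
#' @return A `process_trace` object.
#' @export
process_trace <- function(trace_id, kind = c("primary", "secondary", "blind"),
                          polyline, parent_id = NA_character_,
                          width_samples = NULL, myelinating = FALSE) {
  kind <- match.arg(kind)
  polyline <- as.matrix(polyline)
  if (ncol(polyline) != 2L || nrow(polyline) < 2L) {
    stop("`polyline` must be an n x 2 matrix with n >= 2", call. = FALSE)
  }
  if (kind == "secondary" && is.na(parent_id)) {
    stop("secondary processes must reference a parent primary", call. = FALSE)
  }
  if (!is.null(width_samples)) {
    stopifnot(all(c("position", "width_um") %in% names(width_samples)))
    w <- width_samples$width_um
    # a taper may reach zero exactly at the tip; negative widths are invalid
    if (any(w[is.finite(w)] < 0)) stop("widths must be non-negative", call. = FALSE)
  }
  structure(
    list(trace_id = as.character(trace_id), kind = kind,
         polyline = unname(polyline), parent_id = as.character(parent_id),
         width_samples = width_samples, myelinating = isTRUE(myelinating)),
    class = "process_trace"
  )
}

#' Construct an oligodendrocyte cell
#'
#' @param cell_id Identifier.
#' @param soma_center Numeric (x, y) in um.
#' @param traces List of [process_trace()] objects.
#' @param age_group Optional age-group label.
#' @return An `oligo_cell` object.
#' @export
oligo_cell <- function(cell_id, soma_center, traces, age_group = NA_character_) {
  stopifnot(length(soma_center) == 2L)
  structure(
    list(cell_id = as.character(cell_id), soma_center = as.numeric(soma_center),
         traces = traces, age_group = as.character(age_group)),
    class = "oligo_cell"
  )
}

#' Count processes per class
#'
#' Validates the attachment topology (secondaries must reference an
#' existing primary) and counts primary, secondary and blind processes plus
#' the myelinating ones. "All processes" in reports is the sum of the three
#' classes; myelinating processes are reported separately.
#'
#' @param cell An [oligo_cell()].
#' @return Named integer vector `c(primary, secondary, blind, myelinating)`.
#' @export
classify_processes <- function(cell) {
  stopifnot(inherits(cell, "oligo_cell"))
  ids <- vapply(cell$traces, function(t) t$trace_id, "")
  kinds <- vapply(cell$traces, function(t) t$kind, "")
  primary_ids <- ids[kinds == "primary"]
  for (t in cell$traces) {
    if (t$kind == "secondary" && !(t$parent_id %in% primary_ids)) {
      stop("trace ", t$trace_id, " references missing primary ", t$parent_id,
           call. = FALSE)
    }
  }
  c(primary = sum(kinds == "primary"),
    secondary = sum(kinds == "secondary"),
    blind = sum(kinds == "blind"),
    myelinating = sum(vapply(cell$traces, function(t) t$myelinating, NA)))
}

#' Arc length of a process
#'
#' @param trace A [process_trace()] (or an n x 2 polyline matrix in um).
#' @return Length in micrometres.
#' @export
process_length <- function(trace) {
  p <- if (inherits(trace, "process_trace")) trace$polyline else as.matrix(trace)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Five-point average process diameter
#'
#' The process is divided into five equal sub-segments and the width is
#' read at the center of each (arc-length fractions 0.1, 0.3, 0.5, 0.7,
#' 0.9); the diameter is the mean of the five. Widths come from the trace's
#' `width_samples` by linear interpolation. Where a sample center falls in a
#' stretch marked unmeasurable (overlapping processes, `width_um = NA`), the
#' width at the nearest measurable position on the same trace is
#' substituted.
#'
#' @param trace A [process_trace()] with `width_samples`.
#' @return Mean diameter in um, or `NA` (with a warning) when no position
#'   is measurable.
#' @export
process_diameter <- function(trace) {
  stopifnot(inherits(trace, "process_trace"))
  ws <- trace$width_samples
  if (is.null(ws) || nrow(ws) == 0L) {
    warning("trace ", trace$trace_id, " has no width samples", call. = FALSE)
    return(NA_real_)
  }
  ord <- order(ws$position)
  pos <- ws$position[ord]; wid <- ws$width_um[ord]
  meas <- is.finite(wid)
  if (!any(meas)) {
    warning("trace ", trace$trace_id, " has no measurable width", call. = FALSE)
    return(NA_real_)
  }
  centers <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  w_at <- vapply(centers, function(f) {
    nearest <- which.min(abs(pos - f))
    if (!meas[nearest]) {
      # overlap zone: take the nearest measurable sample instead
      mpos <- pos[meas]; mwid <- wid[meas]
      return(mwid[which.min(abs(mpos - f))])
    }
    if (sum(meas) == 1L) return(wid[meas])
    stats::approx(pos[meas], wid[meas], xout = f, rule = 2, ties = "ordered")$y
  }, numeric(1L))
  mean(w_at)
}

#' Process orientation relative to the medio-lateral axis
#'
#' Angle between the chord from the first to the last polyline point and
#' the medio-lateral (x) axis, folded to [0, 90] degrees (the measure is
#' undirected: a process running medially and one running laterally at the
#' same inclination get the same angle).
#'
#' @param trace A [process_trace()] or polyline matrix.
#' @return Angle in degrees in [0, 90]; `NA` for a zero-length chord.
#' @export
process_orientation <- function(trace) {
  p <- if (inherits(trace, "process_trace")) trace$polyline else as.matrix(trace)
  d <- p[nrow(p), ] - p[1L, ]
  if (all(d == 0)) return(NA_real_)
  atan2(abs(d[2L]), abs(d[1L])) * 180 / pi
}

#' Coverage polygon and Feret descriptors of a cell
#'
#' The tissue area reachable by a cell's processes is approximated by the
#' convex hull of all trace points. The hull's area (shoelace), minimum and
#' maximum Feret (caliper) diameters, their ratio, and the orientation of
#' the maximum-Feret direction are returned. The maximum Feret is the
#' largest pairwise distance between hull vertices; the minimum Feret is
#' found by rotating calipers over hull edges (for a convex polygon the
#' minimum width is always attained perpendicular to an edge).
#'
#' @param cell An [oligo_cell()] (all trace points are used) or an n x 2
#'   point matrix.
#' @return A list: `vertices` (hull, counter-clockwise), `area_um2`,
#'   `feret_min_um`, `feret_max_um`, `shape_ratio` (min/max, in (0, 1]),
#'   `feret_angle_deg` (direction of the maximum Feret, in [0, 180)).
#' @export
coverage <- function(cell) {
  pts <- if (inherits(cell, "oligo_cell")) {
    do.call(rbind, lapply(cell$traces, function(t) t$polyline))
  } else {
    as.matrix(cell)
  }
  pts <- unique(pts)
  if (nrow(pts) < 3L) stop("coverage needs >= 3 distinct points", call. = FALSE)
  h <- grDevices::chull(pts)          # clockwise indices
  hull <- pts[rev(h), , drop = FALSE] # counter-clockwise
  if (nrow(hull) < 3L) stop("degenerate (collinear) cell", call. = FALSE)
  area <- shoelace_area(hull)
  if (area <= 0) stop("degenerate (collinear) cell", call. = FALSE)

  # max Feret: hull diameter
  nh <- nrow(hull)
  dmat <- as.matrix(stats::dist(hull))
  imax <- which(dmat == max(dmat), arr.ind = TRUE)[1L, ]
  feret_max <- dmat[imax[1L], imax[2L]]
  dvec <- hull[imax[2L], ] - hull[imax[1L], ]
  angle <- (atan2(dvec[2L], dvec[1L]) * 180 / pi) %% 180

  # min Feret: smallest width over edge-aligned calipers
  feret_min <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    n_hat <- c(-e[2L], e[1L]) / len
    proj <- (hull[, 1L] - hull[i, 1L]) * n_hat[1L] +
      (hull[, 2L] - hull[i, 2L]) * n_hat[2L]
    feret_min <- min(feret_min, max(proj) - min(proj))
  }

  list(vertices = hull, area_um2 = area,
       feret_min_um = feret_min, feret_max_um = feret_max,
       shape_ratio = feret_min / feret_max,
       feret_angle_deg = angle)
}

#' Full width at half maximum of a cross-profile
#'
#' Measures a process width from an image: the perpendicular intensity
#' profile is thresholded at background plus half the peak elevation and
#' the outer crossing points are located by linear interpolation.
#'
#' @param profile Numeric intensity vector across the process.
#' @param pixel_size_um Micrometres per sample.
#' @param background Background level; defaults to the profile median.
#' @return Width in micrometres (`NA` when the profile never rises above
#'   background).
#' @export
width_fwhm <- function(profile, pixel_size_um, background = NULL) {
  x <- as.numeric(profile)
  if (is.null(background)) background <- stats::median(x)
  peak <- max(x)
  if (peak <= background) return(NA_real_)
  half <- background + (peak - background) / 2
  above <- which(x >= half)
  if (length(above) == 0L) return(NA_real_)
  lo <- min(above); hi <- max(above)
  left <- if (lo > 1L) (lo - 1L) + (half - x[lo - 1L]) / (x[lo] - x[lo - 1L]) else 1
  right <- if (hi < length(x)) hi + (half - x[hi]) / (x[hi + 1L] - x[hi]) else length(x)
  (right - left) * pixel_size_um
}

#' Map postnatal ages to report age groups
#'
#' Ages are pooled into the groups used for morphometric reporting. The
#' mapping is a configuration table, not a constant: pass any named list of
#' integer day vectors to regroup.
#'
#' @param age_days Integer vector of postnatal days.
#' @param mapping Named list; default pools P13/14, P17/18 and P25-30 (the
#'   single-cell groups). Ages outside every group return `NA`.
#' @return Character vector of group labels.
#' @export
assign_age_group <- function(age_days,
                             mapping = list("P10" = 10L, "P13/14" = 13:14,
                                            "P17/18" = 17:18, "P25-30" = 25:30)) {
  vapply(age_days, function(a) {
    for (nm in names(mapping)) if (a %in% mapping[[nm]]) return(nm)
    NA_character_
  }, "")
}

#' Per-cell morphometry summary
#'
#' Runs the full single-cell analysis: process counts by class, per-process
#' length, diameter and orientation, and the coverage polygon descriptors.
#'
#' @param cell An [oligo_cell()].
#' @return List with `counts` (from [classify_processes()]), a `processes`
#'   tibble (trace, kind, length, diameter, orientation, myelinating) and
#'   `coverage` (from [coverage()]; `NULL` for degenerate cells).
#' @export
cell_morphometry <- function(cell) {
  counts <- classify_processes(cell)
  proc <- tibble::tibble(
    trace_id = vapply(cell$traces, function(t) t$trace_id, ""),
    kind = vapply(cell$traces, function(t) t$kind, ""),
    length_um = vapply(cell$traces, process_length, numeric(1L)),
    diameter_um = vapply(cell$traces, function(t) {
      if (is.null(t$width_samples)) NA_real_ else suppressWarnings(process_diameter(t))
    }, numeric(1L)),
    orientation_deg = vapply(cell$traces, process_orientation, numeric(1L)),
    myelinating = vapply(cell$traces, function(t) t$myelinating, NA)
  )
  cov <- tryCatch(coverage(cell), error = function(e) NULL)
  list(counts = counts, processes = proc, coverage = cov)
}
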