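#' Count marks inside a nucleus ROI
#'
#' @param marks Marks tibble in the same pixel frame as `roi`.
#' @param roi A [nucleus_roi()].
#' @return Integer count of marks inside (or on the boundary of) the polygon.
#' @export
count_in_nucleus <- function(marks, roi) {
  if (nrow(marks) == 0L) return(0L)
  sum(point_in_roi(marks, roi))
}

#' Cell density per square millimetre
#'
#' @param count Number of cells.
#' @param area_mm2 ROI area in mm^2 (use [polygon_area()]).
#' @return `count / area_mm2`.
#' @export
density_per_mm2 <- function(count, area_mm2) {
  if (!is.finite(area_mm2) || area_mm2 <= 0) {
    stop("`area_mm2` must be positive", call. = FALSE)
  }
  count / area_mm2
}

#' Bin normalized marks into the 20 x 20 grid
#'
#' The normalized nucleus frame (0--100 percent on each axis) is divided into
#' 5 percent increments, giving a fixed 20 x 20 grid. Bins are half-open
#' `[5k, 5k + 5)` except the last, which closes at 100 so no mark is lost.
#' The returned matrix is indexed `[y bin, x bin]` with row 1 the ventral-most
#' (ry in [0, 5)) stripe and column 1 the medial-most.
#'
#' @param norm Tibble with `rx`, `ry` in [0, 100] (from
#'   [normalize_coordinates()]).
#' @return 20 x 20 integer count matrix whose sum equals `nrow(norm)`.
#' @export
bin_marks <- function(norm) {
  if (any(norm$rx < 0 | norm$rx > 100 | norm$ry < 0 | norm$ry > 100)) {
    stop("normalized coordinates must lie in [0, 100]", call. = FALSE)
  }
  ix <- pmin(floor(norm$rx / 5), 19) + 1L
  iy <- pmin(floor(norm$ry / 5), 19) + 1L
  grid <- matrix(0L, nrow = 20L, ncol = 20L)
  for (k in seq_along(ix)) grid[iy[k], ix[k]] <- grid[iy[k], ix[k]] + 1L
  grid
}

#' Normalize a count grid by its per-section maximum
#'
#' The highest bin count in the section is used as the normalizer, so a
#' single-section density grid always has maximum exactly 1 and all values in
#' [0, 1]. Sections with no marks cannot be normalized and must be excluded
#' upstream.
#'
#' @param counts 20 x 20 count matrix from [bin_marks()].
#' @param section_id,nucleus Provenance labels stored on the grid.
#' @return A `density_grid` object: list with `bins` (20 x 20 in [0, 1]),
#'   `section_id`, `nucleus`, `n_marks`, `bin_width_percent`.
#' @export
normalize_grid <- function(counts, section_id = NA_character_, nucleus = NA_character_) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(20L, 20L)))
  total <- sum(counts)
  if (total == 0L) {
    stop("cannot normalize an all-zero grid; exclude empty sections upstream",
         call. = FALSE)
  }
  structure(
    list(bins = counts / max(counts),
         section_id = as.character(section_id),
         nucleus = as.character(nucleus),
         n_marks = as.integer(total),
         bin_width_percent = 5),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid>", x$nucleus, "section", x$section_id,
      sprintf("(%d marks, max bin %.3f)\n", x$n_marks, max(x$bins)))
  invisible(x)
}

#' Average density grids across sections
#'
#' Element-wise mean of per-section normalized grids for one nucleus and age
#' group. The average is taken on the normalized scale, so its maximum can be
#' below 1 when the sections' densest bins differ in position.
#'
#' @param grids List of `density_grid` objects, all from the same nucleus.
#' @return A `density_grid` with `section_id = "average"` and `n_marks` the
#'   total across sections.
#' @export
average_grids <- function(grids) {
  stopifnot(length(grids) >= 1L)
  nuclei <- unique(vapply(grids, function(g) g$nucleus, ""))
  if (length(nuclei) != 1L) {
    stop("cannot average grids from different nuclei: ",
         paste(nuclei, collapse = ", "), call. = FALSE)
  }
  bins <- Reduce(`+`, lapply(grids, function(g) g$bins)) / length(grids)
  structure(
    list(bins = bins, section_id = "average", nucleus = nuclei,
         n_marks = sum(vapply(grids, function(g) g$n_marks, 0L)),
         bin_width_percent = 5),
    class = "density_grid"
  )
}

#' Render a density grid as an 8-bit grayscale image
#'
#' Higher cell abundance appears darker: normalized density 1 maps to gray 0
#' (black), 0 to gray 255 (white), linearly in between with half-up rounding.
#' The image row order puts the dorsal edge at the top.
#'
#' @param grid A `density_grid`.
#' @param path Optional PNG path; when given the image is also written.
#' @return 20 x 20 integer matrix of gray values in 0..255 (row 1 = dorsal).
#' @export
render_grid <- function(grid, path = NULL) {
  stopifnot(inherits(grid, "density_grid"))
  # round half up: floor(x + 0.5) (R's round() goes half-to-even)
  gray <- floor(255 * (1 - grid$bins) + 0.5)
  gray <- matrix(as.integer(gray), nrow = 20L)
  img <- gray[rev(seq_len(20L)), , drop = FALSE]  # dorsal row on top
  if (!is.null(path)) png::writePNG(img / 255, path)
  img
}

#' Per-section count, area and density records
#'
#' Runs the counting pipeline over sections: for each (section, nucleus) ROI,
#' counts the marks inside, measures the ROI area, and derives the density.
#' Sections with zero marks still contribute count 0 and density 0.
#'
#' @param marks Marks tibble covering one or more sections.
#' @param rois List of [nucleus_roi()] objects.
#' @param frames Named list of [section_frame()] objects keyed by section id,
#'   or a single frame applied to all sections.
#' @return Tibble with `section_id, nucleus, age_group, count, area_mm2,
#'   density_per_mm2`.
#' @export
density_records <- function(marks, rois, frames) {
  single <- inherits(frames, "section_frame")
  rows <- lapply(rois, function(roi) {
    frame <- if (single) frames else frames[[roi$section_id]]
    if (is.null(frame)) stop("no frame for section ", roi$section_id, call. = FALSE)
    sel <- marks[marks$section_id == roi$section_id & marks$nucleus == roi$nucleus, ]
    n <- count_in_nucleus(sel, roi)
    a <- polygon_area(roi, frame)$area_mm2
    tibble::tibble(section_id = roi$section_id, nucleus = roi$nucleus,
                   age_group = frame$age_group, count = n, area_mm2 = a,
                   density_per_mm2 = density_per_mm2(n, a))
  })
  do.call(rbind, rows)
}

#' Density map for one section's nucleus
#'
#' Convenience wrapper: filters marks to the ROI polygon, normalizes the
#' coordinates, bins them and max-normalizes. Marks inside the bounding box
#' but outside the polygon are excluded before binning.
#'
#' @inheritParams normalize_coordinates
#' @return A `density_grid`, or `NULL` (with a warning) when the section has
#'   no marks in the ROI.
#' @export
section_density_grid <- function(marks, roi, invert_y = FALSE, mirror_left = TRUE) {
  inside <- marks[point_in_roi(marks, roi), , drop = FALSE]
  if (nrow(inside) == 0L) {
    warning("section ", roi$section_id, " has no marks in ", roi$nucleus,
            "; excluded from grid averaging", call. = FALSE)
    return(NULL)
  }
  norm <- normalize_coordinates(inside, roi, invert_y = invert_y,
                                mirror_left = mirror_left)
  normalize_grid(bin_marks(norm), section_id = roi$section_id, nucleus = roi$nucleus)
}
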