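#' Construct a section frame
#'
#' A section frame carries the acquisition metadata shared by every mark and
#' ROI drawn on one tissue section: the pixel size of the imaging system, the
#' age group the section belongs to, the species, and the hemisphere the
#' section was imaged from. All pixel-to-micrometre conversions in the
#' package go through the frame, so a single wrong pixel size cannot be
#' introduced twice.
#'
#' @param section_id Character scalar identifying the section.
#' @param pixel_size_um Micrometres per pixel; must be a positive number.
#' @param age_group Character label, e.g. "P5", "P14", "P54".
#' @param species Character, e.g. "gerbil".
#' @param hemisphere "left" or "right". Left-hemisphere data are mirrored in
#'   the normalized frame so that increasing x is always lateral.
#' @param image_height_px Optional image height in pixels. When supplied,
#'   readers convert image-frame y (row 0 at the top) to the anatomical frame
#'   (y increasing dorsally) once at ingest.
#' @return An object of class `section_frame`.
#' @export
section_frame <- function(section_id, pixel_size_um, age_group = NA_character_,
                          species = NA_character_, hemisphere = c("right", "left"),
                          image_height_px = NULL) {
  hemisphere <- match.arg(hemisphere)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  if (!is.null(image_height_px)) {
    stopifnot(is.numeric(image_height_px), image_height_px > 0)
  }
  structure(
    list(section_id = as.character(section_id),
         pixel_size_um = as.numeric(pixel_size_um),
         age_group = as.character(age_group),
         species = as.character(species),
         hemisphere = hemisphere,
         image_height_px = image_height_px),
    class = "section_frame"
  )
}

#' @export
print.section_frame <- function(x, ...) {
  cat("<section_frame>", x$section_id,
      sprintf("(%g um/px, %s, %s hemisphere)\n",
              x$pixel_size_um, x$age_group, x$hemisphere))
  invisible(x)
}

#' Construct a nucleus ROI polygon
#'
#' A closed polygon (in pixel coordinates) outlining one anatomical nucleus
#' in one section, as drawn manually over the structural channel. The polygon
#' is stored open (the closing edge is implicit) and must be simple.
#'
#' @param section_id Section the ROI was drawn on.
#' @param nucleus Nucleus label: one of "MNTB", "MSO", "LSO", "dLSO",
#'   "control", or any other region name.
#' @param vertices Two-column numeric matrix (x, y) of at least 3 vertices,
#'   in pixels; the polygon closes implicitly from the last vertex to the
#'   first.
#' @param axis_spec Which normalized axis carries the tonotopic profile:
#'   "medio-lateral", "dorso-ventral", or "curved-path".
#' @param hemisphere "left" or "right".
#' @return An object of class `nucleus_roi`.
#' @export
nucleus_roi <- function(section_id, nucleus, vertices,
                        axis_spec = c("medio-lateral", "dorso-ventral", "curved-path"),
                        hemisphere = c("right", "left")) {
  axis_spec <- match.arg(axis_spec)
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("`vertices` must have two columns (x, y)", call. = FALSE)
  storage.mode(vertices) <- "double"
  # drop an explicitly repeated closing vertex
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1L, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 distinct vertices", call. = FALSE)
  if (!all(is.finite(vertices))) stop("polygon vertices must be finite", call. = FALSE)
  if (!is_simple_polygon(vertices)) {
    stop("polygon is self-intersecting; ROI outlines must be simple", call. = FALSE)
  }
  if (shoelace_area(vertices) <= 0) stop("polygon has zero area", call. = FALSE)
  structure(
    list(section_id = as.character(section_id),
         nucleus = as.character(nucleus),
         vertices = unname(vertices),
         axis_spec = axis_spec,
         hemisphere = hemisphere),
    class = "nucleus_roi"
  )
}

#' @export
print.nucleus_roi <- function(x, ...) {
  cat("<nucleus_roi>", x$nucleus, "in section", x$section_id,
      sprintf("(%d vertices, %s axis)\n", nrow(x$vertices), x$axis_spec))
  invisible(x)
}

#' Build a table of cell marks
#'
#' Marks are soma centers placed manually on the image; each mark carries the
#' set of fluorescence markers the cell was positive for and, optionally, a
#' measured soma diameter. Marks are kept as a plain tibble so they compose
#' with ordinary data-frame tooling; `markers` is a list-column of character
#' vectors.
#'
#' @param section_id,nucleus Character vectors (recycled).
#' @param x,y Numeric pixel coordinates, finite and non-negative.
#' @param markers Character vector (one marker each) or list of character
#'   vectors (marker sets); must be non-empty per mark.
#' @param soma_diameter_um Optional numeric vector of soma diameters.
#' @return A tibble with one row per mark.
#' @export
cell_marks <- function(section_id, nucleus, x, y, markers,
                       soma_diameter_um = NA_real_) {
  if (!is.list(markers)) markers <- as.list(markers)
  n <- max(length(x), length(y), length(markers))
  if (length(x) != n || length(y) != n || length(markers) != n) {
    stop("`x`, `y` and `markers` must have the same length", call. = FALSE)
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    stop("mark coordinates must be finite and >= 0", call. = FALSE)
  }
  markers <- lapply(markers, function(m) {
    m <- as.character(m)
    if (length(m) == 0L || all(!nzchar(m))) stop("each mark needs at least one marker", call. = FALSE)
    m[nzchar(m)]
  })
  tibble::tibble(
    section_id = rep_len(as.character(section_id), n),
    nucleus = rep_len(as.character(nucleus), n),
    x = x, y = y,
    markers = markers,
    soma_diameter_um = rep_len(as.numeric(soma_diameter_um), n)
  )
}

# --- polygon primitives -----------------------------------------------------

# Signed shoelace area (positive magnitude returned by callers that need it).
shoelace_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# Proper-crossing test between segments p1-p2 and p3-p4 (shared endpoints of
# adjacent polygon edges are allowed and handled by the caller).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

is_simple_polygon <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[if (i == n) 1L else i + 1L, ]
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (share a vertex)
      if (abs(i - j) == 1L || (i == 1L && j == n)) next
      b1 <- v[j, ]; b2 <- v[if (j == n) 1L else j + 1L, ]
      if (segments_cross(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

#' Polygon area of an ROI in physical units
#'
#' Computes the shoelace area of the ROI polygon and converts it with the
#' frame's pixel size. Manual outlines drawn in the image are in pixels, so
#' the area scales with the square of the pixel size.
#'
#' @param roi A [nucleus_roi()].
#' @param frame A [section_frame()] supplying `pixel_size_um`.
#' @return A list with `area_um2` and `area_mm2`.
#' @export
polygon_area <- function(roi, frame) {
  stopifnot(inherits(roi, "nucleus_roi"), inherits(frame, "section_frame"))
  a_px <- shoelace_area(roi$vertices)
  a_um2 <- a_px * frame$pixel_size_um^2
  list(area_um2 = a_um2, area_mm2 = a_um2 / 1e6)
}

# Even-odd crossing-number point-in-polygon with boundary points counted as
# inside (manual marks on a faint nuclear border must not be dropped).
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  xs <- v[, 1L]; ys <- v[, 2L]
  xe <- c(xs[-1L], xs[1L]); ye <- c(ys[-1L], ys[1L])
  m <- length(px)
  res <- logical(m)
  for (k in seq_len(m)) {
    x0 <- px[k]; y0 <- py[k]
    # boundary check: point on any edge counts as inside
    on_edge <- FALSE
    for (i in seq_len(n)) {
      cr <- (xe[i] - xs[i]) * (y0 - ys[i]) - (ye[i] - ys[i]) * (x0 - xs[i])
      if (cr == 0 &&
          x0 >= min(xs[i], xe[i]) && x0 <= max(xs[i], xe[i]) &&
          y0 >= min(ys[i], ye[i]) && y0 <= max(ys[i], ye[i])) {
        on_edge <- TRUE
        break
      }
    }
    if (on_edge) { res[k] <- TRUE; next }
    inside <- FALSE
    for (i in seq_len(n)) {
      if ((ys[i] > y0) != (ye[i] > y0)) {
        xint <- xs[i] + (y0 - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
        if (x0 < xint) inside <- !inside
      }
    }
    res[k] <- inside
  }
  res
}

#' Test whether marks fall inside an ROI
#'
#' Points exactly on the polygon boundary count as inside.
#'
#' @param marks A marks tibble (needs `x`, `y`) or a numeric length-2 vector.
#' @param roi A [nucleus_roi()].
#' @return Logical vector, one element per mark.
#' @export
point_in_roi <- function(marks, roi) {
  stopifnot(inherits(roi, "nucleus_roi"))
  if (is.numeric(marks) && length(marks) == 2L) {
    return(point_in_polygon(marks[1L], marks[2L], roi$vertices))
  }
  point_in_polygon(marks$x, marks$y, roi$vertices)
}

#' Normalize mark coordinates to the ROI bounding box
#'
#' Expresses each mark as a relative position in percent of the ROI's
#' axis-aligned bounding box, the frame in which the 5 percent density bins
#' and all tonotopic profiles are defined. After normalization `rx` increases
#' laterally and `ry` increases dorsally, regardless of hemisphere or image
#' row order: left-hemisphere sections are mirrored (`rx -> 100 - rx`) and,
#' unless the reader already flipped y at ingest using the image height,
#' `invert_y = TRUE` re-anchors y at the bounding box (`ry -> 100 - ry`) to
#' convert from image rows (row 0 at the top) to the anatomical frame.
#'
#' @param marks Marks tibble with `x`, `y` in the same pixel frame as `roi`.
#' @param roi A [nucleus_roi()]; its bounding box defines 0--100 on each axis.
#' @param invert_y Flip the y axis within the bounding box. Use when marks
#'   are still in image-row coordinates.
#' @param mirror_left Mirror x for left-hemisphere ROIs (default TRUE).
#' @return A tibble with columns `rx`, `ry` in [0, 100].
#' @export
normalize_coordinates <- function(marks, roi, invert_y = FALSE, mirror_left = TRUE) {
  stopifnot(inherits(roi, "nucleus_roi"))
  bb <- apply(roi$vertices, 2L, range)
  w <- bb[2L, 1L] - bb[1L, 1L]
  h <- bb[2L, 2L] - bb[1L, 2L]
  if (w <= 0 || h <= 0) stop("degenerate ROI bounding box (zero extent)", call. = FALSE)
  rx <- 100 * (marks$x - bb[1L, 1L]) / w
  ry <- 100 * (marks$y - bb[1L, 2L]) / h
  if (any(rx < -1e-9 | rx > 100 + 1e-9 | ry < -1e-9 | ry > 100 + 1e-9)) {
    stop("marks outside the ROI bounding box; filter with point_in_roi() first",
         call. = FALSE)
  }
  rx <- pmin(pmax(rx, 0), 100)
  ry <- pmin(pmax(ry, 0), 100)
  if (invert_y) ry <- 100 - ry
  if (mirror_left && identical(roi$hemisphere, "left")) rx <- 100 - rx
  tibble::tibble(rx = rx, ry = ry)
}

#' Convert pixels to micrometres (and back)
#'
#' Thin helpers around the frame's pixel size, used wherever printed
#' pixel-rectangle sizes are converted to physical dimensions.
#'
#' @param px,um Numeric values to convert.
#' @param pixel_size_um Micrometres per pixel.
#' @return Numeric vector of converted values.
#' @export
px_to_um <- function(px, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  px * pixel_size_um
}

#' @rdname px_to_um
#' @export
um_to_px <- function(um, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  um / pixel_size_um
}
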