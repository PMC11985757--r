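#' Overlay two mark sets by mutual-nearest-neighbor matching
#'
#' Reproduces the overlay step of manual double-labeling counts: two
#' independently marked point sets (one per marker channel) are paired
#' greedily, always joining the globally closest unmatched pair whose
#' distance does not exceed the tolerance. The procedure is deterministic
#' and order-independent; unmatched marks remain single-labeled.
#'
#' @param a,b Marks tibbles (or two-column coordinate matrices) in the same
#'   frame, coordinates in micrometres.
#' @param tolerance_um Maximum pairing distance (> 0).
#' @return A `match_result`: list with counts `n_only_a`, `n_only_b`,
#'   `n_double`, a two-column matrix `pairs` of matched row indices, and
#'   `tolerance_um`.
#' @export
match_marks <- function(a, b, tolerance_um = 5) {
  stopifnot(tolerance_um > 0)
  pa <- as_coords(a); pb <- as_coords(b)
  na <- nrow(pa); nb <- nrow(pb)
  pairs <- matrix(integer(), ncol = 2L)
  if (na > 0L && nb > 0L) {
    d <- sqrt(outer(pa[, 1L], pb[, 1L], "-")^2 + outer(pa[, 2L], pb[, 2L], "-")^2)
    d[d > tolerance_um] <- Inf
    taken_a <- logical(na); taken_b <- logical(nb)
    repeat {
      m <- which.min(d)
      if (length(m) == 0L || !is.finite(d[m])) break
      i <- (m - 1L) %% na + 1L
      j <- (m - 1L) %/% na + 1L
      pairs <- rbind(pairs, c(i, j))
      taken_a[i] <- TRUE; taken_b[j] <- TRUE
      d[i, ] <- Inf; d[, j] <- Inf
    }
  }
  structure(
    list(n_only_a = na - nrow(pairs), n_only_b = nb - nrow(pairs),
         n_double = nrow(pairs), pairs = pairs, tolerance_um = tolerance_um),
    class = "match_result"
  )
}

as_coords <- function(m) {
  if (is.matrix(m)) {
    stopifnot(ncol(m) == 2L)
    return(m)
  }
  cbind(m$x, m$y)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d double, %d only-A, %d only-B (tol %g um)\n",
              x$n_double, x$n_only_a, x$n_only_b, x$tolerance_um))
  invisible(x)
}

#' Labeling-fraction table from overlay counts
#'
#' Converts single/double (or triple-marker category) counts into
#' percentages of the total cell number, the form in which co-labeling
#' results are reported per region and age group.
#'
#' @param counts Named numeric vector of non-negative category counts, e.g.
#'   `c(only_olig2 = 10, only_sox10 = 0, double = 10)`; any number of
#'   categories is accepted (triple-labeling tables included).
#' @return Tibble with `category`, `count`, `percent`; percentages sum
#'   to 100.
#' @export
fraction_table <- function(counts) {
  counts <- unlist(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("cannot compute fractions of an empty overlay", call. = FALSE)
  tibble::tibble(
    category = names(counts),
    count = as.numeric(counts),
    percent = 100 * as.numeric(counts) / total
  )
}

#' Sampling circle for calyx-proximity counting
#'
#' The sampling area around a calyx is a concentric circle whose diameter is
#' the sum of the drawn calyx-circle diameter and the average soma diameter
#' of an S100-positive cell (17 um by default). A cell whose body fits
#' entirely inside this circle is "in calyx proximity".
#'
#' @param calyx_diameter_um Diameter of the circle drawn around the calyx.
#' @param cell_diameter_um Average soma diameter to add (default 17).
#' @return List with `diameter_um` and `radius_um`.
#' @export
sampling_circle <- function(calyx_diameter_um, cell_diameter_um = 17) {
  if (!is.finite(calyx_diameter_um) || calyx_diameter_um <= 0 ||
      !is.finite(cell_diameter_um) || cell_diameter_um <= 0) {
    stop("diameters must be positive", call. = FALSE)
  }
  d <- calyx_diameter_um + cell_diameter_um
  list(diameter_um = d, radius_um = d / 2)
}

#' Construct a calyx scene
#'
#' One VGluT1-positive calyx with its drawn circle plus the surrounding
#' cells (each a soma center with marker set and, where measured, a soma
#' diameter).
#'
#' @param calyx_center Numeric length-2 (x, y) in micrometres.
#' @param calyx_diameter_um Drawn circle diameter (> 0).
#' @param cells Marks tibble with micron coordinates; `soma_diameter_um`
#'   may be `NA` (a configured default is substituted when classifying).
#' @return A `calyx_scene` object.
#' @export
calyx_scene <- function(calyx_center, calyx_diameter_um, cells) {
  stopifnot(length(calyx_center) == 2L, calyx_diameter_um > 0)
  structure(
    list(calyx_center = as.numeric(calyx_center),
         calyx_diameter_um = as.numeric(calyx_diameter_um),
         cells = cells),
    class = "calyx_scene"
  )
}

#' Classify cells in calyx proximity
#'
#' A cell is counted when its soma disc lies fully within the sampling
#' circle: `dist(cell, calyx center) + soma radius <= sampling radius`.
#' Counted cells are partitioned by their marker sets into single-S100,
#' single-Olig2 and double-labeled.
#'
#' @param scene A [calyx_scene()].
#' @param markers Character pair naming the two markers (default
#'   `c("S100", "Olig2")`).
#' @param default_cell_diameter_um Soma diameter used both to widen the
#'   sampling circle and as fallback for cells without a measured diameter
#'   (default 17).
#' @return Tibble with one row per category (`only_<A>`, `only_<B>`,
#'   `double`) plus attributes `total` and `sampling_diameter_um`.
#' @export
classify_proximal <- function(scene, markers = c("S100", "Olig2"),
                              default_cell_diameter_um = 17) {
  stopifnot(inherits(scene, "calyx_scene"), length(markers) == 2L)
  circ <- sampling_circle(scene$calyx_diameter_um, default_cell_diameter_um)
  cells <- scene$cells
  counts <- c(0L, 0L, 0L)
  names(counts) <- c(paste0("only_", markers[1L]), paste0("only_", markers[2L]), "double")
  if (nrow(cells) > 0L) {
    dia <- cells$soma_diameter_um
    dia[!is.finite(dia)] <- default_cell_diameter_um
    dist <- sqrt((cells$x - scene$calyx_center[1L])^2 +
                   (cells$y - scene$calyx_center[2L])^2)
    inside <- dist + dia / 2 <= circ$radius_um
    for (k in which(inside)) {
      has_a <- markers[1L] %in% cells$markers[[k]]
      has_b <- markers[2L] %in% cells$markers[[k]]
      if (has_a && has_b) counts[3L] <- counts[3L] + 1L
      else if (has_a) counts[1L] <- counts[1L] + 1L
      else if (has_b) counts[2L] <- counts[2L] + 1L
    }
  }
  out <- tibble::tibble(category = names(counts), count = as.integer(counts))
  attr(out, "total") <- sum(counts)
  attr(out, "sampling_diameter_um") <- circ$diameter_um
  out
}

#' Minimal enclosing circle of a calyx outline
#'
#' Optional helper for when the calyx was outlined as a polygon rather than
#' a circle: Welzl's algorithm gives the smallest circle containing all
#' outline points, whose diameter then feeds [sampling_circle()].
#'
#' @param outline Two-column matrix of outline points (micrometres).
#' @return List with `center` (x, y) and `diameter_um`.
#' @export
enclosing_circle <- function(outline) {
  p <- as.matrix(outline)
  stopifnot(ncol(p) == 2L, nrow(p) >= 1L)
  circle_from <- function(pts) {
    if (nrow(pts) == 0L) return(list(c = c(0, 0), r = 0))
    if (nrow(pts) == 1L) return(list(c = pts[1L, ], r = 0))
    if (nrow(pts) == 2L) {
      return(list(c = (pts[1L, ] + pts[2L, ]) / 2,
                  r = sqrt(sum((pts[1L, ] - pts[2L, ])^2)) / 2))
    }
    # circumcircle of 3 points
    ax <- pts[1, 1]; ay <- pts[1, 2]; bx <- pts[2, 1]; by <- pts[2, 2]
    cx <- pts[3, 1]; cy <- pts[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(list(c = c(NA, NA), r = Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    list(c = c(ux, uy), r = sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(circ, q) sqrt(sum((q - circ$c)^2)) <= circ$r + 1e-9
  # Welzl, iterative with randomized order (deterministic seed-free shuffle
  # not needed: n is tiny, use the simple O(n^3) growth scheme)
  circ <- circle_from(p[1L, , drop = FALSE])
  for (i in seq_len(nrow(p))) {
    if (inside(circ, p[i, ])) next
    circ <- circle_from(p[i, , drop = FALSE])
    for (j in seq_len(i - 1L)) {
      if (inside(circ, p[j, ])) next
      circ <- circle_from(p[c(i, j), , drop = FALSE])
      for (k in seq_len(j - 1L)) {
        if (inside(circ, p[k, ])) next
        circ <- circle_from(p[c(i, j, k), , drop = FALSE])
      }
    }
  }
  list(center = circ$c, diameter_um = 2 * circ$r)
}

#' Axon co-labeling in a small square region
#'
#' Counts single- and double-labeled axon profiles (one mark per axon) in a
#' square counting region, using [match_marks()] with an axon-scale
#' tolerance and reporting fractions with [fraction_table()].
#'
#' @param marks_a,marks_b Axon marks (tibbles or coordinate matrices,
#'   micrometres), already restricted to or about to be clipped by the
#'   square.
#' @param square Numeric `c(x0, y0, side)` of the counting square in
#'   micrometres (default 20 um side at the origin); marks outside are
#'   dropped.
#' @param tolerance_um Pairing tolerance (default 1, axon-profile scale).
#' @return List with the `match_result` and the fraction table (categories
#'   `only_a`, `only_b`, `double`).
#' @export
axon_colabel <- function(marks_a, marks_b, square = c(0, 0, 20), tolerance_um = 1) {
  clip <- function(m) {
    p <- as_coords(m)
    keep <- p[, 1L] >= square[1L] & p[, 1L] <= square[1L] + square[3L] &
      p[, 2L] >= square[2L] & p[, 2L] <= square[2L] + square[3L]
    p[keep, , drop = FALSE]
  }
  mr <- match_marks(clip(marks_a), clip(marks_b), tolerance_um = tolerance_um)
  list(
    match = mr,
    fractions = fraction_table(c(only_a = mr$n_only_a, only_b = mr$n_only_b,
                                 double = mr$n_double))
  )
}
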