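#' Construct an intensity profile
#'
#' A 1-D sequence of intensities along an anatomical axis, either extracted
#' from a normalized density map (locations in percent relative location) or
#' from an image line scan (locations in micrometres from the medial edge).
#'
#' @param locations Strictly increasing numeric positions.
#' @param values Intensities, same length as `locations`.
#' @param axis Anatomical orientation label.
#' @param source "density-map" or "image-channel".
#' @param section_id,channel Optional provenance.
#' @return An `intensity_profile` object.
#' @export
intensity_profile <- function(locations, values, axis = NA_character_,
                              source = c("density-map", "image-channel"),
                              section_id = NA_character_, channel = NA_character_) {
  source <- match.arg(source)
  if (length(locations) != length(values)) {
    stop("`locations` and `values` must have equal length", call. = FALSE)
  }
  if (any(diff(locations) <= 0)) {
    stop("`locations` must be strictly increasing", call. = FALSE)
  }
  structure(
    list(locations = as.numeric(locations), values = as.numeric(values),
         axis = axis, source = source, section_id = section_id, channel = channel),
    class = "intensity_profile"
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> %s (%s), %d samples in [%g, %g]\n",
              x$axis, x$source, length(x$values),
              min(x$locations), max(x$locations)))
  invisible(x)
}

#' Tonotopic band profile through a density grid
#'
#' Collapses the normalized density map to a 1-D profile along the tonotopic
#' axis by averaging, at each of the 20 bin centers (2.5, 7.5, ..., 97.5
#' percent), the bins of the orthogonal axis that fall inside a band
#' centered at 50 percent with 50 percent total width (the central quarter
#' to three-quarters of the orthogonal extent). The band center may be
#' shifted by up to +/- 10 percent to adapt to a tilted nucleus.
#'
#' @param grid A `density_grid`.
#' @param axis Profile axis: "medio-lateral" (profile runs along x) or
#'   "dorso-ventral" (along y).
#' @param width_percent Total band width orthogonal to the profile axis.
#' @param center_shift Band center displacement in percent, limited to
#'   +/- 10.
#' @return An `intensity_profile` with locations at the 20 bin centers.
#' @export
band_profile <- function(grid, axis = c("medio-lateral", "dorso-ventral"),
                         width_percent = 50, center_shift = 0) {
  stopifnot(inherits(grid, "density_grid"))
  axis <- match.arg(axis)
  if (abs(center_shift) > 10) {
    stop("`center_shift` is limited to +/- 10 percent", call. = FALSE)
  }
  center <- 50 + center_shift
  lo <- center - width_percent / 2
  hi <- center + width_percent / 2
  if (lo < 0 || hi > 100) stop("band falls outside [0, 100] after shift", call. = FALSE)
  centers <- seq(2.5, 97.5, by = 5)
  band_idx <- which(centers >= lo & centers <= hi)
  vals <- if (axis == "medio-lateral") {
    colMeans(grid$bins[band_idx, , drop = FALSE])   # band over y rows
  } else {
    rowMeans(grid$bins[, band_idx, drop = FALSE])   # band over x columns
  }
  intensity_profile(centers, vals, axis = axis, source = "density-map",
                    section_id = grid$section_id)
}

#' Curved-path profile through a density grid
#'
#' For nuclei whose tonotopic axis bends (the LSO's dorsomedial-to-ventral-
#' to-dorsolateral sweep), the profile follows a user-supplied polyline of
#' control points in the normalized frame. The path is re-sampled uniformly
#' by arc length; at each sample, the intensity is the mean of the grid bins
#' lying within a transverse window perpendicular to the local tangent
#' (half-width `width_percent / 2`) and within half a sampling step along
#' it. A straight path therefore reproduces [band_profile()] at the same
#' width.
#'
#' @param grid A `density_grid`.
#' @param path Two-column matrix of control points (x, y) in [0, 100].
#' @param width_percent Local transverse window width (default 30).
#' @param n_samples Number of arc-length samples (default 20, matching the
#'   bin centers).
#' @return An `intensity_profile` with locations 0--100 percent arc length.
#' @export
curved_profile <- function(grid, path, width_percent = 30, n_samples = 20L) {
  stopifnot(inherits(grid, "density_grid"))
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("path needs at least 2 control points", call. = FALSE)
  if (any(path < 0 | path > 100)) stop("path must stay within [0, 100]^2", call. = FALSE)

  seg <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("path has zero length", call. = FALSE)
  s <- seq(0, total, length.out = n_samples)
  sx <- stats::approx(cum, path[, 1L], xout = s, ties = "ordered")$y
  sy <- stats::approx(cum, path[, 2L], xout = s, ties = "ordered")$y

  centers <- seq(2.5, 97.5, by = 5)
  cx <- matrix(centers, nrow = 20L, ncol = 20L, byrow = TRUE)  # [y, x] -> x center
  cy <- matrix(centers, nrow = 20L, ncol = 20L)                # [y, x] -> y center
  # the along-path window is half a sampling step, but never narrower than
  # half a bin, so end samples between bin centers still see their bin
  step <- max(total / (n_samples - 1L), 5)
  half_w <- width_percent / 2

  vals <- vapply(seq_len(n_samples), function(i) {
    # central-difference tangent
    i0 <- max(i - 1L, 1L); i1 <- min(i + 1L, n_samples)
    tv <- c(sx[i1] - sx[i0], sy[i1] - sy[i0])
    tv <- tv / sqrt(sum(tv^2))
    dx <- cx - sx[i]; dy <- cy - sy[i]
    along <- dx * tv[1L] + dy * tv[2L]
    perp <- -dx * tv[2L] + dy * tv[1L]
    sel <- abs(along) <= step / 2 & abs(perp) <= half_w
    if (!any(sel)) return(NA_real_)
    mean(grid$bins[sel])
  }, numeric(1L))

  intensity_profile(100 * s / total, vals, axis = "curved-path",
                    source = "density-map", section_id = grid$section_id)
}

#' Compare profile edges (5--15 percent vs 85--95 percent)
#'
#' For each section's profile, averages the intensities at relative
#' locations within [5, 15] (medial / dorsal / dorsomedial edge) and within
#' [85, 95] (lateral / ventral / dorsolateral edge); with profiles sampled
#' at the 5 percent bin centers these windows cover the samples at 7.5 and
#' 12.5 and at 87.5 and 92.5 percent. The two per-section samples are then
#' compared with the normality-gated two-group dispatch.
#'
#' @param profiles List of `intensity_profile` objects, one per section
#'   (at least 2).
#' @return A list with per-edge means, the per-section values, the test used
#'   and its p-value.
#' @export
edge_compare <- function(profiles) {
  if (length(profiles) < 2L) stop("edge comparison needs >= 2 sections", call. = FALSE)
  edge_mean <- function(p, lo, hi) {
    sel <- p$locations >= lo & p$locations <= hi
    if (!any(sel)) return(NA_real_)
    mean(p$values[sel])
  }
  first <- vapply(profiles, edge_mean, numeric(1L), lo = 5, hi = 15)
  second <- vapply(profiles, edge_mean, numeric(1L), lo = 85, hi = 95)
  ok <- is.finite(first) & is.finite(second)
  first <- first[ok]; second <- second[ok]
  rep <- dispatch_test(grouped_measurements(
    list(first_edge = first, second_edge = second),
    measure = "normalized density", units = "a.u."
  ))
  list(
    first_edge_mean = mean(first),
    second_edge_mean = mean(second),
    per_section = tibble::tibble(section = seq_along(first),
                                 first_edge = first, second_edge = second),
    test_name = rep$test_name,
    p_value = rep$p_value
  )
}

#' Multi-channel line scan over a rectangle
#'
#' Reproduces a "Plot Profile" line scan: for each channel, the mean over
#' the rectangle's height is taken per pixel column, yielding one intensity
#' per column. The rectangle's long axis must run medio-laterally;
#' left-hemisphere scans are reversed so the output always reads
#' medial-to-lateral. Locations are micrometres from the medial edge
#' (column centers).
#'
#' @param channels Named list of image matrices (`[row, col]`), as returned
#'   by [read_image()] or the image generators.
#' @param rect Integer vector `c(x, y, w, h)`: 1-based top-left pixel column
#'   `x` and row `y`, width and height in pixels.
#' @param pixel_size_um Micrometres per pixel.
#' @param hemisphere "right" or "left".
#' @return Named list of `intensity_profile` objects, one per channel.
#' @export
line_scan <- function(channels, rect, pixel_size_um, hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  if (is.matrix(channels)) channels <- list(channel1 = channels)
  x <- rect[1L]; y <- rect[2L]; w <- rect[3L]; h <- rect[4L]
  nr <- nrow(channels[[1L]]); nc <- ncol(channels[[1L]])
  if (x < 1L || y < 1L || x + w - 1L > nc || y + h - 1L > nr) {
    stop("rectangle exceeds image bounds", call. = FALSE)
  }
  locs <- (seq_len(w) - 0.5) * pixel_size_um
  out <- lapply(names(channels), function(nm) {
    sub <- channels[[nm]][y:(y + h - 1L), x:(x + w - 1L), drop = FALSE]
    vals <- colMeans(sub)
    if (hemisphere == "left") vals <- rev(vals)
    intensity_profile(locs, vals, axis = "medio-lateral",
                      source = "image-channel", channel = nm)
  })
  names(out) <- names(channels)
  out
}

# Local maxima with topographic prominence. Plateaus are reduced to their
# midpoint. Returns a data.frame(index, height, prominence).
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), height = numeric(),
                                prominence = numeric()))
  idx <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(idx) == 0L) return(data.frame(index = integer(), height = numeric(),
                                           prominence = numeric()))
  prom <- vapply(idx, function(p) {
    h <- x[p]
    left_min <- h; k <- p
    while (k > 1L) {
      k <- k - 1L
      if (x[k] > h) break
      left_min <- min(left_min, x[k])
    }
    if (k == 1L && x[1L] <= h) left_min <- min(left_min, x[1L])
    right_min <- h; k <- p
    while (k < n) {
      k <- k + 1L
      if (x[k] > h) break
      right_min <- min(right_min, x[k])
    }
    if (k == n && x[n] <= h) right_min <- min(right_min, x[n])
    h - max(left_min, right_min)
  }, numeric(1L))
  data.frame(index = idx, height = x[idx], prominence = prom)
}

#' Detect a myelin cross-profile
#'
#' A myelinated axon cut transversally shows two bright walls (the sheath)
#' flanking a dim lumen. Given an intensity profile taken across a process,
#' the detector reports `TRUE` when exactly two dominant local maxima are
#' present, the valley between them lies in the central third of the
#' profile, the valley intensity is at most `r_center` times the lower peak,
#' and both peaks rise at least `r_peak`-fold above the background (profile
#' median). A filled (non-myelinated) process yields a single ridge and is
#' rejected.
#'
#' Peaks count as dominant when their topographic prominence is at least
#' `prominence_frac` of the profile's dynamic range.
#'
#' @param profile Numeric vector (length >= 7) of intensities across the
#'   process, e.g. a row/column average of a 5.55 x 5.55 um chip (see
#'   [chip_profile()]).
#' @param r_center Maximum valley-to-peak ratio (default 0.6).
#' @param r_peak Minimum peak-to-background ratio (default 2).
#' @param prominence_frac Prominence threshold as a fraction of the dynamic
#'   range (default 0.1).
#' @return Logical scalar.
#' @export
detect_myelin <- function(profile, r_center = 0.6, r_peak = 2,
                          prominence_frac = 0.1) {
  if (inherits(profile, "intensity_profile")) profile <- profile$values
  profile <- as.numeric(profile)
  if (length(profile) < 7L) stop("profile too short (need >= 7 samples)", call. = FALSE)
  rng <- max(profile) - min(profile)
  if (rng <= 0) return(FALSE)
  background <- stats::median(profile)
  pk <- find_peaks(profile)
  dominant <- pk[pk$prominence >= prominence_frac * rng &
                   pk$height >= r_peak * max(background, .Machine$double.eps), ,
                 drop = FALSE]
  if (nrow(dominant) != 2L) return(FALSE)
  i1 <- min(dominant$index); i2 <- max(dominant$index)
  between <- profile[i1:i2]
  valley <- min(between)
  valley_at <- i1 + which.min(between) - 1L
  n <- length(profile)
  in_center <- valley_at >= n / 3 && valley_at <= 2 * n / 3
  in_center && valley <= r_center * min(dominant$height)
}

#' Average a square chip into a cross-profile
#'
#' Collapses a small image chip to a 1-D profile perpendicular to the
#' process by averaging along the process axis. For a process running
#' vertically (down the image columns), each image column is averaged,
#' giving one intensity per horizontal position; averaging along the tube
#' suppresses pixel noise before [detect_myelin()] is applied.
#'
#' @param chip Numeric matrix.
#' @param axis Direction the process runs: "vertical" (default) or
#'   "horizontal".
#' @return Numeric vector, one value per position across the process.
#' @export
chip_profile <- function(chip, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  if (axis == "vertical") colMeans(chip) else rowMeans(chip)
}
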