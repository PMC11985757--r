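# Seeded generators emulating every input class the pipeline consumes.
# Each generator isolates the RNG (the caller's random state is restored)
# and returns its ground truth alongside the data, so downstream operations
# can be scored without re-deriving what was planted.

with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a point pattern inside a polygon
#'
#' Samples soma-center marks inside an ROI polygon, optionally with a
#' monotone linear density gradient along one normalized axis (the planted
#' analogue of an oligodendrocyte accumulation at the lateral, low-frequency
#' edge of a nucleus). Sampling is by rejection from the bounding box with
#' acceptance proportional to the linear intensity, so the planted rate
#' field is exact. Either a fixed count (`n`, the default mode: sections
#' report counts) or a Poisson draw at a given rate can be used.
#'
#' @param roi A [nucleus_roi()] (or an n x 2 polygon matrix, in which case
#'   a "synthetic" ROI is built around it).
#' @param n Number of marks (fixed-n mode).
#' @param rate Intensity per unit area (Poisson mode; used when `n` is
#'   `NULL`). The realized count is `rpois(area * rate)`.
#' @param gradient_axis `"x"`, `"y"`, or `NA` for homogeneous.
#' @param gradient_ratio Density ratio between the high (lateral/dorsal)
#'   and low edge; 1 = homogeneous; must be > 0.
#' @param marker Marker label attached to every mark.
#' @param seed RNG seed.
#' @return List with `marks` (tibble) and `truth` (planted parameters and
#'   realized count).
#' @export
gen_points <- function(roi, n = 100L, rate = NULL, gradient_axis = NA_character_,
                       gradient_ratio = 1, marker = "Olig2", seed = 1L) {
  if (!inherits(roi, "nucleus_roi")) {
    roi <- nucleus_roi("synthetic", "synthetic", as.matrix(roi))
  }
  if (!is.finite(gradient_ratio) || gradient_ratio <= 0) {
    stop("`gradient_ratio` must be > 0", call. = FALSE)
  }
  v <- roi$vertices
  bb <- apply(v, 2L, range)
  w <- bb[2L, 1L] - bb[1L, 1L]; h <- bb[2L, 2L] - bb[1L, 2L]
  with_rng(seed, {
    if (is.null(n)) {
      if (is.null(rate) || rate <= 0) stop("Poisson mode needs `rate` > 0", call. = FALSE)
      n <- stats::rpois(1L, rate * shoelace_area(v))
    }
    n <- as.integer(n)
    xs <- numeric(0); ys <- numeric(0)
    hi <- max(1, gradient_ratio)
    while (length(xs) < n) {
      m <- max(2L * (n - length(xs)), 32L)
      cx <- stats::runif(m, bb[1L, 1L], bb[2L, 1L])
      cy <- stats::runif(m, bb[1L, 2L], bb[2L, 2L])
      t <- if (identical(gradient_axis, "x")) {
        (cx - bb[1L, 1L]) / w
      } else if (identical(gradient_axis, "y")) {
        (cy - bb[1L, 2L]) / h
      } else {
        rep(0, m)
      }
      wgt <- (1 + (gradient_ratio - 1) * t) / hi
      keep <- stats::runif(m) < wgt & point_in_polygon(cx, cy, v)
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    }
    xs <- xs[seq_len(n)]; ys <- ys[seq_len(n)]
    marks <- cell_marks(roi$section_id, roi$nucleus, xs, ys,
                        markers = rep(list(marker), n))
    list(marks = marks,
         truth = list(n = n, gradient_axis = gradient_axis,
                      gradient_ratio = gradient_ratio, seed = seed))
  })
}

#' Generate a banded tri-channel nucleus image
#'
#' Emulates the layered appearance of the medial superior olive in a
#' transversal section: a central somatic band (MAP2-like channel), the
#' glutamatergic input (VGluT1-like channel) either flanking the somatic
#' band on both dendritic sides ("dendritic" mode, immature) or covering
#' the somatic band ("perisomatic" mode, mature), and an Olig2-like channel
#' that is uniform, accumulated at the VGluT1 transition borders (immature)
#' or concentrated at the somatic band (mature). Bands are Gaussian ridges
#' along the medio-lateral (column) axis plus Gaussian pixel noise.
#'
#' @param width_px,height_px Image size (defaults hold the standard
#'   600 x 120 px scan rectangle with margin).
#' @param pixel_size_um Micrometres per pixel (default 0.6).
#' @param map2_center_um Somatic band center, um from the left (medial)
#'   edge; defaults to the image center.
#' @param map2_sd_um Somatic band Gaussian sigma (default 15).
#' @param vglut1_mode "dendritic" or "perisomatic".
#' @param vglut1_offset_um Dendritic band displacement from the somatic
#'   center (default 60).
#' @param vglut1_sd_um Dendritic band sigma (default 20).
#' @param olig2_pattern "uniform", "border-accumulated" or "somatic".
#' @param amplitude Peak band intensity above baseline (default 150).
#' @param baseline Background intensity (default 20).
#' @param noise_sd Gaussian noise sigma (default 5; 0 gives a
#'   deterministic image).
#' @param seed RNG seed.
#' @return List with `channels` (named list of matrices: MAP2, VGluT1,
#'   Olig2), `pixel_size_um` and `truth` (band centers in um).
#' @export
gen_mso_image <- function(width_px = 700L, height_px = 200L, pixel_size_um = 0.6,
                          map2_center_um = NULL, map2_sd_um = 15,
                          vglut1_mode = c("dendritic", "perisomatic"),
                          vglut1_offset_um = 60, vglut1_sd_um = 20,
                          olig2_pattern = c("uniform", "border-accumulated", "somatic"),
                          amplitude = 150, baseline = 20, noise_sd = 5, seed = 1L) {
  vglut1_mode <- match.arg(vglut1_mode)
  olig2_pattern <- match.arg(olig2_pattern)
  if (is.null(map2_center_um)) map2_center_um <- width_px * pixel_size_um / 2
  x_um <- (seq_len(width_px) - 0.5) * pixel_size_um
  if (map2_center_um < min(x_um) || map2_center_um > max(x_um)) {
    stop("somatic band center falls outside the image", call. = FALSE)
  }
  gauss <- function(c0, s) exp(-((x_um - c0)^2) / (2 * s^2))

  map2_row <- baseline + amplitude * gauss(map2_center_um, map2_sd_um)
  vglut_centers <- if (vglut1_mode == "dendritic") {
    map2_center_um + c(-1, 1) * vglut1_offset_um
  } else {
    map2_center_um
  }
  if (any(vglut_centers < min(x_um)) || any(vglut_centers > max(x_um))) {
    stop("VGluT1 band(s) fall outside the image", call. = FALSE)
  }
  vglut_row <- baseline + amplitude *
    Reduce(`+`, lapply(vglut_centers, gauss, s = vglut1_sd_um))
  olig2_row <- switch(
    olig2_pattern,
    "uniform" = rep(baseline + amplitude / 3, width_px),
    # puncta accumulate where VGluT1 transitions between high and low:
    # one ridge on each side of each dendritic band
    "border-accumulated" = baseline + amplitude / 2 * Reduce(`+`, lapply(
      c(vglut_centers - vglut1_sd_um, vglut_centers + vglut1_sd_um),
      gauss, s = vglut1_sd_um / 2)),
    "somatic" = baseline + amplitude / 2 * gauss(map2_center_um, map2_sd_um)
  )
  with_rng(seed, {
    mk <- function(row) {
      img <- matrix(rep(row, each = height_px), nrow = height_px)
      if (noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                            nrow = height_px)
      pmax(img, 0)
    }
    channels <- list(MAP2 = mk(map2_row), VGluT1 = mk(vglut_row), Olig2 = mk(olig2_row))
    list(channels = channels, pixel_size_um = pixel_size_um,
         truth = list(map2_center_um = map2_center_um,
                      vglut1_centers_um = vglut_centers,
                      vglut1_mode = vglut1_mode, olig2_pattern = olig2_pattern,
                      seed = seed))
  })
}

#' Generate a myelin-chip image
#'
#' A 5.55 x 5.55 um chip containing one vertical process: either a hollow
#' tube (two bright sheath walls flanking a dim lumen -- the myelinated
#' appearance) or a filled tube (uniformly bright core -- unmyelinated).
#' Gaussian pixel noise is scaled so that
#' `snr = (wall - background) / noise_sd`.
#'
#' @param outer_width_um Outer tube width (default 1.5).
#' @param wall_fraction Wall thickness as a fraction of the outer width,
#'   in (0, 0.5) (default 0.25).
#' @param filled `TRUE` for a filled (unmyelinated) tube.
#' @param intensities Named vector `c(wall, lumen, background)`.
#' @param snr Signal-to-noise ratio (wall elevation over noise sigma).
#' @param chip_um Chip side length (default 5.55).
#' @param pixel_size_um Micrometres per pixel (default 0.05).
#' @param seed RNG seed.
#' @return List with `chip` (matrix), `pixel_size_um` and `truth`.
#' @export
gen_tube_chip <- function(outer_width_um = 1.5, wall_fraction = 0.25,
                          filled = FALSE,
                          intensities = c(wall = 200, lumen = 20, background = 10),
                          snr = 8, chip_um = 5.55, pixel_size_um = 0.05, seed = 1L) {
  if (wall_fraction <= 0 || wall_fraction >= 0.5) {
    stop("`wall_fraction` must lie in (0, 0.5)", call. = FALSE)
  }
  npx <- round(chip_um / pixel_size_um)
  x_um <- (seq_len(npx) - 0.5) * pixel_size_um - chip_um / 2
  half <- outer_width_um / 2
  wall_t <- wall_fraction * outer_width_um
  row <- rep(intensities[["background"]], npx)
  inside <- abs(x_um) <= half
  if (filled) {
    row[inside] <- intensities[["wall"]]
  } else {
    row[inside] <- intensities[["lumen"]]
    row[inside & abs(x_um) >= half - wall_t] <- intensities[["wall"]]
  }
  noise_sd <- (intensities[["wall"]] - intensities[["background"]]) / snr
  with_rng(seed, {
    chip <- matrix(rep(row, each = npx), nrow = npx)
    if (is.finite(snr)) {
      chip <- chip + matrix(stats::rnorm(npx * npx, 0, noise_sd), nrow = npx)
    }
    chip <- pmax(chip, 0)
    list(chip = chip, pixel_size_um = pixel_size_um,
         truth = list(filled = filled, outer_width_um = outer_width_um,
                      wall_fraction = wall_fraction, snr = snr, seed = seed,
                      template = row))
  })
}

#' Generate a calyx-proximity scene
#'
#' One calyx circle at the origin with `n_cells` somata placed uniformly in
#' the annulus between the calyx radius and `placement_radius_um`. Marker
#' categories (single-S100, single-Olig2, double) are drawn from the given
#' probabilities; soma diameters scatter around 17 um. The truth records
#' each cell's planted category and whether its body lies fully inside the
#' sampling circle, judged by the same containment rule written out
#' independently of [classify_proximal()].
#'
#' @param calyx_diameter_um Calyx circle diameter (default 13).
#' @param n_cells Number of surrounding cells.
#' @param probs Numeric `c(pS100only, pOlig2only, pDouble)` summing to 1.
#' @param placement_radius_um Outer annulus radius (default 35).
#' @param cell_diameter_mean_um,cell_diameter_sd_um Soma diameter
#'   distribution (default 17 +/- 1.5, truncated at 5).
#' @param seed RNG seed.
#' @return List with `scene` (a [calyx_scene()]) and `truth`.
#' @export
gen_calyx_scene <- function(calyx_diameter_um = 13, n_cells = 12L,
                            probs = c(0.4, 0.2, 0.4), placement_radius_um = 35,
                            cell_diameter_mean_um = 17, cell_diameter_sd_um = 1.5,
                            seed = 1L) {
  if (abs(sum(probs) - 1) > 1e-9) stop("`probs` must sum to 1", call. = FALSE)
  with_rng(seed, {
    r_in <- calyx_diameter_um / 2
    r_out <- placement_radius_um
    if (n_cells > 0L) {
      # uniform-in-area annulus
      r <- sqrt(stats::runif(n_cells, r_in^2, r_out^2))
      th <- stats::runif(n_cells, 0, 2 * pi)
      x <- r * cos(th); y <- r * sin(th)
      cat_idx <- sample.int(3L, n_cells, replace = TRUE, prob = probs)
      category <- c("only_S100", "only_Olig2", "double")[cat_idx]
      markers <- lapply(category, function(cc) switch(cc,
        only_S100 = "S100", only_Olig2 = "Olig2", double = c("S100", "Olig2")))
      dia <- pmax(stats::rnorm(n_cells, cell_diameter_mean_um, cell_diameter_sd_um), 5)
      cells <- cell_marks("synthetic", "MNTB", x + r_out, y + r_out,
                          markers = markers, soma_diameter_um = dia)
      # shift so coordinates stay non-negative; the calyx center shifts too
      center <- c(r_out, r_out)
      sampling_r <- (calyx_diameter_um + cell_diameter_mean_um) / 2
      in_area <- sqrt((cells$x - center[1L])^2 + (cells$y - center[2L])^2) +
        dia / 2 <= sampling_r
    } else {
      cells <- cell_marks(character(), character(), numeric(), numeric(), list())
      center <- c(r_out, r_out)
      category <- character()
      in_area <- logical()
    }
    list(scene = calyx_scene(center, calyx_diameter_um, cells),
         truth = list(category = category, in_sampling_area = in_area,
                      probs = probs, seed = seed))
  })
}

#' Generate a synthetic oligodendrocyte cell
#'
#' Builds a soma with straight radiating processes whose lengths, widths
#' and orientations are planted analytically: each primary or blind process
#' is a three-point polyline of exact length and angle from the soma;
#' secondaries attach at the midpoint of a parent primary. Width functions
#' are linear tapers sampled densely along the arc, so the five-point
#' diameter has a closed-form expectation. Myelination flags are drawn per
#' process (blind endings never myelinate).
#'
#' @param n_primary,n_secondary,n_blind Process counts.
#' @param length_mean_um,length_sd_um Primary/secondary length distribution
#'   (default 30 +/- 8, truncated at 5).
#' @param blind_length_um Blind stub length (default 3).
#' @param width_base_um,width_tip_um Taper endpoints (default 1.6 -> 0.4).
#' @param orientation_deg Optional vector of planted angles (degrees,
#'   recycled over primaries); `NULL` draws uniformly on [0, 360).
#' @param p_myelin Per-process myelination probability (default 0.8).
#' @param seed RNG seed.
#' @return List with `cell` (an [oligo_cell()]) and `truth` (counts and the
#'   exact per-process length, folded orientation and five-point diameter).
#' @export
gen_oligo_cell <- function(n_primary = 5L, n_secondary = 2L, n_blind = 3L,
                           length_mean_um = 30, length_sd_um = 8,
                           blind_length_um = 3,
                           width_base_um = 1.6, width_tip_um = 0.4,
                           orientation_deg = NULL, p_myelin = 0.8, seed = 1L) {
  if (n_secondary > 0L && n_primary == 0L) {
    stop("secondary processes need at least one primary", call. = FALSE)
  }
  with_rng(seed, {
    soma <- c(100, 100)
    taper_positions <- seq(0, 1, by = 0.1)
    taper <- function() {
      data.frame(position = taper_positions,
                 width_um = width_base_um +
                   (width_tip_um - width_base_um) * taper_positions)
    }
    five_point_mean <- mean(width_base_um +
                              (width_tip_um - width_base_um) * c(.1, .3, .5, .7, .9))
    straight <- function(from, L, theta_deg) {
      d <- c(cos(theta_deg * pi / 180), sin(theta_deg * pi / 180))
      rbind(from, from + 0.5 * L * d, from + L * d)
    }
    fold <- function(theta) {
      a <- theta %% 180
      if (a > 90) 180 - a else a
    }
    traces <- list()
    truth_rows <- list()
    angles <- if (is.null(orientation_deg)) {
      stats::runif(n_primary + n_secondary + n_blind, 0, 360)
    } else {
      rep_len(orientation_deg, n_primary + n_secondary + n_blind)
    }
    lens <- pmax(stats::rnorm(n_primary + n_secondary, length_mean_um, length_sd_um), 5)
    myel <- stats::runif(n_primary + n_secondary) < p_myelin
    k <- 0L
    for (i in seq_len(n_primary)) {
      k <- k + 1L
      id <- sprintf("p%02d", i)
      traces[[k]] <- process_trace(id, "primary",
                                   straight(soma, lens[k], angles[k]),
                                   width_samples = taper(), myelinating = myel[k])
      truth_rows[[k]] <- data.frame(trace_id = id, kind = "primary",
                                    length_um = lens[k],
                                    orientation_deg = fold(angles[k]),
                                    diameter_um = five_point_mean,
                                    myelinating = myel[k])
    }
    for (i in seq_len(n_secondary)) {
      k <- k + 1L
      parent <- traces[[sample.int(n_primary, 1L)]]
      id <- sprintf("s%02d", i)
      origin <- parent$polyline[2L, ]  # parent midpoint
      traces[[k]] <- process_trace(id, "secondary",
                                   straight(origin, lens[k], angles[k]),
                                   parent_id = parent$trace_id,
                                   width_samples = taper(), myelinating = myel[k])
      truth_rows[[k]] <- data.frame(trace_id = id, kind = "secondary",
                                    length_um = lens[k],
                                    orientation_deg = fold(angles[k]),
                                    diameter_um = five_point_mean,
                                    myelinating = myel[k])
    }
    for (i in seq_len(n_blind)) {
      k <- k + 1L
      id <- sprintf("b%02d", i)
      traces[[k]] <- process_trace(id, "blind",
                                   straight(soma, blind_length_um, angles[k]),
                                   width_samples = taper(), myelinating = FALSE)
      truth_rows[[k]] <- data.frame(trace_id = id, kind = "blind",
                                    length_um = blind_length_um,
                                    orientation_deg = fold(angles[k]),
                                    diameter_um = five_point_mean,
                                    myelinating = FALSE)
    }
    cell <- oligo_cell("synthetic", soma, traces)
    list(cell = cell,
         truth = list(
           counts = c(primary = n_primary, secondary = n_secondary,
                      blind = n_blind, myelinating = sum(myel)),
           processes = do.call(rbind, truth_rows),
           seed = seed))
  })
}
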