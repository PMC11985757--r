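# Independent oracles and fixture builders shared across the suite.
# Every oracle here re-derives its quantity from first principles, without
# touching the package implementation it is used to check.

# Square ROI with corners (x0, y0) and (x0 + side, y0 + side).
square_roi <- function(side = 100, x0 = 0, y0 = 0, section = "s1",
                       nucleus = "MNTB", ...) {
  nucleus_roi(section, nucleus,
              rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
                    c(x0, y0 + side)), ...)
}

# Star-shaped (hence simple) random polygon: random radii at sorted angles.
random_polygon <- function(n_vertices = 12, r_min = 20, r_max = 60,
                           center = c(80, 80)) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_min, r_max)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# Winding-number point-in-polygon (angle summation) -- an algorithm
# different from the package's even-odd crossing test. Boundary points are
# classified inside to match the package convention.
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  vapply(seq_along(px), function(k) {
    dx <- v[, 1] - px[k]; dy <- v[, 2] - py[k]
    # boundary: point on a segment
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      cross <- dx[i] * dy[j] - dx[j] * dy[i]
      dot <- dx[i] * (px[k] - v[j, 1]) + dy[i] * (py[k] - v[j, 2])
      if (cross == 0 &&
          px[k] >= min(v[i, 1], v[j, 1]) && px[k] <= max(v[i, 1], v[j, 1]) &&
          py[k] >= min(v[i, 2], v[j, 2]) && py[k] <= max(v[i, 2], v[j, 2])) {
        return(TRUE)
      }
    }
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi  # winding number != 0
  }, logical(1))
}

# Vectorized crossing count used only inside the Monte-Carlo area oracle
# (the per-point loop would be too slow at 1e6+ samples).
pip_vectorized <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  xs <- v[, 1]; ys <- v[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  for (i in seq_len(n)) {
    crosses <- (ys[i] > py) != (ye[i] > py)
    xint <- xs[i] + (py - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
    inside <- xor(inside, crosses & (px < xint))
  }
  inside
}

# Monte-Carlo rasterization oracle for polygon area (bounding-box fraction).
oracle_mc_area <- function(v, n_samples = 1e6, chunks = 1) {
  bb <- apply(v, 2, range)
  hits <- 0
  per <- ceiling(n_samples / chunks)
  for (ch in seq_len(chunks)) {
    px <- stats::runif(per, bb[1, 1], bb[2, 1])
    py <- stats::runif(per, bb[1, 2], bb[2, 2])
    hits <- hits + sum(pip_vectorized(px, py, v))
  }
  (bb[2, 1] - bb[1, 1]) * (bb[2, 2] - bb[1, 2]) * hits / (per * chunks)
}

# Projection-sweep Feret oracle: caliper widths over a 0.1-degree grid,
# then recursively refined around the extremes (the width function has a
# linear cusp at its minimum, so the coarse grid alone localizes the
# minimum only to ~1e-4 relative).
oracle_feret_sweep <- function(pts, step_deg = 0.1, refine = 5) {
  width_at <- function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    max(proj) - min(proj)
  }
  sweep_range <- function(lo, hi, n) {
    th <- seq(lo, hi, length.out = n)
    list(th = th, w = vapply(th, width_at, numeric(1)))
  }
  s <- sweep_range(0, pi, ceiling(180 / step_deg) + 1)
  lo_min <- s$th[which.min(s$w)]; lo_max <- s$th[which.max(s$w)]
  h <- step_deg * pi / 180
  for (i in seq_len(refine)) {
    sm <- sweep_range(lo_min - h, lo_min + h, 41)
    lo_min <- sm$th[which.min(sm$w)]
    sx <- sweep_range(lo_max - h, lo_max + h, 41)
    lo_max <- sx$th[which.max(sx$w)]
    h <- h / 20
  }
  c(min = width_at(lo_min), max = width_at(lo_max))
}

# Exhaustive maximum-cardinality, minimum-total-distance assignment oracle
# for small point-matching scenes (<= ~8 points per side).
oracle_assignment <- function(pa, pb, tolerance) {
  na <- nrow(pa); nb <- nrow(pb)
  if (na == 0 || nb == 0) return(0L)
  d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  best <- 0L
  recurse <- function(i, used_b, count) {
    if (i > na) {
      best <<- max(best, count)
      return(invisible())
    }
    # prune: even pairing everything left cannot beat best
    if (count + (na - i + 1L) <= best) return(invisible())
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] <= tolerance) {
        used_b[j] <- TRUE
        recurse(i + 1L, used_b, count + 1L)
        used_b[j] <- FALSE
      }
    }
    recurse(i + 1L, used_b, count)
  }
  recurse(1L, logical(nb), 0L)
  best
}

# Star-shaped cell: n straight primaries radiating from the soma.
star_cell <- function(n = 5, length_um = 20, myelinating = TRUE) {
  soma <- c(0, 0)
  traces <- lapply(seq_len(n), function(i) {
    th <- 2 * pi * (i - 1) / n
    process_trace(paste0("p", i), "primary",
                  rbind(soma, length_um * c(cos(th), sin(th))),
                  myelinating = myelinating)
  })
  oligo_cell("star", soma, traces)
}

# Brute-force band mean over a 20x20 grid: literal double loop.
oracle_band_mean <- function(bins, axis, lo, hi) {
  centers <- seq(2.5, 97.5, by = 5)
  out <- numeric(20)
  for (u in 1:20) {
    acc <- c()
    for (o in 1:20) {
      if (centers[o] >= lo && centers[o] <= hi) {
        acc <- c(acc, if (axis == "medio-lateral") bins[o, u] else bins[u, o])
      }
    }
    out[u] <- mean(acc)
  }
  out
}

# Planted co-labeling scene: n cells on a jittered grid, a fraction double-
# labeled; returns the two coordinate sets and the planted double count.
planted_colabel_scene <- function(n = 200, frac_double = 0.6, jitter_sd = 1,
                                  spacing = 15) {
  side <- ceiling(sqrt(n))
  gx <- ((seq_len(n) - 1) %% side) * spacing
  gy <- ((seq_len(n) - 1) %/% side) * spacing
  n_double <- round(frac_double * n)
  is_double <- sample(c(rep(TRUE, n_double), rep(FALSE, n - n_double)))
  a_idx <- which(is_double | stats::runif(n) < 0.5)  # singles split between sets
  a <- cbind(gx[a_idx], gy[a_idx])
  b_idx <- which(is_double | !(seq_len(n) %in% a_idx))
  b <- cbind(gx[b_idx] + stats::rnorm(length(b_idx), 0, jitter_sd),
             gy[b_idx] + stats::rnorm(length(b_idx), 0, jitter_sd))
  list(a = a, b = b, n_double = n_double,
       n_total = n)
}

# One gradient-experiment replicate: n_sections point patterns with the
# given lateral:medial ratio, turned into per-section density grids and
# band profiles, then edge-compared.
gradient_replicate <- function(n_sections = 14, n_marks = 150, ratio = 2,
                               seed = 1) {
  roi <- square_roi(side = 200)
  profiles <- lapply(seq_len(n_sections), function(s) {
    gp <- gen_points(roi, n = n_marks, gradient_axis = "x",
                     gradient_ratio = ratio, seed = seed * 1000 + s)
    grid <- section_density_grid(gp$marks, roi)
    band_profile(grid, axis = "medio-lateral")
  })
  edge_compare(profiles)
}
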