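mk_grid <- function(bins, section = "s1") {
  # build a density_grid around a prescribed [0, 1] bin matrix by scaling
  # to integer counts; max must be 1 for a faithful reconstruction
  counts <- round(bins * 1000)
  normalize_grid(matrix(as.integer(counts), 20, 20), section, "MNTB")
}

test_that("band profiles average the central orthogonal band", {
  uniform <- mk_grid(matrix(1, 20, 20))
  p <- band_profile(uniform, "medio-lateral")
  expect_equal(p$values, rep(1, 20))
  expect_equal(p$locations, seq(2.5, 97.5, by = 5))

  halves <- matrix(0, 20, 20)
  halves[, 1:10] <- 1   # left half (x < 50) dense
  p2 <- band_profile(mk_grid(halves), "medio-lateral")
  expect_equal(p2$values[1:10], rep(1, 10))
  expect_equal(p2$values[11:20], rep(0, 10))

  set.seed(21)
  rnd <- matrix(runif(400), 20, 20); rnd[1, 1] <- 1
  g <- mk_grid(rnd)
  for (axis in c("medio-lateral", "dorso-ventral")) {
    got <- band_profile(g, axis)$values
    want <- oracle_band_mean(g$bins, axis, 25, 75)
    expect_equal(got, want, tolerance = 1e-12)
  }

  # center shift moves the band; beyond the frame it errors
  shifted <- band_profile(g, "medio-lateral", center_shift = 10)
  expect_equal(shifted$values, oracle_band_mean(g$bins, "medio-lateral", 35, 85),
               tolerance = 1e-12)
  expect_error(band_profile(g, "medio-lateral", center_shift = 11), "10 percent")
  expect_error(band_profile(g, "medio-lateral", width_percent = 90,
                            center_shift = 10), "outside")
})

test_that("band profile is linear: profile of average equals average of profiles", {
  set.seed(31)
  grids <- lapply(1:6, function(i) {
    m <- matrix(runif(400), 20, 20); m[sample(400, 1)] <- 1
    mk_grid(m, section = paste0("s", i))
  })
  avg_then_profile <- band_profile(average_grids(grids), "dorso-ventral")$values
  profile_then_avg <- rowMeans(vapply(grids, function(g) {
    band_profile(g, "dorso-ventral")$values
  }, numeric(20)))
  expect_equal(avg_then_profile, profile_then_avg, tolerance = 1e-12)
})

test_that("curved profiles reduce to band profiles on straight paths", {
  set.seed(41)
  rnd <- matrix(runif(400), 20, 20); rnd[7, 7] <- 1
  g <- mk_grid(rnd)

  straight <- cbind(seq(2.5, 97.5, length.out = 20), rep(50, 20))
  pc <- curved_profile(g, straight, width_percent = 30)
  pb <- band_profile(g, "medio-lateral", width_percent = 30)
  expect_equal(pc$values, pb$values, tolerance = 1e-12)

  flat <- curved_profile(mk_grid(matrix(1, 20, 20)), rbind(c(5, 50), c(95, 50)))
  expect_equal(flat$values, rep(1, length(flat$values)))

  expect_error(curved_profile(g, rbind(c(-5, 50), c(50, 50))), "within")
  expect_error(curved_profile(g, rbind(c(5, 50))), "2 control points")
})

test_that("a U-shaped path reads out the density painted along it", {
  # paint a U through the grid, sample the curved profile on the same U
  u_path <- rbind(c(15, 80), c(15, 20), c(50, 12), c(85, 20), c(85, 80))
  centers <- seq(2.5, 97.5, by = 5)
  bins <- matrix(0, 20, 20)
  # rasterize the path with a generous brush matching the window half-width
  seg <- sqrt(rowSums(diff(u_path)^2))
  cum <- c(0, cumsum(seg))
  s <- seq(0, max(cum), length.out = 400)
  sx <- approx(cum, u_path[, 1], xout = s)$y
  sy <- approx(cum, u_path[, 2], xout = s)$y
  for (iy in 1:20) for (ix in 1:20) {
    d2 <- min((centers[ix] - sx)^2 + (centers[iy] - sy)^2)
    if (d2 <= 15^2) bins[iy, ix] <- 1
  }
  g <- mk_grid(bins)
  p <- curved_profile(g, u_path, width_percent = 30)
  # on-path windows sit inside the painted corridor: high mean everywhere
  expect_true(all(p$values > 0.8))
})

test_that("edge comparison contrasts the 5-15 and 85-95 percent windows", {
  flat <- lapply(1:4, function(i) {
    intensity_profile(seq(2.5, 97.5, by = 5), rep(0.5, 20))
  })
  symm <- edge_compare(flat)
  expect_equal(symm$first_edge_mean - symm$second_edge_mean, 0)

  # the windows cover exactly the samples at 7.5/12.5 and 87.5/92.5
  vals <- seq(0.05, 1, by = 0.05)
  p <- intensity_profile(seq(2.5, 97.5, by = 5), vals)
  ec <- edge_compare(list(p, p, p))
  expect_equal(ec$first_edge_mean, mean(vals[c(2, 3)]))
  expect_equal(ec$second_edge_mean, mean(vals[c(18, 19)]))

  expect_error(edge_compare(list(p)), ">= 2 sections")
})

test_that("edge comparison detects a planted 2:1 gradient and controls the null", {
  # sign recovery at the study's section count; full replicate sweep in the
  # acceptance suite
  hits <- vapply(1:10, function(r) {
    ec <- gradient_replicate(n_sections = 14, n_marks = 150, ratio = 2, seed = r)
    ec$second_edge_mean > ec$first_edge_mean && ec$p_value < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("line scans average columns over the rectangle height", {
  const <- matrix(7, 40, 60)
  ls <- line_scan(const, rect = c(5, 5, 30, 20), pixel_size_um = 0.5)
  expect_equal(ls[[1]]$values, rep(7, 30))
  expect_equal(ls[[1]]$locations, (1:30 - 0.5) * 0.5)

  stripes <- matrix(rep(1:60, each = 40), 40, 60)  # column index as value
  ls2 <- line_scan(stripes, c(11, 1, 10, 40), pixel_size_um = 1)
  expect_equal(ls2[[1]]$values, 11:20)

  expect_error(line_scan(const, c(50, 5, 30, 20), 0.5), "bounds")
})

test_that("line scans are equivariant under mirroring plus hemisphere toggle", {
  set.seed(51)
  img <- matrix(runif(40 * 100), 40, 100)
  rect <- c(11, 3, 70, 30)
  right <- line_scan(list(ch = img), rect, 0.6, hemisphere = "right")
  mirrored <- img[, rev(seq_len(ncol(img)))]
  rect_m <- c(ncol(img) - (rect[1] + rect[3] - 1) + 1, rect[2], rect[3], rect[4])
  left <- line_scan(list(ch = mirrored), rect_m, 0.6, hemisphere = "left")
  expect_equal(left$ch$values, right$ch$values, tolerance = 1e-12)
})

test_that("synthetic nucleus images produce the expected band structure", {
  im <- gen_mso_image(vglut1_mode = "dendritic", olig2_pattern = "border-accumulated",
                      noise_sd = 2, seed = 6)
  px <- im$pixel_size_um
  rect <- c(51, 41, 600, 120)
  ls <- line_scan(im$channels, rect, px)
  rect_offset_um <- (rect[1] - 1) * px

  map2 <- ls$MAP2$values
  map2_peak_um <- ls$MAP2$locations[which.max(map2)] + rect_offset_um
  expect_lt(abs(map2_peak_um - im$truth$map2_center_um), 5)

  vg <- ls$VGluT1$values
  pk <- glioquant:::find_peaks(vg)
  dom <- pk[pk$prominence > 0.2 * (max(vg) - min(vg)), ]
  expect_equal(nrow(dom), 2L)
  pos_um <- ls$VGluT1$locations[dom$index] + rect_offset_um
  expect_lt(abs(min(pos_um) - min(im$truth$vglut1_centers_um)), 5)
  expect_lt(abs(max(pos_um) - max(im$truth$vglut1_centers_um)), 5)
  # MAP2 maximum lies between the two VGluT1 maxima
  expect_true(map2_peak_um > min(pos_um) && map2_peak_um < max(pos_um))

  peri <- gen_mso_image(vglut1_mode = "perisomatic", noise_sd = 2, seed = 7)
  lsp <- line_scan(peri$channels, rect, px)
  vg_peak_um <- lsp$VGluT1$locations[which.max(lsp$VGluT1$values)] + rect_offset_um
  map2_peak2 <- lsp$MAP2$locations[which.max(lsp$MAP2$values)] + rect_offset_um
  expect_lt(abs(vg_peak_um - map2_peak2), 5)
})

test_that("the myelin detector separates hollow from filled cross-profiles", {
  hollow <- gen_tube_chip(filled = FALSE, snr = 8, seed = 61)
  expect_true(detect_myelin(chip_profile(hollow$chip)))

  filled <- gen_tube_chip(filled = TRUE, snr = 8, seed = 62)
  expect_false(detect_myelin(chip_profile(filled$chip)))

  flat <- matrix(10, 50, 50)
  expect_false(detect_myelin(chip_profile(flat)))
  expect_false(detect_myelin(rep(0, 50)))
  expect_error(detect_myelin(c(1, 2, 1)), "7 samples")
})
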