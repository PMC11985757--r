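test_that("overlay matching handles the degenerate extremes", {
  pts <- cbind(runif(8, 0, 50), runif(8, 0, 50))
  same <- match_marks(pts, pts, tolerance_um = 5)
  expect_equal(same$n_double, 8L)
  expect_equal(same$n_only_a, 0L)
  expect_equal(same$n_only_b, 0L)

  far <- match_marks(pts, pts + 100, tolerance_um = 5)
  expect_equal(far$n_double, 0L)
  expect_equal(far$n_only_a, 8L)

  empty <- match_marks(pts[0, , drop = FALSE], pts, tolerance_um = 5)
  expect_equal(empty$n_double, 0L)
  expect_equal(empty$n_only_b, 8L)
})

test_that("matching is symmetric and monotone in tolerance", {
  set.seed(71)
  for (r in 1:10) {
    a <- cbind(runif(12, 0, 40), runif(12, 0, 40))
    b <- cbind(runif(15, 0, 40), runif(15, 0, 40))
    ab <- match_marks(a, b, 6)
    ba <- match_marks(b, a, 6)
    expect_equal(ab$n_double, ba$n_double)
    tols <- c(0.5, 1, 2, 4, 8, 16, 64)
    doubles <- vapply(tols, function(t) match_marks(a, b, t)$n_double, integer(1))
    expect_true(all(diff(doubles) >= 0))
  }
})

test_that("greedy matching agrees with the exhaustive assignment oracle on small scenes", {
  set.seed(72)
  for (r in 1:40) {
    # planted scene at soma scale: separated cells, small channel jitter
    n <- sample(3:10, 1)
    sc <- planted_colabel_scene(n = n, frac_double = runif(1, 0.3, 0.9),
                                jitter_sd = 1, spacing = 15)
    got <- match_marks(sc$a, sc$b, tolerance_um = 5)$n_double
    want <- oracle_assignment(sc$a, sc$b, tolerance = 5)
    expect_equal(got, want)
  }
})

test_that("a planted co-labeled fraction is recovered from the overlay", {
  set.seed(73)
  errs <- vapply(1:20, function(r) {
    sc <- planted_colabel_scene(n = 200, frac_double = 0.6, jitter_sd = 1)
    mr <- match_marks(sc$a, sc$b, tolerance_um = 5)
    total <- mr$n_only_a + mr$n_only_b + mr$n_double
    100 * mr$n_double / total - 60
  }, numeric(1))
  expect_lt(abs(mean(errs)), 3)
})

test_that("fraction tables convert overlay counts to percentages", {
  ft <- fraction_table(c(only_A = 10, only_B = 0, double = 10))
  expect_equal(ft$percent, c(50, 0, 50))
  expect_equal(sum(ft$percent), 100)

  expect_equal(fraction_table(c(a = 0, b = 0, double = 20))$percent, c(0, 0, 100))
  # triple-marker categories pass through unchanged
  tri <- fraction_table(c(s100 = 1, olig2_sox10 = 2, sox10_s100 = 3,
                          olig2_s100 = 2, triple = 2))
  expect_equal(sum(tri$percent), 100)
  expect_error(fraction_table(c(a = 0, b = 0)), "empty")
})

test_that("the sampling circle adds the average soma diameter", {
  expect_equal(sampling_circle(13, 17)$diameter_um, 30)
  expect_equal(sampling_circle(20, 17)$diameter_um, 37)
  expect_equal((sampling_circle(20, 17)$diameter_um / 20)^2, (37 / 20)^2)
  expect_error(sampling_circle(13, 0), "positive")
  expect_error(sampling_circle(-1, 17), "positive")
})

test_that("calyx-proximity classification requires the soma fully inside", {
  cells <- cell_marks("s", "MNTB", c(50, 50 + 12), c(50, 50),
                      markers = list("S100", c("S100", "Olig2")),
                      soma_diameter_um = c(6, 10))
  sc <- calyx_scene(c(50, 50), calyx_diameter_um = 13, cells = cells)
  # sampling radius = (13 + 17)/2 = 15
  res <- classify_proximal(sc)
  # cell 1: dist 0 + r 3 <= 15 -> counted; cell 2: 12 + 5 = 17 > 15 -> out
  expect_equal(res$count[res$category == "only_S100"], 1L)
  expect_equal(attr(res, "total"), 1L)
  expect_equal(attr(res, "sampling_diameter_um"), 30)

  # center inside but body crossing the boundary is excluded
  crossing <- cell_marks("s", "MNTB", 50 + 14, 50, list("Olig2"),
                         soma_diameter_um = 4)
  res2 <- classify_proximal(calyx_scene(c(50, 50), 13, crossing))
  expect_equal(attr(res2, "total"), 0L)
})

test_that("proximity counts are rotation invariant and match the scene truth", {
  for (r in 1:100) {
    g <- gen_calyx_scene(n_cells = 15, seed = 200 + r)
    res <- classify_proximal(g$scene)
    expect_equal(attr(res, "total"), sum(g$truth$in_sampling_area))
    want <- table(factor(g$truth$category[g$truth$in_sampling_area],
                         levels = c("only_S100", "only_Olig2", "double")))
    expect_equal(res$count, as.integer(want))
  }

  g <- gen_calyx_scene(n_cells = 20, seed = 999)
  sc <- g$scene
  th <- 0.7
  rot <- sc
  dx <- sc$cells$x - sc$calyx_center[1]; dy <- sc$cells$y - sc$calyx_center[2]
  rot$cells$x <- sc$calyx_center[1] + cos(th) * dx - sin(th) * dy
  rot$cells$y <- sc$calyx_center[2] + sin(th) * dx + cos(th) * dy
  expect_equal(classify_proximal(rot)$count, classify_proximal(sc)$count)
})

test_that("shrinking the soma recovers center-in-circle membership", {
  g <- gen_calyx_scene(n_cells = 30, seed = 77)
  sc <- g$scene
  sc$cells$soma_diameter_um <- rep(1e-9, nrow(sc$cells))
  res <- classify_proximal(sc, default_cell_diameter_um = 17)
  r_samp <- sampling_circle(sc$calyx_diameter_um, 17)$radius_um
  d <- sqrt((sc$cells$x - sc$calyx_center[1])^2 + (sc$cells$y - sc$calyx_center[2])^2)
  expect_equal(attr(res, "total"), sum(d <= r_samp))
})

test_that("cells without a measured soma get the configured default", {
  cells <- cell_marks("s", "MNTB", 50, 50, list("Olig2"))
  expect_true(all(is.na(cells$soma_diameter_um)))
  res <- classify_proximal(calyx_scene(c(50, 50), 13, cells))
  expect_equal(attr(res, "total"), 1L)  # dist 0 + 8.5 <= 15
  res_big <- classify_proximal(calyx_scene(c(50, 50), 13, cells),
                               default_cell_diameter_um = 40)
  # sampling radius grows too ((13 + 40)/2 = 26.5), dist 0 + 20 still inside
  expect_equal(attr(res_big, "total"), 1L)
})

test_that("the minimal enclosing circle bounds a calyx outline", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  outline <- cbind(10 + 6.5 * cos(th), 20 + 6.5 * sin(th))
  circ <- enclosing_circle(outline)
  expect_equal(circ$diameter_um, 13, tolerance = 1e-6)
  expect_equal(circ$center, c(10, 20), tolerance = 1e-6)
})

test_that("axon co-labeling restricted to the counting square", {
  set.seed(81)
  pts <- cbind(runif(30, 0, 20), runif(30, 0, 20))
  dup <- axon_colabel(pts, pts, square = c(0, 0, 20))
  expect_equal(dup$fractions$percent[dup$fractions$category == "double"], 100)

  grid <- as.matrix(expand.grid(seq(2, 18, 4), seq(2, 14, 4)))
  shifted <- grid + cbind(rep(2, nrow(grid)), 0)  # 2 um apart everywhere
  disjoint <- axon_colabel(grid, shifted, square = c(0, 0, 20), tolerance_um = 1)
  expect_equal(disjoint$fractions$percent[disjoint$fractions$category == "double"], 0)

  # marks outside the square are ignored
  outside <- rbind(pts, c(50, 50))
  clip <- axon_colabel(outside, pts, square = c(0, 0, 20))
  expect_equal(clip$match$n_only_a, 0L)
})

test_that("near-total planted axon overlap is recovered at n = 300", {
  set.seed(82)
  n <- 300
  base <- cbind(runif(n, 0, 20), runif(n, 0, 20))
  is_double <- runif(n) < 0.99
  a <- base
  b <- base[is_double, , drop = FALSE] +
    matrix(rnorm(2 * sum(is_double), 0, 0.1), ncol = 2)
  res <- axon_colabel(a, b, square = c(-1, -1, 23), tolerance_um = 1)
  frac <- res$match$n_double / n * 100
  ci_half <- 100 * 1.96 * sqrt(0.99 * 0.01 / n)
  expect_lt(abs(frac - 99), ci_half + 1)
})
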