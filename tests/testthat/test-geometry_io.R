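test_that("marks CSV round-trips bit-exactly and tolerates malformed rows", {
  m <- cell_marks("s1", "MNTB", c(10, 1 / 3, 200.123456789012), c(20, 2 / 7, 5),
                  markers = list("Olig2", c("Olig2", "SOX10"), "S100"),
                  soma_diameter_um = c(NA, 17, 16.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_marks(m, f)
  back <- read_marks(f)
  expect_identical(back$x, m$x)
  expect_identical(back$y, m$y)
  expect_identical(back$markers, m$markers)

  # single trivial row
  writeLines(c("section_id,nucleus,x,y,markers", "s1,MNTB,10,20,Olig2"), f)
  one <- read_marks(f)
  expect_equal(nrow(one), 1L)
  expect_equal(one$markers[[1]], "Olig2")

  # header only
  writeLines("section_id,nucleus,x,y,markers", f)
  expect_equal(nrow(read_marks(f)), 0L)

  # one bad row among five is skipped with a line-numbered warning
  writeLines(c("section_id,nucleus,x,y,markers",
               "s1,MNTB,1,1,Olig2", "s1,MNTB,2,2,Olig2",
               "s1,MNTB,oops,3,Olig2",
               "s1,MNTB,4,4,Olig2", "s1,MNTB,5,5,Olig2"), f)
  expect_warning(got <- read_marks(f), "line\\(s\\) 4")
  expect_equal(nrow(got), 4L)
  expect_equal(attr(got, "skipped"), 4L)

  # missing required column is a hard error
  writeLines(c("section_id,x,y,markers", "s1,1,1,Olig2"), f)
  expect_error(read_marks(f), "nucleus")
})

test_that("reader flips image-frame y once at ingest when height is known", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("section_id,nucleus,x,y,markers", "s1,MNTB,10,30,Olig2"), f)
  frame <- section_frame("s1", 0.6, image_height_px = 100)
  expect_equal(read_marks(f, frame)$y, 70)
  expect_equal(read_marks(f)$y, 30)  # no height, no flip
})

test_that("Fiji Results tables import through the X/Y columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("X,Y,Area", "12.5,40,100", "13,41,110"), f)
  m <- read_fiji_results(f, "s1", "MSO", "Olig2")
  expect_equal(m$x, c(12.5, 13))
  expect_equal(m$markers[[1]], "Olig2")
})

test_that("polygon area matches closed forms and scales with pixel size", {
  frame1 <- section_frame("s1", 1)
  sq <- nucleus_roi("s1", "MNTB", rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(polygon_area(sq, frame1)$area_um2, 1)
  tri <- nucleus_roi("s1", "MNTB", rbind(c(0, 0), c(4, 0), c(0, 3)))
  expect_equal(polygon_area(tri, frame1)$area_um2, 6)
  expect_equal(polygon_area(tri, frame1)$area_mm2, 6e-6)
  frame2 <- section_frame("s1", 2.5)
  expect_equal(polygon_area(tri, frame2)$area_um2, 6 * 2.5^2)

  # invariance under vertex reversal and translation
  v <- random_polygon()
  a1 <- polygon_area(nucleus_roi("s", "n", v), frame1)$area_um2
  a2 <- polygon_area(nucleus_roi("s", "n", v[rev(seq_len(nrow(v))), ]), frame1)$area_um2
  a3 <- polygon_area(nucleus_roi("s", "n", sweep(v, 2, c(500, -30), "+")), frame1)$area_um2
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("random 12-gon area agrees with the Monte-Carlo rasterization oracle", {
  set.seed(42)
  v <- random_polygon(12)
  area <- polygon_area(nucleus_roi("s", "n", v), section_frame("s", 1))$area_um2
  mc <- oracle_mc_area(v, n_samples = 1e6)
  expect_lt(abs(area - mc) / area, 0.005)
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(nucleus_roi("s", "n", bowtie), "self-intersecting")
})

test_that("point_in_roi matches the winding-number oracle on random polygons", {
  set.seed(7)
  for (rep in 1:20) {
    v <- random_polygon(sample(5:14, 1))
    roi <- nucleus_roi("s", "n", v)
    bb <- apply(v, 2, range)
    px <- runif(50, bb[1, 1] - 5, bb[2, 1] + 5)
    py <- runif(50, bb[1, 2] - 5, bb[2, 2] + 5)
    got <- point_in_roi(cell_marks("s", "n", pmax(px, 0), pmax(py, 0),
                                   rep(list("Olig2"), 50)), roi)
    want <- oracle_point_in_polygon(pmax(px, 0), pmax(py, 0), v)
    expect_identical(got, want)
  }
  # centroid of a convex polygon is inside; far point is outside
  conv <- rbind(c(10, 10), c(50, 12), c(55, 60), c(12, 55))
  roi <- nucleus_roi("s", "n", conv)
  expect_true(point_in_roi(colMeans(conv), roi))
  expect_false(point_in_roi(c(500, 500), roi))
  # boundary point counts as inside
  expect_true(point_in_roi(c(30, 10.5), nucleus_roi("s", "n", rbind(
    c(10, 10.5), c(50, 10.5), c(30, 40)))))
})

test_that("coordinate normalization maps the bounding box to [0, 100]", {
  roi <- square_roi(side = 80, x0 = 20, y0 = 40)
  m <- cell_marks("s1", "MNTB", c(20, 60, 40), c(40, 80, 40),
                  rep(list("Olig2"), 3))
  norm <- normalize_coordinates(m, roi)
  expect_equal(norm$rx, c(0, 50, 25))
  expect_equal(norm$ry, c(0, 50, 0))

  # scale invariance: scaling marks and ROI jointly leaves rx/ry unchanged
  roi2 <- square_roi(side = 160, x0 = 40, y0 = 80)
  m2 <- cell_marks("s1", "MNTB", m$x * 2, m$y * 2, m$markers)
  expect_equal(normalize_coordinates(m2, roi2), norm)

  # left hemisphere mirrors x so that +x is lateral everywhere
  roi_l <- square_roi(side = 80, x0 = 20, y0 = 40, hemisphere = "left")
  norm_l <- normalize_coordinates(m, roi_l)
  expect_equal(norm_l$rx, 100 - norm$rx)

  # y inversion re-anchors at the bbox
  expect_equal(normalize_coordinates(m, roi, invert_y = TRUE)$ry, 100 - norm$ry)

  # degenerate bbox
  expect_error(nucleus_roi("s", "n", rbind(c(0, 0), c(0, 5), c(0, 9))), "area")
  expect_error(normalize_coordinates(
    cell_marks("s", "n", 500, 1, list("Olig2")), roi), "bounding box")
})

test_that("ROI files read in both CSV and JSON dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("section_id,nucleus,vertex_index,x,y",
               "s1,MNTB,1,0,0", "s1,MNTB,2,10,0", "s1,MNTB,3,10,10",
               "s1,MSO,1,20,20", "s1,MSO,2,40,20", "s1,MSO,3,30,50"), f)
  meta <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("section_id,nucleus,hemisphere,axis_spec",
               "s1,MSO,left,dorso-ventral"), meta)
  rois <- read_rois(f, metadata = meta)
  expect_length(rois, 2L)
  expect_equal(rois[[2]]$hemisphere, "left")
  expect_equal(rois[[2]]$axis_spec, "dorso-ventral")
  expect_equal(rois[[1]]$hemisphere, "right")

  j <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(
    section_id = "s2", nucleus = "LSO", hemisphere = "right",
    axis_spec = "curved-path",
    vertices = list(c(0, 0), c(5, 0), c(5, 5))
  )), j, auto_unbox = TRUE)
  rois_j <- read_rois(j)
  expect_equal(rois_j[[1]]$nucleus, "LSO")
  expect_equal(nrow(rois_j[[1]]$vertices), 3L)
})

test_that("config files supply defaults for missing keys", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("pixel_size_um: 0.6", "hemisphere: left", "age_group: P14"), f)
  cfg <- read_config(f)
  expect_equal(cfg$pixel_size_um, 0.6)
  expect_equal(cfg$hemisphere, "left")
  expect_equal(cfg$match_tolerance_um, 5)
  expect_equal(cfg$cell_diameter_um, 17)
})

test_that("images round-trip through TIFF with channel naming", {
  ch <- list(a = matrix(runif(20), 4), b = matrix(runif(20), 4))
  f <- withr::local_tempfile(fileext = ".tif")
  write_image(ch, f)
  back <- read_image(f, channels = c("a", "b"))
  expect_equal(back$a, ch$a, tolerance = 1e-6)
  expect_error(read_image(f, channels = c("a", "b", "c")), "name")
})
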