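#' Read cell marks from CSV
#'
#' Reads a marks table exported from the image-annotation step. The expected
#' columns are `section_id, nucleus, x, y, markers` plus an optional
#' `soma_diameter_um`; `markers` holds one or more marker names separated by
#' semicolons. Rows with non-numeric coordinates are skipped and reported
#' with their line number; a missing required column is a hard error.
#'
#' When the frame carries `image_height_px`, y coordinates are converted
#' from image rows (row 0 at the top) to the anatomical frame
#' (`y = H - y_px`, dorsal up) once at ingest, mirroring how manual
#' annotation tools export centroids with inverted y.
#'
#' @param path CSV file path.
#' @param frame A [section_frame()]; supplies the y-flip convention.
#' @return A marks tibble (see [cell_marks()]). Skipped rows are attached as
#'   attribute `"skipped"` (integer line numbers) and reported via a warning.
#' @export
read_marks <- function(path, frame = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  required <- c("section_id", "nucleus", "x", "y", "markers")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("marks file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(cell_marks(character(), character(), numeric(), numeric(), list()))
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad) > 0L) {
    warning("skipped ", length(bad), " malformed row(s) in ", basename(path),
            " at line(s) ", paste(bad + 1L, collapse = ", "),
            " (non-numeric coordinate)", call. = FALSE)
    raw <- raw[-bad, , drop = FALSE]
    x <- x[-bad]; y <- y[-bad]
  }
  if (!is.null(frame) && !is.null(frame$image_height_px)) {
    y <- frame$image_height_px - y
  }
  soma <- if ("soma_diameter_um" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$soma_diameter_um))
  } else {
    NA_real_
  }
  out <- cell_marks(
    section_id = raw$section_id,
    nucleus = raw$nucleus,
    x = x, y = y,
    markers = strsplit(raw$markers, ";", fixed = TRUE),
    soma_diameter_um = soma
  )
  attr(out, "skipped") <- if (length(bad)) bad + 1L else integer()
  out
}

#' Write cell marks to CSV
#'
#' Coordinates are written with 17 significant digits so that
#' `read_marks(write_marks(m))` reproduces them bit-exactly.
#'
#' @param marks Marks tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marks <- function(marks, path) {
  df <- data.frame(
    section_id = marks$section_id,
    nucleus = marks$nucleus,
    x = vapply(marks$x, function(v) formatC(v, digits = 17, format = "g"), ""),
    y = vapply(marks$y, function(v) formatC(v, digits = 17, format = "g"), ""),
    markers = vapply(marks$markers, paste, "", collapse = ";"),
    soma_diameter_um = marks$soma_diameter_um,
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a Fiji "Results"-style centroid table
#'
#' Annotation done with the point tool in Fiji exports a Results table whose
#' coordinate columns are named `X` and `Y` (optionally with an `Area`
#' column). This importer maps such a table onto the marks schema; section,
#' nucleus and marker identity are not part of the Results table and must be
#' supplied.
#'
#' @param path CSV path of the Results table.
#' @param section_id,nucleus,marker Metadata to attach to every row.
#' @param frame Optional [section_frame()] for the y-flip convention.
#' @return A marks tibble.
#' @export
read_fiji_results <- function(path, section_id, nucleus, marker, frame = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  xcol <- intersect(c("X", "x"), names(raw))[1L]
  ycol <- intersect(c("Y", "y"), names(raw))[1L]
  if (is.na(xcol) || is.na(ycol)) {
    stop("Results table must contain X and Y columns", call. = FALSE)
  }
  y <- as.numeric(raw[[ycol]])
  if (!is.null(frame) && !is.null(frame$image_height_px)) y <- frame$image_height_px - y
  cell_marks(section_id, nucleus, as.numeric(raw[[xcol]]), y,
             markers = rep(list(marker), nrow(raw)))
}

#' Read nucleus ROI polygons
#'
#' Two dialects are accepted. The CSV dialect has one vertex per row with
#' columns `section_id, nucleus, vertex_index, x, y`; hemisphere and axis
#' orientation per (section, nucleus) come from an optional sidecar metadata
#' CSV with columns `section_id, nucleus, hemisphere, axis_spec`. The JSON
#' dialect is a list of objects with the same fields (`vertices` as an array
#' of `[x, y]` pairs).
#'
#' @param path ROI file (.csv or .json).
#' @param metadata Optional path to the sidecar metadata CSV (CSV dialect
#'   only).
#' @return A list of [nucleus_roi()] objects.
#' @export
read_rois <- function(path, metadata = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    specs <- jsonlite::read_json(path, simplifyVector = FALSE)
    return(lapply(specs, function(s) {
      nucleus_roi(
        section_id = s$section_id, nucleus = s$nucleus,
        vertices = do.call(rbind, lapply(s$vertices, unlist)),
        axis_spec = s$axis_spec %||% "medio-lateral",
        hemisphere = s$hemisphere %||% "right"
      )
    }))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("section_id", "nucleus", "vertex_index", "x", "y")
  if (!all(required %in% names(raw))) {
    stop("ROI file must have columns ", paste(required, collapse = ", "), call. = FALSE)
  }
  meta <- if (!is.null(metadata)) utils::read.csv(metadata, stringsAsFactors = FALSE) else NULL
  keys <- unique(raw[, c("section_id", "nucleus")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- raw$section_id == keys$section_id[i] & raw$nucleus == keys$nucleus[i]
    sub <- raw[sel, , drop = FALSE]
    sub <- sub[order(sub$vertex_index), , drop = FALSE]
    hemi <- "right"; axis <- "medio-lateral"
    if (!is.null(meta)) {
      m <- meta[meta$section_id == keys$section_id[i] & meta$nucleus == keys$nucleus[i], ]
      if (nrow(m) >= 1L) {
        if ("hemisphere" %in% names(m)) hemi <- m$hemisphere[1L]
        if ("axis_spec" %in% names(m)) axis <- m$axis_spec[1L]
      }
    }
    nucleus_roi(keys$section_id[i], keys$nucleus[i],
                cbind(sub$x, sub$y), axis_spec = axis, hemisphere = hemi)
  })
}

#' Read a run configuration
#'
#' YAML key-value file with pixel size, hemisphere, age-group mapping,
#' channel order and seeds. Unknown keys are kept as-is so analysis scripts
#' can carry their own settings.
#'
#' @param path YAML file.
#' @return Named list of settings with defaults filled in.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    pixel_size_um = NULL, hemisphere = "right", age_group = NA_character_,
    channels = NULL, seed = 1L,
    match_tolerance_um = 5, axon_tolerance_um = 1, cell_diameter_um = 17
  )
  utils::modifyList(defaults, cfg)
}

#' Read a 2-D multi-channel TIFF
#'
#' Returns a list of numeric matrices, one per channel, each indexed
#' `[row, column]` with row 1 at the top of the image. Grayscale images give
#' a single channel. Channel names are taken from `channels` when supplied.
#'
#' @param path TIFF path.
#' @param channels Optional character vector of channel names in file order.
#' @return Named list of matrices.
#' @export
read_image <- function(path, channels = NULL) {
  # libtiff warns about the photometric tag on >1-channel non-RGB floats
  img <- suppressWarnings(tiff::readTIFF(path, all = FALSE))
  chans <- if (length(dim(img)) == 3L) {
    lapply(seq_len(dim(img)[3L]), function(k) img[, , k])
  } else {
    list(img)
  }
  if (!is.null(channels)) {
    if (length(channels) != length(chans)) {
      stop("got ", length(chans), " channel(s) but ", length(channels), " name(s)",
           call. = FALSE)
    }
    names(chans) <- channels
  }
  chans
}

#' Write channels to TIFF
#'
#' Values are rescaled to [0, 1] only if they exceed that range; otherwise
#' written as-is (32-bit float), so synthetic images round-trip.
#'
#' @param channels Matrix or list of equally sized matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(channels, path) {
  if (is.matrix(channels)) channels <- list(channels)
  arr <- array(0, dim = c(nrow(channels[[1L]]), ncol(channels[[1L]]), length(channels)))
  for (k in seq_along(channels)) arr[, , k] <- channels[[k]]
  mx <- max(arr)
  if (mx > 1) arr <- arr / mx
  if (length(channels) == 1L) arr <- arr[, , 1L]
  tiff::writeTIFF(arr, path, bits.per.sample = 32L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
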