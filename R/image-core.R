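#' B-mode image container
#'
#' Wraps a grayscale pixel matrix together with its spatial calibration.
#' Pixels are stored as a numeric matrix in (row, column) order with
#' intensities in \[0, 1\]; row 0 is the skin side and depth increases with
#' the row index. All geometry in the package uses 0-based coordinates with
#' `x = column` and `y = row`, so the pixel at matrix position `[i, j]` has
#' coordinates `(x = j - 1, y = i - 1)`.
#'
#' @param pixels Numeric matrix of intensities in \[0, 1\] (rows = depth).
#' @param calibration Pixels per millimetre (positive scalar), or a
#'   [calibration_info()] object.
#' @param depth_setting_cm Optional acquisition depth metadata (cm).
#' @param source_id Identifier carried through to result tables.
#' @return An object of class `bmode_image`.
#' @export
#' @examples
#' img <- bmode_image(matrix(runif(100), 10, 10), calibration = 10.2)
#' dim(img$pixels)
bmode_image <- function(pixels, calibration, depth_setting_cm = NULL,
                        source_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  rng <- range(pixels, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("pixel intensities must lie in [0, 1]; rescale by bit depth first",
         call. = FALSE)
  }
  cal <- as_calibration(calibration)
  structure(
    list(
      pixels = pixels,
      width_px = ncol(pixels),
      height_px = nrow(pixels),
      calibration = cal,
      depth_setting_cm = depth_setting_cm,
      source_id = as.character(source_id)
    ),
    class = "bmode_image"
  )
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %s: %d x %d px, %.3g px/mm\n",
              x$source_id, x$width_px, x$height_px,
              x$calibration$pixels_per_mm))
  invisible(x)
}

#' Pixel calibration
#'
#' Records the pixels-per-millimetre factor used to convert pixel distances
#' to physical units. Calibration is never inferred from image content; it
#' must be supplied per image (or read from a sidecar file by
#' [read_bmode()]).
#'
#' @param pixels_per_mm Positive scalar.
#' @param source `"user_provided"` or `"sidecar_file"`.
#' @return A `calibration_info` object.
#' @export
calibration_info <- function(pixels_per_mm,
                             source = c("user_provided", "sidecar_file")) {
  source <- match.arg(source)
  if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1L ||
      !is.finite(pixels_per_mm) || pixels_per_mm <= 0) {
    stop("`pixels_per_mm` must be a positive finite scalar", call. = FALSE)
  }
  structure(list(pixels_per_mm = as.numeric(pixels_per_mm), source = source),
            class = "calibration_info")
}

as_calibration <- function(x) {
  if (inherits(x, "calibration_info")) return(x)
  calibration_info(x)
}

#' Unit conversions between pixels and physical units
#'
#' `mm = px / pixels_per_mm` and `cm = mm / 10`, exactly.
#'
#' @param px,mm,cm Numeric vectors of distances.
#' @param calibration A [calibration_info()] object or pixels-per-mm scalar.
#' @return Numeric vector in the target unit.
#' @export
px_to_mm <- function(px, calibration) px / as_calibration(calibration)$pixels_per_mm

#' @rdname px_to_mm
#' @export
px_to_cm <- function(px, calibration) px_to_mm(px, calibration) / 10

#' @rdname px_to_mm
#' @export
mm_to_px <- function(mm, calibration) mm * as_calibration(calibration)$pixels_per_mm

#' @rdname px_to_mm
#' @export
cm_to_px <- function(cm, calibration) mm_to_px(cm * 10, calibration)

#' Read a B-mode ultrasound image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF, rescales intensities by the
#' declared bit depth (never by the observed range), and attaches the
#' calibration. Multi-channel images are collapsed to grayscale by channel
#' averaging. The calibration is taken from `calibration` if given, else
#' from a JSON sidecar `<path>.json` with a `pixels_per_mm` field.
#'
#' @param path Path to a `.png`, `.tif`, or `.tiff` file.
#' @param calibration Pixels per mm; overrides any sidecar value.
#' @param source_id Identifier; defaults to the file name without extension.
#' @return A [bmode_image()].
#' @export
read_bmode <- function(path, calibration = NULL, source_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(
    ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, all = TRUE)
      if (length(x) > 1L) {
        stop("multi-frame TIFF: ", path,
             "; extract a single frame before analysis", call. = FALSE)
      }
      x[[1]]
    },
    dcm = ,
    dicom = stop("DICOM input is not supported in this build; ",
                 "convert to PNG or single-frame TIFF", call. = FALSE),
    stop("unsupported image format '.", ext, "' for ", path, call. = FALSE)
  )
  # readPNG/readTIFF already normalize by bit depth to [0, 1]
  if (length(dim(px)) == 3L) {
    px <- apply(px[, , seq_len(min(3L, dim(px)[3])), drop = FALSE],
                c(1, 2), mean)
  }
  if (is.null(calibration)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (is.null(meta$pixels_per_mm)) {
        stop("sidecar ", sidecar, " lacks a 'pixels_per_mm' field",
             call. = FALSE)
      }
      calibration <- calibration_info(as.numeric(meta$pixels_per_mm),
                                      source = "sidecar_file")
    } else {
      stop("no calibration supplied for ", path,
           " and no sidecar '", sidecar, "' found; pass `calibration`",
           call. = FALSE)
    }
  }
  if (is.null(source_id)) {
    source_id <- tools::file_path_sans_ext(basename(path))
  }
  bmode_image(px, calibration, source_id = source_id)
}

roi_kinds <- c("parent", "superficial_aponeurosis", "deep_aponeurosis")

#' Region of interest
#'
#' A named region supplied by the user (replacing interactive tracing):
#' the parent region between the aponeuroses, or one of the two aponeurosis
#' bands. Stored as a binary mask congruent with the image; polygons are
#' rasterized with vertices clipped to the image bounds.
#'
#' @param mask Logical matrix with the image's dimensions.
#' @param kind One of `"parent"`, `"superficial_aponeurosis"`,
#'   `"deep_aponeurosis"`.
#' @param polygon Optional source polygon (matrix of `(x, y)` vertices,
#'   0-based), retained for round-tripping.
#' @return An object of class `roi`.
#' @export
roi <- function(mask, kind = roi_kinds, polygon = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  mask <- mask > 0
  if (!any(mask)) stop("ROI mask is empty (all-zero)", call. = FALSE)
  structure(list(kind = kind, mask = mask, polygon = polygon), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> kind=%s, %d px\n", x$kind, sum(x$mask)))
  invisible(x)
}

#' Rasterize a polygon to a binary mask
#'
#' Even-odd scanline fill over pixel centres at integer coordinates;
#' boundary pixels are included (a rectangle with corners (0,0) and (9,9)
#' fills a 10 x 10 block). Vertices outside the image are clipped to its
#' bounds, never wrapped.
#'
#' @param polygon Two-column matrix of `(x, y)` vertices, 0-based pixel
#'   coordinates.
#' @param width_px,height_px Image dimensions.
#' @return Logical matrix `height_px` x `width_px`.
#' @export
polygon_to_mask <- function(polygon, width_px, height_px) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  px <- pmin(pmax(polygon[, 1], 0), width_px - 1)
  py <- pmin(pmax(polygon[, 2], 0), height_px - 1)
  mask <- matrix(FALSE, height_px, width_px)
  n <- length(px)
  nxt <- c(seq_len(n)[-1], 1L)
  y_lo <- ceiling(min(py))
  y_hi <- floor(max(py))
  for (y in y_lo:y_hi) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      y1 <- py[i]; y2 <- py[nxt[i]]
      x1 <- px[i]; x2 <- px[nxt[i]]
      if (y1 == y2) {
        if (y1 == y) xs <- c(xs, x1, x2)  # horizontal edge on the scanline
        next
      }
      if (y >= min(y1, y2) && y <= max(y1, y2)) {
        xs <- c(xs, x1 + (y - y1) / (y2 - y1) * (x2 - x1))
      }
    }
    xs <- sort(unique(xs))
    if (length(xs) == 1L) xs <- c(xs, xs)
    # pair up crossings; odd counts (vertex touches) collapse to spans
    i <- 1L
    while (i < length(xs) + 1L) {
      if (i + 1L > length(xs)) break
      x_from <- ceiling(xs[i]); x_to <- floor(xs[i + 1L])
      if (x_to >= x_from) {
        mask[y + 1L, (x_from:x_to) + 1L] <- TRUE
      }
      i <- i + 2L
    }
  }
  mask
}

#' Load a region of interest from file
#'
#' Accepts either a JSON polygon file (`{"kind": ..., "polygon":
#' [[x, y], ...]}`, 0-based pixel coordinates with x = column, y = row) or a
#' PNG binary mask congruent with the image.
#'
#' @param path Path to a `.json` polygon or `.png` mask.
#' @param kind ROI kind; overrides a kind recorded in the file if supplied.
#' @param image The [bmode_image()] the ROI belongs to.
#' @return An [roi()].
#' @export
load_roi <- function(path, kind = NULL, image) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(kind)) kind <- spec$kind
    poly <- as.matrix(spec$polygon)
    if (is.null(poly) || nrow(poly) < 3L || !is.numeric(poly)) {
      stop("ROI polygon in ", path, " is empty or malformed", call. = FALSE)
    }
    mask <- polygon_to_mask(poly, image$width_px, image$height_px)
    if (!any(mask)) stop("ROI polygon rasterizes to an empty mask", call. = FALSE)
    roi(mask, kind = kind, polygon = poly)
  } else if (ext %in% c("png", "tif", "tiff")) {
    m <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    if (nrow(m) != image$height_px || ncol(m) != image$width_px) {
      stop("ROI mask dimensions (", nrow(m), " x ", ncol(m),
           ") do not match the image (", image$height_px, " x ",
           image$width_px, ")", call. = FALSE)
    }
    if (is.null(kind)) stop("`kind` must be given for mask-file ROIs", call. = FALSE)
    roi(m > 0.5, kind = kind)
  } else {
    stop("unsupported ROI format '.", ext, "'", call. = FALSE)
  }
}

#' Write a polygon ROI to JSON
#'
#' @param x An [roi()] with a stored polygon, or a vertex matrix.
#' @param path Output path.
#' @param kind ROI kind when `x` is a bare matrix.
#' @export
write_roi_json <- function(x, path, kind = NULL) {
  if (inherits(x, "roi")) {
    if (is.null(x$polygon)) stop("ROI has no polygon representation", call. = FALSE)
    kind <- x$kind
    poly <- x$polygon
  } else {
    poly <- as.matrix(x)
  }
  jsonlite::write_json(
    list(kind = kind,
         polygon = lapply(seq_len(nrow(poly)), function(i) unname(poly[i, ]))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

check_roi_set <- function(rois) {
  kinds <- vapply(rois, function(r) r$kind, character(1))
  for (k in roi_kinds) {
    if (sum(kinds == k) != 1L) {
      stop("exactly one ROI of kind '", k, "' is required (got ",
           sum(kinds == k), ")", call. = FALSE)
    }
  }
  rois <- rois[match(roi_kinds, kinds)]
  names(rois) <- roi_kinds
  cen <- function(m) mean(which(m, arr.ind = TRUE)[, 1])
  if (cen(rois$superficial_aponeurosis$mask) >= cen(rois$deep_aponeurosis$mask)) {
    stop("superficial aponeurosis ROI must lie above (smaller row than) the ",
         "deep ROI; check the ROI kinds", call. = FALSE)
  }
  rois
}

#' Export per-image architecture results
#'
#' Writes a long-format table with one row per accepted fascicle
#' (`record = "fascicle"`: pennation angle in degrees, fascicle length in
#' cm) and one summary row per image (`record = "summary"`: mean pennation
#' angle, mean fascicle length, muscle thickness at the 20/50/80% aperture
#' positions and their mean). Rows are ordered by image id then fascicle id
#' so repeated runs are byte-identical.
#'
#' @param results A single `muscle_architecture` result or a list of them.
#' @param path Output `.csv` path; a JSON mirror is written alongside when
#'   `json_mirror = TRUE`.
#' @param json_mirror Also write `<path>.json`.
#' @return The combined tibble, invisibly.
#' @export
write_results <- function(results, path, json_mirror = TRUE) {
  if (inherits(results, "muscle_architecture")) results <- list(results)
  if (length(results) == 0L) {
    stop("no results to write", call. = FALSE)
  }
  tab <- dplyr::bind_rows(lapply(results, results_rows))
  tab <- dplyr::arrange(tab, .data$image_id, .data$record,
                        dplyr::coalesce(.data$fascicle_id, Inf))
  readr::write_csv(tab, path)
  if (json_mirror) {
    jsonlite::write_json(tab, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(tab)
}

results_rows <- function(res) {
  stopifnot(inherits(res, "muscle_architecture"))
  fas <- res$fascicles
  fas_rows <- tibble::tibble(
    image_id = res$image_id,
    record = "fascicle",
    fascicle_id = if (nrow(fas)) fas$region_label else integer(0),
    pennation_deg = if (nrow(fas)) fas$pennation_deg else numeric(0),
    fascicle_length_cm = if (nrow(fas)) fas$fascicle_length_cm else numeric(0)
  )
  th <- res$thickness
  sum_row <- tibble::tibble(
    image_id = res$image_id,
    record = "summary",
    fascicle_id = NA_integer_,
    pennation_deg = NA_real_,
    fascicle_length_cm = NA_real_,
    n_fascicles = nrow(fas),
    mean_pennation_deg = res$summary$mean_pennation_deg,
    mean_fascicle_length_cm = res$summary$mean_fascicle_length_cm,
    mt20_cm = th$thickness_cm[1],
    mt50_cm = th$thickness_cm[2],
    mt80_cm = th$thickness_cm[3],
    mt_mean_cm = th$mean_thickness_cm
  )
  dplyr::bind_rows(fas_rows, sum_row)
}
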