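# Reading and writing images, ROIs, design tables and result tables, plus the
# deterministic bookkeeping (blinding codes) the workflow needs.

#' Read a single-channel grayscale image
#'
#' Reads an 8-bit PNG or an 8/16-bit grayscale TIFF into a [channel_image].
#' Integer intensities are preserved losslessly (PNG values are mapped back to
#' 0..255, TIFF values to their native integer range).
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @param channel Channel label, see [channel_image()].
#' @param pixel_size_um Micrometres per pixel; must be supplied by the user
#'   (scanner metadata is not parsed).
#' @param section_id,animal_id Identifiers attached to the image.
#' @return A [channel_image].
#' @export
read_channel_image <- function(path, channel, pixel_size_um = 1,
                               section_id = "s1", animal_id = "a1") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3) {
      if (dim(arr)[3] > 1 && !all(arr[, , 1] == arr[, , 2]))
        stop("multi-channel PNG without a channel selector: ", path)
      arr <- arr[, , 1]
    }
    pix <- round(arr * 255)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(arr)) == 3) {
      if (dim(arr)[3] > 1) stop("multi-channel TIFF without a channel selector: ", path)
      arr <- arr[, , 1]
    }
    pix <- arr
  } else stop("unsupported image format: ", ext)
  channel_image(pix, channel, pixel_size_um, section_id, animal_id)
}

#' Write a single-channel grayscale image
#'
#' @param img A [channel_image], [binary_mask] (written as 0/255), or numeric
#'   matrix of integer intensities.
#' @param path Output path; format chosen by extension (`.png` 8-bit,
#'   `.tif`/`.tiff` 8- or 16-bit).
#' @param bits Bit depth for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_channel_image <- function(img, path, bits = 8) {
  pix <- if (inherits(img, "channel_image")) img$pixels
         else if (inherits(img, "binary_mask")) img$pixels * 255
         else img
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(pix) > 255) stop("PNG output is 8-bit; intensities exceed 255")
    png::writePNG(pix / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    top <- if (bits == 16) 65535 else 255
    if (max(pix) > top) stop("intensities exceed the requested bit depth")
    tiff::writeTIFF(pix / top, path, bits.per.sample = bits, compression = "none")
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read region-of-interest polygons
#'
#' Reads either the canonical JSON polygon dialect
#' (`{"region": "cortex", "vertices": [[x, y], ...]}`, or a JSON array of such
#' objects) or an ImageJ `.roi` file (polygon type, read-only support).
#' Polygons are validated (simple, >= 3 vertices) and vertices clamped to the
#' image bounds.
#'
#' @param path Path to a `.json` or ImageJ `.roi` file.
#' @param image_shape Integer `(rows, cols)` used for clamping.
#' @return List of [roi_polygon] objects.
#' @export
read_roi <- function(path, image_shape) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  raw_polys <- if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.null(obj$region)) list(obj) else obj
  } else if (ext == "roi") {
    list(read_imagej_roi(path))
  } else stop("unsupported ROI format: ", ext)
  lapply(raw_polys, function(p) {
    v <- if (is.list(p$vertices)) {
      do.call(rbind, lapply(p$vertices, function(xy) as.numeric(unlist(xy))))
    } else as.matrix(p$vertices)
    if (ncol(v) != 2) stop("ROI vertices must be (x, y) pairs")
    v[, 1] <- pmin(pmax(v[, 1], 0), image_shape[2] - 1)
    v[, 2] <- pmin(pmax(v[, 2], 0), image_shape[1] - 1)
    roi_polygon(p$region, v)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal ImageJ .roi reader: polygon/freehand/rectangle types. The format is
# big-endian; coordinates are stored relative to the bounding box.
read_imagej_roi <- function(path, region = "cortex") {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "Iout")) stop("not an ImageJ .roi file")
  readBin(con, "integer", 1, 2, endian = "big")          # version
  type <- readBin(con, "integer", 1, 1, signed = FALSE)  # roi type
  readBin(con, "integer", 1, 1, signed = FALSE)          # pad
  top <- readBin(con, "integer", 1, 2, endian = "big")
  left <- readBin(con, "integer", 1, 2, endian = "big")
  bottom <- readBin(con, "integer", 1, 2, endian = "big")
  right <- readBin(con, "integer", 1, 2, endian = "big")
  n <- readBin(con, "integer", 1, 2, endian = "big")
  if (type == 1) {                       # rectangle
    v <- cbind(c(left, right - 1, right - 1, left),
               c(top, top, bottom - 1, bottom - 1))
    return(list(region = region, vertices = v))
  }
  if (!type %in% c(0, 7)) stop("unsupported ImageJ ROI type: ", type)
  seek(con, 64)
  xs <- readBin(con, "integer", n, 2, endian = "big")
  ys <- readBin(con, "integer", n, 2, endian = "big")
  list(region = region, vertices = cbind(left + xs, top + ys))
}

#' Write ROI polygons as JSON
#'
#' @param rois List of [roi_polygon] objects (or a single one).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_roi <- function(rois, path) {
  if (inherits(rois, "roi_polygon")) rois <- list(rois)
  payload <- lapply(rois, function(p)
    list(region = p$region, vertices = unname(apply(p$vertices, 1, as.list))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort design table
#'
#' CSV with columns `animal_id`, `app_genotype` (WT/APPPS1), `apoa1_genotype`
#' (HEM/KO) and `sex` (F/M); one row per animal.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_design_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_design(d)
}

validate_design <- function(d) {
  need <- c("animal_id", "app_genotype", "apoa1_genotype", "sex")
  if (!all(need %in% names(d))) stop("design table must have columns: ",
                                     paste(need, collapse = ", "))
  d$animal_id <- as.character(d$animal_id)
  if (anyDuplicated(d$animal_id)) stop("duplicate animal ids in design table")
  if (!all(d$app_genotype %in% c("WT", "APPPS1")))
    stop("app_genotype must be WT or APPPS1")
  if (!all(d$apoa1_genotype %in% c("HEM", "KO")))
    stop("apoa1_genotype must be HEM or KO")
  if (!all(d$sex %in% c("F", "M"))) stop("sex must be F or M")
  d
}

#' Assign blinding codes to animals
#'
#' Deterministically (for a fixed seed) maps each animal id to an opaque code
#' carrying no genotype information, emulating analysis by a researcher
#' blinded to genotype. The mapping is a bijection.
#'
#' @param design Design table with unique `animal_id`.
#' @param seed Integer seed.
#' @return Named character vector: `code[animal_id]`.
#' @export
assign_blinding_codes <- function(design, seed = 1) {
  ids <- as.character(design$animal_id)
  if (anyDuplicated(ids)) stop("duplicate animal ids")
  n <- length(ids)
  if (n == 0) return(stats::setNames(character(0), character(0)))
  codes <- withr::with_seed(seed, sprintf("B%04d", sample.int(9999, n)))
  stats::setNames(codes, ids)
}

#' Write / read quantification records
#'
#' Records are one row per measurement with a stable column order; undefined
#' values (zero denominators) are serialized as the explicit `NA` token and
#' survive a round trip.
#'
#' @param records Data frame of [quant_record()] rows.
#' @param path CSV path.
#' @return `path` invisibly (write); data frame (read).
#' @export
write_quant_csv <- function(records, path) {
  cols <- c("animal_id", "section_id", "region", "metric",
            "numerator_px", "denominator_px", "scale", "value")
  if (nrow(records) == 0) {
    records <- records[, cols, drop = FALSE]
  } else {
    if (!all(cols %in% names(records))) stop("records do not share the expected schema")
    records <- records[, cols]
  }
  utils::write.csv(records, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_quant_csv
#' @export
read_quant_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(animal_id = "character",
                                 section_id = "character",
                                 region = "character", metric = "character",
                                 numerator_px = "numeric",
                                 denominator_px = "numeric",
                                 scale = "character", value = "numeric"))
}
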