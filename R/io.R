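# File IO: images (TIFF/PNG), masks, polygon JSON, ImageJ .roi polygons,
# and provenance-stamped CSVs.

#' Read a grayscale cross-section image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG; intensities are scaled to
#' `[0, 1]` by the readers. Multi-channel images are reduced to their first
#' channel.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size_um physical pixel size.
#' @param sample_id,group sample annotation (default: file stem, unknown).
#' @return a [cross_section()].
#' @export
read_cross_section <- function(path, pixel_size_um = 1.0,
                               sample_id = NULL, group = "unknown") {
  st <- "read_cross_section"
  assert_that(file.exists(path), st, paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_xct(st, "unsupported image format '.", ext, "' (use TIFF or PNG)")
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  cross_section(img, pixel_size_um = pixel_size_um,
                sample_id = sample_id %||% tools::file_path_sans_ext(basename(path)),
                group = group)
}

#' Write a cross-section as 16-bit grayscale TIFF
#'
#' @param image a [cross_section()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cross_section <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image$pixels, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Write a label or binary mask as 8-bit TIFF
#'
#' Labels are stored as gray values `label / 255` (suitable for up to 255
#' regions); binary masks as 0/255.
#'
#' @param mask integer label matrix or logical mask.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  if (is.logical(mask)) mask <- mask * 255L
  assert_that(max(mask) <= 255, "write_mask_tiff",
              "more than 255 labels do not fit an 8-bit label TIFF")
  tiff::writeTIFF(mask / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read boundary polygons from JSON
#'
#' The JSON file holds one polygon (an array of `[row, col]` pairs, 0-based
#' pixel-centre coordinates) or a named object of such polygons (e.g.
#' `{"pith": [...], "outer": [...]}`).
#'
#' @param path JSON file path.
#' @return a vertex matrix, or a named list of vertex matrices.
#' @export
read_polygons_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  to_mat <- function(p) {
    m <- if (is.matrix(p)) p else do.call(rbind, p)
    storage.mode(m) <- "double"
    m
  }
  if (is.list(x) && !is.null(names(x))) lapply(x, to_mat) else to_mat(x)
}

#' Read a polygon from an ImageJ .roi file
#'
#' Minimal reader for the binary ImageJ ROI format, supporting polygon,
#' freehand and traced outline types. Coordinates are returned 0-based as
#' (row, col) vertices compatible with [delineate_geometry()].
#'
#' @param path path to a `.roi` file.
#' @return matrix of (row, col) vertices.
#' @export
read_imagej_roi <- function(path) {
  st <- "read_imagej_roi"
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(magic, "Iout"), st, "not an ImageJ .roi file")
  readBin(con, "integer", 1, 2, endian = "big")  # version
  type <- readBin(con, "integer", 1, 1, signed = FALSE)
  readBin(con, "raw", 1)
  top <- readBin(con, "integer", 1, 2, endian = "big")
  left <- readBin(con, "integer", 1, 2, endian = "big")
  readBin(con, "integer", 2, 2, endian = "big")  # bottom, right
  n <- readBin(con, "integer", 1, 2, endian = "big")
  # 0 = polygon, 7 = freehand, 8 = traced
  assert_that(type %in% c(0L, 7L, 8L), st,
              paste0("unsupported ROI type ", type,
                     " (only polygon/freehand/traced outlines)"))
  assert_that(n > 2, st, "ROI has fewer than 3 vertices")
  seek(con, 64)
  x <- readBin(con, "integer", n, 2, endian = "big")
  y <- readBin(con, "integer", n, 2, endian = "big")
  cbind(y + top, x + left)
}

#' Write a provenance-stamped CSV
#'
#' Writes a data frame preceded by a `# config_hash:` comment so that every
#' output table records the exact parameter set that produced it. Read back
#' with `read.csv(path, comment.char = "#")`.
#'
#' @param df data frame.
#' @param path output path.
#' @param config the configuration the table derives from.
#' @return the path, invisibly.
#' @export
write_csv_stamped <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", config_hash(config)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
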