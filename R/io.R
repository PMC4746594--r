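## plain-format interchange: TIFF frames, mosaic manifests (JSON),
## detection / ground-truth cell tables (CSV)

#' Read and write rendered frames as TIFF
#'
#' Frames are stored as single-channel TIFFs at the frame's bit depth. The
#' frame specification travels alongside as a JSON sidecar
#' (`<file>.json`) so stage coordinates survive the round trip.
#'
#' @param image rendered frame (integer matrix with a `"spec"` attribute).
#' @param file output .tif path.
#' @return `writeFrameTiff`: the file path, invisibly. `readFrameTiff`: the
#'   image matrix with its `"spec"` attribute restored.
#' @export
writeFrameTiff <- function(image, file) {
  spec <- attr(image, "spec")
  if (is.null(spec)) stop("image carries no FrameSpec")
  top <- 2^spec@bit_depth - 1
  tiff::writeTIFF(image / top, file, bits.per.sample = spec@bit_depth)
  jsonlite::write_json(
    list(width = spec@width, height = spec@height,
         pixel_size_um = spec@pixel_size,
         offset_um = as.numeric(spec@offset), channel = spec@channel,
         bit_depth = spec@bit_depth),
    paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeFrameTiff
#' @export
readFrameTiff <- function(file) {
  side <- paste0(file, ".json")
  if (!file.exists(side)) stop("missing FrameSpec sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  spec <- frameSpec(meta$width, meta$height, meta$pixel_size_um,
                    meta$offset_um, meta$channel, meta$bit_depth)
  raw <- tiff::readTIFF(file)
  img <- round(raw * (2^spec@bit_depth - 1))
  storage.mode(img) <- "integer"
  attr(img, "spec") <- spec
  img
}

#' Write and read a mosaic scan (tile TIFFs + JSON manifest)
#'
#' The manifest lists each tile file with its stage offset (um) and the
#' shared pixel size, so external tools can place tiles in the stage frame.
#'
#' @param mosaic a [MosaicScan-class].
#' @param dir output directory (created if needed).
#' @param prefix tile filename prefix.
#' @return `writeMosaic`: the manifest path, invisibly. `readMosaic`: a
#'   [MosaicScan-class].
#' @export
writeMosaic <- function(mosaic, dir, prefix = "tile") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(mosaic@tiles))
  for (k in seq_along(mosaic@tiles)) {
    files[k] <- sprintf("%s_%03d.tif", prefix, k)
    img <- mosaic@tiles[[k]]
    attr(img, "spec") <- mosaic@specs[[k]]
    writeFrameTiff(img, file.path(dir, files[k]))
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(
    list(nx = mosaic@nx, ny = mosaic@ny, overlap = mosaic@overlap,
         pixel_size_um = mosaic@specs[[1]]@pixel_size,
         tiles = data.frame(
           file = files,
           offset_x_um = vapply(mosaic@specs, function(s) s@offset[1], 0),
           offset_y_um = vapply(mosaic@specs, function(s) s@offset[2], 0))),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname writeMosaic
#' @param manifest path to a mosaic manifest JSON.
#' @export
readMosaic <- function(manifest) {
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  tiles <- vector("list", nrow(meta$tiles))
  specs <- vector("list", nrow(meta$tiles))
  for (k in seq_len(nrow(meta$tiles))) {
    img <- readFrameTiff(file.path(dir, meta$tiles$file[k]))
    specs[[k]] <- attr(img, "spec")
    tiles[[k]] <- img
  }
  new("MosaicScan", tiles = tiles, specs = specs,
      nx = as.integer(meta$nx), ny = as.integer(meta$ny),
      overlap = as.numeric(meta$overlap))
}

#' Write and read cell tables as CSV
#'
#' The on-disk dialect is the package's canonical detection table:
#' id, x_um, y_um, size_um, brightness, labeled (plus t_s and any bbox
#' columns present).
#'
#' @param cellsTab a cell table.
#' @param file CSV path.
#' @return `writeCellTable`: the path, invisibly. `readCellTable`: the cell
#'   table.
#' @export
writeCellTable <- function(cellsTab, file) {
  write.csv(cellsTab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCellTable
#' @export
readCellTable <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df
}
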