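#' Convert between pixel and stage coordinates
#'
#' Pixels are 0-based (row, col) with coordinates at pixel centres; the map
#' is affine through the frame's pixel size and stage offset:
#' x = col * pixel_size + offset\[1\], y = row * pixel_size + offset\[2\].
#'
#' @param spec a [FrameSpec-class].
#' @param pixel n x 2 matrix (or length-2 vector) of (row, col).
#' @return `stageFromPixel`: n x 2 matrix of (x_um, y_um).
#' @examples
#' stageFromPixel(frameSpec(pixel_size = 1.3, offset = c(100, 200)),
#'                c(10, 20))   # x = 126, y = 213
#' @export
stageFromPixel <- function(spec, pixel) {
  p <- matrix(as.numeric(pixel), ncol = 2)
  cbind(x_um = p[, 2] * spec@pixel_size + spec@offset[1],
        y_um = p[, 1] * spec@pixel_size + spec@offset[2])
}

#' @rdname stageFromPixel
#' @param stage n x 2 matrix (or length-2 vector) of (x_um, y_um).
#' @return `pixelFromStage`: n x 2 matrix of fractional (row, col).
#' @export
pixelFromStage <- function(spec, stage) {
  s <- matrix(as.numeric(stage), ncol = 2)
  cbind(row = (s[, 2] - spec@offset[2]) / spec@pixel_size,
        col = (s[, 1] - spec@offset[1]) / spec@pixel_size)
}

#' Adaptive cell targeting: correct a stale target position
#'
#' Cells in the thin suspension layer are not perfectly immobilized, so the
#' coordinates saved during the initial scan go stale. A fresh image is
#' captured right before picking; the fresh detection nearest the expected
#' position (within `search_radius`) becomes the corrected target. Ties on
#' distance go to the brighter detection, then to the smaller id. With no
#' candidate in the search disc the target is reported lost (lost targets
#' are skipped, not retried).
#'
#' @param expected one-row cell table (or list with `x_um`, `y_um`) holding
#'   the stale coordinates.
#' @param fresh cell table of detections from the fresh image (stage um).
#' @param search_radius matching radius in um (default 50, bounded by the
#'   inter-cell spacing of sparse cultures).
#' @return A list: `status` ("corrected" or "lost"), `corrected_position`
#'   c(x, y) um (when corrected), `displacement` um, `matched_id`.
#' @export
adaptiveRetarget <- function(expected, fresh, search_radius = 50) {
  stopifnot(search_radius > 0)
  ex <- as.numeric(expected$x_um[1])
  ey <- as.numeric(expected$y_um[1])
  if (nrow(fresh) == 0)
    return(list(status = "lost", corrected_position = NULL,
                displacement = NA_real_, matched_id = NA_character_))
  d <- sqrt((fresh$x_um - ex)^2 + (fresh$y_um - ey)^2)
  cand <- which(d <= search_radius)
  if (length(cand) == 0)
    return(list(status = "lost", corrected_position = NULL,
                displacement = NA_real_, matched_id = NA_character_))
  br <- fresh$brightness[cand]
  br[is.na(br)] <- -Inf
  o <- order(d[cand], -br, fresh$id[cand])
  best <- cand[o[1]]
  list(status = "corrected",
       corrected_position = c(x_um = fresh$x_um[best],
                              y_um = fresh$y_um[best]),
       displacement = d[best],
       matched_id = fresh$id[best])
}

#' Write a retarget log
#'
#' @param log data.frame with columns id, expected_x_um, expected_y_um,
#'   corrected_x_um, corrected_y_um, displacement_um, status (as accumulated
#'   by the workflow drivers).
#' @param file output CSV path.
#' @return The file path, invisibly.
#' @export
writeRetargetLog <- function(log, file) {
  write.csv(log, file, row.names = FALSE)
  invisible(file)
}
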