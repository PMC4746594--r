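# shoelace area of a polygon given as an n x 2 vertex matrix
.polyArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

#' Arena accessors
#'
#' `arenaArea()` returns the polygon area in um^2; `mediumVolume()` the
#' medium volume in nl (area x layer height; 1 nl = 1e6 um^3);
#' `arenaBounds()` the bounding box c(xmin, xmax, ymin, ymax);
#' `arenaContains()` tests points for containment (even-odd rule, boundary
#' counted as inside).
#'
#' @param arena an [ArenaGeometry-class].
#' @return `arenaArea`: numeric um^2. `mediumVolume`: numeric nl.
#'   `arenaBounds`: named numeric length 4. `arenaContains`: logical vector.
#' @export
arenaArea <- function(arena) .polyArea(arena@vertices)

#' @rdname arenaArea
#' @export
mediumVolume <- function(arena) arenaArea(arena) * arena@layer_height / 1e6

#' @rdname arenaArea
#' @export
arenaBounds <- function(arena) {
  v <- arena@vertices
  c(xmin = min(v[, 1]), xmax = max(v[, 1]),
    ymin = min(v[, 2]), ymax = max(v[, 2]))
}

#' @rdname arenaArea
#' @param points n x 2 matrix of (x, y) stage um.
#' @export
arenaContains <- function(arena, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  v <- arena@vertices
  n <- nrow(v)
  px <- points[, 1]; py <- points[, 2]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  eps <- 1e-9
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # boundary test: point within eps of segment i-j
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    if (L2 > 0) {
      t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2))
      d2 <- (xi + t * dx - px)^2 + (yi + t * dy - py)^2
      on_edge <- on_edge | d2 <= eps
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Construct or validate a cell table
#'
#' The package-wide tabular representation of detected or simulated cells:
#' one row per cell with columns `id` (character, unique), `x_um`, `y_um`
#' (stage position), `size_um` (equivalent diameter), `brightness`
#' (arbitrary units >= 0), `labeled` (logical: carries a fluorescent label)
#' and `t_s` (timestamp, s). Optional bounding-box columns `bbox_w_um`,
#' `bbox_h_um` are preserved when present.
#'
#' @param id character ids (unique).
#' @param x_um,y_um stage coordinates in um.
#' @param size_um equivalent diameters in um (> 0 where known).
#' @param brightness mean brightness, arbitrary units (>= 0 where known).
#' @param labeled logical label flags.
#' @param t_s timestamps in s.
#' @return A data.frame with the canonical columns.
#' @examples
#' cellTable(id = "c1", x_um = 10, y_um = 20, size_um = 15,
#'           brightness = 180, labeled = TRUE)
#' @export
cellTable <- function(id = character(), x_um = numeric(), y_um = numeric(),
                      size_um = NA_real_, brightness = NA_real_,
                      labeled = TRUE, t_s = 0) {
  n <- length(x_um)
  tab <- data.frame(id = as.character(id),
                    x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                    size_um = rep_len(as.numeric(size_um), n),
                    brightness = rep_len(as.numeric(brightness), n),
                    labeled = rep_len(as.logical(labeled), n),
                    t_s = rep_len(as.numeric(t_s), n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$id)) stop("cell ids must be unique")
  if (any(!is.na(tab$size_um) & tab$size_um <= 0))
    stop("size_um must be > 0")
  if (any(!is.na(tab$brightness) & tab$brightness < 0))
    stop("brightness must be >= 0")
  tab
}

#' @rdname cellTable
#' @export
emptyCellTable <- function() cellTable()

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ArenaGeometry", function(object) {
  cat(sprintf("ArenaGeometry: %d-vertex polygon, area %.3f mm^2, layer %g um, medium %.0f nl\n",
              nrow(object@vertices), arenaArea(object) / 1e6,
              object@layer_height, mediumVolume(object)))
})

setMethod("show", "FrameSpec", function(object) {
  cat(sprintf("FrameSpec: %d x %d px @ %g um/px, offset (%g, %g) um, %s, %d-bit\n",
              object@width, object@height, object@pixel_size,
              object@offset[1], object@offset[2], object@channel,
              object@bit_depth))
})

setMethod("show", "MosaicScan", function(object) {
  cat(sprintf("MosaicScan: %d x %d tiles (overlap %.0f%%)\n",
              object@nx, object@ny, 100 * object@overlap))
})

setMethod("show", "SuspensionState", function(object) {
  cat(sprintf("SuspensionState: %d cells (%d labeled), %.0f nl medium, t = %g s\n",
              nrow(object@cells), sum(object@cells$labeled %in% TRUE),
              object@medium_volume, object@clock))
})

setMethod("show", "MicrowellArray", function(object) {
  cat(sprintf("MicrowellArray: %d x %d wells, pitch %g um, diameter %g um, fill %.0f%%, pick success %.0f%%\n",
              object@n_rows, object@n_cols, object@pitch,
              object@well_diameter, 100 * object@fill_efficiency,
              100 * object@well_pick_success))
})

setMethod("show", "SortPlan", function(object) {
  cat(sprintf("SortPlan: %d targets, path %.0f um, destinations: %s\n",
              nrow(object@targets), object@path_length,
              paste(utils::head(object@destinations$label, 3),
                    collapse = ", ")))
})

## ---------------------------------------------------------------------------
## SuspensionState accessors
## ---------------------------------------------------------------------------

#' Access and replace the cell table of a suspension state
#'
#' @param state a [SuspensionState-class].
#' @return `cells()`: the cell table data.frame.
#' @export
cells <- function(state) state@cells

#' @rdname cells
#' @param value replacement cell table.
#' @export
`cells<-` <- function(state, value) {
  state@cells <- as.data.frame(value)
  validObject(state)
  state
}

#' @rdname cells
#' @export
stateClock <- function(state) state@clock

#' @rdname cells
#' @export
stateVolume <- function(state) state@medium_volume
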