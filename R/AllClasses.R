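#' @import methods
#' @importFrom stats rnorm runif var sd
#' @importFrom utils head read.csv write.csv
NULL

## ---------------------------------------------------------------------------
## Arena geometry
## ---------------------------------------------------------------------------

#' Arena geometry: a confined region of thin-layer cell suspension
#'
#' An arena is the planar region (in stage coordinates, micrometres) holding a
#' thin layer of cell suspension, e.g. one 5 x 5 mm^2 well of a miniature
#' multiwell plate printed into a Petri dish. The medium layer is thin
#' (default 97 um) so that convection-driven cell floating is suppressed.
#'
#' @slot vertices numeric matrix (n x 2) of polygon vertices in stage um,
#'   listed in order (the polygon is implicitly closed).
#' @slot layer_height height of the medium layer in um.
#'
#' @seealso [arenaGeometry()], [rectArena()], [arenaArea()], [mediumVolume()]
#' @exportClass ArenaGeometry
setClass("ArenaGeometry",
         slots = c(vertices = "matrix", layer_height = "numeric"))

setValidity("ArenaGeometry", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2 || nrow(v) < 3)
    return("vertices must be a numeric matrix with 2 columns and >= 3 rows")
  if (any(!is.finite(v))) return("vertices must be finite")
  if (length(object@layer_height) != 1 || object@layer_height <= 0)
    return("layer_height must be a single positive number")
  if (.polyArea(v) <= 0) return("arena area must be > 0")
  TRUE
})

#' Construct an arena from a vertex polygon
#'
#' @param vertices n x 2 numeric matrix of polygon vertices (stage um).
#' @param layer_height medium layer height in um (default 97).
#' @return An [ArenaGeometry-class] object.
#' @examples
#' sq <- rectArena(5000, 5000)         # a 5 x 5 mm^2 well
#' arenaArea(sq) / 1e6                 # area in mm^2
#' mediumVolume(sq)                    # medium volume in nl
#' @export
arenaGeometry <- function(vertices, layer_height = 97) {
  new("ArenaGeometry", vertices = as.matrix(vertices),
      layer_height = as.numeric(layer_height))
}

#' @rdname arenaGeometry
#' @param width,height rectangle extent in um.
#' @param origin lower (x, y) corner in stage um.
#' @export
rectArena <- function(width, height, origin = c(0, 0), layer_height = 97) {
  x0 <- origin[1]; y0 <- origin[2]
  arenaGeometry(rbind(c(x0, y0), c(x0 + width, y0),
                      c(x0 + width, y0 + height), c(x0, y0 + height)),
                layer_height = layer_height)
}

## ---------------------------------------------------------------------------
## Frames and rendering
## ---------------------------------------------------------------------------

#' Camera frame specification
#'
#' Maps pixel indices to stage coordinates. Pixels are indexed 0-based; a
#' pixel's coordinate refers to its centre; x runs along columns (rightwards)
#' and y along rows (downwards), so stage x = col * pixel_size + offset\[1\]
#' and stage y = row * pixel_size + offset\[2\].
#'
#' @slot width,height frame size in pixels.
#' @slot pixel_size um per pixel.
#' @slot offset stage um of pixel (row 0, col 0) centre, as c(x, y).
#' @slot channel "fluorescent" or "phase".
#' @slot bit_depth 8 or 16.
#' @exportClass FrameSpec
setClass("FrameSpec",
         slots = c(width = "integer", height = "integer",
                   pixel_size = "numeric", offset = "numeric",
                   channel = "character", bit_depth = "integer"))

setValidity("FrameSpec", function(object) {
  if (object@width < 1L || object@height < 1L) return("frame dimensions must be >= 1")
  if (object@pixel_size <= 0) return("pixel_size must be > 0")
  if (length(object@offset) != 2 || any(!is.finite(object@offset)))
    return("offset must be finite c(x, y)")
  if (!object@channel %in% c("fluorescent", "phase"))
    return("channel must be 'fluorescent' or 'phase'")
  if (!object@bit_depth %in% c(8L, 16L)) return("bit_depth must be 8 or 16")
  TRUE
})

#' @param width,height frame size in pixels.
#' @param pixel_size um per pixel (the paper's 10x objective leaves this
#'   open; 1.25 um/px is a typical value for the cameras cited).
#' @param offset stage um of pixel (0, 0), c(x, y).
#' @param channel "fluorescent" or "phase".
#' @param bit_depth image bit depth, 8 or 16.
#' @return A [FrameSpec-class] object.
#' @rdname FrameSpec-class
#' @export
frameSpec <- function(width = 512, height = 512, pixel_size = 1.25,
                      offset = c(0, 0), channel = "fluorescent",
                      bit_depth = 8L) {
  new("FrameSpec", width = as.integer(width), height = as.integer(height),
      pixel_size = as.numeric(pixel_size), offset = as.numeric(offset),
      channel = channel, bit_depth = as.integer(bit_depth))
}

#' Rendering parameters for synthetic frames
#'
#' Cells are rendered as isotropic Gaussian spots on a constant background
#' with i.i.d. Gaussian pixel noise; the spot sigma defaults to cell size / 4
#' so that the detected blob diameter approximates the nominal cell size.
#'
#' @slot spot_sigma point-spread width in um; NA means size/4 per cell.
#' @slot peak spot amplitude (brightness units) used when a cell carries no
#'   brightness of its own.
#' @slot background constant background level.
#' @slot noise_sd Gaussian pixel noise standard deviation.
#' @slot bleach_factor per-exposure multiplicative brightness decay (1 = no
#'   bleaching).
#' @exportClass RenderParams
setClass("RenderParams",
         slots = c(spot_sigma = "numeric", peak = "numeric",
                   background = "numeric", noise_sd = "numeric",
                   bleach_factor = "numeric"))

setValidity("RenderParams", function(object) {
  if (!is.na(object@spot_sigma) && object@spot_sigma <= 0)
    return("spot_sigma must be > 0 (or NA for size/4)")
  if (object@noise_sd < 0) return("noise_sd must be >= 0")
  if (object@peak < 0 || object@background < 0)
    return("peak and background must be >= 0")
  if (object@bleach_factor <= 0 || object@bleach_factor > 1)
    return("bleach_factor must be in (0, 1]")
  TRUE
})

#' @param spot_sigma,peak,background,noise_sd,bleach_factor see slots.
#' @return A [RenderParams-class] object.
#' @rdname RenderParams-class
#' @export
renderParams <- function(spot_sigma = NA_real_, peak = 200, background = 20,
                         noise_sd = 5, bleach_factor = 1) {
  new("RenderParams", spot_sigma = as.numeric(spot_sigma),
      peak = as.numeric(peak), background = as.numeric(background),
      noise_sd = as.numeric(noise_sd),
      bleach_factor = as.numeric(bleach_factor))
}

#' A tiled mosaic scan of an arena
#'
#' @slot tiles list of integer image matrices (rows = y, cols = x).
#' @slot specs list of [FrameSpec-class], one per tile (carrying the stage
#'   offset of each tile).
#' @slot nx,ny tile counts along x and y.
#' @slot overlap fractional overlap between adjacent tiles.
#' @exportClass MosaicScan
setClass("MosaicScan",
         slots = c(tiles = "list", specs = "list",
                   nx = "integer", ny = "integer", overlap = "numeric"))

setValidity("MosaicScan", function(object) {
  if (length(object@tiles) != length(object@specs))
    return("tiles and specs must have equal length")
  if (length(object@tiles) != object@nx * object@ny)
    return("tile count must equal nx * ny")
  TRUE
})

## ---------------------------------------------------------------------------
## Detection
## ---------------------------------------------------------------------------

#' Parameters of the local-variance cell detector
#'
#' The detector thresholds the local variance map at
#' `noise_level^2 * sensitivity`, so `sensitivity = 1` means "variance above
#' the noise floor". Components are then gated on equivalent-circle diameter
#' (um) and mean brightness.
#'
#' @slot window_radius half-width of the variance window in px (window is
#'   (2r+1) x (2r+1)).
#' @slot min_brightness,max_brightness mean-brightness gate.
#' @slot min_size,max_size equivalent-diameter gate in um.
#' @slot sensitivity dimensionless threshold multiplier (>= 0).
#' @slot noise_level image noise amplitude in brightness units (>= 0).
#' @exportClass DetectionParams
setClass("DetectionParams",
         slots = c(window_radius = "integer",
                   min_brightness = "numeric", max_brightness = "numeric",
                   min_size = "numeric", max_size = "numeric",
                   sensitivity = "numeric", noise_level = "numeric"))

setValidity("DetectionParams", function(object) {
  if (object@window_radius < 1L) return("window_radius must be >= 1")
  if (object@min_brightness > object@max_brightness)
    return("min_brightness must be <= max_brightness")
  if (object@min_size > object@max_size)
    return("min_size must be <= max_size")
  if (object@sensitivity < 0) return("sensitivity must be >= 0")
  if (object@noise_level < 0) return("noise_level must be >= 0")
  TRUE
})

#' @param window_radius,min_brightness,max_brightness,min_size,max_size,sensitivity,noise_level
#'   see slots.
#' @return A [DetectionParams-class] object.
#' @rdname DetectionParams-class
#' @export
detectionParams <- function(window_radius = 2L, min_brightness = 0,
                            max_brightness = Inf, min_size = 4,
                            max_size = 60, sensitivity = 4, noise_level = 5) {
  new("DetectionParams", window_radius = as.integer(window_radius),
      min_brightness = as.numeric(min_brightness),
      max_brightness = as.numeric(max_brightness),
      min_size = as.numeric(min_size), max_size = as.numeric(max_size),
      sensitivity = as.numeric(sensitivity),
      noise_level = as.numeric(noise_level))
}

#' Column dialect of an external detection table
#'
#' Describes how to read a CSV produced by an external segmenter. Each field
#' is a character vector of candidate column names tried in order; x and y
#' are mandatory in the data, the rest optional.
#'
#' @slot x,y,width,height,brightness candidate column names.
#' @slot units "px" or "um": units of the coordinate columns.
#' @exportClass DetectionDialect
setClass("DetectionDialect",
         slots = c(x = "character", y = "character",
                   width = "character", height = "character",
                   brightness = "character", units = "character"))

setValidity("DetectionDialect", function(object) {
  if (length(object@x) < 1 || length(object@y) < 1)
    return("x and y candidate columns are mandatory")
  if (!object@units %in% c("px", "um")) return("units must be 'px' or 'um'")
  TRUE
})

#' @param x,y,width,height,brightness candidate column names (tried in order).
#' @param units "px" or "um".
#' @return A [DetectionDialect-class] object.
#' @rdname DetectionDialect-class
#' @export
detectionDialect <- function(x, y, width = character(), height = character(),
                             brightness = character(), units = "px") {
  new("DetectionDialect", x = x, y = y, width = width, height = height,
      brightness = brightness, units = units)
}

#' @details `imagejDialect()` matches the ImageJ "Analyze Particles" results
#'   table: XStart/YStart (Record starts option) or X/Y centroids, the
#'   BX/BY/Width/Height bounding rectangle, and Mean brightness, all in
#'   pixels.
#' @rdname DetectionDialect-class
#' @export
imagejDialect <- function() {
  detectionDialect(x = c("XStart", "X"), y = c("YStart", "Y"),
                   width = "Width", height = "Height",
                   brightness = "Mean", units = "px")
}

## ---------------------------------------------------------------------------
## Suspension physics
## ---------------------------------------------------------------------------

#' Cell floating motion model (persistent random walk)
#'
#' Each cell carries a constant speed drawn once from
#' Normal(mean_speed, speed_sd) truncated at 0, and a heading that decorrelates
#' with the persistence time (redrawn uniformly with probability
#' 1 - exp(-dt / persistence_time) per step).
#'
#' Presets reproduce the measured floating speeds: `"open_dish"` 39 +/- 12
#' um/min (2 mm medium, no oil), `"thin_layer"` 5.4 +/- 1.1 um/min (~100 um
#' layer under oil), `"thin_layer_well"` 2.3 +/- 0.6 um/min (thin layer inside
#' a 5 x 5 mm^2 miniature-plate well).
#'
#' @slot mean_speed mean floating speed in um/min.
#' @slot speed_sd across-cell speed standard deviation in um/min.
#' @slot persistence_time direction decorrelation time in s.
#' @exportClass MotionModel
setClass("MotionModel",
         slots = c(mean_speed = "numeric", speed_sd = "numeric",
                   persistence_time = "numeric"))

setValidity("MotionModel", function(object) {
  if (object@mean_speed < 0) return("mean_speed must be >= 0")
  if (object@speed_sd < 0) return("speed_sd must be >= 0")
  if (object@persistence_time <= 0) return("persistence_time must be > 0")
  TRUE
})

#' @param mean_speed,speed_sd,persistence_time see slots.
#' @return A [MotionModel-class] object.
#' @rdname MotionModel-class
#' @export
motionModel <- function(mean_speed = 5.4, speed_sd = 1.1,
                        persistence_time = 300) {
  new("MotionModel", mean_speed = as.numeric(mean_speed),
      speed_sd = as.numeric(speed_sd),
      persistence_time = as.numeric(persistence_time))
}

#' @param preset one of "open_dish", "thin_layer", "thin_layer_well".
#' @rdname MotionModel-class
#' @export
motionPreset <- function(preset = c("thin_layer", "open_dish",
                                    "thin_layer_well")) {
  preset <- match.arg(preset)
  switch(preset,
         open_dish       = motionModel(39, 12, 300),
         thin_layer      = motionModel(5.4, 1.1, 300),
         thin_layer_well = motionModel(2.3, 0.6, 300))
}

#' Micropipette capture physics
#'
#' The sorting resolution of the 30 um I.D. micropipette: every cell within
#' `capture_radius` of the aim point is aspirated; cells farther away are not
#' removed. Volumes are the measured 1.4 nl pick-up and 147 nl deposition
#' volumes.
#'
#' @slot capture_radius capture radius in um.
#' @slot radius_sd optional per-pick Gaussian jitter of the radius (um).
#' @slot pick_volume volume removed per aspiration, nl.
#' @slot deposit_volume volume ejected per deposition, nl.
#' @slot deposit_spread_radius radius (um) within which co-ejected cells land
#'   around the deposition aim point (calibrated, not measured).
#' @slot pick_success_prob probability that an aspiration fires (1 in
#'   suspension).
#' @exportClass CaptureModel
setClass("CaptureModel",
         slots = c(capture_radius = "numeric", radius_sd = "numeric",
                   pick_volume = "numeric", deposit_volume = "numeric",
                   deposit_spread_radius = "numeric",
                   pick_success_prob = "numeric"))

setValidity("CaptureModel", function(object) {
  if (object@capture_radius <= 0) return("capture_radius must be > 0")
  if (object@radius_sd < 0) return("radius_sd must be >= 0")
  if (object@pick_volume <= 0 || object@deposit_volume <= 0)
    return("volumes must be > 0")
  if (object@deposit_spread_radius <= 0)
    return("deposit_spread_radius must be > 0")
  if (object@pick_success_prob < 0 || object@pick_success_prob > 1)
    return("pick_success_prob must be in [0, 1]")
  TRUE
})

#' @param capture_radius,radius_sd,pick_volume,deposit_volume,deposit_spread_radius,pick_success_prob
#'   see slots.
#' @return A [CaptureModel-class] object.
#' @rdname CaptureModel-class
#' @export
captureModel <- function(capture_radius = 34, radius_sd = 0,
                         pick_volume = 1.4, deposit_volume = 147,
                         deposit_spread_radius = 127,
                         pick_success_prob = 1) {
  new("CaptureModel", capture_radius = as.numeric(capture_radius),
      radius_sd = as.numeric(radius_sd),
      pick_volume = as.numeric(pick_volume),
      deposit_volume = as.numeric(deposit_volume),
      deposit_spread_radius = as.numeric(deposit_spread_radius),
      pick_success_prob = as.numeric(pick_success_prob))
}

#' @param preset "sparse" (measured 34 um resolution) or "dense" (effective
#'   63 um radius implied by the 25 bystanders/pick observed at 2,000
#'   cells/mm^2; calibrated, not measured).
#' @rdname CaptureModel-class
#' @export
capturePreset <- function(preset = c("sparse", "dense")) {
  preset <- match.arg(preset)
  switch(preset,
         sparse = captureModel(capture_radius = 34, radius_sd = 4),
         dense  = captureModel(capture_radius = 63, radius_sd = 4))
}

#' State of a thin-layer cell suspension
#'
#' @slot arena the [ArenaGeometry-class] confining the suspension.
#' @slot cells a cell table (see [cellTable()]); motion state columns
#'   `speed_um_min` and `heading_rad` are attached lazily by [stepMotion()].
#' @slot medium_volume current medium volume in nl.
#' @slot clock simulation time in s.
#' @exportClass SuspensionState
setClass("SuspensionState",
         slots = c(arena = "ArenaGeometry", cells = "data.frame",
                   medium_volume = "numeric", clock = "numeric"))

setValidity("SuspensionState", function(object) {
  if (object@medium_volume <= 0) return("medium_volume must be > 0")
  if (nrow(object@cells)) {
    ok <- arenaContains(object@arena,
                        cbind(object@cells$x_um, object@cells$y_um))
    if (!all(ok)) return("all cells must lie inside the arena")
  }
  TRUE
})

#' @param arena an [ArenaGeometry-class].
#' @param cells a cell table data.frame (default empty).
#' @param medium_volume medium volume in nl (default derived from arena
#'   area x layer height).
#' @param clock start time in s.
#' @return A [SuspensionState-class] object.
#' @rdname SuspensionState-class
#' @export
suspensionState <- function(arena, cells = emptyCellTable(),
                            medium_volume = mediumVolume(arena), clock = 0) {
  new("SuspensionState", arena = arena, cells = as.data.frame(cells),
      medium_volume = as.numeric(medium_volume), clock = as.numeric(clock))
}

#' A PDMS microwell array for passive single-cell trapping
#'
#' @slot pitch lattice constant in um.
#' @slot well_diameter well diameter in um (15 um fits monocytes, 20 um 3T3
#'   fibroblasts).
#' @slot n_rows,n_cols grid dimensions.
#' @slot fill_efficiency probability a well traps exactly one cell.
#' @slot well_pick_success probability a trapped cell can be aspirated out
#'   (cells adhere to PDMS; ~50%).
#' @exportClass MicrowellArray
setClass("MicrowellArray",
         slots = c(pitch = "numeric", well_diameter = "numeric",
                   n_rows = "integer", n_cols = "integer",
                   fill_efficiency = "numeric", well_pick_success = "numeric"))

setValidity("MicrowellArray", function(object) {
  if (object@well_diameter >= object@pitch)
    return("well_diameter must be < pitch")
  if (object@n_rows < 1L || object@n_cols < 1L)
    return("grid dimensions must be >= 1")
  if (object@fill_efficiency < 0 || object@fill_efficiency > 1 ||
      object@well_pick_success < 0 || object@well_pick_success > 1)
    return("probabilities must be in [0, 1]")
  TRUE
})

#' @param pitch,well_diameter,n_rows,n_cols,fill_efficiency,well_pick_success
#'   see slots.
#' @return A [MicrowellArray-class] object.
#' @rdname MicrowellArray-class
#' @export
microwellArray <- function(pitch = 100, well_diameter = 20, n_rows = 100L,
                           n_cols = 100L, fill_efficiency = 0.25,
                           well_pick_success = 0.5) {
  new("MicrowellArray", pitch = as.numeric(pitch),
      well_diameter = as.numeric(well_diameter),
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      fill_efficiency = as.numeric(fill_efficiency),
      well_pick_success = as.numeric(well_pick_success))
}

#' @param preset "monocyte" (15 um wells, fill 0.54) or "fibroblast"
#'   (20 um wells, fill 0.25). Both are 100 x 100 wells at 100 um pitch on a
#'   10 x 10 mm^2 PDMS plate.
#' @rdname MicrowellArray-class
#' @export
microwellPreset <- function(preset = c("fibroblast", "monocyte")) {
  preset <- match.arg(preset)
  switch(preset,
         monocyte   = microwellArray(well_diameter = 15,
                                     fill_efficiency = 0.54),
         fibroblast = microwellArray(well_diameter = 20,
                                     fill_efficiency = 0.25))
}

## ---------------------------------------------------------------------------
## Scheduling
## ---------------------------------------------------------------------------

#' Timed pressure/valve protocol of a pick or deposit
#'
#' Defaults are the optimized experimental parameters: a -100 Pa vacuum
#' pulse of 10 ms picks the cell, 1 s of ambient pressure (valve 2) stops the
#' flow, and a +4,200 Pa overpressure applied for 1 s deposits it; the 30 um
#' I.D. pipette approaches the dish surface to 5 um.
#'
#' @slot pipette_inner_diameter um.
#' @slot approach_height pick/deposit height above the surface, um.
#' @slot travel_height safe travel height between targets, um.
#' @slot vacuum Pa (negative).
#' @slot vacuum_pulse vacuum valve opening time, s.
#' @slot ambient_equilibrate ambient-pressure equilibration time, s.
#' @slot overpressure Pa (positive).
#' @slot deposit_pulse overpressure application time, s.
#' @exportClass PickProtocol
setClass("PickProtocol",
         slots = c(pipette_inner_diameter = "numeric",
                   approach_height = "numeric", travel_height = "numeric",
                   vacuum = "numeric", vacuum_pulse = "numeric",
                   ambient_equilibrate = "numeric",
                   overpressure = "numeric", deposit_pulse = "numeric"))

setValidity("PickProtocol", function(object) {
  if (!(object@vacuum < 0 && 0 < object@overpressure))
    return("vacuum must be < 0 < overpressure")
  if (any(c(object@vacuum_pulse, object@ambient_equilibrate,
            object@deposit_pulse) <= 0))
    return("pulse durations must be > 0")
  TRUE
})

#' @param pipette_inner_diameter,approach_height,travel_height,vacuum,vacuum_pulse,ambient_equilibrate,overpressure,deposit_pulse
#'   see slots.
#' @return A [PickProtocol-class] object.
#' @rdname PickProtocol-class
#' @export
pickProtocol <- function(pipette_inner_diameter = 30, approach_height = 5,
                         travel_height = 500, vacuum = -100,
                         vacuum_pulse = 0.010, ambient_equilibrate = 1,
                         overpressure = 4200, deposit_pulse = 1) {
  new("PickProtocol",
      pipette_inner_diameter = as.numeric(pipette_inner_diameter),
      approach_height = as.numeric(approach_height),
      travel_height = as.numeric(travel_height),
      vacuum = as.numeric(vacuum), vacuum_pulse = as.numeric(vacuum_pulse),
      ambient_equilibrate = as.numeric(ambient_equilibrate),
      overpressure = as.numeric(overpressure),
      deposit_pulse = as.numeric(deposit_pulse))
}

#' Destination layout for isolated cells
#'
#' @slot mode "grid" (deposition lattice in a well), "miniature_wells"
#'   (2 x 2 mm^2 wells of the 24-well miniature plate, one cell each) or
#'   "pcr_tubes".
#' @slot grid_pitch lattice constant of the deposition grid, um.
#' @slot grid_origin stage um of the first grid node.
#' @slot grid_ncol columns of the deposition grid (NA = ceiling(sqrt(n))).
#' @slot wells k x 2 matrix of well centres (stage um) in miniature_wells
#'   mode; capacity one cell per well.
#' @slot tube_count number of PCR tubes available.
#' @exportClass DestinationLayout
setClass("DestinationLayout",
         slots = c(mode = "character", grid_pitch = "numeric",
                   grid_origin = "numeric", grid_ncol = "integer",
                   wells = "matrix", tube_count = "integer"))

setValidity("DestinationLayout", function(object) {
  if (!object@mode %in% c("grid", "miniature_wells", "pcr_tubes"))
    return("mode must be grid, miniature_wells or pcr_tubes")
  if (object@grid_pitch <= 0) return("grid_pitch must be > 0")
  if (object@mode == "miniature_wells" && nrow(object@wells) < 1)
    return("well list must be non-empty in miniature_wells mode")
  TRUE
})

#' @param mode,grid_pitch,grid_origin,grid_ncol,wells,tube_count see slots.
#' @return A [DestinationLayout-class] object.
#' @rdname DestinationLayout-class
#' @export
destinationLayout <- function(mode = c("grid", "miniature_wells",
                                       "pcr_tubes"),
                              grid_pitch = 500, grid_origin = c(500, 500),
                              grid_ncol = NA_integer_,
                              wells = matrix(numeric(), 0, 2),
                              tube_count = 96L) {
  mode <- match.arg(mode)
  new("DestinationLayout", mode = mode, grid_pitch = as.numeric(grid_pitch),
      grid_origin = as.numeric(grid_origin),
      grid_ncol = as.integer(grid_ncol), wells = as.matrix(wells),
      tube_count = as.integer(tube_count))
}

#' @details `miniWellPlateLayout()` builds the 24-well miniature plate of
#'   2 x 2 mm^2 squares (4 x 6 grid of well centres, 2.5 mm pitch).
#' @param origin stage um of the first well centre.
#' @rdname DestinationLayout-class
#' @export
miniWellPlateLayout <- function(origin = c(1000, 1000)) {
  centers <- as.matrix(expand.grid(
    x = origin[1] + (0:5) * 2500,
    y = origin[2] + (0:3) * 2500))
  destinationLayout(mode = "miniature_wells", wells = centers)
}

#' An ordered pick-and-place plan
#'
#' @slot targets data.frame of targets in visiting order (id, x_um, y_um).
#' @slot destinations data.frame (label, x_um, y_um) aligned with targets.
#' @slot path_length total micropipette path length in um.
#' @slot protocol the [PickProtocol-class] applied per target.
#' @exportClass SortPlan
setClass("SortPlan",
         slots = c(targets = "data.frame", destinations = "data.frame",
                   path_length = "numeric", protocol = "PickProtocol"))

setValidity("SortPlan", function(object) {
  if (anyDuplicated(object@targets$id))
    return("every target must appear exactly once")
  if (nrow(object@destinations) != nrow(object@targets))
    return("destinations must align with targets")
  TRUE
})
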