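#' Render a synthetic microscope frame of a cell population
#'
#' In the fluorescent channel each labeled cell becomes an isotropic Gaussian
#' spot (sigma = `spot_sigma`, or cell size / 4 when `spot_sigma` is NA) with
#' amplitude equal to the cell's brightness (falling back to `peak`), on a
#' constant background with i.i.d. Gaussian pixel noise, clipped to the bit
#' range and rounded to integers. In the phase channel every cell is drawn as
#' a low-contrast ring at its radius. Cells outside the frame are clipped
#' silently; rendering is translation-equivariant in (cells, stage offset).
#'
#' @param cellsTab a cell table ([cellTable()]).
#' @param spec a [FrameSpec-class].
#' @param params a [RenderParams-class].
#' @param exposure exposure index (>= 1); brightness is scaled by
#'   `bleach_factor^(exposure - 1)`.
#' @param seed optional RNG seed (bit-identical images under a fixed seed).
#' @return Integer matrix `height x width` (rows = y, cols = x) with
#'   attribute `"spec"` carrying the [FrameSpec-class].
#' @examples
#' pop <- makePopulation(rectArena(200, 200), 3, 0, seed = 1)
#' img <- renderFrame(pop, frameSpec(160, 160), renderParams(noise_sd = 0))
#' range(img)
#' @export
renderFrame <- function(cellsTab, spec, params = renderParams(),
                        exposure = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- spec@height; w <- spec@width; ps <- spec@pixel_size
  img <- matrix(params@background, h, w)
  fade <- params@bleach_factor^(exposure - 1)

  if (nrow(cellsTab)) {
    if (spec@channel == "fluorescent") {
      vis <- cellsTab[cellsTab$labeled %in% TRUE, , drop = FALSE]
    } else {
      vis <- cellsTab
    }
    for (i in seq_len(nrow(vis))) {
      size <- vis$size_um[i]
      if (is.na(size)) size <- 16
      sig_um <- if (is.na(params@spot_sigma)) size / 4 else params@spot_sigma
      sig <- sig_um / ps
      amp <- vis$brightness[i]
      if (is.na(amp)) amp <- params@peak
      amp <- amp * fade
      # pixel (0-based, pixel-centre) position of the cell
      px <- (vis$x_um[i] - spec@offset[1]) / ps
      py <- (vis$y_um[i] - spec@offset[2]) / ps
      if (spec@channel == "fluorescent") {
        reach <- ceiling(5 * sig)
        j0 <- max(0L, floor(px) - reach); j1 <- min(w - 1L, ceiling(px) + reach)
        i0 <- max(0L, floor(py) - reach); i1 <- min(h - 1L, ceiling(py) + reach)
        if (j0 > j1 || i0 > i1) next
        dy2 <- ((i0:i1) - py)^2
        dx2 <- ((j0:j1) - px)^2
        patch <- amp * exp(-outer(dy2, dx2, "+") / (2 * sig^2))
        img[(i0:i1) + 1L, (j0:j1) + 1L] <-
          img[(i0:i1) + 1L, (j0:j1) + 1L] + patch
      } else {
        # faint bright ring at the cell radius (phase-contrast halo stand-in)
        R <- size / 2 / ps
        ring_sd <- max(0.75, sig / 2)
        reach <- ceiling(R + 4 * ring_sd)
        j0 <- max(0L, floor(px) - reach); j1 <- min(w - 1L, ceiling(px) + reach)
        i0 <- max(0L, floor(py) - reach); i1 <- min(h - 1L, ceiling(py) + reach)
        if (j0 > j1 || i0 > i1) next
        r <- sqrt(outer(((i0:i1) - py)^2, ((j0:j1) - px)^2, "+"))
        patch <- 0.15 * params@background * exp(-(r - R)^2 / (2 * ring_sd^2))
        img[(i0:i1) + 1L, (j0:j1) + 1L] <-
          img[(i0:i1) + 1L, (j0:j1) + 1L] + patch
      }
    }
  }

  if (params@noise_sd > 0)
    img <- img + matrix(rnorm(h * w, 0, params@noise_sd), h, w)
  top <- 2^spec@bit_depth - 1
  img <- round(pmin(pmax(img, 0), top))
  storage.mode(img) <- "integer"
  attr(img, "spec") <- spec
  img
}

#' Tile an arena into a mosaic scan
#'
#' Covers the arena bounding box with tiles of the given frame extent. Tiles
#' advance by `extent * (1 - overlap)` per axis, so the tile count per axis
#' is `ceiling(span / step)`; each tile records its own stage offset and a
#' cell falling in an overlap strip is rendered in every covering tile.
#'
#' @param arena an [ArenaGeometry-class].
#' @param cellsTab a cell table.
#' @param spec a [FrameSpec-class]; its offset is replaced per tile.
#' @param overlap fractional overlap in `[0, 0.5)`.
#' @param params a [RenderParams-class].
#' @param seed optional seed; per-tile noise streams are derived from it.
#' @return A [MosaicScan-class].
#' @export
generateMosaic <- function(arena, cellsTab, spec, overlap = 0,
                           params = renderParams(), seed = NULL) {
  stopifnot(overlap >= 0, overlap < 0.5)
  bb <- arenaBounds(arena)
  ex <- spec@width * spec@pixel_size
  ey <- spec@height * spec@pixel_size
  step_x <- ex * (1 - overlap)
  step_y <- ey * (1 - overlap)
  span_x <- bb["xmax"] - bb["xmin"]
  span_y <- bb["ymax"] - bb["ymin"]
  nx <- max(1L, as.integer(ceiling(span_x / step_x)))
  ny <- max(1L, as.integer(ceiling(span_y / step_y)))

  tiles <- vector("list", nx * ny)
  specs <- vector("list", nx * ny)
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      k <- k + 1L
      off <- c(bb["xmin"] + (ix - 1) * step_x,
               bb["ymin"] + (iy - 1) * step_y)
      tspec <- spec
      tspec@offset <- as.numeric(off)
      tiles[[k]] <- renderFrame(cellsTab, tspec, params,
                                seed = if (is.null(seed)) NULL else seed + k)
      specs[[k]] <- tspec
    }
  }
  new("MosaicScan", tiles = tiles, specs = specs, nx = nx, ny = ny,
      overlap = as.numeric(overlap))
}
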