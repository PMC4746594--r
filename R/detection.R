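## local-variance segmentation of fluorescent cells, mosaic-wide detection,
## and import of external (ImageJ) detection tables

# symmetric reflection padding by r pixels on every side (edge row included)
.reflectPad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r > nr || r > nc) stop("window does not fit in the image")
  m[c(r:1, 1:nr, nr:(nr - r + 1)), c(r:1, 1:nc, nc:(nc - r + 1)),
    drop = FALSE]
}

# moving k x k window sums; output (nr-k+1) x (nc-k+1)
.boxSum <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2, cumsum)
  v <- if (nr == k) cs[k, , drop = FALSE] else
    rbind(cs[k, ], cs[(k + 1):nr, , drop = FALSE] -
            cs[seq_len(nr - k), , drop = FALSE])
  cs2 <- t(apply(v, 1, cumsum))
  if (nrow(v) == 1) cs2 <- matrix(cs2, nrow = 1)
  if (nc == k) cs2[, k, drop = FALSE] else
    cbind(cs2[, k], cs2[, (k + 1):nc, drop = FALSE] -
            cs2[, seq_len(nc - k), drop = FALSE])
}

#' Local variance map of an image
#'
#' Each output pixel is the sample variance (n - 1 denominator) of the
#' intensities in the (2r+1) x (2r+1) window centred on it; image borders are
#' handled by symmetric reflection. Computed with integral images, so it is
#' O(pixels) regardless of the window size.
#'
#' @param image 2D numeric/integer matrix.
#' @param window_radius window half-width r in px (>= 1).
#' @return Numeric matrix of the same size as `image`.
#' @examples
#' localVarianceMap(matrix(1, 5, 5), 1)   # constant image -> all zero
#' @export
localVarianceMap <- function(image, window_radius = 2L) {
  r <- as.integer(window_radius)
  stopifnot(r >= 1L)
  m <- matrix(as.numeric(image), nrow(image), ncol(image))
  p <- .reflectPad(m, r)
  k <- 2L * r + 1L
  n <- k * k
  S <- .boxSum(p, k)
  S2 <- .boxSum(p * p, k)
  v <- (S2 - S * S / n) / (n - 1)
  pmax(v, 0)
}

# 8-connected labeling: EBImage::bwlabel (4-connected) plus a union-find
# pass merging diagonally adjacent labels
.label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1L))
  mx <- max(lab)
  if (mx <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal
  c2 <- lab[-1, -nc]; d <- lab[-nr, -1]   # up-right diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c2), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(mx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(pairs))) {
    ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(mx), find, 0L)
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Detect fluorescent cells in a single frame
#'
#' The detection pipeline: local variance map, threshold at
#' `noise_level^2 * sensitivity`, 8-connected components with hole filling,
#' then per component the intensity-weighted centroid (stage um), the
#' equivalent-circle diameter from the component area, and the mean
#' brightness. Components outside the size or brightness gates are dropped.
#' Touching cells are not split.
#'
#' @param image integer/numeric image matrix (as from [renderFrame()]).
#' @param params a [DetectionParams-class].
#' @param spec the [FrameSpec-class] of the image (default: its `"spec"`
#'   attribute).
#' @return A cell table sorted by y then x, with ids `d0001`, ...
#' @examples
#' pop <- makePopulation(rectArena(200, 200), 2, 0, min_separation = 80,
#'                       seed = 2)
#' img <- renderFrame(pop, frameSpec(160, 160), renderParams(noise_sd = 0))
#' segmentFrame(img)
#' @export
segmentFrame <- function(image, params = detectionParams(),
                         spec = attr(image, "spec")) {
  if (is.null(spec)) stop("no FrameSpec: pass spec= or use a rendered frame")
  validObject(params)
  ps <- spec@pixel_size
  v <- localVarianceMap(image, params@window_radius)
  mask <- v > params@noise_level^2 * params@sensitivity
  if (!any(mask)) return(emptyCellTable())
  mask <- EBImage::imageData(EBImage::fillHull(mask * 1L)) > 0
  lab <- .label8(mask)
  K <- max(lab)
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  nr <- nrow(img)
  nz <- which(lab > 0)
  lv <- lab[nz]
  rows0 <- (nz - 1L) %% nr          # 0-based pixel row
  cols0 <- (nz - 1L) %/% nr         # 0-based pixel col
  w <- img[nz]
  by <- split(seq_along(nz), lv)
  area <- lengths(by)
  sumw <- vapply(by, function(i) sum(w[i]), 0)
  cx <- vapply(seq_len(K), function(k) {
    i <- by[[k]]
    if (sumw[k] > 0) sum(cols0[i] * w[i]) / sumw[k] else mean(cols0[i])
  }, 0)
  cy <- vapply(seq_len(K), function(k) {
    i <- by[[k]]
    if (sumw[k] > 0) sum(rows0[i] * w[i]) / sumw[k] else mean(rows0[i])
  }, 0)
  mean_b <- sumw / area
  diam_um <- 2 * sqrt(area / pi) * ps
  x_um <- cx * ps + spec@offset[1]
  y_um <- cy * ps + spec@offset[2]
  keep <- diam_um >= params@min_size & diam_um <= params@max_size &
    mean_b >= params@min_brightness & mean_b <= params@max_brightness
  ord <- order(y_um[keep], x_um[keep])
  x_um <- x_um[keep][ord]; y_um <- y_um[keep][ord]
  out <- cellTable(id = sprintf("d%04d", seq_along(x_um)),
                   x_um = x_um, y_um = y_um,
                   size_um = diam_um[keep][ord],
                   brightness = mean_b[keep][ord],
                   labeled = TRUE, t_s = NA_real_)
  out
}

#' Detect cells across a mosaic scan
#'
#' Runs [segmentFrame()] on every tile (tile offsets already map centroids
#' to stage um) and merges detections from different tiles closer than
#' `dedup_radius`, keeping the duplicate whose centroid is farthest from its
#' own tile border (least edge truncation).
#'
#' @param mosaic a [MosaicScan-class].
#' @param params a [DetectionParams-class].
#' @param dedup_radius merge radius in um.
#' @return A cell table with mosaic-unique ids.
#' @export
detectMosaic <- function(mosaic, params = detectionParams(),
                         dedup_radius = 20) {
  psizes <- vapply(mosaic@specs, function(s) s@pixel_size, 0)
  if (length(unique(psizes)) > 1)
    stop("inconsistent pixel sizes across mosaic tiles")
  dets <- vector("list", length(mosaic@tiles))
  for (k in seq_along(mosaic@tiles)) {
    spec <- mosaic@specs[[k]]
    d <- segmentFrame(mosaic@tiles[[k]], params, spec)
    if (nrow(d)) {
      d$id <- sprintf("t%03d_%s", k, d$id)
      dx <- d$x_um - spec@offset[1]
      dy <- d$y_um - spec@offset[2]
      d$.border <- pmin(dx, spec@width * spec@pixel_size - dx,
                        dy, spec@height * spec@pixel_size - dy)
      d$.tile <- k
    }
    dets[[k]] <- d
  }
  all <- do.call(rbind, dets[vapply(dets, nrow, 0L) > 0])
  if (is.null(all) || nrow(all) == 0) return(emptyCellTable())
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d2 <- (all$x_um[(i + 1):n] - all$x_um[i])^2 +
        (all$y_um[(i + 1):n] - all$y_um[i])^2
      js <- which(d2 < dedup_radius^2 &
                    all$.tile[(i + 1):n] != all$.tile[i]) + i
      for (j in js) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  grp <- vapply(seq_len(n), find, 0L)
  keep <- vapply(split(seq_len(n), grp),
                 function(i) i[which.max(all$.border[i])], 0L)
  out <- all[sort(keep), setdiff(names(all), c(".border", ".tile")),
             drop = FALSE]
  out <- out[order(out$y_um, out$x_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import detections from an external segmenter
#'
#' Reads a CSV detection table (e.g. the ImageJ "Analyze Particles" results
#' dialect with XStart/YStart or X/Y, BX/BY/Width/Height and Mean columns)
#' and converts pixel coordinates to stage um through the frame
#' specification.
#'
#' @param file path or connection to the CSV (header row required).
#' @param dialect a [DetectionDialect-class]; default [imagejDialect()].
#' @param spec the [FrameSpec-class] the pixel coordinates refer to.
#' @return A cell table; optional columns missing from the file yield NA
#'   fields. Bounding-box columns `bbox_w_um`/`bbox_h_um` are attached when
#'   present in the source.
#' @export
importExternalDetections <- function(file, dialect = imagejDialect(),
                                     spec = frameSpec()) {
  validObject(dialect)
  df <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  pickCol <- function(cands) {
    hit <- cands[cands %in% names(df)]
    if (length(hit)) hit[1] else NA_character_
  }
  xc <- pickCol(dialect@x)
  yc <- pickCol(dialect@y)
  if (is.na(xc))
    stop(sprintf("missing x column (tried: %s)",
                 paste(dialect@x, collapse = ", ")))
  if (is.na(yc))
    stop(sprintf("missing y column (tried: %s)",
                 paste(dialect@y, collapse = ", ")))
  num <- function(colname) {
    v <- df[[colname]]
    nv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(nv) & !(is.na(v) | v == ""))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at row %d",
                   v[bad[1]], colname, bad[1]))
    nv
  }
  n <- nrow(df)
  if (n == 0) return(emptyCellTable())
  x <- num(xc); y <- num(yc)
  wc <- pickCol(dialect@width); hc <- pickCol(dialect@height)
  bc <- pickCol(dialect@brightness)
  wv <- if (!is.na(wc)) num(wc) else rep(NA_real_, n)
  hv <- if (!is.na(hc)) num(hc) else rep(NA_real_, n)
  bv <- if (!is.na(bc)) num(bc) else rep(NA_real_, n)
  if (dialect@units == "px") {
    ps <- spec@pixel_size
    x <- x * ps + spec@offset[1]
    y <- y * ps + spec@offset[2]
    wv <- wv * ps
    hv <- hv * ps
  }
  size <- ifelse(!is.na(wv) & !is.na(hv), (wv + hv) / 2, NA_real_)
  out <- cellTable(id = sprintf("x%04d", seq_len(n)), x_um = x, y_um = y,
                   size_um = size, brightness = bv, labeled = TRUE,
                   t_s = NA_real_)
  out$bbox_w_um <- wv
  out$bbox_h_um <- hv
  out
}
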