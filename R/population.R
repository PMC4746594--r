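#' Generate a random cell population inside an arena
#'
#' Places labeled and unlabeled cells uniformly at random inside the arena
#' polygon, optionally enforcing a hard-core minimum separation by
#' dart-throwing (rejection with a retry cap of 100 attempts per cell).
#' Sizes and brightnesses are drawn per cell; unlabeled cells carry no
#' fluorescence so their brightness applies only to phase renders.
#'
#' @param arena an [ArenaGeometry-class].
#' @param n_labeled,n_unlabeled cell counts (>= 0).
#' @param min_separation hard-core distance in um (0 disables the check;
#'   must leave the packing fraction below 0.5).
#' @param size_mean,size_sd cell diameter distribution, um (truncated > 1).
#' @param brightness_mean,brightness_sd fluorescence brightness distribution
#'   (truncated > 0).
#' @param seed optional RNG seed for a deterministic population.
#' @return A cell table ([cellTable()]) with `n_labeled + n_unlabeled` rows;
#'   labeled cells first.
#' @examples
#' pop <- makePopulation(rectArena(1000, 1000), n_labeled = 5,
#'                       n_unlabeled = 50, min_separation = 20, seed = 1)
#' nrow(pop)
#' @export
makePopulation <- function(arena, n_labeled, n_unlabeled,
                           min_separation = 0,
                           size_mean = 16, size_sd = 2,
                           brightness_mean = 200, brightness_sd = 15,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_labeled >= 0, n_unlabeled >= 0, min_separation >= 0)
  n <- n_labeled + n_unlabeled
  if (n == 0) return(emptyCellTable())

  area <- arenaArea(arena)
  if (min_separation > 0) {
    packing <- n * pi * (min_separation / 2)^2 / area
    if (packing >= 0.5)
      stop(sprintf("infeasible packing: fraction %.2f >= 0.5", packing))
  }

  bb <- arenaBounds(arena)
  pos <- matrix(NA_real_, n, 2)
  if (min_separation == 0) {
    # fast path: plain uniform rejection against the polygon
    placed <- 0L
    while (placed < n) {
      m <- max(2L * (n - placed), 100L)
      cand <- cbind(runif(m, bb["xmin"], bb["xmax"]),
                    runif(m, bb["ymin"], bb["ymax"]))
      cand <- cand[arenaContains(arena, cand), , drop = FALSE]
      take <- min(nrow(cand), n - placed)
      if (take > 0) {
        pos[(placed + 1):(placed + take), ] <- cand[seq_len(take), ]
        placed <- placed + take
      }
    }
  } else {
    # dart throwing with a grid hash so only neighboring bins are scanned
    bin <- min_separation
    nbx <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / bin))
    nby <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / bin))
    grid <- vector("list", nbx * nby)
    cap <- 100L * n
    attempts <- 0L
    placed <- 0L
    min2 <- min_separation^2
    while (placed < n) {
      if (attempts >= cap)
        stop(sprintf(
          "infeasible packing: retry cap exceeded after placing %d of %d cells",
          placed, n))
      attempts <- attempts + 1L
      x <- runif(1, bb["xmin"], bb["xmax"])
      y <- runif(1, bb["ymin"], bb["ymax"])
      if (!arenaContains(arena, cbind(x, y))) next
      ix <- min(nbx - 1L, max(0L, floor((x - bb["xmin"]) / bin)))
      iy <- min(nby - 1L, max(0L, floor((y - bb["ymin"]) / bin)))
      clash <- FALSE
      for (jx in max(0L, ix - 1L):min(nbx - 1L, ix + 1L)) {
        for (jy in max(0L, iy - 1L):min(nby - 1L, iy + 1L)) {
          pts <- grid[[jx + nbx * jy + 1L]]
          if (!is.null(pts) &&
              any((pts[, 1] - x)^2 + (pts[, 2] - y)^2 < min2)) {
            clash <- TRUE
            break
          }
        }
        if (clash) break
      }
      if (clash) next
      placed <- placed + 1L
      pos[placed, ] <- c(x, y)
      key <- ix + nbx * iy + 1L
      grid[[key]] <- rbind(grid[[key]], c(x, y))
    }
  }

  rtrunc <- function(k, mean, sd, lo) {
    out <- rnorm(k, mean, sd)
    bad <- which(out <= lo)
    while (length(bad)) {
      out[bad] <- rnorm(length(bad), mean, sd)
      bad <- bad[out[bad] <= lo]
    }
    out
  }
  cellTable(id = sprintf("c%05d", seq_len(n)),
            x_um = pos[, 1], y_um = pos[, 2],
            size_um = rtrunc(n, size_mean, size_sd, 1),
            brightness = rtrunc(n, brightness_mean, brightness_sd, 0),
            labeled = rep(c(TRUE, FALSE), c(n_labeled, n_unlabeled)),
            t_s = 0)
}
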