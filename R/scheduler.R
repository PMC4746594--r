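#' Plan the visiting order of targets (greedy nearest-neighbour tour)
#'
#' From the start point, repeatedly visit the nearest unvisited target
#' (ties broken by smaller id). The micropipette path length is the sum of
#' consecutive Euclidean distances including the entry segment from `start`.
#'
#' @param cellsTab cell table of targets.
#' @param start stage um c(x, y) of the pipette before the first pick.
#' @return A list: `order` (character ids in visiting order), `path_length`
#'   (um).
#' @export
planRoute <- function(cellsTab, start = c(0, 0)) {
  n <- nrow(cellsTab)
  if (n == 0) return(list(order = character(), path_length = 0))
  x <- cellsTab$x_um; y <- cellsTab$y_um; id <- cellsTab$id
  left <- seq_len(n)
  cur <- c(start[1], start[2])
  ord <- integer(n)
  len <- 0
  for (k in seq_len(n)) {
    d <- sqrt((x[left] - cur[1])^2 + (y[left] - cur[2])^2)
    pick <- left[order(d, id[left])[1]]
    len <- len + sqrt((x[pick] - cur[1])^2 + (y[pick] - cur[2])^2)
    ord[k] <- pick
    cur <- c(x[pick], y[pick])
    left <- setdiff(left, pick)
  }
  list(order = id[ord], path_length = len)
}

#' Assign destinations to isolated cells
#'
#' Grid mode places cells row-major on a lattice (default 500 um pitch, the
#' deposition grid of the dense-sorting experiment); miniature-wells mode
#' places one cell per 2 x 2 mm^2 well centre (24-well plate capacity);
#' PCR-tube mode numbers tubes 1..n.
#'
#' @param n number of cells (>= 0).
#' @param layout a [DestinationLayout-class].
#' @return data.frame with columns label, x_um, y_um (NA coordinates for
#'   tubes).
#' @export
assignDestinations <- function(n, layout = destinationLayout()) {
  stopifnot(n >= 0)
  if (n == 0)
    return(data.frame(label = character(), x_um = numeric(),
                      y_um = numeric(), stringsAsFactors = FALSE))
  switch(layout@mode,
    grid = {
      ncol <- if (is.na(layout@grid_ncol)) ceiling(sqrt(n)) else
        layout@grid_ncol
      i <- seq_len(n) - 1L
      data.frame(label = sprintf("grid_%03d", seq_len(n)),
                 x_um = layout@grid_origin[1] + (i %% ncol) *
                   layout@grid_pitch,
                 y_um = layout@grid_origin[2] + (i %/% ncol) *
                   layout@grid_pitch,
                 stringsAsFactors = FALSE)
    },
    miniature_wells = {
      cap <- nrow(layout@wells)
      if (n > cap)
        stop(sprintf("%d cells exceed the %d-well capacity", n, cap))
      data.frame(label = sprintf("well_%02d", seq_len(n)),
                 x_um = layout@wells[seq_len(n), 1],
                 y_um = layout@wells[seq_len(n), 2],
                 stringsAsFactors = FALSE)
    },
    pcr_tubes = {
      if (n > layout@tube_count)
        stop(sprintf("%d cells exceed the %d-tube capacity", n,
                     layout@tube_count))
      data.frame(label = sprintf("tube_%02d", seq_len(n)),
                 x_um = NA_real_, y_um = NA_real_, stringsAsFactors = FALSE)
    })
}

#' Build a sort plan: route + destinations + protocol
#'
#' @param cellsTab cell table of targets.
#' @param layout a [DestinationLayout-class].
#' @param start pipette start position, stage um.
#' @param protocol a [PickProtocol-class].
#' @return A [SortPlan-class].
#' @export
buildSortPlan <- function(cellsTab, layout = destinationLayout(),
                          start = c(0, 0), protocol = pickProtocol()) {
  route <- planRoute(cellsTab, start)
  ord <- match(route$order, cellsTab$id)
  targets <- data.frame(id = cellsTab$id[ord],
                        x_um = cellsTab$x_um[ord],
                        y_um = cellsTab$y_um[ord],
                        stringsAsFactors = FALSE)
  dest <- assignDestinations(nrow(targets), layout)
  new("SortPlan", targets = targets, destinations = dest,
      path_length = route$path_length, protocol = protocol)
}

#' Emit the timed pressure/valve action sequence of a sort plan
#'
#' Per pick: move above the target, descend to the approach height, open
#' valve 1 for the vacuum pulse (10 ms at -100 Pa), open valve 2 to ambient
#' pressure for 1 s to stop the flow, ascend. Per deposit: move, descend,
#' open valve 1 at +4,200 Pa for 1 s, ascend. Moves are instantaneous;
#' timestamps are absolute and advance only by the pulse durations
#' (5 actions per pick, 4 per deposit).
#'
#' @param plan a [SortPlan-class].
#' @param protocol a [PickProtocol-class] (default: the plan's).
#' @param deposits emit the deposit actions as well (default TRUE; FALSE
#'   gives a pick-only sequence).
#' @return data.frame with columns t_s, action, x_um, y_um, z_um,
#'   pressure_Pa, duration_s.
#' @export
emitProtocol <- function(plan, protocol = plan@protocol, deposits = TRUE) {
  n <- nrow(plan@targets)
  rows <- vector("list", 9L * n)
  t <- 0
  k <- 0L
  add <- function(action, x, y, z, p, dur) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(t_s = t, action = action, x_um = x, y_um = y,
                             z_um = z, pressure_Pa = p, duration_s = dur,
                             stringsAsFactors = FALSE)
    t <<- t + dur
  }
  for (i in seq_len(n)) {
    tx <- plan@targets$x_um[i]; ty <- plan@targets$y_um[i]
    add("move", tx, ty, protocol@travel_height, 0, 0)
    add("descend", tx, ty, protocol@approach_height, 0, 0)
    add("valve1_vacuum", tx, ty, protocol@approach_height,
        protocol@vacuum, protocol@vacuum_pulse)
    add("valve2_ambient", tx, ty, protocol@approach_height, 0,
        protocol@ambient_equilibrate)
    add("ascend", tx, ty, protocol@travel_height, 0, 0)
    if (deposits) {
      dx <- plan@destinations$x_um[i]; dy <- plan@destinations$y_um[i]
      add("move", dx, dy, protocol@travel_height, 0, 0)
      add("descend", dx, dy, protocol@approach_height, 0, 0)
      add("valve1_overpressure", dx, dy, protocol@approach_height,
          protocol@overpressure, protocol@deposit_pulse)
      add("ascend", dx, dy, protocol@travel_height, 0, 0)
    }
  }
  if (k == 0)
    return(data.frame(t_s = numeric(), action = character(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      pressure_Pa = numeric(), duration_s = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

#' Serialize a sort plan to JSON / an action sequence to CSV
#'
#' @param plan a [SortPlan-class].
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeSortPlan <- function(plan, file) {
  jsonlite::write_json(
    list(targets = plan@targets, destinations = plan@destinations,
         path_length_um = plan@path_length,
         protocol = list(
           pipette_inner_diameter_um = plan@protocol@pipette_inner_diameter,
           approach_height_um = plan@protocol@approach_height,
           vacuum_Pa = plan@protocol@vacuum,
           vacuum_pulse_s = plan@protocol@vacuum_pulse,
           ambient_equilibrate_s = plan@protocol@ambient_equilibrate,
           overpressure_Pa = plan@protocol@overpressure,
           deposit_pulse_s = plan@protocol@deposit_pulse)),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeSortPlan
#' @param actions action data.frame from [emitProtocol()].
#' @export
writeProtocolCsv <- function(actions, file) {
  write.csv(actions, file, row.names = FALSE)
  invisible(file)
}
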