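## digital twin of the thin-layer suspension: floating motion, capture
## physics with nanoliter accounting, deposition spread, microwell trapping

# draw truncated-at-zero normal speeds
.rspeed <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

# reflect positions into [lo, hi] by folding
.reflect1 <- function(p, lo, hi) {
  L <- hi - lo
  if (L <= 0) return(rep(lo, length(p)))
  q <- (p - lo) %% (2 * L)
  ifelse(q > L, lo + 2 * L - q, lo + q)
}

# ensure motion-state columns exist (speed drawn once per cell)
.ensureMotion <- function(tab, model) {
  n <- nrow(tab)
  if (is.null(tab$speed_um_min)) tab$speed_um_min <- NA_real_
  if (is.null(tab$heading_rad)) tab$heading_rad <- NA_real_
  miss <- which(is.na(tab$speed_um_min))
  if (length(miss)) {
    tab$speed_um_min[miss] <- .rspeed(length(miss), model@mean_speed,
                                      model@speed_sd)
    tab$heading_rad[miss] <- runif(length(miss), 0, 2 * pi)
  }
  tab
}

#' Advance cell floating motion by one time step
#'
#' Persistent random walk (run-and-tumble): each cell keeps a constant speed
#' drawn once from Normal(mean_speed, speed_sd) truncated at 0, and a heading
#' redrawn uniformly with probability 1 - exp(-dt / persistence_time).
#' Displacement is speed x dt along the heading, with reflecting boundaries
#' at the arena bounding box. The clock advances by dt.
#'
#' @param state a [SuspensionState-class].
#' @param dt time step in s (> 0).
#' @param model a [MotionModel-class].
#' @return The advanced [SuspensionState-class].
#' @export
stepMotion <- function(state, dt, model = motionPreset("thin_layer")) {
  stopifnot(dt > 0)
  tab <- state@cells
  if (nrow(tab)) {
    tab <- .ensureMotion(tab, model)
    n <- nrow(tab)
    redraw <- runif(n) < 1 - exp(-dt / model@persistence_time)
    if (any(redraw))
      tab$heading_rad[redraw] <- runif(sum(redraw), 0, 2 * pi)
    step_um <- tab$speed_um_min / 60 * dt
    bb <- arenaBounds(state@arena)
    tab$x_um <- .reflect1(tab$x_um + step_um * cos(tab$heading_rad),
                          bb["xmin"], bb["xmax"])
    tab$y_um <- .reflect1(tab$y_um + step_um * sin(tab$heading_rad),
                          bb["ymin"], bb["ymax"])
    tab$t_s <- state@clock + dt
  }
  state@cells <- tab
  state@clock <- state@clock + dt
  state
}

#' Aspirate at a stage position: capture-radius pick physics
#'
#' With probability `pick_success_prob` the pick fires and every cell within
#' the capture radius of the aim point (default the measured 34 um sorting
#' resolution, with optional per-pick radius jitter) is removed from the
#' suspension; cells farther away are never removed. The medium volume
#' decreases by `pick_volume` (1.4 nl) whether or not the pick fires — fluid
#' is drawn regardless.
#'
#' @param state a [SuspensionState-class].
#' @param aim stage um c(x, y); must lie inside the arena.
#' @param capture a [CaptureModel-class].
#' @param target_id optional id of the intended target, recorded in the
#'   event.
#' @return A list with `event` (list: aim, target_id, target_picked,
#'   picked_ids, picked (cell table rows), n_bystanders, removed_volume_nl,
#'   success, radius_um) and `state` (the updated state).
#' @export
pickAt <- function(state, aim, capture = capturePreset("sparse"),
                   target_id = NULL) {
  aim <- as.numeric(aim)
  if (!arenaContains(state@arena, matrix(aim, 1)))
    stop("aim point lies outside the arena")
  radius <- max(1e-6, capture@capture_radius +
                  rnorm(1, 0, capture@radius_sd))
  success <- runif(1) <= capture@pick_success_prob
  tab <- state@cells
  idx <- integer()
  if (success && nrow(tab)) {
    d2 <- (tab$x_um - aim[1])^2 + (tab$y_um - aim[2])^2
    idx <- which(d2 <= radius^2)
  }
  picked <- tab[idx, , drop = FALSE]
  if (length(idx)) state@cells <- tab[-idx, , drop = FALSE]
  state@medium_volume <- state@medium_volume - capture@pick_volume
  target_picked <- !is.null(target_id) && target_id %in% picked$id
  n_by <- nrow(picked) - as.integer(target_picked)
  list(event = list(aim = aim, target_id = target_id,
                    target_picked = target_picked,
                    picked_ids = picked$id, picked = picked,
                    n_bystanders = n_by,
                    removed_volume_nl = capture@pick_volume,
                    success = success, radius_um = radius),
       state = state)
}

#' Deposit cells around a stage position
#'
#' Ejects the given cells into the destination suspension: they land
#' uniformly within `deposit_spread_radius` (127 um, calibrated) of the aim
#' point, clipped to the arena, and the medium volume increases by
#' `deposit_volume` (147 nl) whether or not any cells are carried. Ids are
#' preserved.
#'
#' @param state destination [SuspensionState-class].
#' @param cellsTab cell table of the carried cells (may be empty).
#' @param aim stage um c(x, y) inside the destination arena.
#' @param capture a [CaptureModel-class].
#' @return The updated destination state.
#' @export
depositAt <- function(state, cellsTab, aim,
                      capture = capturePreset("sparse")) {
  aim <- as.numeric(aim)
  if (!arenaContains(state@arena, matrix(aim, 1)))
    stop("aim point lies outside the arena")
  n <- nrow(cellsTab)
  if (n) {
    r <- capture@deposit_spread_radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    bb <- arenaBounds(state@arena)
    cellsTab$x_um <- pmin(pmax(aim[1] + r * cos(th), bb["xmin"]),
                          bb["xmax"])
    cellsTab$y_um <- pmin(pmax(aim[2] + r * sin(th), bb["ymin"]),
                          bb["ymax"])
    cellsTab$t_s <- state@clock
    old <- state@cells
    for (cn in setdiff(names(old), names(cellsTab)))
      cellsTab[[cn]] <- NA
    for (cn in setdiff(names(cellsTab), names(old)))
      if (nrow(old)) old[[cn]] <- NA else old[[cn]] <-
          cellsTab[[cn]][0]
    state@cells <- rbind(old[names(cellsTab)], cellsTab)
  }
  state@medium_volume <- state@medium_volume + capture@deposit_volume
  validObject(state)
  state
}

#' Load a microwell array with settling cells
#'
#' Bernoulli-per-well trapping: each well is independently occupied with
#' probability `fill_efficiency` (at most one cell per well — wells are
#' cell-sized), capped by the number of applied cells. Untrapped cells are
#' washed away.
#'
#' @param array a [MicrowellArray-class].
#' @param n_applied number of cells applied to the plate (>= 0).
#' @return A list: `occupancy` (logical n_rows x n_cols matrix), `trapped`,
#'   `untrapped`, `untrapped_fraction`, `fill_fraction`.
#' @export
loadMicrowellArray <- function(array, n_applied) {
  stopifnot(n_applied >= 0)
  nw <- array@n_rows * array@n_cols
  occ <- runif(nw) < array@fill_efficiency
  extra <- sum(occ) - n_applied
  if (extra > 0) {
    drop <- sample(which(occ), extra)
    occ[drop] <- FALSE
  }
  trapped <- sum(occ)
  untrapped <- n_applied - trapped
  list(occupancy = matrix(occ, array@n_rows, array@n_cols),
       trapped = trapped, untrapped = untrapped,
       untrapped_fraction = if (n_applied > 0) untrapped / n_applied else
         NA_real_,
       fill_fraction = trapped / nw)
}

#' Expected untrapped fraction of a microwell array (closed form)
#'
#' @param array a [MicrowellArray-class].
#' @param n_applied number of applied cells (> 0).
#' @return Expected fraction of applied cells not trapped:
#'   (n_applied - n_wells * fill_efficiency) / n_applied, floored at 0.
#' @export
expectedUntrappedFraction <- function(array, n_applied) {
  stopifnot(n_applied > 0)
  nw <- array@n_rows * array@n_cols
  max(0, (n_applied - nw * array@fill_efficiency) / n_applied)
}

#' Attempt to aspirate a cell out of one microwell
#'
#' Cells adhere to the PDMS wells: an occupied well yields the cell with
#' probability `well_pick_success` (about 50%), otherwise the cell remains
#' stuck (at risk of damage); an empty well yields nothing.
#'
#' @param occupancy logical occupancy matrix from [loadMicrowellArray()].
#' @param index well index (position in the matrix).
#' @param well_pick_success aspiration success probability.
#' @return A list: `outcome` ("isolated", "stuck" or "empty") and the
#'   updated `occupancy`.
#' @export
pickFromWell <- function(occupancy, index, well_pick_success = 0.5) {
  stopifnot(index >= 1, index <= length(occupancy))
  if (!occupancy[index])
    return(list(outcome = "empty", occupancy = occupancy))
  if (runif(1) <= well_pick_success) {
    occupancy[index] <- FALSE
    list(outcome = "isolated", occupancy = occupancy)
  } else {
    list(outcome = "stuck", occupancy = occupancy)
  }
}

#' Record time-lapse trajectories of floating cells
#'
#' Mirrors the floating-speed measurement: positions recorded every
#' `frame_interval` (30 s) for `duration` (1 h), giving
#' 1 + floor(duration / frame_interval) frames per cell.
#'
#' @param state a [SuspensionState-class].
#' @param model a [MotionModel-class].
#' @param frame_interval sampling interval in s.
#' @param duration total duration in s (>= frame_interval).
#' @return A track table: data.frame(t_s, id, x_um, y_um, labeled), one row
#'   per cell per frame.
#' @export
simulateTimelapse <- function(state, model = motionPreset("thin_layer"),
                              frame_interval = 30, duration = 3600) {
  stopifnot(frame_interval > 0, frame_interval <= duration)
  nframes <- 1L + floor(duration / frame_interval)
  out <- vector("list", nframes)
  snap <- function(s, t) data.frame(t_s = t, id = s@cells$id,
                                    x_um = s@cells$x_um,
                                    y_um = s@cells$y_um,
                                    labeled = s@cells$labeled,
                                    stringsAsFactors = FALSE)
  t0 <- state@clock
  out[[1]] <- snap(state, 0)
  for (k in seq_len(nframes - 1L)) {
    state <- stepMotion(state, frame_interval, model)
    out[[k + 1L]] <- snap(state, state@clock - t0)
  }
  tracks <- do.call(rbind, out)
  rownames(tracks) <- NULL
  tracks
}

#' Write simulator outputs as plain-text tables
#'
#' `writeTrackSet()` writes a track table as CSV; `writeEventLog()` writes
#' pick/deposit events as JSON lines.
#'
#' @param tracks track table from [simulateTimelapse()].
#' @param file output path.
#' @return The file path, invisibly.
#' @export
writeTrackSet <- function(tracks, file) {
  write.csv(tracks, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTrackSet
#' @param events list of pick/deposit event lists.
#' @export
writeEventLog <- function(events, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (e in events) {
    e$picked <- NULL  # keep the log line compact: ids carry the identity
    writeLines(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(file)
}
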