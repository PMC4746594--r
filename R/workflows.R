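## the three in-silico experiments: sparse isolation, successive enrichment,
## microwell comparison; plus the floating-speed estimator and detection
## metrics

#' Estimate cell floating speed from time-lapse tracks
#'
#' Reproduces the measurement design: displacements are taken over
#' non-overlapping intervals (120 s rather than the 30 s sampling, to
#' average out the error), converted to um/min, averaged per cell and then
#' across cells.
#'
#' @param tracks track table from [simulateTimelapse()] (columns t_s, id,
#'   x_um, y_um).
#' @param interval estimation interval in s; must be a multiple of the track
#'   sampling interval, and tracks must span at least two intervals.
#' @return A list: `mean_speed` (um/min), `sd` (across cells), `n_cells`,
#'   `interval_s`.
#' @export
estimateFloatingSpeed <- function(tracks, interval = 120) {
  stopifnot(interval > 0)
  per <- split(tracks, tracks$id)
  speeds <- vapply(per, function(tr) {
    tr <- tr[order(tr$t_s), ]
    dt <- unique(round(diff(tr$t_s), 9))
    if (length(dt) != 1)
      stop("irregular track sampling")
    if (abs(interval / dt - round(interval / dt)) > 1e-9)
      stop("interval must be a multiple of the track sampling interval")
    if (max(tr$t_s) - min(tr$t_s) < 2 * interval)
      stop("tracks must span at least 2 x interval")
    stride <- round(interval / dt)
    idx <- seq(1, nrow(tr), by = stride)
    disp <- sqrt(diff(tr$x_um[idx])^2 + diff(tr$y_um[idx])^2)
    mean(disp) / interval * 60
  }, 0)
  list(mean_speed = mean(speeds), sd = sd(speeds),
       n_cells = length(speeds), interval_s = interval)
}

#' Precision and recall of a detection set against ground truth
#'
#' Greedy one-to-one matching by ascending distance within `match_radius`;
#' precision = matched / detected (0 when nothing was detected), recall =
#' matched / truth.
#'
#' @param detections,truth cell tables.
#' @param match_radius maximal match distance in um.
#' @return A list: `precision`, `recall`, `matched`.
#' @export
detectionMetrics <- function(detections, truth, match_radius = 10) {
  stopifnot(match_radius > 0)
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(precision = if (nd == 0) 0 else 0,
                recall = 0, matched = 0L))
  d2 <- outer(detections$x_um, truth$x_um, "-")^2 +
    outer(detections$y_um, truth$y_um, "-")^2
  ok <- which(d2 <= match_radius^2, arr.ind = TRUE)
  if (nrow(ok)) {
    ok <- ok[order(d2[ok]), , drop = FALSE]
    used_d <- logical(nd); used_t <- logical(nt)
    m <- 0L
    for (r in seq_len(nrow(ok))) {
      i <- ok[r, 1]; j <- ok[r, 2]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- used_t[j] <- TRUE
        m <- m + 1L
      }
    }
  } else m <- 0L
  list(precision = m / nd, recall = m / nt, matched = m)
}

## ---------------------------------------------------------------------------
## sparse isolation
## ---------------------------------------------------------------------------

#' Configuration of the sparse single-cell isolation experiment
#'
#' Defaults follow the sparse-sorting conditions: 2,000 cells injected into
#' a 5 x 5 mm^2 miniature-plate well (80 cells/mm^2), floating at the
#' in-well thin-layer speed (2.3 um/min), picked at the measured 34 um
#' resolution and deposited one per 2 x 2 mm^2 well of the 24-well miniature
#' plate. One sorting session targets 20 cells at 20 s per pick-deposit
#' cycle (the 3 cells/min sorting speed). `transfer_success_prob` is the
#' probability that a picked cell actually arrives in its vessel (losses
#' inside the pipette; calibrated to the observed above-75% recovery).
#'
#' @param arena,n_cells,n_targets,min_separation population settings.
#' @param motion a [MotionModel-class].
#' @param capture a [CaptureModel-class].
#' @param detection a [DetectionParams-class] (used on the fresh frames).
#' @param render a [RenderParams-class] for the fresh frames.
#' @param fresh_frame_px,pixel_size fresh-image geometry (160 px at 1.25
#'   um/px = the 200 x 200 um fresh frame).
#' @param search_radius adaptive-targeting match radius, um.
#' @param cycle_time seconds of cell motion per pick-deposit cycle.
#' @param transfer_success_prob probability a picked cell is delivered.
#' @param layout destination [DestinationLayout-class].
#' @param adaptive use adaptive re-targeting (FALSE = pick at stale scan
#'   coordinates).
#' @param imaging_retarget render and segment a real fresh frame (TRUE) or
#'   use ideal fresh detections (FALSE).
#' @param start pipette start position, stage um.
#' @return A named list understood by [runSparseIsolation()].
#' @export
sparseIsolationConfig <- function(arena = rectArena(5000, 5000),
                                  n_cells = 2000, n_targets = 20,
                                  min_separation = 20,
                                  motion = motionPreset("thin_layer_well"),
                                  capture = capturePreset("sparse"),
                                  detection = detectionParams(),
                                  render = renderParams(),
                                  fresh_frame_px = 160L, pixel_size = 1.25,
                                  search_radius = 50, cycle_time = 20,
                                  transfer_success_prob = 0.8,
                                  layout = miniWellPlateLayout(),
                                  adaptive = TRUE, imaging_retarget = TRUE,
                                  start = c(0, 0)) {
  list(arena = arena, n_cells = n_cells, n_targets = n_targets,
       min_separation = min_separation, motion = motion, capture = capture,
       detection = detection, render = render,
       fresh_frame_px = as.integer(fresh_frame_px),
       pixel_size = pixel_size, search_radius = search_radius,
       cycle_time = cycle_time,
       transfer_success_prob = transfer_success_prob, layout = layout,
       adaptive = adaptive, imaging_retarget = imaging_retarget,
       start = start)
}

# render a fresh frame centred on the expected position and detect in it
.freshDetections <- function(state, expected, cfg) {
  half <- cfg$fresh_frame_px * cfg$pixel_size / 2
  spec <- frameSpec(cfg$fresh_frame_px, cfg$fresh_frame_px,
                    pixel_size = cfg$pixel_size,
                    offset = c(expected$x_um - half, expected$y_um - half))
  if (cfg$imaging_retarget) {
    img <- renderFrame(state@cells, spec, cfg$render)
    segmentFrame(img, cfg$detection, spec)
  } else {
    lab <- state@cells[state@cells$labeled %in% TRUE, , drop = FALSE]
    near <- abs(lab$x_um - expected$x_um) <= half &
      abs(lab$y_um - expected$y_um) <= half
    lab[near, , drop = FALSE]
  }
}

#' Run the sparse single-cell isolation experiment
#'
#' Full loop: synthesize the population, scan it (targets selected from the
#' scan), plan a greedy route, then per target advance the suspension by the
#' cycle time, capture a fresh 200 x 200 um frame, re-detect and correct the
#' target coordinates, aspirate at the corrected position and deposit into
#' the target's own vessel. A pick whose target was transferred alone is a
#' single-cell success; a transferred target accompanied by bystanders is a
#' contamination; targets lost by re-detection or missed by the capture disc
#' count as losses.
#'
#' @param config from [sparseIsolationConfig()].
#' @param n_sessions number of independent sorting sessions to aggregate.
#' @param seed optional RNG seed.
#' @return An isolation report list: `attempted`, `single_cell_successes`,
#'   `lost_targets`, `contaminations`, `transferred`, `recovery_fraction`,
#'   per-target data.frame `per_target`, conservation and volume ledgers,
#'   and `warnings`.
#' @export
runSparseIsolation <- function(config = sparseIsolationConfig(),
                               n_sessions = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  per <- vector("list", n_sessions)
  ledger <- list(n_initial = 0L, n_remaining = 0L, n_deposited = 0L,
                 n_lost_in_pipette = 0L, picks_fired = 0L,
                 source_volume_drawn_nl = 0, dest_volume_added_nl = 0)
  warnings <- character()
  dens <- cfg$n_cells / arenaArea(cfg$arena)
  lam <- dens * pi * cfg$capture@capture_radius^2
  if (lam > 3)
    warnings <- c(warnings, sprintf(
      "density too high for single-cell picks: expected %.1f cells per capture disc", lam))

  for (s in seq_len(n_sessions)) {
    pop <- makePopulation(cfg$arena, n_labeled = cfg$n_targets,
                          n_unlabeled = cfg$n_cells - cfg$n_targets,
                          min_separation = cfg$min_separation)
    state <- suspensionState(cfg$arena, pop)
    v0 <- state@medium_volume
    scan <- pop[pop$labeled, , drop = FALSE]
    route <- planRoute(scan, cfg$start)
    dest <- assignDestinations(length(route$order), cfg$layout)
    bb <- arenaBounds(cfg$arena)
    rows <- vector("list", length(route$order))
    n_dep <- 0L; n_pipette_lost <- 0L; n_dep_cells <- 0L
    dest_vol <- 0
    for (i in seq_along(route$order)) {
      id <- route$order[i]
      state <- stepMotion(state, cfg$cycle_time, cfg$motion)
      expected <- scan[scan$id == id, , drop = FALSE]
      status <- "picked"
      aim <- NULL
      displacement <- NA_real_
      if (cfg$adaptive) {
        fresh <- .freshDetections(state, expected, cfg)
        rt <- adaptiveRetarget(expected, fresh, cfg$search_radius)
        if (rt$status == "lost") {
          rows[[i]] <- data.frame(session = s, id = id, status = "lost",
                                  target_picked = FALSE, n_bystanders = 0L,
                                  transferred = FALSE, single = FALSE,
                                  displacement_um = NA_real_,
                                  stringsAsFactors = FALSE)
          next
        }
        aim <- rt$corrected_position
        displacement <- rt$displacement
      } else {
        aim <- c(expected$x_um, expected$y_um)
      }
      aim <- c(min(max(aim[1], bb["xmin"]), bb["xmax"]),
               min(max(aim[2], bb["ymin"]), bb["ymax"]))
      res <- pickAt(state, aim, cfg$capture, target_id = id)
      state <- res$state
      ev <- res$event
      ledger$picks_fired <- ledger$picks_fired + 1L
      transfer_ok <- runif(1) <= cfg$transfer_success_prob
      # the robot always ejects at the vessel; cells arrive only if they
      # did not stick inside the pipette
      n_dep <- n_dep + 1L
      dest_vol <- dest_vol + cfg$capture@deposit_volume
      if (transfer_ok) {
        n_dep_cells <- n_dep_cells + nrow(ev$picked)
      } else {
        n_pipette_lost <- n_pipette_lost + nrow(ev$picked)
      }
      transferred <- ev$target_picked && transfer_ok
      rows[[i]] <- data.frame(session = s, id = id,
                              status = if (ev$target_picked) "picked" else
                                "missed",
                              target_picked = ev$target_picked,
                              n_bystanders = ev$n_bystanders,
                              transferred = transferred,
                              single = transferred && ev$n_bystanders == 0L,
                              displacement_um = displacement,
                              stringsAsFactors = FALSE)
    }
    per[[s]] <- do.call(rbind, rows)
    ledger$n_initial <- ledger$n_initial + nrow(pop)
    ledger$n_remaining <- ledger$n_remaining + nrow(state@cells)
    ledger$n_deposited <- ledger$n_deposited + n_dep_cells
    ledger$n_lost_in_pipette <- ledger$n_lost_in_pipette + n_pipette_lost
    ledger$source_volume_drawn_nl <- ledger$source_volume_drawn_nl +
      (v0 - state@medium_volume)
    ledger$dest_volume_added_nl <- ledger$dest_volume_added_nl + dest_vol
  }
  tab <- do.call(rbind, per)
  attempted <- nrow(tab)
  list(attempted = attempted,
       single_cell_successes = sum(tab$single),
       lost_targets = sum(tab$status == "lost" | tab$status == "missed"),
       contaminations = sum(tab$transferred & tab$n_bystanders > 0),
       transferred = sum(tab$transferred),
       recovery_fraction = sum(tab$transferred) / attempted,
       per_target = tab, ledger = ledger, warnings = warnings)
}

## ---------------------------------------------------------------------------
## successive enrichment
## ---------------------------------------------------------------------------

#' Configuration of the successive-enrichment experiment
#'
#' Defaults are the dense-sorting conditions: 50,000 unlabeled plus 50
#' labeled cells (the 1,000:1 inoculum) in the first of four 5 x 5 mm^2
#' wells. Pass 1 picks at the dense effective capture radius (63 um,
#' calibrated to the observed 25 bystanders per labeled cell at 2,000
#' cells/mm^2); later passes re-pick the now-sparse deposited clusters at
#' the measured 34 um resolution. Each labeled cell is deposited, with its
#' bystanders, on a 500 um grid in the next well.
#'
#' @param arena_size side of the square wells, um.
#' @param n_arenas number of wells available (passes <= n_arenas - 1).
#' @param n_labeled,n_unlabeled initial population.
#' @param motion a [MotionModel-class].
#' @param capture_first,capture_later [CaptureModel-class] for pass 1 and
#'   for subsequent passes.
#' @param grid_pitch,grid_origin,grid_ncol deposition grid in each
#'   destination well.
#' @param cycle_time seconds of motion per pick-deposit cycle.
#' @param start pipette start position.
#' @return A named list understood by [runSuccessiveEnrichment()].
#' @export
enrichmentConfig <- function(arena_size = 5000, n_arenas = 4,
                             n_labeled = 50, n_unlabeled = 50000,
                             motion = motionPreset("thin_layer_well"),
                             capture_first = capturePreset("dense"),
                             capture_later = capturePreset("sparse"),
                             grid_pitch = 500, grid_origin = c(500, 500),
                             grid_ncol = 8L, cycle_time = 20,
                             start = c(0, 0)) {
  list(arena_size = arena_size, n_arenas = n_arenas, n_labeled = n_labeled,
       n_unlabeled = n_unlabeled, motion = motion,
       capture_first = capture_first, capture_later = capture_later,
       grid_pitch = grid_pitch, grid_origin = grid_origin,
       grid_ncol = as.integer(grid_ncol), cycle_time = cycle_time,
       start = start)
}

#' Run the successive-enrichment experiment
#'
#' Pass k picks every labeled cell in well k and deposits each, with its
#' co-aspirated bystanders, at its own node of a 500 um grid in well k + 1.
#' Because the deposit spreads cells over a much larger disc (127 um) than
#' the re-pick captures (34 um), the unlabeled load is thinned geometrically
#' by roughly (34/127)^2 per pass until only labeled cells transfer.
#'
#' @param config from [enrichmentConfig()].
#' @param n_passes number of sorting passes (needs n_passes + 1 wells).
#' @param seed optional RNG seed.
#' @return An enrichment report list: `per_pass` data.frame (pass,
#'   labeled_picked, bystanders_mean, bystanders_sd, total_transferred,
#'   purity), `inoculum_ratio`, conservation/volume `ledger`, and the final
#'   `states`.
#' @export
runSuccessiveEnrichment <- function(config = enrichmentConfig(),
                                    n_passes = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  stopifnot(n_passes >= 1)
  if (n_passes + 1 > cfg$n_arenas)
    stop(sprintf("%d passes need %d wells; only %d available", n_passes,
                 n_passes + 1, cfg$n_arenas))
  arena <- rectArena(cfg$arena_size, cfg$arena_size)
  states <- vector("list", cfg$n_arenas)
  pop <- makePopulation(arena, cfg$n_labeled, cfg$n_unlabeled,
                        min_separation = 0)
  states[[1]] <- suspensionState(arena, pop)
  for (k in 2:cfg$n_arenas) states[[k]] <- suspensionState(arena)
  n_initial <- nrow(pop)
  passes <- vector("list", n_passes)
  vol_drawn <- 0; vol_added <- 0; picks_total <- 0L

  for (k in seq_len(n_passes)) {
    src <- states[[k]]; dst <- states[[k + 1]]
    capture <- if (k == 1) cfg$capture_first else cfg$capture_later
    targets <- src@cells[src@cells$labeled %in% TRUE, , drop = FALSE]
    route <- planRoute(targets, cfg$start)
    n_t <- length(route$order)
    grid <- assignDestinations(
      n_t, destinationLayout("grid", grid_pitch = cfg$grid_pitch,
                             grid_origin = cfg$grid_origin,
                             grid_ncol = cfg$grid_ncol))
    v0 <- src@medium_volume
    bycount <- rep(NA_real_, n_t)
    labeled_picked <- 0L; transferred_lab <- 0L; transferred_unlab <- 0L
    for (i in seq_len(n_t)) {
      id <- route$order[i]
      src <- stepMotion(src, cfg$cycle_time, cfg$motion)
      row <- src@cells[src@cells$id == id, , drop = FALSE]
      if (nrow(row) == 0) next  # already co-transferred with an earlier pick
      res <- pickAt(src, c(row$x_um, row$y_um), capture, target_id = id)
      src <- res$state
      picks_total <- picks_total + 1L
      picked <- res$event$picked
      if (res$event$target_picked) {
        labeled_picked <- labeled_picked + 1L
        bycount[i] <- sum(!picked$labeled)
      }
      transferred_lab <- transferred_lab + sum(picked$labeled)
      transferred_unlab <- transferred_unlab + sum(!picked$labeled)
      dst <- depositAt(dst, picked, c(grid$x_um[i], grid$y_um[i]), capture)
    }
    vol_drawn <- vol_drawn + (v0 - src@medium_volume)
    vol_added <- vol_added + (dst@medium_volume - mediumVolume(arena))
    states[[k]] <- src; states[[k + 1]] <- dst
    total <- transferred_lab + transferred_unlab
    passes[[k]] <- data.frame(
      pass = k, labeled_picked = labeled_picked,
      bystanders_mean = mean(bycount, na.rm = TRUE),
      bystanders_sd = sd(bycount[!is.na(bycount)]),
      total_transferred = total,
      purity = if (total > 0) transferred_lab / total else NA_real_)
  }
  per_pass <- do.call(rbind, passes)
  n_final <- sum(vapply(states, function(s) nrow(s@cells), 0L))
  list(per_pass = per_pass,
       inoculum_ratio = cfg$n_unlabeled / cfg$n_labeled,
       ledger = list(n_initial = n_initial, n_final_total = n_final,
                     picks_fired = picks_total,
                     source_volume_drawn_nl = vol_drawn,
                     dest_volume_added_nl = vol_added),
       states = states)
}

## ---------------------------------------------------------------------------
## microwell comparison
## ---------------------------------------------------------------------------

#' Configuration of the microwell-entrapment comparison
#'
#' @param array a [MicrowellArray-class] preset.
#' @param n_applied cells applied to the PDMS plate (the experiments used
#'   200,000-400,000).
#' @return A named list understood by [runMicrowellComparison()].
#' @export
microwellConfig <- function(array = microwellPreset("fibroblast"),
                            n_applied = 300000) {
  list(array = array, n_applied = n_applied)
}

#' Run the microwell entrapment + sorting comparison
#'
#' Loads the microwell array (cells not trapped are lost in the washing
#' steps), selects every occupied well, and attempts to aspirate each
#' trapped cell out; about half adhere too strongly to the PDMS and remain
#' stuck.
#'
#' @param config from [microwellConfig()].
#' @param seed optional RNG seed.
#' @return A comparison report list: `untrapped_fraction` /
#'   `untrapped_pct`, closed-form expectation, `fill_fraction`, `selected`,
#'   `isolated`, `stuck`, and `recovery` (isolated / selected).
#' @export
runMicrowellComparison <- function(config = microwellConfig(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arr <- config$array
  load <- loadMicrowellArray(arr, config$n_applied)
  occ <- load$occupancy
  sel <- which(occ)
  iso <- 0L; stuck <- 0L
  for (w in sel) {
    out <- pickFromWell(occ, w, arr@well_pick_success)
    occ <- out$occupancy
    if (out$outcome == "isolated") iso <- iso + 1L else
      stuck <- stuck + 1L
  }
  list(untrapped_fraction = load$untrapped_fraction,
       untrapped_pct = 100 * load$untrapped_fraction,
       expected_untrapped_fraction =
         expectedUntrappedFraction(arr, config$n_applied),
       fill_fraction = load$fill_fraction,
       trapped = load$trapped, selected = length(sel),
       isolated = iso, stuck = stuck,
       recovery = if (length(sel)) iso / length(sel) else NA_real_)
}
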