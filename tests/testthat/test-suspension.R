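test_that("floating motion: static limit, pure drift and confinement", {
  arena <- rectArena(2000, 2000)
  pop <- makePopulation(arena, 20, 0, seed = 14)
  state <- suspensionState(arena, pop)

  # zero speed: positions unchanged, clock advances
  still <- stepMotion(state, 60, motionModel(0, 0, 300))
  expect_equal(still@cells$x_um, pop$x_um)
  expect_equal(still@cells$y_um, pop$y_um)
  expect_equal(still@clock, 60)

  # ballistic limit: one step of dt at speed v displaces by v * dt exactly
  pop_c <- makePopulation(rectArena(200, 200, origin = c(900, 900)), 30, 0,
                          seed = 15)
  st <- suspensionState(arena, pop_c)
  v <- 6  # um/min
  moved <- stepMotion(st, 30, motionModel(v, 0, 1e12))
  disp <- sqrt((moved@cells$x_um - pop_c$x_um)^2 +
                 (moved@cells$y_um - pop_c$y_um)^2)
  expect_lt(max(abs(disp - v / 60 * 30)), 1e-9)

  # cells stay inside the arena over 1e4 reflecting steps
  set.seed(16)
  st2 <- suspensionState(rectArena(300, 300),
                         makePopulation(rectArena(300, 300), 5, 0))
  model <- motionPreset("open_dish")
  for (i in 1:10000) st2 <- stepMotion(st2, 30, model)
  bb <- arenaBounds(st2@arena)
  expect_true(all(st2@cells$x_um >= bb["xmin"] &
                    st2@cells$x_um <= bb["xmax"]))
  expect_true(all(st2@cells$y_um >= bb["ymin"] &
                    st2@cells$y_um <= bb["ymax"]))
})

test_that("mean squared displacement is ballistic under long persistence
          and diffusive under short persistence", {
  set.seed(17)
  big <- rectArena(4e5, 4e5)
  core <- rectArena(1000, 1000, origin = c(2e5, 2e5))
  pop <- makePopulation(core, 400, 0)
  msd_at <- function(persistence, t1, t2, dt) {
    st <- suspensionState(big, pop)
    model <- motionModel(30, 0, persistence)
    out <- c()
    t <- 0
    while (t < t2) {
      st <- stepMotion(st, dt, model)
      t <- t + dt
      if (abs(t - t1) < dt / 2 || abs(t - t2) < dt / 2) {
        out <- c(out, mean((st@cells$x_um - pop$x_um)^2 +
                             (st@cells$y_um - pop$y_um)^2))
      }
    }
    out
  }
  # persistence >> duration: MSD(2t)/MSD(t) ~ 4 (ballistic)
  mb <- msd_at(1e9, 300, 600, 30)
  expect_gt(mb[2] / mb[1], 3.5)
  # persistence << duration: MSD(2t)/MSD(t) ~ 2 (random walk)
  md <- msd_at(10, 1500, 3000, 10)
  expect_lt(md[2] / md[1], 2.6)
  expect_gt(md[2] / md[1], 1.5)
})

test_that("capture-radius picks remove exactly the cells inside the disc
          and keep the volume ledger", {
  arena <- rectArena(1000, 1000)
  # isolated target
  tab <- cellTable(c("t", "n20", "n50"),
                   x_um = c(500, 520, 550), y_um = 500,
                   size_um = 15, brightness = 100)
  st <- suspensionState(arena, tab)
  v0 <- st@medium_volume
  res <- pickAt(st, c(500, 500), captureModel(), target_id = "t")
  # neighbour at 20 um co-picked, neighbour at 50 um retained
  expect_setequal(res$event$picked_ids, c("t", "n20"))
  expect_true(res$event$target_picked)
  expect_equal(res$event$n_bystanders, 1L)
  expect_equal(res$state@cells$id, "n50")
  expect_equal(v0 - res$state@medium_volume, 1.4)

  # truly isolated cell -> exactly one removed
  st1 <- suspensionState(arena, cellTable("solo", 300, 300, 15, 100))
  r1 <- pickAt(st1, c(300, 300), captureModel(), target_id = "solo")
  expect_equal(r1$event$picked_ids, "solo")
  expect_equal(nrow(r1$state@cells), 0)

  # failed pick removes nothing but still draws fluid
  st2 <- suspensionState(arena, tab)
  r2 <- pickAt(st2, c(500, 500), captureModel(pick_success_prob = 0))
  expect_equal(nrow(r2$event$picked), 0)
  expect_equal(nrow(r2$state@cells), 3)
  expect_equal(st2@medium_volume - r2$state@medium_volume, 1.4)

  # aim outside the arena is rejected
  expect_error(pickAt(st2, c(-10, 500), captureModel()), "outside")
})

test_that("bystander counts over a uniform field follow the Poisson area
          law and agree with brute-force circle counting", {
  set.seed(18)
  arena <- rectArena(2000, 2000)
  R <- 34
  n_cells <- 800            # density 2e-4 / um^2
  lam <- n_cells / arenaArea(arena) * pi * R^2
  capture <- captureModel(capture_radius = R, radius_sd = 0)
  counts <- integer(0)
  for (field in 1:50) {
    pop <- makePopulation(arena, 0, n_cells)
    st <- suspensionState(arena, pop)
    aims <- cbind(runif(20, 200, 1800), runif(20, 200, 1800))
    for (k in 1:20) {
      bf <- bfCircleCount(st@cells$x_um, st@cells$y_um,
                          aims[k, 1], aims[k, 2], R)
      res <- pickAt(st, aims[k, ], capture)
      expect_equal(length(res$event$picked_ids), bf)
      st <- res$state
      counts <- c(counts, bf)
    }
  }
  expect_equal(length(counts), 1000)
  # mean within 3 binomial/Poisson standard errors (depletion over the 20
  # picks per field lowers the density by < 2%, well inside the band)
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / length(counts)) + 0.02 * lam)
})

test_that("deposits spread cells inside the spread radius and add the
          deposition volume", {
  arena <- rectArena(5000, 5000)
  st <- suspensionState(arena)
  v0 <- st@medium_volume

  # zero cells: volume still increases by 147 nl
  st1 <- depositAt(st, emptyCellTable(), c(2500, 2500), captureModel())
  expect_equal(st1@medium_volume - v0, 147)
  expect_equal(nrow(st1@cells), 0)

  # 26 cells: all land within the spread radius (all-pairs distance scan)
  set.seed(19)
  carried <- cellTable(sprintf("c%d", 1:26), runif(26, 0, 100),
                       runif(26, 0, 100), 15, 100)
  st2 <- depositAt(st1, carried, c(2500, 2500), captureModel())
  expect_equal(nrow(st2@cells), 26)
  expect_setequal(st2@cells$id, carried$id)
  d <- sqrt((st2@cells$x_um - 2500)^2 + (st2@cells$y_um - 2500)^2)
  expect_true(all(d <= 127 + 1e-9))
  expect_equal(st2@medium_volume - v0, 2 * 147)
})

test_that("microwell loading is Bernoulli-per-well with the preset
          efficiencies", {
  arr <- microwellPreset("fibroblast")
  expect_equal(arr@n_rows * arr@n_cols, 10000L)

  # zero efficiency -> nothing trapped
  arr0 <- microwellArray(fill_efficiency = 0)
  l0 <- loadMicrowellArray(arr0, 5000)
  expect_equal(l0$trapped, 0)
  expect_equal(l0$untrapped, 5000)

  # binomial mean and sd of the trapped count (10^3 replicates)
  set.seed(20)
  arrm <- microwellPreset("monocyte")
  trapped <- replicate(1000, loadMicrowellArray(arrm, 3e5)$trapped)
  expect_lt(abs(mean(trapped) - 5400), 3 * 50 / sqrt(1000))
  expect_lt(abs(sd(trapped) - sqrt(10000 * 0.54 * 0.46)), 5)

  # 300,000 applied on the fibroblast preset: ~99.2% untrapped
  l <- loadMicrowellArray(microwellPreset("fibroblast"), 3e5)
  expect_equal(100 * l$untrapped_fraction, 99.17, tolerance = 0.01)

  # the occupancy cap: never more trapped than applied
  lc <- loadMicrowellArray(arrm, 100)
  expect_lte(lc$trapped, 100)
  expect_gte(lc$untrapped, 0)
})

test_that("well picks split isolated/stuck/empty at the adhesion-limited
          rate", {
  occ <- matrix(c(TRUE, FALSE), 1, 2)
  # success probability 1 -> always isolated, well emptied
  r <- pickFromWell(occ, 1, 1)
  expect_equal(r$outcome, "isolated")
  expect_false(r$occupancy[1])
  # empty well
  expect_equal(pickFromWell(occ, 2, 1)$outcome, "empty")
  # 10^4 trials at 0.5: isolated fraction within the binomial CI
  set.seed(22)
  full <- matrix(TRUE, 1, 1)
  iso <- replicate(1e4, pickFromWell(full, 1, 0.5)$outcome == "isolated")
  expect_lt(abs(mean(iso) - 0.5), 0.02)
})

test_that("time-lapse recording matches the 30 s / 1 h measurement design", {
  arena <- rectArena(20000, 20000)
  pop <- makePopulation(rectArena(2000, 2000, origin = c(9000, 9000)),
                        5, 0, seed = 23)
  st <- suspensionState(arena, pop)

  # 1 h at 30 s -> 121 samples per cell
  tr <- simulateTimelapse(st, motionModel(5.4, 1.1, 300), 30, 3600)
  expect_equal(nrow(tr), 5 * 121)
  expect_equal(sort(unique(tr$t_s)), seq(0, 3600, by = 30))

  # zero-speed model -> constant tracks
  tr0 <- simulateTimelapse(st, motionModel(0, 0, 300), 30, 300)
  for (id in unique(tr0$id)) {
    sub <- tr0[tr0$id == id, ]
    expect_equal(length(unique(sub$x_um)), 1)
  }

  # drifting cell: per-interval displacement = v * 30 s
  trd <- simulateTimelapse(st, motionModel(12, 0, 1e12), 30, 600)
  sub <- trd[trd$id == pop$id[1], ]
  sub <- sub[order(sub$t_s), ]
  step <- sqrt(diff(sub$x_um)^2 + diff(sub$y_um)^2)
  expect_lt(max(abs(step - 12 / 60 * 30)), 1e-9)
})
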