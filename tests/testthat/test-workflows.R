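test_that("floating-speed estimation recovers drift exactly and
          underestimates tumbling walks", {
  arena <- rectArena(50000, 50000)
  center <- rectArena(1000, 1000, origin = c(25000, 25000))
  pop <- makePopulation(center, 10, 0, seed = 24)
  st <- suspensionState(arena, pop)

  # static tracks -> 0 um/min
  tr0 <- simulateTimelapse(st, motionModel(0, 0, 300), 30, 600)
  expect_equal(estimateFloatingSpeed(tr0, 120)$mean_speed, 0)

  # pure drift at v, 30 s sampling, 120 s intervals -> exactly v
  set.seed(25)
  trd <- simulateTimelapse(st, motionModel(7.5, 0, 1e12), 30, 1200)
  est <- estimateFloatingSpeed(trd, 120)
  expect_lt(abs(est$mean_speed - 7.5), 1e-9)
  expect_equal(est$n_cells, 10)

  # persistence far below the 120 s interval: path folds back, so the
  # interval estimate undershoots the nominal speed
  set.seed(26)
  trw <- simulateTimelapse(st, motionModel(20, 0, 5), 30, 3600)
  expect_lt(estimateFloatingSpeed(trw, 120)$mean_speed, 20 * 0.9)

  # interval must be a multiple of the sampling interval
  expect_error(estimateFloatingSpeed(trd, 45), "multiple")
})

test_that("detection metrics count greedy one-to-one matches", {
  truth <- cellTable(sprintf("t%d", 1:10), seq(10, 100, 10),
                     seq(10, 100, 10), 15, 100)
  # identical detections -> perfect precision and recall
  m0 <- detectionMetrics(truth, truth, 5)
  expect_equal(m0$precision, 1)
  expect_equal(m0$recall, 1)

  # two spurious detections: precision 10/12, recall 1
  extra <- cellTable(c(sprintf("d%d", 1:10), "s1", "s2"),
                     c(seq(10, 100, 10), 500, 600),
                     c(seq(10, 100, 10), 500, 600), 15, 100)
  m1 <- detectionMetrics(extra, truth, 5)
  expect_equal(m1$precision, 10 / 12)
  expect_equal(m1$recall, 1)

  # no detections: precision falls back to 0, recall 0
  m2 <- detectionMetrics(emptyCellTable(), truth, 5)
  expect_equal(m2$precision, 0)
  expect_equal(m2$recall, 0)
})

test_that("sparse isolation is perfect in the idealized limit and degrades
          gracefully at the defaults", {
  # motion disabled + ideal fresh detection + no pipette losses; the
  # hard core exceeds the capture diameter so no pick can swallow a
  # second target
  cfg0 <- sparseIsolationConfig(motion = motionModel(0, 0, 300),
                                transfer_success_prob = 1,
                                min_separation = 70,
                                imaging_retarget = FALSE)
  r0 <- runSparseIsolation(cfg0, seed = 27)
  expect_equal(r0$recovery_fraction, 1)
  expect_equal(r0$lost_targets, 0)

  # default conditions over 10 sessions (200 targets): above-75% recovery
  rd <- runSparseIsolation(sparseIsolationConfig(), n_sessions = 10,
                           seed = 28)
  expect_equal(rd$attempted, 200)
  expect_gt(rd$recovery_fraction, 0.75)

  # cell conservation and volume ledger are exact
  lg <- rd$ledger
  expect_equal(lg$n_initial,
               lg$n_remaining + lg$n_deposited + lg$n_lost_in_pipette)
  expect_equal(lg$source_volume_drawn_nl, lg$picks_fired * 1.4,
               tolerance = 1e-9)

  # warning when the density makes single-cell picks impossible a priori
  dense_cfg <- sparseIsolationConfig(n_cells = 50000, n_targets = 2,
                                     min_separation = 0)
  rw <- runSparseIsolation(dense_cfg, seed = 29)
  expect_match(rw$warnings, "density", all = FALSE)
})

test_that("adaptive targeting strictly beats stale coordinates in the full
          sparse workflow (paired seeds)", {
  base <- sparseIsolationConfig(motion = motionPreset("thin_layer"),
                                imaging_retarget = FALSE)
  on <- runSparseIsolation(base, n_sessions = 5, seed = 30)
  base_off <- base
  base_off$adaptive <- FALSE
  off <- runSparseIsolation(base_off, n_sessions = 5, seed = 30)
  expect_gt(on$recovery_fraction, off$recovery_fraction)
})

test_that("sparse recovery does not increase with floating speed", {
  recov <- vapply(c(0, 5.4, 39), function(v) {
    cfg <- sparseIsolationConfig(motion = motionModel(v, v / 5, 300),
                                 imaging_retarget = FALSE)
    runSparseIsolation(cfg, n_sessions = 5, seed = 31)$recovery_fraction
  }, 0)
  expect_true(all(diff(recov) <= 0))
})

test_that("successive enrichment thins bystanders geometrically and keeps
          exact ledgers", {
  # a pure inoculum gives purity 1 at the first pass
  pure <- runSuccessiveEnrichment(enrichmentConfig(n_unlabeled = 0),
                                  n_passes = 1, seed = 32)
  expect_equal(pure$per_pass$purity[1], 1)

  # the default inoculum is the 1,000:1 dense culture
  cfg <- enrichmentConfig()
  expect_equal(cfg$n_unlabeled / cfg$n_labeled, 1000)

  res <- runSuccessiveEnrichment(cfg, n_passes = 3, seed = 33)
  pp <- res$per_pass
  # bystanders per labeled cell shrink every pass; purity rises
  expect_true(all(diff(pp$bystanders_mean) < 0))
  expect_true(all(diff(pp$purity) > 0))
  # pass 1 sits near the analytic dense-capture load d * pi * R^2
  lam1 <- 50050 / 25e6 * pi * 63^2
  expect_lt(abs(pp$bystanders_mean[1] - lam1), 3 * sqrt(lam1 / 50))
  # cell conservation across all four wells is exact
  expect_equal(res$ledger$n_initial, res$ledger$n_final_total)
  # volume ledger: 1.4 nl per pick drawn, 147 nl per deposit added
  expect_equal(res$ledger$source_volume_drawn_nl,
               res$ledger$picks_fired * 1.4, tolerance = 1e-9)
  expect_equal(res$ledger$dest_volume_added_nl %% 147, 0, tolerance = 1e-6)

  # passes cannot outnumber the available wells
  expect_error(runSuccessiveEnrichment(cfg, n_passes = 4), "wells")
})

test_that("the pass-2/pass-1 thinning ratio matches the pair-distance
          closed form when motion is frozen", {
  # re-picking at 34 um from clusters spread over a 127 um disc retains
  # bystanders at P(|U1 - U2| <= 34) for uniform points in the disc
  set.seed(34)
  p_exact <- pcloseDisc(34, 127)
  ratios <- vapply(1:4, function(i) {
    cfg <- enrichmentConfig(cycle_time = 1e-3,
                            capture_first = captureModel(63, 0),
                            capture_later = captureModel(34, 0))
    pp <- runSuccessiveEnrichment(cfg, n_passes = 2)$per_pass
    pp$bystanders_mean[2] / pp$bystanders_mean[1]
  }, 0)
  expect_equal(mean(ratios), p_exact, tolerance = 0.2)
})

test_that("the microwell comparison reproduces untrapped, fill and
          recovery rates", {
  r <- runMicrowellComparison(microwellConfig(), seed = 35)
  expect_gt(r$untrapped_pct, 98)
  expect_equal(r$untrapped_fraction, r$expected_untrapped_fraction,
               tolerance = 0.002)
  expect_equal(r$recovery, 0.5, tolerance = 0.1)
  expect_equal(r$selected, r$isolated + r$stuck)

  # perfect trapping and aspiration -> full recovery
  perfect <- microwellConfig(array = microwellArray(fill_efficiency = 1,
                                                    well_pick_success = 1),
                             n_applied = 20000)
  rp <- runMicrowellComparison(perfect, seed = 36)
  expect_equal(rp$recovery, 1)
})

test_that("simulator tables round-trip through the plain-text formats", {
  arena <- rectArena(500, 500)
  pop <- makePopulation(arena, 3, 2, seed = 37)

  f <- withr::local_tempfile(fileext = ".csv")
  writeCellTable(pop, f)
  back <- readCellTable(f)
  expect_equal(back$x_um, pop$x_um)
  expect_equal(back$labeled, pop$labeled)

  img <- renderFrame(pop, frameSpec(64, 64), renderParams(noise_sd = 3),
                     seed = 38)
  tf <- withr::local_tempfile(fileext = ".tif")
  writeFrameTiff(img, tf)
  img2 <- readFrameTiff(tf)
  expect_identical(as.vector(img2), as.vector(img))
  expect_equal(attr(img2, "spec")@pixel_size, 1.25)

  mos <- generateMosaic(arena, pop, frameSpec(160, 160), 0.1,
                        renderParams(noise_sd = 0))
  md <- withr::local_tempdir()
  manifest <- writeMosaic(mos, md)
  mos2 <- readMosaic(manifest)
  expect_equal(mos2@nx, mos@nx)
  expect_identical(as.vector(mos2@tiles[[2]]), as.vector(mos@tiles[[2]]))

  ev <- list(list(aim = c(1, 2), picked_ids = c("a", "b"),
                  removed_volume_nl = 1.4, success = TRUE))
  jf <- withr::local_tempfile(fileext = ".jsonl")
  writeEventLog(ev, jf)
  line <- jsonlite::fromJSON(readLines(jf)[1])
  expect_equal(line$removed_volume_nl, 1.4)
})
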