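# Time-lapse generator and behavior trackers on one small shared movie.

test_that("movies are deterministic and respect the frame grid", {
  cfg <- preset("control_movie", seed = 77)
  cfg$n_cells <- 60L; cfg$field_um <- c(50, 50)
  cfg$division_rate_per_hour <- 0.1; cfg$rosette_count <- 3L
  cfg$duration_min <- 60
  tl1 <- make_timelapse(cfg)
  tl2 <- make_timelapse(cfg)
  expect_equal(tl1$n_frames, 11L)
  expect_identical(tl1$frames[[5]]$label, tl2$frames[[5]]$label)
  expect_identical(tl1$frames[[5]]$AJ, tl2$frames[[5]]$AJ)
  expect_identical(tl1$truth$divisions, tl2$truth$divisions)
})

test_that("uniform constriction reaches the configured area checkpoints", {
  mv <- small_movie()
  af <- mv$tl$truth$area_factor
  expect_equal(af$factor[af$t_min == 90], 1 - 0.17)
  expect_equal(af$factor[af$t_min == 180], 1 - 0.22)
  at <- area_trajectory(mv$graphs)
  expect_false(any(at$unreliable))
  expect_lt(abs(at$pct_decrease[at$t_min == 90] - 17), 1)
  expect_lt(abs(at$pct_decrease[at$t_min == 180] - 22), 1)
})

test_that("division tracking recovers the truth outcomes event by event", {
  mv <- small_movie()
  dt <- track_divisions(mv$tl)
  tru <- mv$tl$truth$divisions
  m <- merge(dt, tru, by = c("cell", "t0_frame"))
  expect_equal(nrow(m), nrow(tru))
  expect_equal(mean(m$censored_at_90), mean(m$failed))
  expect_gte(mean(m$censored_at_90 == m$failed), 0.95)
  # completed divisions finish on the 6-min grid within the window
  ct <- dt$completion_time_min[dt$completed]
  expect_true(all(ct %% 6 == 0))
  expect_true(all(ct <= 90))
  # with no scheduled failures every division completes
  cfg0 <- preset("control_movie", seed = 91)
  cfg0$n_cells <- 80L; cfg0$field_um <- c(60, 60)
  cfg0$p_no_new_interface <- 0; cfg0$rosette_count <- 0L
  cfg0$division_rate_per_hour <- 0.15
  tl0 <- make_timelapse(cfg0)
  dt0 <- track_divisions(tl0)
  expect_true(all(!tl0$truth$divisions$failed))
  expect_true(all(dt0$completed))
})

test_that("rosette tracks match the schedule in number, timing and mode", {
  mv <- small_movie()
  rt <- track_rosettes(mv$graphs)
  tru <- mv$tl$truth$rosettes
  # the base mesh may contain a (legitimate) preexisting high-order vertex
  # from its proximity cleanup; scheduled rosettes are the rearranged ones
  formed <- rt[rt$formation_mode == "rearrangement", , drop = FALSE]
  expect_lte(abs(nrow(formed) - nrow(tru)), 1)
  det_first <- sort(formed$first_frame)
  tru_first <- sort(tru$form_frame)
  n <- min(length(det_first), length(tru_first))
  expect_lte(stats::median(abs(det_first[seq_len(n)] - tru_first[seq_len(n)])), 1)
  expect_true(all(rt$formation_mode %in% c("rearrangement", "preexisting")))
  expect_true(all(rt$first_frame[rt$formation_mode == "preexisting"] == 1L))
  expect_true(all(rt$max_order >= 5))
})

test_that("a preexisting high-order vertex is labeled as such", {
  cfg <- preset("control_movie", seed = 55)
  cfg$n_cells <- 60L; cfg$field_um <- c(50, 50)
  cfg$n_order5 <- 2L         # built into the mesh before frame 1
  cfg$rosette_count <- 0L
  cfg$division_rate_per_hour <- 0
  cfg$duration_min <- 36
  tl <- make_timelapse(cfg)
  rt <- track_rosettes(movie_graphs(tl))
  expect_gte(nrow(rt), 1)
  expect_true(all(rt$formation_mode == "preexisting"))
  expect_true(all(rt$first_frame == 1L))
})

test_that("gap fates are recovered and classes partition the tracks", {
  mv <- small_movie()
  rt <- rosette_gap_fates(track_rosettes(mv$graphs), mv$tl)
  expect_true(all(rt$gap_fate %in% c("no_gap", "repaired", "persistent",
                                     "expanding")))
  tru <- mv$tl$truth$rosettes
  expect_within_3se(mean(rt$gap_fate != "no_gap"), mean(tru$gapped),
                    nrow(rt), "gapped rosette fraction")
  # fate classes sum to the track count (exhaustive and exclusive)
  expect_equal(sum(table(rt$gap_fate)), nrow(rt))
})

test_that("the cumulative new-interface curve is monotone and complete", {
  mv <- small_movie()
  dt <- track_divisions(mv$tl)
  cv <- cumulative_new_interface(dt)
  expect_true(all(diff(cv$cumulative_fraction) >= 0))
  expect_equal(cv$cumulative_fraction[cv$t_min == 90], 1)  # completed basis
  # brute-force counting oracle
  ct <- dt$completion_time_min[dt$completed & !dt$censored]
  for (t in c(12, 30, 60)) {
    expect_equal(cv$cumulative_fraction[cv$t_min == t],
                 sum(ct <= t) / length(ct))
  }
  # all-divisions denominator is bounded by the completed one
  cva <- cumulative_new_interface(dt, denominator = "all")
  expect_true(all(cva$cumulative_fraction <= cv$cumulative_fraction + 1e-12))
})

test_that("events scheduled past the movie end are dropped with a warning", {
  cfg <- preset("mutant_movie", seed = 13)
  cfg$n_cells <- 60L; cfg$field_um <- c(50, 50)
  cfg$rosette_count <- 2L
  cfg$division_rate_per_hour <- 0.3
  cfg$duration_min <- 42  # 8 frames: some completions would exceed the end
  expect_warning(make_timelapse(cfg), "past movie end|rosettes")
})
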