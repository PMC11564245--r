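test_that("ideal square-wave traces are segmented at the exact seeded frames", {
  cfg <- trace_sim_config(noise_sd = 0, seed = 1)
  sim <- generate_tracks(cfg, 10)
  for (i in seq_along(sim$tracks)) {
    seg <- segment_track_phases(sim$tracks[[i]])
    expect_identical(attr(seg, "boundary_frames"),
                     attr(sim$truth[[i]], "boundary_frames"))
    expect_equal(seg$duration_hr, sim$truth[[i]]$duration_hr)
    expect_false(attr(seg, "low_confidence"))
  }
})

test_that("boundaries stay within one frame at 10% intensity noise", {
  sim <- generate_tracks(trace_sim_config(noise_sd = 0.1, seed = 21), 30)
  errs <- mapply(function(tr, truth) {
    max(abs(attr(segment_track_phases(tr), "boundary_frames") -
              attr(truth, "boundary_frames")))
  }, sim$tracks, sim$truth)
  expect_true(all(errs <= 1))
})

test_that("boundary recovery is threshold-insensitive on clean traces", {
  sim <- generate_tracks(trace_sim_config(noise_sd = 0, seed = 5), 5)
  for (off in c(0.1, 0.2, 0.3)) {
    for (on in c(0.4, 0.5, 0.6)) {
      errs <- mapply(function(tr, truth) {
        seg <- segment_track_phases(tr, theta_off = off, theta_on = on)
        max(abs(attr(seg, "boundary_frames") - attr(truth, "boundary_frames")))
      }, sim$tracks, sim$truth)
      expect_true(all(errs <= 1))
    }
  }
})

test_that("unsegmentable spans are rejected", {
  flat <- cell_track(1, t_hr = (0:50) / 6, venus = rep(1, 51),
                     cherry = rep(0, 51), mitosis_frames = c(1L, 51L))
  expect_error(segment_track_phases(flat), "unsegmentable")
  noisy_flat <- cell_track(1, t_hr = (0:50) / 6,
                           venus = rep(1, 51) + seq(0, 0.001, length.out = 51),
                           cherry = rep(0, 51), mitosis_frames = c(1L, 51L))
  expect_error(segment_track_phases(noisy_flat), "unsegmentable")
})

test_that("a missing cherry rise flags the span as low confidence", {
  sim <- generate_tracks(trace_sim_config(noise_sd = 0, seed = 2), 1)
  tr <- sim$tracks[[1]]
  # cherry expressed only in early G1, never during the detected S interval
  tr$cherry <- rep(0.05, length(tr$cherry))
  tr$cherry[1:3] <- 1
  seg <- segment_track_phases(tr)
  expect_true(attr(seg, "low_confidence"))
})

test_that("duration summaries add per-phase means and report the G2/S ratio", {
  seg_of <- function(g1, s, g2) {
    data.frame(phase = c("G1", "S", "G2"),
               start_hr = c(0, g1, g1 + s),
               end_hr = c(g1, g1 + s, g1 + s + g2),
               duration_hr = c(g1, s, g2))
  }
  d <- summarize_durations(list(seg_of(8.1, 5.8, 1.8)))
  expect_equal(d$total_hr, 15.7)
  expect_equal(d$g2_s_ratio, 0.3)
  d2 <- summarize_durations(list(seg_of(2, 2, 2)))
  expect_equal(d2$total_hr, 6)
  expect_error(summarize_durations(list()), "no segmentations")
})

test_that("intermitotic intervals difference consecutive mitosis times", {
  expect_equal(intermitotic_interval(c(1.0, 16.9)), 15.9)
  expect_equal(intermitotic_interval(c(0, 10)), 10)
  expect_error(intermitotic_interval(c(5)), ">= 2")
  sim <- generate_tracks(trace_sim_config(seed = 4), 15)
  ivals <- vapply(sim$tracks, function(tr) intermitotic_interval(tr), numeric(1))
  # seeded total 15.7 h; 3 SE of the truncated-normal sum at n = 15
  se <- sqrt(sum(c(1.5, 1.0, 0.4)^2)) / sqrt(15)
  expect_lt(abs(mean(ivals) - 15.7), 3 * se)
})

test_that("phase durations tile the intermitotic interval exactly", {
  sim <- generate_tracks(trace_sim_config(noise_sd = 0.05, seed = 6), 20)
  for (tr in sim$tracks) {
    seg <- segment_track_phases(tr)
    expect_equal(sum(seg$duration_hr), intermitotic_interval(tr),
                 tolerance = 1e-9)
  }
})

test_that("migration metrics recover per-phase speeds", {
  sim <- generate_tracks(trace_sim_config(noise_sd = 0, seed = 3), 1)
  tr <- sim$tracks[[1]]
  seg <- segment_track_phases(tr)

  still <- tr
  still$x <- rep(0, length(tr$x)); still$y <- rep(0, length(tr$y))
  mm <- migration_metrics(still, seg)
  expect_equal(mm$velocity_px_hr, rep(0, 3))

  straight <- tr
  straight$x <- seq_along(tr$x) - 1; straight$y <- rep(0, length(tr$y))
  mm2 <- migration_metrics(straight, seg)
  expect_equal(mm2$velocity_px_hr, rep(6, 3))  # 1 px per 10-min frame

  # seeded G1 speed is twice the S speed
  sim2 <- generate_tracks(trace_sim_config(noise_sd = 0, seed = 8), 40)
  ratios <- mapply(function(tr, truth) {
    mm <- migration_metrics(tr, truth)
    mm$velocity_px_hr[mm$phase == "G1"] / mm$velocity_px_hr[mm$phase == "S"]
  }, sim2$tracks, sim2$truth)
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})

test_that("tracks round-trip through CSV", {
  sim <- generate_tracks(trace_sim_config(seed = 12), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(sim$tracks, path)
  back <- read_tracks(path)
  expect_length(back, 3)
  expect_equal(back[[1]]$venus, sim$tracks[[1]]$venus)
  expect_identical(back[[2]]$mitosis_frames, sim$tracks[[2]]$mitosis_frames)
})
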