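make_tracked_scene <- function(noise_sigma = 0.05, seed = 1L,
                               frame_size = 64L) {
  spec <- test_spec(frame_size = frame_size, center = c(32.5, 32.5),
                    sigma = c(6, 3), noise_sigma = noise_sigma, seed = seed)
  list(spec = spec,
       roi_spec = data.frame(label = "facial", x = 17, y = 17,
                             height = 32, width = 32))
}

test_that("ROI definition validates geometry and template content", {
  sc <- make_tracked_scene()
  fr <- render_frame(sc$spec)

  rois <- define_rois(fr, sc$roi_spec)
  expect_length(rois, 1)
  # warm-blob descriptor peaks at the innermost ring and decays outward
  rpt <- rois[[1]]$ref_rpt
  expect_equal(which.max(rpt), 1L)
  expect_lt(rpt[length(rpt)], rpt[1] - 1)

  # touching the frame edge exactly is accepted; 1 px outside is not
  edge <- data.frame(label = "edge", x = 33, y = 33, height = 32, width = 32)
  expect_length(define_rois(fr, edge), 1)
  out <- data.frame(label = "out", x = 34, y = 33, height = 32, width = 32)
  expect_error(define_rois(fr, out), "outside the frame")

  flat <- thermal_frame(matrix(34, 64, 64))
  expect_error(define_rois(flat, sc$roi_spec), "degenerate template")
})

test_that("searching the reference frame returns the reference position with score 100", {
  sc <- make_tracked_scene()
  fr <- render_frame(sc$spec)
  for (matcher in c("rpt", "ncc")) {
    rois <- define_rois(fr, sc$roi_spec, run_config(matcher = matcher))
    res <- search_frame(fr, rois[[1]], window = 8)
    expect_equal(c(res$x, res$y), c(17, 17))
    expect_equal(res$score, 100, tolerance = 1e-9)
  }
})

test_that("integer translations are recovered exactly within the window", {
  sc <- make_tracked_scene(noise_sigma = 0)
  fr0 <- render_frame(sc$spec)
  fr1 <- render_frame(sc$spec, pose = list(translate = c(3, -2)))
  for (matcher in c("rpt", "ncc")) {
    rois <- define_rois(fr0, sc$roi_spec, run_config(matcher = matcher))
    res <- search_frame(fr1, rois[[1]], window = 8)
    expect_equal(c(res$x, res$y), c(17 + 3, 17 - 2))
  }
})

test_that("a 90-degree rotation about the ROI center keeps the RPT match perfect", {
  sc <- make_tracked_scene(noise_sigma = 0)
  fr0 <- render_frame(sc$spec)
  fr90 <- render_frame(sc$spec, pose = list(rotate = 90))
  rois <- define_rois(fr0, sc$roi_spec, run_config(matcher = "rpt"))
  res <- search_frame(fr90, rois[[1]], window = 6)
  expect_equal(c(res$x, res$y), c(17, 17))
  expect_equal(res$score, 100, tolerance = 1e-6)
})

test_that("windowed search equals an exhaustive full-frame scan", {
  sc <- make_tracked_scene(frame_size = 48L)
  spec <- test_spec(frame_size = 48L, center = c(24.5, 24.5), sigma = c(6, 3),
                    seed = 2)
  fr0 <- render_frame(spec)
  fr1 <- render_frame(spec, pose = list(translate = c(2, 1)), seed = 77)
  roi_spec <- data.frame(label = "facial", x = 13, y = 13,
                         height = 24, width = 24)
  for (matcher in c("rpt", "ncc")) {
    rois <- define_rois(fr0, roi_spec, run_config(matcher = matcher))
    windowed <- search_frame(fr1, rois[[1]], window = 12)
    full <- search_frame(fr1, rois[[1]], window = Inf)
    expect_equal(windowed[c("x", "y", "score")], full[c("x", "y", "score")])
  }
  expect_error(
    search_frame(render_frame(spec), define_rois(
      render_frame(spec),
      data.frame(label = "f", x = 1, y = 1, height = 48, width = 48))[[1]],
      window = 60) -> tmp, NA)
})

test_that("a static sequence yields a constant, fully valid track", {
  sc <- make_tracked_scene()
  fr <- render_frame(sc$spec)
  frames <- lapply(0:9, function(i)
    thermal_frame(fr$values, frame_index = i, plausible_range = NULL))
  seqs <- thermal_sequence(frames)
  for (matcher in c("rpt", "ncc")) {
    rois <- define_rois(frames[[1]], sc$roi_spec, run_config(matcher = matcher))
    res <- track_sequence(seqs, rois, run_config(matcher = matcher))
    expect_true(all(res$trajectories$valid))
    expect_true(all(res$trajectories$x == 17 & res$trajectories$y == 17))
    expect_equal(length(unique(res$readings$temperature_C)), 1L)
  }
})

test_that("scripted linear motion is recovered frame-perfectly", {
  sc <- make_tracked_scene(seed = 3)
  tri <- function(i, amp) { p <- i %% (2 * amp); ifelse(p <= amp, p, 2 * amp - p) }
  script <- motion_script(50, dx = tri(0:49, 12), dy = 0)  # 1 px/frame
  gen <- generate_sequence(sc$spec, script)
  rois <- define_rois(gen$sequence$frames[[1]], sc$roi_spec,
                      run_config(matcher = "ncc"))
  res <- track_sequence(gen$sequence, rois, run_config(matcher = "ncc",
                                                       window = 4))
  truth <- roi_truth(rois, gen$truth)
  m <- merge(res$trajectories, truth, by = c("frame_index", "roi"))
  expect_true(all(m$valid))
  expect_true(all(m$x.x == m$x.y & m$y.x == m$y.y))
})

test_that("full occlusion invalidates frames and reacquisition is immediate", {
  sc <- make_tracked_scene(seed = 4)
  script <- motion_script(30, occlusions = list(c(10, 14)))
  gen <- generate_sequence(sc$spec, script)
  rois <- define_rois(gen$sequence$frames[[1]], sc$roi_spec,
                      run_config(matcher = "ncc"))
  res <- track_sequence(gen$sequence, rois, run_config(matcher = "ncc"))
  tr <- res$trajectories
  expect_false(any(tr$valid[tr$frame_index %in% 10:14]))
  expect_true(all(is.na(res$readings$temperature_C[tr$frame_index %in% 10:14])))
  reacq <- min(tr$frame_index[tr$frame_index > 14 & tr$valid])
  expect_lte(reacq - 15, 3)
  expect_equal(tr$x[tr$frame_index == reacq], 17)
  expect_equal(tr$y[tr$frame_index == reacq], 17)
})

test_that("tracking is bit-deterministic for identical inputs", {
  sc <- make_tracked_scene(seed = 5)
  script <- motion_script(10, dx = 0:9)
  gen <- generate_sequence(sc$spec, script)
  rois <- define_rois(gen$sequence$frames[[1]], sc$roi_spec)
  r1 <- track_sequence(gen$sequence, rois, run_config())
  r2 <- track_sequence(gen$sequence, rois, run_config())
  expect_identical(r1$trajectories, r2$trajectories)
})

test_that("reported temperatures equal the corrected mean over the tracked window", {
  sc <- make_tracked_scene(seed = 6)
  script <- motion_script(8, dx = 0:7)
  gen <- generate_sequence(sc$spec, script)
  cfg <- run_config(matcher = "ncc")
  rois <- define_rois(gen$sequence$frames[[1]], sc$roi_spec, cfg)
  res <- track_sequence(gen$sequence, rois, cfg)
  tr <- res$trajectories
  for (i in which(tr$valid)) {
    f <- gen$sequence$frames[[match(tr$frame_index[i],
      vapply(gen$sequence$frames, `[[`, integer(1), "frame_index"))]]
    win <- f$values[tr$y[i]:(tr$y[i] + 31), tr$x[i]:(tr$x[i] + 31)]
    expect_equal(res$readings$temperature_C[i],
                 mean(correct_temperature(win, cfg$calibration)),
                 tolerance = 1e-12)
  }
})

test_that("tracking reports reproduce the hand-computed success arithmetic", {
  # 50 frames, one ROI: 41 within tolerance -> 82 %
  traj <- data.frame(frame_index = 0:49, roi = "a", label = "facial",
                     x = 10, y = 10, score = 90, scale = NA,
                     valid = TRUE)
  truth <- data.frame(frame_index = 0:49, roi = "a", x = 10, y = 10)
  truth$x[1:9] <- 20      # 9 frames off by 10 px
  rep1 <- evaluate_tracking(traj, truth, tolerance_px = 2)
  expect_equal(rep1$per_roi$success_rate, 82)

  # a perfect trajectory scores 100 %
  rep2 <- evaluate_tracking(traj, data.frame(frame_index = 0:49, roi = "a",
                                             x = 10, y = 10))
  expect_equal(rep2$per_roi$success_rate, 100)

  # region with 5 desired ROIs, 4 tracked, 1 misallocated -> scoring 80
  traj5 <- do.call(rbind, lapply(1:5, function(k)
    data.frame(frame_index = 0:9, roi = paste0("r", k), label = "lower-limb",
               x = 10 + if (k == 5) 30 else 0, y = 10, score = 90,
               scale = NA, valid = TRUE)))
  truth5 <- do.call(rbind, lapply(1:5, function(k)
    data.frame(frame_index = 0:9, roi = paste0("r", k), x = 10, y = 10)))
  rep3 <- evaluate_tracking(traj5, truth5, tolerance_px = 2)
  reg <- rep3$per_region
  expect_equal(reg$desired, 5)
  expect_equal(reg$tracked, 4)
  expect_equal(reg$misallocated, 1)
  expect_equal(reg$scoring_percentage, 80)
  expect_equal(reg$tracked + reg$misallocated, reg$desired)

  # mismatched indices are an error
  expect_error(evaluate_tracking(traj, truth[1:10, ]), "index mismatch")
})
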