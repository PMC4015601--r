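test_that("delimited frame matrices read back exactly what was written", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("30,31", "32,33"), p)
  fr <- read_frame_matrix(p)
  expect_identical(fr$values, rbind(c(30, 31), c(32, 33)))

  for (delim in c(",", "\t", ";")) {
    m <- matrix(round(runif(30, 20, 40), 6), 5, 6)
    q <- withr::local_tempfile(fileext = ".txt")
    write_frame_matrix(thermal_frame(m), q, delimiter = delim)
    expect_equal(read_frame_matrix(q, delimiter = delim)$values, m,
                 ignore_attr = TRUE)
  }
})

test_that("malformed frame matrices fail with located errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("30,31,32", "33,34,35,36"), p)
  expect_error(read_frame_matrix(p), "ragged")

  writeLines(c("30,31", "32,oops"), p)
  expect_error(read_frame_matrix(p), "row 2, column 2")
})

test_that("thermal frame and sequence invariants are enforced", {
  expect_error(thermal_frame(matrix(c(1, NA, 3, 4), 2, 2)), "non-finite")
  expect_error(thermal_frame(matrix(30, 1, 5)), "2x2")
  expect_warning(thermal_frame(matrix(80, 3, 3)), "plausible range")
  expect_silent(thermal_frame(matrix(80, 3, 3), plausible_range = NULL))

  f1 <- thermal_frame(matrix(34, 4, 4), frame_index = 0L)
  f2 <- thermal_frame(matrix(34, 4, 5), frame_index = 1L)
  expect_error(thermal_sequence(list(f1, f2)), "identical dimensions")
  f3 <- thermal_frame(matrix(34, 4, 4), frame_index = 0L)
  expect_error(thermal_sequence(list(f1, f3)), "strictly increasing")
})

test_that("16-bit TIFF sequences round-trip within quantization tolerance", {
  fr <- thermal_frame(matrix(30, 8, 8))
  seq1 <- thermal_sequence(list(fr))
  p <- withr::local_tempfile(fileext = ".tif")
  write_sequence_tiff(seq1, p, scale = 0.01, offset = 0)
  back <- read_sequence_tiff(p)  # sidecar supplies scale/offset
  expect_equal(back$frames[[1]]$values, matrix(30, 8, 8), tolerance = 1e-12)

  frames <- lapply(0:2, function(i)
    thermal_frame(matrix(runif(64, 25, 40), 8, 8), frame_index = i))
  seq2 <- thermal_sequence(frames, frame_rate = 10)
  write_sequence_tiff(seq2, p, scale = 0.01, offset = 0)
  back2 <- read_sequence_tiff(p)
  expect_equal(back2$frame_rate, 10)
  for (i in 1:3)
    expect_lt(max(abs(back2$frames[[i]]$values - frames[[i]]$values)), 0.005 + 1e-9)
})

test_that("non-grayscale or mixed-size TIFF pages are format errors", {
  p <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0.5, 4, 4), matrix(0.5, 4, 5)), p,
                  bits.per.sample = 16L)
  expect_error(read_sequence_tiff(p, scale = 0.01, offset = 0), "mixed sizes")

  tiff::writeTIFF(array(0.5, c(4, 4, 3)), p, bits.per.sample = 16L)
  expect_error(read_sequence_tiff(p, scale = 0.01, offset = 0),
               "non-grayscale")

  writeLines("this is not a tiff", p)
  expect_error(read_sequence_tiff(p, scale = 0.01, offset = 0),
               "format error")
})

test_that("radiometric correction is the identity for a blackbody registration", {
  cal <- calibration_config(emissivity = 1, foil_transmission = 1,
                            ambient_temperature = 34,
                            registered_emissivity = 1)
  expect_equal(correct_temperature(36, cal), 36, tolerance = 1e-12)
  expect_equal(correct_temperature(c(20, 30, 40), cal), c(20, 30, 40),
               tolerance = 1e-12)
})

test_that("radiometric correction matches the frozen root-finding value", {
  # independent scipy.brentq solve of the fourth-power balance, computed
  # before this implementation: apparent 36.0, eps 0.972, tau 0.93,
  # ambient = foil = 34.0 -> 36.21021965574166
  cal <- calibration_config(emissivity = 0.972, foil_transmission = 0.93,
                            ambient_temperature = 34, foil_temperature = 34)
  expect_equal(correct_temperature(36, cal), 36.21021965574166,
               tolerance = 1e-6)
})

test_that("lower emissivity raises the corrected temperature of a warm object", {
  vals <- vapply(c(0.99, 0.972, 0.9, 0.8), function(eps)
    correct_temperature(36, calibration_config(
      emissivity = eps, foil_transmission = 1, ambient_temperature = 34,
      foil_temperature = 34)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("correction agrees with a bisection oracle on random parameter draws", {
  set.seed(101)
  for (k in 1:100) {
    eps <- runif(1, 0.7, 1); tau <- runif(1, 0.7, 1)
    t_amb <- runif(1, 20, 40); t_foil <- runif(1, 20, 40)
    app <- runif(1, 30, 40)
    eps_reg <- sample(c(1, runif(1, 0.9, 1)), 1)
    cal <- calibration_config(emissivity = eps, foil_transmission = tau,
                              ambient_temperature = t_amb,
                              foil_temperature = t_foil,
                              registered_emissivity = eps_reg)
    expect_equal(correct_temperature(app, cal),
                 correction_oracle(app, eps, tau, t_amb, t_foil, eps_reg),
                 tolerance = 1e-6)
  }
})

test_that("nonphysical parameter combinations raise a domain error", {
  cal <- calibration_config(emissivity = 0.05, foil_transmission = 0.99,
                            ambient_temperature = 60, foil_temperature = 60)
  expect_error(correct_temperature(5, cal), "domain error")
})
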