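test_that("CSV recordings load with the expected length and metadata", {
  # 3 minutes at 10 Hz
  n <- 1800
  t <- (0:(n - 1)) / 10
  path <- write_fixture_csv(list(time = t, O2Hb = sin(t), HHb = cos(t)))
  rec <- read_nirs_recording(path, condition = "baseline",
                             subject_id = "S07")
  expect_s3_class(rec, "nirs_recording")
  expect_length(rec, 1800)
  expect_identical(names(rec$channels), c("O2Hb", "HHb"))
  expect_identical(rec$subject_id, "S07")
  expect_identical(rec$condition, "baseline")

  one <- write_fixture_csv(list(O2Hb = 0.5))
  expect_length(read_nirs_recording(one, "loaded"), 1)
})

test_that("non-numeric cells are an error naming row and column", {
  path <- write_fixture_csv(list(O2Hb = c("1.0", "NA", "3.0"),
                                 HHb = c("0", "0", "0")))
  expect_error(read_nirs_recording(path, "baseline"),
               "row 2.*column 'O2Hb'")
})

test_that("missing files and absent declared columns are errors", {
  expect_error(read_nirs_recording(tempfile(), "baseline"), "not found")
  path <- write_fixture_csv(list(O2Hb = 1:3))
  expect_error(read_nirs_recording(path, "baseline",
                                   channel_map = c(HHb = "deoxy")),
               "absent")
  nochan <- write_fixture_csv(list(foo = 1:3))
  expect_error(read_nirs_recording(nochan, "baseline"), "channel")
})

test_that("the exclusion mask drops the listed sample ranges", {
  path <- write_fixture_csv(list(O2Hb = as.numeric(1:100)))
  mask <- tempfile(fileext = ".json")
  writeLines('[{"start": 1, "end": 10}, {"start": 51, "end": 60}]', mask)
  rec <- read_nirs_recording(path, "baseline", exclusion_mask = mask)
  expect_length(rec, 80)
  expect_identical(rec$channels$O2Hb[1], 11)
})

test_that("recording invariants are enforced", {
  expect_error(nirs_recording(list(O2Hb = 1:5, HHb = 1:4), "baseline"),
               "share one length")
  expect_error(nirs_recording(list(O2Hb = 1:5), "jogging"))
  expect_error(nirs_recording(list(bogus = 1:5), "baseline"), "unknown")
  expect_error(nirs_recording(list(O2Hb = 1:5), "baseline",
                              sampling_rate = 0), "sampling_rate")
})

test_that("window counts follow floor(L / stride) with remainder discarded", {
  cases <- list(c(1800, 28), c(64, 1), c(63, 0), c(3000, 46), c(128, 2))
  for (cs in cases) {
    ws <- crop_windows(fixture_recording(cs[1]), 64)
    expect_length(ws, cs[2])
  }
})

test_that("cropped windows tile the recording exactly and inherit metadata", {
  rec <- fixture_recording(200, condition = "loaded", subject = "S03")
  ws <- crop_windows(rec, 64)
  expect_length(ws, 3)
  expect_true(all(ws$label == "loaded"))
  expect_true(all(ws$subject_id == "S03"))
  expect_identical(ws$source_offset, c(1L, 65L, 129L))
  # concatenating the windows reproduces the first floor(L/w)*w samples
  recon <- as.vector(t(ws$x[, 1, ]))
  expect_identical(recon, rec$channels$O2Hb[1:192])
  # overlapping stride
  expect_length(crop_windows(rec, 64, stride = 32), 5)
  expect_error(crop_windows(rec, 0), ">= 1")
})

test_that("channel selection fixes order and rejects derived channels", {
  ws <- crop_windows(fixture_recording(128), 64)
  one <- select_channels(ws, "O2Hb")
  expect_identical(dim(one$x), c(2L, 1L, 64L))
  # order is O2Hb then HHb regardless of request order
  both <- select_channels(ws, c("HHb", "O2Hb"))
  expect_identical(both$channels, c("O2Hb", "HHb"))
  expect_identical(dim(both$x), c(2L, 2L, 64L))
  expect_error(select_channels(ws, "TSI"), "excluded by design")
  expect_error(select_channels(ws, "THb"), "excluded by design")
  expect_error(select_channels(ws, "XYZ"), "unknown")
})

test_that("per-window normalization zeroes each channel mean", {
  ws <- crop_windows(fixture_recording(640), 64)
  nw <- normalize_windows(ws)
  mus <- apply(nw$x, c(1, 2), mean)
  expect_lt(max(abs(mus)), 1e-12)
  expect_true(nw$normalized)
  # amplitude is untouched
  expect_equal(apply(nw$x, 1, max) - apply(nw$x, 1, min),
               apply(ws$x, 1, max) - apply(ws$x, 1, min))
})

test_that("window containers round-trip through the single-file format", {
  ws <- crop_windows(fixture_recording(256), 64)
  path <- tempfile(fileext = ".rds")
  write_windows(ws, path)
  back <- read_windows(path)
  expect_identical(back$x, ws$x)
  expect_identical(back$label, ws$label)
  expect_error(read_windows(tempfile()), "not found")
})
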