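test_that("map exchange format parses and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\\time\t0\t0.5\t1", "0\t1\t2\t3", "1\t4\t5\t6"), path)
  m <- read_stmap(path, "diameter_mm")
  expect_equal(m$positions, c(0, 1))
  expect_equal(m$times, c(0, 0.5, 1))
  expect_equal(m$values, matrix(1:6, 2, 3, byrow = TRUE))

  m2 <- stmap(matrix(c(1.123456789, NA, pi, -2.5e-4), 2, 2),
              c(0, 2.5), c(10, 20), "pressure_mmHg")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_stmap(m2, p2)
  back <- read_stmap(p2, "pressure_mmHg")
  expect_equal(back$values, m2$values, tolerance = 1e-8)
  expect_true(is.na(back$values[2, 1]))
  expect_equal(back$positions, m2$positions)
})

test_that("malformed map files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\\time\t0\t0\t1", "0\t1\t2\t3"), path)  # duplicated time
  expect_error(read_stmap(path), "non-increasing time axis")
  writeLines(c("pos\\time\t0\t1", "0\t1\tx"), path)
  expect_error(read_stmap(path), "non-numeric")
  writeLines(c("xx\t0\t1", "0\t1\t2"), path)
  expect_error(read_stmap(path), "pos")
  expect_error(stmap(matrix(numeric(0), 0, 0), numeric(0), numeric(0)),
               "empty map")
})

test_that("resampling is bilinear: exact on constants, linears and midpoints", {
  const <- stmap(matrix(5, 3, 5), 0:2, seq(0, 2, 0.5), "diameter_mm")
  r <- resample(const, dx = 0.25, dt = 0.1)
  expect_true(all(r$values == 5))

  corners <- stmap(matrix(c(0, 4, 2, 6), 2, 2), c(0, 1), c(0, 1), "diameter_mm")
  mid <- resample(corners, positions = 0.5, times = 0.5)
  expect_equal(mid$values[1, 1], 3)

  lin <- stmap(matrix(rep(seq(0, 10, 0.5), each = 2), 2), c(0, 1),
               seq(0, 10, 0.5), "diameter_mm")
  fine <- resample(lin, dx = 1, dt = 0.25)
  expect_equal(fine$values[1, ], fine$times, tolerance = 1e-12)

  # idempotent on its own grid
  again <- resample(fine, positions = fine$positions, times = fine$times)
  expect_equal(again$values, fine$values, tolerance = 1e-12)

  expect_error(resample(corners, positions = 2, times = 0.5), "extent")
})

test_that("missing values propagate through any stencil that uses them", {
  v <- matrix(1, 3, 3); v[2, 2] <- NA
  m <- stmap(v, 0:2, 0:2, "diameter_mm")
  r <- resample(m, positions = c(0.5, 1.5), times = c(0.5, 1.5))
  expect_true(all(is.na(r$values)))
  # on-grid queries away from the hole are unaffected
  r2 <- resample(m, positions = 0, times = 0:2)
  expect_equal(r2$values[1, ], c(1, 1, 1))
})

test_that("baseline drift removal zeroes constants and keeps short pulses", {
  tt <- seq(0, 600, 0.5)
  const <- stmap(matrix(7, 2, length(tt)), 0:1, tt, "pressure_mmHg")
  expect_true(all(abs(remove_baseline_drift(const, 120)$values) < 1e-12))

  ramp <- stmap(matrix(0.01 * tt, 1, byrow = TRUE), 0, tt, "pressure_mmHg")
  res <- remove_baseline_drift(ramp, 120)
  interior <- tt > 60 & tt < 540
  expect_lt(max(abs(res$values[1, interior])), 0.01 * 60)

  x <- rep(5, length(tt)); x[tt >= 300 & tt < 302] <- 15
  pulse <- stmap(matrix(x, 1, byrow = TRUE), 0, tt, "pressure_mmHg")
  res2 <- remove_baseline_drift(pulse, 120)
  expect_equal(res2$values[1, which.min(abs(tt - 301))], 10, tolerance = 1e-9)

  expect_error(remove_baseline_drift(ramp, 4), "10 samples")
})

test_that("alignment recovers affine clock mappings exactly", {
  set.seed(42)
  tA <- seq(0, 19)
  mA <- stmap(matrix(runif(200), 10, 20), 0:9, tA, "diameter_mm")
  mB <- stmap(matrix(runif(200), 10, 20), 0:9, tA + 3, "pressure_mmHg")
  ev <- c(1, 5, 10, 15)
  cmp <- align(mA, sync_events(ev), mB, sync_events(ev + 3))
  al <- attr(cmp, "alignment")
  expect_equal(al$alpha, 1, tolerance = 1e-12)
  expect_equal(al$beta, 3, tolerance = 1e-12)
  expect_lt(al$residual_rms, 1e-9)

  mB2 <- stmap(mB$values, mB$positions, 1.001 * tA + 3, "pressure_mmHg")
  cmp2 <- align(mA, sync_events(ev), mB2, sync_events(1.001 * ev + 3))
  al2 <- attr(cmp2, "alignment")
  expect_equal(al2$alpha, 1.001, tolerance = 1e-9)
  expect_equal(al2$beta, 3, tolerance = 1e-9)
  expect_lt(al2$residual_rms, 1e-9)
  expect_s3_class(cmp2, "composite_map")

  expect_error(align(mA, sync_events(c(1, 2, 3)), mB, sync_events(c(1, 2))),
               "alignment error")
  expect_warning(align(mA, sync_events(ev), mB2, sync_events(1.2 * ev + 3)),
                 "clock-rate anomaly")
})

test_that("Laplace tension follows pressure x radius / thickness", {
  expect_equal(laplace_tension(0, 6, 1, units = "mmHg"), 0)
  expect_equal(laplace_tension(2, 6, 1, units = "mmHg"), 6)
  expect_equal(laplace_tension(2, 6, 1, units = "kPa"), 6 * 0.133322)
  # doubling wall thickness halves the tension
  expect_equal(laplace_tension(5, 9, 2, units = "mmHg"),
               laplace_tension(5, 9, 1, units = "mmHg") / 2)
  expect_error(laplace_tension(2, 6, 0), "thickness")
})

test_that("sync event tables round-trip through TSV", {
  ev <- sync_events(c(1.5, 10, 30.25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sync_events(ev, path)
  expect_equal(as.numeric(read_sync_events(path)), as.numeric(ev))
  expect_error(sync_events(c(2, 1)), "strictly increasing")
})
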