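test_that("ruler calibration uses the median inter-mark gap", {
  expect_equal(calibrate(c(0, 100, 200))$mm_per_px, 0.1)
  expect_equal(calibrate(c(0, 98, 202))$mm_per_px, 10 / 101, tolerance = 1e-12)
  expect_error(calibrate(50), "at least 2")
  expect_error(calibrate(c(10, 10, 20)), "coincident")
})

test_that("diameter profiles measure the dark band width", {
  cal <- calibrate(c(0, 100, 200))
  frame <- matrix(1, 100, 60)
  frame[31:70, ] <- 0  # 40 px band
  d <- extract_diameter_profile(frame, cal, threshold = 0.5)
  interior <- 3:58
  expect_true(all(abs(d[interior] - 4.0) < 1e-12))
  expect_true(all(is.na(d[c(1, 2, 59, 60)])))  # excluded edge columns

  # tapering band: 40 px down to 20 px across the frame
  frame2 <- matrix(1, 100, 60)
  w <- round(seq(40, 20, length.out = 60))
  for (j in 1:60) frame2[(51 - ceiling(w[j] / 2)):(50 + floor(w[j] / 2)), j] <- 0
  d2 <- extract_diameter_profile(frame2, cal, threshold = 0.5)
  expected <- seq(4, 2, length.out = 60)
  expect_true(all(abs(d2[interior] - expected[interior]) <= 0.1 + 1e-12))

  blank <- matrix(1, 100, 60)
  expect_true(all(is.na(extract_diameter_profile(blank, cal, threshold = 0.5))))
})

test_that("auto threshold is invariant to affine intensity rescaling", {
  cal <- calibrate(c(0, 100, 200))
  frame <- matrix(0.9, 80, 40)
  frame[21:50, ] <- 0.1
  d1 <- extract_diameter_profile(frame, cal, threshold = "auto")
  d2 <- extract_diameter_profile(0.5 * frame + 0.4, cal, threshold = "auto")
  expect_equal(d1, d2)
  expect_equal(d1[10], 3.0)
})

test_that("DMaps assemble from stacks with frame-rate timing", {
  cal <- calibrate(c(0, 100, 200))
  frame <- matrix(1, 100, 60); frame[31:70, ] <- 0
  stack <- frame_stack(rep(list(frame), 8), fps = 4)
  dm <- build_dmap(stack, cal, threshold = 0.5)
  expect_equal(dm$times, seq(0, 1.75, 0.25))
  expect_equal(dm$positions, (0:59) * 0.01)
  expect_true(all(abs(dm$values[3:58, ] - 4) < 1e-12))
  expect_error(frame_stack(list(), 4), "empty")
})

test_that("LED rising edges become sync events", {
  make_frame <- function(on) {
    f <- matrix(0.2, 50, 50)
    if (on) f[1:10, 1:10] <- 1
    f
  }
  on <- rep(FALSE, 50); on[11:13] <- TRUE; on[41:42] <- TRUE  # frames 10-12, 40-41 (0-based)
  stack <- frame_stack(lapply(on, make_frame), fps = 4)
  ev <- detect_sync_led(stack, roi = c(1, 10, 1, 10), on_threshold = 0.5)
  expect_equal(as.numeric(ev), c(2.5, 10.0))

  never <- frame_stack(lapply(rep(FALSE, 10), make_frame), fps = 4)
  expect_length(detect_sync_led(never, c(1, 10, 1, 10), 0.5), 0L)
  always <- frame_stack(lapply(rep(TRUE, 10), make_frame), fps = 4)
  expect_length(detect_sync_led(always, c(1, 10, 1, 10), 0.5), 0L)
  expect_error(detect_sync_led(stack, c(0, 10, 1, 10), 0.5), "roi")
})

test_that("render -> extract round trip recovers the map within one pixel", {
  par <- synth_params(length = 6, duration = 10, dt = 0.5,
                      myogenic = list(extent = 1),
                      neurogenic = list(origin = 1.5, anal_zone = 1,
                                        dilation_extent = 1,
                                        contraction_extent = 1,
                                        isometric_extent = 0.5,
                                        recovery_extent = 1,
                                        first_wave = 2, speed = 0.5))
  dm <- generate_dataset(par)$truth$dmap
  cal <- calibrate(c(0, 100, 200))
  stack <- render_frames(dm, cal, height_px = 160)
  back <- build_dmap(stack, cal, threshold = 0.5)
  interior <- dm$positions > 0.1 & dm$positions < 5.9
  got <- motimech:::interp_bilinear(back$values, back$positions, back$times,
                                    dm$positions[interior], dm$times)
  expect_lt(max(abs(got - dm$values[interior, ])), 0.1 + 1e-9)

  # frame stacks survive PNG round trips
  dir <- withr::local_tempdir()
  write_frame_stack(stack, dir)
  stack2 <- read_frame_stack(dir, fps = stack$fps)
  expect_equal(stack2$frames[[1]], stack$frames[[1]], tolerance = 1e-2)
  back2 <- build_dmap(stack2, cal, threshold = 0.5)
  expect_lt(max(abs(back2$values[3:598, ] - back$values[3:598, ]),
                na.rm = TRUE), 0.05)
})
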