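test_that("shortening velocity is minus the diameter derivative", {
  tt <- seq(0, 10, 0.25)
  orb <- orbit(tt, 10 - tt, rep(5, length(tt)))
  v <- shortening_velocity(orb, sigma_t = 0)
  expect_equal(v[3:(length(v) - 2)], rep(1, length(v) - 4), tolerance = 1e-12)

  vc <- shortening_velocity(orbit(tt, rep(7, length(tt)), tt), sigma_t = 0)
  expect_true(all(abs(vc) < 1e-12))

  orb_s <- orbit(tt, 5 + sin(tt), rep(5, length(tt)))
  vs <- shortening_velocity(orb_s, sigma_t = 0)
  interior <- 2:(length(tt) - 1)
  bound <- max(abs(-cos(tt[interior]) * sin(0.25) / 0.25 + cos(tt[interior])))
  expect_lt(max(abs(vs[interior] + cos(tt[interior]))), bound + 0.02)
  expect_error(shortening_velocity(orbit(c(0, 1), c(1, 2), c(1, 2))), "3 samples")
})

test_that("exact hyperbola points are recovered to numerical precision", {
  fit <- fit_hill(data.frame(P = c(0, 1, 3), V = c(3, 1, 0)))
  expect_equal(fit$a, 1, tolerance = 1e-9)
  expect_equal(fit$b, 1, tolerance = 1e-9)
  expect_equal(fit$C, 4, tolerance = 1e-9)
  expect_equal(fit$Pmax, 3, tolerance = 1e-9)
  # C = (Pmax + a) b identity and V(Pmax) = 0
  expect_equal(fit$C, (fit$Pmax + fit$a) * fit$b, tolerance = 1e-9)
  expect_equal(predict_velocity(fit, fit$Pmax), 0, tolerance = 1e-9)
  expect_equal(predict_velocity(fit, 1), 1, tolerance = 1e-9)
})

test_that("constants on the reported rabbit-colon hyperbola are recovered", {
  pts <- hill_curve_samples(a = 0.037, b = 0.49, Pmax = 77, n = 20)
  fit <- fit_hill(pts)
  expect_equal(fit$a, 0.037, tolerance = 1e-6)
  expect_equal(fit$b, 0.49, tolerance = 1e-6)
  expect_equal(fit$Pmax, 77, tolerance = 1e-6)
  expect_lt(fit$rms, 1e-6)
})

test_that("random noiseless hyperbola points are recovered exactly", {
  set.seed(31)
  for (rep in 1:10) {
    a <- runif(1, 0.5, 20); b <- runif(1, 0.1, 3); Pmax <- runif(1, 30, 120)
    pts <- hill_curve_samples(a, b, Pmax, n = sample(3:25, 1))
    fit <- fit_hill(pts)
    expect_equal(fit$a, a, tolerance = 1e-6)
    expect_equal(fit$b, b, tolerance = 1e-6)
    expect_equal(fit$Pmax, Pmax, tolerance = 1e-6)
  }
})

test_that("the fitted curve is strictly decreasing and convex on [0, Pmax]", {
  fit <- fit_hill(hill_curve_samples(2, 0.6, 80, n = 15))
  pp <- seq(0, fit$Pmax, length.out = 200)
  v <- predict_velocity(fit, pp)
  expect_true(all(diff(v) < 0))
  expect_true(all(diff(diff(v)) > 0))
  expect_error(predict_velocity(fit, -fit$a - 1), "pole")
})

test_that("degenerate designs are rejected", {
  expect_error(fit_hill(data.frame(P = c(1, 2), V = c(1, 2))), "at least 3")
  expect_error(fit_hill(data.frame(P = c(2, 2, 2), V = c(1, 2, 3))),
               "positive range|collinear")
})

test_that("noisy velocity samples recover Pmax with small bias", {
  set.seed(77)
  a <- 5; b <- 0.49; Pmax <- 77
  C <- (Pmax + a) * b
  vrange <- C / a - b
  est <- replicate(100, {
    P <- runif(200, 0, Pmax)
    V <- C / (P + a) - b + rnorm(200, sd = 0.05 * vrange)
    fit_hill(data.frame(P = P, V = V))$Pmax
  })
  expect_lt(abs(mean(est) - Pmax) / Pmax, 0.02)
})

test_that("pressure-velocity pooling over windows respects phase structure", {
  # isotonic phase: constant P, falling D -> shared pressure, positive V
  tt <- seq(0, 20, 0.25)
  cm <- trace_cmap(10 - 0.3 * tt, rep(6, length(tt)), dt = 0.25, np = 3)
  pv <- collect_pv_samples(cm, data.frame(position = 1, t0 = 1, t1 = 19),
                           sigma_t = 0)
  expect_true(all(abs(pv$P - 6) < 1e-9))
  expect_true(all(pv$V > 0))

  # isometric phase: constant D -> V ~ 0, varying P (lengthening kept)
  cm2 <- trace_cmap(rep(4, length(tt)), 2 + tt, dt = 0.25, np = 3)
  pv2 <- collect_pv_samples(cm2, data.frame(position = 1, t0 = 1, t1 = 19),
                            sigma_t = 0, include_lengthening = TRUE)
  expect_true(all(abs(pv2$V) < 1e-9))
  expect_gt(diff(range(pv2$P)), 10)

  # samples drawn from a known hyperbola lie back on it
  a <- 2; b <- 0.5; Pmax <- 60; C <- (Pmax + a) * b
  P <- seq(5, 55, length.out = 101)
  V <- C / (P + a) - b
  D <- 10 - cumsum(c(0, (V[-1] + V[-length(V)]) / 2 * 0.25))  # integrate -V
  cm3 <- trace_cmap(D, P, dt = 0.25, np = 3)
  pv3 <- collect_pv_samples(cm3, data.frame(position = 1, t0 = 0, t1 = 25),
                            sigma_t = 0)
  fit3 <- fit_hill(pv3)
  expect_equal(fit3$Pmax, Pmax, tolerance = 0.05)
})
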