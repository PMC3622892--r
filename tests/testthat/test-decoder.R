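test_that("derivative estimator is exact on linear and constant signals", {
  tt <- seq(0, 10, 0.25)
  cm <- trace_cmap(5 - 0.5 * tt, 2 + 0 * tt, dt = 0.25, np = 2)
  der <- estimate_derivatives(cm, sigma_t = 0)
  interior <- 2:(length(tt) - 1)
  expect_equal(der$dD[1, interior], rep(-0.5, length(interior)), tolerance = 1e-12)
  expect_true(all(abs(der$dP) < 1e-12))

  # sinusoid: central-difference amplitude is A * sin(w dt)/dt
  w <- 2 * pi * 0.2; A <- 3; dt <- 0.25
  cms <- trace_cmap(5 + A * sin(w * tt), 2 + 0 * tt, dt = dt)
  ders <- estimate_derivatives(cms, sigma_t = 0)
  expect_equal(max(abs(ders$dD[1, interior])), A * sin(w * dt) / dt,
               tolerance = 0.02)
  expect_error(estimate_derivatives(trace_cmap(c(1, 2), c(1, 2)), 0), "3 time")
})

test_that("pooled robust scales recover the generating noise SD", {
  set.seed(99)
  nt <- 2500
  # iid N(0,1) increments scaled so the central-difference derivatives are N(0,1)
  dt <- 1
  cm <- trace_cmap(rnorm(nt), rnorm(nt), dt = dt, np = 4)
  model <- fit_emission_model(cm, sigma_t = 0)
  # derivative of white noise at dt=1 has SD 1/sqrt(2); MAD-based scale agrees
  expect_equal(model$sigma_dD, 1 / sqrt(2), tolerance = 0.05)
  expect_equal(model$sigma_dP, 1 / sqrt(2), tolerance = 0.05)
})

test_that("the occlusion boundary lands between well-separated diameter modes", {
  set.seed(5)
  d <- c(rnorm(600, 3.3, 0.1), rnorm(600, 10, 0.1))
  nt <- 120
  D <- matrix(d, 10, nt)
  cm <- composite_map(stmap(D, 1:10, seq_len(nt), "diameter_mm"),
                      stmap(matrix(rnorm(10 * nt), 10, nt), 1:10, seq_len(nt),
                            "pressure_mmHg"))
  model <- fit_emission_model(cm, sigma_t = 0)
  expect_gt(model$theta, 4)
  expect_lt(model$theta, 9)
  # equal-posterior point for equal-weight equal-SD components is the midpoint
  expect_equal(model$theta, (3.3 + 10) / 2, tolerance = 0.2)
})

test_that("mixture boundary agrees with an independent mixture fit", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(5)
  d <- c(rnorm(600, 3.3, 0.12), rnorm(600, 10, 0.3))
  mix <- motimech:::fit_diameter_mixture(d)
  mc <- mclust::Mclust(d, G = 2, modelNames = "V", verbose = FALSE)
  mu <- unname(sort(mc$parameters$mean))
  expect_equal(sort(mix$fit$mean), mu, tolerance = 0.1)
  expect_gt(mix$theta, mu[1])
  expect_lt(mix$theta, mu[2])
})

test_that("constant diameter fields fall back to the midrange boundary", {
  cm <- const_cmap(d = 4.2, p = 3, np = 5, nt = 40)
  model <- fit_emission_model(cm, sigma_t = 0)
  expect_equal(model$theta, 4.2)
  sm <- decode_states(cm, model)
  # degenerate lumen evidence: the configured default flag decides
  expect_true(all(state_label(sm$codes) == "DISTENDED_QUIESCENCE"))
  model2 <- fit_emission_model(cm, sigma_t = 0, default_lumen = "occluded")
  sm2 <- decode_states(cm, model2)
  expect_true(all(state_label(sm2$codes) == "OCCLUDED_QUIESCENCE"))
})

test_that("a constant occluded composite decodes to occluded quiescence", {
  cm <- const_cmap(d = 3.3, p = 5, np = 4, nt = 120)
  # boundary information cannot come from a constant field; supply it
  model <- fit_emission_model(cm, sigma_t = 0)
  model$theta <- 6; model$softness <- 0.5
  sm <- decode_states(cm, model)
  expect_true(all(state_label(sm$codes) == "OCCLUDED_QUIESCENCE"))
})

test_that("temporal smoothing by the HMM absorbs isolated blips", {
  nt <- 101
  dtrace <- rep(3.3, nt); ptrace <- rep(5, nt)
  cm <- trace_cmap(dtrace, ptrace, dt = 1)
  model <- fit_emission_model(cm, sigma_t = 0)
  model$theta <- 6; model$softness <- 0.5
  model$sigma_dP <- 1; model$sigma_dD <- 1
  # single-sample pressure blip producing derivative excursions of 2*kappa*sigma
  ptrace2 <- ptrace
  ptrace2[51] <- ptrace2[51] + 4 * model$kappa * model$sigma_dP
  cm2 <- trace_cmap(dtrace, ptrace2, dt = 1)
  sm_sticky <- decode_states(cm2, model, p_stay = 0.99)
  expect_true(all(state_label(sm_sticky$codes) == "OCCLUDED_QUIESCENCE"))
  sm_loose <- decode_states(cm2, model, p_stay = 0.5)
  expect_true(any(state_label(sm_loose$codes) != "OCCLUDED_QUIESCENCE"))
})

test_that("with uniform transitions Viterbi equals per-sample argmax emissions", {
  set.seed(21)
  nt <- 60
  cm <- trace_cmap(6 + cumsum(rnorm(nt, sd = 0.3)),
                   8 + cumsum(rnorm(nt, sd = 0.6)), dt = 0.5, np = 3)
  model <- fit_emission_model(cm, sigma_t = 0)
  sm <- decode_states(cm, model, p_stay = 1 / 12)
  der <- estimate_derivatives(cm, model$sigma_t)
  E <- motimech:::emission_loglik(cm$diameter$values, der$dD, der$dP, model)
  argmax <- apply(E, c(1, 2), which.max) - 1L
  expect_equal(sm$codes, matrix(as.integer(argmax), nrow(argmax)))
})

test_that("raising kappa never adds moving-state labels", {
  set.seed(8)
  nt <- 300
  cm <- trace_cmap(6 + cumsum(rnorm(nt, sd = 0.2)),
                   8 + cumsum(rnorm(nt, sd = 0.5)), dt = 0.5, np = 2)
  moving_count <- function(kappa) {
    model <- fit_emission_model(cm, sigma_t = 0, kappa = kappa)
    sm <- decode_states(cm, model)
    alph <- mechanical_states()
    moving <- alph$code[alph$sP != 0 | alph$sD != 0]
    sum(sm$codes %in% moving)
  }
  counts <- vapply(c(0.5, 1, 2, 4), moving_count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("decoding is equivariant under position permutation", {
  set.seed(13)
  np <- 6; nt <- 80
  D <- 6 + matrix(cumsum(rnorm(np * nt, sd = 0.1)), np, nt)
  P <- 8 + matrix(cumsum(rnorm(np * nt, sd = 0.3)), np, nt)
  mk <- function(D, P) composite_map(
    stmap(D, seq_len(np), seq_len(nt) * 0.5, "diameter_mm"),
    stmap(P, seq_len(np), seq_len(nt) * 0.5, "pressure_mmHg"))
  cm <- mk(D, P)
  model <- fit_emission_model(cm, sigma_t = 0)
  sm <- decode_states(cm, model)
  perm <- sample(np)
  sm_perm <- decode_states(mk(D[perm, ], P[perm, ]), model)
  expect_equal(sm_perm$codes, sm$codes[perm, ])
})

test_that("state maps serialise with a JSON legend sidecar", {
  codes <- matrix(sample(0:11, 12, TRUE), 3)
  sm <- state_map(codes, 1:3, 1:4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_state_map(sm, path)
  back <- read_stmap(path, "diameter_mm")
  expect_equal(matrix(as.integer(back$values), 3), codes)
  legend <- jsonlite::read_json(paste0(path, ".legend.json"))
  expect_length(legend, 12L)
  expect_equal(legend[["0"]]$label, "ISOMETRIC_CONTRACTION")
})
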