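#' Parameters of the synthetic motility generator
#'
#' The generator emulates a closed, isolated segment of distal colon carrying
#' two motor patterns: rhythmic non-propulsive myogenic activity in an
#' occluded oral region (isometric pressure ripples), and repeated
#' anterogradely propagating neurogenic peristaltic waves. Each wave is a
#' kinematic travelling profile: a leading (anal) dilation at constant
#' pressure (isotonic relaxation), a contraction front where diameter falls as
#' pressure rises (auxotonic contraction), an occluded plateau where pressure
#' peaks then decays (isometric contraction/relaxation), and a recovery back
#' to the resting diameter at baseline pressure (isotonic relaxation). When a
#' wave reaches the closed anal end, the distended terminal zone shows a
#' passive isometric pressure rise and fall. The travelling-profile
#' construction conserves luminal volume during propulsion by design.
#'
#' @param length segment length, cm.
#' @param duration recording duration, s.
#' @param dx,dt grid spacings, cm and s.
#' @param occluded_diameter diameter of the fully occluded lumen (the
#'   catheter diameter), mm.
#' @param distended_diameter fully distended diameter, mm.
#' @param resting_diameter resting (moderately filled) diameter, mm.
#' @param wall_thickness wall thickness used for the internal-diameter and
#'   admittance fields, mm.
#' @param baseline_pressure resting intraluminal pressure, mmHg.
#' @param myogenic list: `extent` (cm of the oral occluded region),
#'   `frequency` (Hz), `pressure_amplitude` (mmHg), `diameter_amplitude`
#'   (mm; 0 keeps the ripples isometric).
#' @param neurogenic list: `origin` (cm), `speed` (cm/s), `repeat_interval`
#'   (s), `first_wave` (s), `dilation_amplitude` (mm above resting),
#'   `contraction_depth` (mm below distended), `dilation_extent`,
#'   `contraction_extent`, `isometric_extent`, `recovery_extent` (cm),
#'   `pressure_peak` (mmHg above baseline), `anal_zone` (cm),
#'   `anal_pulse_duration` (s), `anal_pulse_amplitude` (mmHg).
#' @param noise list of noise scales: additive Gaussian `diameter_sd` (mm)
#'   and `pressure_sd` (mmHg), multiplicative lognormal `admittance_sd`.
#' @param k_admittance true area-per-admittance constant (mm^2/mS) relating
#'   internal cross-sectional area to generated admittance.
#' @param seed RNG seed for the noise draws.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(length = 20, duration = 600, dx = 1, dt = 0.25,
                         occluded_diameter = 3.2, distended_diameter = 12,
                         resting_diameter = 9, wall_thickness = 0.6,
                         baseline_pressure = 2,
                         myogenic = list(), neurogenic = list(), noise = list(),
                         k_admittance = 0.5, seed = 1) {
  myo <- utils::modifyList(list(extent = 5, frequency = 0.1,
                                pressure_amplitude = 6,
                                diameter_amplitude = 0), myogenic)
  neu <- utils::modifyList(list(origin = 6, speed = 0.5, repeat_interval = 90,
                                first_wave = 30, dilation_amplitude = 3,
                                contraction_depth = 8.8, dilation_extent = 2,
                                contraction_extent = 2, isometric_extent = 1,
                                recovery_extent = 3, pressure_peak = 25,
                                anal_zone = 4, anal_pulse_duration = 8,
                                anal_pulse_amplitude = 10), neurogenic)
  noi <- utils::modifyList(list(diameter_sd = 0.05, pressure_sd = 0.3,
                                admittance_sd = 0.02), noise)
  if (dx <= 0 || dt <= 0) stop("dx and dt must be positive", call. = FALSE)
  if (myo$extent < 0 || myo$extent > length)
    stop("myogenic extent outside the segment", call. = FALSE)
  x_end <- length - neu$anal_zone
  if (neu$origin < myo$extent || neu$origin >= x_end)
    stop("neurogenic wave parameters exceed segment bounds", call. = FALSE)
  if (neu$dilation_extent + neu$contraction_extent + neu$isometric_extent +
        neu$recovery_extent > x_end - neu$origin)
    stop("neurogenic wave profile longer than its running room", call. = FALSE)
  amps <- c(myo$pressure_amplitude, myo$diameter_amplitude,
            neu$dilation_amplitude, neu$contraction_depth, neu$pressure_peak,
            neu$anal_pulse_amplitude)
  if (any(amps < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (resting_diameter + neu$dilation_amplitude > distended_diameter + 1e-9)
    stop("dilation amplitude exceeds the distended diameter", call. = FALSE)
  structure(list(length = length, duration = duration, dx = dx, dt = dt,
                 occluded_diameter = occluded_diameter,
                 distended_diameter = distended_diameter,
                 resting_diameter = resting_diameter,
                 wall_thickness = wall_thickness,
                 baseline_pressure = baseline_pressure,
                 myogenic = myo, neurogenic = neu, noise = noi,
                 k_admittance = k_admittance, seed = seed),
            class = "synth_params")
}

#' Silence the neurogenic component (tetrodotoxin mode)
#'
#' Tetrodotoxin blocks all neural activity, abolishing peristalsis while
#' leaving myogenic pacemaker activity intact. All neurogenic amplitudes are
#' zeroed; the myogenic settings are untouched. Idempotent.
#'
#' @param params a [synth_params()].
#' @return The modified `synth_params`.
#' @export
apply_ttx <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  params$neurogenic$dilation_amplitude <- 0
  params$neurogenic$contraction_depth <- 0
  params$neurogenic$pressure_peak <- 0
  params$neurogenic$anal_pulse_amplitude <- 0
  params
}

# cubic smoothstep on [0, 1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Diameter deviation (mm, relative to resting) of the travelling wave profile
# as a function of the front-relative coordinate xi = x - x_front (cm).
wave_diameter_dev <- function(xi, neu) {
  Ld <- neu$dilation_extent; Lc <- neu$contraction_extent
  Li <- neu$isometric_extent; Lr <- neu$recovery_extent
  dil <- neu$dilation_amplitude; depth <- neu$contraction_depth
  dev <- numeric(length(xi))
  i <- xi >= 0 & xi < Ld
  dev[i] <- dil * smoothstep(1 - xi[i] / Ld)
  i <- xi >= -Lc & xi < 0
  dev[i] <- dil - depth * smoothstep(-xi[i] / Lc)
  i <- xi >= -(Lc + Li) & xi < -Lc
  dev[i] <- dil - depth
  i <- xi >= -(Lc + Li + Lr) & xi < -(Lc + Li)
  dev[i] <- (dil - depth) * (1 - smoothstep((-xi[i] - Lc - Li) / Lr))
  dev
}

# Pressure deviation (mmHg, relative to baseline) of the travelling profile.
wave_pressure_dev <- function(xi, neu) {
  Lc <- neu$contraction_extent; Li <- neu$isometric_extent
  peak <- neu$pressure_peak; mid <- 0.6 * peak
  dev <- numeric(length(xi))
  i <- xi >= -Lc & xi < 0
  dev[i] <- mid * smoothstep(-xi[i] / Lc)
  i <- xi >= -(Lc + Li / 2) & xi < -Lc
  dev[i] <- mid + (peak - mid) * smoothstep((-xi[i] - Lc) / (Li / 2))
  i <- xi >= -(Lc + Li) & xi < -(Lc + Li / 2)
  dev[i] <- peak * (1 - smoothstep((-xi[i] - Lc - Li / 2) / (Li / 2)))
  dev
}

# symmetric smooth pulse on [0, 1]
smooth_pulse <- function(u) {
  out <- numeric(length(u))
  i <- u >= 0 & u <= 0.5
  out[i] <- smoothstep(2 * u[i])
  i <- u > 0.5 & u <= 1
  out[i] <- smoothstep(2 * (1 - u[i]))
  out
}

#' Generate a synthetic motility dataset with known ground truth
#'
#' Builds noiseless diameter and pressure fields from the motor-pattern rules
#' in [synth_params()], derives ground-truth mechanical-state labels from the
#' noiseless derivative signs (exact zero bands, lumen split at the midpoint
#' between occluded and distended diameters), computes admittance from the
#' internal cross-sectional area, and finally adds the configured measurement
#' noise. With a fixed seed the output is bit-reproducible.
#'
#' @param params a [synth_params()].
#' @return A list of class `synth_dataset`: `dmap`, `pmap`, `imap` (noisy
#'   [stmap()]s) and `truth` -- a list with the ground-truth `states`
#'   ([state_map()]), the noiseless `dmap` and `pmap`, the noiseless
#'   `internal_dmap`, and the wave arrival bookkeeping.
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  p <- params
  pos <- seq(0, p$length, by = p$dx)
  tim <- seq(0, p$duration, by = p$dt)
  np <- length(pos); nt <- length(tim)
  neu <- p$neurogenic; myo <- p$myogenic
  x_end <- p$length - neu$anal_zone

  D <- matrix(p$resting_diameter, np, nt)
  P <- matrix(p$baseline_pressure, np, nt)

  # myogenic region: occluded lumen, rhythmic isometric pressure ripples
  myo_rows <- which(pos <= myo$extent + 1e-9)
  osc <- 0.5 - 0.5 * cos(2 * pi * myo$frequency * tim)
  if (length(myo_rows)) {
    D[myo_rows, ] <- p$occluded_diameter +
      myo$diameter_amplitude * rep(osc, each = length(myo_rows))
    P[myo_rows, ] <- P[myo_rows, ] +
      myo$pressure_amplitude * rep(osc, each = length(myo_rows))
  }

  # anal zone: fully distended, closed end
  anal_rows <- which(pos >= x_end - 1e-9)
  if (length(anal_rows)) D[anal_rows, ] <- p$distended_diameter

  # neurogenic waves: travelling profiles between origin and the anal zone
  neuro_rows <- which(pos >= neu$origin - 1e-9 & pos < x_end - 1e-9)
  wave_starts <- seq(neu$first_wave, p$duration, by = neu$repeat_interval)
  arrivals <- wave_starts + (x_end - neu$origin) / neu$speed
  for (Tk in wave_starts) {
    xf <- neu$origin + neu$speed * (tim - Tk)
    if (length(neuro_rows)) {
      xi <- outer(pos[neuro_rows], xf, "-")
      D[neuro_rows, ] <- D[neuro_rows, ] + wave_diameter_dev(xi, neu)
      P[neuro_rows, ] <- P[neuro_rows, ] + wave_pressure_dev(xi, neu)
    }
  }
  # passive isometric pressure pulse at the closed anal end on wave arrival
  if (length(anal_rows)) {
    for (ta in arrivals) {
      u <- (tim - ta) / neu$anal_pulse_duration
      P[anal_rows, ] <- P[anal_rows, ] +
        neu$anal_pulse_amplitude * rep(smooth_pulse(u), each = length(anal_rows))
    }
  }
  D <- pmin(pmax(D, p$occluded_diameter), p$distended_diameter)

  dmap_true <- stmap(D, pos, tim, "diameter_mm", "synthetic/noiseless")
  pmap_true <- stmap(P, pos, tim, "pressure_mmHg", "synthetic/noiseless")

  # ground-truth labels from the noiseless derivative signs
  truth_states <- truth_labels(dmap_true, pmap_true,
                               occl_boundary = (p$occluded_diameter +
                                                p$distended_diameter) / 2)

  D_int <- pmax(D - 2 * p$wall_thickness, 0.5)
  internal_true <- stmap(D_int, pos, tim, "internal_diameter_mm",
                         "synthetic/noiseless")
  csa <- pi * (D_int / 2)^2
  G <- csa / p$k_admittance

  set.seed(p$seed)
  Dn <- D + stats::rnorm(np * nt, sd = p$noise$diameter_sd)
  Pn <- P + stats::rnorm(np * nt, sd = p$noise$pressure_sd)
  Gn <- G * exp(stats::rnorm(np * nt, sd = p$noise$admittance_sd))

  structure(list(
    dmap = stmap(Dn, pos, tim, "diameter_mm", "synthetic"),
    pmap = stmap(Pn, pos, tim, "pressure_mmHg", "synthetic"),
    imap = stmap(Gn, pos, tim, "admittance_mS", "synthetic"),
    truth = list(states = truth_states, dmap = dmap_true, pmap = pmap_true,
                 internal_dmap = internal_true,
                 wave_starts = wave_starts, arrivals = arrivals),
    params = p), class = "synth_dataset")
}

# Classify every sample of a noiseless field pair by exact-zero-band
# derivative signs; shared by the generator and the consistency tests.
truth_labels <- function(dmap, pmap, occl_boundary, eps = 1e-9) {
  dt <- stmap_dt(dmap)
  dD <- central_diff_rows(dmap$values, dt)
  dP <- central_diff_rows(pmap$values, dt)
  sD <- ifelse(abs(dD) <= eps, 0L, ifelse(dD > 0, 1L, -1L))
  sP <- ifelse(abs(dP) <= eps, 0L, ifelse(dP > 0, 1L, -1L))
  lumen <- ifelse(dmap$values < occl_boundary, "occluded", "distended")
  codes <- matrix(state_code(state_from_signs(as.vector(sP), as.vector(sD),
                                              as.vector(lumen))),
                  nrow(dD), ncol(dD))
  state_map(codes, dmap$positions, dmap$times)
}

#' Luminal volume of a diameter map
#'
#' Total luminal "volume" proxy `sum(CSA * dx)` assuming a circular lumen of
#' internal diameter `max(D - 2 * wall_thickness, 0)`.
#'
#' @param dmap an [stmap()] of external diameters (mm).
#' @param wall_thickness wall thickness, mm.
#' @return Numeric vector: one volume (mm^2 * cm) per time sample.
#' @export
luminal_volume <- function(dmap, wall_thickness = 0.6) {
  d_int <- pmax(dmap$values - 2 * wall_thickness, 0)
  csa <- pi * (d_int / 2)^2
  dx <- stmap_dx(dmap)
  colSums(csa) * dx
}

#' Time windows of pure propulsion
#'
#' For each generated wave, the interval during which the entire travelling
#' profile lies strictly inside the wave's running room, so that luminal
#' volume is conserved frame-to-frame.
#'
#' @param params a [synth_params()].
#' @return Data.frame with columns `t0`, `t1` (s); zero rows if the profile
#'   never fits entirely inside.
#' @export
propulsion_windows <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  neu <- params$neurogenic
  x_end <- params$length - neu$anal_zone
  trail <- neu$contraction_extent + neu$isometric_extent + neu$recovery_extent
  lo <- neu$origin + trail
  hi <- x_end - neu$dilation_extent
  if (hi <= lo) return(data.frame(t0 = numeric(0), t1 = numeric(0)))
  starts <- seq(neu$first_wave, params$duration, by = neu$repeat_interval)
  t0 <- starts + (lo - neu$origin) / neu$speed
  t1 <- starts + (hi - neu$origin) / neu$speed
  keep <- t1 <= params$duration
  data.frame(t0 = t0[keep], t1 = t1[keep])
}

#' Noise scales for a target derivative signal-to-noise ratio
#'
#' Additive white noise of SD `s` on a field sampled at step `dt` induces
#' central-difference derivative noise of SD `s / (sqrt(2) dt)`. Given the
#' noiseless dataset, this helper returns the per-field sample noise SDs that
#' set the ratio of the noiseless derivative scale (SD of the derivative
#' field) to the derivative noise SD to `snr`.
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @param snr target derivative signal-to-noise ratio.
#' @return List with `diameter_sd` (mm) and `pressure_sd` (mmHg).
#' @export
derivative_snr_noise <- function(truth, snr) {
  dt <- stmap_dt(truth$dmap)
  sig_dD <- stats::sd(central_diff_rows(truth$dmap$values, dt))
  sig_dP <- stats::sd(central_diff_rows(truth$pmap$values, dt))
  list(diameter_sd = sig_dD / snr * sqrt(2) * dt,
       pressure_sd = sig_dP / snr * sqrt(2) * dt)
}

#' Render video frames from a diameter map
#'
#' Draws one grayscale frame per time sample: a dark horizontal band centred
#' vertically on a white background, with per-column width equal to the
#' local diameter divided by the pixel scale; optional ruler tick marks are
#' drawn along the top edge at 1-cm positions. Used for round-trip testing of
#' the video extraction pipeline.
#'
#' @param dmap an [stmap()] of diameters (mm).
#' @param cal a [calibrate()] result.
#' @param height_px frame height in pixels; the largest diameter (plus the
#'   ruler margin) must fit.
#' @param include_ruler draw ruler ticks?
#' @return A [frame_stack()] with `fps = 1/dt`.
#' @export
render_frames <- function(dmap, cal, height_px = 200, include_ruler = TRUE) {
  stopifnot(inherits(dmap, "stmap"), inherits(cal, "calibration"))
  mmpx <- cal$mm_per_px
  span_cm <- dmap$positions[length(dmap$positions)] - dmap$positions[1]
  width_px <- floor(10 * span_cm / mmpx) + 1L
  margin <- if (include_ruler) 5L else 0L
  dmax <- max(dmap$values, na.rm = TRUE)
  if (dmax / mmpx + 2 * margin >= height_px)
    stop("diameter exceeding frame height at this calibration", call. = FALSE)
  col_pos <- dmap$positions[1] + (seq_len(width_px) - 1L) * mmpx / 10
  rows <- seq_len(height_px)
  center <- (height_px + 1) / 2
  tick_cm <- seq(ceiling(dmap$positions[1]), floor(col_pos[width_px]), by = 1)
  tick_cols <- unique(pmin(pmax(
    round((tick_cm - dmap$positions[1]) * 10 / mmpx) + 1L, 1L), width_px))
  frames <- vector("list", length(dmap$times))
  for (j in seq_along(dmap$times)) {
    dcol <- stats::approx(dmap$positions, dmap$values[, j], xout = col_pos,
                          rule = 2)$y
    w <- round(dcol / mmpx)
    w[is.na(w)] <- 0L
    start <- round(center - w / 2 + 0.5)
    frame <- matrix(1, height_px, width_px)
    band <- outer(rows, seq_len(width_px), function(r, cidx)
      w[cidx] > 0 & r >= start[cidx] & r <= start[cidx] + w[cidx] - 1L)
    frame[band] <- 0
    if (include_ruler && length(tick_cols)) frame[1:3, tick_cols] <- 0
    frames[[j]] <- frame
  }
  frame_stack(frames, fps = 1 / stmap_dt(dmap), source = "rendered")
}
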