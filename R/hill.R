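#' Shortening velocity along an orbit
#'
#' The velocity of circular-muscle shortening, positive while the diameter
#' decreases: `V(t) = -dD/dt`, computed with the same Gaussian-smoothed
#' central-difference estimator as the state decoder.
#'
#' @param orb an [orbit()] (>= 3 samples).
#' @param sigma_t temporal smoothing scale, s (default 0.5).
#' @return Numeric vector of velocities (mm/s), one per orbit sample.
#' @export
shortening_velocity <- function(orb, sigma_t = 0.5) {
  stopifnot(inherits(orb, "orbit"))
  if (nrow(orb) < 3) stop("need at least 3 samples", call. = FALSE)
  dt <- stats::median(diff(orb$time))
  x <- matrix(orb$diameter, nrow = 1)
  sm <- gauss_smooth_rows(x, sigma_t / dt)[1, ]
  n <- length(sm)
  d <- numeric(n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (orb$time[3:n] - orb$time[1:(n - 2)])
  d[1] <- (sm[2] - sm[1]) / (orb$time[2] - orb$time[1])
  d[n] <- (sm[n] - sm[n - 1]) / (orb$time[n] - orb$time[n - 1])
  -d
}

#' Pool pressure-velocity samples from contraction episodes
#'
#' Extracts the fixed-position orbit for each window, computes the shortening
#' velocity, and pools the (pressure, velocity) pairs. Contractions that start
#' isotonic and end isometric sweep the pressure range needed to constrain the
#' force-velocity curve. Lengthening samples (V < 0) are excluded by default.
#'
#' @param cmap a [composite_map()].
#' @param windows data.frame with columns `position` (cm), `t0`, `t1` (s).
#' @param sigma_t velocity smoothing scale, s.
#' @param include_lengthening keep samples with V < 0?
#' @return A data.frame of class `pv_samples` with columns `P` (mmHg) and
#'   `V` (mm/s), plus a `windows` attribute recording provenance.
#' @export
collect_pv_samples <- function(cmap, windows, sigma_t = 0.5,
                               include_lengthening = FALSE) {
  stopifnot(inherits(cmap, "composite_map"))
  pieces <- lapply(seq_len(nrow(windows)), function(i) {
    orb <- orbit_at(cmap, windows$position[i], windows$t0[i], windows$t1[i])
    data.frame(P = orb$pressure, V = shortening_velocity(orb, sigma_t))
  })
  out <- do.call(rbind, pieces)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  if (!include_lengthening) out <- out[out$V >= 0, , drop = FALSE]
  if (!nrow(out)) stop("no pressure-velocity samples pooled", call. = FALSE)
  attr(out, "windows") <- windows
  class(out) <- c("pv_samples", "data.frame")
  out
}

#' Fit Hill's force-velocity rectangular hyperbola
#'
#' Fits `(P + a)(V + b) = C` to pooled pressure-velocity samples. Expanding
#' the hyperbola gives the exact linearisation `P V = alpha + beta V + gamma P`
#' with `a = -beta`, `b = -gamma`, `C = alpha + a b`, solved by ordinary least
#' squares; the linear solution then seeds one Levenberg-Marquardt refinement
#' pass minimising `sum(V - (C/(P + a) - b))^2`, which guards against the
#' noise-induced bias of the linearisation. The refinement is kept only if it
#' does not worsen the velocity-space residual. The maximal isometric pressure
#' is `Pmax = C/b - a`; constants carry the pressure units of the input.
#'
#' @param samples a [collect_pv_samples()] table, or any data.frame with
#'   columns `P` and `V` (>= 3 non-collinear pairs, positive pressure span).
#' @return An object of class `hill_fit` with elements `a`, `b`, `C`, `Pmax`,
#'   `rms` (velocity-space residual RMS), `n`, `method`, and the samples.
#' @export
#' @examples
#' pts <- data.frame(P = c(0, 1, 3), V = c(3, 1, 0))  # (P+1)(V+1) = 4
#' fit <- fit_hill(pts)
#' coef(fit)
fit_hill <- function(samples) {
  P <- samples$P; V <- samples$V
  ok <- is.finite(P) & is.finite(V)
  P <- P[ok]; V <- V[ok]
  if (length(P) < 3) stop("need at least 3 pressure-velocity pairs", call. = FALSE)
  if (diff(range(P)) <= 0) stop("pressures must span a positive range", call. = FALSE)
  X <- cbind(1, V, P)
  if (qr(X)$rank < 3) stop("degenerate design: pairs are collinear", call. = FALSE)
  beta_hat <- qr.coef(qr(X), P * V)
  a <- -beta_hat[[2]]
  b <- -beta_hat[[3]]
  C <- beta_hat[[1]] + a * b
  rms_of <- function(par) {
    if (par[1] <= -min(P)) return(Inf)  # pole inside the data
    pred <- par[3] / (P + par[1]) - par[2]
    sqrt(mean((V - pred)^2))
  }
  par_lin <- c(a = a, b = b, C = C)
  rms_lin <- rms_of(par_lin)
  # The linearisation is exact on noiseless data but, with velocity noise on
  # both sides of the regression, can seed the refinement badly (even past the
  # hyperbola pole). Profile seeds: for a on a grid, (C, b) solve by OLS of
  # V on 1/(P + a); take the best-RMS seed.
  pscale <- diff(range(P))
  a_grid <- pscale * c(0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3, 10)
  a_grid <- a_grid[a_grid > -min(P)]
  profile_par <- function(av) {
    x <- 1 / (P + av)
    cf <- stats::lsfit(x, V)$coefficients
    c(a = av, b = -cf[[1]], C = cf[[2]])
  }
  cands <- lapply(a_grid, profile_par)
  if (is.finite(rms_lin)) cands <- c(list(par_lin), cands)
  rmss <- vapply(cands, rms_of, numeric(1))
  par <- cands[[which.min(rmss)]]
  rms_lin <- min(rmss)
  method <- if (identical(par, par_lin)) "linearised" else "profiled"
  par_lin <- par
  refined <- try(minpack.lm::nls.lm(
    par = par_lin,
    fn = function(p) {
      if (p[1] <= -min(P)) return(rep(1e6, length(V)))
      V - (p[3] / (P + p[1]) - p[2])
    },
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (!inherits(refined, "try-error") && all(is.finite(refined$par))) {
    rms_ref <- rms_of(refined$par)
    if (is.finite(rms_ref) && rms_ref <= rms_lin + 1e-12) {
      par <- refined$par
      method <- paste0(method, "+LM")
    }
  }
  a <- unname(par[1]); b <- unname(par[2]); C <- unname(par[3])
  if (b <= 0)
    warning("fitted b <= 0: non-physiological force-velocity fit")
  fit <- structure(list(a = a, b = b, C = C, Pmax = C / b - a,
                        rms = rms_of(par), n = length(P), method = method,
                        samples = data.frame(P = P, V = V)),
                   class = "hill_fit")
  fit
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill force-velocity fit: (P + a)(V + b) = C\n")
  cat(sprintf("  a    = %.6g mmHg  (%.6g kPa)\n", x$a, x$a * 0.133322))
  cat(sprintf("  b    = %.6g mm/s\n", x$b))
  cat(sprintf("  C    = %.6g mmHg.mm/s\n", x$C))
  cat(sprintf("  Pmax = %.6g mmHg  (%.6g kPa)\n", x$Pmax, x$Pmax * 0.133322))
  cat(sprintf("  residual RMS = %.4g mm/s over n = %d pairs [%s]\n",
              x$rms, x$n, x$method))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...)
  c(a = object$a, b = object$b, C = object$C, Pmax = object$Pmax)

#' @export
predict.hill_fit <- function(object, pressure = NULL, ...) {
  if (is.null(pressure)) pressure <- object$samples$P
  predict_velocity(object, pressure)
}

#' @export
residuals.hill_fit <- function(object, ...)
  object$samples$V - predict_velocity(object, object$samples$P)

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$samples$P, x$samples$V, xlab = "Pressure (mmHg)",
                 ylab = "Shortening velocity (mm/s)",
                 main = "Hill force-velocity relation", ...)
  pp <- seq(max(0, min(x$samples$P)), max(x$samples$P, x$Pmax), length.out = 200)
  pp <- pp[pp > -x$a]
  graphics::lines(pp, predict_velocity(x, pp), col = "red", lwd = 2)
  invisible(x)
}

#' Predicted shortening velocity at a given pressure
#'
#' `V = C/(P + a) - b`, defined for `P > -a`. Velocity is strictly decreasing
#' and convex in pressure whenever `a, b > 0`, reaching zero at `Pmax`.
#'
#' @param fit a [fit_hill()] result.
#' @param pressure pressures, same units as the fit (must exceed `-a`).
#' @return Velocities, mm/s.
#' @export
predict_velocity <- function(fit, pressure) {
  stopifnot(inherits(fit, "hill_fit"))
  if (any(pressure <= -fit$a))
    stop("pressure must exceed -a (hyperbola pole)", call. = FALSE)
  fit$C / (pressure + fit$a) - fit$b
}

#' Sample a noiseless Hill hyperbola
#'
#' Convenience generator for validation: given constants `a`, `b` and `Pmax`,
#' computes `C = (Pmax + a) b` and returns `n` pairs at pressures evenly
#' spaced over `[0, Pmax]`.
#'
#' @param a,b,Pmax hyperbola constants (pressure, mm/s, pressure).
#' @param n number of pairs.
#' @return Data.frame with columns `P`, `V`.
#' @export
hill_curve_samples <- function(a, b, Pmax, n = 20) {
  C <- (Pmax + a) * b
  P <- seq(0, Pmax, length.out = n)
  data.frame(P = P, V = C / (P + a) - b)
}
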