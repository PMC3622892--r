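#' Temporal derivative fields of a composite map
#'
#' Per position, the diameter and pressure traces are smoothed in time with a
#' Gaussian kernel of scale `sigma_t` and differentiated by central
#' differences (one-sided at the boundaries). With `sigma_t = 0` the estimator
#' reduces to plain central differences, which are exact on linear signals.
#'
#' @param cmap a [composite_map()].
#' @param sigma_t temporal smoothing scale, s (>= 0; default 0.5).
#' @return List with matrices `dD` (mm/s) and `dP` (mmHg/s) on the map grid.
#' @export
estimate_derivatives <- function(cmap, sigma_t = 0.5) {
  stopifnot(inherits(cmap, "composite_map"))
  if (sigma_t < 0) stop("sigma_t must be >= 0", call. = FALSE)
  dt <- stmap_dt(cmap$diameter)
  if (ncol(cmap$diameter$values) < 3)
    stop("need at least 3 time samples for derivative estimation", call. = FALSE)
  sig <- sigma_t / dt
  list(dD = central_diff_rows(gauss_smooth_rows(cmap$diameter$values, sig), dt),
       dP = central_diff_rows(gauss_smooth_rows(cmap$pressure$values, sig), dt))
}

#' Gaussian emission model for mechanical-state decoding
#'
#' The time derivatives of diameter and pressure are modelled as Gaussians
#' whose pooled robust scales (1.4826 x MAD) set the per-state emission
#' widths; a recorded sample identifies contraction versus relaxation by the
#' Gaussian tail it falls on. The boundary between occlusion and distension is
#' the equal-posterior point of a two-component Gaussian mixture fitted to the
#' pooled diameters (EM, 100 iterations, components initialised at the
#' 10th/90th percentiles); when the components overlap (means closer than one
#' pooled SD) the boundary falls back to the data midrange. The smaller
#' component SD sets the softness of the occlusion evidence.
#'
#' @param cmap a [composite_map()] with at least 100 samples.
#' @param sigma_t derivative smoothing scale, s (default 0.5).
#' @param kappa dimensionless offset of the nonzero-change state means, in
#'   pooled-SD units (default 2).
#' @param default_lumen lumen condition assumed when the diameter field is
#'   degenerate and carries no occlusion information.
#' @return An object of class `emission_model`: pooled scales `sigma_dP`
#'   (mmHg/s) and `sigma_dD` (mm/s), occlusion boundary `theta` (mm),
#'   `softness` (mm), `kappa`, and the `sigma_t` used.
#' @export
fit_emission_model <- function(cmap, sigma_t = 0.5, kappa = 2,
                               default_lumen = c("distended", "occluded")) {
  stopifnot(inherits(cmap, "composite_map"))
  default_lumen <- match.arg(default_lumen)
  D <- cmap$diameter$values
  if (sum(!is.na(D)) < 100) stop("need at least 100 samples", call. = FALSE)
  der <- estimate_derivatives(cmap, sigma_t)
  if (all(is.na(der$dD)) || all(is.na(der$dP)))
    stop("all-missing derivative field", call. = FALSE)
  sigma_dD <- robust_scale(as.vector(der$dD))
  sigma_dP <- robust_scale(as.vector(der$dP))

  mix <- fit_diameter_mixture(as.vector(D))
  structure(list(sigma_dP = sigma_dP, sigma_dD = sigma_dD,
                 theta = mix$theta, softness = mix$softness,
                 kappa = kappa, sigma_t = sigma_t,
                 default_lumen = default_lumen, mixture = mix$fit),
            class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat("<emission_model>\n")
  cat(sprintf("  sigma_dP = %.4g mmHg/s, sigma_dD = %.4g mm/s, kappa = %.3g\n",
              x$sigma_dP, x$sigma_dD, x$kappa))
  cat(sprintf("  occlusion boundary theta = %.4g mm (softness %.4g mm)\n",
              x$theta, x$softness))
  invisible(x)
}

# Two-component 1-D Gaussian mixture on pooled diameters; returns the
# equal-posterior boundary and the softness (min component SD).
fit_diameter_mixture <- function(d, iters = 100L) {
  d <- d[!is.na(d)]
  pooled_sd <- stats::sd(d)
  rng <- range(d)
  midrange <- mean(rng)
  if (!is.finite(pooled_sd) || pooled_sd < 1e-9)  # constant field
    return(list(theta = midrange, softness = 1e-3, fit = NULL))
  q <- stats::quantile(d, c(0.1, 0.9), names = FALSE)
  # k-means-style hard assignment to the two percentile seeds
  assign2 <- abs(d - q[1]) > abs(d - q[2])
  mu <- c(mean(d[!assign2]), mean(d[assign2]))
  s2 <- c(stats::var(d[!assign2]), stats::var(d[assign2]))
  s2[!is.finite(s2) | s2 < 1e-6] <- 1e-6
  pi1 <- mean(!assign2)
  w <- c(pi1, 1 - pi1)
  for (it in seq_len(iters)) {
    l1 <- log(w[1]) + stats::dnorm(d, mu[1], sqrt(s2[1]), log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(d, mu[2], sqrt(s2[2]), log = TRUE)
    m <- pmax(l1, l2)
    r1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
    n1 <- sum(r1); n2 <- length(d) - n1
    if (n1 < 1e-9 || n2 < 1e-9) break
    mu <- c(sum(r1 * d) / n1, sum((1 - r1) * d) / n2)
    s2 <- c(sum(r1 * (d - mu[1])^2) / n1, sum((1 - r1) * (d - mu[2])^2) / n2)
    s2 <- pmax(s2, 1e-6)
    w <- c(n1, n2) / length(d)
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); s2 <- rev(s2); w <- rev(w) }
  softness <- max(sqrt(min(s2)), 1e-3)
  fit <- list(mean = mu, sd = sqrt(s2), weight = w)
  if (abs(diff(mu)) < pooled_sd)  # overlapping components: midrange fallback
    return(list(theta = midrange, softness = softness, fit = fit))
  theta <- equal_posterior_boundary(mu, sqrt(s2), w, rng)
  list(theta = theta, softness = softness, fit = fit)
}

# Solve w1 N(x; mu1, s1) = w2 N(x; mu2, s2) for x; prefer a root between the
# component means, else the data midrange.
equal_posterior_boundary <- function(mu, s, w, rng) {
  A <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
  B <- mu[1] / s[1]^2 - mu[2] / s[2]^2
  C <- mu[2]^2 / (2 * s[2]^2) - mu[1]^2 / (2 * s[1]^2) +
    log(w[1] / w[2]) + log(s[2] / s[1])
  if (abs(A) < 1e-15) {
    if (abs(B) < 1e-15) return(mean(rng))
    x <- -C / B
    return(if (x > min(mu) && x < max(mu)) x else mean(rng))
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(mean(rng))
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  inside <- roots[roots > min(mu) & roots < max(mu)]
  if (length(inside)) inside[which.min(abs(inside - mean(mu)))] else mean(rng)
}

# Per-state emission parameters: means of the derivative Gaussians and the
# lumen flag used by the occlusion evidence (NA = lumen-indifferent).
state_emission_table <- function(model) {
  alph <- mechanical_states()
  data.frame(code = alph$code,
             muP = alph$sP * model$kappa * model$sigma_dP,
             muD = alph$sD * model$kappa * model$sigma_dD,
             lumen = alph$lumen,
             sD = alph$sD,
             stringsAsFactors = FALSE)
}

#' Decode a composite map into a mechanical-state map
#'
#' Viterbi decoding of the 12-state alphabet, run independently at each
#' position over time. The emission log-density of state s at a sample is the
#' sum of Gaussian log-densities of the observed pressure and diameter
#' derivatives about state-specific means (0 for "no change" states,
#' +/- kappa pooled-SDs for moving states) plus, for the six steady-diameter
#' states, soft occlusion evidence `log sigmoid(-/+ (D - theta)/softness)`.
#' Transitions place probability `p_stay` on remaining in a state and spread
#' the rest uniformly over the other 11; the initial distribution is uniform.
#'
#' @param cmap a [composite_map()].
#' @param model an [fit_emission_model()] result.
#' @param p_stay self-transition probability, strictly between 0 and 1
#'   (default 0.95).
#' @return An object of class `state_map`: integer code matrix `codes` on the
#'   map grid plus the `positions`/`times` axes.
#' @export
decode_states <- function(cmap, model, p_stay = 0.95) {
  stopifnot(inherits(cmap, "composite_map"), inherits(model, "emission_model"))
  if (p_stay <= 0 || p_stay >= 1) stop("p_stay must be strictly between 0 and 1", call. = FALSE)
  if (model$sigma_dP <= 0 || model$sigma_dD <= 0 || model$softness <= 0)
    stop("model scales must be positive", call. = FALSE)
  der <- estimate_derivatives(cmap, model$sigma_t)
  E <- emission_loglik(cmap$diameter$values, der$dD, der$dP, model)
  codes <- viterbi_grid(E, p_stay)
  state_map(codes, cmap$diameter$positions, cmap$diameter$times)
}

# Emission log-likelihood array [npos, ntime, 12].
emission_loglik <- function(D, dD, dP, model) {
  tab <- state_emission_table(model)
  np <- nrow(D); nt <- ncol(D)
  z <- (D - model$theta) / model$softness
  if (all(abs(z) < 1e-9, na.rm = TRUE))  # degenerate diameter field
    z[] <- if (model$default_lumen == "distended") 1 else -1
  occ_term <- log_sigmoid(-z)   # evidence for occluded lumen
  dis_term <- log_sigmoid(z)    # evidence for distended lumen
  E <- array(0, dim = c(np, nt, 12L))
  for (k in seq_len(12L)) {
    e <- stats::dnorm(dP, tab$muP[k], model$sigma_dP, log = TRUE) +
         stats::dnorm(dD, tab$muD[k], model$sigma_dD, log = TRUE)
    if (tab$sD[k] == 0L) {
      e <- e + if (tab$lumen[k] == "occluded") occ_term else dis_term
    }
    E[, , k] <- e
  }
  E[is.na(E)] <- 0  # missing observations are uninformative
  E
}

# Vectorised-over-positions Viterbi for the uniform-off-diagonal transition
# matrix; returns an integer matrix of 0-based state codes.
viterbi_grid <- function(E, p_stay) {
  np <- dim(E)[1]; nt <- dim(E)[2]; ns <- dim(E)[3]
  log_stay <- log(p_stay)
  log_move <- log((1 - p_stay) / (ns - 1))
  delta <- matrix(log(1 / ns), np, ns) + E[, 1, ]
  if (np == 1) delta <- matrix(delta, 1, ns)
  psi <- array(0L, dim = c(np, nt, ns))
  for (t in seq_len(nt)[-1]) {
    # best predecessor: either stay (diagonal) or the overall best other state
    best1 <- max.col(delta, ties.method = "first")
    best1val <- delta[cbind(seq_len(np), best1)]
    tmp <- delta
    tmp[cbind(seq_len(np), best1)] <- -Inf
    best2 <- max.col(tmp, ties.method = "first")
    best2val <- tmp[cbind(seq_len(np), best2)]
    newdelta <- matrix(0, np, ns)
    for (s in seq_len(ns)) {
      move_prev <- ifelse(best1 != s, best1, best2)
      move_val <- ifelse(best1 != s, best1val, best2val) + log_move
      stay_val <- delta[, s] + log_stay
      take_stay <- stay_val >= move_val
      prev <- ifelse(take_stay, s, move_prev)
      newdelta[, s] <- ifelse(take_stay, stay_val, move_val) + E[, t, s]
      psi[, t, s] <- prev
    }
    delta <- newdelta
  }
  codes <- matrix(0L, np, nt)
  codes[, nt] <- max.col(delta, ties.method = "first")
  for (t in rev(seq_len(nt - 1)))
    codes[, t] <- psi[cbind(seq_len(np), t + 1L, codes[, t + 1L])]
  codes - 1L
}

#' Spatiotemporal maps of mechanical-state labels
#'
#' @param codes integer matrix of state codes 0-11 on the composite grid.
#' @param positions,times the grid axes (cm, s).
#' @return An object of class `state_map`.
#' @export
state_map <- function(codes, positions, times) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (any(!is.na(codes) & (codes < 0L | codes > 11L)))
    stop("state codes must be in 0-11", call. = FALSE)
  if (nrow(codes) != length(positions) || ncol(codes) != length(times))
    stop("codes shape must match the grid", call. = FALSE)
  structure(list(codes = codes, positions = positions, times = times),
            class = "state_map")
}

#' @export
print.state_map <- function(x, ...) {
  cat(sprintf("<state_map> %d positions x %d times\n",
              length(x$positions), length(x$times)))
  fr <- state_fractions(x)
  top <- utils::head(fr[order(-fr$fraction), ], 3)
  cat("  top states:",
      paste(sprintf("%s %.1f%%", top$label, 100 * top$fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname state_map
#' @param smap a `state_map`.
#' @param path output path; the integer-code matrix is written in the map
#'   exchange format, with a sidecar JSON legend `<path>.legend.json` mapping
#'   codes to labels and display colours.
#' @export
write_state_map <- function(smap, path) {
  m <- stmap(smap$codes, smap$positions, smap$times, quantity = "diameter_mm")
  m$values <- matrix(as.double(smap$codes), nrow(smap$codes))
  write_stmap(m, path)
  alph <- mechanical_states()
  legend <- lapply(seq_len(nrow(alph)), function(i)
    list(label = alph$label[i], color = unname(state_palette()[alph$label[i]])))
  names(legend) <- as.character(alph$code)
  jsonlite::write_json(legend, paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Cluster the 12-state map into active excitation and inhibition
#'
#' Isometric, auxotonic and isotonic contractions are clustered as
#' `ACTIVE_CONTRACTION` (regions where the muscle is excited); auxotonic and
#' isotonic relaxations as `ACTIVE_RELAXATION` (regions where it is
#' inhibited). All seven remaining states -- including isometric relaxation,
#' which merely reflects excitation wearing off in an occluded segment -- are
#' `OTHER`.
#'
#' @param smap a [state_map()].
#' @return An object of class `clustered_map` with a character matrix
#'   `classes` over `{ACTIVE_CONTRACTION, ACTIVE_RELAXATION, OTHER}`.
#' @export
cluster_states <- function(smap) {
  stopifnot(inherits(smap, "state_map"))
  lab <- state_label(smap$codes)
  cls <- ifelse(lab %in% active_contraction_states(), "ACTIVE_CONTRACTION",
         ifelse(lab %in% active_relaxation_states(), "ACTIVE_RELAXATION", "OTHER"))
  classes <- matrix(cls, nrow(smap$codes), ncol(smap$codes))
  structure(list(classes = classes, positions = smap$positions,
                 times = smap$times),
            class = "clustered_map")
}

#' Per-state sample fractions of a state map
#'
#' @param smap a [state_map()].
#' @return Data.frame with `code`, `label`, `count`, `fraction` for all 12
#'   states; fractions sum to 1.
#' @export
state_fractions <- function(smap) {
  stopifnot(inherits(smap, "state_map"))
  alph <- mechanical_states()
  counts <- tabulate(smap$codes + 1L, nbins = 12L)
  data.frame(code = alph$code, label = alph$label, count = counts,
             fraction = counts / sum(counts))
}
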