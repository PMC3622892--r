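# Internal numerical helpers shared across modules.

# Bilinear interpolation of a position x time matrix onto arbitrary new axes.
# Stencil cells that are actually used must be non-missing; a weight of zero
# collapses the stencil so that on-grid queries touch only one cell.
interp_bilinear <- function(values, positions, times, newpos, newtimes) {
  if (any(newpos < positions[1] - 1e-9) || any(newpos > positions[length(positions)] + 1e-9))
    stop("target positions outside source extent", call. = FALSE)
  if (any(newtimes < times[1] - 1e-9) || any(newtimes > times[length(times)] + 1e-9))
    stop("target times outside source extent", call. = FALSE)
  newpos <- pmin(pmax(newpos, positions[1]), positions[length(positions)])
  newtimes <- pmin(pmax(newtimes, times[1]), times[length(times)])

  bracket <- function(axis, q) {
    i0 <- findInterval(q, axis, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1L), length(axis) - 1L)
    if (length(axis) == 1L) return(list(i0 = rep(1L, length(q)), i1 = rep(1L, length(q)), w = rep(0, length(q))))
    w <- (q - axis[i0]) / (axis[i0 + 1L] - axis[i0])
    i1 <- i0 + 1L
    snap0 <- w < 1e-12
    snap1 <- w > 1 - 1e-12
    i1[snap0] <- i0[snap0]; w[snap0] <- 0
    i0[snap1] <- i1[snap1]; w[snap1] <- 0
    list(i0 = i0, i1 = i1, w = w)
  }
  bp <- bracket(positions, newpos)
  bt <- bracket(times, newtimes)

  v00 <- values[bp$i0, bt$i0, drop = FALSE]
  v10 <- values[bp$i1, bt$i0, drop = FALSE]
  v01 <- values[bp$i0, bt$i1, drop = FALSE]
  v11 <- values[bp$i1, bt$i1, drop = FALSE]
  wp <- bp$w; wt <- bt$w
  a <- (1 - wp) * v00 + wp * v10           # recycles wp down rows
  b <- (1 - wp) * v01 + wp * v11
  out <- sweep(a, 2, 1 - wt, "*") + sweep(b, 2, wt, "*")
  dimnames(out) <- NULL
  out
}

# Gaussian smoothing along rows of a matrix (time axis = columns).
# sigma in samples; sigma <= 0 returns the input. Kernel truncated at 4 sigma
# and renormalised; edges use the renormalised partial kernel.
gauss_smooth_rows <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  n <- ncol(x)
  out <- x
  for (i in seq_len(nrow(x))) {
    row <- x[i, ]
    if (all(is.na(row))) next
    # pad by edge replication so the smoother is mass-preserving at the ends
    padded <- c(rep(row[1], half), row, rep(row[n], half))
    sm <- stats::filter(padded, k, sides = 2)
    out[i, ] <- sm[(half + 1):(half + n)]
  }
  out
}

# Central differences along columns-of-time with one-sided ends; dt scalar.
central_diff_rows <- function(x, dt) {
  n <- ncol(x)
  if (n < 3) stop("need at least 3 time samples for derivative estimation", call. = FALSE)
  d <- x
  d[, 2:(n - 1)] <- (x[, 3:n] - x[, 1:(n - 2)]) / (2 * dt)
  d[, 1] <- (x[, 2] - x[, 1]) / dt
  d[, n] <- (x[, n] - x[, n - 1]) / dt
  d
}

# Numerically stable log(1/(1+exp(-z))).
log_sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0 & !is.na(z)
  out[pos] <- -log1p(exp(-z[pos]))
  out[!pos & !is.na(z)] <- z[!pos & !is.na(z)] - log1p(exp(z[!pos & !is.na(z)]))
  out[is.na(z)] <- NA_real_
  out
}

# Length of the largest contiguous run of TRUE.
largest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

# Otsu's between-class-variance maximising threshold on intensities in [0, 1].
otsu_threshold <- function(x, levels = 256L) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("cannot threshold an all-missing frame", call. = FALSE)
  h <- tabulate(pmin(pmax(floor(x * levels) + 1L, 1L), levels), nbins = levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, levels)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(bcv)] + 0.5 / levels  # boundary just above the chosen bin
}

# Robust scale: 1.4826 * median absolute deviation about the median.
robust_scale <- function(x, floor_sd = 1e-3) {
  s <- stats::mad(x, na.rm = TRUE)
  max(s, floor_sd)
}
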