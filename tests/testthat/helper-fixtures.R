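# Shared fixture builders: everything is generated in code at test time.

# small composite map with constant fields
const_cmap <- function(d = 5, p = 10, np = 4, nt = 50, dt = 0.25) {
  pos <- seq(0, np - 1)
  tim <- seq(0, by = dt, length.out = nt)
  composite_map(
    stmap(matrix(d, np, nt), pos, tim, "diameter_mm"),
    stmap(matrix(p, np, nt), pos, tim, "pressure_mmHg"))
}

# composite map from explicit per-time traces, replicated over positions
trace_cmap <- function(dtrace, ptrace, dt = 0.25, np = 1) {
  nt <- length(dtrace)
  pos <- seq(0, np - 1)
  tim <- seq(0, by = dt, length.out = nt)
  composite_map(
    stmap(matrix(dtrace, np, nt, byrow = TRUE), pos, tim, "diameter_mm"),
    stmap(matrix(ptrace, np, nt, byrow = TRUE), pos, tim, "pressure_mmHg"))
}

# mask of samples whose ground-truth label is constant within +-hw samples
nontransition_mask <- function(codes, hw = 6L) {
  np <- nrow(codes); nt <- ncol(codes)
  m <- matrix(TRUE, np, nt)
  for (k in seq_len(hw)) {
    eq <- codes[, (1 + k):nt] == codes[, 1:(nt - k)]
    m[, (1 + k):nt] <- m[, (1 + k):nt] & eq
    m[, 1:(nt - k)] <- m[, 1:(nt - k)] & eq
  }
  m
}

# synthetic three-phase orbit mimicking a peristaltic event: isotonic
# relaxation -> auxotonic contraction -> isometric relaxation
three_phase_orbit <- function() {
  D <- c(seq(6, 10, length.out = 20), seq(9.66, 3.2, length.out = 20),
         rep(3.2, 20))
  P <- c(rep(2, 20), seq(3.2, 24.8, length.out = 20),
         seq(23.8, 4.8, length.out = 20))
  orbit(0:59, D, P)
}

# four-phase orbit: isotonic relaxation -> isotonic contraction ->
# isometric contraction -> isometric relaxation
four_phase_orbit <- function() {
  D <- c(seq(6, 10.8, length.out = 20), seq(10.4, 3.2, length.out = 20),
         rep(3.2, 40))
  P <- c(rep(2, 40), seq(3.5, 32, length.out = 20),
         seq(30.8, 6, length.out = 20))
  orbit(0:79, D, P)
}
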