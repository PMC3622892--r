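#' The twelve mechanical states of intestinal circular muscle
#'
#' A segment of gut wall, observed through paired diameter and pressure
#' signals, can at any instant be in exactly one of twelve mechanical states.
#' The state is determined by the sign of the pressure change, the sign of the
#' diameter change, and -- where both diameter and pressure are steady or only
#' pressure moves -- whether the lumen is occluded (collapsed onto the
#' catheter) or distended. Active states (isometric, auxotonic and isotonic
#' contractions; auxotonic and isotonic relaxations) reflect excitation or
#' inhibition of the muscle; the remaining states are passive consequences of
#' content movement or quiescence.
#'
#' `mechanical_states()` returns the full alphabet: integer code (0-11), label,
#' the pressure/diameter sign pattern and the lumen condition (`NA` where the
#' state applies in both lumen conditions).
#'
#' @return A data.frame with columns `code`, `label`, `sP`, `sD`, `lumen`.
#' @export
#' @examples
#' mechanical_states()
mechanical_states <- function() {
  data.frame(
    code  = 0:11,
    label = c("ISOMETRIC_CONTRACTION", "ISOMETRIC_RELAXATION",
              "AUXOTONIC_CONTRACTION", "AUXOTONIC_RELAXATION",
              "ISOTONIC_CONTRACTION", "ISOTONIC_RELAXATION",
              "PASSIVE_DILATION", "PASSIVE_SHORTENING",
              "PASSIVE_ISOMETRIC_PRESSURE_INCREASE",
              "PASSIVE_ISOMETRIC_PRESSURE_DECREASE",
              "OCCLUDED_QUIESCENCE", "DISTENDED_QUIESCENCE"),
    sP    = c(+1L, -1L, +1L, -1L, 0L, 0L, +1L, -1L, +1L, -1L, 0L, 0L),
    sD    = c(0L, 0L, -1L, +1L, -1L, +1L, +1L, -1L, 0L, 0L, 0L, 0L),
    lumen = c("occluded", "occluded", NA, NA, NA, NA, NA, NA,
              "distended", "distended", "occluded", "distended"),
    stringsAsFactors = FALSE
  )
}

#' Map sign patterns to a mechanical state
#'
#' Total, deterministic lookup from the sign of the pressure change (`sP`), the
#' sign of the diameter change (`sD`) and the lumen condition to the mechanical
#' state label. The lumen condition only disambiguates the six states in which
#' diameter is steady; for moving-diameter states it is ignored.
#'
#' @param sP integer vector in {-1, 0, +1}: sign of the pressure change.
#' @param sD integer vector in {-1, 0, +1}: sign of the diameter change.
#' @param lumen character vector, `"occluded"` or `"distended"`.
#' @return Character vector of state labels (see [mechanical_states()]).
#' @export
#' @examples
#' state_from_signs(+1, 0, "occluded")   # ISOMETRIC_CONTRACTION
#' state_from_signs(-1, +1, "distended") # AUXOTONIC_RELAXATION
state_from_signs <- function(sP, sD, lumen) {
  n <- max(length(sP), length(sD), length(lumen))
  sP <- rep_len(as.integer(sP), n)
  sD <- rep_len(as.integer(sD), n)
  lumen <- rep_len(lumen, n)
  if (any(!sP %in% c(-1L, 0L, 1L)) || any(!sD %in% c(-1L, 0L, 1L)))
    stop("signs must be -1, 0 or +1", call. = FALSE)
  if (any(!lumen %in% c("occluded", "distended")))
    stop("lumen must be 'occluded' or 'distended'", call. = FALSE)
  occ <- lumen == "occluded"
  out <- character(n)
  out[sP == +1 & sD == 0 & occ]  <- "ISOMETRIC_CONTRACTION"
  out[sP == -1 & sD == 0 & occ]  <- "ISOMETRIC_RELAXATION"
  out[sP == +1 & sD == -1]       <- "AUXOTONIC_CONTRACTION"
  out[sP == -1 & sD == +1]       <- "AUXOTONIC_RELAXATION"
  out[sP == 0 & sD == -1]        <- "ISOTONIC_CONTRACTION"
  out[sP == 0 & sD == +1]        <- "ISOTONIC_RELAXATION"
  out[sP == +1 & sD == +1]       <- "PASSIVE_DILATION"
  out[sP == -1 & sD == -1]       <- "PASSIVE_SHORTENING"
  out[sP == +1 & sD == 0 & !occ] <- "PASSIVE_ISOMETRIC_PRESSURE_INCREASE"
  out[sP == -1 & sD == 0 & !occ] <- "PASSIVE_ISOMETRIC_PRESSURE_DECREASE"
  out[sP == 0 & sD == 0 & occ]   <- "OCCLUDED_QUIESCENCE"
  out[sP == 0 & sD == 0 & !occ]  <- "DISTENDED_QUIESCENCE"
  out
}

#' @rdname state_from_signs
#' @param label character vector of state labels.
#' @return `state_code()`: the integer codes (0-11) for the given labels.
#' @export
state_code <- function(label) {
  alph <- mechanical_states()
  idx <- match(label, alph$label)
  if (anyNA(idx) && !anyNA(label)) stop("unknown state label", call. = FALSE)
  alph$code[idx]
}

#' @rdname state_from_signs
#' @param code integer vector of state codes (0-11).
#' @return `state_label()`: the labels for the given codes.
#' @export
state_label <- function(code) {
  alph <- mechanical_states()
  idx <- match(as.integer(code), alph$code)
  if (anyNA(idx) && !anyNA(code)) stop("state code out of range 0-11", call. = FALSE)
  alph$label[idx]
}

# Cluster membership used by cluster_states(): contraction cluster in red,
# relaxation cluster in blue, everything else (including isometric relaxation)
# is "OTHER".
active_contraction_states <- function()
  c("ISOMETRIC_CONTRACTION", "AUXOTONIC_CONTRACTION", "ISOTONIC_CONTRACTION")
active_relaxation_states <- function()
  c("AUXOTONIC_RELAXATION", "ISOTONIC_RELAXATION")

#' Display palette for state maps
#'
#' Named colours for the twelve mechanical states: active contractions in
#' reds/oranges, active relaxations in blues, passive states in greys/purples
#' and quiescence in greens.
#'
#' @return Named character vector of colours, in state-code order.
#' @export
state_palette <- function() {
  c(ISOMETRIC_CONTRACTION = "#d7191c",
    ISOMETRIC_RELAXATION = "#7b3294",
    AUXOTONIC_CONTRACTION = "#f46d43",
    AUXOTONIC_RELAXATION = "#2c7bb6",
    ISOTONIC_CONTRACTION = "#fdae61",
    ISOTONIC_RELAXATION = "#abd9e9",
    PASSIVE_DILATION = "#bcbddc",
    PASSIVE_SHORTENING = "#969696",
    PASSIVE_ISOMETRIC_PRESSURE_INCREASE = "#d9d9d9",
    PASSIVE_ISOMETRIC_PRESSURE_DECREASE = "#737373",
    OCCLUDED_QUIESCENCE = "#1a9641",
    DISTENDED_QUIESCENCE = "#a6d96a")
}
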