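#' Frame stacks of gut-preparation video
#'
#' An ordered list of equally sized 2-D grayscale frames (intensities in
#' [0, 1]) with a frame rate. The preparation is assumed straight, lying along
#' one image axis (columns by default).
#'
#' @param frames list of numeric matrices, all with equal dimensions.
#' @param fps frames per second (> 0).
#' @param source provenance tag (e.g. the frame directory).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps, source = "") {
  if (!length(frames)) stop("empty frame stack", call. = FALSE)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  d <- dim(frames[[1]])
  if (length(d) != 2) stop("frames must be 2-D grayscale matrices", call. = FALSE)
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) stop("all frames must have equal dimensions", call. = FALSE)
  structure(list(frames = frames, fps = fps, source = source),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px at %g fps\n",
              length(x$frames), d[1], d[2], x$fps))
  invisible(x)
}

#' @rdname frame_stack
#' @param dir directory of PNG or TIFF frames; lexicographic filename order is
#'   time order. Colour frames are converted to grayscale by channel
#'   averaging.
#' @export
read_frame_stack <- function(dir, fps) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no PNG or TIFF frames found in ", dir, call. = FALSE)
  read_one <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
    img
  }
  frame_stack(lapply(files, read_one), fps, source = dir)
}

#' @rdname frame_stack
#' @param stack a `frame_stack`.
#' @export
write_frame_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    f <- pmin(pmax(stack$frames[[i]], 0), 1)
    png::writePNG(f, file.path(dir, sprintf("frame_%05d.png", i - 1L)))
  }
  invisible(dir)
}

#' Pixel calibration from ruler marks
#'
#' A ruler with marks at known spacing placed next to the preparation fixes
#' the pixel scale: `mm_per_px = 10 * mark_spacing_cm / median inter-mark
#' pixel gap`. The median gap is robust to an occasional mislocated mark.
#'
#' @param mark_px_positions pixel coordinates of at least two ruler marks.
#' @param mark_spacing_cm physical spacing between adjacent marks (cm,
#'   default 1).
#' @param gut_axis image axis along which the preparation lies: 2 = columns
#'   (default), 1 = rows.
#' @return An object of class `calibration` with `mm_per_px` and `gut_axis`.
#' @export
#' @examples
#' calibrate(c(0, 100, 200))$mm_per_px  # 0.1 mm/px
calibrate <- function(mark_px_positions, mark_spacing_cm = 1, gut_axis = 2L) {
  if (length(mark_px_positions) < 2)
    stop("calibration error: need at least 2 ruler marks", call. = FALSE)
  gaps <- diff(sort(mark_px_positions))
  if (any(gaps <= 0)) stop("calibration error: coincident ruler marks", call. = FALSE)
  structure(list(mm_per_px = 10 * mark_spacing_cm / stats::median(gaps),
                 gut_axis = as.integer(gut_axis)),
            class = "calibration")
}

#' Per-position diameter profile of a single frame
#'
#' The tissue appears dark on a light background (set `invert = TRUE`
#' otherwise). For every image column perpendicular to the gut axis the
#' diameter is the largest contiguous run of tissue pixels times the pixel
#' scale; the largest-run rule rejects detached shadows and ruler ticks.
#' Columns with no tissue pixel are missing, as are the 2 columns nearest
#' each frame border (boundary artifacts).
#'
#' @param frame numeric matrix, intensities in [0, 1] (values above 1 are
#'   rescaled by 255).
#' @param cal a [calibrate()] result.
#' @param threshold intensity threshold, or `"auto"` for an Otsu-style
#'   bimodal split of the frame histogram.
#' @param invert tissue lighter than background?
#' @return Numeric vector of diameters (mm), one per column along the gut
#'   axis; `NA` where no tissue is found.
#' @export
extract_diameter_profile <- function(frame, cal, threshold = "auto",
                                     invert = FALSE) {
  stopifnot(inherits(cal, "calibration"))
  if (max(frame, na.rm = TRUE) > 1) frame <- frame / 255
  if (cal$gut_axis == 1L) frame <- t(frame)
  thr <- if (identical(threshold, "auto")) otsu_threshold(frame) else threshold
  tissue <- if (invert) frame > thr else frame < thr
  tissue[is.na(tissue)] <- FALSE
  runs <- apply(tissue, 2, largest_run)
  d <- runs * cal$mm_per_px
  d[runs == 0] <- NA_real_
  nc <- length(d)
  edge <- 2L
  if (nc > 2 * edge) d[c(seq_len(edge), (nc - edge + 1):nc)] <- NA_real_
  d
}

#' Build a diameter map (DMap) from a video frame stack
#'
#' Extracts the per-column diameter profile of every frame and assembles a
#' spatiotemporal diameter map: positions are column coordinates converted to
#' cm through the calibration, times are frame index / fps.
#'
#' @param stack a [frame_stack()].
#' @param cal a [calibrate()] result.
#' @param threshold see [extract_diameter_profile()].
#' @param invert see [extract_diameter_profile()].
#' @return An [stmap()] with quantity `diameter_mm`.
#' @export
build_dmap <- function(stack, cal, threshold = "auto", invert = FALSE) {
  stopifnot(inherits(stack, "frame_stack"), inherits(cal, "calibration"))
  profiles <- vapply(stack$frames,
                     function(f) extract_diameter_profile(f, cal, threshold, invert),
                     numeric(if (cal$gut_axis == 1L) nrow(stack$frames[[1]])
                             else ncol(stack$frames[[1]])))
  np <- nrow(profiles)
  positions <- (seq_len(np) - 1L) * cal$mm_per_px / 10  # cm
  times <- (seq_along(stack$frames) - 1L) / stack$fps
  stmap(profiles, positions, times, quantity = "diameter_mm",
        source = stack$source)
}

#' Detect LED synchronisation flashes in a video
#'
#' The mean intensity inside a fixed region of interest is tracked across
#' frames; a sync event is recorded at every rising edge (intensity crossing
#' the threshold upward). A frame that starts already lit produces no event.
#'
#' @param stack a [frame_stack()].
#' @param roi integer vector `c(row0, row1, col0, col1)` (inclusive, within
#'   the frame bounds).
#' @param on_threshold intensity above which the LED counts as on.
#' @return A [sync_events()] vector of times in the video clock (s).
#' @export
detect_sync_led <- function(stack, roi, on_threshold) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames[[1]])
  roi <- as.integer(roi)
  if (length(roi) != 4 || roi[1] < 1 || roi[2] > d[1] || roi[3] < 1 ||
      roi[4] > d[2] || roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi outside frame bounds", call. = FALSE)
  intensity <- vapply(stack$frames,
                      function(f) mean(f[roi[1]:roi[2], roi[3]:roi[4]]),
                      numeric(1))
  on <- intensity >= on_threshold
  rising <- which(on & !c(TRUE, on[-length(on)]))  # first frame never an edge
  sync_events((rising - 1L) / stack$fps)
}
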