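#' Build a frame stack from a pixel array
#'
#' A `frame_stack` is the package's in-memory representation of a microscopy
#' recording: a 3-D intensity array indexed `(frame, row, col)` plus the
#' acquisition timebase. Frame `k` (1-based) is taken at
#' `t = (k - 1) * frame_interval` seconds; no exposure-midpoint correction is
#' applied. Coordinates are 0-based `(row, col)` with the origin at the
#' top-left pixel.
#'
#' @param pixels numeric 3-D array `(frame, row, col)`; all values finite.
#' @param frame_interval seconds per frame, > 0.
#' @param origin_label free-text source identifier kept for provenance.
#'
#' @return An object of class `frame_stack` with elements `pixels`,
#'   `frame_interval`, `origin_label`.
#' @export
#' @examples
#' px <- array(runif(5 * 8 * 8), dim = c(5, 8, 8))
#' stk <- frame_stack(px, frame_interval = 0.025)
#' n_frames(stk)
#' stack_time(stk)
frame_stack <- function(pixels, frame_interval, origin_label = "memory") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    abort_input("`pixels` must be a 3-D array (frame, row, col)")
  if (dim(pixels)[1L] < 2L)
    abort_input("a frame stack needs at least 2 frames")
  if (!all(is.finite(pixels)))
    abort_input("all pixel intensities must be finite")
  if (!is_scalar_number(frame_interval) || frame_interval <= 0)
    abort_input("`frame_interval` must be a single positive number (seconds)")
  structure(
    list(pixels = pixels, frame_interval = as.numeric(frame_interval),
         origin_label = as.character(origin_label)),
    class = "frame_stack"
  )
}

#' @rdname frame_stack
#' @param x a `frame_stack`.
#' @export
n_frames <- function(x) dim(x$pixels)[1L]

#' @rdname frame_stack
#' @export
frame_dim <- function(x) dim(x$pixels)[2:3]

#' @rdname frame_stack
#' @export
stack_time <- function(x) (seq_len(n_frames(x)) - 1) * x$frame_interval

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px, %.6g s/frame (%.3g s total) [%s]\n",
    d[1L], d[2L], d[3L], x$frame_interval, (d[1L] - 1) * x$frame_interval,
    x$origin_label))
  invisible(x)
}

#' Read an image stack from disk
#'
#' Reads a multi-page TIFF into a [frame_stack()]. Colour frames are collapsed
#' to grayscale by averaging the channels; frame order is preserved. TIFF
#' containers carry no reliable timing metadata, so the frame interval must be
#' supplied by the caller (25 ms for a 40 fps recording).
#'
#' AVI input is not supported; convert the movie to an image stack first
#' (any microscopy toolchain, e.g. ImageJ, exports multi-page TIFF).
#'
#' @param path path to a multi-page TIFF file.
#' @param frame_interval seconds per frame; required.
#'
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, frame_interval = NULL) {
  if (grepl("\\.avi$", path, ignore.case = TRUE))
    abort_input("AVI input is not supported; export the movie as multi-page TIFF")
  if (!file.exists(path)) abort_input(sprintf("stack file not found: %s", path))
  if (is.null(frame_interval))
    abort_input("`frame_interval` must be given: TIFF containers carry no timing metadata")
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e) abort_input(
                       sprintf("unreadable TIFF '%s': %s", path, conditionMessage(e))))
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) < 2L)
    abort_input(sprintf("'%s' has %d frame(s); at least 2 are required", path, length(frames)))
  gray <- lapply(frames, collapse_gray)
  hw <- dim(gray[[1L]])
  if (!all(vapply(gray, function(m) identical(dim(m), hw), logical(1L))))
    abort_input("all frames must share the same height and width")
  px <- array(0, dim = c(length(gray), hw[1L], hw[2L]))
  for (k in seq_along(gray)) px[k, , ] <- gray[[k]]
  frame_stack(px, frame_interval, origin_label = basename(path))
}

# mean over colour channels; identity for grayscale
collapse_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3L) return(apply(frame, c(1L, 2L), mean))
  abort_input("unsupported frame layout in TIFF")
}

#' Write a frame stack to a multi-page TIFF
#'
#' Intensities are stored as 32-bit float samples normalised into `[0, 1]`
#' over the whole stack: nonnegative stacks are divided by their maximum (a
#' pure scale, so ratio quantities such as f/f0 and all pixel-displacement
#' measures are unaffected); stacks containing negative values are min-max
#' shifted. Absolute intensity units are not preserved -- the same is true of
#' most microscopy export paths.
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  rng <- range(stack$pixels)
  if (rng[1L] >= 0) {
    off <- 0
    scale <- if (rng[2L] > 0) rng[2L] else 1
  } else {
    off <- rng[1L]
    scale <- if (diff(rng) > 0) diff(rng) else 1
  }
  frames <- lapply(seq_len(n_frames(stack)), function(k)
    (stack$pixels[k, , ] - off) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}
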