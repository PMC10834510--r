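#' Construct a 16-bit depth frame
#'
#' A depth frame is one single-channel image whose pixel values are
#' distances from the camera to the scene in millimetres, stored as
#' unsigned 16-bit integers. A value of 0 marks an invalid pixel (sensor
#' dropout / no return). Frames are the unit record of every downstream
#' operation: bit-plane splitting, encoding, quality metrics and the
#' synthetic scene generator all consume and produce `depth_frame`
#' objects.
#'
#' Pixel coordinates throughout the package are 0-based, x rightward,
#' y downward; `values[y + 1, x + 1]` addresses the pixel at (x, y).
#'
#' @param values integer (or whole-number numeric) matrix, `height` rows
#'   by `width` columns, every entry in `[0, 65535]`.
#' @param timestamp seconds since the start of the recording.
#' @param frame_index ordinal position in the sequence, starting at 0.
#' @return An object of class `depth_frame`: a list with elements
#'   `values` (integer matrix), `timestamp` and `frame_index`.
#' @seealso [split_frame()], [depth_sequence()]
#' @export
#' @examples
#' f <- depth_frame(matrix(298L, 4, 6))
#' dim(f$values)
depth_frame <- function(values, timestamp = 0, frame_index = 0L) {
  if (!is.matrix(values)) stop("'values' must be a matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("frame dimensions must be positive", call. = FALSE)
  v <- values
  if (!is.integer(v)) {
    if (any(v != round(v))) stop("depth samples must be whole numbers", call. = FALSE)
    storage.mode(v) <- "integer"
  }
  if (anyNA(v) || min(v) < 0L || max(v) > 65535L)
    stop("depth samples must lie in [0, 65535]", call. = FALSE)
  if (frame_index < 0) stop("'frame_index' must be >= 0", call. = FALSE)
  structure(
    list(values = v, timestamp = as.numeric(timestamp),
         frame_index = as.integer(frame_index)),
    class = "depth_frame"
  )
}

#' @export
print.depth_frame <- function(x, ...) {
  cat(sprintf("<depth_frame> %d x %d px, frame %d, t = %.3f s, range [%d, %d]\n",
              ncol(x$values), nrow(x$values), x$frame_index, x$timestamp,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct an ordered sequence of depth frames
#'
#' @param frames list of [depth_frame()] objects with identical
#'   dimensions and `frame_index` running 0, 1, 2, ...
#' @param frame_rate frames per second.
#' @param range_mode `"aligned"` when the depth stream has been
#'   re-projected into the colour camera's coordinates, which restricts
#'   valid samples to `[0, 4096]`; `"full"` for the native `[0, 65535]`
#'   range.
#' @return An object of class `depth_sequence`.
#' @export
depth_sequence <- function(frames, frame_rate, range_mode = c("aligned", "full")) {
  range_mode <- match.arg(range_mode)
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of depth_frame objects", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "depth_frame")))
    stop("all elements of 'frames' must be depth_frame objects", call. = FALSE)
  if (frame_rate <= 0) stop("'frame_rate' must be positive", call. = FALSE)
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (!identical(idx, seq_along(frames) - 1L))
    stop("frame_index must run 0, 1, ... in order", call. = FALSE)
  d <- dim(frames[[1L]]$values)
  same <- vapply(frames, function(f) identical(dim(f$values), d), logical(1))
  if (!all(same)) stop("all frames must share dimensions", call. = FALSE)
  if (range_mode == "aligned") {
    mx <- max(vapply(frames, function(f) max(f$values), integer(1)))
    if (mx > 4096L)
      stop("aligned-range sequence contains samples > 4096; clamp first or use range_mode = 'full'",
           call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate), range_mode = range_mode),
    class = "depth_sequence"
  )
}

#' @export
print.depth_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]]$values)
  cat(sprintf("<depth_sequence> %d frames, %d x %d px, %.4g fps, range_mode = %s\n",
              length(x$frames), d[2L], d[1L], x$frame_rate, x$range_mode))
  invisible(x)
}

#' Dimensions of a depth sequence
#'
#' @param seq a [depth_sequence()].
#' @return Named integer vector `c(width = , height = , n_frames = )`.
#' @export
sequence_dims <- function(seq) {
  stopifnot(inherits(seq, "depth_sequence"))
  d <- dim(seq$frames[[1L]]$values)
  c(width = ncol(seq$frames[[1L]]$values), height = d[1L],
    n_frames = length(seq$frames))
}

#' Split a 16-bit depth frame into its two byte planes
#'
#' Every 16-bit sample `v` is decomposed into the most-significant byte
#' `msb = v %/% 256` and least-significant byte `lsb = v %% 256`, so that
#' `v = msb * 256 + lsb` exactly. The MSB plane carries the coarse scene
#' geometry and changes slowly over time; the LSB plane carries the fine
#' depth detail and sensor noise. The two planes are what the dual-stream
#' encoder compresses.
#'
#' @param frame a [depth_frame()].
#' @return An object of class `bit_plane_pair`: list with integer
#'   matrices `msb` and `lsb`, each with entries in `[0, 255]` and the
#'   dimensions of the source frame.
#' @seealso [merge_planes()]
#' @export
#' @examples
#' f <- depth_frame(matrix(4660L, 2, 2))
#' p <- split_frame(f)
#' p$msb[1, 1]  # 18
#' p$lsb[1, 1]  # 52
split_frame <- function(frame) {
  stopifnot(inherits(frame, "depth_frame"))
  v <- frame$values
  structure(list(msb = v %/% 256L, lsb = v %% 256L), class = "bit_plane_pair")
}

#' Recombine two byte planes into a 16-bit depth frame
#'
#' Inverse of [split_frame()]: `value = msb * 256 + lsb`. For any valid
#' frame `f`, `merge_planes(split_frame(f))` reproduces `f` pixel for
#' pixel.
#'
#' @param pair a `bit_plane_pair`, or a list with integer matrices `msb`
#'   and `lsb` of identical dimensions and entries in `[0, 255]`.
#' @param timestamp,frame_index metadata for the reconstructed frame.
#' @return A [depth_frame()].
#' @export
merge_planes <- function(pair, timestamp = 0, frame_index = 0L) {
  if (!is.list(pair) || is.null(pair$msb) || is.null(pair$lsb))
    stop("'pair' must contain 'msb' and 'lsb' matrices", call. = FALSE)
  if (!identical(dim(pair$msb), dim(pair$lsb)))
    stop("msb and lsb planes have mismatched dimensions", call. = FALSE)
  rng <- range(pair$msb, pair$lsb)
  if (rng[1L] < 0 || rng[2L] > 255)
    stop("plane samples must lie in [0, 255]", call. = FALSE)
  depth_frame(pair$msb * 256L + pair$lsb, timestamp = timestamp,
              frame_index = frame_index)
}

#' Clamp a depth frame to the range of its depth mode
#'
#' In aligned mode (depth re-projected onto the colour camera) valid
#' samples lie in `[0, 4096]`; samples above the ceiling are clamped to
#' 4096 rather than rejected, so a transient sensor glitch cannot abort a
#' long recording. The number of clamped pixels is returned in the
#' `n_clamped` attribute for logging. Full-range mode passes the frame
#' through unchanged.
#'
#' @param frame a [depth_frame()].
#' @param mode `"aligned"` or `"full"`.
#' @return The (possibly clamped) `depth_frame`, with integer attribute
#'   `n_clamped` giving the number of pixels that were reduced.
#' @export
clamp_to_range <- function(frame, mode = c("aligned", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(frame, "depth_frame"))
  if (mode == "full") {
    attr(frame, "n_clamped") <- 0L
    return(frame)
  }
  over <- frame$values > 4096L
  n <- sum(over)
  if (n > 0L) frame$values[over] <- 4096L
  attr(frame, "n_clamped") <- n
  frame
}
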