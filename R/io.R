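#' Write a depth sequence as raw 16-bit binary with a JSON header
#'
#' The `.d16` interchange format is little-endian unsigned 16-bit,
#' row-major from the top-left pixel, frames concatenated in order, with
#' a JSON sidecar header describing the geometry. It matches the common
#' layout of raw depth-sensor dumps and is the package's lossless
#' interchange format.
#'
#' @param seq a [depth_sequence()].
#' @param path output path ending in `.d16`; the header is written next
#'   to it with the extension replaced by `.json`.
#' @return Invisibly, the two paths written (`data`, `header`).
#' @export
write_d16 <- function(seq, path) {
  stopifnot(inherits(seq, "depth_sequence"))
  if (!grepl("\\.d16$", path)) path <- paste0(path, ".d16")
  dims <- sequence_dims(seq)
  header <- list(
    width = unname(dims["width"]), height = unname(dims["height"]),
    frame_count = unname(dims["n_frames"]), frame_rate = seq$frame_rate,
    range_mode = seq$range_mode, endianness = "little"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  for (f in seq$frames) {
    # row-major: transpose R's column-major storage before writing
    writeBin(as.integer(t(f$values)), con, size = 2L, endian = "little")
  }
  hpath <- sub("\\.d16$", ".json", path)
  jsonlite::write_json(header, hpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(data = path, header = hpath))
}

#' Read a `.d16` raw depth recording
#'
#' @param path path to the `.d16` file; the JSON header is expected next
#'   to it (same name, `.json` extension).
#' @return A [depth_sequence()]. Frame timestamps are reconstructed as
#'   `frame_index / frame_rate`.
#' @export
read_d16 <- function(path) {
  hpath <- sub("\\.d16$", ".json", path)
  if (!file.exists(path)) stop("missing depth data file: ", path, call. = FALSE)
  if (!file.exists(hpath)) stop("missing header file: ", hpath, call. = FALSE)
  h <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  need <- c("width", "height", "frame_count", "frame_rate", "range_mode")
  if (!all(need %in% names(h)))
    stop("header is missing fields: ", paste(setdiff(need, names(h)), collapse = ", "),
         call. = FALSE)
  endian <- if (is.null(h$endianness)) "little" else h$endianness
  w <- as.integer(h$width); ht <- as.integer(h$height)
  n <- as.integer(h$frame_count)
  px <- w * ht
  con <- file(path, "rb")
  on.exit(close(con))
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    raw_i <- readBin(con, "integer", n = px, size = 2L, signed = FALSE,
                     endian = endian)
    if (length(raw_i) < px)
      stop("truncated .d16 file: frame ", i - 1L, " incomplete", call. = FALSE)
    vals <- matrix(raw_i, nrow = ht, ncol = w, byrow = TRUE)
    frames[[i]] <- depth_frame(vals, timestamp = (i - 1L) / h$frame_rate,
                               frame_index = i - 1L)
  }
  depth_sequence(frames, frame_rate = h$frame_rate, range_mode = h$range_mode)
}

#' Write a depth sequence as a 16-bit grayscale TIFF frame sequence
#'
#' One file per frame, zero-padded numeric filenames
#' (`<prefix>000000.tif`, ...), 16-bit grayscale. TIFF is used for
#' writing because it stores the full 16-bit sample exactly.
#'
#' @param seq a [depth_sequence()].
#' @param dir output directory (created if absent).
#' @param prefix filename prefix.
#' @return Invisibly, the vector of paths written.
#' @export
write_frames <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "depth_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(seq$frames))
  for (i in seq_along(seq$frames)) {
    p <- file.path(dir, sprintf("%s%06d.tif", prefix, i - 1L))
    tiff::writeTIFF(seq$frames[[i]]$values / 65535, p, bits.per.sample = 16L)
    paths[i] <- p
  }
  invisible(paths)
}

#' Read a 16-bit grayscale frame sequence (TIFF or PNG)
#'
#' Files matching `<prefix><digits>.(tif|tiff|png)` in `dir` are read in
#' numeric order. 16-bit PNG input is supported; both readers return
#' intensities scaled to `[0, 1]`, which are mapped back to integer
#' samples by `round(x * 65535)` (exact for 16-bit sources).
#'
#' @param dir directory containing the frames.
#' @param prefix filename prefix to match.
#' @param frame_rate frames per second recorded in the returned sequence.
#' @param range_mode depth-range mode of the returned sequence.
#' @return A [depth_sequence()].
#' @export
read_frames <- function(dir, prefix = "frame", frame_rate = 15,
                        range_mode = c("aligned", "full")) {
  range_mode <- match.arg(range_mode)
  pat <- paste0("^", prefix, "[0-9]+\\.(tif|tiff|png)$")
  files <- list.files(dir, pattern = pat, full.names = TRUE)
  if (length(files) == 0L)
    stop("no frames matching '", prefix, "NNN.tif/.png' in ", dir, call. = FALSE)
  ord <- order(as.integer(sub("^.*?([0-9]+)\\.[a-z]+$", "\\1", basename(files))))
  files <- files[ord]
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- if (grepl("\\.png$", files[i])) png::readPNG(files[i])
           else tiff::readTIFF(files[i])
    if (length(dim(img)) == 3L) img <- img[, , 1L]  # ignore extra channels
    frames[[i]] <- depth_frame(round(img * 65535), timestamp = (i - 1L) / frame_rate,
                               frame_index = i - 1L)
  }
  depth_sequence(frames, frame_rate = frame_rate, range_mode = range_mode)
}
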