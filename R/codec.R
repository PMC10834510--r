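#' Encoder settings for the dual-stream depth codec
#'
#' The codec always stores the MSB plane losslessly: it carries the
#' coarse geometry, changes rarely, and any error there would be worth
#' 256 mm or more. Only the LSB plane has a quality ladder:
#'
#' * `"lossless"` - quantizer step 1 (bit-exact; full 16-bit round trip)
#' * `"high"`     - step 4  (per-pixel depth error <= 2 mm)
#' * `"medium"`   - step 16 (per-pixel depth error <= 8 mm)
#' * `"low"`      - step 64 (per-pixel depth error <= 32 mm)
#'
#' Each lossy rung quantizes the LSB byte uniformly before entropy
#' coding; since the MSB plane is exact, the reconstruction error is
#' always confined to the low byte and bounded by half the step.
#'
#' @param lsb_quality one of `"lossless"`, `"high"`, `"medium"`, `"low"`.
#' @param clip_duration optional clip length in seconds; when set, the
#'   output streams are segmented into consecutive clips of at most this
#'   duration (the last clip may be shorter).
#' @return An object of class `encoder_settings`.
#' @export
encoder_settings <- function(lsb_quality = c("medium", "lossless", "high", "low"),
                             clip_duration = NULL) {
  lsb_quality <- match.arg(lsb_quality)
  if (!is.null(clip_duration) && clip_duration <= 0)
    stop("'clip_duration' must be positive", call. = FALSE)
  structure(
    list(msb_mode = "lossless", lsb_quality = lsb_quality,
         clip_duration = clip_duration),
    class = "encoder_settings"
  )
}

# quantizer step for each rung of the LSB quality ladder
.lsb_quant_step <- function(lsb_quality) {
  switch(lsb_quality, lossless = 1L, high = 4L, medium = 16L, low = 64L,
         stop("unknown lsb_quality: ", lsb_quality, call. = FALSE))
}

# ---- plane stream container (.dsv) --------------------------------------
#
# One 8-bit grayscale plane stream per file. Layout (little-endian):
#   magic "DSV1" | u8 plane_id | u8 quant | u16 version |
#   u32 width | u32 height | u32 n_frames |
#   per frame: u8 predictor (0 raw, 1 temporal delta) | u32 payload_len |
#              DEFLATE payload of the quantized byte plane (row-major)
# Temporal prediction stores byte-wise differences mod 256 against the
# previous frame's quantized plane; the cheaper of raw/temporal coding is
# chosen per frame.

.write_plane_stream <- function(planes, path, plane_id, quant) {
  con <- file(path, "wb")
  on.exit(close(con))
  h <- dim(planes[[1L]])[1L]; w <- dim(planes[[1L]])[2L]
  writeBin(charToRaw("DSV1"), con)
  writeBin(as.raw(c(plane_id, quant)), con)
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(c(w, h, length(planes)), con, size = 4L, endian = "little")
  prev <- NULL
  for (m in planes) {
    lv <- as.integer(t(m)) %/% quant         # row-major quantized levels
    raw_bytes <- as.raw(lv)
    z_raw <- memCompress(raw_bytes, "gzip")
    if (!is.null(prev)) {
      z_tmp <- memCompress(as.raw((lv - prev) %% 256L), "gzip")
      if (length(z_tmp) < length(z_raw)) {
        writeBin(as.raw(1L), con)
        writeBin(length(z_tmp), con, size = 4L, endian = "little")
        writeBin(z_tmp, con)
        prev <- lv
        next
      }
    }
    writeBin(as.raw(0L), con)
    writeBin(length(z_raw), con, size = 4L, endian = "little")
    writeBin(z_raw, con)
    prev <- lv
  }
  invisible(path)
}

.read_plane_stream <- function(path) {
  if (!file.exists(path))
    stop("missing stream file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, charToRaw("DSV1")))
    stop("corrupted stream (bad magic) in ", path, call. = FALSE)
  ids <- as.integer(readBin(con, "raw", 2L))
  plane_id <- ids[1L]; quant <- ids[2L]
  readBin(con, "integer", 1L, size = 2L, endian = "little")  # version
  geom <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  w <- geom[1L]; h <- geom[2L]; n <- geom[3L]
  planes <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    pred <- as.integer(readBin(con, "raw", 1L))
    len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    payload <- readBin(con, "raw", len)
    if (length(payload) < len || length(pred) == 0L)
      stop("corrupted stream (truncated frame ", i - 1L, ") in ", path, call. = FALSE)
    lv <- as.integer(memDecompress(payload, "gzip"))
    if (length(lv) != w * h)
      stop("corrupted stream (bad frame size) in ", path, call. = FALSE)
    if (pred == 1L) {
      if (is.null(prev))
        stop("corrupted stream (temporal frame without reference) in ", path,
             call. = FALSE)
      lv <- (prev + lv) %% 256L
    }
    prev <- lv
    rec <- if (quant == 1L) lv else pmin(lv * quant + quant %/% 2L, 255L)
    planes[[i]] <- matrix(rec, nrow = h, ncol = w, byrow = TRUE)
  }
  list(plane_id = plane_id, quant = quant, width = w, height = h,
       frames = planes)
}

# ---- recording-level encode / decode ------------------------------------

#' Encode a depth sequence into a dual-stream recording
#'
#' Splits every frame into MSB/LSB byte planes ([split_frame()]) and
#' writes two compressed 8-bit plane streams: `<prefix>.msb.dsv`
#' (always lossless) and `<prefix>.lsb.dsv` (at the requested quality
#' rung), plus a JSON sidecar `<prefix>.json` holding geometry, frame
#' timestamps, encoder settings, experiment metadata and byte counts.
#' With `clip_duration` set in the settings, the streams are segmented
#' into consecutive clips (`<prefix>.clip0000.msb.dsv`, ...) whose
#' decoded concatenation equals the unsegmented decode.
#'
#' @param seq a non-empty [depth_sequence()].
#' @param settings an [encoder_settings()].
#' @param out_prefix output path prefix (directory must exist).
#' @param metadata optional [experiment_metadata()] carried verbatim
#'   into the sidecar.
#' @return An object of class `encoded_recording`: list with `prefix`,
#'   `sidecar_path`, `sidecar` (the parsed metadata), `raw_bytes` and
#'   `encoded_bytes`.
#' @seealso [decode_recording()], [verify_recording()]
#' @export
encode_sequence <- function(seq, settings, out_prefix, metadata = NULL) {
  stopifnot(inherits(seq, "depth_sequence"), inherits(settings, "encoder_settings"))
  if (length(seq$frames) == 0L) stop("empty sequence", call. = FALSE)
  if (!is.null(metadata) && !inherits(metadata, "experiment_metadata"))
    stop("'metadata' must be an experiment_metadata object", call. = FALSE)
  dims <- sequence_dims(seq)
  n <- unname(dims["n_frames"])
  quant <- .lsb_quant_step(settings$lsb_quality)

  ranges <- if (is.null(settings$clip_duration)) {
    list(c(0L, n))
  } else {
    segment_into_clips(n, seq$frame_rate, settings$clip_duration)
  }
  single <- length(ranges) == 1L && is.null(settings$clip_duration)

  pairs <- lapply(seq$frames, split_frame)
  clips <- vector("list", length(ranges))
  for (k in seq_along(ranges)) {
    r <- ranges[[k]]
    idx <- seq.int(r[1L] + 1L, r[2L])
    base <- if (single) out_prefix else sprintf("%s.clip%04d", out_prefix, k - 1L)
    msb_path <- paste0(base, ".msb.dsv")
    lsb_path <- paste0(base, ".lsb.dsv")
    .write_plane_stream(lapply(pairs[idx], `[[`, "msb"), msb_path,
                        plane_id = 0L, quant = 1L)
    .write_plane_stream(lapply(pairs[idx], `[[`, "lsb"), lsb_path,
                        plane_id = 1L, quant = quant)
    clips[[k]] <- list(start_frame = r[1L], end_frame = r[2L],
                       msb = basename(msb_path), lsb = basename(lsb_path))
  }

  raw_bytes <- n * unname(dims["width"]) * unname(dims["height"]) * 2
  enc_files <- unlist(lapply(clips, function(cl)
    file.path(dirname(out_prefix), c(cl$msb, cl$lsb))))
  encoded_bytes <- sum(file.size(enc_files))

  sidecar <- list(
    format = "dsv1",
    width = unname(dims["width"]), height = unname(dims["height"]),
    frame_count = n, frame_rate = seq$frame_rate, range_mode = seq$range_mode,
    settings = list(msb_mode = "lossless", lsb_quality = settings$lsb_quality,
                    lsb_quant_step = quant, clip_duration = settings$clip_duration),
    metadata = if (is.null(metadata)) NULL else unclass(metadata),
    timestamps = vapply(seq$frames, `[[`, numeric(1), "timestamp"),
    clips = clips,
    raw_bytes = raw_bytes, encoded_bytes = encoded_bytes
  )
  sidecar_path <- paste0(out_prefix, ".json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  structure(
    list(prefix = out_prefix, sidecar_path = sidecar_path, sidecar = sidecar,
         raw_bytes = raw_bytes, encoded_bytes = encoded_bytes),
    class = "encoded_recording"
  )
}

#' @export
print.encoded_recording <- function(x, ...) {
  cat(sprintf("<encoded_recording> %d frames %d x %d | %s LSB | %d clip(s) | %.0f -> %.0f bytes (%.2fx)\n",
              x$sidecar$frame_count, x$sidecar$width, x$sidecar$height,
              x$sidecar$settings$lsb_quality, length(x$sidecar$clips),
              x$raw_bytes, x$encoded_bytes, x$raw_bytes / x$encoded_bytes))
  invisible(x)
}

# accept either an encoded_recording or a sidecar path
.load_recording <- function(rec) {
  if (inherits(rec, "encoded_recording")) return(rec)
  if (is.character(rec) && length(rec) == 1L) {
    if (!file.exists(rec)) stop("missing sidecar file: ", rec, call. = FALSE)
    sc <- jsonlite::read_json(rec, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    return(structure(
      list(prefix = sub("\\.json$", "", rec), sidecar_path = rec, sidecar = sc,
           raw_bytes = sc$raw_bytes, encoded_bytes = sc$encoded_bytes),
      class = "encoded_recording"))
  }
  stop("'rec' must be an encoded_recording or a sidecar path", call. = FALSE)
}

#' Decode a dual-stream recording back to depth
#'
#' Reads the MSB and LSB plane streams of every clip, recombines them
#' with [merge_planes()], and restores frame timestamps from the
#' sidecar. Stream frame counts are checked against the sidecar; a
#' mismatch or a missing/corrupted stream is rejected with the stream's
#' identity in the error. For lossy recordings in aligned range mode,
#' reconstructed samples are capped at 4096 (quantization can otherwise
#' push a sample just past the aligned ceiling; the cap only moves it
#' back toward the true value).
#'
#' @param rec an `encoded_recording` or the path to its JSON sidecar.
#' @return A [depth_sequence()].
#' @export
decode_recording <- function(rec) {
  rec <- .load_recording(rec)
  sc <- rec$sidecar
  dir <- dirname(rec$prefix)
  lossless <- identical(sc$settings$lsb_quality, "lossless")
  frames <- vector("list", sc$frame_count)
  for (cl in sc$clips) {
    msb_path <- file.path(dir, cl$msb)
    lsb_path <- file.path(dir, cl$lsb)
    if (!file.exists(msb_path))
      stop("missing MSB stream: ", msb_path, call. = FALSE)
    if (!file.exists(lsb_path))
      stop("missing LSB stream: ", lsb_path, call. = FALSE)
    msb <- .read_plane_stream(msb_path)
    lsb <- .read_plane_stream(lsb_path)
    n_clip <- cl$end_frame - cl$start_frame
    if (length(msb$frames) != n_clip)
      stop("frame-count mismatch between sidecar and MSB stream ", cl$msb,
           call. = FALSE)
    if (length(lsb$frames) != n_clip)
      stop("frame-count mismatch between sidecar and LSB stream ", cl$lsb,
           call. = FALSE)
    for (j in seq_len(n_clip)) {
      i <- cl$start_frame + j              # 1-based position in sequence
      vals <- msb$frames[[j]] * 256L + lsb$frames[[j]]
      if (!lossless && sc$range_mode == "aligned") vals <- pmin(vals, 4096L)
      frames[[i]] <- depth_frame(vals, timestamp = sc$timestamps[i],
                                 frame_index = i - 1L)
    }
  }
  if (any(vapply(frames, is.null, logical(1))))
    stop("clips do not cover all frames declared by the sidecar", call. = FALSE)
  depth_sequence(frames, frame_rate = sc$frame_rate, range_mode = sc$range_mode)
}

#' Compression ratio
#'
#' `raw_bytes / encoded_bytes`, where the raw size of a depth recording
#' is `frames * width * height * 2` bytes (2 bytes per 16-bit sample)
#' and the encoded size is the total size of both stream files.
#'
#' @param raw_bytes,encoded_bytes positive byte counts.
#' @return Dimensionless ratio (> 1 means the encoding saved space).
#' @export
compression_ratio <- function(raw_bytes, encoded_bytes) {
  if (length(raw_bytes) != 1L || length(encoded_bytes) != 1L ||
      is.na(raw_bytes) || is.na(encoded_bytes) ||
      raw_bytes <= 0 || encoded_bytes <= 0)
    stop("byte sizes must be positive scalars", call. = FALSE)
  raw_bytes / encoded_bytes
}

#' Verify a recording against its original sequence
#'
#' Decodes the recording and compares it to the original: pooled
#' MSE/PSNR, compression ratio, and an `exact` flag for bit-exact
#' reconstruction. This is the playback integrity check run after an
#' acquisition session.
#'
#' @param seq the original [depth_sequence()] that was encoded.
#' @param rec the `encoded_recording` (or sidecar path) produced from it.
#' @return A [quality_report()].
#' @export
verify_recording <- function(seq, rec) {
  rec <- .load_recording(rec)
  dec <- decode_recording(rec)
  if (length(seq$frames) != length(dec$frames))
    stop("original and decoded sequences have different frame counts", call. = FALSE)
  if (!identical(dim(seq$frames[[1L]]$values), dim(dec$frames[[1L]]$values)))
    stop("original and decoded sequences have mismatched dimensions", call. = FALSE)
  sequence_quality(seq, dec, raw_bytes = rec$raw_bytes,
                   encoded_bytes = rec$encoded_bytes)
}
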