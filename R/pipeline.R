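#' Experiment metadata carried into the recording sidecar
#'
#' Free-form descriptive fields (cage information such as age, gender
#' and strain; trial name; experimenter) stored verbatim in the JSON
#' sidecar of every recording, so a video file can always be traced back
#' to its experiment.
#'
#' @param trial_name,experimenter_name,notes character scalars.
#' @param cage_info named list of free-form cage descriptors
#'   (e.g. `list(age = "12w", gender = "F", strain = "C57BL/6J")`).
#' @return An object of class `experiment_metadata`.
#' @export
experiment_metadata <- function(trial_name = "", experimenter_name = "",
                                cage_info = list(), notes = "") {
  structure(
    list(trial_name = as.character(trial_name),
         experimenter_name = as.character(experimenter_name),
         cage_info = cage_info, notes = as.character(notes)),
    class = "experiment_metadata"
  )
}

#' Is a timestamp inside the scheduled recording window?
#'
#' Recording schedules are half-open intervals `[start, stop)`: a frame
#' stamped exactly at `start` is recorded, one stamped at `stop` is not.
#' With no schedule, recording is always on. Timestamps are plain
#' numbers on whatever clock the caller injects (seconds since recording
#' start in the pipeline); core logic never consults the system clock.
#'
#' @param t numeric timestamp(s).
#' @param schedule `NULL`, or a list with numeric `start` and `stop`,
#'   `stop > start`.
#' @return Logical vector, `TRUE` where `t` falls inside the window.
#' @export
within_window <- function(t, schedule = NULL) {
  if (is.null(schedule) || (is.null(schedule$start) && is.null(schedule$stop)))
    return(rep(TRUE, length(t)))
  if (is.null(schedule$start) || is.null(schedule$stop) ||
      schedule$stop <= schedule$start)
    stop("schedule must have stop > start", call. = FALSE)
  t >= schedule$start & t < schedule$stop
}

#' Partition a recording into fixed-duration clips
#'
#' Returns contiguous half-open frame ranges `[start_frame, end_frame)`
#' covering `[0, frame_count)` exactly, each spanning at most
#' `clip_duration` seconds at the given frame rate; the final clip may
#' be shorter. When `clip_duration` is below one frame interval, each
#' clip holds a single frame.
#'
#' @param frame_count total number of frames (> 0).
#' @param fps frames per second (> 0).
#' @param clip_duration clip length in seconds (> 0).
#' @return List of integer vectors `c(start_frame, end_frame)`, 0-based.
#' @export
#' @examples
#' segment_into_clips(101, 10, 5)  # [(0,50), (50,100), (100,101)]
segment_into_clips <- function(frame_count, fps, clip_duration) {
  if (frame_count <= 0 || fps <= 0 || clip_duration <= 0)
    stop("frame_count, fps and clip_duration must all be positive", call. = FALSE)
  per_clip <- max(1L, as.integer(floor(fps * clip_duration)))
  starts <- seq.int(0L, frame_count - 1L, by = per_clip)
  lapply(starts, function(s) c(as.integer(s), as.integer(min(s + per_clip, frame_count))))
}

#' Recording configuration
#'
#' One object holding everything a pipeline run needs: where the input
#' comes from (a `.d16` recording or the synthetic scene generator),
#' where output goes, depth-range handling, encoder settings, optional
#' clip segmentation and recording schedule, the random seed, and the
#' experiment metadata. Serializes losslessly to/from JSON via
#' [write_config()] / [read_config()].
#'
#' @param input path to a `.d16` recording, or `"simulate"` to generate
#'   input from the synthetic scene model.
#' @param out_prefix output path prefix for the encoded recording.
#' @param range_mode `"aligned"` or `"full"`.
#' @param lsb_quality LSB quality rung, see [encoder_settings()].
#' @param clip_duration optional clip length in seconds.
#' @param schedule `NULL` or `list(start =, stop =)` in seconds since
#'   recording start; frames outside the window are dropped.
#' @param seed integer seed for all randomness in the run.
#' @param n_frames,fps,dims simulation size used when
#'   `input = "simulate"`: frame count, frame rate, and depth-frame
#'   `c(width, height)`.
#' @param coat_color simulated mouse coat colour.
#' @param verify if `TRUE`, decode after encoding and attach a
#'   [quality_report()].
#' @param metadata an [experiment_metadata()].
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(input = "simulate", out_prefix = "recording",
                             range_mode = c("aligned", "full"),
                             lsb_quality = "medium", clip_duration = NULL,
                             schedule = NULL, seed = 1L,
                             n_frames = 150L, fps = 15, dims = c(320L, 240L),
                             coat_color = "black", verify = TRUE,
                             metadata = experiment_metadata()) {
  range_mode <- match.arg(range_mode)
  if (!is.null(schedule)) {
    if (is.null(schedule$start) || is.null(schedule$stop) ||
        schedule$stop <= schedule$start)
      stop("schedule must have stop > start", call. = FALSE)
    schedule <- list(start = as.numeric(schedule$start),
                     stop = as.numeric(schedule$stop))
  }
  if (!is.null(clip_duration)) {
    if (clip_duration <= 0) stop("'clip_duration' must be positive", call. = FALSE)
    clip_duration <- as.numeric(clip_duration)
  }
  if (!inherits(metadata, "experiment_metadata"))
    metadata <- do.call(experiment_metadata, as.list(metadata))
  structure(
    list(input = as.character(input), out_prefix = as.character(out_prefix),
         range_mode = range_mode, lsb_quality = as.character(lsb_quality),
         clip_duration = clip_duration, schedule = schedule,
         seed = as.integer(seed), n_frames = as.integer(n_frames),
         fps = as.numeric(fps), dims = as.integer(dims),
         coat_color = as.character(coat_color), verify = isTRUE(verify),
         metadata = metadata),
    class = "recording_config"
  )
}

#' @rdname recording_config
#' @param config a `recording_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "recording_config"))
  x <- unclass(config)
  x$metadata <- unclass(x$metadata)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname recording_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(recording_config, x)
}

#' Run the acquisition pipeline end to end
#'
#' Reads or simulates depth input, drops frames outside the recording
#' schedule, clamps samples to the configured depth range, encodes the
#' dual-stream recording (with clip segmentation when configured),
#' writes the sidecar, and optionally verifies by decoding and scoring.
#' Progress is reported as structured `key=value` log lines via
#' [message()].
#'
#' @param config a [recording_config()].
#' @return List with elements `recording` (the `encoded_recording`),
#'   `report` (a [quality_report()] or `NULL`), and `log` (named counts:
#'   frames in/kept, clamped pixels, byte sizes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "recording_config"))
  seq <- if (identical(config$input, "simulate")) {
    scene <- cage_scene(depth_dims = config$dims)
    simulate_sequence(scene, n_frames = config$n_frames, fps = config$fps,
                      coat_color = config$coat_color, seed = config$seed)$sequence
  } else {
    tryCatch(read_d16(config$input),
             error = function(e) stop("input stage: ", conditionMessage(e), call. = FALSE))
  }
  n_in <- length(seq$frames)

  keep <- within_window(vapply(seq$frames, `[[`, numeric(1), "timestamp"),
                        config$schedule)
  if (!any(keep)) stop("schedule stage: no frames inside the recording window",
                       call. = FALSE)
  frames <- seq$frames[keep]

  n_clamped <- 0L
  for (i in seq_along(frames)) {
    f <- clamp_to_range(frames[[i]], config$range_mode)
    n_clamped <- n_clamped + attr(f, "n_clamped")
    attr(f, "n_clamped") <- NULL
    f$frame_index <- i - 1L
    frames[[i]] <- f
  }
  seq <- depth_sequence(frames, frame_rate = seq$frame_rate,
                        range_mode = config$range_mode)

  settings <- encoder_settings(lsb_quality = config$lsb_quality,
                               clip_duration = config$clip_duration)
  rec <- tryCatch(
    encode_sequence(seq, settings, out_prefix = config$out_prefix,
                    metadata = config$metadata),
    error = function(e) stop("encode stage: ", conditionMessage(e), call. = FALSE))

  report <- NULL
  if (config$verify) {
    report <- tryCatch(verify_recording(seq, rec),
                       error = function(e) stop("verify stage: ", conditionMessage(e),
                                                call. = FALSE))
  }
  log <- c(frames_in = n_in, frames_kept = length(seq$frames),
           pixels_clamped = n_clamped, raw_bytes = rec$raw_bytes,
           encoded_bytes = rec$encoded_bytes, clips = length(rec$sidecar$clips))
  message(paste(sprintf("%s=%s", names(log), format(log, scientific = FALSE, trim = TRUE)),
                collapse = " "))
  list(recording = rec, report = report, log = log)
}
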