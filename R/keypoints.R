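#' Read and write keypoint annotation tables
#'
#' Annotations are plain CSV with columns `frame_id`, `annotator_id`,
#' `bodypart` (one of nose, left_ear, right_ear, tail_base), `x`, `y`,
#' `coordinate_space` (`"rgb"` or `"depth"`), `visible` (0/1), and
#' optionally `color` (coat colour of the animal in the frame).
#'
#' @param path CSV file path.
#' @return `read_annotations()` returns the validated data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("missing annotation file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_id", "annotator_id", "bodypart", "x", "y",
            "coordinate_space", "visible")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("annotation CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  dup <- duplicated(df[, c("frame_id", "annotator_id", "bodypart",
                           "coordinate_space")])
  if (any(dup))
    stop("duplicate (frame, annotator, bodypart) annotation records", call. = FALSE)
  df
}

#' @rdname read_annotations
#' @param annotations annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' Transfer RGB-space coordinates onto the depth frame
#'
#' The colour and depth streams are recorded simultaneously; labels
#' drawn on the (easier to read) RGB frames are mapped onto the depth
#' frames by the uniform scaling that fits one frame onto the other:
#' `x' = x * depth_w / rgb_w`, `y' = y * depth_h / rgb_h`. For
#' 1920x1080 RGB onto 1280x720 depth this is a uniform factor of 2/3.
#' The two frame geometries must share their aspect ratio - anisotropic
#' scaling would silently distort inter-keypoint distances - so a
#' mismatch beyond `tol` is rejected.
#'
#' @param points data frame with `x`, `y` columns (or a 2-column
#'   matrix / length-2 vector).
#' @param rgb_dims,depth_dims `c(width, height)` of the two frames.
#' @param tol maximum tolerated relative difference between the x and y
#'   scale factors.
#' @return Same shape as `points`, coordinates in depth pixels.
#' @export
#' @examples
#' rgb_to_depth(c(960, 540), c(1920, 1080), c(1280, 720))  # (640, 360)
rgb_to_depth <- function(points, rgb_dims = c(1920, 1080),
                         depth_dims = c(1280, 720), tol = 1e-6) {
  sx <- depth_dims[1L] / rgb_dims[1L]
  sy <- depth_dims[2L] / rgb_dims[2L]
  if (abs(sx - sy) > tol * max(sx, sy))
    stop("rgb_dims and depth_dims do not share an aspect ratio; ",
         "refusing anisotropic scaling", call. = FALSE)
  if (is.data.frame(points)) {
    points$x <- points$x * sx
    points$y <- points$y * sy
    points
  } else if (is.matrix(points)) {
    points[, 1L] <- points[, 1L] * sx
    points[, 2L] <- points[, 2L] * sy
    points
  } else {
    c(points[1L] * sx, points[2L] * sy)
  }
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.round_half_up <- function(x) floor(x + 0.5)

#' Partition annotated frame ids into train / validation / test sets
#'
#' Uniform random partition under a seed. First `test_frac` of the ids
#' (rounded half-up) are held out for testing; of the remainder,
#' `val_frac` (rounded half-up) form the validation set and the rest the
#' training set. With the default fractions and 100 ids this yields
#' 25 test, 4 validation and 71 training ids (5% of 75 is 3.75,
#' rounded up to a whole image).
#'
#' @param ids vector of unique frame ids.
#' @param seed integer seed; the same seed always yields the same split.
#' @param test_frac fraction of all ids held out for testing.
#' @param val_frac fraction of the non-test ids used for validation.
#' @return List with elements `train`, `val`, `test` (disjoint, union =
#'   `ids`).
#' @export
split_dataset <- function(ids, seed = 1L, test_frac = 0.25, val_frac = 0.05) {
  if (anyDuplicated(ids)) stop("duplicate ids in input", call. = FALSE)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 ids to split", call. = FALSE)
  n_test <- .round_half_up(test_frac * n)
  n_val <- .round_half_up(val_frac * (n - n_test))
  perm <- .with_seed(seed, sample(ids))
  test <- perm[seq_len(n_test)]
  val <- perm[n_test + seq_len(n_val)]
  train <- perm[-seq_len(n_test + n_val)]
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' @rdname split_dataset
#' @param ids_by_color named list of id vectors, one per coat colour.
#' @return `split_dataset_by_color()` returns a named list of splits
#'   (class `data_split`), one per colour; each colour uses a distinct
#'   sub-seed derived from `seed`.
#' @export
split_dataset_by_color <- function(ids_by_color, seed = 1L,
                                   test_frac = 0.25, val_frac = 0.05) {
  out <- lapply(seq_along(ids_by_color), function(i)
    split_dataset(ids_by_color[[i]], seed = seed + i,
                  test_frac = test_frac, val_frac = val_frac))
  names(out) <- names(ids_by_color)
  structure(out, class = "data_split")
}

#' @rdname split_dataset
#' @param split a `data_split`.
#' @param path JSON output path.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, pretty = TRUE)
  invisible(path)
}

#' Object scale of a keypoint record
#'
#' OKS needs a per-object size normalizer. Segmentation areas are not
#' available from keypoint-only annotations, so the scale is the square
#' root of the area of the axis-aligned bounding box of the visible
#' keypoints, floored at 1 pixel to avoid division blow-ups when points
#' (nearly) coincide. Scaling all coordinates by `c` scales the result
#' by `c` (above the floor).
#'
#' @param record data frame with `x`, `y` and `visible` columns for one
#'   (frame, annotator) record.
#' @return Scalar scale in pixels, `>= 1`.
#' @export
object_scale <- function(record) {
  vis <- record[record$visible > 0, , drop = FALSE]
  if (nrow(vis) < 2L)
    stop("object_scale needs at least 2 visible keypoints", call. = FALSE)
  area <- diff(range(vis$x)) * diff(range(vis$y))
  max(1, sqrt(area))
}

#' Estimate per-keypoint OKS falloff constants from dual annotations
#'
#' Two independent annotators labelling the same frames calibrate how
#' precisely each bodypart can be localized: for each part i, the
#' constant `k_i` is the standard deviation over frames of the
#' scale-normalized inter-annotator distance `d_i / s`, where `s` is the
#' object scale of the frame (computed from the midpoint record of the
#' two annotators, which is symmetric in them). Frames missing either
#' annotation for a part are skipped; a part with no usable pairs is an
#' error naming the part; a part on which the annotators agree exactly
#' everywhere is flagged degenerate (`k = 0` cannot be used in OKS).
#'
#' @param annotations annotation data frame (see [read_annotations()]).
#' @param annotators the two annotator ids to compare.
#' @param space coordinate space in which to compare (default `"rgb"`,
#'   where human annotation happens).
#' @return An object of class `sigma_set`: data frame with `bodypart`,
#'   `k`, `n_pairs`, plus attribute `n_frames_used`.
#' @export
estimate_sigmas <- function(annotations, annotators = c("a1", "a2"),
                            space = "rgb") {
  stopifnot(length(annotators) == 2L)
  a <- annotations[annotations$coordinate_space == space &
                     annotations$annotator_id %in% annotators &
                     annotations$visible > 0, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("no annotations from the requested annotators in space '", space, "'",
         call. = FALSE)
  w1 <- a[a$annotator_id == annotators[1L], c("frame_id", "bodypart", "x", "y")]
  w2 <- a[a$annotator_id == annotators[2L], c("frame_id", "bodypart", "x", "y")]
  m <- merge(w1, w2, by = c("frame_id", "bodypart"), suffixes = c("_1", "_2"))
  if (length(unique(m$frame_id)) < 2L)
    stop("need at least 2 frames labelled by both annotators", call. = FALSE)
  # per-frame object scale from the annotator midpoint record
  frames <- split(m, m$frame_id)
  scales <- vapply(frames, function(fr) {
    mid <- data.frame(x = (fr$x_1 + fr$x_2) / 2, y = (fr$y_1 + fr$y_2) / 2,
                      visible = 1L)
    object_scale(mid)
  }, numeric(1))
  m$s <- scales[m$frame_id]
  m$dnorm <- sqrt((m$x_1 - m$x_2)^2 + (m$y_1 - m$y_2)^2) / m$s
  parts <- sort(unique(annotations$bodypart))
  k <- numeric(length(parts)); np <- integer(length(parts))
  for (i in seq_along(parts)) {
    di <- m$dnorm[m$bodypart == parts[i]]
    if (length(di) < 2L)
      stop("no usable dual-annotation pairs for bodypart '", parts[i], "'",
           call. = FALSE)
    k[i] <- stats::sd(di)
    np[i] <- length(di)
  }
  if (any(k == 0))
    warning("degenerate sigma estimate (annotators agree exactly) for: ",
            paste(parts[k == 0], collapse = ", "))
  structure(
    data.frame(bodypart = parts, k = k, n_pairs = np),
    n_frames_used = length(frames), class = c("sigma_set", "data.frame")
  )
}

#' @rdname estimate_sigmas
#' @param sigmas a `sigma_set`.
#' @param path JSON path.
#' @export
write_sigmas_json <- function(sigmas, path) {
  jsonlite::write_json(as.data.frame(unclass(sigmas)), path, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname estimate_sigmas
#' @export
read_sigmas_json <- function(path) {
  df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  structure(df, class = c("sigma_set", "data.frame"))
}

# scale of a truth record for OKS: bounding box of every keypoint that
# carries coordinates, whether or not it is visible. Visibility gates
# which parts enter the kernel sum, not the size of the animal, so a
# frame with a single visible keypoint still has a well-defined scale.
.oks_scale <- function(truth) {
  has_xy <- !(is.na(truth$x) | is.na(truth$y))
  all_vis <- truth[has_xy, , drop = FALSE]
  all_vis$visible <- 1L
  object_scale(all_vis)
}

# named vector of k by bodypart, validated > 0
.sigma_lookup <- function(sigmas, parts) {
  kv <- stats::setNames(sigmas$k, sigmas$bodypart)
  miss <- setdiff(parts, names(kv))
  if (length(miss) > 0L)
    stop("no sigma for bodypart(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(kv[parts] <= 0))
    stop("sigma constants must be > 0 (degenerate estimate?)", call. = FALSE)
  kv[parts]
}

#' Object keypoint similarity between a prediction and the truth
#'
#' The standard keypoint-similarity kernel: for each truth-visible
#' bodypart i at distance `d_i` from its prediction,
#' `OKS = mean_i exp(-d_i^2 / (2 s^2 k_i^2))`, where `s` is the object
#' scale of the truth record (bounding box of all truth keypoints with
#' coordinates, so a frame with one visible part still has a scale) and
#' `k_i` the per-part falloff constant.
#' A perfect prediction scores 1; scores decay smoothly toward 0 as
#' distances grow relative to the object size. Predictions for parts
#' invisible in the truth are ignored.
#'
#' @param pred,truth single-frame data frames with `bodypart`, `x`, `y`,
#'   `visible` columns.
#' @param sigmas a `sigma_set` from [estimate_sigmas()] (or any data
#'   frame with `bodypart` and `k > 0`).
#' @return OKS score in `[0, 1]`.
#' @export
oks <- function(pred, truth, sigmas) {
  tv <- truth[truth$visible > 0, , drop = FALSE]
  if (nrow(tv) == 0L)
    stop("OKS undefined: no visible truth keypoints", call. = FALSE)
  s <- .oks_scale(truth)
  m <- merge(tv[, c("bodypart", "x", "y")],
             pred[, c("bodypart", "x", "y")],
             by = "bodypart", suffixes = c("_t", "_p"))
  if (nrow(m) < nrow(tv))
    stop("prediction is missing bodypart(s): ",
         paste(setdiff(tv$bodypart, m$bodypart), collapse = ", "), call. = FALSE)
  d2 <- (m$x_t - m$x_p)^2 + (m$y_t - m$y_p)^2
  mean(exp(-d2 / (2 * s^2 * .sigma_lookup(sigmas, m$bodypart)^2)))
}

#' Mean OKS over a set of frames, optionally per coat colour
#'
#' Matches prediction and truth records frame by frame, scores each
#' frame with [oks()], and averages: one pooled mean and, when a
#' `color` column is present and `by_color = TRUE`, one mean per coat
#' colour. Groups that end up empty are omitted with a warning.
#'
#' @param pred,truth annotation data frames covering the same frames
#'   (single annotator each, same coordinate space).
#' @param sigmas a `sigma_set`.
#' @param by_color aggregate per coat colour as well?
#' @return List with `overall` (scalar), `by_color` (named numeric or
#'   `NULL`), and `per_frame` (data frame `frame_id`, `color`, `oks`).
#' @export
mean_oks <- function(pred, truth, sigmas, by_color = TRUE) {
  ids <- intersect(unique(truth$frame_id), unique(pred$frame_id))
  if (length(ids) == 0L) stop("no common frames between pred and truth", call. = FALSE)
  scores <- numeric(length(ids))
  cols <- character(length(ids))
  for (i in seq_along(ids)) {
    tr <- truth[truth$frame_id == ids[i], , drop = FALSE]
    pr <- pred[pred$frame_id == ids[i], , drop = FALSE]
    scores[i] <- oks(pr, tr, sigmas)
    cols[i] <- if ("color" %in% names(tr)) tr$color[1L] else NA_character_
  }
  per_frame <- data.frame(frame_id = ids, color = cols, oks = scores)
  out <- list(overall = mean(scores), by_color = NULL, per_frame = per_frame)
  if (by_color && !all(is.na(cols))) {
    groups <- split(scores, cols)
    empty <- vapply(groups, length, integer(1)) == 0L
    if (any(empty))
      warning("empty colour group(s) omitted: ",
              paste(names(groups)[empty], collapse = ", "))
    out$by_color <- vapply(groups[!empty], mean, numeric(1))
  }
  out
}
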