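#' Synthetic home-cage scene description
#'
#' Describes the static geometry and sensor model of a top-down depth
#' view of a single-housed mouse cage: a flat floor at the camera's
#' working distance, raised static fixtures (the accessible edge of the
#' food hopper and a mezzanine-like platform), Gaussian sensor noise,
#' and zero-valued dropout pixels. The paired pseudo-RGB view is exactly
#' 1.5x the depth resolution on both axes, mirroring a 1920x1080 colour
#' stream alongside a 1280x720 depth stream.
#'
#' Defaults are test-scale (320x240 depth / 480x360 RGB); pass
#' `depth_dims = c(1280L, 720L)` for full scale. The depth pixel pitch
#' is set by `px_per_mm`, by default chosen so the frame spans ~256 mm
#' of cage floor horizontally.
#'
#' @param depth_dims integer `c(width, height)` of the depth frame; both
#'   must be even so the 1.5x RGB dimensions are whole pixels.
#' @param camera_height distance from camera to cage floor, mm.
#' @param noise_sd depth sensor noise standard deviation, mm.
#' @param dropout_prob probability that a pixel reads 0 (no return).
#' @param px_per_mm depth-image scale; `NULL` for the default
#'   `depth_dims[1] / 256`.
#' @param floor_margin fraction of each image border excluded from the
#'   walkable floor region.
#' @return An object of class `cage_scene`.
#' @export
cage_scene <- function(depth_dims = c(320L, 240L), camera_height = 298,
                       noise_sd = 2, dropout_prob = 0.01, px_per_mm = NULL,
                       floor_margin = 0.1) {
  depth_dims <- as.integer(depth_dims)
  if (length(depth_dims) != 2L || any(depth_dims <= 0L))
    stop("'depth_dims' must be two positive integers", call. = FALSE)
  if (any(depth_dims %% 2L != 0L))
    stop("'depth_dims' must be even so rgb_dims = 1.5 * depth_dims is integral",
         call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("'dropout_prob' must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  rgb_dims <- as.integer((depth_dims * 3L) %/% 2L)
  if (is.null(px_per_mm)) px_per_mm <- depth_dims[1L] / 256
  w <- depth_dims[1L]; h <- depth_dims[2L]
  mx <- round(floor_margin * w); my <- round(floor_margin * h)
  # hopper grate edge: raised strip along the top border; mezzanine:
  # raised block in the lower-right corner, both outside floor_region
  fixtures <- list(
    hopper = list(region = c(0, 0, w - 1, max(1, round(0.06 * h))), height_mm = 40),
    mezzanine = list(region = c(round(0.92 * w), round(0.75 * h), w - 1, h - 1),
                     height_mm = 30)
  )
  structure(
    list(depth_dims = depth_dims, rgb_dims = rgb_dims,
         camera_height = camera_height, noise_sd = noise_sd,
         dropout_prob = dropout_prob, px_per_mm = px_per_mm,
         floor_region = c(mx, my, w - 1 - mx, h - 1 - my),
         fixtures = fixtures),
    class = "cage_scene"
  )
}

#' Mouse pose state
#'
#' Position, heading and body-size parameters of the simulated mouse.
#' The body is modelled as an elongated Gaussian elevation hump; the
#' four tracked keypoints (nose, left ear, right ear, tail base) are
#' placed deterministically from the pose: nose and tail base at the two
#' ends of the heading axis, ears forward of centre and offset laterally.
#'
#' @param centroid `c(x, y)` body centre in depth-image pixels (0-based).
#' @param heading direction of travel, radians (0 = +x, increasing
#'   toward +y).
#' @param body_length,body_width,body_height body dimensions, mm.
#' @param coat_color one of `"black"`, `"white"`, `"tan"`.
#' @return An object of class `mouse_state`.
#' @export
mouse_state <- function(centroid, heading = 0, body_length = 80,
                        body_width = 35, body_height = 35,
                        coat_color = c("black", "white", "tan")) {
  coat_color <- match.arg(coat_color)
  structure(
    list(centroid = as.numeric(centroid), heading = as.numeric(heading),
         body_length = body_length, body_width = body_width,
         body_height = body_height, coat_color = coat_color),
    class = "mouse_state"
  )
}

#' Ground-truth keypoints of a pose
#'
#' @param state a [mouse_state()].
#' @param scene the [cage_scene()] providing the mm-to-pixel scale.
#' @return Data frame with columns `bodypart`, `x`, `y` (depth-image
#'   pixels) for nose, left_ear, right_ear, tail_base.
#' @export
keypoints_from_pose <- function(state, scene) {
  s <- scene$px_per_mm
  L <- state$body_length * s; W <- state$body_width * s
  dirv <- c(cos(state$heading), sin(state$heading))
  perp <- c(-dirv[2L], dirv[1L])   # left of heading in image coords
  cx <- state$centroid
  pts <- rbind(
    nose      = cx + 0.5  * L * dirv,
    left_ear  = cx + 0.25 * L * dirv - 0.35 * W * perp,
    right_ear = cx + 0.25 * L * dirv + 0.35 * W * perp,
    tail_base = cx - 0.5  * L * dirv
  )
  data.frame(bodypart = rownames(pts), x = pts[, 1L], y = pts[, 2L],
             row.names = NULL)
}

#' Advance the mouse one step of a bounded random walk
#'
#' Heading is perturbed by wrapped-normal noise, a nonnegative speed is
#' drawn (half-normal), and the centroid advances along the heading,
#' reflecting (position and heading) at the walkable floor boundary so
#' the animal never leaves the floor region. Uses R's global RNG stream;
#' seed at the sequence level for reproducibility.
#'
#' @param state a [mouse_state()].
#' @param scene a [cage_scene()].
#' @param heading_sd heading perturbation SD, radians/step.
#' @param speed_sd scale of the half-normal step length, mm/step.
#' @return The updated `mouse_state`.
#' @export
step_mouse <- function(state, scene, heading_sd = 0.35, speed_sd = 8) {
  h <- state$heading + stats::rnorm(1L, 0, heading_sd)
  h <- ((h + pi) %% (2 * pi)) - pi
  speed <- abs(stats::rnorm(1L, 0, speed_sd)) * scene$px_per_mm
  pos <- state$centroid + speed * c(cos(h), sin(h))
  fr <- scene$floor_region
  lo <- fr[1:2]; hi <- fr[3:4]
  # reflect until inside (a large step can bounce more than once)
  for (ax in 1:2) {
    while (pos[ax] < lo[ax] || pos[ax] > hi[ax]) {
      if (pos[ax] < lo[ax]) pos[ax] <- 2 * lo[ax] - pos[ax]
      if (pos[ax] > hi[ax]) pos[ax] <- 2 * hi[ax] - pos[ax]
      h <- if (ax == 1L) pi - h else -h
    }
  }
  h <- ((h + pi) %% (2 * pi)) - pi
  state$centroid <- pos
  state$heading <- h
  state
}

# noiseless elevation map (mm) of the body hump on an arbitrary pixel grid
.body_elevation <- function(state, width, height, px_per_mm) {
  sL <- state$body_length * px_per_mm / 4   # along-body Gaussian sd, px
  sW <- state$body_width * px_per_mm / 4
  x <- matrix(rep(0:(width - 1L), each = height), nrow = height)
  y <- matrix(rep(0:(height - 1L), times = width), nrow = height)
  dx <- x - state$centroid[1L]; dy <- y - state$centroid[2L]
  u <- cos(state$heading) * dx + sin(state$heading) * dy
  v <- -sin(state$heading) * dx + cos(state$heading) * dy
  state$body_height * exp(-0.5 * ((u / sL)^2 + (v / sW)^2))
}

#' Render one synthetic depth frame
#'
#' Background pixels read approximately `camera_height` mm; fixtures are
#' closer by their fixed height; the mouse body appears as a smooth
#' elevation hump (closer to the camera, hence smaller depth). Gaussian
#' sensor noise is added and rounded to integer millimetres, samples are
#' clamped to the aligned range `[0, 4096]`, and dropout pixels are set
#' to 0 last. Draws from R's global RNG stream.
#'
#' @param scene a [cage_scene()].
#' @param state a [mouse_state()], or `NULL` for an empty cage.
#' @param timestamp,frame_index frame metadata.
#' @return A [depth_frame()] whose samples satisfy the aligned-range
#'   invariant by construction.
#' @export
render_depth <- function(scene, state = NULL, timestamp = 0, frame_index = 0L) {
  w <- scene$depth_dims[1L]; h <- scene$depth_dims[2L]
  depth <- matrix(scene$camera_height, nrow = h, ncol = w)
  for (fx in scene$fixtures) {
    r <- fx$region
    depth[(r[2L]:r[4L]) + 1L, (r[1L]:r[3L]) + 1L] <-
      scene$camera_height - fx$height_mm
  }
  if (!is.null(state))
    depth <- depth - .body_elevation(state, w, h, scene$px_per_mm)
  if (scene$noise_sd > 0)
    depth <- depth + stats::rnorm(w * h, 0, scene$noise_sd)
  depth <- pmin(pmax(round(depth), 0), 4096)
  if (scene$dropout_prob > 0)
    depth[stats::runif(w * h) < scene$dropout_prob] <- 0
  depth_frame(depth, timestamp = timestamp, frame_index = frame_index)
}

# coat-colour body intensities for the pseudo-RGB render
.coat_intensity <- c(black = 0.15, white = 0.90, tan = 0.60)

#' Render the paired pseudo-RGB frame
#'
#' A flat-shaded body (intensity set by coat colour) over a fixed
#' procedural bedding texture, at `rgb_dims` = 1.5x the depth
#' resolution. The render is geometrically consistent with
#' [render_depth()]: a keypoint at depth coordinates `(x, y)` appears at
#' RGB coordinates `(1.5x, 1.5y)`. Deterministic given scene and state
#' (the texture is procedural, not sampled).
#'
#' @param scene a [cage_scene()].
#' @param state a [mouse_state()], or `NULL` for an empty cage.
#' @return Numeric array `height x width x 3` with values in `[0, 1]`.
#' @export
render_rgb <- function(scene, state = NULL) {
  w <- scene$rgb_dims[1L]; h <- scene$rgb_dims[2L]
  x <- matrix(rep(0:(w - 1L), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1L), times = w), nrow = h)
  bg <- 0.45 + 0.06 * sin(x / 7) * cos(y / 9) +
    0.04 * sin((x + 2 * y) / 23)                # procedural bedding texture
  img <- bg
  if (!is.null(state)) {
    st <- state
    st$centroid <- state$centroid * 1.5
    elev <- .body_elevation(st, w, h, scene$px_per_mm * 1.5)
    mask <- elev > 1                             # mm; body footprint
    img[mask] <- .coat_intensity[[state$coat_color]]
  }
  img <- pmin(pmax(img, 0), 1)
  array(img, dim = c(h, w, 3L))
}

#' Simulate a depth recording with ground-truth keypoints
#'
#' Runs the random-walk pose model for `n_frames` steps, rendering a
#' depth frame at each step and recording the ground-truth keypoints in
#' both coordinate systems. All randomness is governed by `seed`.
#'
#' @param scene a [cage_scene()].
#' @param n_frames number of frames.
#' @param fps frame rate.
#' @param coat_color simulated coat colour.
#' @param seed integer seed.
#' @param render if `FALSE`, skip depth rendering and return keypoints
#'   only (fast path for large keypoint-geometry studies).
#' @return List with `sequence` (a [depth_sequence()], or `NULL` when
#'   `render = FALSE`), `keypoints` (data frame: `frame_index`,
#'   `bodypart`, `x`, `y` in depth pixels), and `states`.
#' @export
simulate_sequence <- function(scene, n_frames, fps = 15,
                              coat_color = "black", seed = 1L,
                              render = TRUE) {
  stopifnot(n_frames >= 1L)
  set.seed(seed)
  fr <- scene$floor_region
  state <- mouse_state(centroid = c(mean(fr[c(1, 3)]), mean(fr[c(2, 4)])),
                       heading = stats::runif(1L, -pi, pi),
                       coat_color = coat_color)
  frames <- if (render) vector("list", n_frames) else NULL
  states <- vector("list", n_frames)
  kps <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    states[[i]] <- state
    kp <- keypoints_from_pose(state, scene)
    kp <- cbind(frame_index = i - 1L, kp)
    kps[[i]] <- kp
    if (render)
      frames[[i]] <- render_depth(scene, state, timestamp = (i - 1L) / fps,
                                  frame_index = i - 1L)
    state <- step_mouse(state, scene)
  }
  list(
    sequence = if (render) depth_sequence(frames, frame_rate = fps,
                                          range_mode = "aligned") else NULL,
    keypoints = do.call(rbind, kps),
    states = states
  )
}

#' Generate an annotated synthetic dataset
#'
#' Simulates an independent trajectory per coat colour and emits a
#' keypoint annotation table in the package's CSV schema: ground-truth
#' rows (`annotator_id = "truth"`) in both the RGB and depth coordinate
#' spaces, and, in dual-annotation mode, two simulated human annotators
#' (`"a1"`, `"a2"`) whose RGB-space labels are the truth plus
#' independent isotropic Gaussian jitter of standard deviation
#' `jitter_sd` pixels per coordinate - the standard inter-rater noise
#' model used to calibrate per-keypoint OKS falloff constants.
#'
#' @param n_frames_per_color annotated frames per coat colour.
#' @param colors coat colours to simulate.
#' @param seed integer seed governing trajectories and jitter.
#' @param dual if `TRUE`, add the two jittered annotators.
#' @param jitter_sd annotator jitter SD in RGB pixels.
#' @param scene a [cage_scene()].
#' @param render if `TRUE`, also return the rendered depth sequences
#'   (one per colour).
#' @return List with `annotations` (data frame: `frame_id`,
#'   `annotator_id`, `bodypart`, `x`, `y`, `coordinate_space`,
#'   `visible`, `color`) and `sequences` (named list or `NULL`).
#' @export
generate_dataset <- function(n_frames_per_color = 100L,
                             colors = c("black", "white", "tan"),
                             seed = 1L, dual = FALSE, jitter_sd = 3,
                             scene = cage_scene(), render = FALSE) {
  stopifnot(n_frames_per_color >= 1L)
  out <- vector("list", length(colors))
  seqs <- if (render) stats::setNames(vector("list", length(colors)), colors) else NULL
  for (ci in seq_along(colors)) {
    col <- colors[ci]
    sim <- simulate_sequence(scene, n_frames_per_color, coat_color = col,
                             seed = seed + ci, render = render)
    if (render) seqs[[col]] <- sim$sequence
    kp <- sim$keypoints
    frame_id <- sprintf("%s_%04d", col, kp$frame_index)
    truth_depth <- data.frame(frame_id = frame_id, annotator_id = "truth",
                              bodypart = kp$bodypart, x = kp$x, y = kp$y,
                              coordinate_space = "depth", visible = 1L,
                              color = col)
    truth_rgb <- truth_depth
    truth_rgb$x <- kp$x * 1.5; truth_rgb$y <- kp$y * 1.5
    truth_rgb$coordinate_space <- "rgb"
    ann <- rbind(truth_depth, truth_rgb)
    if (dual) {
      n <- nrow(truth_rgb)
      for (a in c("a1", "a2")) {
        jit <- truth_rgb
        jit$annotator_id <- a
        jit$x <- jit$x + stats::rnorm(n, 0, jitter_sd)
        jit$y <- jit$y + stats::rnorm(n, 0, jitter_sd)
        ann <- rbind(ann, jit)
      }
    }
    out[[ci]] <- ann
  }
  list(annotations = do.call(rbind, out), sequences = seqs)
}
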