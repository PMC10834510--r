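test_that("scene geometry keeps the exact 1.5x RGB/depth ratio", {
  sc <- cage_scene(depth_dims = c(320L, 240L))
  expect_identical(sc$rgb_dims, c(480L, 360L))
  expect_error(cage_scene(depth_dims = c(321L, 240L)), "even")
  expect_error(cage_scene(dropout_prob = 1), "dropout")
})

test_that("a degenerate walk (zero noise, zero speed) leaves the state fixed", {
  sc <- tiny_scene()
  st <- mouse_state(centroid = c(30, 25), heading = 1)
  st2 <- step_mouse(st, sc, heading_sd = 0, speed_sd = 0)
  expect_equal(st2$centroid, st$centroid)
  expect_equal(st2$heading, st$heading)
})

test_that("the random walk is seed-deterministic and stays on the floor", {
  sc <- tiny_scene()
  walk <- function(seed, n) {
    set.seed(seed)
    st <- mouse_state(centroid = c(30, 25))
    out <- matrix(0, n, 2)
    for (i in seq_len(n)) { st <- step_mouse(st, sc); out[i, ] <- st$centroid }
    out
  }
  expect_identical(walk(99, 50), walk(99, 50))
  traj <- walk(7, 10000)
  fr <- sc$floor_region
  expect_true(all(traj[, 1] >= fr[1] & traj[, 1] <= fr[3]))
  expect_true(all(traj[, 2] >= fr[2] & traj[, 2] <= fr[4]))
})

test_that("an empty noiseless cage renders floor depth and fixture offsets", {
  sc <- cage_scene(depth_dims = c(64L, 48L), noise_sd = 0, dropout_prob = 0)
  f <- render_depth(sc, state = NULL)
  fr <- sc$floor_region
  floor_px <- f$values[(fr[2]:fr[4]) + 1L, (fr[1]:fr[3]) + 1L]
  expect_true(all(floor_px == 298L))                # camera height, mm
  hop <- sc$fixtures$hopper
  expect_true(all(f$values[1L, ] == 298L - hop$height_mm))
})

test_that("the mouse appears as an elevation (smaller depth than floor)", {
  sc <- cage_scene(depth_dims = c(64L, 48L), noise_sd = 0, dropout_prob = 0)
  st <- mouse_state(centroid = c(32, 24))
  f <- render_depth(sc, st)
  fr <- sc$floor_region
  floor_px <- f$values[(fr[2]:fr[4]) + 1L, (fr[1]:fr[3]) + 1L]
  expect_lt(min(floor_px), 298L)
  # the body apex (at the centroid) is body_height mm above the floor
  expect_equal(min(floor_px), 298L - round(st$body_height))
})

test_that("rendered samples always satisfy the aligned-range invariant", {
  sc <- tiny_scene(noise_sd = 50)   # heavy noise still cannot escape the range
  set.seed(4)
  st <- mouse_state(centroid = c(30, 25))
  for (i in 1:5) {
    f <- render_depth(sc, st)
    expect_true(min(f$values) >= 0L && max(f$values) <= 4096L)
  }
})

test_that("dropout probability is honoured on a binomial check", {
  sc <- cage_scene(depth_dims = c(640L, 480L), noise_sd = 0, dropout_prob = 0.05)
  set.seed(12)
  f <- render_depth(sc, NULL)
  frac <- mean(f$values == 0L)
  n <- 640 * 480
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / n))
})

test_that("keypoints lie inside the rendered body mask, nose opposite tail", {
  sc <- tiny_scene()
  set.seed(31)
  for (i in 1:20) {
    st <- mouse_state(centroid = c(runif(1, 15, 45), runif(1, 15, 35)),
                      heading = runif(1, -pi, pi))
    kp <- keypoints_from_pose(st, sc)
    elev <- cagecodec:::.body_elevation(st, 64L, 48L, sc$px_per_mm)
    for (j in seq_len(nrow(kp))) {
      px <- round(kp$x[j]); py <- round(kp$y[j])
      expect_gt(elev[py + 1L, px + 1L], 1)          # on the body hump
    }
    nose <- as.numeric(kp[kp$bodypart == "nose", c("x", "y")])
    tail <- as.numeric(kp[kp$bodypart == "tail_base", c("x", "y")])
    along <- c(cos(st$heading), sin(st$heading))
    expect_gt(sum((nose - st$centroid) * along), 0)
    expect_lt(sum((tail - st$centroid) * along), 0)
  }
})

test_that("depth and RGB renders are geometrically consistent", {
  sc <- tiny_scene()
  st <- mouse_state(centroid = c(30, 25), heading = 0.7)
  kp_depth <- keypoints_from_pose(st, sc)
  # a keypoint at depth (x, y) appears at rgb (1.5x, 1.5y); mapping the
  # rgb coordinates back through the alignment transform recovers depth
  # ground truth to well under half a pixel
  kp_rgb <- kp_depth; kp_rgb$x <- kp_rgb$x * 1.5; kp_rgb$y <- kp_rgb$y * 1.5
  back <- rgb_to_depth(kp_rgb, sc$rgb_dims, sc$depth_dims)
  expect_true(all(abs(back$x - kp_depth$x) < 0.5))
  expect_true(all(abs(back$y - kp_depth$y) < 0.5))
  # rgb body pixels carry the coat shade at the scaled positions
  img <- render_rgb(sc, st)
  px <- round(st$centroid * 1.5)
  expect_equal(img[px[2] + 1L, px[1] + 1L, 1L],
               cagecodec:::.coat_intensity[["black"]])
})

test_that("coat colour sets body contrast against the bedding", {
  sc <- tiny_scene()
  st_b <- mouse_state(centroid = c(30, 25), coat_color = "black")
  st_w <- mouse_state(centroid = c(30, 25), coat_color = "white")
  bg <- render_rgb(sc, NULL)[, , 1L]
  body_mask <- render_rgb(sc, st_b)[, , 1L] != bg
  expect_lt(mean(render_rgb(sc, st_b)[, , 1L][body_mask]), mean(bg))
  expect_gt(mean(render_rgb(sc, st_w)[, , 1L][body_mask]), mean(bg))
})

test_that("identical seeds yield bit-identical simulations", {
  sc <- tiny_scene()
  a <- simulate_sequence(sc, 5L, seed = 77L)
  b <- simulate_sequence(sc, 5L, seed = 77L)
  expect_identical(frame_values(a$sequence), frame_values(b$sequence))
  expect_identical(a$keypoints, b$keypoints)
  c <- simulate_sequence(sc, 5L, seed = 78L)
  expect_false(identical(frame_values(a$sequence), frame_values(c$sequence)))
})

test_that("generate_dataset emits the full annotation schema per colour", {
  ds <- generate_dataset(10L, seed = 2L, scene = tiny_scene())
  ann <- ds$annotations
  expect_setequal(unique(ann$color), c("black", "white", "tan"))
  # 10 frames x 3 colours x 4 bodyparts x 2 coordinate spaces
  expect_equal(nrow(ann), 10 * 3 * 4 * 2)
  expect_equal(length(unique(ann$frame_id)), 30L)
  expect_setequal(unique(ann$bodypart),
                  c("nose", "left_ear", "right_ear", "tail_base"))
  # rgb coordinates are exactly 1.5x the depth coordinates
  d <- ann[ann$coordinate_space == "depth", ]
  r <- ann[ann$coordinate_space == "rgb", ]
  key <- function(z) paste(z$frame_id, z$bodypart)
  r <- r[match(key(d), key(r)), ]
  expect_equal(r$x, d$x * 1.5)
  expect_equal(r$y, d$y * 1.5)
})

test_that("dual-annotator jitter has the configured magnitude", {
  # zero jitter: the two annotators agree exactly
  ds0 <- generate_dataset(5L, colors = "black", seed = 3L, dual = TRUE,
                          jitter_sd = 0, scene = tiny_scene())
  a1 <- ds0$annotations[ds0$annotations$annotator_id == "a1", ]
  a2 <- ds0$annotations[ds0$annotations$annotator_id == "a2", ]
  expect_equal(a1$x, a2$x)
  expect_equal(a1$y, a2$y)
  # jitter sd s: mean inter-annotator distance is the Rayleigh mean
  # s*sqrt(2)*sqrt(pi/2) = s*sqrt(pi) (difference of two iid 2-D Gaussians)
  s <- 4
  ds <- generate_dataset(600L, colors = "black", seed = 4L, dual = TRUE,
                         jitter_sd = s, scene = tiny_scene())
  a1 <- ds$annotations[ds$annotations$annotator_id == "a1", ]
  a2 <- ds$annotations[ds$annotations$annotator_id == "a2", ]
  d <- sqrt((a1$x - a2$x)^2 + (a1$y - a2$y)^2)
  expect_equal(mean(d), s * sqrt(pi), tolerance = 0.05)
})
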