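test_that("rgb_to_depth maps the standard stream geometries exactly", {
  expect_equal(rgb_to_depth(c(0, 0)), c(0, 0))
  expect_equal(rgb_to_depth(c(1920, 1080)), c(1280, 720))  # corner to corner
  expect_equal(rgb_to_depth(c(960, 540)), c(640, 360))     # uniform 2/3
  df <- data.frame(x = c(0, 1920), y = c(0, 1080))
  out <- rgb_to_depth(df)
  expect_equal(out$x, c(0, 1280))
  expect_equal(out$y, c(0, 720))
  expect_error(rgb_to_depth(c(1, 1), c(1920, 1080), c(1280, 800)),
               "aspect ratio")
})

test_that("split_dataset reproduces the 25/4/71 partition of 100 ids", {
  ids <- sprintf("f%03d", 1:100)
  sp <- split_dataset(ids, seed = 5L)
  expect_length(sp$test, 25L)
  expect_length(sp$val, 4L)     # 5% of 75 = 3.75, rounded up to a whole image
  expect_length(sp$train, 71L)
  # pairwise disjoint, union is the full id set
  expect_equal(length(intersect(sp$train, sp$val)), 0L)
  expect_equal(length(intersect(sp$train, sp$test)), 0L)
  expect_equal(length(intersect(sp$val, sp$test)), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  # deterministic under the seed
  expect_identical(sp, split_dataset(ids, seed = 5L))
  expect_false(identical(sp$test, split_dataset(ids, seed = 6L)$test))
  expect_error(split_dataset(c("a", "a", "b")), "duplicate")
})

test_that("per-colour splitting keeps colours independent and serializes", {
  ids <- list(black = sprintf("b%03d", 1:100), white = sprintf("w%03d", 1:100),
              tan = sprintf("t%03d", 1:100))
  sp <- split_dataset_by_color(ids, seed = 9L)
  expect_named(sp, c("black", "white", "tan"))
  for (cl in names(sp)) expect_length(sp[[cl]]$test, 25L)
  td <- withr::local_tempdir()
  p <- write_split_json(sp, file.path(td, "split.json"))
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$black$test, sp$black$test)
})

test_that("object_scale is sqrt of keypoint bounding-box area, floored", {
  r <- kp_record(x = c(0, 30, 10, 20), y = c(0, 6, 12, 3))
  expect_equal(object_scale(r), sqrt(30 * 12))     # sqrt(360) ~ 18.97
  # homogeneity: scaling coordinates by c scales s by c
  r2 <- r; r2$x <- r2$x * 3; r2$y <- r2$y * 3
  expect_equal(object_scale(r2), 3 * object_scale(r))
  # degenerate floor at 1 px
  expect_equal(object_scale(kp_record(x = rep(5, 4), y = rep(5, 4))), 1)
  # visibility and arity contracts
  expect_error(object_scale(kp_record(x = 1:4, y = 1:4, visible = 0L)),
               "2 visible")
})

test_that("estimate_sigmas recovers known jitter against a Monte-Carlo oracle", {
  parts <- c("nose", "left_ear", "right_ear", "tail_base")
  base <- data.frame(bodypart = parts, x = c(60, 45, 45, 0), y = c(15, 5, 25, 15))
  sigma <- 2.5
  n <- 2000L
  set.seed(101)
  rows <- list()
  for (a in c("a1", "a2")) {
    jx <- base[rep(1:4, n), ]
    jx$frame_id <- rep(sprintf("f%05d", 1:n), each = 4L)
    jx$annotator_id <- a
    jx$x <- jx$x + rnorm(4L * n, 0, sigma)
    jx$y <- jx$y + rnorm(4L * n, 0, sigma)
    jx$coordinate_space <- "rgb"; jx$visible <- 1L
    rows[[a]] <- jx
  }
  est <- estimate_sigmas(do.call(rbind, rows))
  # independent oracle: simulate the same observation model directly and
  # measure sd(d/s) without going through the estimator
  set.seed(202)
  oracle_one <- function(n_mc) {
    d_over_s <- matrix(0, n_mc, 4L)
    for (i in seq_len(n_mc)) {
      p1 <- cbind(base$x + rnorm(4, 0, sigma), base$y + rnorm(4, 0, sigma))
      p2 <- cbind(base$x + rnorm(4, 0, sigma), base$y + rnorm(4, 0, sigma))
      mid <- (p1 + p2) / 2
      s <- max(1, sqrt(diff(range(mid[, 1])) * diff(range(mid[, 2]))))
      d_over_s[i, ] <- sqrt(rowSums((p1 - p2)^2)) / s
    }
    apply(d_over_s, 2L, sd)
  }
  oracle <- oracle_one(2000L)
  names(oracle) <- parts
  for (p in parts) {
    expect_equal(est$k[est$bodypart == p], oracle[[p]],
                 tolerance = 0.08)    # two independent 2000-frame estimates
  }
  expect_equal(unique(est$n_pairs), n)
})

test_that("estimate_sigmas flags degenerate agreement and missing parts", {
  parts <- c("nose", "left_ear", "right_ear", "tail_base")
  mk <- function(a) data.frame(frame_id = rep(c("f1", "f2"), each = 4L),
                               annotator_id = a, bodypart = rep(parts, 2L),
                               x = rep(c(0, 30, 15, 10), 2L) + rep(c(0, 5), each = 4L),
                               y = rep(c(0, 4, 12, 6), 2L),
                               coordinate_space = "rgb", visible = 1L)
  ann <- rbind(mk("a1"), mk("a2"))
  expect_warning(estimate_sigmas(ann), "degenerate")
  # a part never labelled by the second annotator is an error naming it
  ann2 <- ann[!(ann$annotator_id == "a2" & ann$bodypart == "nose"), ]
  expect_error(estimate_sigmas(ann2), "nose")
})

test_that("200 dual-annotated frames yield n_pairs_used = 200 per part", {
  ds <- generate_dataset(67L, seed = 10L, dual = TRUE, jitter_sd = 2,
                         scene = tiny_scene())
  ann <- ds$annotations
  keep <- unique(ann$frame_id)[1:200]               # 200-image dual subset
  est <- estimate_sigmas(ann[ann$frame_id %in% keep, ])
  expect_true(all(est$n_pairs == 200L))
  expect_equal(attr(est, "n_frames_used"), 200L)
})

test_that("oks matches its closed forms", {
  sig <- uniform_sigmas(0.05)
  truth <- kp_record(x = c(60, 45, 45, 0), y = c(15, 5, 25, 15))
  expect_equal(oks(truth, truth, sig), 1)           # perfect prediction
  # single visible keypoint at d = s*k*sqrt(2 ln 2) scores exactly 0.5
  t1 <- truth; t1$visible <- c(1L, 0L, 0L, 0L)
  s <- object_scale(truth)                          # scale uses all truth parts
  d <- s * 0.05 * sqrt(2 * log(2))
  p1 <- truth; p1$x[1] <- p1$x[1] + d
  expect_equal(oks(p1, t1, sig), 0.5, tolerance = 1e-12)
  # kernel tail: huge distances drive the score to 0
  pfar <- truth; pfar$x <- pfar$x + 1e6
  expect_lt(oks(pfar, truth, sig), 1e-10)
  # contracts
  t0 <- truth; t0$visible <- 0L
  expect_error(oks(truth, t0, sig), "no visible")
  expect_error(oks(truth[-1, ], truth, sig), "missing bodypart")
})

test_that("oks is scale invariant and strictly decreasing in distance", {
  sig <- uniform_sigmas(0.04)
  set.seed(55)
  for (i in 1:25) {
    truth <- kp_record(x = runif(4, 0, 100), y = runif(4, 0, 60))
    pred <- truth
    pred$x <- pred$x + rnorm(4, 0, 3); pred$y <- pred$y + rnorm(4, 0, 3)
    base <- oks(pred, truth, sig)
    cc <- runif(1, 0.5, 20)
    ts <- truth; ts$x <- ts$x * cc; ts$y <- ts$y * cc
    ps <- pred; ps$x <- ps$x * cc; ps$y <- ps$y * cc
    expect_equal(oks(ps, ts, sig), base, tolerance = 1e-12)
    # moving one prediction further out strictly lowers the score
    worse <- pred; worse$x[1] <- worse$x[1] + 50
    expect_lt(oks(worse, truth, sig), base)
    expect_true(base >= 0 && base <= 1)
  }
})

test_that("OKS is identical in RGB space and after depth transfer", {
  sig <- uniform_sigmas(0.06)
  set.seed(66)
  for (i in 1:10) {
    truth <- kp_record(x = runif(4, 100, 1800), y = runif(4, 100, 1000))
    pred <- truth
    pred$x <- pred$x + rnorm(4, 0, 8); pred$y <- pred$y + rnorm(4, 0, 8)
    a <- oks(pred, truth, sig)
    b <- oks(rgb_to_depth(pred), rgb_to_depth(truth), sig)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("mean_oks aggregates per colour and pools with equal weights", {
  sig <- uniform_sigmas(0.05)
  ds <- generate_dataset(6L, seed = 12L, dual = TRUE, jitter_sd = 1.5,
                         scene = tiny_scene())
  ann <- ds$annotations
  truth <- ann[ann$annotator_id == "truth" & ann$coordinate_space == "rgb", ]
  pred <- ann[ann$annotator_id == "a1", ]
  m <- mean_oks(pred, truth, sig)
  expect_length(m$by_color, 3L)
  expect_true(all(m$per_frame$oks >= 0 & m$per_frame$oks <= 1))
  # equal group sizes: pooled mean is the mean of the group means
  expect_equal(m$overall, mean(m$by_color))
  # perfect predictions score 1 everywhere
  mp <- mean_oks(truth, truth, sig)
  expect_equal(mp$overall, 1)
  expect_true(all(mp$by_color == 1))
})

test_that("annotation CSV round trips through the documented schema", {
  ds <- generate_dataset(3L, colors = "tan", seed = 2L, scene = tiny_scene())
  td <- withr::local_tempdir()
  p <- file.path(td, "ann.csv")
  write_annotations(ds$annotations, p)
  back <- read_annotations(p)
  expect_equal(back, ds$annotations, ignore_attr = TRUE)
  bad <- ds$annotations[, setdiff(names(ds$annotations), "bodypart")]
  write_annotations(bad, p)
  expect_error(read_annotations(p), "missing columns: bodypart")
})
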