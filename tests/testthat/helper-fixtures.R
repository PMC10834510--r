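# Shared fixtures, generated in code. The standard test fixture is a
# short synthetic cage recording at reduced resolution; the larger
# 320x240 / 10 s fixture used by the acceptance tests is cached per
# session so the per-rung encodes don't regenerate it.

tiny_scene <- function(dims = c(64L, 48L), ...) cage_scene(depth_dims = dims, ...)

tiny_sequence <- function(n_frames = 8L, seed = 42L, dims = c(64L, 48L), ...) {
  simulate_sequence(tiny_scene(dims, ...), n_frames = n_frames, fps = 15,
                    seed = seed)$sequence
}

frame_values <- function(seq) lapply(seq$frames, `[[`, "values")

# single-frame keypoint record helper
kp_record <- function(x, y, parts = c("nose", "left_ear", "right_ear", "tail_base"),
                      visible = 1L) {
  data.frame(bodypart = parts, x = x, y = y, visible = visible)
}

uniform_sigmas <- function(k, parts = c("nose", "left_ear", "right_ear", "tail_base")) {
  data.frame(bodypart = parts, k = k)
}

.fixture_cache <- new.env(parent = emptyenv())

# 10 s of 320x240 depth at 15 fps, fixed seed: the reference fixture for
# codec-level round-trip, ladder and clip tests
acceptance_fixture <- function() {
  if (is.null(.fixture_cache$seq))
    .fixture_cache$seq <- simulate_sequence(cage_scene(depth_dims = c(320L, 240L)),
                                            n_frames = 150L, fps = 15,
                                            seed = 20260901L)$sequence
  .fixture_cache$seq
}

# encoded recording of the fixture at a given rung, cached
fixture_recording <- function(lsb_quality) {
  key <- paste0("rec_", lsb_quality)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("ccfix_", lsb_quality))
    dir.create(dir, showWarnings = FALSE)
    .fixture_cache[[key]] <- encode_sequence(
      acceptance_fixture(), encoder_settings(lsb_quality),
      out_prefix = file.path(dir, "fix"))
  }
  .fixture_cache[[key]]
}
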