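# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small noisy scene with all defaults except size/counts (105 x 105 um).
scene_small <- function() {
  get_fixture("scene_small", function() {
    render_scene(scene_spec(
      width_um = 105, height_um = 105,
      n_cells = c(ramified = 5, hypertrophic = 4, ameboid = 5), seed = 11
    ))
  })
}

# Noiseless, blur-free, background-free scene: painted values are exact.
scene_noiseless <- function() {
  get_fixture("scene_noiseless", function() {
    render_scene(scene_spec(
      width_um = 105, height_um = 105,
      n_cells = c(ramified = 4, hypertrophic = 3, ameboid = 4),
      background_level = 0, background_gradient_amplitude = 0,
      gaussian_noise_sd = 0, poisson_scaling = 0, psf_sigma_um = 0,
      seed = 13
    ))
  })
}

# Full-size default scene (210 um, 20 cells/class) for recovery checks.
scene_default <- function() {
  get_fixture("scene_default", function() {
    render_scene(scene_spec(seed = 7))
  })
}

test_config <- function(threshold = 300, ...) {
  pipeline_config(threshold_gray = threshold, ...)
}

# Rasterized disk mask (radius in pixels).
disk_mask <- function(r) {
  d <- seq(-r, r)
  outer(d^2, d^2, "+") <= r^2
}
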