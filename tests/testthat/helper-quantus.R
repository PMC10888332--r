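# shared reduced acquisition geometry for simulation-based tests:
# 25.6 x 25.6 mm phantom, 64-element probe, 3 steering angles
small_grid <- function() phantom_grid(0.2, 128L, 128L)

small_probe <- function(angles = c(-8, 0, 8))
  probe_config(n_elements = 64L, steering_angles_deg = angles,
               n_samples = 2300L)

# cache expensive shared fixtures across test files within one run
.fixture_env <- new.env()
cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

small_reference <- function() cached("small_reference",
  reference_rf(small_probe(), small_grid(), rng_seed = 99L, n_frames = 2L))

small_windows <- function() analysis_windows(z_min_mm = 4, z_max_mm = 23)
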