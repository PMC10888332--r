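#' Network input planes from plane-wave RF
#'
#' Desk-scale input representation: per steering angle, the channel-data
#' envelope (magnitude of the analytic signal) is block-averaged in
#' depth and linearly interpolated across elements onto a `size x size`
#' grid, then log-compressed and normalized to `[0, 1]` per frame. The
#' stack of per-angle planes preserves the amplitude decay (AC), the
#' angle-dependent arrival structure (SoS) and the envelope texture
#' (ESD/ESC) that the conditions need.
#'
#' @param rf a `plane_wave_rf`.
#' @param size output grid size.
#' @param dynamic_range_db log-compression range.
#' @return numeric array `size x size x n_angles`.
#' @export
rf_to_input <- function(rf, size = 128L, dynamic_range_db = 50) {
  stopifnot(inherits(rf, "plane_wave_rf"))
  env <- Mod(analytic_signal(rf$data))
  d <- dim(env)
  n_dep <- d[1] %/% size
  out <- array(0, c(size, size, d[3]))
  for (a in seq_len(d[3])) {
    e <- env[seq_len(n_dep * size), , a, drop = TRUE]
    dim(e) <- c(n_dep, size, d[2])
    dep <- apply(e, c(2, 3), mean)               # size x n_elements
    # lateral interpolation onto `size` columns
    xi <- seq(1, d[2], length.out = size)
    i0 <- pmin(floor(xi), d[2] - 1L); frac <- xi - i0
    lat <- dep[, i0] * rep(1 - frac, each = size) +
      dep[, i0 + 1L] * rep(frac, each = size)
    lo <- 10^(-dynamic_range_db / 20)
    ln <- 20 * log10(pmax(lat / max(lat), lo))
    out[, , a] <- (ln + dynamic_range_db) / dynamic_range_db
  }
  out
}

# normalization ranges mapping physical values to [0, 1] network targets
qus_target_ranges <- function() {
  list(AC = c(0, 1.2), SoS = c(1400, 1650), ESD = c(40, 130),
       ESC = c(0, 5))
}

normalize_map <- function(m, range) (m - range[1]) / (range[2] - range[1])

# resample a phantom property map onto a 128 x 128 target grid
map_to_target <- function(m, out = 128L) {
  H <- nrow(m); W <- ncol(m)
  zi <- pmin(pmax(round(seq(1, H, length.out = out)), 1L), H)
  xi <- pmin(pmax(round(seq(1, W, length.out = out)), 1L), W)
  m[zi, xi]
}

#' Simulated training dataset of (input, condition, target) triples
#'
#' Generates lesion phantoms (uniform soft-tissue background, one
#' elliptical inclusion with stylized contrasts: AC and ESC raised, SoS
#' and ESD lowered inside the lesion), simulates their multi-angle RF,
#' and emits one triple per phantom and condition. Each phantom
#' contributes four triples sharing one input; `n` is the triple count
#' and must be a multiple of 4.
#'
#' @param n number of triples.
#' @param seed RNG seed.
#' @param probe,grid acquisition configuration; defaults are a reduced
#'   desk geometry (64 elements over a 25.6 mm phantom).
#' @param snr_db simulation noise level.
#' @return list of `n` samples: `list(input, cond, target, truth)`
#'   where `target` is the normalized 128 x 128 parameter map and
#'   `truth` names the parameter.
#' @export
make_toy_dataset <- function(n = 64L, seed = 1L,
                             probe = NULL, grid = NULL, snr_db = 25) {
  stopifnot(n %% 4L == 0L)
  if (is.null(grid)) grid <- phantom_grid(0.2, 128L, 128L)
  if (is.null(probe))
    probe <- probe_config(n_elements = 64L,
                          steering_angles_deg = c(-8, 0, 8),
                          n_samples = 2300L)
  rng <- qus_target_ranges()
  pars <- c("AC", "SoS", "ESD", "ESC")
  maps <- c(AC = "ac_map", SoS = "sos_map", ESD = "esd_map",
            ESC = "esc_map")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  dataset <- vector("list", n)
  half_w <- grid$roi_mm[["width"]] / 2
  for (ph_i in seq_len(n %/% 4L)) {
    set.seed(seed + ph_i * 17L)
    ax <- stats::runif(2, 2.5, 5)
    cx <- stats::runif(1, -(half_w - max(ax) - 2), half_w - max(ax) - 2)
    cz <- stats::runif(1, max(ax) + 4, grid$roi_mm[["depth"]] - max(ax) - 4)
    les <- lesion_spec("ellipse", c(cx, cz), ax,
                       properties = list(ac = stats::runif(1, 0.75, 1.0),
                                         sos = stats::runif(1, 1470, 1500),
                                         esd = stats::runif(1, 60, 72),
                                         esc = stats::runif(1, 3.2, 4.2)),
                       class_label = "malignant")
    bg <- list(ac = stats::runif(1, 0.4, 0.55),
               sos = stats::runif(1, 1530, 1560),
               esd = stats::runif(1, 88, 100),
               esc = stats::runif(1, 1.6, 2.4))
    ph <- generate_phantom(layers = list(list(class = "gland",
                                              thickness_mm = Inf)),
                           lesion = les, rng_seed = seed + ph_i,
                           grid = grid)
    # overwrite the sampled layer with the drawn background values
    for (p in pars) {
      m <- matrix(bg[[tolower(p)]], grid$nz, grid$nx)
      m[ph$lesion_mask] <- les$properties[[tolower(p)]]
      ph[[maps[[p]]]] <- m
    }
    rf <- simulate_rf(ph, probe, rng_seed = seed + 1000L + ph_i,
                      snr_db = snr_db)
    input <- rf_to_input(rf)
    for (ci in 1:4) {
      target <- normalize_map(map_to_target(ph[[maps[[pars[ci]]]]]),
                              rng[[pars[ci]]])
      dataset[[(ph_i - 1L) * 4L + ci]] <-
        list(input = input, cond = ci, target = target,
             truth = pars[ci])
    }
  }
  dataset
}
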