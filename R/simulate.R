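#' Linear-array plane-wave probe configuration
#'
#' Defaults model a 128-element 5 MHz linear probe sampled at 62.5 MHz
#' with 3018 samples per channel, transmitting plane waves at a small set
#' of steering angles.
#'
#' @param n_elements element count.
#' @param center_freq_hz pulse center frequency (Hz).
#' @param pitch_mm element pitch (mm).
#' @param sampling_rate_hz receive sampling rate (Hz).
#' @param n_samples samples per channel.
#' @param steering_angles_deg plane-wave steering angles (degrees).
#' @param pulse_fractional_bandwidth -6 dB fractional bandwidth of the
#'   Gaussian pulse.
#' @param c_ref reference tissue speed used in the transmit delay law
#'   (m/s).
#' @return object of class `probe_config`; includes `elem_x_mm`, element
#'   lateral centers (aperture centered on 0).
#' @export
probe_config <- function(n_elements = 128L, center_freq_hz = 5e6,
                         pitch_mm = 0.3, sampling_rate_hz = 62.5e6,
                         n_samples = 3018L,
                         steering_angles_deg = c(-10, -5, 0, 5, 10),
                         pulse_fractional_bandwidth = 0.6,
                         c_ref = 1540) {
  stopifnot(n_elements >= 2L, sampling_rate_hz > 2 * center_freq_hz,
            all(is.finite(steering_angles_deg)),
            all(abs(steering_angles_deg) < 90),
            pulse_fractional_bandwidth > 0, pitch_mm > 0, n_samples > 0)
  n_elements <- as.integer(n_elements)
  structure(list(
    n_elements = n_elements, center_freq_hz = center_freq_hz,
    pitch_mm = pitch_mm, sampling_rate_hz = sampling_rate_hz,
    n_samples = as.integer(n_samples),
    steering_angles_deg = steering_angles_deg,
    pulse_fractional_bandwidth = pulse_fractional_bandwidth,
    c_ref = c_ref,
    elem_x_mm = (seq_len(n_elements) - (n_elements + 1) / 2) * pitch_mm),
    class = "probe_config")
}

#' Plane-wave transmit delays
#'
#' Per-element pulse emission delay for a steering angle:
#' `delay(n) = n * pitch * sin(theta) / c_ref` for element index
#' n = 0, ..., N-1. Negative delays are permitted; callers shift the set
#' to non-negative by subtracting the minimum before firing.
#'
#' @param probe a [probe_config()].
#' @param angle_deg steering angle in degrees, |angle| < 90.
#' @return numeric vector of delays in seconds, one per element.
#' @export
transmit_delays <- function(probe, angle_deg) {
  stopifnot(inherits(probe, "probe_config"), abs(angle_deg) < 90)
  n <- seq_len(probe$n_elements) - 1L
  n * (probe$pitch_mm * 1e-3) * sin(angle_deg * pi / 180) / probe$c_ref
}

# spectral sigma (Hz) of the Gaussian pulse from its -6 dB fractional
# bandwidth (FWHM of the amplitude spectrum)
pulse_sigma_f <- function(probe) {
  probe$pulse_fractional_bandwidth * probe$center_freq_hz /
    (2 * sqrt(2 * log(2)))
}

#' Draw a random scatterer field from a phantom
#'
#' Scatterer counts per pixel are Poisson with expectation
#' `esc_map * pixel_area / lambda^2` (lambda at the probe center frequency
#' in 1540 m/s reference tissue); positions are uniform within the pixel.
#' Base reflectivities are zero-mean Gaussian with standard deviation
#' scaling as `(esd / 85 um)^(3/2)` so that echo power grows with the
#' local scatterer size (Rayleigh-like d^3 power weighting); the
#' frequency-dependent part of the Gaussian form factor is applied at
#' simulation time.
#'
#' @param phantom a `tissue_phantom`.
#' @param rng_seed integer seed.
#' @param lambda_mm acoustic wavelength defining the ESC unit area;
#'   default 1540 / 5 MHz = 0.308 mm.
#' @return object of class `scatterer_field`: `positions_mm` (n x 2,
#'   lateral/depth), `amplitudes`, `esd_um`, `pixel` (linear index).
#' @export
generate_scatterers <- function(phantom, rng_seed = 1L, lambda_mm = 0.308) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  g <- phantom$grid
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)

  mean_n <- phantom$esc_map * (g$pitch_mm^2 / lambda_mm^2)
  n_px <- stats::rpois(length(mean_n), mean_n)
  total <- sum(n_px)
  if (total == 0L) {
    return(structure(list(positions_mm = matrix(numeric(0), 0, 2),
                          amplitudes = numeric(0), esd_um = numeric(0),
                          pixel = integer(0), seed = rng_seed),
                     class = "scatterer_field"))
  }
  px <- rep.int(seq_along(n_px), n_px)
  iz <- (px - 1L) %% g$nz + 1L
  ix <- (px - 1L) %/% g$nz + 1L
  x <- g$x_mm[ix] + stats::runif(total, -0.5, 0.5) * g$pitch_mm
  z <- g$z_mm[iz] + stats::runif(total, -0.5, 0.5) * g$pitch_mm
  z <- pmin(pmax(z, 1e-3), g$roi_mm[["depth"]])
  esd <- phantom$esd_map[cbind(iz, ix)]
  amp <- stats::rnorm(total, 0, 1) * (esd / 85)^1.5
  structure(list(positions_mm = cbind(lateral = x, depth = z),
                 amplitudes = amp, esd_um = esd, pixel = px,
                 seed = rng_seed),
            class = "scatterer_field")
}

#' Simulate multi-angle plane-wave RF channel data
#'
#' Desk-scale point-scatterer forward model. For every steering angle and
#' scatterer, a Gaussian-modulated echo is placed at the two-way travel
#' time obtained from the plane-wave transmit geometry and the straight
#' receive path, using the depth-averaged slowness of the speed-of-sound
#' map. Amplitude combines the scatterer reflectivity, cumulative
#' frequency-dependent attenuation from the AC map, the Gaussian
#' form-factor roll-off from the ESD map, and cylindrical spreading.
#' Because the pulse spectrum is Gaussian and both attenuation
#' (`exp(-a f)`) and the form factor (`exp(-b f^2)`) are log-polynomial in
#' frequency, each echo remains an exact Gaussian pulse with a shifted
#' center frequency and narrowed bandwidth; `attenuation_mode =
#' "center_only"` instead applies attenuation as a pure amplitude factor
#' at the center frequency.
#'
#' @param phantom a `tissue_phantom`.
#' @param probe a [probe_config()].
#' @param rng_seed integer seed (scatterer draw + measurement noise).
#' @param snr_db white measurement noise level relative to signal RMS.
#' @param scatterers optional pre-drawn [generate_scatterers()] field.
#' @param attenuation_mode `"frequency_dependent"` (default) or
#'   `"center_only"`.
#' @return object of class `plane_wave_rf`: `data` array (samples x
#'   elements x angles), `probe`, `provenance`.
#' @export
simulate_rf <- function(phantom, probe = probe_config(), rng_seed = 1L,
                        snr_db = 30,
                        scatterers = NULL,
                        attenuation_mode = c("frequency_dependent",
                                             "center_only")) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(probe, "probe_config"))
  attenuation_mode <- match.arg(attenuation_mode)
  g <- phantom$grid
  aperture <- max(abs(probe$elem_x_mm))
  if (aperture > g$roi_mm[["width"]] / 2 + g$pitch_mm)
    stop("probe/phantom geometry mismatch: aperture exceeds the phantom width")

  if (is.null(scatterers))
    scatterers <- generate_scatterers(phantom, rng_seed,
                                      lambda_mm = probe$c_ref /
                                        probe$center_freq_hz * 1e3)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed + 7L)

  angles <- probe$steering_angles_deg
  rf <- array(0, dim = c(probe$n_samples, probe$n_elements, length(angles)))
  ns <- nrow(scatterers$positions_mm)
  if (ns > 0L) {
    sx <- scatterers$positions_mm[, 1] * 1e-3
    sz <- scatterers$positions_mm[, 2] * 1e-3
    ix <- pmin(pmax(
      as.integer(floor((scatterers$positions_mm[, 1] - g$x_mm[1]) /
                         g$pitch_mm + 1.5)), 1L), g$nx)
    iz <- pmin(pmax(
      as.integer(ceiling(scatterers$positions_mm[, 2] / g$pitch_mm)),
      1L), g$nz)

    # per-column cumulative slowness and attenuation down to each depth
    cum_slow <- apply(1 / phantom$sos_map, 2, cumsum)       # s/m * px
    cum_ac <- apply(phantom$ac_map, 2, cumsum) * (g$pitch_mm / 10)  # dB/MHz
    idx <- cbind(iz, ix)
    c_path <- iz / cum_slow[idx] * 1  # harmonic-mean speed over the column
    ac_cum <- cum_ac[idx]

    f0 <- probe$center_freq_hz
    sig0 <- pulse_sigma_f(probe)
    # Gaussian form factor, amplitude spectrum: exp(-0.827 k^2 d^2 / 8)
    b <- 0.827 * (2 * pi / c_path)^2 * (scatterers$esd_um * 1e-6)^2 / 8
    den <- 1 + 2 * b * sig0^2
    sig1 <- sig0 / sqrt(den)
    f1 <- f0 / den
    amp <- scatterers$amplitudes * exp(-b * f0^2 / den) * (sig1 / sig0)
    # two-way attenuation exp(-a f), a from the cumulative dB/MHz column
    a_att <- log(10) / 20 * 2 * ac_cum * 1e-6               # per Hz
    if (attenuation_mode == "frequency_dependent") {
      amp <- amp * exp(-a_att * f1 + a_att^2 * sig1^2 / 2)
      fc <- f1 - a_att * sig1^2
    } else {
      amp <- amp * exp(-a_att * f0)
      fc <- f1
    }

    elem_x <- probe$elem_x_mm * 1e-3
    for (ai in seq_along(angles)) {
      th <- angles[ai] * pi / 180
      x0 <- if (th >= 0) elem_x[1] else elem_x[probe$n_elements]
      sin_med <- pmin(pmax(c_path * sin(th) / probe$c_ref, -1), 1)
      t_tx <- (sx - x0) * sin(th) / probe$c_ref +
        sz * sqrt(1 - sin_med^2) / c_path
      rf[, , ai] <- cpp_add_echoes(probe$n_samples, probe$sampling_rate_hz,
                                   elem_x, sx, sz, t_tx, c_path,
                                   amp, fc, sig1)
    }
  }

  rms <- sqrt(mean(rf^2))
  noise_sd <- (if (rms > 0) rms else 1) * 10^(-snr_db / 20)
  rf <- rf + stats::rnorm(length(rf), 0, noise_sd)

  structure(list(data = rf, probe = probe,
                 provenance = list(phantom_seed = phantom$seed,
                                   rng_seed = rng_seed, snr_db = snr_db,
                                   n_scatterers = ns,
                                   attenuation_mode = attenuation_mode)),
            class = "plane_wave_rf")
}

#' @export
print.plane_wave_rf <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("plane_wave_rf: %d angles x %d elements x %d samples @ %.1f MHz\n",
              d[3], d[2], d[1], x$probe$sampling_rate_hz / 1e6))
  invisible(x)
}

# analytic signal per channel (FFT Hilbert transform along the first dim)
analytic_signal <- function(rf_array) {
  d <- dim(rf_array)
  n <- d[1]
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  m <- matrix(rf_array, n)
  sp <- stats::mvfft(m) * h
  out <- stats::mvfft(sp, inverse = TRUE) / n
  array(out, d)
}

#' Delay-and-sum beamforming of plane-wave RF
#'
#' Beamforms the analytic channel signals of every steering angle onto a
#' pixel grid at an assumed speed of sound and coherently compounds the
#' angles. The envelope is the magnitude of the compounded analytic
#' image.
#'
#' @param rf a `plane_wave_rf`.
#' @param assumed_c beamforming speed of sound (m/s).
#' @param x_mm,z_mm pixel center coordinates (defaults: 0.2 mm grid over
#'   the aperture and covered depth).
#' @param compound if FALSE, return the per-angle complex images instead.
#' @return for `compound = TRUE`, a list with `envelope` (nz x nx),
#'   `complex`, `x_mm`, `z_mm`; otherwise per-angle complex array
#'   (nz x nx x angles).
#' @export
beamform_das <- function(rf, assumed_c = 1540, x_mm = NULL, z_mm = NULL,
                         compound = TRUE) {
  stopifnot(inherits(rf, "plane_wave_rf"))
  probe <- rf$probe
  if (is.null(x_mm))
    x_mm <- seq(min(probe$elem_x_mm), max(probe$elem_x_mm), by = 0.2)
  if (is.null(z_mm)) {
    zmax <- probe$n_samples / probe$sampling_rate_hz * assumed_c / 2 * 1e3
    z_mm <- seq(0.4, zmax * 0.98, by = 0.2)
  }
  an <- analytic_signal(rf$data)
  angles <- probe$steering_angles_deg * pi / 180
  elem_x <- probe$elem_x_mm * 1e-3
  x0 <- ifelse(angles >= 0, elem_x[1], elem_x[probe$n_elements])
  res <- cpp_das(as.numeric(Re(an)), as.numeric(Im(an)),
                 probe$n_samples, probe$n_elements, length(angles),
                 elem_x, angles, x0, probe$sampling_rate_hz,
                 assumed_c, probe$c_ref, x_mm * 1e-3, z_mm * 1e-3)
  img <- array(complex(real = res$re, imaginary = res$im),
               dim = c(length(z_mm), length(x_mm), length(angles)))
  if (!compound) {
    attr(img, "x_mm") <- x_mm; attr(img, "z_mm") <- z_mm
    return(img)
  }
  comp <- apply(img, c(1, 2), sum)
  list(envelope = Mod(comp), complex = comp, x_mm = x_mm, z_mm = z_mm)
}
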