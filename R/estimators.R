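#' Analysis window grid for spectral QUS estimation
#'
#' @param lateral_mm,depth_mm window spans.
#' @param overlap fractional overlap between neighbouring windows, in
#'   `[0, 1)`.
#' @param z_min_mm,z_max_mm analyzed depth range; `z_max_mm = NULL` uses
#'   the depth covered by the RF record.
#' @return object of class `analysis_windows`.
#' @export
analysis_windows <- function(lateral_mm = 4, depth_mm = 4, overlap = 0.5,
                             z_min_mm = 5, z_max_mm = NULL) {
  stopifnot(lateral_mm > 0, depth_mm > 0, overlap >= 0, overlap < 1)
  structure(list(lateral_mm = lateral_mm, depth_mm = depth_mm,
                 overlap = overlap, z_min_mm = z_min_mm,
                 z_max_mm = z_max_mm),
            class = "analysis_windows")
}

#' Reference acquisition for spectral normalization
#'
#' Simulates RF from a uniform reference phantom of known properties with
#' the given probe; spectral QUS estimators normalize tissue spectra by
#' this reference to cancel the system response, diffraction and
#' depth-gating effects.
#'
#' @param probe a [probe_config()].
#' @param grid phantom grid for the reference (should cover the analyzed
#'   depth).
#' @param ac,sos,esd,esc known reference properties.
#' @param rng_seed seed for the reference speckle realizations.
#' @param snr_db reference acquisition noise level.
#' @param n_frames number of independent speckle realizations; averaging
#'   their spectra reduces the reference-side estimation variance, as
#'   scanning a physical reference phantom at several positions would.
#' @return object of class `qus_reference`: the RF frame(s) plus the
#'   true properties.
#' @export
reference_rf <- function(probe = probe_config(), grid = phantom_grid(),
                         ac = 0.5, sos = 1540, esd = 85, esc = 2,
                         rng_seed = 99L, snr_db = 30, n_frames = 4L) {
  ph <- uniform_phantom(ac = ac, sos = sos, esd = esd, esc = esc,
                        grid = grid)
  frames <- lapply(seq_len(n_frames), function(k)
    simulate_rf(ph, probe, rng_seed = rng_seed + (k - 1L) * 101L,
                snr_db = snr_db))
  structure(list(rf = frames[[1]], frames = frames,
                 ac = ac, sos = sos, esd = esd, esc = esc),
            class = "qus_reference")
}

# spectra of the reference, averaged over its speckle realizations
reference_spectra <- function(reference, windows) {
  sps <- lapply(reference$frames, window_spectra, windows = windows)
  out <- sps[[1]]
  if (length(sps) > 1L) {
    out$power <- Reduce(`+`, lapply(sps, `[[`, "power")) / length(sps)
    out$noise_floor <- Reduce(`+`, lapply(sps, `[[`, "noise_floor")) /
      length(sps)
  }
  out
}

check_reference <- function(rf, reference) {
  stopifnot(inherits(rf, "plane_wave_rf"),
            inherits(reference, "qus_reference"))
  p1 <- rf$probe; p2 <- reference$rf$probe
  same <- isTRUE(all.equal(p1[c("n_elements", "center_freq_hz", "pitch_mm",
                                "sampling_rate_hz", "n_samples")],
                           p2[c("n_elements", "center_freq_hz", "pitch_mm",
                                "sampling_rate_hz", "n_samples")]))
  if (!same) stop("reference probe configuration does not match the RF probe")
  invisible(TRUE)
}

# Per-window power spectra averaged over in-window elements and all
# steering angles (echo gates are shifted per angle by the plane-wave
# transmit geometry).
# Returns list(freq_hz, centers (data.frame x/z), power (n_freq x n_windows)).
window_spectra <- function(rf, windows, nfft = 512L) {
  probe <- rf$probe
  fs <- probe$sampling_rate_hz
  c0 <- probe$c_ref

  step_x <- windows$lateral_mm * (1 - windows$overlap)
  step_z <- windows$depth_mm * (1 - windows$overlap)
  half_ap <- max(probe$elem_x_mm)
  cx <- seq(-half_ap + windows$lateral_mm / 2,
            half_ap - windows$lateral_mm / 2, by = step_x)
  z_rec <- (probe$n_samples / fs) * c0 / 2 * 1e3
  z_hi <- min(windows$z_max_mm %||% Inf, z_rec - windows$depth_mm / 2 - 1)
  cz <- seq(windows$z_min_mm + windows$depth_mm / 2, z_hi, by = step_z)
  if (length(cz) < 3L)
    stop("analysis windows do not fit in the RF record")

  seg_len <- round(windows$depth_mm * 1e-3 * 2 / c0 * fs)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  pad <- matrix(0, nfft - seg_len, 1)
  angles <- probe$steering_angles_deg * pi / 180
  elem_x <- probe$elem_x_mm
  x0 <- ifelse(angles >= 0, elem_x[1], elem_x[probe$n_elements]) * 1e-3

  centers <- expand.grid(z = cz, x = cx)
  pow <- matrix(0, nfft, nrow(centers))
  for (w in seq_len(nrow(centers))) {
    el <- which(abs(elem_x - centers$x[w]) <= windows$lateral_mm / 2)
    z0 <- (centers$z[w] - windows$depth_mm / 2) * 1e-3
    acc <- 0
    for (ai in seq_along(angles)) {
      th <- angles[ai]
      t0 <- (centers$x[w] * 1e-3 - x0[ai]) * sin(th) / c0 +
        z0 * (1 + cos(th)) / c0
      i0 <- round(t0 * fs)
      idx <- i0 + seq_len(seg_len)
      if (idx[1] < 1L || idx[seg_len] > probe$n_samples) next
      seg <- rf$data[idx, el, ai, drop = TRUE] * win
      sp <- stats::mvfft(rbind(seg, pad[, rep(1, length(el)), drop = FALSE]))
      acc <- acc + rowMeans(Mod(sp)^2)
    }
    pow[, w] <- acc
  }
  freq <- (seq_len(nfft) - 1L) / nfft * fs
  # white-noise floor from bins just below Nyquist, outside the pulse band
  nz_bins <- which(freq >= 0.86 * fs / 2 & freq <= 0.98 * fs / 2)
  list(freq_hz = freq, centers = centers, power = pow,
       noise_floor = colMeans(pow[nz_bins, , drop = FALSE]),
       nx = length(cx), nz = length(cz), x = cx, z = cz)
}

# noise-subtracted band power (floored at a small fraction of the floor)
denoise_power <- function(sp, band) {
  p <- sp$power[band, , drop = FALSE]
  fl <- rep(sp$noise_floor, each = length(band))
  pmax(p - fl, 0.02 * fl)
}

# per-window band SNR (linear power ratio over the noise floor)
band_snr <- function(sp, band) {
  colMeans(sp$power[band, , drop = FALSE]) / sp$noise_floor
}

usable_band <- function(probe, sp) {
  f0 <- probe$center_freq_hz
  # usable band: center frequency +/- 40%
  which(sp$freq_hz >= 0.6 * f0 & sp$freq_hz <= 1.4 * f0)
}

#' Attenuation coefficient map by spectral log difference
#'
#' Per analysis window, the band-limited log-spectral difference between
#' tissue and reference acquisitions is regressed on frequency; the depth
#' derivative of that spectral slope, taken over a sliding neighbourhood
#' of windows in the same lateral column, yields the local attenuation
#' coefficient relative to the known reference AC.
#'
#' @param rf tissue `plane_wave_rf`.
#' @param windows an [analysis_windows()].
#' @param reference a [reference_rf()] acquired with an identical probe.
#' @param neighbourhood window rows on each side used for the local depth
#'   regression.
#' @return a [qus_image()] of AC (dB/cm/MHz) on the window-center grid.
#' @export
estimate_ac <- function(rf, windows = analysis_windows(),
                        reference, neighbourhood = 2L) {
  check_reference(rf, reference)
  sp_s <- window_spectra(rf, windows)
  sp_r <- reference_spectra(reference, windows)
  band <- usable_band(rf$probe, sp_s)
  f_mhz <- sp_s$freq_hz[band] / 1e6

  d_db <- 10 * log10(denoise_power(sp_s, band) / denoise_power(sp_r, band))
  # spectral slope (dB/MHz) of the normalized spectrum, per window
  X <- cbind(1, f_mhz)
  slope <- (solve(crossprod(X), crossprod(X, d_db)))[2, ]
  sl <- matrix(slope, sp_s$nz, sp_s$nx)
  # windows whose in-band signal sits near the noise floor carry little
  # attenuation information; down-weight them in the depth regression
  wt <- matrix(pmin(band_snr(sp_s, band) / 4, 1)^2, sp_s$nz, sp_s$nx)

  z_cm <- sp_s$z / 10
  vals <- matrix(NA_real_, sp_s$nz, sp_s$nx)
  for (i in seq_len(sp_s$nz)) {
    rows <- max(1, i - neighbourhood):min(sp_s$nz, i + neighbourhood)
    for (j in seq_len(sp_s$nx)) {
      wj <- wt[rows, j]
      if (sum(wj > 0.01) < 2L) wj <- rep(1, length(rows))
      zc <- z_cm[rows] - sum(wj * z_cm[rows]) / sum(wj)
      # d(slope)/dz = -2 * (AC - AC_ref)
      dz <- sum(wj * zc * sl[rows, j]) / sum(wj * zc^2)
      vals[i, j] <- reference$ac - dz / 2
    }
  }
  qus_image(vals, "AC", sp_s$x, sp_s$z)
}

#' Global speed of sound by multi-angle coherence maximization
#'
#' Beamforms each steering angle separately at candidate speeds and
#' selects the speed maximizing the cross-angle coherence factor of the
#' complex images over a central patch, with parabolic refinement around
#' the discrete peak. Ties break toward the lowest candidate.
#'
#' @param rf a `plane_wave_rf` with at least two steering angles.
#' @param candidate_speeds candidate speeds (m/s), ascending.
#' @param patch_x_mm,patch_z_mm beamformed patch extents.
#' @param pitch_mm patch pixel pitch.
#' @return a 1 x 1 [qus_image()] of SoS; attributes `coherence` (profile
#'   over candidates) and `clamped` (TRUE when the optimum sat on the
#'   search boundary, with a warning).
#' @export
estimate_sos <- function(rf, candidate_speeds = seq(1400, 1650, by = 2),
                         patch_x_mm = c(-12, 12), patch_z_mm = c(8, 30),
                         pitch_mm = 0.4) {
  stopifnot(inherits(rf, "plane_wave_rf"))
  if (length(rf$probe$steering_angles_deg) < 2L)
    stop("SoS requires multiple steering angles")
  candidate_speeds <- sort(candidate_speeds)
  z_rec <- (rf$probe$n_samples / rf$probe$sampling_rate_hz) * 1400 / 2 * 1e3
  x <- seq(patch_x_mm[1], patch_x_mm[2], by = pitch_mm)
  z <- seq(patch_z_mm[1], min(patch_z_mm[2], z_rec * 0.9), by = pitch_mm)

  an <- analytic_signal(rf$data)
  probe <- rf$probe
  angles <- probe$steering_angles_deg * pi / 180
  elem_x <- probe$elem_x_mm * 1e-3
  x0 <- ifelse(angles >= 0, elem_x[1], elem_x[probe$n_elements])
  re <- as.numeric(Re(an)); im <- as.numeric(Im(an))

  coh <- vapply(candidate_speeds, function(cc) {
    res <- cpp_das(re, im, probe$n_samples, probe$n_elements,
                   length(angles), elem_x, angles, x0,
                   probe$sampling_rate_hz, cc, probe$c_ref,
                   x * 1e-3, z * 1e-3)
    img <- array(complex(real = res$re, imaginary = res$im),
                 dim = c(length(z), length(x), length(angles)))
    num <- sum(Mod(apply(img, c(1, 2), sum))^2)
    den <- length(angles) * sum(Mod(img)^2)
    num / den
  }, numeric(1))

  k <- which.max(coh)   # first maximum = lowest candidate on ties
  clamped <- k == 1L || k == length(candidate_speeds)
  if (clamped) {
    warning("speed-of-sound search clamped at the candidate boundary")
    best <- candidate_speeds[k]
  } else {
    # parabolic refinement through the peak and its neighbours
    y <- coh[(k - 1):(k + 1)]
    s <- candidate_speeds[(k - 1):(k + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    best <- if (abs(denom) < 1e-15) s[2] else
      s[2] + 0.5 * (y[1] - y[3]) / denom * (s[3] - s[2])
  }
  out <- qus_image(matrix(best, 1, 1), "SoS", mean(x), mean(z))
  attr(out, "coherence") <- data.frame(speed = candidate_speeds,
                                       coherence = coh)
  attr(out, "clamped") <- clamped
  out
}

#' Effective scatterer diameter and concentration by Gaussian form-factor
#' fit
#'
#' Per analysis window, the log of the reference-normalized backscatter
#' power spectrum is fitted by least squares to
#' `c0 + c2 f^2` over the usable band after attenuation compensation.
#' The quadratic term is the Gaussian form-factor log-ratio
#' `-0.827 k^2 (ESD_s^2 - ESD_r^2) / 4` and yields ESD. ESC is read
#' from envelope statistics: for N scatterers with Gaussian strengths
#' per resolution cell, the beamformed intensity moments obey
#' `E[I^2]/E[I]^2 = 2 + 1/N` independently of the scatterer strength,
#' so the ratio of `1/N` between tissue and the matched reference
#' window — which cancels the resolution-cell geometry — rescales the
#' known reference concentration.
#'
#' Attenuation along the path to each window would otherwise leak into
#' the fit (a term linear in f, nearly collinear with the constant over
#' the usable band); it is compensated beforehand using the
#' spectral-log-difference AC estimate accumulated over depth.
#'
#' @inheritParams estimate_ac
#' @param ac_image optional precomputed [estimate_ac()] result on the
#'   same window grid; computed internally when `NULL`.
#' @param sos_mps optional speed of sound (e.g. from [estimate_sos()])
#'   used to beamform the envelope-statistics image for ESC; the probe
#'   reference speed when `NULL`.
#' @return list of [qus_image()] maps `ESD` (um) and `ESC` (scatterers
#'   per squared wavelength) on the window-center grid, plus
#'   `window_snr`, the per-window in-band SNR.
#' @export
estimate_esd_esc <- function(rf, windows = analysis_windows(), reference,
                             ac_image = NULL, sos_mps = NULL) {
  check_reference(rf, reference)
  sp_s <- window_spectra(rf, windows)
  sp_r <- reference_spectra(reference, windows)
  band <- usable_band(rf$probe, sp_s)
  if (any(sp_s$power[band, ] <= 0) || any(sp_r$power[band, ] <= 0))
    stop("non-positive spectra in the usable band")
  f <- sp_s$freq_hz[band] / 1e6                    # MHz for conditioning

  # mild lateral smoothing of the window power maps (3 columns) trades
  # lateral resolution for form-factor fit variance
  smooth_lat <- function(p) {
    a <- array(p, c(nrow(p), sp_s$nz, sp_s$nx))
    out <- a
    for (j in seq_len(sp_s$nx)) {
      cols <- max(1, j - 1):min(sp_s$nx, j + 1)
      out[, , j] <- apply(a[, , cols, drop = FALSE], c(1, 2), mean)
    }
    matrix(out, nrow(p))
  }
  lnr <- log(smooth_lat(denoise_power(sp_s, band)) /
               smooth_lat(denoise_power(sp_r, band)))

  # two-way attenuation compensation from the SLD attenuation map:
  # the ln-power term is -(ln10/10) * 2 * cum(dAC dz) * f, depth in cm
  if (is.null(ac_image)) ac_image <- estimate_ac(rf, windows, reference)
  step_cm <- (sp_s$z[2] - sp_s$z[1]) / 10
  dac <- ac_image$values - reference$ac
  cum_dac <- apply(dac, 2, cumsum) * step_cm +
    rep((sp_s$z[1] / 10 - step_cm) * dac[1, ], each = sp_s$nz)
  lnr <- lnr + log(10) / 10 * 2 * outer(f, as.numeric(cum_dac))

  X <- cbind(1, f^2)
  b2 <- solve(crossprod(X), crossprod(X, lnr))     # 2 x n_windows

  cc <- rf$probe$c_ref
  kf2 <- 0.827 * (2 * pi * 1e6 / cc)^2 / 4         # ln F = -kf2 f_MHz^2 d^2
  d_ref <- reference$esd * 1e-6
  d2 <- d_ref^2 - b2[2, ] / kf2
  esd <- sqrt(pmax(d2, (10e-6)^2)) * 1e6           # um, floored at 10 um
  # ESC from envelope statistics: scatterer number density is read from
  # the intensity-moment ratio of the beamformed single-angle image
  # (E[I^2]/E[I]^2 = 2 + 1/N for N Gaussian scatterers per resolution
  # cell, independent of scatterer strength); referencing the matched
  # window of the known phantom cancels the resolution-cell geometry.
  esc <- esc_from_envelope(rf, sp_s, reference, sos_mps = sos_mps)
  snr_w <- band_snr(sp_s, band)

  list(ESD = qus_image(matrix(esd, sp_s$nz, sp_s$nx), "ESD", sp_s$x, sp_s$z),
       ESC = qus_image(matrix(esc, sp_s$nz, sp_s$nx), "ESC", sp_s$x, sp_s$z),
       window_snr = matrix(snr_w, sp_s$nz, sp_s$nx))
}

# single-angle beamformed intensity per analysis window
window_intensity_moments <- function(rf, sp, assumed_c) {
  probe <- rf$probe
  ai <- which.min(abs(probe$steering_angles_deg))
  sub <- rf
  sub$data <- rf$data[, , ai, drop = FALSE]
  sub$probe$steering_angles_deg <- probe$steering_angles_deg[ai]
  half_w <- (sp$x[2] - sp$x[1]) / 2
  half_z <- (sp$z[2] - sp$z[1]) / 2
  x_px <- seq(min(sp$x) - half_w, max(sp$x) + half_w, by = 0.2)
  z_px <- seq(min(sp$z) - half_z, max(sp$z) + half_z, by = 0.2)
  img <- beamform_das(sub, assumed_c, x_mm = x_px, z_mm = z_px,
                      compound = FALSE)
  inten <- Mod(img[, , 1])^2
  m1 <- matrix(0, sp$nz, sp$nx); m2 <- matrix(0, sp$nz, sp$nx)
  for (j in seq_len(sp$nx)) for (i in seq_len(sp$nz)) {
    px <- which(abs(x_px - sp$x[j]) <= half_w)
    pz <- which(abs(z_px - sp$z[i]) <= half_z)
    v <- inten[pz, px]
    m1[i, j] <- mean(v); m2[i, j] <- mean(v^2)
  }
  list(m1 = m1, m2 = m2)
}

# effective-scatterer-concentration map from envelope statistics
esc_from_envelope <- function(rf, sp_s, reference, sos_mps = NULL) {
  c_bf <- sos_mps %||% rf$probe$c_ref
  ms <- window_intensity_moments(rf, sp_s, c_bf)
  mr1 <- 0; mr2 <- 0
  for (fr in reference$frames) {
    mm <- window_intensity_moments(fr, sp_s, reference$sos)
    mr1 <- mr1 + mm$m1 / length(reference$frames)
    mr2 <- mr2 + mm$m2 / length(reference$frames)
  }
  r_s <- pmax(ms$m2 / ms$m1^2 - 2, 0.02)      # = 1/N per resolution cell
  r_r <- pmax(mr2 / mr1^2 - 2, 0.02)
  pmin(pmax(reference$esc * r_r / r_s, 1e-3), 50)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
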