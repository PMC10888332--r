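#' Phantom pixel grid
#'
#' Regular grid of pixel centers over the imaging region of interest.
#' Lateral coordinates (`x_mm`) are centered on the probe axis; depth
#' coordinates (`z_mm`) start just below the surface at `pitch/2`.
#'
#' @param pitch_mm pixel pitch in mm.
#' @param nx,nz grid size (lateral x depth). The default 0.2 mm x 256
#'   covers a 51.2 x 51.2 mm region of interest.
#' @return list with `pitch_mm`, `nx`, `nz`, `x_mm`, `z_mm`, `roi_mm`.
#' @export
phantom_grid <- function(pitch_mm = 0.2, nx = 256L, nz = 256L) {
  stopifnot(pitch_mm > 0, nx >= 1L, nz >= 1L)
  list(pitch_mm = pitch_mm, nx = as.integer(nx), nz = as.integer(nz),
       x_mm = (seq_len(nx) - (nx + 1) / 2) * pitch_mm,
       z_mm = (seq_len(nz) - 0.5) * pitch_mm,
       roi_mm = c(width = nx * pitch_mm, depth = nz * pitch_mm))
}

#' Default acoustic property ranges per tissue class
#'
#' Uniform sampling ranges bracketing reported group statistics for
#' breast-tissue-mimicking phantoms: AC in dB/cm/MHz, SoS in m/s, ESD in
#' um, ESC in scatterers per squared wavelength.
#'
#' @return named list: one list per tissue class (`fat`, `gland`, `skin`,
#'   `cyst`, `benign`, `malignant`), each holding `c(lo, hi)` ranges for
#'   `ac`, `sos`, `esd`, `esc`.
#' @export
tissue_property_ranges <- function() {
  bg <- list(ac = c(0.3, 0.8), sos = c(1420, 1580),
             esd = c(80, 110), esc = c(1.2, 4.2))
  list(
    fat = bg, gland = bg, skin = bg,
    cyst = list(ac = c(0.05, 0.2), sos = c(1480, 1540),
                esd = c(80, 110), esc = c(1.2, 4.2)),
    benign = list(ac = c(0.35, 0.65), sos = c(1520, 1560),
                  esd = c(85, 105), esc = c(1.2, 4.2)),
    malignant = list(ac = c(0.6, 1.1), sos = c(1545, 1600),
                     esd = c(70, 92), esc = c(1.2, 4.2)))
}

#' Sample acoustic properties for a tissue class
#'
#' Draws one value per property (AC, SoS, ESD, ESC) uniformly from the
#' class's configured range. Deterministic under a fixed seed.
#'
#' @param tissue_class one of `fat`, `gland`, `skin`, `cyst`, `benign`,
#'   `malignant` (or any class present in `ranges`).
#' @param rng_seed integer seed.
#' @param ranges property range configuration, see
#'   [tissue_property_ranges()].
#' @return named list `ac`, `sos`, `esd`, `esc`.
#' @export
sample_tissue_properties <- function(tissue_class, rng_seed = 1L,
                                     ranges = tissue_property_ranges()) {
  if (!tissue_class %in% names(ranges))
    stop("unknown tissue class: '", tissue_class, "'")
  r <- ranges[[tissue_class]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  u <- stats::runif(4)
  list(ac = r$ac[1] + u[1] * diff(r$ac),
       sos = r$sos[1] + u[2] * diff(r$sos),
       esd = r$esd[1] + u[3] * diff(r$esd),
       esc = r$esc[1] + u[4] * diff(r$esc))
}

#' Lesion geometry and property specification
#'
#' @param shape `"ellipse"` or `"perturbed-polygon"`.
#' @param center_mm lesion center `c(x, z)` in mm (x lateral, z depth).
#' @param axes_mm semi-axes `c(a, b)` in mm; both positive.
#' @param boundary_roughness relative radial perturbation amplitude
#'   (0 = smooth).
#' @param properties named list (`ac`, `sos`, `esd`, `esc`) of lesion
#'   values; `NULL` to sample from the class range at phantom generation.
#' @param class_label `"cyst"`, `"benign"` or `"malignant"`.
#' @param roughness_seed seed for the boundary perturbation so the shape
#'   is a pure function of the spec.
#' @param n_vertices vertex count for the perturbed polygon.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(shape = c("ellipse", "perturbed-polygon"),
                        center_mm, axes_mm, boundary_roughness = 0,
                        properties = NULL, class_label = "benign",
                        roughness_seed = 1L, n_vertices = 12L) {
  shape <- match.arg(shape)
  stopifnot(length(center_mm) == 2L, length(axes_mm) == 2L,
            all(axes_mm > 0), boundary_roughness >= 0,
            class_label %in% c("cyst", "benign", "malignant"))
  structure(list(shape = shape, center_mm = center_mm, axes_mm = axes_mm,
                 boundary_roughness = boundary_roughness,
                 properties = properties, class_label = class_label,
                 roughness_seed = roughness_seed,
                 n_vertices = as.integer(n_vertices)),
            class = "lesion_spec")
}

# radial boundary r(phi) of a lesion in its local polar frame
lesion_radius <- function(spec, phi) {
  a <- spec$axes_mm[1]; b <- spec$axes_mm[2]
  base <- if (spec$shape == "ellipse") {
    a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  } else {
    # polygon with perturbed vertex radii, linearly interpolated in angle
    k <- spec$n_vertices
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$roughness_seed)
    vr <- stats::runif(k, 0.8, 1.2)
    ang <- 2 * pi * (0:k) / k
    vr <- c(vr, vr[1])
    r_mean <- sqrt(a * b)
    stats::approx(ang, vr * r_mean, xout = phi %% (2 * pi))$y
  }
  if (spec$boundary_roughness > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$roughness_seed + 1L)
    # low-order harmonic perturbation keeps the boundary smooth but wavy
    amp <- stats::runif(3, -1, 1)
    pha <- stats::runif(3, 0, 2 * pi)
    mod <- 1 + spec$boundary_roughness *
      (amp[1] * cos(2 * phi + pha[1]) + amp[2] * cos(3 * phi + pha[2]) +
         amp[3] * cos(5 * phi + pha[3])) / sqrt(3)
    base <- base * pmax(mod, 0.1)
  }
  base
}

#' Rasterize a lesion onto a pixel grid
#'
#' Marks the pixels whose centers fall inside the (optionally
#' boundary-perturbed) lesion shape.
#'
#' @param spec a [lesion_spec()].
#' @param grid a [phantom_grid()].
#' @return logical matrix (depth x lateral).
#' @export
rasterize_lesion <- function(spec, grid) {
  stopifnot(inherits(spec, "lesion_spec"))
  dx <- outer(rep(1, grid$nz), grid$x_mm) - spec$center_mm[1]
  dz <- outer(grid$z_mm, rep(1, grid$nx)) - spec$center_mm[2]
  rr <- sqrt(dx^2 + dz^2)
  phi <- atan2(dz, dx)
  mask <- rr <= lesion_radius(spec, phi)
  dim(mask) <- c(grid$nz, grid$nx)
  mask
}

#' Generate a breast-tissue-mimicking phantom
#'
#' Builds co-registered property maps (AC, SoS, density, ESD, ESC) for a
#' layered background (e.g. skin / fat / gland, from the surface down)
#' with an optional embedded lesion. Each layer and the lesion receive
#' class-sampled properties; the result is a pure function of the specs
#' and the seed.
#'
#' @param layers list of `list(class =, thickness_mm =)` entries ordered
#'   from the surface; the last layer extends to the bottom of the grid.
#'   Defaults to 2 mm skin over 8 mm fat over gland.
#' @param lesion a [lesion_spec()] or `NULL`.
#' @param rng_seed integer seed.
#' @param grid a [phantom_grid()].
#' @param ranges class property ranges, see [tissue_property_ranges()].
#' @return object of class `tissue_phantom`: matrices `ac_map`
#'   (dB/cm/MHz), `sos_map` (m/s), `density_map` (kg/m3), `esd_map` (um),
#'   `esc_map` (scatterers per squared wavelength), all depth x lateral;
#'   plus `lesion_mask`, `lesion_class`, `grid`, `seed`.
#' @export
generate_phantom <- function(layers = default_layers(), lesion = NULL,
                             rng_seed = 1L, grid = phantom_grid(),
                             ranges = tissue_property_ranges()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  maps <- lapply(1:5, function(i) matrix(0, grid$nz, grid$nx))
  names(maps) <- c("ac", "sos", "density", "esd", "esc")
  z <- grid$z_mm
  top <- 0
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    bottom <- if (i == length(layers)) Inf else top + ly$thickness_mm
    rows <- which(z >= top & z < bottom)
    if (length(rows) > 0L) {
      pr <- sample_tissue_properties(ly$class, rng_seed + i, ranges)
      maps$ac[rows, ] <- pr$ac
      maps$sos[rows, ] <- pr$sos
      maps$esd[rows, ] <- pr$esd
      maps$esc[rows, ] <- pr$esc
      maps$density[rows, ] <- 1000
    }
    top <- bottom
  }

  mask <- matrix(FALSE, grid$nz, grid$nx)
  lesion_class <- "none"
  if (!is.null(lesion)) {
    half <- grid$roi_mm / 2
    if (abs(lesion$center_mm[1]) + max(lesion$axes_mm) > half["width"] ||
        lesion$center_mm[2] + max(lesion$axes_mm) > grid$roi_mm["depth"] ||
        lesion$center_mm[2] - max(lesion$axes_mm) < 0)
      stop("lesion does not fit inside the region of interest")
    mask <- rasterize_lesion(lesion, grid)
    lesion_class <- lesion$class_label
    pr <- lesion$properties
    if (is.null(pr))
      pr <- sample_tissue_properties(lesion$class_label,
                                     rng_seed + 1000L, ranges)
    maps$ac[mask] <- pr$ac
    maps$sos[mask] <- pr$sos
    maps$esd[mask] <- pr$esd
    maps$esc[mask] <- pr$esc
    set.seed(rng_seed + 2000L)
    # density participates in scattering contrast only; +-5% lesion offset
    maps$density[mask] <- 1000 * (1 + stats::runif(1, -0.05, 0.05))
  }

  ph <- structure(list(ac_map = maps$ac, sos_map = maps$sos,
                       density_map = maps$density, esd_map = maps$esd,
                       esc_map = maps$esc, lesion_mask = mask,
                       lesion_class = lesion_class, grid = grid,
                       seed = rng_seed),
                  class = "tissue_phantom")
  validate_phantom(ph)
}

#' Default layered background: 2 mm skin, 8 mm fat, gland below
#' @return list of layer specs for [generate_phantom()].
#' @export
default_layers <- function() {
  list(list(class = "skin", thickness_mm = 2),
       list(class = "fat", thickness_mm = 8),
       list(class = "gland", thickness_mm = Inf))
}

#' Uniform single-tissue phantom
#'
#' Convenience constructor for estimator calibration and recovery tests:
#' every map is constant.
#'
#' @param ac,sos,esd,esc property values.
#' @param grid a [phantom_grid()].
#' @return a `tissue_phantom`.
#' @export
uniform_phantom <- function(ac = 0.5, sos = 1540, esd = 85, esc = 2,
                            grid = phantom_grid()) {
  m <- function(v) matrix(v, grid$nz, grid$nx)
  ph <- structure(list(ac_map = m(ac), sos_map = m(sos),
                       density_map = m(1000), esd_map = m(esd),
                       esc_map = m(esc),
                       lesion_mask = matrix(FALSE, grid$nz, grid$nx),
                       lesion_class = "none", grid = grid, seed = NA_integer_),
                  class = "tissue_phantom")
  validate_phantom(ph)
}

validate_phantom <- function(ph) {
  stopifnot(inherits(ph, "tissue_phantom"))
  dims <- lapply(ph[c("ac_map", "sos_map", "density_map", "esd_map",
                      "esc_map", "lesion_mask")], dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("property maps must share one grid")
  if (any(ph$ac_map < 0)) stop("ac_map must be non-negative")
  if (any(ph$sos_map < 1300 | ph$sos_map > 1700))
    stop("sos_map must lie within [1300, 1700] m/s")
  if (any(ph$esd_map <= 0) || any(ph$esc_map < 0))
    stop("esd_map must be positive and esc_map non-negative")
  if (xor(ph$lesion_class == "none", !any(ph$lesion_mask)))
    stop("lesion_mask must be empty iff lesion_class is 'none'")
  ph
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("tissue_phantom: %d x %d px @ %.2f mm (%.1f x %.1f mm), lesion: %s\n",
              x$grid$nz, x$grid$nx, x$grid$pitch_mm,
              x$grid$roi_mm["width"], x$grid$roi_mm["depth"],
              x$lesion_class))
  for (nm in c("ac_map", "sos_map", "esd_map", "esc_map"))
    cat(sprintf("  %s: [%.4g, %.4g]\n", nm, min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}
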