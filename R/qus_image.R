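qus_units <- c(AC = "dB/cm/MHz", SoS = "m/s", ESD = "um",
               ESC = "scatterers/wavelength^2")

#' Reconstructed QUS parameter map
#'
#' @param values numeric matrix (depth x lateral) of parameter values.
#' @param parameter one of `"AC"`, `"SoS"`, `"ESD"`, `"ESC"`.
#' @param x_mm,z_mm coordinates of the value grid (mm).
#' @return object of class `qus_image` with a `units` field.
#' @export
qus_image <- function(values, parameter, x_mm, z_mm) {
  parameter <- match.arg(parameter, names(qus_units))
  values <- as.matrix(values)
  stopifnot(all(is.finite(values)), nrow(values) == length(z_mm),
            ncol(values) == length(x_mm))
  structure(list(values = values, parameter = parameter,
                 units = qus_units[[parameter]], x_mm = x_mm, z_mm = z_mm),
            class = "qus_image")
}

#' @export
print.qus_image <- function(x, ...) {
  cat(sprintf("qus_image [%s, %s]: %d x %d, mean %.4g, range [%.4g, %.4g]\n",
              x$parameter, x$units, nrow(x$values), ncol(x$values),
              mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Scalar lesion measurement from QUS maps
#'
#' Averages each reconstructed parameter map over the lesion mask (or the
#' whole map when no mask is given), yielding one cohort-table row.
#'
#' @param images named list with elements `AC`, `SoS`, `ESD`, `ESC`, each
#'   a [qus_image()].
#' @param phantom optional `tissue_phantom` whose lesion mask selects the
#'   averaging region (mask is looked up at each map's own grid).
#' @param id row identifier.
#' @param label lesion label if known.
#' @return one-row data.frame with columns `id`, `ac`, `sos`, `esd`,
#'   `esc`, `label`.
#' @export
lesion_measurement <- function(images, phantom = NULL, id = "lesion",
                               label = NA_character_) {
  val <- function(img) {
    if (is.null(phantom) || !any(phantom$lesion_mask)) return(mean(img$values))
    g <- phantom$grid
    iz <- pmin(pmax(round(img$z_mm / g$pitch_mm + 0.5), 1), g$nz)
    ix <- pmin(pmax(round((img$x_mm - g$x_mm[1]) / g$pitch_mm + 1), 1), g$nx)
    sel <- phantom$lesion_mask[iz, ix, drop = FALSE]
    if (!any(sel)) mean(img$values) else mean(img$values[sel])
  }
  data.frame(id = id, ac = val(images$AC), sos = val(images$SoS),
             esd = val(images$ESD), esc = val(images$ESC), label = label,
             stringsAsFactors = FALSE)
}
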