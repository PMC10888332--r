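# Array/object artifacts are stored as RDS (no HDF5 bindings are
# available in this toolchain); tables as CSV, manifests as JSON, quick
# looks as PNG.

#' Save a matrix-valued map as a PNG quick-look image
#'
#' @param values numeric matrix (depth x lateral).
#' @param path output file.
#' @param main title (e.g. parameter and units).
#' @param db log-compress to this dynamic range (dB) before display;
#'   `NULL` displays linearly.
#' @return `path`, invisibly.
#' @export
export_png <- function(values, path, main = "", db = NULL) {
  v <- values
  if (!is.null(db)) {
    v <- v / max(abs(v))
    v <- pmax(20 * log10(pmax(abs(v), 1e-12)), -db)
  }
  grDevices::png(path, width = 640, height = 640)
  op <- graphics::par(mar = c(2, 2, 3, 6))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  m <- t(v)[, rev(seq_len(nrow(v))), drop = FALSE]
  if (length(m) == 1L) m <- matrix(m[1], 2, 2)   # image() needs >1 cell
  graphics::image(m, col = grDevices::gray(0:255 / 255),
                  axes = FALSE, main = main)
  invisible(path)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
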