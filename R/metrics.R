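#' Mean normalized absolute error
#'
#' Mean absolute error normalized by the dynamic range of the reference.
#'
#' @param pred,ref numeric arrays of identical shape.
#' @return scalar MNAE.
#' @export
mnae <- function(pred, ref) {
  rng <- diff(range(ref))
  if (rng == 0) rng <- 1
  mean(abs(pred - ref)) / rng
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)`.
#'
#' @param pred,ref numeric arrays of identical shape.
#' @param peak signal peak value (dynamic range of the reference by
#'   default).
#' @return PSNR in dB (Inf for identical inputs).
#' @export
psnr <- function(pred, ref, peak = diff(range(ref))) {
  mse <- mean((pred - ref)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index (mean SSIM)
#'
#' Gaussian-window SSIM (11 x 11 window, sigma 1.5, K1 = 0.01,
#' K2 = 0.03), averaged over the map.
#'
#' @param pred,ref numeric matrices of identical shape.
#' @param dynamic_range value range L of the data (reference range by
#'   default).
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(pred, ref, dynamic_range = diff(range(ref))) {
  stopifnot(identical(dim(pred), dim(ref)))
  if (dynamic_range == 0) dynamic_range <- 1
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  g <- outer(stats::dnorm(-5:5, sd = 1.5), stats::dnorm(-5:5, sd = 1.5))
  g <- g / sum(g)
  filt <- function(m) {
    # 'valid' 2-D convolution with the separable-equivalent window
    H <- nrow(m); W <- ncol(m)
    out <- matrix(0, H - 10L, W - 10L)
    for (i in 1:11) for (j in 1:11)
      out <- out + g[i, j] * m[i:(H - 11L + i), j:(W - 11L + j)]
    out
  }
  mu_x <- filt(pred); mu_y <- filt(ref)
  sxx <- filt(pred * pred) - mu_x^2
  syy <- filt(ref * ref) - mu_y^2
  sxy <- filt(pred * ref) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(s)
}
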