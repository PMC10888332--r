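# Minimal dense-linear-algebra neural-network layers for the conditional
# encoder-decoder. Feature maps are stored as matrices of shape
# (H*W*B) x C with rows ordered pixel-fastest, then batch; the spatial
# geometry travels alongside as (H, W, B). All convolutions are realized
# as im2col gathers followed by one BLAS matrix product, and every layer
# implements an explicit backward pass.

fm <- function(x, H, W, B) list(x = x, H = H, W = W, B = B)

# cached im2col gather indices for a (H, W) plane, 3x3 kernel, stride s,
# zero padding 1. Index 0 marks a padded (zero) tap.
im2col_index <- function(H, W, stride) {
  Ho <- as.integer(ceiling(H / stride))
  Wo <- as.integer(ceiling(W / stride))
  oi <- rep(seq_len(Ho), Wo); oj <- rep(seq_len(Wo), each = Ho)
  ci <- (oi - 1L) * stride + 1L; cj <- (oj - 1L) * stride + 1L
  idx <- matrix(0L, Ho * Wo, 9L)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    ii <- ci + di; jj <- cj + dj
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    idx[ok, k] <- ii[ok] + (jj[ok] - 1L) * H
  }
  list(idx = idx, Ho = Ho, Wo = Wo)
}

.im2col_cache <- new.env(parent = emptyenv())
get_im2col <- function(H, W, stride) {
  key <- paste(H, W, stride, sep = "_")
  if (is.null(.im2col_cache[[key]]))
    .im2col_cache[[key]] <- im2col_index(H, W, stride)
  .im2col_cache[[key]]
}

# gather: x (H*W*B x C) -> M ((Ho*Wo*B) x 9C)
im2col <- function(f, stride) {
  ic <- get_im2col(f$H, f$W, stride)
  M <- cpp_im2col(f$x, ic$idx, f$H * f$W, f$B)
  list(M = M, Ho = ic$Ho, Wo = ic$Wo, idx = ic$idx, C = ncol(f$x))
}

# scatter-add transpose of im2col
col2im <- function(dM, col, H, W, B) {
  cpp_col2im(dM, col$idx, H * W, B)
}

he_init <- function(n_in, n_out, rng) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

layer_conv <- function(c_in, c_out, kernel = 3L, stride = 1L,
                       zero_init = FALSE) {
  n_in <- if (kernel == 3L) 9L * c_in else c_in
  W <- if (zero_init) matrix(0, n_in, c_out) else he_init(n_in, c_out)
  list(type = "conv", kernel = kernel, stride = stride,
       params = list(W = W, b = rep(0, c_out)))
}

conv_forward <- function(layer, f) {
  if (layer$kernel == 3L) {
    col <- im2col(f, layer$stride)
    y <- col$M %*% layer$params$W
    y <- sweep_add(y, layer$params$b)
    list(out = fm(y, col$Ho, col$Wo, f$B),
         cache = list(col = col, H = f$H, W = f$W, B = f$B))
  } else {                                   # 1x1 convolution
    y <- f$x %*% layer$params$W
    y <- sweep_add(y, layer$params$b)
    list(out = fm(y, f$H, f$W, f$B), cache = list(x = f$x))
  }
}

conv_backward <- function(layer, cache, dout) {
  if (layer$kernel == 3L) {
    dW <- crossprod(cache$col$M, dout$x)
    db <- colSums(dout$x)
    dM <- tcrossprod(dout$x, layer$params$W)
    dx <- col2im(dM, cache$col, cache$H, cache$W, cache$B)
    list(dx = fm(dx, cache$H, cache$W, dout$B),
         grads = list(W = dW, b = db))
  } else {
    dW <- crossprod(cache$x, dout$x)
    db <- colSums(dout$x)
    dx <- tcrossprod(dout$x, layer$params$W)
    list(dx = fm(dx, dout$H, dout$W, dout$B),
         grads = list(W = dW, b = db))
  }
}

sweep_add <- function(m, v) m + rep(v, each = nrow(m))

# Conditional instance normalization: per-channel statistics per
# instance; the affine scale/shift pair is selected per instance by its
# condition index (gamma/beta tables are n_cond x C).
layer_cin <- function(c_out, n_cond = 4L, eps = 1e-5) {
  # small per-condition jitter breaks the symmetry between conditions so
  # the one-hot input is behaviorally active from the first step
  list(type = "cin", eps = eps,
       params = list(
         gamma = matrix(1 + stats::rnorm(n_cond * c_out, 0, 0.05),
                        n_cond, c_out),
         beta = matrix(stats::rnorm(n_cond * c_out, 0, 0.02),
                       n_cond, c_out)))
}

cin_forward <- function(layer, f, cond) {
  HW <- f$H * f$W; C <- ncol(f$x)
  xa <- array(f$x, c(HW, f$B, C))
  mu <- colMeans(xa)                          # B x C
  xc <- xa - rep(mu, each = HW)
  v <- colMeans(xc * xc)                      # population variance, B x C
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- xc * rep(inv_sd, each = HW)
  g <- layer$params$gamma[cond, , drop = FALSE]   # B x C
  b <- layer$params$beta[cond, , drop = FALSE]
  y <- xhat * rep(g, each = HW) + rep(b, each = HW)
  list(out = fm(matrix(y, HW * f$B, C), f$H, f$W, f$B),
       cache = list(xhat = xhat, inv_sd = inv_sd, cond = cond, HW = HW,
                    B = f$B, C = C))
}

cin_backward <- function(layer, cache, dout) {
  HW <- cache$HW; B <- cache$B; C <- cache$C
  dya <- array(dout$x, c(HW, B, C))
  g <- layer$params$gamma[cache$cond, , drop = FALSE]
  dgamma_inst <- colSums(dya * cache$xhat)    # B x C
  dbeta_inst <- colSums(dya)                  # B x C
  n_cond <- nrow(layer$params$gamma)
  dgamma <- matrix(0, n_cond, C); dbeta <- matrix(0, n_cond, C)
  for (cc in unique(cache$cond)) {
    rows <- which(cache$cond == cc)
    dgamma[cc, ] <- colSums(dgamma_inst[rows, , drop = FALSE])
    dbeta[cc, ] <- colSums(dbeta_inst[rows, , drop = FALSE])
  }
  dxhat <- dya * rep(g, each = HW)
  m1 <- colMeans(dxhat)                       # B x C
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- (dxhat - rep(m1, each = HW) -
           cache$xhat * rep(m2, each = HW)) * rep(cache$inv_sd, each = HW)
  list(dx = fm(matrix(dx, HW * B, C), dout$H, dout$W, B),
       grads = list(gamma = dgamma, beta = dbeta))
}

relu_forward <- function(f) {
  m <- f$x > 0
  f$x <- f$x * m
  list(out = f, cache = m)
}
relu_backward <- function(cache, dout) {
  dout$x <- dout$x * cache
  dout
}

dropout_forward <- function(f, keep, training, rng_stream) {
  if (!training || keep >= 1) return(list(out = f, cache = NULL))
  mask <- (matrix(stats::runif(length(f$x)), nrow(f$x)) < keep) / keep
  f$x <- f$x * mask
  list(out = f, cache = mask)
}
dropout_backward <- function(cache, dout) {
  if (!is.null(cache)) dout$x <- dout$x * cache
  dout
}

# nearest-neighbour upsampling by an integer factor
upsample_index <- function(H, W, r) {
  Ho <- H * r; Wo <- W * r
  oi <- rep(seq_len(Ho), Wo); oj <- rep(seq_len(Wo), each = Ho)
  ((oi - 1L) %/% r + 1L) + ((oj - 1L) %/% r) * H
}
.up_cache <- new.env(parent = emptyenv())
get_upsample <- function(H, W, r) {
  key <- paste(H, W, r, sep = "_")
  if (is.null(.up_cache[[key]]))
    .up_cache[[key]] <- upsample_index(H, W, r)
  .up_cache[[key]]
}

upsample_forward <- function(f, r) {
  if (r == 1L) return(list(out = f, cache = NULL))
  idx <- get_upsample(f$H, f$W, r)
  y <- cpp_gather_rows(f$x, idx, f$H * f$W, f$B)
  list(out = fm(y, f$H * r, f$W * r, f$B),
       cache = list(H = f$H, W = f$W, r = r))
}
upsample_backward <- function(cache, dout) {
  if (is.null(cache)) return(dout)
  idx <- get_upsample(cache$H, cache$W, cache$r)
  fm(cpp_scatter_rows(dout$x, idx, cache$H * cache$W, dout$B),
     cache$H, cache$W, dout$B)
}

# block-average downsampling (used for auxiliary-resolution targets)
avg_pool_map <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  Ho <- H %/% r; Wo <- W %/% r
  a <- array(m[seq_len(Ho * r), seq_len(Wo * r)], c(r, Ho, r, Wo))
  apply(a, c(2, 4), mean)
}
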