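#' Conditional encoder-decoder network configuration
#'
#' The reconstruction network maps multi-angle plane-wave input planes to
#' one QUS parameter map, selected by a one-hot condition vector through
#' conditional instance normalization. The encoder compresses the input
#' to a 16 x 16 spatial latent; the decoder is a parallel
#' multi-resolution bank of residual subnetworks producing auxiliary
#' outputs at 16, 32, 64 and 128 pixels, whose feature maps are
#' upsampled, concatenated and fused by a bottleneck convolution into the
#' final 128 x 128 map.
#'
#' @param in_channels input planes (one per steering angle by default).
#' @param scale `"desk"` (64-channel latent) or `"full"` (512-channel
#'   latent, the published scale).
#' @param enc_channels,dec_channels per-stage channel widths; defaults
#'   depend on `scale`.
#' @param input_size input spatial size (must reduce to 16 by the
#'   stride-2 encoder stages).
#' @param dropout_keep retention probability of latent dropout during
#'   training.
#' @param eps instance-normalization stabilizer.
#' @param lambda_l2 L2 penalty on convolution weights.
#' @param lr,beta1,beta2 Adam hyperparameters. The published learning
#'   rate 1e-4 is tied to the full-scale regime (15.5k samples, ~230k
#'   optimizer steps); since Adam moves each parameter by about `lr` per
#'   step, a desk run of a few hundred steps needs a proportionally
#'   larger step, so the desk default is 3e-3 (`lr = NULL` selects by
#'   scale).
#' @param batch_size training batch size.
#' @param max_epochs,patience epoch cap and early-stopping patience on
#'   validation loss.
#' @return list of class `qus_net_config`.
#' @export
qus_net_config <- function(in_channels = 5L, scale = c("desk", "full"),
                           enc_channels = NULL, dec_channels = NULL,
                           input_size = 128L, dropout_keep = 0.5,
                           eps = 1e-5, lambda_l2 = 1e-4, lr = NULL,
                           beta1 = 0.9, beta2 = 0.999, batch_size = 8L,
                           max_epochs = 120L, patience = 10L) {
  scale <- match.arg(scale)
  if (is.null(lr)) lr <- if (scale == "desk") 3e-3 else 1e-4
  if (is.null(enc_channels))
    enc_channels <- if (scale == "desk") c(16L, 32L, 64L) else
      c(128L, 256L, 512L)
  if (is.null(dec_channels))
    dec_channels <- if (scale == "desk") c(24L, 12L, 8L, 6L) else
      c(256L, 128L, 64L, 32L)
  n_stages <- length(enc_channels)
  stopifnot(input_size / 2^n_stages == 16L, length(dec_channels) == 4L,
            dropout_keep > 0, dropout_keep <= 1)
  structure(list(in_channels = as.integer(in_channels), scale = scale,
                 enc_channels = enc_channels, dec_channels = dec_channels,
                 resolutions = c(16L, 32L, 64L, 128L),
                 input_size = as.integer(input_size),
                 dropout_keep = dropout_keep, eps = eps,
                 lambda_l2 = lambda_l2, lr = lr, beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "qus_net_config")
}

#' One-hot condition vector for a QUS parameter
#'
#' Parameter order (AC, SoS, ESD, ESC): AC is `c(1,0,0,0)`.
#'
#' @param parameter `"AC"`, `"SoS"`, `"ESD"` or `"ESC"`, or an index 1-4.
#' @return list with `one_hot` (length-4 0/1 vector) and `index`.
#' @export
condition_vector <- function(parameter) {
  pars <- c("AC", "SoS", "ESD", "ESC")
  idx <- if (is.numeric(parameter)) as.integer(parameter) else
    match(match.arg(parameter, pars), pars)
  if (is.na(idx) || idx < 1L || idx > 4L)
    stop("malformed condition: ", parameter)
  oh <- integer(4); oh[idx] <- 1L
  list(one_hot = oh, index = idx, parameter = pars[idx])
}

cond_index <- function(cond) {
  if (is.list(cond) && !is.null(cond$index)) return(cond$index)
  if (is.numeric(cond) && length(cond) == 4L) {
    if (sum(cond) != 1L || !all(cond %in% c(0, 1)))
      stop("malformed condition vector: must be one-hot")
    return(which(cond == 1L))
  }
  condition_vector(cond)$index
}

# ---- network construction ------------------------------------------------

init_qus_net <- function(config, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  enc <- list()
  c_prev <- config$in_channels
  for (i in seq_along(config$enc_channels)) {
    c_out <- config$enc_channels[i]
    enc[[i]] <- list(conv = layer_conv(c_prev, c_out, 3L, 2L),
                     cin = layer_cin(c_out, eps = config$eps))
    c_prev <- c_out
  }
  dec <- list()
  for (r in seq_along(config$resolutions)) {
    cd <- config$dec_channels[r]
    dec[[r]] <- list(
      head = layer_conv(c_prev, cd, 1L),
      head_cin = layer_cin(cd, eps = config$eps),
      res1 = layer_conv(cd, cd, 3L, 1L),
      res_cin = layer_cin(cd, eps = config$eps),
      res2 = layer_conv(cd, cd, 3L, 1L, zero_init = TRUE),
      aux = layer_conv(cd, 1L, 1L))
  }
  # conditional normalization of the fused features feeds the bottleneck
  # directly (no rectifier in between), so a condition can invert the
  # contrast of a shared spatial feature via the sign of its gamma row
  fuse_cin <- layer_cin(sum(config$dec_channels), eps = config$eps)
  bottleneck <- layer_conv(sum(config$dec_channels), 1L, 1L)
  list(config = config, encoder = enc, decoder = dec,
       fuse_cin = fuse_cin, bottleneck = bottleneck)
}

# forward pass; cond is a vector of condition indices, one per sample
qus_net_forward <- function(net, x, cond, training = FALSE) {
  cfg <- net$config
  caches <- list(enc = list(), dec = list())
  f <- x
  for (i in seq_along(net$encoder)) {
    st <- net$encoder[[i]]
    cv <- conv_forward(st$conv, f)
    cn <- cin_forward(st$cin, cv$out, cond)
    rl <- relu_forward(cn$out)
    caches$enc[[i]] <- list(conv = cv$cache, cin = cn$cache, relu = rl$cache)
    f <- rl$out
  }
  dp <- dropout_forward(f, cfg$dropout_keep, training)
  caches$dropout <- dp$cache
  latent <- dp$out

  aux <- list(); feats <- list()
  for (r in seq_along(net$decoder)) {
    br <- net$decoder[[r]]
    hd <- conv_forward(br$head, latent)
    hc <- cin_forward(br$head_cin, hd$out, cond)
    hr <- relu_forward(hc$out)
    up <- upsample_forward(hr$out, cfg$resolutions[r] %/% 16L)
    r1 <- conv_forward(br$res1, up$out)
    rc <- cin_forward(br$res_cin, r1$out, cond)
    rr <- relu_forward(rc$out)
    r2 <- conv_forward(br$res2, rr$out)
    skip <- r2$out; skip$x <- skip$x + up$out$x      # residual connection
    sr <- relu_forward(skip)
    ax <- conv_forward(br$aux, sr$out)
    fu <- upsample_forward(sr$out, 128L %/% cfg$resolutions[r])
    caches$dec[[r]] <- list(head = hd$cache, head_cin = hc$cache,
                            head_relu = hr$cache, up = up$cache,
                            res1 = r1$cache, res_cin = rc$cache,
                            res_relu = rr$cache, res2 = r2$cache,
                            skip_relu = sr$cache, aux = ax$cache,
                            fuse_up = fu$cache)
    aux[[r]] <- ax$out
    feats[[r]] <- fu$out
  }
  cat_x <- do.call(cbind, lapply(feats, `[[`, "x"))
  cat_f <- fm(cat_x, 128L, 128L, latent$B)
  fc <- cin_forward(net$fuse_cin, cat_f, cond)
  caches$fuse_cin <- fc$cache
  bn <- conv_forward(net$bottleneck, fc$out)
  caches$bottleneck <- bn$cache
  caches$dec_widths <- vapply(feats, function(f) ncol(f$x), integer(1))
  list(final = bn$out, aux = aux, latent = latent, caches = caches)
}

# backward pass from gradients on the final and auxiliary outputs;
# returns gradients in the same tree shape as the network parameters
qus_net_backward <- function(net, fw, d_final, d_aux, cond) {
  cfg <- net$config
  grads <- list(encoder = list(), decoder = list())
  bn_bw <- conv_backward(net$bottleneck, fw$caches$bottleneck, d_final)
  grads$bottleneck <- bn_bw$grads
  fc_bw <- cin_backward(net$fuse_cin, fw$caches$fuse_cin, bn_bw$dx)
  grads$fuse_cin <- fc_bw$grads
  d_cat <- fc_bw$dx

  widths <- fw$caches$dec_widths
  col0 <- cumsum(c(0L, widths))
  B <- d_final$B
  d_latent_acc <- NULL
  for (r in seq_along(net$decoder)) {
    br <- net$decoder[[r]]
    ch <- fw$caches$dec[[r]]
    d_feat <- fm(d_cat$x[, (col0[r] + 1L):col0[r + 1L], drop = FALSE],
                 128L, 128L, B)
    d_sr <- upsample_backward(ch$fuse_up, d_feat)
    ax_bw <- conv_backward(br$aux, ch$aux, d_aux[[r]])
    d_sr$x <- d_sr$x + ax_bw$dx$x
    d_skip <- relu_backward(ch$skip_relu, d_sr)
    r2_bw <- conv_backward(br$res2, ch$res2, d_skip)
    d_rr <- relu_backward(ch$res_relu, r2_bw$dx)
    rc_bw <- cin_backward(br$res_cin, ch$res_cin, d_rr)
    r1_bw <- conv_backward(br$res1, ch$res1, rc_bw$dx)
    d_up <- r1_bw$dx; d_up$x <- d_up$x + d_skip$x    # residual skip path
    d_hr <- upsample_backward(ch$up, d_up)
    d_hc <- relu_backward(ch$head_relu, d_hr)
    hc_bw <- cin_backward(br$head_cin, ch$head_cin, d_hc)
    hd_bw <- conv_backward(br$head, ch$head, hc_bw$dx)
    grads$decoder[[r]] <- list(head = hd_bw$grads, head_cin = hc_bw$grads,
                               res1 = r1_bw$grads, res_cin = rc_bw$grads,
                               res2 = r2_bw$grads, aux = ax_bw$grads)
    d_latent_acc <- if (is.null(d_latent_acc)) hd_bw$dx$x else
      d_latent_acc + hd_bw$dx$x
  }
  d_latent <- fm(d_latent_acc, 16L, 16L, B)
  d_latent <- dropout_backward(fw$caches$dropout, d_latent)

  d <- d_latent
  for (i in rev(seq_along(net$encoder))) {
    st <- net$encoder[[i]]
    ch <- fw$caches$enc[[i]]
    d <- relu_backward(ch$relu, d)
    cn_bw <- cin_backward(st$cin, ch$cin, d)
    cv_bw <- conv_backward(st$conv, ch$conv, cn_bw$dx)
    grads$encoder[[i]] <- list(conv = cv_bw$grads, cin = cn_bw$grads)
    d <- cv_bw$dx
  }
  grads
}

#' Conditional instance normalization
#'
#' Normalizes each channel of each instance to zero mean and unit
#' standard deviation, then applies the scale and shift selected by the
#' condition: `gamma_cond * (x - mu(x)) / sigma(x) + beta_cond`, with an
#' epsilon stabilizer inside the square root.
#'
#' @param x numeric array `H x W x C` (single instance) or a matrix
#'   treated as one channel.
#' @param cond condition: a [condition_vector()], one-hot vector,
#'   parameter name, or index 1-4.
#' @param gamma_table,beta_table `n_cond x C` parameter tables.
#' @param eps stabilizer added to the variance.
#' @return array of the same shape as `x`.
#' @export
conditional_instance_norm <- function(x, cond, gamma_table, beta_table,
                                      eps = 1e-5) {
  ci <- cond_index(cond)
  dims <- dim(x) %||% c(length(x), 1L, 1L)
  if (length(dims) == 2L) dims <- c(dims, 1L)
  a <- array(x, dims)
  C <- dims[3]
  stopifnot(ncol(gamma_table) == C, ncol(beta_table) == C,
            ci <= nrow(gamma_table))
  for (cc in seq_len(C)) {
    v <- a[, , cc]
    mu <- mean(v)
    sd_ <- sqrt(mean((v - mu)^2) + eps)
    a[, , cc] <- gamma_table[ci, cc] * (v - mu) / sd_ + beta_table[ci, cc]
  }
  if (is.null(dim(x))) as.numeric(a) else array(a, dim(x))
}

# ---- loss ----------------------------------------------------------------

conv_weights <- function(net) {
  out <- list(net$bottleneck$params$W)
  for (st in net$encoder) out <- c(out, list(st$conv$params$W))
  for (br in net$decoder)
    out <- c(out, list(br$head$params$W, br$res1$params$W,
                       br$res2$params$W, br$aux$params$W))
  out
}

#' Training loss of the reconstruction network
#'
#' `loss = ||y - y_hat||^2 + L_R + L2` where the main term is the summed
#' squared error of the final prediction, `L_R` sums the squared errors
#' of the per-resolution auxiliary outputs against average-pooled
#' targets, and `L2 = lambda * sum(w^2)` over convolution weights.
#'
#' @param final_pred numeric matrix/vector, final 128 x 128 prediction.
#' @param aux_preds list of auxiliary predictions (16, 32, 64, 128).
#' @param target ground-truth map.
#' @param aux_targets list of downsampled ground-truth maps.
#' @param conv_w list of convolution weight matrices (for the L2 term);
#'   may be empty.
#' @param lambda_l2 L2 coefficient.
#' @return list with `total`, `main`, `lr` (auxiliary term), `l2`.
#' @export
loss_qi <- function(final_pred, aux_preds, target, aux_targets,
                    conv_w = list(), lambda_l2 = 0) {
  if (length(final_pred) != length(target))
    stop("prediction/target shape mismatch")
  main <- sum((final_pred - target)^2)
  lr <- 0
  for (r in seq_along(aux_preds)) {
    if (length(aux_preds[[r]]) != length(aux_targets[[r]]))
      stop("auxiliary prediction/target shape mismatch at resolution ", r)
    lr <- lr + sum((aux_preds[[r]] - aux_targets[[r]])^2)
  }
  l2 <- lambda_l2 * sum(vapply(conv_w, function(w) sum(w^2), numeric(1)))
  list(total = main + lr + l2, main = main, lr = lr, l2 = l2)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(net) {
  walk <- function(p) lapply(p, function(q)
    if (is.list(q)) walk(q) else array(0, dim(q) %||% length(q)))
  tree <- net_param_tree(net)
  list(m = walk(tree), v = walk(tree), t = 0L)
}

net_param_tree <- function(net) {
  list(encoder = lapply(net$encoder, function(st)
         list(conv = st$conv$params, cin = st$cin$params)),
       decoder = lapply(net$decoder, function(br)
         list(head = br$head$params, head_cin = br$head_cin$params,
              res1 = br$res1$params, res_cin = br$res_cin$params,
              res2 = br$res2$params, aux = br$aux$params)),
       fuse_cin = net$fuse_cin$params,
       bottleneck = net$bottleneck$params)
}

net_set_params <- function(net, tree) {
  for (i in seq_along(net$encoder)) {
    net$encoder[[i]]$conv$params <- tree$encoder[[i]]$conv
    net$encoder[[i]]$cin$params <- tree$encoder[[i]]$cin
  }
  for (r in seq_along(net$decoder)) {
    net$decoder[[r]]$head$params <- tree$decoder[[r]]$head
    net$decoder[[r]]$head_cin$params <- tree$decoder[[r]]$head_cin
    net$decoder[[r]]$res1$params <- tree$decoder[[r]]$res1
    net$decoder[[r]]$res_cin$params <- tree$decoder[[r]]$res_cin
    net$decoder[[r]]$res2$params <- tree$decoder[[r]]$res2
    net$decoder[[r]]$aux$params <- tree$decoder[[r]]$aux
  }
  net$fuse_cin$params <- tree$fuse_cin
  net$bottleneck$params <- tree$bottleneck
  net
}

# map gradient tree (same shape as params, but cin grads named
# gamma/beta under $cin etc.) onto the parameter tree layout
grads_as_tree <- function(grads) {
  list(encoder = lapply(grads$encoder, function(g)
         list(conv = g$conv, cin = g$cin)),
       decoder = lapply(grads$decoder, function(g)
         list(head = g$head, head_cin = g$head_cin, res1 = g$res1,
              res_cin = g$res_cin, res2 = g$res2, aux = g$aux)),
       fuse_cin = grads$fuse_cin,
       bottleneck = grads$bottleneck)
}

adam_step <- function(params, grads, state, lr, beta1, beta2,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {        # positional: stage lists are unnamed
        r <- rec(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else upd(p, g, m, v)
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
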