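#' Train/test split with the published ratio
#'
#' The published design splits 16,500 simulated acquisitions into 15,500
#' training and 1,000 held-out samples; the held-out fraction is
#' therefore 1/16.5 of the dataset.
#'
#' @param n total sample count.
#' @param seed shuffle seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(n, seed = 1L) {
  stopifnot(n >= 2L)
  n_test <- max(1L, round(n / 16.5))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n - n_test)]),
       test = sort(perm[(n - n_test + 1L):n]))
}

# stack a list of samples into batch tensors; each sample is
# list(input = H x W x C array, cond = index 1..4, target = 128 x 128)
make_batch <- function(dataset, idx) {
  s1 <- dataset[[idx[1]]]
  H <- dim(s1$input)[1]; W <- dim(s1$input)[2]; C <- dim(s1$input)[3]
  B <- length(idx)
  x <- matrix(0, H * W * B, C)
  targ <- matrix(0, 128L * 128L * B, 1L)
  cond <- integer(B)
  for (b in seq_along(idx)) {
    s <- dataset[[idx[b]]]
    rows <- (b - 1L) * H * W + seq_len(H * W)
    x[rows, ] <- matrix(s$input, H * W, C)
    targ[(b - 1L) * 128L * 128L + seq_len(128L * 128L), 1L] <-
      as.numeric(s$target)
    cond[b] <- cond_index(s$cond)
  }
  list(x = fm(x, H, W, B), target = targ, cond = cond)
}

batch_aux_targets <- function(dataset, idx, resolutions) {
  lapply(resolutions, function(R) {
    r <- 128L %/% R
    m <- lapply(idx, function(i)
      as.numeric(avg_pool_map(dataset[[i]]$target, r)))
    matrix(unlist(m), ncol = 1L)
  })
}

batch_loss_and_grads <- function(net, batch, aux_t, training = TRUE) {
  fw <- qus_net_forward(net, batch$x, batch$cond, training = training)
  lo <- loss_qi(fw$final$x, lapply(fw$aux, `[[`, "x"), batch$target,
                aux_t, conv_weights(net), net$config$lambda_l2)
  if (!training) return(list(loss = lo, fw = fw))
  d_final <- fw$final
  d_final$x <- 2 * (fw$final$x - batch$target)
  d_aux <- lapply(seq_along(fw$aux), function(r) {
    d <- fw$aux[[r]]
    d$x <- 2 * (fw$aux[[r]]$x - aux_t[[r]])
    d
  })
  grads <- qus_net_backward(net, fw, d_final, d_aux, batch$cond)
  # L2 gradient on convolution weights
  lam <- net$config$lambda_l2
  if (lam > 0) {
    add_l2 <- function(g, p) { g$W <- g$W + 2 * lam * p$W; g }
    for (i in seq_along(net$encoder))
      grads$encoder[[i]]$conv <- add_l2(grads$encoder[[i]]$conv,
                                        net$encoder[[i]]$conv$params)
    for (r in seq_along(net$decoder)) {
      grads$decoder[[r]]$head <- add_l2(grads$decoder[[r]]$head,
                                        net$decoder[[r]]$head$params)
      grads$decoder[[r]]$res1 <- add_l2(grads$decoder[[r]]$res1,
                                        net$decoder[[r]]$res1$params)
      grads$decoder[[r]]$res2 <- add_l2(grads$decoder[[r]]$res2,
                                        net$decoder[[r]]$res2$params)
      grads$decoder[[r]]$aux <- add_l2(grads$decoder[[r]]$aux,
                                       net$decoder[[r]]$aux$params)
    }
    grads$bottleneck <- add_l2(grads$bottleneck, net$bottleneck$params)
  }
  list(loss = lo, fw = fw, grads = grads)
}

#' Train the conditional encoder-decoder on a QUS dataset
#'
#' Mini-batch Adam optimization of [loss_qi()]: the dataset is split
#' with the published train/test ratio, batches of `batch_size` are
#' drawn each epoch, dropout (retention `dropout_keep`) is applied to
#' the latent, and training stops at `max_epochs` or when the
#' validation loss has not improved for `patience` epochs. Validation
#' MNAE, PSNR and SSIM are recorded every epoch.
#'
#' @param dataset list of samples, each
#'   `list(input = H x W x C array, cond = parameter/one-hot/index,
#'   target = 128 x 128 matrix)`.
#' @param config a [qus_net_config()].
#' @param seed RNG seed governing initialization, split, shuffling and
#'   dropout.
#' @param epochs optional epoch cap below `config$max_epochs`.
#' @param verbose print per-epoch progress.
#' @return object of class `qus_train_state`: the trained `net`,
#'   `history` data.frame (epoch, train_loss, val_loss, mnae, psnr,
#'   ssim), `split`, `config`, `seed`.
#' @export
train_qus <- function(dataset, config = qus_net_config(), seed = 1L,
                      epochs = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  n_epochs <- min(config$max_epochs, epochs %||% config$max_epochs)
  net <- init_qus_net(config, seed)
  opt <- adam_init(net)
  sp <- split_dataset(length(dataset), seed)
  if (length(sp$train) < config$batch_size)
    stop("dataset too small for one batch")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)

  val_aux <- batch_aux_targets(dataset, sp$test, config$resolutions)
  val_batch <- make_batch(dataset, sp$test)
  hist <- NULL
  best_val <- Inf; best_tree <- NULL; stall <- 0L
  for (ep in seq_len(n_epochs)) {
    ord <- sample(sp$train)
    n_b <- floor(length(ord) / config$batch_size)
    tr_loss <- 0
    for (bi in seq_len(n_b)) {
      idx <- ord[(bi - 1L) * config$batch_size + seq_len(config$batch_size)]
      batch <- make_batch(dataset, idx)
      aux_t <- batch_aux_targets(dataset, idx, config$resolutions)
      res <- batch_loss_and_grads(net, batch, aux_t, training = TRUE)
      tr_loss <- tr_loss + res$loss$total
      st <- adam_step(net_param_tree(net), grads_as_tree(res$grads), opt,
                      config$lr, config$beta1, config$beta2)
      net <- net_set_params(net, st$params)
      opt <- st$state
    }
    tr_loss <- tr_loss / (n_b * config$batch_size)

    vres <- batch_loss_and_grads(net, val_batch, val_aux, training = FALSE)
    vB <- length(sp$test)
    v_pred <- matrix(vres$fw$final$x, 128L * 128L, vB)
    v_true <- matrix(val_batch$target, 128L * 128L, vB)
    v_mnae <- mean(vapply(seq_len(vB), function(b)
      mnae(v_pred[, b], v_true[, b]), numeric(1)))
    v_psnr <- mean(vapply(seq_len(vB), function(b)
      psnr(v_pred[, b], v_true[, b]), numeric(1)))
    v_ssim <- mean(vapply(seq_len(vB), function(b)
      ssim(matrix(v_pred[, b], 128L), matrix(v_true[, b], 128L)),
      numeric(1)))
    v_loss <- vres$loss$total / vB
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = v_loss, mnae = v_mnae,
                                   psnr = v_psnr, ssim = v_ssim))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  mnae %.4f", ep,
                      tr_loss, v_loss, v_mnae))
    if (v_loss < best_val - 1e-12) {
      best_val <- v_loss; best_tree <- net_param_tree(net); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  if (!is.null(best_tree)) net <- net_set_params(net, best_tree)
  structure(list(net = net, history = hist, split = sp, config = config,
                 seed = seed),
            class = "qus_train_state")
}

#' @export
print.qus_train_state <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "qus_train_state: %d epochs, final train loss %.4f, val loss %.4f (mnae %.4f)\n",
    nrow(h), h$train_loss[nrow(h)], h$val_loss[nrow(h)], h$mnae[nrow(h)]))
  invisible(x)
}

#' Predict a QUS parameter map with a trained network
#'
#' One call reconstructs one parameter map; running the four conditions
#' reconstructs the full QUS profile.
#'
#' @param input either a `plane_wave_rf` (converted with
#'   [rf_to_input()]) or a prepared `H x W x C` input array.
#' @param cond condition (parameter name, one-hot vector or index).
#' @param state a [train_qus()] result.
#' @param denormalize optional `c(lo, hi)` range mapping the network's
#'   normalized output back to physical units.
#' @return 128 x 128 matrix (a [qus_image()] when `denormalize` and a
#'   parameter name are given).
#' @export
predict_qus <- function(input, cond, state, denormalize = NULL) {
  if (!inherits(state, "qus_train_state"))
    stop("untrained state: pass the result of train_qus()")
  if (inherits(input, "plane_wave_rf"))
    input <- rf_to_input(input, state$config$input_size)
  H <- dim(input)[1]; W <- dim(input)[2]; C <- dim(input)[3]
  f <- fm(matrix(input, H * W, C), H, W, 1L)
  ci <- cond_index(cond)
  fw <- qus_net_forward(state$net, f, ci, training = FALSE)
  out <- matrix(fw$final$x, 128L, 128L)
  if (!is.null(denormalize))
    out <- denormalize[1] + out * (denormalize[2] - denormalize[1])
  out
}
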