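#' Mann-Whitney U test
#'
#' Two-sided rank-sum test comparing two independent groups. The statistic
#' reported is U for `group_a` (number of (a, b) pairs with a ranked above
#' b, counting ties as 1/2). Exact p-values are used for small untied
#' samples; the tie-corrected normal approximation otherwise, matching
#' common statistical-package behaviour.
#'
#' @param group_a,group_b numeric vectors.
#' @param exact_limit use the exact distribution when both groups have at
#'   most this many observations and there are no ties.
#' @return list with elements `U` (for group_a), `p`, and `method`.
#' @export
mann_whitney <- function(group_a, group_b, exact_limit = 20L) {
  stopifnot(length(group_a) > 0L, length(group_b) > 0L)
  n1 <- length(group_a); n2 <- length(group_b)
  r <- rank(c(group_a, group_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (U == n1 * n2 / 2 && length(unique(c(group_a, group_b))) == 1L) {
    # all observations identical: no evidence of a shift
    return(list(U = U, p = 1, method = "degenerate"))
  }
  ties <- any(duplicated(c(group_a, group_b)))
  use_exact <- !ties && n1 <= exact_limit && n2 <= exact_limit
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact,
                       correct = !use_exact))
  list(U = unname(U), p = min(1, unname(wt$p.value)),
       method = if (use_exact) "exact" else "normal approximation")
}

auc_rank <- function(scores, labels) {
  y <- as.integer(labels == "malignant" | labels == 1 | labels == TRUE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  y <- as.integer(labels == "malignant" | labels == 1 | labels == TRUE)
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  # step through unique thresholds
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  data.frame(fpr = c(0, fp / sum(1 - y)), tpr = c(0, tp / sum(y)))
}

auc_trapezoid <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' Computes the area under the receiver-operating-characteristic curve by
#' the trapezoidal rule (cross-checked internally against the equivalent
#' rank statistic) and a stratified percentile bootstrap confidence
#' interval.
#'
#' @param scores numeric classifier scores (higher = more malignant).
#' @param labels vector with two classes; `"malignant"`, `1` or `TRUE`
#'   marks the positive class.
#' @param n_boot number of stratified bootstrap resamples.
#' @param seed RNG seed for the bootstrap (mandatory for reproducibility).
#' @param ci_level confidence level.
#' @return object of class `qus_roc`: list with `auc`, `ci`, `n`,
#'   `n_positive`, `curve` (data.frame of fpr/tpr points), `boot_auc`.
#' @export
roc_auc <- function(scores, labels, n_boot = 2000L, seed = 1L,
                    ci_level = 0.95) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels == "malignant" | labels == 1 | labels == TRUE)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  auc <- auc_trapezoid(scores, y)

  ipos <- which(y == 1); ineg <- which(y == 0)
  boot <- numeric(n_boot)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- c(sample(ipos, length(ipos), replace = TRUE),
             sample(ineg, length(ineg), replace = TRUE))
    boot[b] <- auc_rank(scores[idx], y[idx])
  }
  alpha <- 1 - ci_level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                               type = 6))
  ci <- c(min(ci[1], auc), max(ci[2], auc))  # CI always brackets the point
  structure(list(auc = auc, ci = ci, n = length(y),
                 n_positive = sum(y), curve = roc_points(scores, y),
                 boot_auc = boot, ci_level = ci_level),
            class = "qus_roc")
}

#' @export
print.qus_roc <- function(x, ...) {
  cat(sprintf("ROC analysis: AUC %.4f (%d%% CI %.4f-%.4f), n = %d (%d positive)\n",
              x$auc, round(100 * x$ci_level), x$ci[1], x$ci[2],
              x$n, x$n_positive))
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval for a binomial proportion from beta quantiles:
#' lower = qbeta(alpha/2, s, n - s + 1), upper = qbeta(1 - alpha/2,
#' s + 1, n - s), with the conventional 0 and 1 endpoints at s = 0 and
#' s = n.
#'
#' @param successes,trials integer counts, 0 <= successes <= trials.
#' @param level confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials <= 0L) stop("trials must be positive")
  if (successes < 0L || successes > trials)
    stop("successes must lie in [0, trials]")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
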