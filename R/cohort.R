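#' Fit a distribution to a reported median and quartiles
#'
#' Clinical QUS tables report group statistics as median (IQR). This
#' inverts those summaries to distribution parameters: for the log-normal
#' family `mu = ln(median)`, `sigma = ln(q3/q1) / (2 * 0.67449)`; for the
#' normal family `mean = median`, `sd = (q3 - q1) / (2 * 0.67449)`
#' (0.67449 is the standard normal upper quartile).
#'
#' @param median,q1,q3 reported median and quartiles.
#' @param family `"log-normal"` or `"normal"`.
#' @return list with `family` and its parameters (`mu`/`sigma` or
#'   `mean`/`sd`).
#' @export
fit_distribution_from_quartiles <- function(median, q1, q3,
                                            family = c("log-normal",
                                                       "normal")) {
  family <- match.arg(family)
  if (q1 > q3) stop("q1 must not exceed q3")
  z75 <- stats::qnorm(0.75)
  if (family == "log-normal") {
    if (median <= 0 || q1 <= 0 || q3 <= 0)
      stop("log-normal family requires positive median and quartiles")
    list(family = family, mu = log(median), sigma = log(q3 / q1) / (2 * z75))
  } else {
    list(family = family, mean = median, sd = (q3 - q1) / (2 * z75))
  }
}

sample_from_fit <- function(fit, n) {
  if (n == 0L) return(numeric(0))
  if (fit$family == "log-normal")
    stats::rlnorm(n, fit$mu, fit$sigma)
  else
    stats::rnorm(n, fit$mean, fit$sd)
}

# family used per QUS parameter: strictly-positive skewed parameters are
# log-normal, SoS (narrow relative spread around ~1540 m/s) is normal
cohort_families <- c(ac = "log-normal", sos = "normal",
                     esd = "log-normal", esc = "log-normal")

#' Sample a synthetic QUS lesion cohort
#'
#' Draws per-lesion AC, SoS, ESD and ESC for a benign and a malignant
#' group, with each parameter's marginal distribution matched to reported
#' group medians and interquartile ranges (AC/ESD/ESC log-normal, SoS
#' normal). Parameters are drawn independently within a group unless a
#' correlation matrix is supplied (a Gaussian-copula hook; the default is
#' identity because clinical inter-parameter correlations are not
#' reported).
#'
#' @param n_benign,n_malignant group sizes (defaults: the 32/23 clinical
#'   cohort).
#' @param summaries group summary table as returned by
#'   [clinical_group_summaries()] (columns `group`, `parameter`, `median`,
#'   `q1`, `q3`).
#' @param seed RNG seed.
#' @param correlation optional 4x4 correlation matrix (ac, sos, esd, esc)
#'   applied via a Gaussian copula within each group.
#' @return data.frame with columns `id`, `ac`, `sos`, `esd`, `esc`,
#'   `label`.
#' @export
sample_cohort <- function(n_benign = 32L, n_malignant = 23L,
                          summaries = clinical_group_summaries(),
                          seed = 1L, correlation = NULL) {
  stopifnot(n_benign >= 0L, n_malignant >= 0L)
  pars <- c("ac", "sos", "esd", "esc")
  if (!is.null(correlation))
    stopifnot(is.matrix(correlation), all(dim(correlation) == 4L))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  draw_group <- function(group, n) {
    if (n == 0L) return(NULL)
    fits <- lapply(pars, function(p) {
      row <- summaries[summaries$group == group & summaries$parameter == p, ]
      if (nrow(row) != 1L)
        stop("summaries must hold exactly one row for ", group, "/", p)
      fit_distribution_from_quartiles(row$median, row$q1, row$q3,
                                      cohort_families[[p]])
    })
    names(fits) <- pars
    if (is.null(correlation)) {
      vals <- lapply(fits, sample_from_fit, n = n)
    } else {
      ch <- chol(correlation)
      z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% ch
      u <- stats::pnorm(z)
      vals <- lapply(seq_along(pars), function(j) {
        f <- fits[[j]]
        if (f$family == "log-normal")
          stats::qlnorm(u[, j], f$mu, f$sigma)
        else
          stats::qnorm(u[, j], f$mean, f$sd)
      })
      names(vals) <- pars
    }
    data.frame(ac = vals$ac, sos = vals$sos, esd = vals$esd,
               esc = vals$esc, label = group, stringsAsFactors = FALSE)
  }

  out <- rbind(draw_group("benign", n_benign),
               draw_group("malignant", n_malignant))
  if (is.null(out))
    out <- data.frame(ac = numeric(0), sos = numeric(0), esd = numeric(0),
                      esc = numeric(0), label = character(0))
  out <- cbind(id = if (nrow(out)) sprintf("syn%03d", seq_len(nrow(out)))
               else character(0), out)
  rownames(out) <- NULL
  out
}
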