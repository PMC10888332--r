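#' QUS logistic malignancy model
#'
#' Constructs a logistic model on the four quantitative ultrasound (QUS)
#' parameters: attenuation coefficient (AC, dB/cm/MHz), speed of sound
#' (SoS, m/s), effective scatterer diameter (ESD, um) and effective
#' scatterer concentration (ESC, scatterers per squared wavelength).
#' The log-odds of malignancy are
#' \deqn{\log \mathrm{odds} = \beta_0 + \beta_{AC}\,AC + \beta_{SoS}\,SoS +
#'       \beta_{ESD}\,ESD + \beta_{ESC}\,ESC}
#' and the malignancy probability is the sigmoid of the log-odds.
#'
#' @param intercept,coef_ac,coef_sos,coef_esd,coef_esc model coefficients.
#' @param inference optional data.frame with per-coefficient inference
#'   (columns `parameter`, `coef`, `se`, `z`, `p`, `ci_low`, `ci_high`).
#' @return an object of class `qus_logistic`.
#' @seealso [default_qus_model()] for the packaged clinical coefficients.
#' @export
qus_logistic <- function(intercept, coef_ac, coef_sos, coef_esd, coef_esc,
                         inference = NULL) {
  coefs <- c(intercept = intercept, ac = coef_ac, sos = coef_sos,
             esd = coef_esd, esc = coef_esc)
  stopifnot(all(is.finite(coefs)))
  structure(list(coefficients = coefs, inference = inference),
            class = "qus_logistic")
}

#' Packaged clinical QUS malignancy model
#'
#' The logistic model relating the four QUS parameters of a breast lesion to
#' its probability of malignancy, with the published coefficients:
#' log odds = -31.7558 + 10.6396 AC + 0.0210 SoS - 0.0975 ESD + 0.0805 ESC.
#'
#' @return a `qus_logistic` model carrying the clinical coefficients.
#' @examples
#' m <- default_qus_model()
#' log_odds(data.frame(ac = 0.8061, sos = 1590, esd = 89.88, esc = 1.976), m)
#' @export
default_qus_model <- function() {
  qus_logistic(intercept = -31.7558,
               coef_ac   = 10.6396,
               coef_sos  = 0.0210,
               coef_esd  = -0.0975,
               coef_esc  = 0.0805)
}

#' @export
print.qus_logistic <- function(x, ...) {
  cat("QUS logistic malignancy model\n")
  cat("  log odds =", format(x$coefficients["intercept"]))
  for (p in c("ac", "sos", "esd", "esc")) {
    b <- x$coefficients[p]
    cat(sprintf(" %s %s*%s", if (b >= 0) "+" else "-", format(abs(b)),
                toupper(p)))
  }
  cat("\n")
  if (!is.null(x$inference)) {
    cat("Inference table:\n")
    print(x$inference, row.names = FALSE)
  }
  invisible(x)
}

check_measurements <- function(m) {
  need <- c("ac", "sos", "esd", "esc")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0L)
    stop("missing QUS parameter(s): ", paste(missing, collapse = ", "))
  for (p in need) {
    v <- m[[p]]
    if (any(!is.finite(v))) stop("non-finite values in '", p, "'")
  }
  invisible(m)
}

#' Log-odds of malignancy for lesion measurements
#'
#' @param measurements data.frame (or named list for a single lesion) with
#'   columns `ac`, `sos`, `esd`, `esc`.
#' @param model a `qus_logistic` model; defaults to the packaged clinical
#'   model.
#' @return numeric vector of log-odds, one per lesion.
#' @export
log_odds <- function(measurements, model = default_qus_model()) {
  stopifnot(inherits(model, "qus_logistic"))
  m <- as.data.frame(check_measurements(measurements))
  b <- model$coefficients
  b[["intercept"]] + b[["ac"]] * m$ac + b[["sos"]] * m$sos +
    b[["esd"]] * m$esd + b[["esc"]] * m$esc
}

#' Sigmoid transform of a log-odds score
#'
#' `probability(x) = 1 / (1 + exp(-x))`, numerically stable for large |x|.
#'
#' @param score numeric log-odds.
#' @return probabilities in (0, 1).
#' @export
probability <- function(score) {
  p <- ifelse(score >= 0,
              1 / (1 + exp(-score)),
              exp(score) / (1 + exp(score)))
  as.numeric(p)
}

#' Classify lesions with a QUS logistic model
#'
#' @inheritParams log_odds
#' @param threshold probability cut for calling a lesion malignant.
#' @return data.frame with `log_odds`, `probability` and `predicted` label.
#' @export
classify_lesions <- function(measurements, model = default_qus_model(),
                             threshold = 0.5) {
  lo <- log_odds(measurements, model)
  p <- probability(lo)
  out <- as.data.frame(measurements)
  out$log_odds <- lo
  out$probability <- p
  out$predicted <- ifelse(p >= threshold, "malignant", "benign")
  out
}

#' Fit a QUS logistic regression on a labeled cohort
#'
#' Maximum-likelihood logistic regression of the benign/malignant label on
#' AC, SoS, ESD and ESC, with a Wald inference table (coefficient and
#' odds-ratio scale standard errors, z, two-sided p, 95% CI).
#'
#' @param cohort data.frame with columns `ac`, `sos`, `esd`, `esc` and
#'   `label` (`"benign"`/`"malignant"`).
#' @param level confidence level for the Wald intervals.
#' @return a `qus_logistic` model with an `inference` table attached;
#'   attribute `separation` is TRUE when (quasi-)perfect separation was
#'   detected (fitted probabilities degenerate), in which case a warning is
#'   raised rather than silently returning a diverged fit.
#' @export
fit_logistic <- function(cohort, level = 0.95) {
  cohort <- as.data.frame(cohort)
  check_measurements(cohort)
  if (!"label" %in% names(cohort)) stop("cohort must have a 'label' column")
  y <- as.integer(cohort$label == "malignant")
  if (length(unique(y)) < 2L)
    stop("both benign and malignant labels must be present")
  if (nrow(cohort) < 10L) stop("need at least 10 lesions to fit")

  fit <- suppressWarnings(
    stats::glm(y ~ ac + sos + esd + esc, data = cohort,
               family = stats::binomial()))
  sep <- !fit$converged ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (sep)
    warning("possible (quasi-)perfect separation: coefficients unreliable")

  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    # rank deficiency (e.g. constant covariates): drop to zero effect
    warning("rank-deficient fit: NA coefficients set to 0")
    cf[is.na(cf)] <- 0
  }
  se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  se_ok <- sqrt(diag(stats::vcov(fit)))
  se[names(se_ok)] <- se_ok
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- cf / se
  tab <- data.frame(
    parameter = c("intercept", "ac", "sos", "esd", "esc"),
    coef = unname(cf),
    se = unname(se),
    odds_ratio = unname(exp(cf)),
    se_or = unname(exp(cf) * se),         # delta-method SE on the OR scale
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    ci_low = unname(exp(cf - zq * se)),
    ci_high = unname(exp(cf + zq * se)))

  model <- qus_logistic(cf[["(Intercept)"]], cf[["ac"]], cf[["sos"]],
                        cf[["esd"]], cf[["esc"]], inference = tab)
  attr(model, "separation") <- sep
  attr(model, "glm") <- fit
  model
}

#' Odds-ratio inference table of a QUS logistic model
#'
#' Exponentiates the coefficients to odds ratios; when standard errors are
#' available, adds OR-scale Wald confidence intervals
#' `exp(coef +- z * SE)`.
#'
#' @param model a `qus_logistic` model.
#' @param level confidence level.
#' @return data.frame with one row per QUS parameter.
#' @export
odds_ratio_table <- function(model, level = 0.95) {
  stopifnot(inherits(model, "qus_logistic"))
  pars <- c("ac", "sos", "esd", "esc")
  cf <- model$coefficients[pars]
  out <- data.frame(parameter = pars, coef = unname(cf),
                    odds_ratio = unname(exp(cf)))
  inf <- model$inference
  if (!is.null(inf)) {
    i <- match(pars, inf$parameter)
    zq <- stats::qnorm(1 - (1 - level) / 2)
    out$se <- inf$se[i]
    out$se_or <- exp(cf) * inf$se[i]
    out$z <- cf / inf$se[i]
    out$p <- 2 * stats::pnorm(-abs(out$z))
    out$ci_low <- exp(cf - zq * inf$se[i])
    out$ci_high <- exp(cf + zq * inf$se[i])
  }
  out
}

#' Packaged clinical lesion table (BI-RADS 3/4 lesions)
#'
#' Nine lesions from BI-RADS categories 3 and 4 with their measured QUS
#' parameters and biopsy label.
#'
#' @return data.frame with columns `id`, `birads`, `ac`, `sos`, `esd`,
#'   `esc`, `label`.
#' @export
clinical_lesions <- function() {
  utils::read.csv(system.file("extdata", "table5_lesions.csv",
                              package = "quantus"),
                  stringsAsFactors = FALSE)
}

#' Published group-level QUS summaries
#'
#' Median and quartiles of AC, SoS, ESD and ESC per diagnostic group
#' (benign, malignant, and the IDC/DCIS malignant subgroups).
#'
#' @return data.frame with columns `group`, `parameter`, `median`, `q1`,
#'   `q3`.
#' @export
clinical_group_summaries <- function() {
  utils::read.csv(system.file("extdata", "table4_summaries.csv",
                              package = "quantus"),
                  stringsAsFactors = FALSE)
}

#' Published inference table of the clinical QUS logistic model
#'
#' Odds ratios, OR-scale standard errors, z statistics, p-values and 95%
#' confidence intervals of the clinical logistic fit.
#'
#' @return data.frame with one row per QUS parameter.
#' @export
clinical_inference_table <- function() {
  utils::read.csv(system.file("extdata", "table2_inference.csv",
                              package = "quantus"),
                  stringsAsFactors = FALSE)
}
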