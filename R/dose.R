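## Enzyme-inhibition dose-response analysis: percentage inhibition from
## raw absorbances and log-logistic IC50 fitting.

#' Percentage inhibition from absorbances
#'
#' `(blank - test) / blank * 100`: the fraction of enzyme activity lost
#' relative to the uninhibited blank. Scale-free: rescaling both
#' absorbances by a common factor leaves it unchanged.
#'
#' @param absBlank blank (uninhibited) absorbance, > 0.
#' @param absTest test absorbance.
#' @return percentage inhibition (vectorized).
#' @examples
#' percentInhibition(0.8, 0.2)  # 75
#' @export
percentInhibition <- function(absBlank, absTest) {
  if (any(absBlank <= 0)) stop("blank absorbance must be positive")
  (absBlank - absTest) / absBlank * 100
}

#' Fit a log-logistic IC50 curve
#'
#' Least-squares fit of percentage inhibition against log10
#' concentration:
#' `bottom + (top - bottom) / (1 + 10^((log10(IC50) - log10(c)) * hill))`.
#' The default `"normalized_two_param"` model fixes `bottom = 0`,
#' `top = 100` (normalized inhibition curves); `"four_param_logistic"`
#' also estimates both asymptotes. Fitting is parameterized in
#' log10(IC50) with a multistart over the tested-concentration quantiles
#' crossed with Hill slopes {0.5, 1, 2}; the best converged start wins.
#' A fitted negative Hill slope (inhibition decreasing with
#' concentration) is flagged with a warning, never silently accepted, as
#' is an IC50 outside the tested concentration range.
#'
#' @param concentrations strictly positive concentrations (>= 4 distinct
#'   values).
#' @param inhibition mean percentage inhibition per concentration (or per
#'   record, aligned with `concentrations`).
#' @param model `"normalized_two_param"` or `"four_param_logistic"`.
#' @param rescale rescale inhibition to span 0-100 before fitting
#'   (per-curve normalization; default off).
#' @return list: `ic50`, `ic50_se` (delta-method from the log-scale SE),
#'   `log10_ic50`, `log10_ic50_se`, `hill`, `hill_se`, `top`, `bottom`,
#'   `fitted`, `residuals`, `rss`, `converged`, `flags` (character vector,
#'   possibly empty).
#' @examples
#' d <- genDoseResponse(27.26, concentrations = c(10, 25, 50, 100, 200))
#' fitIc50(d$concentration, d$inhibition)$ic50
#' @export
fitIc50 <- function(concentrations, inhibition,
                    model = c("normalized_two_param",
                              "four_param_logistic"),
                    rescale = FALSE) {
  model <- match.arg(model)
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (length(unique(concentrations)) < 4)
    stop("need at least 4 distinct concentrations")
  stopifnot(length(concentrations) == length(inhibition))
  if (rescale) {
    rng <- range(inhibition)
    if (diff(rng) == 0) stop("cannot rescale a flat curve")
    inhibition <- (inhibition - rng[1]) / diff(rng) * 100
  }
  lc <- log10(concentrations)
  df <- data.frame(lc = lc, y = inhibition)
  starts <- expand.grid(
    lic50 = stats::quantile(lc, c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(0.5, 1, 2))
  fits <- list()
  for (i in seq_len(nrow(starts))) {
    start <- list(lic50 = starts$lic50[i], hill = starts$hill[i])
    form <- if (model == "normalized_two_param")
      y ~ 100 / (1 + 10^((lic50 - lc) * hill))
    else y ~ bottom + (top - bottom) / (1 + 10^((lic50 - lc) * hill))
    if (model == "four_param_logistic")
      start <- c(start, list(top = max(inhibition),
                             bottom = min(inhibition)))
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
  }
  if (!length(fits)) {
    ## report the best multistart residual even on failure
    best <- min(vapply(seq_len(nrow(starts)), function(i) {
      mu <- 100 / (1 + 10^((starts$lic50[i] - lc) * starts$hill[i]))
      sum((inhibition - mu)^2)
    }, numeric(1)))
    stop("IC50 fit did not converge from any start (best multistart ",
         "residual sum of squares: ", signif(best, 4), ")")
  }
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  fit <- fits[[which.min(rss)]]
  est <- summary(fit)$coefficients
  lic50 <- est["lic50", "Estimate"]
  lic50Se <- est["lic50", "Std. Error"]
  hill <- est["hill", "Estimate"]
  flags <- character()
  if (hill < 0) {
    flags <- c(flags, "negative_hill")
    warning("fitted Hill slope is negative ",
            "(inhibition decreases with concentration)")
  }
  ic50 <- 10^lic50
  if (ic50 < min(concentrations) || ic50 > max(concentrations)) {
    flags <- c(flags, "ic50_outside_tested_range")
    warning("fitted IC50 (", signif(ic50, 4),
            ") lies outside the tested concentration range")
  }
  list(ic50 = ic50, ic50_se = ic50 * log(10) * lic50Se,
       log10_ic50 = lic50, log10_ic50_se = lic50Se,
       hill = hill, hill_se = est["hill", "Std. Error"],
       top = if (model == "four_param_logistic")
         est["top", "Estimate"] else 100,
       bottom = if (model == "four_param_logistic")
         est["bottom", "Estimate"] else 0,
       fitted = stats::fitted(fit), residuals = stats::residuals(fit),
       rss = min(rss), converged = TRUE, flags = flags)
}

#' Summarize replicate IC50 determinations
#'
#' Arithmetic mean and sample standard deviation over independent
#' replicate IC50 estimates (e.g. triplicate determinations).
#'
#' @param fits numeric vector of IC50 estimates, or a list of [fitIc50()]
#'   results.
#' @return list: `mean`, `sd`, `n`.
#' @examples
#' ic50Summary(c(27.2, 27.3, 27.3))
#' @export
ic50Summary <- function(fits) {
  est <- if (is.numeric(fits)) fits
         else vapply(fits, function(f) f$ic50, numeric(1))
  if (length(est) < 2)
    stop("need at least 2 replicate determinations")
  list(mean = mean(est), sd = stats::sd(est), n = length(est))
}
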