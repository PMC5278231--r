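# Wald CI and p helpers for glm/lm coefficient tables
wald_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = est - z * se, upper = est + z * se)
}

covariate_formula_rhs <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0) "1"
  else paste(colnames(covariates), collapse = " + ")
}

#' Quartile logistic association of an OBS with metabolic syndrome
#'
#' Fits one logistic model of case status on OBS quartile (indicator
#' coding, Q1 = lowest scores = reference) plus optional covariates, and
#' reports per-quartile odds ratios with Wald 95% confidence intervals and
#' p-values alongside case/control counts.
#'
#' @param status Binary outcome (0/1 or logical).
#' @param quartile Factor `Q1`-`Q4` from [obs_quartiles()].
#' @param covariates Optional data frame of adjustment covariates
#'   (conventionally `age`, `sex`, `area`, `bmi`); `NULL` for a crude
#'   model.
#' @param level Confidence level.
#' @return Data frame with one row per quartile: `quartile`, `n_cases`,
#'   `n_controls`, `or`, `ci_lower`, `ci_upper`, `p` (reference row: OR 1,
#'   no CI). The fitted model is attached as attribute `"fit"`.
#' @export
fit_quartile_logistic <- function(status, quartile, covariates = NULL,
                                  level = 0.95) {
  status <- as.integer(status)
  dat <- data.frame(.y = status, quartile = quartile)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  if (anyNA(dat)) stop("complete cases required", call. = FALSE)
  counts <- table(quartile, factor(status, levels = 0:1))
  if (any(counts == 0))
    stop("every quartile needs at least one case and one control",
         call. = FALSE)
  fml <- stats::as.formula(paste(".y ~ quartile +",
                                 covariate_formula_rhs(covariates)))
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  if (!fit$converged)
    stop("quartile logistic model did not converge", call. = FALSE)
  cf <- summary(fit)$coefficients
  terms <- paste0("quartile", levels(quartile)[-1])
  est <- cf[terms, "Estimate"]; se <- cf[terms, "Std. Error"]
  ci <- wald_ci(est, se, level)
  out <- data.frame(
    quartile = levels(quartile),
    n_cases = as.integer(counts[, "1"]),
    n_controls = as.integer(counts[, "0"]),
    or = c(1, exp(est)),
    ci_lower = c(NA, exp(ci[, "lower"])),
    ci_upper = c(NA, exp(ci[, "upper"])),
    p = c(NA, cf[terms, "Pr(>|z|)"]),
    row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Linear-trend test across OBS quartiles
#'
#' Re-enters the quartile as a single ordinal score (1-4) in the logistic
#' model and reports the Wald p-value of that term. Invariant to affine
#' recodings of the score.
#'
#' @inheritParams fit_quartile_logistic
#' @return A list: `p_trend`, `estimate` (log-odds per quartile step),
#'   `se`.
#' @export
trend_test <- function(status, quartile, covariates = NULL) {
  dat <- data.frame(.y = as.integer(status), .trend = as.integer(quartile))
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  if (anyNA(dat)) stop("complete cases required", call. = FALSE)
  fml <- stats::as.formula(paste(".y ~ .trend +",
                                 covariate_formula_rhs(covariates)))
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  cf <- summary(fit)$coefficients
  list(p_trend = cf[".trend", "Pr(>|z|)"],
       estimate = cf[".trend", "Estimate"],
       se = cf[".trend", "Std. Error"])
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve of a predicted score against a binary outcome,
#' computed as the normalized rank sum of cases (mid-ranks for ties), i.e.
#' the concordance probability. Invariant under strictly monotone
#' transforms of the score.
#'
#' @param pred Numeric predictions (e.g. fitted probabilities).
#' @param status Binary outcome.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(pred, status) {
  status <- as.integer(status)
  if (length(pred) != length(status))
    stop("pred and status lengths differ", call. = FALSE)
  n1 <- sum(status == 1); n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: outcome has a single class", call. = FALSE)
  r <- rank(pred)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a fitted quartile association model
#'
#' @param assoc Result of [fit_quartile_logistic()].
#' @return AUC of the model's fitted probabilities against the outcome.
#' @export
model_auc <- function(assoc) {
  fit <- attr(assoc, "fit")
  compute_auc(stats::fitted(fit), fit$y)
}

#' Linear model of an inflammation marker on OBS quartiles
#'
#' Ordinary least squares of the (optionally log-transformed) marker on
#' quartile indicators (Q1 reference) plus covariates; reports per-quartile
#' coefficients with Wald confidence intervals and an ordinal trend
#' p-value.
#'
#' @param marker Numeric marker values (e.g. CRP mg/dL, WBC 10^3/uL).
#' @param quartile Factor `Q1`-`Q4`.
#' @param covariates Optional adjustment data frame.
#' @param log_transform Log the marker first (for right-skewed markers
#'   such as CRP)?
#' @param offset Added before logging when non-positive values occur.
#' @param level Confidence level.
#' @return Data frame with `quartile`, `beta`, `ci_lower`, `ci_upper`,
#'   `p` (Q1 row: beta 0), plus attributes `"p_trend"` and `"fit"`.
#' @export
fit_marker_linear <- function(marker, quartile, covariates = NULL,
                              log_transform = FALSE, offset = 0,
                              level = 0.95) {
  y <- marker
  if (log_transform) {
    if (any(y + offset <= 0, na.rm = TRUE))
      stop("non-positive marker values under log transform; set offset",
           call. = FALSE)
    y <- log(y + offset)
  }
  dat <- data.frame(.y = y, quartile = quartile)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  if (anyNA(dat)) stop("complete cases required", call. = FALSE)
  fml <- stats::as.formula(paste(".y ~ quartile +",
                                 covariate_formula_rhs(covariates)))
  fit <- stats::lm(fml, data = dat)
  cf <- summary(fit)$coefficients
  terms <- paste0("quartile", levels(quartile)[-1])
  est <- cf[terms, "Estimate"]; se <- cf[terms, "Std. Error"]
  ci <- wald_ci(est, se, level)
  out <- data.frame(
    quartile = levels(quartile),
    beta = c(0, est),
    ci_lower = c(NA, ci[, "lower"]),
    ci_upper = c(NA, ci[, "upper"]),
    p = c(NA, cf[terms, "Pr(>|t|)"]),
    row.names = NULL)
  dat$.trend <- as.integer(dat$quartile)
  tfit <- stats::lm(stats::as.formula(
    paste(".y ~ .trend +", covariate_formula_rhs(covariates))), data = dat)
  attr(out, "p_trend") <- summary(tfit)$coefficients[".trend", "Pr(>|t|)"]
  attr(out, "fit") <- fit
  out
}
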