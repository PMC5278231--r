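#' @keywords internal
"_PACKAGE"

# Exposure columns feeding the seven OBS components. Antioxidants score
# ascending with tertile; iron (prooxidant) descending; smoking and
# alcohol have their own categorical rules.
obs_exposures <- c("iron", "vitc", "retinol", "carotene", "activity",
                   "smoking", "alcohol")
obs_score_cols <- c("iron_score", "vitc_score", "retinol_score",
                    "carotene_score", "activity_score", "smoking_score",
                    "alcohol_score")
obs_antioxidant_scores <- c("vitc_score", "retinol_score", "carotene_score",
                            "activity_score")

#' Log-transform skewed OBS exposures
#'
#' Applies the natural log to the continuous OBS exposure columns except
#' physical activity (the only one treated as approximately normal).
#' Columns containing zeros use `log(x + offset)`; strictly positive
#' columns use `log(x)` so a column of ones maps to zeros exactly.
#'
#' @param cohort Data frame with exposure columns `iron`, `vitc`,
#'   `retinol`, `carotene`, `alcohol` (and untouched `activity`,
#'   `smoking`).
#' @param offset Offset added before logging columns that contain zeros.
#' @return The data frame with transformed exposure columns.
#' @export
obs_log_transform <- function(cohort, offset = 1) {
  cols <- c("iron", "vitc", "retinol", "carotene", "alcohol")
  for (col in intersect(cols, names(cohort))) {
    x <- cohort[[col]]
    if (any(x < 0, na.rm = TRUE))
      stop(sprintf("negative values in exposure column '%s'", col),
           call. = FALSE)
    cohort[[col]] <- if (any(x == 0, na.rm = TRUE)) log(x + offset) else log(x)
  }
  cohort
}

#' Empirical tertile cut-points
#'
#' Cut-points at the 1/3 and 2/3 empirical quantiles (type-7,
#' linear-interpolation). Membership downstream is lower-inclusive:
#' `(-Inf, t1]`, `(t1, t2]`, `(t2, Inf)`.
#'
#' @param values Numeric vector with at least 3 distinct values.
#' @return Numeric length-2 vector `c(lower, upper)`.
#' @export
obs_tertiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 3L)
    stop("need at least 3 distinct values for tertiles", call. = FALSE)
  cp <- stats::quantile(values, c(1 / 3, 2 / 3), type = 7, names = FALSE)
  if (cp[1] >= cp[2])
    stop("degenerate distribution: tertile cut-points coincide",
         call. = FALSE)
  cp
}

# 0/1/2 tertile index, lower-inclusive bins.
tertile_index <- function(x, cutpoints) {
  (x > cutpoints[1]) + (x > cutpoints[2])
}

#' Score the seven OBS components
#'
#' Assigns 0-2 points per component. Antioxidant nutrients (vitamin C,
#' retinol, carotene) and physical activity score 0/1/2 ascending with
#' tertile; iron, a prooxidant, scores 2/1/0 descending. Smoking scores
#' never = 2, former = 1, current = 0. Alcohol scores 0 for heavy drinking
#' (at or above `alcohol_cutoff` g/day) and 2 otherwise. Higher totals
#' always mean antioxidant predominance.
#'
#' @param cohort Data frame with the exposure columns (raw or
#'   monotone-transformed scale; tertile scores are transform-invariant,
#'   but `alcohol_cutoff` must be expressed on the same scale as the
#'   `alcohol` column).
#' @param cutpoints Optional named list of length-2 tertile cut-points for
#'   `iron`, `vitc`, `retinol`, `carotene`, `activity`; computed from
#'   `cohort` itself when omitted (the analysis-cohort convention).
#' @param alcohol_cutoff Heavy-drinking threshold (default 50 g/day).
#' @param heavy_score,nonheavy_score Points for heavy / non-heavy drinkers
#'   (defaults 0 / 2; exposed because published descriptions of the rule
#'   disagree on direction).
#' @return Data frame of integer component scores (one column per
#'   component, `*_score`), with the cut-points used attached as attribute
#'   `"cutpoints"`.
#' @export
obs_score_components <- function(cohort, cutpoints = NULL,
                                 alcohol_cutoff = 50,
                                 heavy_score = 0L, nonheavy_score = 2L) {
  tert_cols <- c("iron", "vitc", "retinol", "carotene", "activity")
  if (is.null(cutpoints))
    cutpoints <- lapply(cohort[tert_cols], obs_tertiles)
  smoking <- as.character(cohort$smoking)
  bad <- setdiff(unique(smoking[!is.na(smoking)]),
                 c("never", "former", "current"))
  if (length(bad) > 0)
    stop("unknown smoking category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  idx <- lapply(tert_cols, function(col)
    tertile_index(cohort[[col]], cutpoints[[col]]))
  names(idx) <- tert_cols
  scores <- data.frame(
    iron_score = 2L - idx$iron,
    vitc_score = idx$vitc,
    retinol_score = idx$retinol,
    carotene_score = idx$carotene,
    activity_score = idx$activity,
    smoking_score = c(never = 2L, former = 1L, current = 0L)[smoking],
    alcohol_score = ifelse(cohort$alcohol >= alcohol_cutoff,
                           heavy_score, nonheavy_score))
  rownames(scores) <- NULL
  attr(scores, "cutpoints") <- cutpoints
  scores
}

#' Quartile assignment of a continuous score
#'
#' Cuts at the empirical 25/50/75 percentiles (type-7 quantiles),
#' lower-inclusive bins; Q1 holds the lowest scores (prooxidant
#' predominance when applied to an OBS).
#'
#' @param score Numeric vector with at least 4 distinct values.
#' @return Factor with levels `Q1`-`Q4`.
#' @export
obs_quartiles <- function(score) {
  if (length(unique(score[!is.na(score)])) < 4L)
    stop("need at least 4 distinct score values for quartiles",
         call. = FALSE)
  q <- stats::quantile(score, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (anyDuplicated(q))
    stop("degenerate score distribution: quartile cut-points collapse",
         call. = FALSE)
  factor(paste0("Q", 1L + (score > q[1]) + (score > q[2]) + (score > q[3])),
         levels = paste0("Q", 1:4))
}

obs_result <- function(score, scheme, weights, provenance = NULL) {
  res <- data.frame(score = as.numeric(score),
                    quartile = obs_quartiles(score),
                    scheme = scheme, stringsAsFactors = FALSE)
  attr(res, "weights") <- weights
  attr(res, "provenance") <- provenance
  class(res) <- c("obs_result", "data.frame")
  res
}

#' Equal-weight oxidative balance score
#'
#' Simple unweighted sum of the seven component scores; range 0-14, higher
#' values indicating antioxidant predominance.
#'
#' @param scores Component-score data frame from [obs_score_components()].
#' @return An `obs_result` data frame (`score`, `quartile`, `scheme`) with
#'   unit weights attached as attribute `"weights"`.
#' @export
obs_equal <- function(scores) {
  s <- rowSums(scores[obs_score_cols])
  w <- stats::setNames(rep(1, length(obs_score_cols)), obs_score_cols)
  obs_result(s, "equal", w)
}

#' Beta-coefficient-weighted oxidative balance score
#'
#' Fits one multivariable logistic model of the outcome on all seven
#' component scores plus age, sex, area and BMI, takes minus one times each
#' component's coefficient as its weight (so protective components weigh
#' positively), and scores each participant as the weighted sum of
#' component scores.
#'
#' @param scores Component-score data frame from [obs_score_components()].
#' @param cohort Data frame providing `age`, `sex`, `area`, `bmi`.
#' @param outcome Binary outcome vector (e.g. metabolic syndrome flag).
#' @return An `obs_result` with weights and the fitted model summary in
#'   attributes `"weights"` and `"provenance"`.
#' @export
obs_beta <- function(scores, cohort, outcome) {
  dat <- cbind(scores[obs_score_cols],
               cohort[c("age", "sex", "area", "bmi")],
               .y = as.integer(outcome))
  if (anyNA(dat)) stop("missing covariates or scores", call. = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(
    c(obs_score_cols, "age", "sex", "area", "bmi"), collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  if (!fit$converged)
    stop("beta-weight logistic model did not converge", call. = FALSE)
  coefs <- stats::coef(fit)[obs_score_cols]
  if (anyNA(coefs) || any(abs(coefs) > 15))
    stop("separation detected in beta-weight logistic model", call. = FALSE)
  w <- -coefs
  s <- as.numeric(as.matrix(scores[obs_score_cols]) %*% w)
  obs_result(s, "beta", w, provenance = list(coefficients = stats::coef(fit),
                                             se = sqrt(diag(stats::vcov(fit)))))
}

#' PCA-weighted oxidative balance score
#'
#' Standardizes the seven component scores, extracts principal components,
#' retains those with eigenvalue > 1, and scores each participant by the
#' loadings of the first retained component, sign-oriented so that the mean
#' loading of the four antioxidant components is positive.
#'
#' @param scores Component-score data frame from [obs_score_components()].
#' @return An `obs_result`; attribute `"provenance"` carries the
#'   eigenvalues, the retained-PC count, and the (oriented) loadings.
#' @export
obs_pca <- function(scores) {
  X <- as.matrix(scores[obs_score_cols])
  if (nrow(X) < length(obs_score_cols))
    stop("need at least as many participants as components", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance component score: ",
         paste(obs_score_cols[sds == 0], collapse = ", "), call. = FALSE)
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  n_retained <- max(1L, sum(eig > 1))
  loading <- pc$rotation[, 1]
  if (mean(loading[obs_antioxidant_scores]) < 0) loading <- -loading
  s <- as.numeric(Z %*% loading)
  obs_result(s, "pca", loading,
             provenance = list(eigenvalues = eig, n_retained = n_retained,
                               loadings = loading))
}

#' Score a cohort under one or all weighting schemes
#'
#' Convenience wrapper running the full scoring chain: component scoring
#' on cohort-derived tertiles, then the requested weighting scheme(s).
#'
#' @param cohort Data frame with exposures (plus `age`, `sex`, `area`,
#'   `bmi` and `outcome` when the beta scheme is requested).
#' @param scheme `"equal"`, `"beta"`, `"pca"`, or `"all"`.
#' @param outcome Binary outcome for the beta scheme.
#' @param ... Passed to [obs_score_components()].
#' @return For a single scheme, an `obs_result`; for `"all"`, a named list
#'   of the three.
#' @export
score_obs <- function(cohort, scheme = c("equal", "beta", "pca", "all"),
                      outcome = NULL, ...) {
  scheme <- match.arg(scheme)
  scores <- obs_score_components(cohort, ...)
  one <- function(sch) switch(sch,
    equal = obs_equal(scores),
    beta = {
      if (is.null(outcome)) stop("beta scheme needs an outcome", call. = FALSE)
      obs_beta(scores, cohort, outcome)
    },
    pca = obs_pca(scores))
  if (scheme == "all") {
    res <- lapply(c("equal", "beta", "pca"), one)
    names(res) <- c("equal", "beta", "pca")
    res
  } else one(scheme)
}
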