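#' NCEP-ATP III metabolic syndrome criteria (Korean waist cut-offs)
#'
#' Immutable defaults, overridable per argument: abdominal obesity at waist
#' >= 90 cm (men) / >= 85 cm (women), triglycerides >= 150 mg/dL, HDL
#' < 40 (men) / < 50 (women) mg/dL, blood pressure >= 130 systolic or
#' >= 85 diastolic mmHg or antihypertensive medication, fasting glucose
#' >= 100 mg/dL or antidiabetic medication; metabolic syndrome = at least
#' `n_components` (3) positive components. All thresholds are inclusive on
#' the adverse side exactly as written.
#'
#' @param waist_male,waist_female,tg,hdl_male,hdl_female,sbp,dbp,glucose
#'   Clinical cut-offs.
#' @param n_components Component count defining the syndrome.
#' @return A named list of class `mets_criteria`.
#' @export
mets_criteria <- function(waist_male = 90, waist_female = 85, tg = 150,
                          hdl_male = 40, hdl_female = 50,
                          sbp = 130, dbp = 85, glucose = 100,
                          n_components = 3L) {
  structure(list(waist_male = waist_male, waist_female = waist_female,
                 tg = tg, hdl_male = hdl_male, hdl_female = hdl_female,
                 sbp = sbp, dbp = dbp, glucose = glucose,
                 n_components = as.integer(n_components)),
            class = "mets_criteria")
}

#' Classify metabolic syndrome and its five components
#'
#' Evaluates the five NCEP-ATP III components with sex-specific cut-offs;
#' antihypertensive medication forces the blood-pressure component and
#' antidiabetic medication (or insulin) the glucose component regardless of
#' measurements. Participants missing any required trait are flagged
#' `excluded` with `NA` statuses (complete-case policy).
#'
#' @param data Data frame with `sex` (M/F), `waist`, `tg`, `hdl`, `sbp`,
#'   `dbp`, `fpg`, and logical `antihypertensive`, `antidiabetic`
#'   (optionally `insulin`).
#' @param criteria A [mets_criteria()].
#' @return Data frame with the five component logicals
#'   (`abdominal_obesity`, `high_triglycerides`, `low_hdl`,
#'   `high_blood_pressure`, `high_fasting_glucose`), `mets_score` (0-5),
#'   `mets`, and `excluded`.
#' @export
classify_mets <- function(data, criteria = mets_criteria()) {
  req <- c("sex", "waist", "tg", "hdl", "sbp", "dbp", "fpg",
           "antihypertensive", "antidiabetic")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  insulin <- if ("insulin" %in% names(data)) data$insulin else FALSE
  male <- data$sex == "M"
  ok <- stats::complete.cases(data[req])

  out <- data.frame(
    abdominal_obesity =
      data$waist >= ifelse(male, criteria$waist_male, criteria$waist_female),
    high_triglycerides = data$tg >= criteria$tg,
    low_hdl = data$hdl < ifelse(male, criteria$hdl_male, criteria$hdl_female),
    high_blood_pressure =
      data$sbp >= criteria$sbp | data$dbp >= criteria$dbp |
        data$antihypertensive,
    high_fasting_glucose =
      data$fpg >= criteria$glucose | data$antidiabetic | insulin)
  out$mets_score <- as.integer(rowSums(out))
  out$mets <- out$mets_score >= criteria$n_components
  out$excluded <- !ok
  out[!ok, setdiff(names(out), "excluded")] <- NA
  if ("id" %in% names(data)) out <- cbind(id = data$id, out)
  out
}

#' Classify diabetes
#'
#' Positive if fasting plasma glucose >= 126 mg/dL, 2-hour post-load
#' glucose >= 200 mg/dL, HbA1c >= 6.5%, or current insulin / oral
#' antidiabetic treatment. Missing criteria are ignored as long as at least
#' one is measurable (or a medication flag is present).
#'
#' @param fpg Fasting plasma glucose, mg/dL.
#' @param ogtt_2h 2-hour OGTT glucose, mg/dL (may be `NA`).
#' @param hba1c HbA1c, percent (may be `NA`).
#' @param insulin,antidiabetic Logical medication flags.
#' @return Logical vector.
#' @export
classify_diabetes <- function(fpg = NA_real_, ogtt_2h = NA_real_,
                              hba1c = NA_real_, insulin = FALSE,
                              antidiabetic = FALSE) {
  n <- max(length(fpg), length(ogtt_2h), length(hba1c),
           length(insulin), length(antidiabetic))
  fpg <- rep_len(fpg, n); ogtt_2h <- rep_len(ogtt_2h, n)
  hba1c <- rep_len(hba1c, n)
  insulin <- rep_len(insulin, n); antidiabetic <- rep_len(antidiabetic, n)
  all_missing <- is.na(fpg) & is.na(ogtt_2h) & is.na(hba1c) &
    is.na(insulin) & is.na(antidiabetic)
  if (any(all_missing))
    stop("all diabetes criteria missing for ", sum(all_missing),
         " participant(s)", call. = FALSE)
  crit <- cbind(fpg >= 126, ogtt_2h >= 200, hba1c >= 6.5,
                insulin, antidiabetic)
  apply(crit, 1, function(r) any(r, na.rm = TRUE))
}
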