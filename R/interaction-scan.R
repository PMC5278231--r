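# Wald standard errors from a glm.fit object (mirrors summary.glm's use of
# the pivoted QR of the weighted design).
glmfit_se <- function(fit) {
  p <- fit$rank
  p1 <- seq_len(p)
  covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- rep(NA_real_, length(fit$coefficients))
  names(se) <- names(fit$coefficients)
  se[fit$qr$pivot[p1]] <- sqrt(diag(covmat))
  se
}

#' Additive minor-allele coding of a genotype matrix
#'
#' Recodes dosages so each SNP counts copies of its minor allele (0/1/2):
#' SNPs whose coded allele has sample frequency above 0.5 are flipped
#' `2 - g`. Monomorphic SNPs are flagged for skipping.
#'
#' @param genotypes Participants x SNPs matrix of allele counts in
#'   `{0, 1, 2}` (`NA` allowed).
#' @return A list: `dosage` (recoded matrix), `maf` (sample minor-allele
#'   frequency per SNP), `flipped` (logical), `monomorphic` (logical).
#' @export
code_additive <- function(genotypes) {
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  flipped <- !is.na(af) & af > 0.5
  dosage <- genotypes
  if (any(flipped))
    dosage[, flipped] <- 2L - genotypes[, flipped, drop = FALSE]
  maf <- pmin(af, 1 - af)
  monomorphic <- is.na(maf) | maf == 0
  list(dosage = dosage, maf = maf, flipped = flipped,
       monomorphic = monomorphic)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test conditioning on the observed allele counts: the p-value sums
#' the probabilities of all heterozygote counts no more probable than the
#' observed one.
#'
#' @param n_het Heterozygote count.
#' @param n_hom_minor,n_hom_major Homozygote counts.
#' @return Exact p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  if (n == 0) return(1)
  n_minor <- 2 * n_hom_minor + n_het
  if (n_minor > n) n_minor <- 2L * n - n_minor
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  n_aa <- (n_minor - hets) / 2
  n_AA <- n - n_aa - hets
  lp <- hets * log(2) - lgamma(n_aa + 1) - lgamma(hets + 1) - lgamma(n_AA + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Per-SNP quality control
#'
#' Conventional marginal-scan defaults: call rate >= 0.95, minor-allele
#' frequency >= 0.01, Hardy-Weinberg exact p >= 1e-6.
#'
#' @param genotypes Participants x SNPs dosage matrix.
#' @param min_call_rate,min_maf,min_hwe_p QC thresholds.
#' @return Logical vector: SNP passes QC.
#' @export
snp_qc <- function(genotypes, min_call_rate = 0.95, min_maf = 0.01,
                   min_hwe_p = 1e-6) {
  call_rate <- colMeans(!is.na(genotypes))
  coded <- code_additive(genotypes)
  hwe <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- coded$dosage[, j]
    g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 1), sum(g == 2), sum(g == 0))
  }, numeric(1))
  call_rate >= min_call_rate & !coded$monomorphic &
    coded$maf >= min_maf & hwe >= min_hwe_p
}

#' Fit the per-SNP gene-by-OBS interaction model
#'
#' Maximum-likelihood logistic fit of
#' `logit P(case) = b0 + b_age Age + b_sex Sex + b_area Area + b_obs OBS +
#' b_bmi BMI + b_g G + b_gobs G*OBS`
#' with a 1-df test of the product term (Wald by default, likelihood-ratio
#' optionally).
#'
#' @param dosage Additive minor-allele dosage vector (`NA` dropped,
#'   per-SNP complete case).
#' @param obs Continuous OBS (the regression-coefficient-weighted score by
#'   convention); standardized to unit variance when `standardize_obs`.
#' @param status Binary outcome.
#' @param covariates Data frame with `age`, `sex`, `area`, `bmi`.
#' @param test `"wald"` or `"lrt"` for the interaction p-value.
#' @param standardize_obs Scale the OBS to mean 0, variance 1 first?
#' @return A list: `beta` (named coefficients), `se`, `beta_g`, `beta_gobs`,
#'   `se_g`, `se_gobs`, `p` (interaction), `n`, `converged`.
#' @export
fit_gxe <- function(dosage, obs, status, covariates,
                    test = c("wald", "lrt"), standardize_obs = TRUE) {
  test <- match.arg(test)
  if (standardize_obs) obs <- as.numeric(scale(obs))
  base <- stats::model.matrix(~ age + sex + area + bmi, data = covariates)
  keep <- !is.na(dosage)
  X <- cbind(base, obs = obs, g = dosage, gobs = dosage * obs)[keep, , drop = FALSE]
  y <- as.integer(status)[keep]
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  se <- tryCatch(glmfit_se(fit), error = function(e) rep(NA_real_, ncol(X)))
  beta <- fit$coefficients
  converged <- isTRUE(fit$converged) && fit$rank == ncol(X) &&
    all(is.finite(beta)) && all(is.finite(se)) && max(abs(beta)) < 15
  p <- NA_real_
  if (converged) {
    if (test == "wald") {
      z <- beta[["gobs"]] / se[["gobs"]]
      p <- 2 * stats::pnorm(-abs(z))
    } else {
      fit0 <- suppressWarnings(
        stats::glm.fit(X[, colnames(X) != "gobs", drop = FALSE], y,
                       family = stats::binomial()))
      p <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                         lower.tail = FALSE)
    }
    p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  }
  list(beta = beta, se = se,
       beta_g = beta[["g"]], beta_gobs = beta[["gobs"]],
       se_g = se[["g"]], se_gobs = se[["gobs"]],
       p = p, n = sum(keep), converged = converged)
}

#' Genome-wide SNP-by-OBS interaction scan
#'
#' Runs [fit_gxe()] for every polymorphic SNP in deterministic column
#' order and attaches Benjamini-Hochberg q-values over the converged
#' interaction p-values. Chunked processing gives identical results to a
#' single pass (pure refactoring of the loop).
#'
#' @param genotypes Participants x SNPs matrix of allele counts.
#' @param obs Continuous OBS vector.
#' @param status Binary outcome.
#' @param covariates Data frame with `age`, `sex`, `area`, `bmi`.
#' @param snps Optional SNP metadata (`snp`, `chr`, `pos`) merged into the
#'   result; must cover every column of `genotypes`.
#' @param test,standardize_obs Passed to [fit_gxe()].
#' @param chunk_size SNPs per processing chunk (`NULL` = one pass).
#' @param verbose Log progress every chunk?
#' @return Data frame of class `gxe_scan`: one row per polymorphic SNP
#'   (`snp`, optional `chr`/`pos`, `maf`, `n`, `beta_g`, `se_g`,
#'   `beta_gobs`, `se_gobs`, `p`, `q`, `converged`), with attribute
#'   `"skipped"` (monomorphic SNP ids) and `"obs_scheme"` passed through
#'   from `attr(obs, "scheme")` when present.
#' @export
scan_gxe <- function(genotypes, obs, status, covariates, snps = NULL,
                     test = c("wald", "lrt"), standardize_obs = TRUE,
                     chunk_size = NULL, verbose = FALSE) {
  test <- match.arg(test)
  n <- nrow(genotypes)
  if (length(obs) != n || length(status) != n || nrow(covariates) != n)
    stop("participant dimensions are not aligned", call. = FALSE)
  if (!is.null(rownames(genotypes)) && .row_names_info(covariates) > 0 &&
      !identical(rownames(genotypes), rownames(covariates)))
    stop("participant ids of genotypes and covariates disagree",
         call. = FALSE)
  snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%06d", seq_len(ncol(genotypes)))
  coded <- code_additive(genotypes)
  poly <- which(!coded$monomorphic)
  skipped <- snp_ids[coded$monomorphic]
  if (standardize_obs) obs <- as.numeric(scale(obs))

  chunks <- if (is.null(chunk_size)) list(poly) else
    split(poly, ceiling(seq_along(poly) / chunk_size))
  rows <- vector("list", length(poly))
  k <- 0L
  for (ch in chunks) {
    for (j in ch) {
      f <- fit_gxe(coded$dosage[, j], obs, status, covariates,
                   test = test, standardize_obs = FALSE)
      k <- k + 1L
      rows[[k]] <- data.frame(snp = snp_ids[j], maf = coded$maf[j],
                              n = f$n, beta_g = f$beta_g, se_g = f$se_g,
                              beta_gobs = f$beta_gobs, se_gobs = f$se_gobs,
                              p = f$p, converged = f$converged,
                              stringsAsFactors = FALSE)
    }
    if (verbose)
      message(sprintf("scanned %d / %d SNPs", k, length(poly)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- bh_qvalue(out$p[ok])
  if (!is.null(snps)) {
    m <- match(out$snp, snps$snp)
    if (anyNA(m)) stop("snps metadata does not cover all scanned SNPs",
                       call. = FALSE)
    out <- cbind(out[, "snp", drop = FALSE],
                 snps[m, c("chr", "pos"), drop = FALSE],
                 out[, setdiff(names(out), "snp"), drop = FALSE])
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  attr(out, "obs_scheme") <- attr(obs, "scheme")
  attr(out, "test") <- test
  class(out) <- c("gxe_scan", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjusted p-values with enforced
#' monotonicity (the standard BH adjustment).
#'
#' @param p Numeric p-values in `(0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_qvalue <- function(p) {
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
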