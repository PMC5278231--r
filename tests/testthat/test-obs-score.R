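toy_cohort <- function(n = 9, seed = 1) {
  set.seed(seed)
  data.frame(iron = stats::rlnorm(n, 2, 0.5), vitc = stats::rlnorm(n, 4, 0.5),
             retinol = stats::rlnorm(n, 4, 0.7),
             carotene = stats::rlnorm(n, 7, 0.6),
             activity = stats::rnorm(n, 82, 20),
             smoking = sample(c("never", "former", "current"), n, TRUE),
             alcohol = ifelse(stats::runif(n) < 0.5, 0,
                              stats::rlnorm(n, 2.7, 1)))
}

test_that("log transform spares physical activity and handles zeros", {
  cohort <- toy_cohort(50)
  tr <- obs_log_transform(cohort)
  expect_identical(tr$activity, cohort$activity)
  expect_identical(tr$smoking, cohort$smoking)
  expect_equal(tr$vitc, log(cohort$vitc))
  # alcohol contains zeros -> offset applied
  expect_equal(tr$alcohol, log(cohort$alcohol + 1))
  ones <- cohort
  ones$vitc <- 1
  expect_equal(obs_log_transform(ones)$vitc, rep(0, 50))
  neg <- cohort
  neg$iron[3] <- -1
  expect_error(obs_log_transform(neg), "negative")
  # symmetry restored on a log-normal sample
  set.seed(4)
  x <- stats::rlnorm(10000, 3, 0.8)
  skew <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  expect_lt(abs(skew(log(x))), 0.1)
  expect_gt(skew(x), 1)
})

test_that("tertile cut-points partition 1..9 into equal thirds", {
  cp <- obs_tertiles(1:9)
  grp <- (1:9 > cp[1]) + (1:9 > cp[2])
  expect_equal(grp, rep(0:2, each = 3))
  expect_error(obs_tertiles(rep(5, 10)), "distinct")
  expect_error(obs_tertiles(c(1, 1, 1, 1, 1, 1, 2, 3)), "degenerate")
})

test_that("component scoring follows the assignment scheme", {
  cohort <- toy_cohort(30)
  # physical-activity tertiles published for the reference cohort:
  # 0-72.7 MET/day = 0; 72.8-92.4 = 1; >= 92.5 = 2
  cohort$activity[1:4] <- c(80, 72.7, 92.4, 92.5)
  cohort$smoking[1:3] <- c("current", "former", "never")
  cohort$alcohol[1:2] <- c(60, 10)
  cuts <- list(iron = obs_tertiles(cohort$iron),
               vitc = obs_tertiles(cohort$vitc),
               retinol = obs_tertiles(cohort$retinol),
               carotene = obs_tertiles(cohort$carotene),
               activity = c(72.7, 92.4))
  sc <- obs_score_components(cohort, cutpoints = cuts)
  expect_equal(sc$activity_score[1:4], c(1L, 0L, 1L, 2L))
  expect_equal(sc$smoking_score[1:3], c(0L, 1L, 2L))
  expect_equal(sc$alcohol_score[1:2], c(0L, 2L))
  # prooxidant iron scores inversely with tertile
  top_iron <- cohort$iron > cuts$iron[2]
  expect_true(all(sc$iron_score[top_iron] == 0L))
  bottom_iron <- cohort$iron <= cuts$iron[1]
  expect_true(all(sc$iron_score[bottom_iron] == 2L))
  expect_true(all(as.matrix(sc) %in% 0:2))
  bad <- cohort
  bad$smoking[5] <- "pipe"
  expect_error(obs_score_components(bad, cutpoints = cuts), "pipe")
})

test_that("equal-weight OBS spans 0-14 and steps by component units", {
  maxi <- data.frame(iron_score = 2L, vitc_score = 2L, retinol_score = 2L,
                     carotene_score = 2L, activity_score = 2L,
                     smoking_score = 2L, alcohol_score = 2L)
  mini <- maxi; mini[] <- 0L
  scores <- rbind(maxi, mini, maxi, maxi, maxi)
  scores$vitc_score[3] <- 1L           # one vitamin-C tertile step down
  scores$alcohol_score[4] <- 0L
  s <- rowSums(scores)
  expect_equal(s[1:4], c(14, 0, 13, 12))
  cohort <- toy_cohort(200)
  res <- obs_equal(obs_score_components(cohort))
  expect_true(all(res$score >= 0 & res$score <= 14))
})

test_that("equal-weight OBS is monotone in its components", {
  set.seed(7)
  for (i in 1:50) {
    base <- as.data.frame(matrix(sample(0:2, 7, TRUE), nrow = 1,
      dimnames = list(NULL, c("iron_score", "vitc_score", "retinol_score",
                              "carotene_score", "activity_score",
                              "smoking_score", "alcohol_score"))))
    up <- base
    col <- sample(names(base), 1)
    up[[col]] <- min(up[[col]] + 1L, 2L)
    expect_gte(rowSums(up), rowSums(base))
  }
})

test_that("tertile scoring is invariant to monotone exposure transforms", {
  cohort <- toy_cohort(300, seed = 8)
  raw <- obs_score_components(cohort)
  logged <- obs_score_components(obs_log_transform(cohort),
                                 alcohol_cutoff = log(50 + 1))
  expect_identical(raw, logged, ignore_attr = TRUE)
  expect_equal(obs_equal(raw)$score, obs_equal(logged)$score)
  cubed <- cohort
  for (col in c("iron", "vitc", "retinol", "carotene", "activity"))
    cubed[[col]] <- cohort[[col]]^3
  cubed_sc <- obs_score_components(cubed)
  expect_equal(rowSums(raw), rowSums(cubed_sc))
})

test_that("beta weights are minus the fitted coefficients and recover truth", {
  st <- small_study(n = 2500, seed = 31)
  scores <- obs_score_components(st$cohort)
  # outcome driven by vitamin C alone, known log-odds -0.6
  set.seed(1)
  y <- stats::rbinom(nrow(scores), 1,
                     stats::plogis(-0.5 - 0.6 * scores$vitc_score))
  res <- obs_beta(scores, st$cohort, y)
  w <- attr(res, "weights")
  cf <- attr(res, "provenance")$coefficients
  expect_equal(unname(w), unname(-cf[names(w)]))
  expect_gt(w[["vitc_score"]], 0.3)     # protective => positive weight
  se <- attr(res, "provenance")$se["vitc_score"]
  expect_lt(abs(w[["vitc_score"]] - 0.6), 1.96 * se)
  others <- setdiff(names(w), "vitc_score")
  expect_true(all(abs(w[others]) < 0.25))
  expect_equal(res$score,
               as.numeric(as.matrix(scores[names(w)]) %*% w))
})

test_that("beta weights are near zero when the outcome is independent", {
  st <- small_study(n = 3000, seed = 32)
  scores <- obs_score_components(st$cohort)
  set.seed(2)
  y <- stats::rbinom(nrow(scores), 1, 0.3)
  w <- attr(obs_beta(scores, st$cohort, y), "weights")
  expect_true(all(abs(w) < 0.2))
})

test_that("PCA weighting handles rank-1 structure and orients loadings", {
  z <- stats::rnorm(100)
  cols <- c("iron_score", "vitc_score", "retinol_score", "carotene_score",
            "activity_score", "smoking_score", "alcohol_score")
  rank1 <- as.data.frame(stats::setNames(rep(list(z), 7), cols))
  res1 <- obs_pca(rank1)
  prov <- attr(res1, "provenance")
  expect_equal(prov$eigenvalues[1], 7, tolerance = 1e-8)
  expect_equal(unname(abs(prov$loadings)), rep(1 / sqrt(7), 7),
               tolerance = 1e-8)
  expect_gt(mean(prov$loadings[c("vitc_score", "retinol_score",
                                 "carotene_score", "activity_score")]), 0)

  set.seed(12)
  iid <- as.data.frame(stats::setNames(
    lapply(1:7, function(i) stats::rnorm(4000)), cols))
  prov2 <- attr(obs_pca(iid), "provenance")
  expect_true(all(abs(prov2$eigenvalues - 1) < 0.2))
  expect_lte(prov2$n_retained, 4)

  degen <- iid; degen$alcohol_score <- 1
  expect_error(obs_pca(degen), "zero-variance")
})

test_that("quartiles cut at empirical quarters and are rank-invariant", {
  q <- obs_quartiles(1:8)
  expect_equal(as.integer(table(q)), rep(2L, 4))
  expect_identical(q, obs_quartiles(exp(1:8)))
  expect_error(obs_quartiles(rep(3, 10)), "distinct")
  expect_error(obs_quartiles(c(rep(1, 50), 2, 3, 4)), "collapse")
  set.seed(3)
  x <- stats::rnorm(1000)
  expect_identical(obs_quartiles(x), obs_quartiles(stats::pnorm(x)))
  # near-equal partition for continuous scores
  expect_true(all(abs(table(obs_quartiles(x)) - 250) <= 1))
  expect_true(all(levels(q) == paste0("Q", 1:4)))
})

test_that("quartile sizes differ only by boundary ties", {
  st <- small_study(n = 2000, seed = 33)
  res <- obs_equal(obs_score_components(st$cohort))
  sizes <- table(res$quartile)
  expect_equal(sum(sizes), 2000)
  # every participant in exactly one quartile
  expect_false(anyNA(res$quartile))
  # tied integer scores may distort sizes, but cut order must hold
  m <- tapply(res$score, res$quartile, max)
  expect_true(all(diff(m) > 0))
})
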