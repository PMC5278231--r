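#' Simulate a baseline cohort of exposures and covariates
#'
#' Draws per-participant covariates and the seven oxidative-balance
#' exposures: four log-normal nutrient intakes (vitamin C, retinol,
#' carotene, iron), smoking status, zero-inflated log-normal alcohol
#' consumption, and truncated-normal physical activity. Ages are uniform on
#' 40-75 years (population-based cohort of adults aged >= 40).
#'
#' @param config A [sim_config()].
#' @return A `data.frame` with one row per participant: `id`, `age`, `sex`
#'   (M/F), `area` (rural/urban), `bmi`, `vitc`, `retinol`, `carotene`,
#'   `iron` (intakes per day), `smoking` (never/former/current), `alcohol`
#'   (g/day), `activity` (MET/day), and medication flags
#'   `antihypertensive`, `antidiabetic`, `insulin`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_participants
  set.seed(sim_seed(config, "cohort"))
  cohort <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    age = stats::runif(n, 40, 75),
    sex = factor(sample(c("M", "F"), n, replace = TRUE), levels = c("M", "F")),
    area = factor(sample(c("rural", "urban"), n, replace = TRUE),
                  levels = c("rural", "urban")),
    bmi = stats::rnorm(n, 24.5, 3),
    vitc = stats::rlnorm(n, log(90), 0.6),
    retinol = stats::rlnorm(n, log(55), 0.8),
    carotene = stats::rlnorm(n, log(2300), 0.7),
    iron = stats::rlnorm(n, log(9.3), 0.45),
    smoking = factor(sample(c("never", "former", "current"), n,
                            replace = TRUE, prob = c(0.62, 0.19, 0.19)),
                     levels = c("never", "former", "current")),
    alcohol = 0,
    activity = pmax(stats::rnorm(n, 82, 21), 0),
    antihypertensive = stats::runif(n) < 0.08,
    antidiabetic = stats::runif(n) < 0.05,
    insulin = stats::runif(n) < 0.01,
    stringsAsFactors = FALSE)
  # ~50% drinkers; conditional intake log-normal => ~5% of the cohort at or
  # above the 50 g/day heavy-drinking cut.
  drinker <- stats::runif(n) < 0.5
  cohort$alcohol[drinker] <- stats::rlnorm(sum(drinker), log(15), 1)
  if (config$missing_fraction > 0) {
    for (col in c("vitc", "retinol", "carotene", "iron")) {
      miss <- stats::runif(n) < config$missing_fraction
      cohort[[col]][miss] <- NA_real_
    }
  }
  cohort
}

#' Simulate gene intervals and pathway gene sets
#'
#' Places non-overlapping gene intervals on two chromosomes with
#' inter-gene gaps wide enough that every gene has both a flanking
#' (within `config$flank` bp) and a distal region, then samples pathways as
#' gene-id sets with sizes in `pathway_size_range`. Causal pathways are the
#' first `length(causal_pathways)` pathway ids; causal SNPs are later drawn
#' from genes of those pathways, so the pathways contain their host genes
#' by construction.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (a [GenomicRanges::GRanges] with `gene_id`
#'   metadata, 1-based inclusive coordinates), `pathways` (named list of
#'   gene-id character vectors), and `pathway_sources` (named character
#'   vector labelling each set KEGG/Biocarta/GO-style).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "annotation"))
  ng <- config$n_genes
  chrom <- rep(c("chr1", "chr2"), length.out = ng)
  len <- round(stats::runif(ng, 10000, 30000))
  # start-to-start spacing leaves > 2*flank between consecutive gene bodies
  gap <- round(stats::runif(ng, 2 * config$flank + 60000, 2 * config$flank + 200000))
  start <- integer(ng)
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    start[i] <- 50000L + cumsum(c(0L, (len[i] + gap[i])[-length(i)]))
  }
  genes <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = start + len - 1L),
    gene_id = sprintf("G%04d", seq_len(ng)))
  sizes <- sample(seq(config$pathway_size_range[1],
                      config$pathway_size_range[2]),
                  config$n_pathways, replace = TRUE)
  pathways <- lapply(sizes, function(s)
    sort(sample(genes$gene_id, s, replace = FALSE)))
  names(pathways) <- sprintf("PW%03d", seq_len(config$n_pathways))
  sources <- sample(c("KEGG", "Biocarta", "GO"), config$n_pathways,
                    replace = TRUE, prob = c(0.4, 0.3, 0.3))
  names(sources) <- names(pathways)
  missing_causal <- setdiff(config$causal_pathways, names(pathways))
  if (length(missing_causal) > 0)
    stop("causal pathway id(s) not generated: ",
         paste(missing_causal, collapse = ", "), call. = FALSE)
  list(genes = genes, pathways = pathways, pathway_sources = sources)
}

#' Simulate biallelic genotypes and SNP metadata
#'
#' Dosages are drawn per SNP as Binomial(2, maf) (Hardy-Weinberg
#' proportions) with maf uniform in `config$maf_range`. SNP positions are
#' placed relative to the simulated genes so that the configured fractions
#' fall inside gene bodies, within `flank` bp of a gene, or beyond the
#' flank of every gene.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()]; regenerated from
#'   `config` when omitted (deterministic given the seed).
#' @return A list with `genotypes` (participants x SNPs integer matrix of
#'   minor-allele dosages, dimnames set) and `snps` (data.frame: `snp`,
#'   `chr`, `pos` (1-based), `a1`, `a2`, `maf`, `placement`, `gene`).
#' @export
simulate_genotypes <- function(config, annotation = simulate_annotation(config)) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "genotypes"))
  n <- config$n_participants
  m <- config$n_snps
  genes <- annotation$genes
  gstart <- GenomicRanges::start(genes)
  gend <- GenomicRanges::end(genes)
  gchr <- as.character(GenomicRanges::seqnames(genes))
  flank <- config$flank

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  placement <- sample(names(config$snp_placement), m, replace = TRUE,
                      prob = config$snp_placement)
  host <- sample(length(genes), m, replace = TRUE)
  pos <- integer(m)
  for (j in seq_len(m)) {
    g <- host[j]
    pos[j] <- switch(placement[j],
      inside = round(stats::runif(1, gstart[g], gend[g])),
      near = {
        off <- sample.int(flank, 1L)
        if (stats::runif(1) < 0.5 && gstart[g] - off >= 1L)
          gstart[g] - off else gend[g] + off
      },
      far = gend[g] + flank + sample.int(50000L, 1L) + 1L)
  }
  alle <- t(replicate(m, sample(c("A", "C", "G", "T"), 2)))
  geno <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)),
                 nrow = n, ncol = m)
  snp_id <- sprintf("rs%06d", seq_len(m))
  dimnames(geno) <- list(sprintf("S%05d", seq_len(n)), snp_id)
  snps <- data.frame(snp = snp_id, chr = gchr[host], pos = pos,
                     a1 = alle[, 1], a2 = alle[, 2], maf = maf,
                     placement = placement, gene = genes$gene_id[host],
                     stringsAsFactors = FALSE)
  list(genotypes = geno, snps = snps)
}

#' Select causal SNPs and record planted effects
#'
#' Draws `n_causal_snps_per_pathway` SNPs from inside gene bodies of each
#' configured causal pathway and records the planted genotype main effect
#' and SNP-by-OBS interaction coefficient for each, plus the liability and
#' marker coefficients used by the outcome generators. Every causal SNP
#' lies inside a gene of its pathway, hence maps to it under the
#' gene +/- flank rule.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @param snps SNP metadata from [simulate_genotypes()].
#' @return A list of class `sim_truth`: `causal` (data.frame `snp`,
#'   `pathway`, `beta_g`, `beta_gobs`), `obs_main_beta`, `marker_slopes`,
#'   `liability` (covariate coefficients).
#' @export
simulate_truth <- function(config, annotation, snps) {
  validate_sim_config(config)
  set.seed(sim_seed(config, "truth"))
  causal <- data.frame(snp = character(0), pathway = character(0),
                       beta_g = numeric(0), beta_gobs = numeric(0),
                       stringsAsFactors = FALSE)
  for (pw in config$causal_pathways) {
    pw_genes <- annotation$pathways[[pw]]
    pool <- snps$snp[snps$placement == "inside" & snps$gene %in% pw_genes]
    pool <- setdiff(pool, causal$snp)
    if (length(pool) < config$n_causal_snps_per_pathway)
      stop(sprintf("pathway %s hosts only %d in-gene SNPs (< %d requested)",
                   pw, length(pool), config$n_causal_snps_per_pathway),
           call. = FALSE)
    chosen <- sample(pool, config$n_causal_snps_per_pathway)
    causal <- rbind(causal, data.frame(
      snp = chosen, pathway = pw,
      beta_g = config$snp_main_beta,
      beta_gobs = config$interaction_beta, stringsAsFactors = FALSE))
  }
  structure(list(causal = causal,
                 obs_main_beta = config$obs_main_beta,
                 marker_slopes = config$marker_obs_slopes,
                 liability = c(age = 0.03, sexF = 0.20, bmi = 0.25)),
            class = "sim_truth")
}

# Standardized equal-weight OBS: the "true antioxidant index" that outcome
# generators plant effects on. Equal weighting keeps the truth independent
# of any fitted weighting scheme.
true_antioxidant_index <- function(cohort) {
  scores <- obs_score_components(cohort)
  as.numeric(scale(rowSums(scores)))
}

# Shared linear predictor of planted genetic effects. The interaction is
# planted on the centered dosage: the per-SNP model still estimates
# beta_gobs on the raw product (the shift is absorbed by the OBS main
# term), but the planted interactions no longer distort the marginal
# OBS-outcome association.
genetic_effects <- function(genotypes, truth, index) {
  eta <- numeric(nrow(genotypes))
  if (nrow(truth$causal) == 0) return(eta)
  G <- genotypes[, truth$causal$snp, drop = FALSE]
  Gc <- sweep(G, 2, colMeans(G))
  eta <- as.numeric(G %*% truth$causal$beta_g) +
    as.numeric((Gc * index) %*% truth$causal$beta_gobs)
  eta
}

#' Simulate metabolic outcomes, traits and inflammation markers
#'
#' Liability-threshold generation of the five metabolic-syndrome
#' components: each component's latent liability is a sum of covariate
#' effects, `obs_main_beta` times the standardized antioxidant index
#' (equal-weight OBS), planted causal-SNP main and interaction effects, and
#' Gaussian noise. Liabilities are thresholded at the empirical quantile
#' that yields the configured prevalence; for blood pressure and glucose,
#' medicated participants count as positive and the threshold for the rest
#' is adjusted so the total prevalence still matches. Continuous trait
#' values (waist, triglycerides, HDL, blood pressures, fasting glucose) are
#' emitted around the clinical cut-offs so that NCEP-ATP III classification
#' reproduces the intended binary states exactly. CRP is log-linear and WBC
#' linear in the antioxidant index.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param genotypes Genotype matrix from [simulate_genotypes()].
#' @param truth Output of [simulate_truth()].
#' @param config A [sim_config()].
#' @return `cohort` augmented with `waist`, `tg`, `hdl`, `sbp`, `dbp`,
#'   `fpg`, `ogtt_2h`, `hba1c`, `crp`, `wbc`, the intended component states
#'   `true_abdominal_obesity`, `true_high_triglycerides`, `true_low_hdl`,
#'   `true_high_blood_pressure`, `true_high_fasting_glucose`, and
#'   `true_mets`.
#' @export
simulate_outcomes <- function(cohort, genotypes, truth, config) {
  validate_sim_config(config)
  n <- nrow(cohort)
  if (nrow(genotypes) != n)
    stop("cohort and genotype matrix are not row-aligned", call. = FALSE)
  if (!is.null(rownames(genotypes)) &&
      !identical(rownames(genotypes), cohort$id))
    stop("cohort ids and genotype rownames disagree", call. = FALSE)
  set.seed(sim_seed(config, "outcomes"))
  idx <- true_antioxidant_index(cohort)
  gen <- genetic_effects(genotypes, truth, idx)
  lia <- truth$liability
  covar_eta <- lia["age"] * (cohort$age - 57.5) +
    lia["sexF"] * (cohort$sex == "F") +
    lia["bmi"] * (cohort$bmi - 24.5) / 3
  prev <- config$component_prevalences

  liab_state <- function(prevalence, med = NULL, extra_covar = 0) {
    L <- covar_eta + extra_covar + truth$obs_main_beta * idx + gen +
      stats::rnorm(n, 0, config$noise_sd)
    if (is.null(med)) {
      t0 <- stats::quantile(L, 1 - prevalence, names = FALSE)
      list(L = L, t = t0, state = L > t0)
    } else {
      p_med <- mean(med)
      adj <- max((prevalence - p_med) / (1 - p_med), 0.001)
      t0 <- stats::quantile(L[!med], 1 - adj, names = FALSE)
      list(L = L, t = t0, state = (L > t0) | med)
    }
  }
  # abdominal obesity leans harder on BMI than the shared covariate set
  ob <- liab_state(prev[[1]], extra_covar = 0.6 * (cohort$bmi - 24.5) / 3)
  tg <- liab_state(prev[[2]])
  hd <- liab_state(prev[[3]])
  bp <- liab_state(prev[[4]], med = cohort$antihypertensive)
  gl <- liab_state(prev[[5]], med = cohort$antidiabetic | cohort$insulin)

  # Continuous traits: linear in (L - t) around each clinical cut-off, with
  # a small guard band so classification never flips on rounding; clipped
  # far from the threshold to stay physiological.
  gap <- function(state, d) ifelse(state, d, -d)
  waist_thr <- ifelse(cohort$sex == "M", 90, 85)
  raw_ob <- ob$L > ob$t   # trait follows liability; meds absent here
  cohort$waist <- pmax(waist_thr + 6 * (ob$L - ob$t) + gap(raw_ob, 0.5), 55)
  cohort$tg <- pmax(150 + 70 * (tg$L - tg$t) + gap(tg$L > tg$t, 2), 30)
  hdl_thr <- ifelse(cohort$sex == "M", 40, 50)
  cohort$hdl <- pmax(hdl_thr - 8 * (hd$L - hd$t) - gap(hd$L > hd$t, 0.5), 10)
  raw_bp <- bp$L > bp$t
  cohort$sbp <- pmax(130 + 10 * (bp$L - bp$t) + gap(raw_bp, 0.5), 85)
  cohort$dbp <- pmax(85 + 6 * (bp$L - bp$t) + gap(raw_bp, 0.4) - 2, 50)
  raw_gl <- gl$L > gl$t
  cohort$fpg <- pmax(100 + 12 * (gl$L - gl$t) + gap(raw_gl, 0.5), 60)
  cohort$ogtt_2h <- pmax(2 * cohort$fpg - 60 + stats::rnorm(n, 0, 15), 60)
  cohort$hba1c <- pmax(4.5 + 0.02 * (cohort$fpg - 80) + stats::rnorm(n, 0, 0.2), 3.5)

  slopes <- truth$marker_slopes
  cohort$crp <- exp(log(1.2) + slopes[["crp"]] * idx + stats::rnorm(n, 0, 0.7))
  cohort$wbc <- pmax(6.4 + slopes[["wbc"]] * idx + stats::rnorm(n, 0, 1.6), 1)

  cohort$true_abdominal_obesity <- ob$state
  cohort$true_high_triglycerides <- tg$state
  cohort$true_low_hdl <- hd$state
  cohort$true_high_blood_pressure <- bp$state
  cohort$true_high_fasting_glucose <- gl$state
  cohort$true_mets <- (ob$state + tg$state + hd$state + bp$state + gl$state) >= 3
  cohort
}

#' Simulate case status directly from the interaction logistic model
#'
#' Draws a binary outcome from the exact per-SNP logistic model used by the
#' interaction scan: logit P(case) = intercept + covariate effects +
#' `obs_main_beta` x standardized OBS + planted SNP main effects + planted
#' SNP-by-OBS interactions. This mode is for estimator calibration and
#' power studies, where the fitted interaction coefficient must target the
#' planted value exactly; the liability-threshold generator
#' ([simulate_outcomes()]) emulates the full clinical phenotype instead.
#'
#' @inheritParams simulate_outcomes
#' @param base_prevalence Approximate case fraction when all effects are 0.
#' @return A list: `status` (0/1 integer vector), `index` (the standardized
#'   antioxidant index the effects were planted on).
#' @export
simulate_gxe_status <- function(cohort, genotypes, truth, config,
                                base_prevalence = 0.25) {
  validate_sim_config(config)
  n <- nrow(cohort)
  if (nrow(genotypes) != n)
    stop("cohort and genotype matrix are not row-aligned", call. = FALSE)
  set.seed(sim_seed(config, "status"))
  idx <- true_antioxidant_index(cohort)
  eta <- stats::qlogis(base_prevalence) +
    0.02 * (cohort$age - 57.5) +
    0.15 * (cohort$sex == "F") +
    0.10 * (cohort$area == "urban") +
    0.10 * (cohort$bmi - 24.5) / 3 +
    truth$obs_main_beta * idx +
    genetic_effects(genotypes, truth, idx)
  status <- stats::rbinom(n, 1L, stats::plogis(eta))
  list(status = status, index = idx)
}

#' Simulate a complete synthetic study
#'
#' Orchestrates annotation, cohort, genotypes, ground truth and outcomes
#' into one reproducible bundle.
#'
#' @param config A [sim_config()].
#' @param outcome_model `"liability"` for the full clinical phenotype
#'   (default) or `"logistic"` for direct case status from the interaction
#'   model (adds `$status` and `$index`).
#' @return A list: `config`, `cohort` (with outcomes), `genotypes`, `snps`,
#'   `genes`, `pathways`, `pathway_sources`, `truth`, and for the logistic
#'   mode `status` and `index`.
#' @export
simulate_study <- function(config, outcome_model = c("liability", "logistic")) {
  outcome_model <- match.arg(outcome_model)
  ann <- simulate_annotation(config)
  cohort <- simulate_cohort(config)
  gt <- simulate_genotypes(config, ann)
  truth <- simulate_truth(config, ann, gt$snps)
  out <- list(config = config, genotypes = gt$genotypes, snps = gt$snps,
              genes = ann$genes, pathways = ann$pathways,
              pathway_sources = ann$pathway_sources, truth = truth)
  if (outcome_model == "liability") {
    out$cohort <- simulate_outcomes(cohort, gt$genotypes, truth, config)
  } else {
    st <- simulate_gxe_status(cohort, gt$genotypes, truth, config)
    out$cohort <- cohort
    out$status <- st$status
    out$index <- st$index
  }
  out
}
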