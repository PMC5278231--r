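#' Simulation configuration for a synthetic OBS/MetS study
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size, SNP
#' panel, gene/pathway annotation geometry, planted gene-by-OBS interaction
#' effects, metabolic-component prevalences, and inflammation-marker slopes.
#' Defaults emulate a Korean population-based cohort aged 40 years and over:
#' right-skewed nutrient intakes, roughly 62/19/19% never/former/current
#' smokers, half non-drinkers with ~5% heavy (>= 50 g/day) drinkers, and
#' component prevalences near 34% (abdominal obesity), 31% (high
#' triglycerides), 57% (low HDL), 22% (high blood pressure) and 19% (high
#' fasting glucose).
#'
#' @param n_participants Number of participants.
#' @param n_snps Number of biallelic SNPs.
#' @param n_genes Number of non-overlapping gene intervals.
#' @param n_pathways Number of gene sets.
#' @param pathway_size_range Length-2 integer vector, inclusive bounds on
#'   pathway sizes (in genes). Keep within the 20-200 enrichment filter if
#'   planted pathways must survive filtering.
#' @param maf_range Length-2 numeric in (0, 0.5]; minor-allele frequencies
#'   are drawn uniformly from this interval.
#' @param snp_placement Named fractions (`inside`, `near`, `far`) of SNPs
#'   placed within a gene body, within `flank` bp of a gene, or beyond.
#' @param causal_pathways Character vector of pathway ids carrying planted
#'   SNP-by-OBS interaction effects.
#' @param n_causal_snps_per_pathway Causal SNPs planted per causal pathway.
#' @param interaction_beta Planted log-odds per (dosage x standardized-OBS
#'   unit) for each causal SNP.
#' @param snp_main_beta Planted genotype main-effect log-odds per dosage
#'   unit for each causal SNP.
#' @param obs_main_beta Log-odds (liability units in liability mode) per
#'   standardized-OBS unit on each outcome.
#' @param component_prevalences Named fractions in (0,1) for the five
#'   metabolic components, in the order abdominal obesity, high
#'   triglycerides, low HDL, high blood pressure, high fasting glucose.
#' @param marker_obs_slopes Named slopes (`crp`, `wbc`) of log(CRP) and WBC
#'   on the standardized antioxidant index.
#' @param noise_sd Standard deviation of the liability noise.
#' @param missing_fraction Fraction of nutrient values set missing
#'   (default 0: complete cases, as in the motivating analysis).
#' @param flank Gene flank in bp used for SNP placement and mapping.
#' @param seed Integer seed; every generator derives its stream from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_participants = 2000L,
                       n_snps = 500L,
                       n_genes = 100L,
                       n_pathways = 20L,
                       pathway_size_range = c(20L, 30L),
                       maf_range = c(0.05, 0.5),
                       snp_placement = c(inside = 0.5, near = 0.3, far = 0.2),
                       causal_pathways = character(0),
                       n_causal_snps_per_pathway = 10L,
                       interaction_beta = 0,
                       snp_main_beta = 0,
                       obs_main_beta = -0.1,
                       component_prevalences = c(abdominal_obesity = 0.34,
                                                 high_triglycerides = 0.31,
                                                 low_hdl = 0.57,
                                                 high_blood_pressure = 0.22,
                                                 high_fasting_glucose = 0.19),
                       marker_obs_slopes = c(crp = -0.15, wbc = -0.35),
                       noise_sd = 1,
                       missing_fraction = 0,
                       flank = 100000L,
                       seed = 1L) {
  # unlist() so YAML round-trips (maps read back as lists) stay valid
  snp_placement <- unlist(snp_placement)
  component_prevalences <- unlist(component_prevalences)
  marker_obs_slopes <- unlist(marker_obs_slopes)
  cfg <- list(n_participants = as.integer(n_participants),
              n_snps = as.integer(n_snps),
              n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              maf_range = as.numeric(maf_range),
              snp_placement = snp_placement,
              causal_pathways = as.character(causal_pathways),
              n_causal_snps_per_pathway = as.integer(n_causal_snps_per_pathway),
              interaction_beta = as.numeric(interaction_beta),
              snp_main_beta = as.numeric(snp_main_beta),
              obs_main_beta = as.numeric(obs_main_beta),
              component_prevalences = component_prevalences,
              marker_obs_slopes = marker_obs_slopes,
              noise_sd = as.numeric(noise_sd),
              missing_fraction = as.numeric(missing_fraction),
              flank = as.integer(flank),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.na(cfg$n_participants) || cfg$n_participants <= 0L)
    stop("n_participants must be a positive integer", call. = FALSE)
  if (cfg$n_snps <= 0L) stop("n_snps must be positive", call. = FALSE)
  if (cfg$n_genes <= 0L) stop("n_genes must be positive", call. = FALSE)
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || diff(cfg$maf_range) < 0)
    stop("maf_range must be ascending and within (0, 0.5]", call. = FALSE)
  if (length(cfg$pathway_size_range) != 2L ||
      cfg$pathway_size_range[1] < 1L ||
      diff(cfg$pathway_size_range) < 0L)
    stop("pathway_size_range must be ascending positive integers",
         call. = FALSE)
  if (cfg$pathway_size_range[2] > cfg$n_genes)
    stop("n_genes too small to honour pathway_size_range", call. = FALSE)
  if (any(cfg$component_prevalences <= 0 | cfg$component_prevalences >= 1))
    stop("component_prevalences must lie in (0, 1)", call. = FALSE)
  if (length(cfg$component_prevalences) != 5L)
    stop("component_prevalences must have 5 entries", call. = FALSE)
  if (!all(c("inside", "near", "far") %in% names(cfg$snp_placement)) ||
      abs(sum(cfg$snp_placement) - 1) > 1e-8)
    stop("snp_placement must be named fractions summing to 1", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  if (length(cfg$causal_pathways) > 0 &&
      (cfg$pathway_size_range[1] < 20L || cfg$pathway_size_range[2] > 200L))
    stop("planted pathways would not survive the 20-200 gene-set filter",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic OBS/MetS study configuration\n")
  cat(sprintf("  participants: %d, SNPs: %d, genes: %d, pathways: %d\n",
              x$n_participants, x$n_snps, x$n_genes, x$n_pathways))
  cat(sprintf("  causal pathways: %s (%d SNPs each, beta_gxe = %.3g)\n",
              if (length(x$causal_pathways)) paste(x$causal_pathways,
                                                   collapse = ", ") else "none",
              x$n_causal_snps_per_pathway, x$interaction_beta))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Per-stage seed offsets keep generator streams distinct but fully
# determined by config$seed.
sim_seed <- function(cfg, stage) {
  offsets <- c(cohort = 0L, genotypes = 1L, annotation = 2L,
               outcomes = 3L, status = 4L, truth = 5L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}
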