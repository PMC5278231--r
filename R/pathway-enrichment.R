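#' Map SNPs to genes with a flanking window
#'
#' A SNP maps to a gene iff its (1-based) position lies within
#' `[start - flank, end + flank]` of the gene body, boundary inclusive, on
#' the same chromosome. One SNP may map to several genes. Implemented by
#' interval overlap of flank-extended gene ranges.
#'
#' @param snps Data frame with `snp`, `chr`, `pos` (1-based).
#' @param genes [GenomicRanges::GRanges] with a `gene_id` metadata column
#'   (1-based inclusive coordinates, as returned by [read_gene_bed()]).
#' @param flank Window in bp (default 100,000).
#' @return Data frame with one row per (snp, gene) pair: `snp`, `gene`.
#'   SNPs on chromosomes absent from `genes` simply map nowhere.
#' @export
snp_gene_map <- function(snps, genes, flank = 100000L) {
  ext <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(
      start = pmax(GenomicRanges::start(genes) - flank, 1L),
      end = GenomicRanges::end(genes) + flank))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chr,
    ranges = IRanges::IRanges(start = snps$pos, end = snps$pos))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(snp_gr, ext, ignore.strand = TRUE))
  out <- data.frame(snp = snps$snp[S4Vectors::queryHits(hits)],
                    gene = genes$gene_id[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  out[order(out$snp, out$gene), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Gene-level statistics from SNP interaction p-values
#'
#' Each gene's statistic is the maximum of `-log10(p)` over its mapped,
#' tested SNPs. Genes with no tested SNP are dropped (they are not
#' "selected"). The ranking is descending by statistic with lexicographic
#' gene-id tie-breaking for determinism.
#'
#' @param scan A [scan_gxe()] result (or any data frame with `snp` and
#'   `p`); rows with `NA` p are ignored.
#' @param map SNP-to-gene pairs from [snp_gene_map()].
#' @return Data frame `gene`, `stat`, sorted as ranked.
#' @export
gene_stats <- function(scan, map) {
  p <- scan$p[match(map$snp, scan$snp)]
  keep <- !is.na(p)
  if (!any(keep)) stop("no mapped SNP has a tested p-value", call. = FALSE)
  lp <- -log10(p[keep])
  st <- vapply(split(lp, map$gene[keep]), max, numeric(1))
  out <- data.frame(gene = names(st), stat = unname(st),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$stat, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter gene sets by selected-gene count
#'
#' Retains sets whose count of genes present in the ranked gene list
#' ("selected genes") lies within `[min_genes, max_genes]`; alternatively
#' filters on the full definition size (`count_on = "all"`).
#'
#' @param pathways Named list of gene-id vectors.
#' @param ranked Ranked gene data frame from [gene_stats()].
#' @param min_genes,max_genes Inclusive size bounds (defaults 20 and 200).
#' @param count_on `"selected"` (default) or `"all"`.
#' @return The eligible subset of `pathways`; excluded set names attached
#'   as attribute `"excluded"`.
#' @export
filter_pathways <- function(pathways, ranked, min_genes = 20L,
                            max_genes = 200L,
                            count_on = c("selected", "all")) {
  count_on <- match.arg(count_on)
  size <- vapply(pathways, function(set) {
    if (count_on == "selected") sum(set %in% ranked$gene) else length(set)
  }, integer(1))
  keep <- size >= min_genes & size <= max_genes
  if (!any(keep))
    stop("no gene set survives the size filter", call. = FALSE)
  out <- pathways[keep]
  attr(out, "excluded") <- names(pathways)[!keep]
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running sum down the ranked gene list: at a set gene the sum
#' rises by `|stat|^exponent` normalized by the set total; at a non-set
#' gene it falls by `1/(N - N_set)`. The ES is the signed maximum
#' deviation from zero. If every set gene has statistic 0, increments are
#' uniform `1/N_set`.
#'
#' @param ranked Ranked gene data frame (`gene`, `stat`) from
#'   [gene_stats()].
#' @param set Character vector of gene ids (only those present in
#'   `ranked` contribute).
#' @param exponent Weight exponent on the gene statistic (default 1).
#' @return The enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(ranked, set, exponent = 1) {
  hit <- ranked$gene %in% set
  nh <- sum(hit)
  N <- nrow(ranked)
  if (nh == 0) stop("gene set has no gene in the ranking", call. = FALSE)
  if (nh == N) stop("gene set covers the whole ranking", call. = FALSE)
  w <- abs(ranked$stat)^exponent
  denom <- sum(w[hit])
  inc <- if (denom > 0) ifelse(hit, w / denom, 0) else
    ifelse(hit, 1 / nh, 0)
  dec <- ifelse(hit, 0, 1 / (N - nh))
  run <- cumsum(inc - dec)
  run[which.max(abs(run))]
}

#' Significance-proportion correction factor
#'
#' A gene is "significant" when at least one of its mapped SNPs falls in
#' the top `top_fraction` of all tested SNP p-values. The factor
#' `k = (proportion significant within the set) / (proportion significant
#' among all ranked genes)` corrects the enrichment score (`ES* = k ES`)
#' for sets whose signal is carried by few genes.
#'
#' @param set Gene-id vector.
#' @param ranked Ranked gene data frame.
#' @param sig_genes Character vector of significant gene ids (see
#'   [run_igsea()] for their construction).
#' @return A list: `k` (0 when the set holds no significant gene, `NA`
#'   when no ranked gene is significant), `n_sig`, `n_selected`.
#' @export
sig_proportion <- function(set, ranked, sig_genes) {
  selected <- intersect(set, ranked$gene)
  n_sel <- length(selected)
  n_sig <- sum(selected %in% sig_genes)
  bg <- length(sig_genes) / nrow(ranked)
  k <- if (bg == 0) NA_real_ else (n_sig / n_sel) / bg
  list(k = k, n_sig = n_sig, n_selected = n_sel)
}

#' Enrichment analysis configuration
#'
#' @param min_genes,max_genes Selected-gene size filter (20-200).
#' @param top_fraction Fraction of SNP p-values defining "significant"
#'   SNPs/genes (default 0.05).
#' @param permutations Number of SNP-label permutations (B >= 100).
#' @param weight_exponent Exponent on the gene statistic in the running
#'   sum.
#' @param fdr_threshold Reporting threshold.
#' @param seed Seed for the permutation stream.
#' @return A validated list of class `igsea_config`.
#' @export
igsea_config <- function(min_genes = 20L, max_genes = 200L,
                         top_fraction = 0.05, permutations = 1000L,
                         weight_exponent = 1, fdr_threshold = 0.05,
                         seed = 1L) {
  if (top_fraction <= 0 || top_fraction >= 1)
    stop("top_fraction must be in (0, 1)", call. = FALSE)
  if (permutations < 100L)
    stop("need at least 100 permutations", call. = FALSE)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 top_fraction = top_fraction,
                 permutations = as.integer(permutations),
                 weight_exponent = weight_exponent,
                 fdr_threshold = fdr_threshold,
                 seed = as.integer(seed)),
            class = "igsea_config")
}

# Gene statistics (max -log10 p) and significant genes for one assignment
# of -log10 p values to SNP slots; idx_list maps gene -> indices into lp.
igsea_gene_level <- function(lp, idx_list, lp_thr) {
  st <- vapply(idx_list, function(ix) max(lp[ix]), numeric(1))
  ranked <- data.frame(gene = names(st), stat = unname(st),
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$stat, ranked$gene), , drop = FALSE]
  list(ranked = ranked, sig = names(st)[st >= lp_thr])
}

igsea_set_scores <- function(ranked, sig, sets, exponent) {
  bg <- length(sig) / nrow(ranked)
  vapply(sets, function(set) {
    es <- gsea_es(ranked, set, exponent)
    selected <- intersect(set, ranked$gene)
    k <- if (bg == 0) 0 else (sum(selected %in% sig) / length(selected)) / bg
    k * es
  }, numeric(1))
}

#' Significance-proportion-corrected gene-set enrichment of interaction
#' p-values
#'
#' Full i-GSEA-style pipeline: gene statistics as max `-log10(p)` over
#' mapped SNPs, weighted KS enrichment score per eligible pathway,
#' significance-proportion correction `ES* = k ES`, and SNP-label
#' permutation inference. Permutations reassign the observed p-values to
#' SNP positions uniformly at random; nominal
#' `p = (1 + #\{permuted ES* >= observed\}) / (B + 1)`. The FDR is
#' GSEA-style: each ES* is normalized by the mean of its pathway's
#' positive permuted ES*, and FDR(i) = (fraction of all permuted
#' normalized scores >= NES_i) / (fraction of observed NES >= NES_i),
#' clipped to [0, 1]. Benjamini-Hochberg over the nominal pathway p-values
#' is also reported (`q_bh`).
#'
#' @param scan A [scan_gxe()] result (needs `snp`, `p`).
#' @param map SNP-to-gene pairs from [snp_gene_map()].
#' @param pathways Named list of gene-id vectors.
#' @param sources Optional named character vector labelling each pathway's
#'   resource (KEGG/Biocarta/GO); passed through to the report.
#' @param config An [igsea_config()].
#' @return Data frame of class `igsea_result`, one row per eligible
#'   pathway: `pathway`, `source`, `es`, `k`, `es_star`, `nes`, `p`,
#'   `fdr`, `q_bh`, `n_sig`, `n_selected`, `n_all`.
#' @export
run_igsea <- function(scan, map, pathways, sources = NULL,
                      config = igsea_config()) {
  stopifnot(inherits(config, "igsea_config"))
  tested <- scan[!is.na(scan$p), c("snp", "p")]
  map <- map[map$snp %in% tested$snp, , drop = FALSE]
  if (nrow(map) == 0) stop("no tested SNP maps to any gene", call. = FALSE)
  lp_all <- -log10(tested$p)
  # permuting lp over ALL tested SNPs (mapped or not) reassigns p-values to
  # SNP positions; the significance cut is a rank cut on the full panel, so
  # the -log10 threshold is permutation-invariant
  k_cut <- ceiling(config$top_fraction * nrow(tested))
  lp_thr <- sort(lp_all, decreasing = TRUE)[k_cut]
  idx_list <- split(match(map$snp, tested$snp), map$gene)

  obs <- igsea_gene_level(lp_all, idx_list, lp_thr)
  sets <- filter_pathways(pathways, obs$ranked,
                          min_genes = config$min_genes,
                          max_genes = config$max_genes)
  es_obs <- vapply(sets, function(s)
    gsea_es(obs$ranked, s, config$weight_exponent), numeric(1))
  prop <- lapply(sets, sig_proportion, ranked = obs$ranked,
                 sig = obs$sig)
  k_obs <- vapply(prop, function(x) ifelse(is.na(x$k), 0, x$k), numeric(1))
  undefined_bg <- any(vapply(prop, function(x) is.na(x$k), logical(1)))
  es_star_obs <- k_obs * es_obs

  B <- config$permutations
  set.seed(config$seed)
  perm <- matrix(NA_real_, nrow = length(sets), ncol = B,
                 dimnames = list(names(sets), NULL))
  for (b in seq_len(B)) {
    g <- igsea_gene_level(sample(lp_all), idx_list, lp_thr)
    perm[, b] <- igsea_set_scores(g$ranked, g$sig, sets,
                                  config$weight_exponent)
  }

  p_nom <- (1 + rowSums(perm >= es_star_obs)) / (B + 1)
  if (undefined_bg) p_nom[] <- 1

  pos_mean <- apply(perm, 1, function(x) {
    x <- x[x > 0]
    if (length(x) == 0) NA_real_ else mean(x)
  })
  nes_obs <- es_star_obs / pos_mean
  nes_perm <- sweep(perm, 1, pos_mean, "/")
  ratio <- vapply(seq_along(nes_obs), function(i) {
    if (!is.finite(nes_obs[i]) || nes_obs[i] <= 0) return(1)
    num <- mean(nes_perm >= nes_obs[i], na.rm = TRUE)
    den <- mean(nes_obs >= nes_obs[i], na.rm = TRUE)
    min(1, max(0, num / den))
  }, numeric(1))
  # q-value: minimum estimated FDR over all NES thresholds that would
  # reject the pathway, which enforces monotonicity in NES (the raw ratio
  # is not monotone at small B)
  fdr <- rep(1, length(nes_obs))
  ok <- which(is.finite(nes_obs) & nes_obs > 0)
  if (length(ok) > 0) {
    o <- ok[order(nes_obs[ok], decreasing = TRUE)]
    fdr[o] <- rev(cummin(rev(ratio[o])))
  }

  out <- data.frame(
    pathway = names(sets),
    source = if (is.null(sources)) NA_character_ else
      unname(sources[names(sets)]),
    es = unname(es_obs),
    k = unname(k_obs),
    es_star = unname(es_star_obs),
    nes = unname(nes_obs),
    p = unname(p_nom),
    fdr = unname(fdr),
    q_bh = unname(bh_qvalue(p_nom)),
    n_sig = vapply(prop, `[[`, integer(1), "n_sig"),
    n_selected = vapply(prop, `[[`, integer(1), "n_selected"),
    n_all = lengths(pathways[names(sets)]),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- attr(sets, "excluded")
  attr(out, "config") <- config
  class(out) <- c("igsea_result", "data.frame")
  out
}

#' Format an enrichment result for reporting
#'
#' Sorts by permutation FDR then nominal p and renders the
#' significant/selected/all gene counts as `"a/b/c"`.
#'
#' @param records An `igsea_result` from [run_igsea()].
#' @return Data frame `pathway`, `source`, `p`, `fdr`, `q_bh`, `genes`
#'   (counts string), `es`, `es_star`.
#' @export
igsea_report <- function(records) {
  stopifnot(all(records$n_sig <= records$n_selected),
            all(records$n_selected <= records$n_all))
  ord <- order(records$fdr, records$p, records$pathway)
  rec <- records[ord, , drop = FALSE]
  data.frame(pathway = rec$pathway, source = rec$source,
             p = rec$p, fdr = rec$fdr, q_bh = rec$q_bh,
             genes = sprintf("%d/%d/%d", rec$n_sig, rec$n_selected,
                             rec$n_all),
             es = rec$es, es_star = rec$es_star,
             row.names = NULL, stringsAsFactors = FALSE)
}
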