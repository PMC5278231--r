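toy_genes <- function() {
  GenomicRanges::GRanges("chr1",
                         IRanges::IRanges(start = c(500000, 1200000),
                                          end = c(520000, 1230000)),
                         gene_id = c("GA", "GB"))
}

test_that("the 100 kb mapping boundary is inclusive", {
  genes <- toy_genes()
  snps <- data.frame(
    snp = sprintf("s%d", 1:6),
    chr = "chr1",
    pos = c(510000,            # inside GA
            520000 + 100000,   # exactly 100 kb past GA end -> mapped
            520000 + 100001,   # one bp further -> unmapped
            500000 - 100000,   # exactly 100 kb before GA start -> mapped
            1199999,           # 1 bp before GB start, within flank
            2000000))          # far from everything
  m <- snp_gene_map(snps, genes, flank = 100000)
  got <- split(m$gene, m$snp)
  expect_equal(got[["s1"]], "GA")
  expect_equal(got[["s2"]], "GA")
  expect_false("s3" %in% m$snp)
  expect_equal(got[["s4"]], "GA")
  expect_equal(got[["s5"]], "GB")
  expect_false("s6" %in% m$snp)
})

test_that("mapping equals the brute-force all-pairs interval check", {
  set.seed(14)
  for (trial in 1:40) {
    genes_df <- data.frame(
      chr = sample(c("chr1", "chr2"), 8, TRUE),
      start = sample.int(3e6, 8), gene_id = sprintf("g%02d", 1:8))
    genes_df$end <- genes_df$start + sample.int(50000, 8)
    genes <- GenomicRanges::GRanges(genes_df$chr,
      IRanges::IRanges(genes_df$start, genes_df$end),
      gene_id = genes_df$gene_id)
    snps <- data.frame(snp = sprintf("s%02d", 1:30),
                       chr = sample(c("chr1", "chr2"), 30, TRUE),
                       pos = sample.int(3e6, 30))
    flank <- sample(c(0, 1000, 100000), 1)
    got <- snp_gene_map(snps, genes, flank = flank)
    want <- map_by_hand(snps, genes_df, flank)
    expect_equal(got, want)
  }
})

test_that("gene statistics take max -log10 p with deterministic ties", {
  scan <- data.frame(snp = c("s1", "s2", "s3", "s4"),
                     p = c(0.1, 0.001, 0.05, NA))
  map <- data.frame(snp = c("s1", "s2", "s2", "s3", "s4"),
                    gene = c("gA", "gA", "gB", "gC", "gC"))
  gs <- gene_stats(scan, map)
  expect_equal(gs$stat[gs$gene == "gA"], 3)
  expect_equal(gs$stat[gs$gene == "gB"], 3)
  expect_equal(gs$stat[gs$gene == "gC"], -log10(0.05))
  expect_equal(gs$gene, c("gA", "gB", "gC"))  # ties broken by id
  # untested gene dropped entirely
  map2 <- data.frame(snp = "s4", gene = "gZ")
  expect_error(gene_stats(scan, map2), "p-value")
  equal <- data.frame(snp = c("s1", "s2"), p = c(0.5, 0.5))
  mape <- data.frame(snp = c("s1", "s2"), gene = c("zz", "aa"))
  expect_equal(gene_stats(equal, mape)$gene, c("aa", "zz"))
})

test_that("size filtering keeps 20-200 selected genes inclusively", {
  ranked <- data.frame(gene = sprintf("g%03d", 1:250),
                       stat = seq(250, 1) / 100)
  sets <- list(too_small = ranked$gene[1:19],
               min_edge = ranked$gene[1:20],
               max_edge = ranked$gene[1:200],
               too_big = ranked$gene[1:201],
               half_out = c(ranked$gene[1:15], sprintf("x%02d", 1:10)))
  kept <- filter_pathways(sets, ranked)
  expect_equal(names(kept), c("min_edge", "max_edge"))
  expect_equal(attr(kept, "excluded"),
               c("too_small", "too_big", "half_out"))
  # the alternative counts the full definition size
  kept_all <- filter_pathways(sets, ranked, count_on = "all")
  expect_true("half_out" %in% names(kept_all))
  expect_error(filter_pathways(list(a = ranked$gene[1:5]), ranked),
               "size filter")
})

test_that("the enrichment score matches pencil-and-paper running sums", {
  ranked <- data.frame(gene = paste0("g", 1:6), stat = c(4, 3, 2, 1, 1, 0))
  # set {g1, g4}: increments 4/5 and 1/5, decrements 1/4;
  # running sum: .8, .55, .30, .50, .25, 0 -> ES = 0.8
  expect_equal(gsea_es(ranked, c("g1", "g4")), 0.8)
  # set {g5, g6}: all decrements come first -> ES = -1 at position 4
  expect_equal(gsea_es(ranked, c("g5", "g6")), -1)
  # set = exact top genes -> ES = +1
  expect_equal(gsea_es(ranked, c("g1", "g2")), 1)
  expect_error(gsea_es(ranked, "absent"), "no gene")
  expect_error(gsea_es(ranked, ranked$gene), "whole ranking")
})

test_that("the enrichment score equals the brute-force loop recomputation", {
  set.seed(15)
  for (trial in 1:30) {
    N <- sample(10:40, 1)
    ranked <- data.frame(gene = sprintf("g%02d", 1:N),
                         stat = sort(c(0, round(stats::rexp(N - 1), 3)),
                                     decreasing = TRUE))
    set <- sample(ranked$gene, sample(2:(N - 2), 1))
    expo <- sample(c(0.5, 1, 2), 1)
    expect_equal(gsea_es(ranked, set, expo), es_by_hand(ranked, set, expo))
    # appending a zero-statistic non-set gene only changes the decrement
    # normalization; both routes must still agree exactly
    ranked2 <- rbind(ranked, data.frame(gene = "zzz", stat = 0))
    expect_equal(gsea_es(ranked2, set, expo),
                 es_by_hand(ranked2, set, expo))
  }
})

test_that("the significance-proportion factor is the plain ratio", {
  ranked <- data.frame(gene = sprintf("g%03d", 1:400), stat = 400:1)
  sig <- ranked$gene[1:100]                 # background proportion 1/4
  set <- c(ranked$gene[1:10], ranked$gene[390:399])  # 10 of 20 significant
  got <- sig_proportion(set, ranked, sig)
  expect_equal(got$k, (10 / 20) / (100 / 400))  # = 2
  expect_equal(got$n_sig, 10)
  expect_equal(got$n_selected, 20)
  none <- sig_proportion(ranked$gene[201:220], ranked, sig)
  expect_equal(none$k, 0)
  eq <- sig_proportion(ranked$gene[seq(1, 400, by = 4)], ranked, sig)
  expect_equal(eq$k, 1)
  expect_true(is.na(sig_proportion(set, ranked, character(0))$k))
})

test_that("permutation inference is seeded, bounded and consistent", {
  st <- simulate_study(sim_config(n_participants = 600, n_snps = 150,
                                  n_genes = 60, n_pathways = 8,
                                  pathway_size_range = c(8L, 12L),
                                  seed = 61), outcome_model = "logistic")
  scan <- scan_gxe(st$genotypes, st$index, st$status,
                   st$cohort[c("age", "sex", "area", "bmi")])
  map <- snp_gene_map(st$snps, st$genes)
  cfg <- igsea_config(min_genes = 5, max_genes = 200, permutations = 120,
                      seed = 3)
  r1 <- run_igsea(scan, map, st$pathways, st$pathway_sources, cfg)
  r2 <- run_igsea(scan, map, st$pathways, st$pathway_sources, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 1 / 121 & r1$p <= 1))
  expect_true(all(r1$fdr >= 0 & r1$fdr <= 1))
  expect_true(all(r1$n_sig <= r1$n_selected))
  expect_true(all(r1$n_selected <= r1$n_all))
  # doubling B under the same seed stays within Monte-Carlo error
  r3 <- run_igsea(scan, map, st$pathways, st$pathway_sources,
                  igsea_config(min_genes = 5, max_genes = 200,
                               permutations = 240, seed = 3))
  mc_se <- sqrt(r1$p * (1 - r1$p) / 120)
  expect_true(all(abs(r1$p - r3$p) <= 4 * mc_se + 0.02))
  expect_error(igsea_config(permutations = 50), "100")
  expect_error(igsea_config(top_fraction = 1.2), "top_fraction")
})

test_that("reports sort by FDR, format counts and round-trip", {
  rec <- data.frame(pathway = c("a", "b", "c"),
                    source = c("KEGG", "GO", "Biocarta"),
                    es = c(0.5, 0.4, 0.6), k = 1, es_star = c(0.5, 0.4, 0.6),
                    nes = 1, p = c(0.01, 0.02, 0.005),
                    fdr = c(0.02, 0.05, 0.01), q_bh = c(0.02, 0.03, 0.015),
                    n_sig = c(3L, 2L, 5L), n_selected = c(10L, 8L, 9L),
                    n_all = c(12L, 9L, 11L))
  rep_ <- igsea_report(rec)
  expect_equal(rep_$fdr, c(0.01, 0.02, 0.05))
  expect_equal(rep_$genes, c("5/9/11", "3/10/12", "2/8/9"))
  path <- tempfile(fileext = ".tsv")
  write_table_tsv(rep_, path, params = list(permutations = 120))
  back <- read_table_tsv(path)
  expect_equal(back$pathway, rep_$pathway)
  expect_equal(back$fdr, rep_$fdr)
  expect_equal(back$genes, rep_$genes)
  bad <- rec
  bad$n_sig[1] <- 99L
  expect_error(igsea_report(bad))
})
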