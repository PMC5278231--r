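# Small deterministic fixtures shared across test files.

small_study <- function(n = 500, seed = 42, ...) {
  simulate_study(sim_config(n_participants = n, n_snps = 60, n_genes = 30,
                            n_pathways = 5, pathway_size_range = c(5L, 8L),
                            seed = seed, ...))
}

# Brute-force O(n^2) concordant-pair AUC (independent of the rank-based
# implementation).
pair_auc <- function(pred, status) {
  cases <- pred[status == 1]
  controls <- pred[status == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Hand step-up Benjamini-Hochberg (independent of stats::p.adjust).
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Brute-force GSEA running sum, loop form (independent of the vectorized
# implementation).
es_by_hand <- function(ranked, set, exponent = 1) {
  N <- nrow(ranked)
  hit <- ranked$gene %in% set
  denom <- sum(abs(ranked$stat[hit])^exponent)
  nh <- sum(hit)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + if (denom > 0) abs(ranked$stat[i])^exponent / denom else 1 / nh
    } else {
      run <- run - 1 / (N - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# All-pairs interval membership check for SNP-to-gene mapping.
map_by_hand <- function(snps, genes_df, flank) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(genes_df))) {
      if (snps$chr[i] == genes_df$chr[j] &&
          snps$pos[i] >= genes_df$start[j] - flank &&
          snps$pos[i] <= genes_df$end[j] + flank) {
        out[[length(out) + 1]] <- data.frame(snp = snps$snp[i],
                                             gene = genes_df$gene_id[j])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(snp = character(0), gene = character(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$snp, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Write a minimal SNP-major PLINK triplet from a dosage matrix (dosage =
# count of a1). Independent of the package's reader.
write_plink_fixture <- function(genotypes, snps, prefix) {
  n <- nrow(genotypes)
  fam <- data.frame(fid = rownames(genotypes), iid = rownames(genotypes),
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = sub("chr", "", snps$chr), snp = snps$snp, cm = 0,
                    pos = snps$pos, a1 = snps$a1, a2 = snps$a2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  code_of <- function(g) {                 # 2-bit codes per genotype
    if (is.na(g)) 1L else c(3L, 2L, 0L)[g + 1L]
  }
  bytes <- raw(0)
  for (j in seq_len(ncol(genotypes))) {
    codes <- vapply(genotypes[, j], code_of, integer(1))
    pad <- (-n) %% 4
    codes <- c(codes, rep(0L, pad))
    byte_vals <- colSums(matrix(codes, nrow = 4) * c(1L, 4L, 16L, 64L))
    bytes <- c(bytes, as.raw(byte_vals))
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(c(as.raw(0x6c), as.raw(0x1b), as.raw(0x01), bytes), con)
  close(con)
  invisible(prefix)
}
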