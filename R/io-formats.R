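# All text outputs are UTF-8 TSV with '.' for missing values; every writer
# can stamp parameters as '# key: value' header lines, which every reader
# skips.

stamp_lines <- function(params) {
  if (length(params) == 0) return(character(0))
  vapply(names(params), function(k)
    sprintf("# %s: %s", k, paste(format(params[[k]]), collapse = " ")),
    character(1))
}

#' Write a result table as stamped TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param params Named list echoed as `# key: value` header lines
#'   (reproducibility stamp).
#' @export
write_table_tsv <- function(df, path, params = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(stamp_lines(params), con)
  df[] <- lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "."
    x
  })
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a stamped TSV table
#'
#' @param path File path.
#' @return Data frame with `'.'` read as `NA`; header stamp returned as
#'   attribute `"params"`.
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  params <- sub("^# ", "", lines[hdr])
  df <- utils::read.delim(text = lines[setdiff(seq_along(lines), hdr)],
                          na.strings = ".", stringsAsFactors = FALSE)
  attr(df, "params") <- params
  df
}

pheno_numeric_cols <- c("age", "bmi", "vitc", "retinol", "carotene", "iron",
                        "alcohol", "activity", "waist", "tg", "hdl", "sbp",
                        "dbp", "fpg", "ogtt_2h", "hba1c", "crp", "wbc")
pheno_factor_cols <- list(sex = c("M", "F"), area = c("rural", "urban"),
                          smoking = c("never", "former", "current"))
pheno_logical_cols <- c("antihypertensive", "antidiabetic", "insulin")

#' Read a phenotype/exposure table
#'
#' Validates column types against the cohort schema: numeric exposures and
#' traits, factor `sex`/`area`/`smoking` with fixed levels, logical
#' medication flags, unique `id`. Violations are reported with file, column
#' and line number.
#'
#' @param path TSV path (`'.'` = missing).
#' @return Typed cohort data frame.
#' @export
read_pheno_tsv <- function(path) {
  df <- read_table_tsv(path)
  if (!"id" %in% names(df))
    stop(sprintf("%s: missing required column 'id'", path), call. = FALSE)
  dup <- which(duplicated(df$id))
  if (length(dup) > 0)
    stop(sprintf("%s: duplicated id '%s' at line %d", path,
                 df$id[dup[1]], dup[1] + 1L), call. = FALSE)
  for (col in intersect(pheno_numeric_cols, names(df))) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(x))
    if (length(bad) > 0)
      stop(sprintf("%s: column '%s', line %d: not a number ('%s')",
                   path, col, bad[1] + 1L, df[[col]][bad[1]]),
           call. = FALSE)
    df[[col]] <- x
  }
  for (col in intersect(names(pheno_factor_cols), names(df))) {
    lv <- pheno_factor_cols[[col]]
    bad <- which(!is.na(df[[col]]) & !df[[col]] %in% lv)
    if (length(bad) > 0)
      stop(sprintf("%s: column '%s', line %d: invalid level '%s'",
                   path, col, bad[1] + 1L, df[[col]][bad[1]]),
           call. = FALSE)
    df[[col]] <- factor(df[[col]], levels = lv)
  }
  for (col in intersect(pheno_logical_cols, names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' Write a phenotype/exposure table
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @param params Reproducibility stamp.
#' @export
write_pheno_tsv <- function(cohort, path, params = list()) {
  write_table_tsv(cohort, path, params)
}

#' Write an additive-dosage genotype matrix as TSV
#'
#' One row per SNP: `snp`, `chr`, `pos`, `a1`, `a2`, then one dosage
#' column per participant id.
#'
#' @param genotypes Participants x SNPs dosage matrix (dimnames required).
#' @param snps SNP metadata (`snp`, `chr`, `pos`, `a1`, `a2`).
#' @param path Output path.
#' @param params Reproducibility stamp.
#' @export
write_dosage_tsv <- function(genotypes, snps, path, params = list()) {
  stopifnot(!is.null(rownames(genotypes)), !is.null(colnames(genotypes)),
            identical(colnames(genotypes), snps$snp))
  df <- cbind(snps[c("snp", "chr", "pos", "a1", "a2")],
              as.data.frame(t(genotypes)))
  write_table_tsv(df, path, params)
}

#' Read an additive-dosage genotype TSV
#'
#' @param path TSV path as written by [write_dosage_tsv()].
#' @return A list: `genotypes` (participants x SNPs integer matrix),
#'   `snps` (metadata data frame).
#' @export
read_dosage_tsv <- function(path) {
  df <- read_table_tsv(path)
  meta_cols <- c("snp", "chr", "pos", "a1", "a2")
  miss <- setdiff(meta_cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  dup <- which(duplicated(df$snp))
  if (length(dup) > 0)
    stop(sprintf("%s: duplicated snp '%s' at line %d", path,
                 df$snp[dup[1]], dup[1] + 1L), call. = FALSE)
  dos <- as.matrix(df[setdiff(names(df), meta_cols)])
  bad <- which(!is.na(dos) & !dos %in% 0:2, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("%s: line %d: dosage '%s' not in {0,1,2}", path,
                 bad[1, 1] + 1L, dos[bad[1, , drop = FALSE]]),
         call. = FALSE)
  storage.mode(dos) <- "integer"
  geno <- t(dos)
  dimnames(geno) <- list(colnames(dos), df$snp)
  list(genotypes = geno, snps = df[meta_cols])
}

#' Read a PLINK bed/bim/fam triplet
#'
#' Reads the binary SNP-major `.bed` (2 bits per genotype) with its `.bim`
#' map and `.fam` sample files. Dosages count A1 alleles (PLINK's usual
#' minor allele): hom-A1 = 2, het = 1, hom-A2 = 0, missing = `NA`.
#' Read-only; writers in this package emit the TSV dialect instead.
#'
#' @param prefix Path prefix (without extension).
#' @return A list: `genotypes` (participants x SNPs), `snps` (`snp`,
#'   `chr`, `pos`, `a1`, `a2`), `fam` (sample table).
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  ok <- file.exists(paths)
  if (!all(ok))
    stop("missing PLINK file(s): ", paste(paths[!ok], collapse = ", "),
         call. = FALSE)
  fam <- utils::read.table(paths[3], stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"))
  bim <- utils::read.table(paths[2], stringsAsFactors = FALSE,
                           col.names = c("chr", "snp", "cm", "pos",
                                         "a1", "a2"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop(paths[1], ": not a PLINK .bed file (bad magic)", call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop(paths[1], ": only SNP-major .bed supported", call. = FALSE)
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3L != bps * m)
    stop(paths[1], ": size inconsistent with .bim/.fam", call. = FALSE)
  # 2-bit codes: 00 hom A1, 01 missing, 10 het, 11 hom A2
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  body <- as.integer(raw[-(1:3)])
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  geno <- matrix(lut[as.character(codes)], nrow = 4L * bps)[seq_len(n), ,
                                                            drop = FALSE]
  geno <- matrix(geno, nrow = n, ncol = m,
                 dimnames = list(fam$iid, bim$snp))
  list(genotypes = geno,
       snps = bim[c("snp", "chr", "pos", "a1", "a2")], fam = fam)
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; coordinates are converted once, at this
#' boundary, to the 1-based inclusive convention of
#' [GenomicRanges::GRanges]. Column 4 (name) becomes `gene_id`.
#'
#' @param path BED path (3+ columns).
#' @return `GRanges` with `gene_id`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  id <- gr$name
  if (is.null(id) || anyNA(id)) id <- sprintf("gene%05d", seq_along(gr))
  dup <- which(duplicated(id))
  if (length(dup) > 0)
    stop(sprintf("%s: duplicated gene id '%s' (line %d)", path,
                 id[dup[1]], dup[1]), call. = FALSE)
  out <- GenomicRanges::granges(gr)
  out$gene_id <- id
  out
}

#' Write gene intervals as BED
#'
#' @param genes `GRanges` with `gene_id` (1-based inclusive).
#' @param path Output path (0-based half-open on disk).
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(chr = as.character(GenomicRanges::seqnames(genes)),
                   start = GenomicRanges::start(genes) - 1L,
                   end = GenomicRanges::end(genes),
                   name = genes$gene_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' Tab-separated: set id, description, then gene ids. The description
#' column (often the source resource) is preserved.
#'
#' @param path GMT path.
#' @return Named list of gene-id vectors with attribute `"description"`
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0)
    stop(sprintf("%s: line %d: expected at least 3 tab-separated fields",
                 path, short[1]), call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1)
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    stop(sprintf("%s: duplicated set id '%s' at line %d", path,
                 ids[dup[1]], dup[1]), call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), ids)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of gene-id vectors.
#' @param path Output path.
#' @param description Optional named descriptions (defaults to the
#'   attribute on `sets`, else `"na"`).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description))
    description <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, description[[id]], sets[[id]]), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  # named vectors must become maps, or YAML drops the names
  for (nm in c("snp_placement", "component_prevalences",
               "marker_obs_slopes"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @return `read_sim_config()` returns a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(sim_config, x)
}
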