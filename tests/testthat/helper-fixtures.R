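# fixture builders and independent oracles shared across test files

# toy phased VCF: 3 samples, 4 biallelic SNVs and 1 indel on chr1
write_toy_vcf <- function(path, gt_override = NULL) {
  gt <- matrix(c(
    "0|1", "0|0", "1|1",
    "1|0", "0|1", "0|0",
    "0|0", "1|1", "0|1",
    "0|1", "0|1", "0|0"
  ), nrow = 4, byrow = TRUE)
  if (!is.null(gt_override)) gt[gt_override$i, gt_override$j] <- gt_override$value
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("chr1", "100", "rsA", "A", "G", ".", "PASS", ".", "GT", gt[1, ]), collapse = "\t"),
    paste(c("chr1", "200", "rsB", "C", "T", ".", "PASS", ".", "GT", gt[2, ]), collapse = "\t"),
    paste(c("chr1", "250", "indel1", "CT", "C", ".", "PASS", ".", "GT", "0|0", "0|1", "0|0"), collapse = "\t"),
    paste(c("chr1", "300", "rsC", "G", "A", ".", "PASS", ".", "GT", gt[3, ]), collapse = "\t"),
    paste(c("chr1", "400", "rsD", "T", "C", ".", "PASS", ".", "GT", gt[4, ]), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

# build a hap_matrix directly from a haplotype x site 0/1 matrix
toy_matrix <- function(geno, pos = NULL, chrom = "chr1") {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) %% 2 == 0)
  n_sites <- ncol(geno)
  pos <- pos %||% seq(100, by = 100, length.out = n_sites)
  sites <- data.frame(
    chrom = chrom, pos = pos,
    ref = rep(c("A", "C", "G", "T"), length.out = n_sites),
    alt = rep(c("G", "T", "A", "C"), length.out = n_sites),
    rsid = sprintf("rs%03d", seq_len(n_sites)),
    ancestral = NA_character_, stringsAsFactors = FALSE
  )
  samples <- sprintf("S%02d", seq_len(nrow(geno) / 2))
  archhap:::new_hap_matrix(sites, matrix(as.integer(geno), nrow = nrow(geno)),
                           samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent r^2 oracle: squared Pearson correlation of allele indicators
r2_oracle <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  stats::cor(a[ok], b[ok])^2
}

# sequence pair with a prescribed number of AG / CT transitions and
# transversions over n base-balanced sites
make_pair <- function(n, n_ag, n_ct, n_tv) {
  a <- rep(c("A", "C", "G", "T"), length.out = n)
  b <- a
  ag <- which(a == "A")[seq_len(n_ag)]; b[ag] <- "G"
  ct <- which(a == "C")[seq_len(n_ct)]; b[ct] <- "T"
  tv <- which(a == "G")[seq_len(n_tv)]; b[tv] <- "C"
  list(a = a, b = b)
}

# Kimura 2-parameter closed form (P transitions, Q transversions)
k2p_distance <- function(P, Q) {
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# random small haplotype matrix guaranteed polymorphic at both sites
random_two_site_matrix <- function(n_hap) {
  repeat {
    g <- matrix(stats::rbinom(n_hap * 2L, 1L, stats::runif(1, 0.2, 0.8)), ncol = 2L)
    f <- colMeans(g)
    if (all(f > 0 & f < 1)) return(g)
  }
}

# archaic_genotypes object from a character matrix (individuals x sites)
toy_archaic <- function(calls, sites) {
  calls <- as.matrix(calls)
  colnames(calls) <- archhap:::site_key(sites)
  structure(calls, class = "archaic_genotypes", sites = sites)
}
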