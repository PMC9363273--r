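#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Reads a VCF (4.x) with phased `GT` fields and returns the biallelic SNVs
#' in a region as a `hap_matrix`: one row per phased haplotype (two per
#' sample, side 1 before side 2, samples in VCF header order), one column
#' per retained site in ascending position order.
#'
#' Multi-allelic records and indels are dropped, never split; the counts of
#' dropped records are attached as attribute `"dropped"` and reported with
#' a message. An unphased genotype (`/` separator) at any retained site is
#' an error, as the downstream linkage-disequilibrium and alignment
#' machinery requires phase.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param region Optional `"chrom:start-end"` string (1-based inclusive);
#'   `NULL` keeps all records.
#' @return An object of class `hap_matrix` with elements `sites` (data frame
#'   `chrom`, `pos`, `ref`, `alt`, `rsid`, `ancestral`), `geno` (integer
#'   matrix, haplotypes x sites, entries 0 = ref, 1 = alt, `NA` = missing),
#'   `hap_ids` and `samples`.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  fix$POS <- as.numeric(fix$POS)

  keep_region <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep_region <- fix$CHROM == rg$chrom & fix$POS >= rg$start & fix$POS <= rg$end
    if (!any(keep_region)) stop("no VCF records in region ", rg$chrom, ":", rg$start, "-", rg$end)
  }

  nuc <- c("A", "C", "G", "T")
  is_snv <- toupper(fix$REF) %in% nuc & toupper(fix$ALT) %in% nuc
  keep <- keep_region & is_snv
  dropped <- c(
    non_biallelic_snv = sum(keep_region & !is_snv),
    outside_region = sum(!keep_region)
  )
  if (dropped[["non_biallelic_snv"]] > 0L)
    message("read_phased_vcf: dropped ", dropped[["non_biallelic_snv"]],
            " non-biallelic-SNV record(s)")
  if (!any(keep)) stop("no biallelic SNV records retained from ", path)

  sites <- data.frame(
    chrom = fix$CHROM[keep], pos = fix$POS[keep],
    ref = toupper(fix$REF[keep]), alt = toupper(fix$ALT[keep]),
    rsid = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".", NA_character_, fix$ID[keep]),
    ancestral = NA_character_, stringsAsFactors = FALSE
  )
  ord <- order(sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE][ord, , drop = FALSE]
  samples <- colnames(gt)
  if (is.null(samples) || length(samples) == 0L) stop("VCF has no sample columns: ", path)

  # "/" marks an unphased call; a fully missing "./." carries no phase to lose
  unphased <- which(grepl("/", gt, fixed = TRUE) & !grepl("^\\.[/|]\\.$", gt))
  if (length(unphased) > 0L) {
    i <- arrayInd(unphased[1L], dim(gt))
    stop("unphased genotype at retained site ", site_key(sites[i[1L], ]),
         " (sample ", samples[i[2L]], "): phased GT required")
  }

  n_sites <- nrow(sites)
  n_hap <- 2L * length(samples)
  geno <- matrix(NA_integer_, nrow = n_hap, ncol = n_sites)
  allele_int <- function(a) ifelse(a %in% c("0", "1"), as.integer(a), NA_integer_)
  for (j in seq_len(n_sites)) {
    parts <- strsplit(gt[j, ], "|", fixed = TRUE)
    bad <- lengths(parts) != 2L & !is.na(gt[j, ])
    if (any(bad)) {
      parts[bad] <- list(c(NA_character_, NA_character_))
    }
    parts[is.na(gt[j, ])] <- list(c(NA_character_, NA_character_))
    al <- matrix(unlist(parts), nrow = 2L)
    geno[seq(1L, n_hap, by = 2L), j] <- allele_int(al[1L, ])
    geno[seq(2L, n_hap, by = 2L), j] <- allele_int(al[2L, ])
  }

  hap_ids <- as.vector(t(outer(samples, c("_1", "_2"), paste0)))
  dimnames(geno) <- list(hap_ids, site_key(sites))
  out <- structure(
    list(sites = sites, geno = geno, hap_ids = hap_ids, samples = samples),
    class = "hap_matrix"
  )
  attr(out, "dropped") <- dropped
  out
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("hap_matrix:", length(x$samples), "samples (", nrow(x$geno),
      "phased haplotypes ) x", nrow(x$sites), "biallelic SNVs\n")
  cat("  span:", x$sites$chrom[1L], ":", min(x$sites$pos), "-", max(x$sites$pos), "\n")
  invisible(x)
}

# internal constructor used by the simulator; validates invariants
new_hap_matrix <- function(sites, geno, samples) {
  stopifnot(nrow(geno) == 2L * length(samples),
            ncol(geno) == nrow(sites),
            !is.unsorted(sites$pos, strictly = TRUE),
            all(geno %in% c(0L, 1L, NA)))
  hap_ids <- as.vector(t(outer(samples, c("_1", "_2"), paste0)))
  dimnames(geno) <- list(hap_ids, site_key(sites))
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, hap_ids = hap_ids, samples = samples),
            class = "hap_matrix")
}
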