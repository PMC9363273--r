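#' Parse a genomic region string
#'
#' Accepts `"chrom:start-end"` with optional thousands separators
#' (`"chr10:96,537,863-96,851,277"`). Coordinates are 1-based inclusive.
#'
#' @param region Region string, or a list with `chrom`, `start`, `end`.
#' @return A list with elements `chrom` (character), `start`, `end` (numeric).
#' @export
parse_region <- function(region) {
  if (is.list(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    region$start <- as.numeric(region$start)
    region$end <- as.numeric(region$end)
    if (region$start > region$end) stop("region start exceeds end")
    return(region[c("chrom", "start", "end")])
  }
  stopifnot(is.character(region), length(region) == 1L)
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L) stop("malformed region string: ", region)
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (start > end) stop("region start exceeds end: ", region)
  list(chrom = m[2], start = start, end = end)
}

#' Defining variants of the CYP2C8*3 / CYP2C9*2 haplotype
#'
#' The three amino-acid-replacement variants that define the star alleles
#' CYP2C8*3 (R139K and K399R) and CYP2C9*2 (R144C), with hg19 coordinates.
#' These are the default index/defining variants when analysing the CYP2C
#' locus on chromosome 10.
#'
#' @return A data frame with columns `rsid`, `star_allele`, `aa_change`,
#'   `chrom`, `pos`, `ref`, `alt`.
#' @export
cyp2c_defining_variants <- function() {
  data.frame(
    rsid = c("rs11572080", "rs10509681", "rs1799853"),
    star_allele = c("CYP2C8*3", "CYP2C8*3", "CYP2C9*2"),
    aa_change = c("R139K", "K399R", "R144C"),
    chrom = "chr10",
    pos = c(96827030, 96798749, 96702047),
    ref = c("C", "T", "C"),
    alt = c("T", "C", "T"),
    stringsAsFactors = FALSE
  )
}

# site keys used as column names throughout
site_key <- function(sites) paste0(sites$chrom, ":", sites$pos)

# resolve a site reference (integer index, rsid, or "chrom:pos") to an index
match_site <- function(x, site) {
  stopifnot(inherits(x, "hap_matrix"))
  if (is.numeric(site)) {
    i <- as.integer(site)
    if (i < 1L || i > nrow(x$sites)) stop("site index out of range: ", site)
    return(i)
  }
  i <- match(site, x$sites$rsid)
  if (is.na(i)) i <- match(site, site_key(x$sites))
  if (is.na(i)) stop("site not found in haplotype matrix: ", site)
  i
}

`%||%` <- function(a, b) if (is.null(a)) b else a
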