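#' Linkage disequilibrium r-squared between two sites
#'
#' Computes r^2 from phased haplotype counts: with p_A, p_B the alt-allele
#' frequencies at the two sites and p_AB the frequency of haplotypes
#' carrying both alt alleles, D = p_AB - p_A p_B and
#' r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B)). Haplotypes missing at either
#' site are excluded pairwise. This is haplotype-based LD, not genotype
#' correlation: it requires phase.
#'
#' A site that is monomorphic among the retained haplotypes has no defined
#' LD; this raises a condition of class `archhap_undefined_ld`, which is
#' distinct from r^2 = 0.
#'
#' @param hap_a,hap_b Integer vectors of phased alleles (0/1/`NA`) for the
#'   same haplotypes at two sites.
#' @return r^2 in \[0, 1\].
#' @export
r_squared <- function(hap_a, hap_b) {
  stopifnot(length(hap_a) == length(hap_b))
  ok <- !is.na(hap_a) & !is.na(hap_b)
  a <- hap_a[ok]; b <- hap_b[ok]
  if (length(a) < 2L)
    stop(undefined_ld_error("fewer than two haplotypes after missing-data exclusion"))
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop(undefined_ld_error("monomorphic site after missing-data exclusion"))
  pab <- mean(a == 1L & b == 1L)
  d <- pab - pa * pb
  # grouping the variance terms keeps the result exactly symmetric in a,b
  r2 <- d^2 / ((pa * (1 - pa)) * (pb * (1 - pb)))
  min(max(r2, 0), 1)
}

undefined_ld_error <- function(msg) {
  errorCondition(paste0("undefined LD: ", msg),
                 class = c("archhap_undefined_ld", "error"))
}

#' Alternate-allele frequency of a site within a population group
#'
#' @param x A `hap_matrix`.
#' @param site Site reference: integer index, rsid, or `"chrom:pos"`.
#' @param panel Population panel data frame (`sample`, `pop`, `super_pop`);
#'   required unless `group = "ALL"`.
#' @param group `"ALL"` (pooled), a super-population code, or a population
#'   code.
#' @return Alt-allele count divided by non-missing haplotype count in the
#'   group.
#' @export
allele_frequency <- function(x, site, panel = NULL, group = "ALL") {
  stopifnot(inherits(x, "hap_matrix"))
  i <- match_site(x, site)
  col <- x$geno[, i]
  if (!identical(group, "ALL")) {
    if (is.null(panel)) stop("panel required for group-specific frequencies")
    absent <- setdiff(x$samples, panel$sample)
    if (length(absent) > 0L)
      stop("sample(s) missing from panel: ", paste(utils::head(absent, 3L), collapse = ", "))
    grp_samples <- panel$sample[panel$super_pop == group | panel$pop == group]
    keep_samples <- intersect(x$samples, grp_samples)
    if (length(keep_samples) == 0L) stop("no samples in group ", group)
    col <- col[sub("_[12]$", "", x$hap_ids) %in% keep_samples]
  }
  col <- col[!is.na(col)]
  if (length(col) == 0L) stop("no non-missing haplotypes for site in group ", group)
  mean(col)
}

#' Allele-frequency table by population group
#'
#' One row per site, one column per group (plus `"ALL"`), shaped like the
#' per-super-population frequency tables of population reference panels.
#'
#' @param x A `hap_matrix`.
#' @param sites Vector of site references (see [allele_frequency()]).
#' @param panel Population panel data frame.
#' @param by Panel column defining groups: `"super_pop"` or `"pop"`.
#' @return A data frame with columns `rsid`, `site`, one per group, `ALL`.
#' @export
frequency_table <- function(x, sites, panel, by = c("super_pop", "pop")) {
  by <- match.arg(by)
  groups <- sort(unique(panel[[by]]))
  idx <- vapply(sites, function(s) match_site(x, s), integer(1))
  out <- data.frame(
    rsid = x$sites$rsid[idx], site = site_key(x$sites)[idx],
    stringsAsFactors = FALSE
  )
  for (g in groups)
    out[[g]] <- vapply(idx, function(i) allele_frequency(x, i, panel, g), numeric(1))
  out$ALL <- vapply(idx, function(i) allele_frequency(x, i), numeric(1))
  out
}

#' Pairwise r-squared matrix for a set of sites
#'
#' @param x A `hap_matrix`.
#' @param sites Vector of site references.
#' @return Symmetric matrix of r^2 values (diagonal 1); pairs with
#'   undefined LD are `NA`.
#' @export
ld_matrix <- function(x, sites) {
  idx <- vapply(sites, function(s) match_site(x, s), integer(1))
  n <- length(idx)
  lab <- ifelse(is.na(x$sites$rsid[idx]), site_key(x$sites)[idx], x$sites$rsid[idx])
  m <- diag(1, n)
  dimnames(m) <- list(lab, lab)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- tryCatch(
      r_squared(x$geno[, idx[i]], x$geno[, idx[j]]),
      archhap_undefined_ld = function(e) NA_real_)
  }
  m
}

#' Delineate the haplotype block linked to an index variant
#'
#' Finds every site in the matrix whose r^2 with the index variant is at
#' least `threshold` (the index itself included, r^2 = 1 with itself) and
#' returns the min-max envelope of the linked sites. There is no
#' contiguity requirement: the block is the genomic span from the first to
#' the last linked site. Sites with undefined LD (monomorphic) are
#' skipped. Block length is defined as `span_end - span_start`, the
#' distance between the outermost linked positions.
#'
#' @param x A `hap_matrix`.
#' @param index Index-site reference (integer index, rsid or
#'   `"chrom:pos"`); must be polymorphic.
#' @param threshold r^2 cutoff for block membership (default 0.8).
#' @return An object of class `hap_block`: list with `index_site`,
#'   `member_sites` (data frame with an `r2` column), `span_start`,
#'   `span_end`, `length`, `threshold`, `n_undefined`.
#' @export
ld_block <- function(x, index, threshold = 0.8) {
  stopifnot(inherits(x, "hap_matrix"), threshold >= 0, threshold <= 1)
  i <- match_site(x, index)
  idx_col <- x$geno[, i]
  p <- mean(idx_col, na.rm = TRUE)
  if (is.nan(p) || p %in% c(0, 1)) stop("index site is monomorphic; LD block undefined")

  n_sites <- nrow(x$sites)
  r2 <- rep(NA_real_, n_sites)
  r2[i] <- 1
  for (j in seq_len(n_sites)) {
    if (j == i) next
    r2[j] <- tryCatch(r_squared(idx_col, x$geno[, j]),
                      archhap_undefined_ld = function(e) NA_real_)
  }
  member <- which(!is.na(r2) & r2 >= threshold)
  members <- x$sites[member, , drop = FALSE]
  members$r2 <- r2[member]
  rownames(members) <- NULL
  span_start <- min(members$pos)
  span_end <- max(members$pos)
  structure(list(
    index_site = x$sites[i, , drop = FALSE],
    member_sites = members,
    span_start = span_start, span_end = span_end,
    length = span_end - span_start,
    threshold = threshold,
    n_undefined = sum(is.na(r2))
  ), class = "hap_block")
}

#' @export
print.hap_block <- function(x, ...) {
  lab <- if (is.na(x$index_site$rsid)) site_key(x$index_site) else x$index_site$rsid
  cat("hap_block: index", lab, "| r2 >=", x$threshold, "\n")
  cat("  ", nrow(x$member_sites), "linked sites spanning ",
      x$index_site$chrom, ":", x$span_start, "-", x$span_end,
      " (", x$length, " bp)\n", sep = "")
  invisible(x)
}
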