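#' Match a block's defining alleles against archaic genotypes
#'
#' Tabulates each archaic individual's genotype at the defining variants of
#' a haplotype and assigns a carrier verdict: `"homozygous carrier"` when
#' the individual is hom-alt at every non-missing defining site,
#' `"heterozygous carrier"` when every non-missing site carries the alt
#' allele but at least one is het, `"partial/non-carrier"` when the alt
#' allele is present at some sites but absent at others, `"non-carrier"`
#' when hom-ref throughout, and `"no data"` when all calls are missing.
#' Missing calls are reported, never fatal.
#'
#' @param table An `archaic_genotypes` object.
#' @param defining_sites Vector of site references (rsid, `"chrom:pos"`, or
#'   integer index into the site table).
#' @return A list with `genotypes` (data frame individual x site, long
#'   form) and `verdicts` (data frame `individual`, `verdict`,
#'   `n_missing`).
#' @export
archaic_match <- function(table, defining_sites) {
  stopifnot(inherits(table, "archaic_genotypes"))
  sites <- attr(table, "sites")
  idx <- vapply(defining_sites, function(s) {
    if (is.numeric(s)) return(as.integer(s))
    i <- match(s, sites$rsid)
    if (is.na(i)) i <- match(s, site_key(sites))
    if (is.na(i)) stop("defining site not found: ", s)
    i
  }, integer(1))

  inds <- rownames(table)
  calls <- table[, idx, drop = FALSE]
  genotypes <- data.frame(
    individual = rep(inds, times = length(idx)),
    site = rep(colnames(table)[idx], each = length(inds)),
    rsid = rep(sites$rsid[idx], each = length(inds)),
    genotype = as.vector(calls),
    stringsAsFactors = FALSE
  )
  verdicts <- data.frame(
    individual = inds,
    verdict = apply(calls, 1L, carrier_verdict),
    n_missing = apply(calls, 1L, function(g) sum(is.na(g))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(genotypes = genotypes, verdicts = verdicts)
}

carrier_verdict <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0L) return("no data")
  if (all(g == "hom_alt")) return("homozygous carrier")
  if (all(g %in% c("hom_alt", "het"))) return("heterozygous carrier")
  if (all(g == "hom_ref")) return("non-carrier")
  "partial/non-carrier"
}

#' Select sites for the haplotype phylogeny
#'
#' Returns the sites that (a) fall in the region, (b) segregate among the
#' modern haplotypes and (c) carry a homozygous-alternate call in the
#' chosen reference archaic individual, i.e. positions where the reference
#' archaic is homozygous for the non-reference (derived, relative to the
#' human reference assembly) allele. These are the informative positions
#' for placing modern haplotypes relative to the archaic lineage.
#'
#' @param x A `hap_matrix`.
#' @param table An `archaic_genotypes` object on the same site list.
#' @param reference_archaic Name (row) of the reference archaic individual.
#' @param region Optional `"chrom:start-end"` restriction.
#' @return Integer vector of site indices into `x$sites`, ascending; errors
#'   if empty.
#' @export
select_phylo_sites <- function(x, table, reference_archaic, region = NULL) {
  stopifnot(inherits(x, "hap_matrix"), inherits(table, "archaic_genotypes"))
  if (!reference_archaic %in% rownames(table))
    stop("reference archaic not in genotype table: ", reference_archaic)
  f <- colMeans(x$geno, na.rm = TRUE)
  segregating <- !is.nan(f) & f > 0 & f < 1
  hom_alt <- !is.na(table[reference_archaic, ]) & table[reference_archaic, ] == "hom_alt"
  keep <- segregating & hom_alt
  if (!is.null(region)) {
    rg <- parse_region(region)
    keep <- keep & x$sites$chrom == rg$chrom &
      x$sites$pos >= rg$start & x$sites$pos <= rg$end
  }
  idx <- unname(which(keep))
  if (length(idx) == 0L)
    stop("no sites segregate in the modern sample and are hom-alt in ",
         reference_archaic, "; phylogeny impossible")
  idx[order(x$sites$pos[idx])]
}

#' Build a haplotype alignment for phylogeny estimation
#'
#' Assembles a nucleotide matrix over the selected sites: one sequence per
#' chosen modern haplotype (0 -> ref base, 1 -> alt base), one
#' pseudo-haploid sequence per archaic individual (hom calls give that
#' allele; het calls are resolved by a uniform draw governed by `seed`;
#' missing calls give `N`), and one ancestral sequence from the sites'
#' ancestral annotation. Sites lacking an ancestral allele are dropped
#' with a warning, since the tree is rooted on the ancestral sequence.
#'
#' @param x A `hap_matrix` whose sites carry ancestral annotation.
#' @param sites Integer site indices (from [select_phylo_sites()]).
#' @param haplotypes Character vector of modern haplotype ids
#'   (`"SAMPLE_1"` / `"SAMPLE_2"`); each must be non-missing at all sites.
#' @param table An `archaic_genotypes` object.
#' @param seed Integer seed for resolving archaic het calls.
#' @param region Optional `"chrom:start-end"` giving the genomic span the
#'   haplotype sequences cover. Positions in the span that are not
#'   selected sites are invariant across all taxa; their count is stored
#'   as `n_invariant` so that distances can be expressed per bp of the
#'   region (substitutions per site of the full sequence, as on a tree
#'   scale bar) rather than per variable column. Default: the span of the
#'   selected sites.
#' @return An object of class `hap_alignment`: list with `states`
#'   (character matrix taxa x sites of A/C/G/T/N), `sites`, `taxa` and
#'   `n_invariant`.
#' @export
build_alignment <- function(x, sites, haplotypes, table, seed = 1L,
                            region = NULL) {
  stopifnot(inherits(x, "hap_matrix"), inherits(table, "archaic_genotypes"))
  bad <- setdiff(haplotypes, x$hap_ids)
  if (length(bad) > 0L) stop("unknown haplotype id(s): ", paste(bad, collapse = ", "))

  st <- x$sites[sites, , drop = FALSE]
  no_anc <- is.na(st$ancestral)
  if (any(no_anc)) {
    warning("dropping ", sum(no_anc), " site(s) without ancestral annotation")
    sites <- sites[!no_anc]
    st <- st[!no_anc, , drop = FALSE]
  }
  if (nrow(st) == 0L) stop("no sites with ancestral annotation remain")

  g <- x$geno[haplotypes, sites, drop = FALSE]
  if (anyNA(g)) {
    i <- which(is.na(g), arr.ind = TRUE)[1L, ]
    stop("chosen haplotype ", haplotypes[i[1L]], " has a missing allele at ",
         site_key(st[i[2L], ]), "; fully phased haplotypes required")
  }
  modern <- t(apply(g, 1L, function(row) ifelse(row == 1L, st$alt, st$ref)))

  arch_names <- rownames(table)
  arch_calls <- table[, sites, drop = FALSE]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  archaic <- t(vapply(arch_names, function(ind) {
    calls <- arch_calls[ind, ]
    out <- rep("N", length(calls))
    out[!is.na(calls) & calls == "hom_ref"] <- st$ref[!is.na(calls) & calls == "hom_ref"]
    out[!is.na(calls) & calls == "hom_alt"] <- st$alt[!is.na(calls) & calls == "hom_alt"]
    het <- which(!is.na(calls) & calls == "het")
    if (length(het) > 0L) {
      pick_alt <- stats::runif(length(het)) < 0.5
      out[het] <- ifelse(pick_alt, st$alt[het], st$ref[het])
    }
    out
  }, character(nrow(st))))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
    rm(".Random.seed", envir = globalenv())

  states <- rbind(modern, archaic, ancestral = st$ancestral)
  taxa <- c(haplotypes, arch_names, "ancestral")
  dimnames(states) <- list(taxa, site_key(st))
  span <- if (is.null(region)) max(st$pos) - min(st$pos) + 1 else {
    rg <- parse_region(region)
    rg$end - rg$start + 1
  }
  structure(list(states = states, sites = st, taxa = taxa, seed = seed,
                 n_invariant = max(0, span - nrow(st))),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("hap_alignment:", length(x$taxa), "taxa x", nrow(x$sites), "sites\n")
  invisible(x)
}
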