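#' Run the full archaic-introgression analysis for a candidate region
#'
#' Orchestrates the five analysis stages on one candidate region: (1) read
#' and normalize inputs; (2) delineate the LD block around the index
#' variant and tabulate allele frequencies of the defining variants by
#' population group; (3) match the defining alleles against the archaic
#' genotypes; (4) run the incomplete-lineage-sorting haplotype-length
#' test; (5) select phylogeny sites, build the haplotype alignment and
#' estimate the rooted bootstrapped neighbor-joining tree. Every seed and
#' parameter used is recorded in the report so a run is auditable and
#' reproducible.
#'
#' Inputs may be given as file paths (`vcf`, `panel`, `archaic`,
#' `ancestral`, `map`) or as the in-memory objects produced by
#' [simulate_dataset()] via `data`.
#'
#' @param vcf,panel,archaic,ancestral,map Input file paths (see
#'   `genomic_io` readers). `archaic` may be a vector of paths.
#' @param data Alternative to the file arguments: a list with elements
#'   `matrix`, `panel`, `archaic`, `map` (sites already
#'   ancestral-annotated), e.g. the return value of [simulate_dataset()].
#' @param region Candidate region `"chrom:start-end"`; default: full span
#'   of the input sites.
#' @param index Index-variant reference (rsid, `"chrom:pos"` or integer).
#' @param defining Vector of defining-variant references (default: the
#'   index variant alone).
#' @param ld_threshold r^2 cutoff for block membership.
#' @param split_time,generation_time,branch_factor ILS test parameters
#'   (years, years/generation, lineages); see [ils_test()].
#' @param reference_archaic Archaic individual whose homozygous-alternate
#'   calls select the phylogeny sites (default: first individual).
#' @param outgroup_pop Population (panel `pop` code) supplying outgroup
#'   haplotypes for the tree.
#' @param n_outgroup Number of outgroup haplotypes in the tree.
#' @param carrier_haplotype Modern haplotype id to represent the carrier
#'   lineage; default: first haplotype carrying the alt allele at every
#'   defining variant.
#' @param bootstrap_B Bootstrap replicate count.
#' @param seed Master seed for archaic het resolution and bootstrap.
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `tree.nwk`, `block.bed`, `frequencies.tsv` and
#'   `ld_matrix.tsv`.
#' @return A list of class `archhap_report` with components `frequencies`,
#'   `ld`, `block`, `ils`, `archaic_match`, `phylo`, `parameters`.
#' @export
run_full_analysis <- function(vcf = NULL, panel = NULL, archaic = NULL,
                              ancestral = NULL, map = NULL, data = NULL,
                              region = NULL, index, defining = NULL,
                              ld_threshold = 0.8, split_time = 550000,
                              generation_time = 29, branch_factor = 2,
                              reference_archaic = NULL, outgroup_pop = NULL,
                              n_outgroup = 5L, carrier_haplotype = NULL,
                              bootstrap_B = 1000L, seed = 42L,
                              out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }

  ## stage 1: ingest
  if (is.null(data)) {
    x <- stage("io", read_phased_vcf(vcf, region))
    pan <- stage("io", read_panel(panel))
    x <- stage("io", read_ancestral(ancestral, x))
    arch <- stage("io", read_archaic(archaic, x))
    gmap <- stage("io", read_genetic_map(map))
  } else {
    x <- data$matrix; pan <- data$panel; arch <- data$archaic; gmap <- data$map
  }
  defining <- defining %||% index

  ## stage 2: LD block and frequencies
  block <- stage("ld", ld_block(x, index, threshold = ld_threshold))
  freq <- stage("ld", frequency_table(x, defining, pan))
  ldm <- stage("ld", ld_matrix(x, defining))

  ## stage 3: archaic genotype match
  amatch <- stage("archaic", archaic_match(arch, defining))

  ## stage 4: ILS test
  ils <- stage("ils", ils_test(block, gmap, split_time = split_time,
                               generation_time = generation_time,
                               branch_factor = branch_factor))

  ## stage 5: phylogeny
  reference_archaic <- reference_archaic %||% rownames(arch)[1L]
  phylo_region <- region %||% sprintf("%s:%d-%d", block$index_site$chrom,
                                      as.integer(block$span_start),
                                      as.integer(block$span_end))
  sites <- stage("phylo", select_phylo_sites(x, arch, reference_archaic,
                                             region = phylo_region))
  if (is.null(carrier_haplotype)) {
    def_idx <- vapply(defining, function(s) match_site(x, s), integer(1))
    carries <- rowSums(x$geno[, def_idx, drop = FALSE] == 1L) == length(def_idx)
    carries[is.na(carries)] <- FALSE
    if (!any(carries)) stop("stage [phylo]: no modern haplotype carries all defining alleles")
    carrier_haplotype <- x$hap_ids[which(carries)[1L]]
  }
  outgroup_pop <- outgroup_pop %||% setdiff(
    pan$pop, pan$pop[pan$sample == sub("_[12]$", "", carrier_haplotype)])[1L]
  out_samples <- utils::head(pan$sample[pan$pop == outgroup_pop], n_outgroup)
  outgroup_haps <- paste0(out_samples, "_1")
  aln <- stage("phylo", build_alignment(x, sites,
                                        c(carrier_haplotype, outgroup_haps),
                                        arch, seed = seed,
                                        region = phylo_region))
  bs <- stage("phylo", bootstrap_supports(aln, B = bootstrap_B, seed = seed))
  rooted <- stage("phylo", root_tree(bs$tree, "ancestral"))
  carrier_clade <- c(carrier_haplotype, rownames(arch))
  support <- stage("phylo", clade_support(bs, carrier_clade))

  report <- structure(list(
    frequencies = freq,
    ld = list(matrix = ldm, defining = defining),
    block = list(index = block$index_site, n_members = nrow(block$member_sites),
                 span_start = block$span_start, span_end = block$span_end,
                 length = block$length, threshold = block$threshold),
    ils = unclass(ils),
    ils_not_rejected = ils$p_value >= 0.05,
    archaic_match = amatch,
    phylo = list(n_sites = length(sites), reference_archaic = reference_archaic,
                 carrier_haplotype = carrier_haplotype,
                 outgroup_haplotypes = outgroup_haps,
                 B = bs$B, n_degenerate = bs$n_degenerate,
                 carrier_archaic_clade_support = support,
                 newick = write_newick(rooted)),
    parameters = list(region = region, index = index,
                      ld_threshold = ld_threshold, split_time = split_time,
                      generation_time = generation_time,
                      branch_factor = branch_factor, bootstrap_B = bootstrap_B,
                      seed = seed)
  ), class = "archhap_report")
  attr(report, "tree") <- rooted
  attr(report, "block") <- block

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.json"))
    write_newick(rooted, file.path(out_dir, "tree.nwk"))
    write_block_bed(block, file.path(out_dir, "block.bed"))
    utils::write.table(freq, file.path(out_dir, "frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ldm, file.path(out_dir, "ld_matrix.tsv"),
                       sep = "\t", quote = FALSE)
  }
  report
}

#' @export
print.archhap_report <- function(x, ...) {
  cat("archhap report\n")
  cat("  block: ", x$block$n_members, " sites, ",
      x$block$span_start, "-", x$block$span_end,
      " (", x$block$length, " bp)\n", sep = "")
  cat("  ILS p =", signif(x$ils$p_value, 2),
      if (x$ils_not_rejected) "(ILS not rejected)" else "(ILS rejected)", "\n")
  cat("  phylogeny:", x$phylo$n_sites, "sites; carrier+archaic clade support",
      x$phylo$carrier_archaic_clade_support, "/", x$phylo$B, "\n")
  invisible(x)
}
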