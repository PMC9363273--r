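#' Configuration for the synthetic introgression simulator
#'
#' Defines the generative model: an ancestral sequence; derived mutations
#' placed independently on the archaic and modern stem branches (Poisson
#' with mean `mutation_rate * split_generations * region_length` per
#' branch); shared ancestral polymorphisms segregating in both groups; a
#' single introgressed archaic tract centred on `tract_center` whose two
#' half-lengths are independent exponentials with mean
#' `1/(recomb_rate_per_bp * admix_generations)` (recombination erosion
#' since admixture), carried by each recipient-population haplotype with
#' probability `admix_fraction`; archaic diploids drawn from the archaic
#' pool with a small per-site heterozygosity; and a uniform genetic map.
#'
#' Defaults emulate a CYP2C-like candidate region: a 300 kb region with
#' 400 SNVs, introgressed-haplotype frequency 0.1, admixture 2,000
#' generations ago, a local recombination rate of 0.27 cM/Mb, an
#' archaic-modern split of 19,000 generations (about 550 kyr at 29
#' years/generation) and a genome-average mutation rate of 1.25e-8 per bp
#' per generation.
#'
#' @param region_length Region length in bp.
#' @param n_sites Number of candidate SNV positions.
#' @param n_recipient,n_outgroup Diploid sample sizes of the recipient
#'   (admixed) and outgroup (non-admixed) populations.
#' @param n_archaic Number of archaic diploid individuals.
#' @param split_generations Generations separating the archaic and modern
#'   stems.
#' @param admix_generations Generations since the introgression pulse;
#'   must be below `split_generations`.
#' @param admix_fraction Probability that a recipient haplotype carries
#'   the introgressed tract.
#' @param mutation_rate Per-bp per-generation mutation rate.
#' @param recomb_rate Uniform recombination rate, cM/Mb.
#' @param tract_center Centre of the planted tract in bp (default: region
#'   midpoint).
#' @param tract_length Optional fixed total tract length in bp, overriding
#'   the exponential half-length draws (useful for boundary-recovery
#'   tests).
#' @param archaic_het Per-site flip probability generating within-pool
#'   archaic diversity (terminal-branch noise).
#' @param chrom Chromosome name used in all emitted files.
#' @param region_start First bp of the region.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(region_length = 300000, n_sites = 400,
                       n_recipient = 100, n_outgroup = 100, n_archaic = 4,
                       split_generations = 19000, admix_generations = 2000,
                       admix_fraction = 0.1, mutation_rate = 1.25e-8,
                       recomb_rate = 0.27, tract_center = NULL,
                       tract_length = NULL, archaic_het = 0.02,
                       chrom = "chr10", region_start = 1000001, seed = 1L) {
  cfg <- list(region_length = region_length, n_sites = n_sites,
              n_recipient = n_recipient, n_outgroup = n_outgroup,
              n_archaic = n_archaic, split_generations = split_generations,
              admix_generations = admix_generations,
              admix_fraction = admix_fraction, mutation_rate = mutation_rate,
              recomb_rate = recomb_rate,
              tract_center = tract_center %||% (region_start + region_length / 2),
              tract_length = tract_length, archaic_het = archaic_het,
              chrom = chrom, region_start = region_start, seed = as.integer(seed))
  with(cfg, {
    stopifnot(region_length > 0, n_sites > 1, n_recipient > 0, n_outgroup > 0,
              n_archaic > 0, admix_generations < split_generations,
              admix_fraction >= 0, admix_fraction <= 1,
              mutation_rate > 0, recomb_rate > 0, archaic_het >= 0)
  })
  structure(cfg, class = "sim_config")
}

# exponential tract half-lengths under recombination erosion
sim_tract_half_lengths <- function(n, recomb_rate, admix_generations) {
  rexp_rate <- recomb_rate * 1e-8 * admix_generations
  stats::rexp(n, rate = rexp_rate)
}

#' Simulate a complete synthetic introgression dataset
#'
#' Draws a dataset under the model described in [sim_config()] and,
#' optionally, writes all pipeline input files (phased VCF, population
#' panel TSV, archaic genotype TSV, ancestral-allele TSV, genetic-map
#' TSV). Site classes in the truth record are `"archaic_derived"`
#' (mutation on the archaic stem, present in moderns only via the planted
#' tract and absent from the outgroup population), `"modern_derived"`
#' (segregating among moderns, absent from the archaic pool) and
#' `"shared"` (ancestral polymorphism segregating in both).
#'
#' @param config A `sim_config`.
#' @param dir Output directory for the emitted files; `NULL` skips file
#'   output.
#' @return A list with the in-memory objects (`matrix`, `panel`,
#'   `archaic`, `map`), the emitted `files` (or `NULL`), the generating
#'   `config` and `truth` (per-haplotype carrier flags and tract
#'   intervals, site classes, the shared tract interval and the donor
#'   haplotype).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  region_end <- cfg$region_start + cfg$region_length - 1

  # site positions and alleles; ref is the ancestral state for derived
  # mutations (hg19-like reference carrying the ancestral allele)
  pos <- sort(sample(seq(cfg$region_start, region_end), cfg$n_sites))
  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, cfg$n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1L), character(1))

  # site classes: stem mutations are Poisson per branch (infinite sites)
  expected_stem <- cfg$mutation_rate * cfg$split_generations * cfg$region_length
  k_arch <- stats::rpois(1L, expected_stem)
  k_mod <- stats::rpois(1L, expected_stem)
  if (k_arch + k_mod > cfg$n_sites)
    stop("more stem mutations than candidate sites; increase n_sites")
  shuffled <- sample.int(cfg$n_sites)
  class <- rep("shared", cfg$n_sites)
  class[shuffled[seq_len(k_arch)]] <- "archaic_derived"
  if (k_mod > 0)
    class[shuffled[k_arch + seq_len(k_mod)]] <- "modern_derived"

  # background alt frequencies among moderns: U-shaped (neutral-like) SFS,
  # truncated away from fixation; archaic pool allele at shared sites is
  # frequency-weighted (the pool descends from the same ancestral population)
  bg_freq <- numeric(cfg$n_sites)
  seg <- class != "archaic_derived"
  bg_freq[seg] <- pmin(pmax(stats::rbeta(sum(seg), 0.5, 0.5), 0.02), 0.98)
  arch_consensus <- integer(cfg$n_sites)
  arch_consensus[class == "archaic_derived"] <- 1L
  arch_consensus[class == "shared"] <-
    stats::rbinom(sum(class == "shared"), 1L, bg_freq[class == "shared"])

  # ancestral allele: ref for stem-derived sites; at shared polymorphisms
  # the ancestral allele is frequency-weighted (derived alleles skew rare)
  ancestral <- ref
  sh <- class == "shared"
  anc_is_alt <- stats::runif(sum(sh)) < bg_freq[sh]
  ancestral[sh][anc_is_alt] <- alt[sh][anc_is_alt]

  # the introgressed tract: one shared segment, eroded by recombination
  if (is.null(cfg$tract_length)) {
    halves <- sim_tract_half_lengths(2L, cfg$recomb_rate, cfg$admix_generations)
  } else {
    halves <- rep(cfg$tract_length / 2, 2L)
  }
  tract <- c(max(cfg$region_start, cfg$tract_center - halves[1L]),
             min(region_end, cfg$tract_center + halves[2L]))
  in_tract <- pos >= tract[1L] & pos <= tract[2L]

  # modern haplotypes: independent background draws, tract copied from donor
  n_hap_rec <- 2L * cfg$n_recipient
  n_hap_out <- 2L * cfg$n_outgroup
  n_hap <- n_hap_rec + n_hap_out
  geno <- matrix(stats::rbinom(n_hap * cfg$n_sites, 1L,
                               rep(bg_freq, each = n_hap)), nrow = n_hap)
  donor <- arch_consensus
  carrier <- c(stats::rbinom(n_hap_rec, 1L, cfg$admix_fraction) == 1L,
               rep(FALSE, n_hap_out))
  if (cfg$admix_fraction > 0 && any(carrier) && any(in_tract))
    geno[carrier, in_tract] <- matrix(rep(donor[in_tract], each = sum(carrier)),
                                      nrow = sum(carrier))

  # archaic diploids from the archaic pool with terminal-branch noise
  n_arch_hap <- 2L * cfg$n_archaic
  arch_hap <- matrix(rep(arch_consensus, each = n_arch_hap), nrow = n_arch_hap)
  flips <- matrix(stats::runif(n_arch_hap * cfg$n_sites) < cfg$archaic_het,
                  nrow = n_arch_hap)
  arch_hap[flips] <- 1L - arch_hap[flips]
  arch_names <- paste0("archaic", seq_len(cfg$n_archaic))
  arch_gt <- t(vapply(seq_len(cfg$n_archaic), function(i) {
    s <- arch_hap[2L * i - 1L, ] + arch_hap[2L * i, ]
    c("hom_ref", "het", "hom_alt")[s + 1L]
  }, character(cfg$n_sites)))
  rownames(arch_gt) <- arch_names

  samples <- c(sprintf("REC%03d", seq_len(cfg$n_recipient)),
               sprintf("OUT%03d", seq_len(cfg$n_outgroup)))
  sites <- data.frame(chrom = cfg$chrom, pos = pos, ref = ref, alt = alt,
                      rsid = sprintf("sim%04d", seq_len(cfg$n_sites)),
                      ancestral = ancestral, stringsAsFactors = FALSE)
  x <- new_hap_matrix(sites, geno, samples)
  colnames(arch_gt) <- site_key(sites)
  arch_obj <- structure(arch_gt, class = "archaic_genotypes", sites = sites)

  panel <- data.frame(
    sample = samples,
    pop = rep(c("RCP", "OUT"), c(cfg$n_recipient, cfg$n_outgroup)),
    super_pop = rep(c("RCP", "OUT"), c(cfg$n_recipient, cfg$n_outgroup)),
    stringsAsFactors = FALSE
  )

  map_pos <- round(seq(cfg$region_start, region_end, length.out = 31L))
  map <- structure(
    data.frame(pos = map_pos,
               cm = (map_pos - cfg$region_start) * cfg$recomb_rate / 1e6),
    class = c("genetic_map", "data.frame"))

  truth <- list(
    haplotypes = data.frame(
      hap_id = x$hap_ids,
      population = rep(panel$pop, each = 2L),
      carrier = carrier,
      tract_start = ifelse(carrier, tract[1L], NA_real_),
      tract_end = ifelse(carrier, tract[2L], NA_real_),
      stringsAsFactors = FALSE
    ),
    site_class = class,
    tract = tract,
    donor = donor,
    config = cfg
  )

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      vcf = file.path(dir, "modern.vcf"),
      panel = file.path(dir, "panel.tsv"),
      archaic = file.path(dir, "archaic.tsv"),
      ancestral = file.path(dir, "ancestral.tsv"),
      map = file.path(dir, "map.tsv")
    )
    write_sim_vcf(x, files$vcf)
    utils::write.table(panel, files$panel, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    arch_num <- t(apply(arch_gt, 1L, function(g)
      c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[g]))
    arch_tab <- cbind(sites[, c("chrom", "pos", "ref", "alt")],
                      as.data.frame(t(arch_num), stringsAsFactors = FALSE))
    utils::write.table(arch_tab, files$archaic, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(data.frame(pos = sites$pos, allele = sites$ancestral),
                       files$ancestral, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(pos = map$pos, cm = sprintf("%.8f", map$cm)),
                       files$map, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(matrix = x, panel = panel, archaic = arch_obj, map = map,
       files = files, truth = truth, config = cfg)
}

# minimal phased VCF emitter for simulated data
write_sim_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=archhap-simulate",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  ), con)
  h1 <- x$geno[seq(1L, nrow(x$geno), by = 2L), , drop = FALSE]
  h2 <- x$geno[seq(2L, nrow(x$geno), by = 2L), , drop = FALSE]
  for (j in seq_len(nrow(x$sites))) {
    gt <- paste0(h1[, j], "|", h2[, j])
    writeLines(paste(c(x$sites$chrom[j], x$sites$pos[j], x$sites$rsid[j],
                       x$sites$ref[j], x$sites$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
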