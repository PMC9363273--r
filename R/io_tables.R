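#' Read a deCODE-style genetic map
#'
#' Expects a whitespace- or tab-delimited table with a physical position
#' column and a cumulative centimorgan column (a header line is tolerated;
#' columns named like `pos`/`position` and `cm`/`cM` are used when present,
#' otherwise the first two columns). Positions must be strictly increasing
#' and cumulative cM non-decreasing; at least two rows are required so that
#' an interval rate can be defined.
#'
#' @param path Path to the map file.
#' @return An object of class `genetic_map`: a data frame with columns
#'   `pos` (bp) and `cm` (cumulative centimorgans).
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- any(is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "\\s+")[[1]]))))
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    nm <- tolower(names(tab))
    ip <- which(grepl("^pos", nm))[1]
    ic <- which(nm == "cm" | grepl("^cm\\b|centimorgan", nm))[1]
    if (is.na(ip) || is.na(ic)) { ip <- 1L; ic <- 2L }
  } else { ip <- 1L; ic <- 2L }
  map <- data.frame(pos = as.numeric(tab[[ip]]), cm = as.numeric(tab[[ic]]))
  if (nrow(map) < 2L)
    stop("genetic map must contain at least two rows to define an interval rate")
  hdr_off <- if (has_header) 1L else 0L
  bad_pos <- which(diff(map$pos) <= 0)
  if (length(bad_pos) > 0L)
    stop("genetic map positions not strictly increasing at line ",
         bad_pos[1L] + 1L + hdr_off)
  bad_cm <- which(diff(map$cm) < 0)
  if (length(bad_cm) > 0L)
    stop("genetic map cumulative cM decreases at line ", bad_cm[1L] + 1L + hdr_off)
  structure(map, class = c("genetic_map", "data.frame"))
}

#' Read a population panel
#'
#' A 1000 Genomes-style TSV mapping sample to population and
#' super-population, with a header containing columns `sample`, `pop` and
#' `super_pop`.
#'
#' @param path Path to the panel file.
#' @return A data frame with columns `sample`, `pop`, `super_pop`.
#' @export
read_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  need <- c("sample", "pop", "super_pop")
  idx <- match(need, nm)
  if (anyNA(idx)) stop("panel file must have columns sample, pop, super_pop")
  out <- tab[, idx]
  names(out) <- need
  out
}

#' Annotate sites with ancestral alleles
#'
#' Reads an ancestral-allele track, either a two-column TSV (`pos`,
#' `allele`) or a FASTA slice whose first base corresponds to
#' `fasta_start`, and fills the `ancestral` column of a haplotype matrix's
#' site table. Lower-case alleles (low-confidence calls in Ensembl-style
#' tracks) are uppercased; alleles not in A/C/G/T, or not matching the
#' site's ref or alt allele, become unknown (`NA`).
#'
#' @param path Path to the ancestral TSV or FASTA file.
#' @param x A `hap_matrix` (or a site data frame with `pos`, `ref`, `alt`).
#' @param format `"auto"` (by file extension), `"tsv"` or `"fasta"`.
#' @param fasta_start Genomic position of the first FASTA base.
#' @return `x` with its site table's `ancestral` column filled.
#' @export
read_ancestral <- function(path, x, format = c("auto", "tsv", "fasta"),
                           fasta_start = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  sites <- if (inherits(x, "hap_matrix")) x$sites else x

  if (format == "tsv") {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("pos", "allele"))
    if (is.na(suppressWarnings(as.numeric(tab$pos[1L])))) tab <- tab[-1L, , drop = FALSE]
    anc <- toupper(tab$allele)[match(sites$pos, as.numeric(tab$pos))]
  } else {
    if (is.null(fasta_start)) stop("fasta_start required for a FASTA ancestral slice")
    lines <- readLines(path)
    seq <- toupper(paste(lines[!startsWith(lines, ">")], collapse = ""))
    off <- sites$pos - fasta_start + 1L
    anc <- rep(NA_character_, nrow(sites))
    ok <- off >= 1L & off <= nchar(seq)
    anc[ok] <- substring(seq, off[ok], off[ok])
  }
  anc[!(anc %in% c("A", "C", "G", "T"))] <- NA_character_
  mismatch <- !is.na(anc) & anc != sites$ref & anc != sites$alt
  if (any(mismatch)) {
    warning(sum(mismatch), " ancestral allele(s) match neither ref nor alt; set to unknown")
    anc[mismatch] <- NA_character_
  }
  sites$ancestral <- anc
  if (inherits(x, "hap_matrix")) { x$sites <- sites; x } else sites
}

#' Read archaic genotype calls matched to modern sites
#'
#' Reads one or more archaic genotype files and matches their records to
#' the site list of a modern haplotype matrix on (chrom, pos, ref, alt).
#' Two formats are accepted: a VCF (sample columns become archaic
#' individuals) or a wide TSV with columns `chrom`, `pos`, `ref`, `alt`
#' followed by one genotype column per individual (`0/0`, `0/1`, `1/1`,
#' `./.`; `|` separators also accepted). Records whose ref/alt are swapped
#' relative to the modern site are excluded with a warning; unmatched sites
#' are recorded as missing.
#'
#' @param paths Character vector of file paths.
#' @param x A `hap_matrix` providing the modern site list.
#' @return An object of class `archaic_genotypes`: a character matrix
#'   (individuals x sites) with entries `"hom_ref"`, `"het"`, `"hom_alt"`
#'   or `NA`, and the site table attached as attribute `"sites"`.
#' @export
read_archaic <- function(paths, x) {
  stopifnot(inherits(x, "hap_matrix"))
  sites <- x$sites
  keys <- site_key(sites)
  rows <- list()
  for (path in paths) {
    if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      v <- vcfR::read.vcfR(path, verbose = FALSE)
      fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
      gt <- vcfR::extract.gt(v, element = "GT")
      tab <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                        ref = toupper(fix$REF), alt = toupper(fix$ALT),
                        stringsAsFactors = FALSE)
      tab <- cbind(tab, as.data.frame(gt, stringsAsFactors = FALSE))
    } else {
      tab <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, check.names = FALSE)
      names(tab)[1:4] <- tolower(names(tab)[1:4])
    }
    inds <- setdiff(names(tab), c("chrom", "pos", "ref", "alt"))
    hit <- match(paste0(tab$chrom, ":", tab$pos), keys)
    matched <- !is.na(hit)
    swapped <- matched & (toupper(tab$ref) != sites$ref[hit] |
                            toupper(tab$alt) != sites$alt[hit])
    if (any(swapped)) {
      warning("excluded ", sum(swapped), " archaic record(s) in ", basename(path),
              " with ref/alt not matching the modern site (allele swap or mismatch)")
      matched <- matched & !swapped
    }
    for (ind in inds) {
      calls <- rep(NA_character_, length(keys))
      calls[hit[matched]] <- classify_gt(tab[[ind]][matched])
      rows[[ind]] <- calls
    }
  }
  if (length(rows) == 0L) stop("no archaic individuals found in input")
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(rows), keys)
  structure(out, class = "archaic_genotypes", sites = sites)
}

# "0/0" -> hom_ref etc.; anything unparseable -> NA
classify_gt <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) != 2L || any(!p %in% c("0", "1"))) return(NA_character_)
    s <- sum(as.integer(p))
    c("hom_ref", "het", "hom_alt")[s + 1L]
  }, character(1))
}

#' @export
print.archaic_genotypes <- function(x, ...) {
  cat("archaic_genotypes:", nrow(x), "individual(s) x", ncol(x), "sites;",
      sum(is.na(x)), "missing calls\n")
  invisible(x)
}

#' Write a haplotype block as a BED line
#'
#' Converts the block's 1-based inclusive span to BED's 0-based half-open
#' convention.
#'
#' @param block A `hap_block`.
#' @param path Output path; `NULL` returns the line invisibly only.
#' @return The BED line, invisibly.
#' @export
write_block_bed <- function(block, path = NULL) {
  stopifnot(inherits(block, "hap_block"))
  name <- block$index_site$rsid
  if (is.na(name)) name <- "block"
  line <- sprintf("%s\t%d\t%d\t%s", block$index_site$chrom,
                  as.integer(block$span_start) - 1L, as.integer(block$span_end),
                  name)
  if (!is.null(path)) writeLines(line, path)
  invisible(line)
}

#' Write a phylogeny in Newick format
#'
#' Branch lengths are kept; integer bootstrap counts stored as node labels
#' are emitted as internal-node labels.
#'
#' @param tree An `ape` `phylo` object.
#' @param path Output path; `NULL` returns the Newick string.
#' @return The Newick string, invisibly.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Write a structured JSON report
#'
#' @param results A named list (typically from [run_full_analysis()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
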