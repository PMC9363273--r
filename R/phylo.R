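#' Tamura-Nei (1993) distance between two nucleotide sequences
#'
#' Corrects the raw mismatch proportions for unequal base frequencies and
#' for the two transition classes. With `g` the supplied base frequencies,
#' `gR = gA + gG`, `gY = gC + gT`, `P1` the proportion of A<->G
#' transitions, `P2` the proportion of C<->T transitions and `Q` the
#' proportion of transversions (over the pairwise-comparable columns):
#'
#' `d = -k1 log(1 - P1/k1 - Q/(2 gR)) - k2 log(1 - P2/k2 - Q/(2 gY))
#'      - k3 log(1 - Q/(2 gR gY))`
#'
#' with `k1 = 2 gA gG / gR`, `k2 = 2 gC gT / gY` and
#' `k3 = 2 (gR gY - gA gG gY / gR - gC gT gR / gY)`.
#'
#' Columns where either sequence is not a plain A/C/G/T state are excluded
#' pairwise. If any logarithm argument is non-positive the sequences are
#' saturated for this model and an error of class `archhap_saturation` is
#' raised; no fallback model is substituted.
#'
#' @param seq_a,seq_b Character vectors of states (A/C/G/T; anything else
#'   is treated as missing).
#' @param base_freqs Named numeric vector of frequencies for A, C, G, T;
#'   all positive, summing to 1.
#' @param n_invariant Number of additional invariant columns represented
#'   by the sequences but not stored explicitly (0 for a literal
#'   alignment). Used when the stored columns are the variable sites of a
#'   longer genomic sequence, so that the distance is per site of the
#'   full sequence.
#' @return Distance in substitutions per site.
#' @export
tn93_distance <- function(seq_a, seq_b, base_freqs, n_invariant = 0) {
  stopifnot(length(seq_a) == length(seq_b))
  g <- base_freqs[c("A", "C", "G", "T")]
  if (anyNA(g) || any(g <= 0) || abs(sum(g) - 1) > 1e-8)
    stop("base_freqs must be positive frequencies for A,C,G,T summing to 1")
  a <- toupper(seq_a); b <- toupper(seq_b)
  nuc <- c("A", "C", "G", "T")
  ok <- a %in% nuc & b %in% nuc
  n <- sum(ok) + n_invariant
  if (n == 0L) stop("no comparable columns between sequences")
  a <- a[ok]; b <- b[ok]
  diffs <- a != b
  pair <- paste0(pmin(a, b), pmax(a, b))
  p1 <- sum(diffs & pair == "AG") / n   # purine transitions
  p2 <- sum(diffs & pair == "CT") / n   # pyrimidine transitions
  q <- sum(diffs & !(pair %in% c("AG", "CT"))) / n

  gr <- g[["A"]] + g[["G"]]; gy <- g[["C"]] + g[["T"]]
  k1 <- 2 * g[["A"]] * g[["G"]] / gr
  k2 <- 2 * g[["C"]] * g[["T"]] / gy
  k3 <- 2 * (gr * gy - g[["A"]] * g[["G"]] * gy / gr - g[["C"]] * g[["T"]] * gr / gy)
  w1 <- 1 - p1 / k1 - q / (2 * gr)
  w2 <- 1 - p2 / k2 - q / (2 * gy)
  w3 <- 1 - q / (2 * gr * gy)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop(errorCondition(
      "sequences saturated under the Tamura-Nei model (log argument <= 0)",
      class = c("archhap_saturation", "error")))
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' Empirical base frequencies of an alignment
#'
#' Pooled over all taxa and all A/C/G/T cells.
#'
#' @param aln A `hap_alignment` (or a character state matrix).
#' @return Named frequency vector over A, C, G, T.
#' @export
alignment_base_freqs <- function(aln) {
  states <- if (inherits(aln, "hap_alignment")) aln$states else aln
  s <- toupper(as.vector(states))
  s <- s[s %in% c("A", "C", "G", "T")]
  if (length(s) == 0L) stop("alignment has no A/C/G/T cells")
  tab <- table(factor(s, levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab) / sum(tab)
  names(f) <- c("A", "C", "G", "T")
  if (any(f == 0))
    # a zero frequency makes the TN93 coefficients degenerate; regularize
    f <- (as.numeric(tab) + 0.5) / sum(tab + 0.5)
  names(f) <- c("A", "C", "G", "T")
  f
}

#' Pairwise Tamura-Nei distance matrix for an alignment
#'
#' Base frequencies are estimated once from the pooled alignment (all
#' taxa, all non-missing cells) unless supplied. Columns missing in more
#' than `max_missing` of the taxa are dropped before analysis (reported
#' via attribute `"n_dropped_columns"`); remaining missing states are
#' handled by pairwise deletion inside [tn93_distance()].
#'
#' @param aln A `hap_alignment`.
#' @param base_freqs Optional base-frequency vector; default pooled
#'   empirical frequencies.
#' @param max_missing Maximum tolerated fraction of missing states per
#'   column (default 0.5).
#' @param n_invariant Invariant-column count passed to [tn93_distance()];
#'   default: the alignment's own `n_invariant` (0 for a bare matrix).
#' @return A symmetric matrix of distances with zero diagonal, taxa as
#'   dimnames.
#' @export
distance_matrix <- function(aln, base_freqs = NULL, max_missing = 0.5,
                            n_invariant = NULL) {
  if (is.null(n_invariant))
    n_invariant <- if (inherits(aln, "hap_alignment")) aln$n_invariant %||% 0 else 0
  states <- if (inherits(aln, "hap_alignment")) aln$states else aln
  if (nrow(states) < 3L) stop("at least three taxa required")
  nuc <- c("A", "C", "G", "T")
  miss_frac <- colMeans(matrix(!(toupper(states) %in% nuc), nrow = nrow(states)))
  drop_cols <- miss_frac > max_missing
  if (any(drop_cols)) states <- states[, !drop_cols, drop = FALSE]
  if (ncol(states) == 0L) stop("no alignment columns left after missing-data filter")
  if (is.null(base_freqs)) base_freqs <- alignment_base_freqs(states)

  taxa <- rownames(states)
  n <- nrow(states)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- tryCatch(
      tn93_distance(states[i, ], states[j, ], base_freqs, n_invariant = n_invariant),
      archhap_saturation = function(e)
        stop("saturated pair: ", taxa[i], " vs ", taxa[j], call. = FALSE))
  }
  attr(d, "base_freqs") <- base_freqs
  attr(d, "n_dropped_columns") <- sum(drop_cols)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (exact on additive matrices); negative branch
#' lengths, which NJ can produce on noisy matrices, are clamped to zero
#' with the total clamped deficit recorded in attribute
#' `"clamped_negative_length"`.
#'
#' @param d A symmetric distance matrix (or `dist`).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  deficit <- -sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  attr(tr, "clamped_negative_length") <- deficit
  tr
}

#' Bootstrap supports for the neighbor-joining tree of an alignment
#'
#' Builds the full-data tree, then `B` replicates each resampling
#' alignment columns with replacement (same length), rebuilding distances
#' and the NJ tree, and counting, for each internal edge of the full-data
#' tree, the replicates whose tree contains that bipartition. Replicate
#' `r` uses the deterministic seed `seed + r`, so runs are reproducible
#' and independent of taxon order. A replicate whose resampled columns
#' are all constant (degenerate distances) or saturated contributes no
#' bipartitions (a star tree) and is counted in `n_degenerate`.
#'
#' @param aln A `hap_alignment`.
#' @param B Number of bootstrap replicates.
#' @param seed Master seed.
#' @param base_freqs Optional fixed base frequencies (default: pooled,
#'   re-estimated per replicate).
#' @return A list with `tree` (the full-data unrooted NJ tree whose
#'   `node.label` holds integer support counts out of `B`), `B`, and
#'   `n_degenerate`.
#' @export
bootstrap_supports <- function(aln, B = 1000L, seed = 1L, base_freqs = NULL) {
  stopifnot(B >= 1L)
  states <- if (inherits(aln, "hap_alignment")) aln$states else aln
  n_inv <- if (inherits(aln, "hap_alignment")) aln$n_invariant %||% 0 else 0
  full <- nj_tree(distance_matrix(states, base_freqs = base_freqs,
                                  n_invariant = n_inv))
  ncols <- ncol(states)
  rep_trees <- vector("list", B)
  n_degenerate <- 0L
  for (r in seq_len(B)) {
    idx <- local({ set.seed(seed + r); sample.int(ncols, ncols, replace = TRUE) })
    rep_states <- states[, idx, drop = FALSE]
    dm <- tryCatch(
      distance_matrix(rep_states, base_freqs = base_freqs, n_invariant = n_inv),
      error = function(e) NULL)
    if (is.null(dm) || max(dm) == 0) { n_degenerate <- n_degenerate + 1L; next }
    rep_trees[[r]] <- nj_tree(dm)
  }
  rep_trees <- rep_trees[!vapply(rep_trees, is.null, logical(1))]
  counts <- if (length(rep_trees) > 0L)
    ape::prop.clades(full, rep_trees, rooted = FALSE) else
      rep(0L, full$Nnode)
  counts[is.na(counts)] <- 0L
  full$node.label <- as.integer(counts)
  list(tree = full, B = as.integer(B), n_degenerate = n_degenerate)
}

#' Root a tree on an outgroup leaf
#'
#' Places the root on the branch subtending the outgroup, splitting that
#' branch's length equally between the two root edges. Bootstrap supports
#' stored as node labels are carried onto the induced bipartitions.
#'
#' @param tree A `phylo` tree.
#' @param outgroup Outgroup leaf label (default `"ancestral"`).
#' @return A rooted `phylo` tree.
#' @export
root_tree <- function(tree, outgroup = "ancestral") {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup not a leaf of the tree: ", outgroup)
  r <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
  root_node <- ape::Ntip(r) + 1L
  root_edges <- which(r$edge[, 1L] == root_node)
  if (length(root_edges) == 2L) {
    total <- sum(r$edge.length[root_edges])
    r$edge.length[root_edges] <- total / 2
  }
  r
}

#' Bootstrap support for the clade formed by a set of taxa
#'
#' Looks up the internal node of the (unrooted) support-labelled tree
#' whose bipartition separates exactly `taxa` from the rest and returns
#' its support count; 0 if no such bipartition exists in the tree.
#'
#' @param bs A result of [bootstrap_supports()] (or a `phylo` with integer
#'   node labels).
#' @param taxa Character vector of tip labels forming the clade.
#' @return Integer support count.
#' @export
clade_support <- function(bs, taxa) {
  tree <- if (is.list(bs) && !inherits(bs, "phylo")) bs$tree else bs
  tips <- tree$tip.label
  if (!all(taxa %in% tips)) stop("taxa not all present in tree")
  target <- sort(match(taxa, tips))
  other <- sort(setdiff(seq_along(tips), target))
  parts <- ape::prop.part(tree)
  for (i in seq_along(parts)) {
    p <- sort(parts[[i]])
    if (identical(p, target) || identical(p, other))
      return(as.integer(tree$node.label[i]))
  }
  0L
}
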