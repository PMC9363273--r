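eqf <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

test_that("TN93 distance is zero for identical sequences and symmetric", {
  s <- rep(c("A", "C", "G", "T"), 10)
  expect_equal(tn93_distance(s, s, eqf), 0)
  p <- make_pair(60, 3, 2, 4)
  expect_identical(tn93_distance(p$a, p$b, eqf), tn93_distance(p$b, p$a, eqf))
  expect_gt(tn93_distance(p$a, p$b, eqf), 0)
})

test_that("TN93 matches an independent evaluation of the formula", {
  # 3 A<->G transitions among 50 sites, equal base frequencies:
  # d = -0.25 log(1 - 4 * 0.06) = 0.0686092114
  p <- make_pair(50, 3, 0, 0)
  expect_equal(tn93_distance(p$a, p$b, eqf), -0.25 * log(0.76), tolerance = 1e-12)
  expect_equal(tn93_distance(p$a, p$b, eqf), 0.0686092114, tolerance = 1e-9)
})

test_that("TN93 reduces to the K2P closed form with equal frequencies and P1 = P2", {
  for (cfg in list(c(4, 4, 6), c(2, 2, 2), c(10, 10, 4))) {
    p <- make_pair(200, cfg[1], cfg[2], cfg[3])
    P <- (cfg[1] + cfg[2]) / 200
    Q <- cfg[3] / 200
    expect_equal(tn93_distance(p$a, p$b, eqf), k2p_distance(P, Q),
                 tolerance = 1e-9)
  }
})

test_that("TN93 agrees with the reference implementation in ape", {
  set.seed(44)
  for (i in 1:10) {
    a <- sample(c("A", "C", "G", "T"), 400, replace = TRUE)
    b <- ifelse(runif(400) < 0.12,
                vapply(a, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                       character(1)), a)
    bin <- ape::as.DNAbin(rbind(a = tolower(a), b = tolower(b)))
    d_ape <- as.numeric(ape::dist.dna(bin, model = "TN93"))
    # ape estimates base frequencies from the two sequences; supply the same
    freqs <- alignment_base_freqs(rbind(a, b))
    expect_equal(tn93_distance(a, b, freqs), d_ape, tolerance = 1e-9)
  }
})

test_that("saturated pairs raise a saturation error rather than a fallback", {
  a <- rep(c("A", "C"), 30)
  b <- rep(c("G", "T"), 30)  # every site a transition: beyond the model
  expect_error(tn93_distance(a, b, eqf), class = "archhap_saturation")
})

test_that("invariant-column correction equals literal padding with constant columns", {
  p <- make_pair(100, 4, 4, 4)
  d0 <- tn93_distance(p$a, p$b, eqf)
  d1 <- tn93_distance(p$a, p$b, eqf, n_invariant = 900)
  expect_lt(d1, d0)
  pad <- rep(c("A", "C", "G", "T"), length.out = 900)
  expect_equal(d1, tn93_distance(c(p$a, pad), c(p$b, pad), eqf),
               tolerance = 1e-12)
})

test_that("distance_matrix is zero for identical taxa and permutation-consistent", {
  s <- rep(c("A", "C", "G", "T"), 25)
  st <- rbind(t1 = s, t2 = s, t3 = s)
  expect_true(all(distance_matrix(st) == 0))
  set.seed(50)
  anc <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
  mut <- function(k) {
    s <- anc
    i <- sample(200, k)
    s[i] <- vapply(s[i], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                   character(1))
    s
  }
  st2 <- rbind(t1 = mut(8), t2 = mut(12), t3 = mut(20), t4 = mut(25), t5 = mut(30))
  d <- distance_matrix(st2)
  perm <- c(3, 1, 5, 2, 4)
  d_perm <- distance_matrix(st2[perm, ])
  expect_equal(d_perm, d[perm, perm], ignore_attr = TRUE)
  expect_equal(d, t(d), ignore_attr = TRUE)
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  # b_A = (d_AB + d_AC - d_BC)/2 etc.
  expect_equal(bl[["A"]], 0.5)
  expect_equal(bl[["B"]], 1.5)
  expect_equal(bl[["C"]], 2.5)
})

test_that("NJ is exact on an additive four-taxon matrix", {
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- cophenetic(gen)
  tr <- nj_tree(d)
  expect_true(ape::dist.topo(ape::unroot(gen), tr) == 0)
  expect_equal(sum(tr$edge.length), sum(ape::unroot(gen)$edge.length),
               tolerance = 1e-9)
  # path lengths reproduced exactly
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d, tolerance = 1e-9)
})

test_that("NJ recovers the generating topology from random additive matrices", {
  set.seed(61)
  for (i in 1:15) {
    gen <- ape::rtree(10, rooted = FALSE)
    tr <- nj_tree(cophenetic(gen))
    expect_true(ape::dist.topo(gen, tr) == 0)
  }
})

test_that("negative NJ branch lengths are clamped and logged", {
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.1  # distort towards a negative internal edge
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_true(is.numeric(attr(tr, "clamped_negative_length")))
})

test_that("bootstrap supports are deterministic under a fixed seed", {
  set.seed(70)
  n_sites <- 120
  anc <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  mut <- function(k) {
    s <- anc
    i <- sample(n_sites, k)
    s[i] <- vapply(s[i], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                   character(1))
    s
  }
  st <- rbind(t1 = mut(10), t2 = mut(10), t3 = mut(18), t4 = mut(18),
              t5 = mut(25), t6 = mut(25))
  b1 <- bootstrap_supports(st, B = 50, seed = 3)
  b2 <- bootstrap_supports(st, B = 50, seed = 3)
  expect_identical(b1$tree$node.label, b2$tree$node.label)
  expect_equal(b1$B, 50L)
})

test_that("an unambiguous split gets full bootstrap support", {
  # ten variable columns, all supporting t1t2 | t3t4, among base-balanced
  # constant ones
  colA <- c("A", "A", "G", "G")
  st <- cbind(matrix(colA, 4, 10),
              matrix(rep(c("A", "C", "G", "T"), each = 30), 4, 120, byrow = TRUE))
  rownames(st) <- paste0("t", 1:4)
  bs <- bootstrap_supports(st, B = 100, seed = 1)
  expect_equal(clade_support(bs, c("t1", "t2")), 100L)
  expect_equal(bs$n_degenerate, 0L)
})

test_that("rooting splits the outgroup branch and preserves structure", {
  set.seed(80)
  tr <- ape::rtree(7, rooted = FALSE)
  tr$tip.label[1] <- "ancestral"
  r <- root_tree(tr, "ancestral")
  expect_true(ape::is.rooted(r))
  root_node <- ape::Ntip(r) + 1L
  kids <- which(r$edge[, 1] == root_node)
  expect_equal(length(kids), 2L)
  expect_equal(r$edge.length[kids[1]], r$edge.length[kids[2]], tolerance = 1e-12)
  # involution: unrooting restores topology and total length
  expect_true(ape::dist.topo(ape::unroot(r), tr) == 0)
  expect_equal(sum(r$edge.length), sum(tr$edge.length), tolerance = 1e-9)
  expect_error(root_tree(tr, "nonexistent"), "not a leaf")
})

test_that("rooting a three-leaf tree yields two root children", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "ancestral"), c("A", "B", "ancestral")))
  r <- root_tree(nj_tree(d))
  expect_true(ape::is.rooted(r))
  expect_equal(sum(r$edge[, 1] == ape::Ntip(r) + 1L), 2L)
})

test_that("total tree length scales with the simulated mutation rate", {
  # sequences evolved on a fixed star-like genealogy with increasing
  # per-branch substitution counts
  set.seed(91)
  n_sites <- 1500
  anc <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  mutate <- function(s, k) {
    i <- sample(n_sites, k)
    s[i] <- vapply(s[i], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                   character(1))
    s
  }
  rates <- seq(5, 95, by = 10)
  total_len <- vapply(rates, function(k) {
    st <- rbind(t1 = mutate(anc, k), t2 = mutate(anc, k), t3 = mutate(anc, k),
                t4 = mutate(anc, k))
    sum(nj_tree(distance_matrix(st))$edge.length)
  }, numeric(1))
  expect_gt(cor(rates, total_len, method = "spearman"), 0.99)
})

test_that("distances recover simulated divergence within 10% at 1000 sites", {
  set.seed(95)
  n_sites <- 1000
  anc <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  mutate <- function(s, k) {
    i <- sample(n_sites, k)
    s[i] <- vapply(s[i], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                   character(1))
    s
  }
  # two taxa at 60 substitutions each from the ancestor (120 apart on the
  # path, minus back/parallel hits corrected by the model)
  st <- rbind(t1 = mutate(anc, 60), t2 = mutate(anc, 60), anc = anc)
  d <- distance_matrix(st)
  expect_equal(d["t1", "t2"] * n_sites, 120, tolerance = 0.10 * 120)
  expect_equal(d["t1", "anc"] * n_sites, 60, tolerance = 0.10 * 60)
})
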