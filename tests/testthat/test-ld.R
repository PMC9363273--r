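test_that("r^2 reproduces hand-counted haplotype tabulations", {
  # a column against itself
  a <- c(0L, 1L, 1L, 0L, 1L, 0L)
  expect_equal(r_squared(a, a), 1.0)
  # joint counts n_AB=4, n_Ab=1, n_aB=1, n_ab=4 over 10 haplotypes:
  # pA = pB = 0.5, pAB = 0.4, D = 0.15, r^2 = 0.0225/0.0625 = 0.36
  hap_a <- c(rep(1L, 5L), rep(0L, 5L))
  hap_b <- c(rep(1L, 4L), 0L, 1L, rep(0L, 4L))
  expect_equal(r_squared(hap_a, hap_b), 0.36)
})

test_that("r^2 matches the squared-correlation oracle on random matrices", {
  set.seed(42)
  for (i in 1:200) {
    g <- random_two_site_matrix(sample(6:40, 1L))
    expect_equal(r_squared(g[, 1], g[, 2]), r2_oracle(g[, 1], g[, 2]),
                 tolerance = 1e-12)
  }
})

test_that("r^2 is symmetric and invariant to ref/alt relabeling", {
  set.seed(7)
  for (i in 1:25) {
    g <- random_two_site_matrix(20L)
    a <- g[, 1]; b <- g[, 2]
    expect_identical(r_squared(a, b), r_squared(b, a))
    expect_equal(r_squared(1L - a, b), r_squared(a, b), tolerance = 1e-12)
    expect_equal(r_squared(a, 1L - b), r_squared(a, b), tolerance = 1e-12)
  }
})

test_that("monomorphic sites raise an undefined-LD condition, not r^2 = 0", {
  a <- c(0L, 1L, 0L, 1L)
  expect_error(r_squared(a, c(0L, 0L, 0L, 0L)), class = "archhap_undefined_ld")
  # missing-data exclusion can induce monomorphism
  b <- c(1L, 1L, 1L, NA)
  expect_error(r_squared(a, b), class = "archhap_undefined_ld")
})

test_that("missing data are excluded pairwise", {
  a <- c(0L, 1L, 1L, 0L, NA, 1L)
  b <- c(0L, 1L, 0L, 0L, 1L, NA)
  expect_equal(r_squared(a, b), r2_oracle(a, b), tolerance = 1e-12)
})

test_that("allele frequencies count alt alleles within panel groups", {
  # 5 diploids, one group, per-sample alt counts 0,1,1,1,0 -> 3/10
  g <- matrix(0L, nrow = 10, ncol = 2)
  g[c(3, 5, 7), 1] <- 1L
  g[, 2] <- rep(c(0L, 1L), 5)
  x <- toy_matrix(g)
  panel <- data.frame(sample = x$samples, pop = "P1", super_pop = "G1")
  expect_equal(allele_frequency(x, 1, panel, "G1"), 0.3)
  expect_equal(allele_frequency(x, 1), 0.3)
  # monomorphic site in a group is frequency zero, not an error
  g2 <- cbind(c(rep(0L, 6), 1L, 1L, 0L, 0L), rep(0L, 10))
  x2 <- toy_matrix(g2)
  panel2 <- data.frame(sample = x2$samples, pop = rep(c("A", "B"), c(3, 2)),
                       super_pop = rep(c("A", "B"), c(3, 2)))
  expect_equal(allele_frequency(x2, 1, panel2, "A"), 0.0)
  expect_error(allele_frequency(x2, 1, panel2, "ZZZ"), "no samples in group")
  # sample missing from panel when grouping is requested
  expect_error(allele_frequency(x2, 1, panel2[-1, ], "A"), "missing from panel")
})

test_that("perfectly linked sites have identical frequencies in every group", {
  set.seed(3)
  col <- rbinom(40, 1, 0.3)
  g <- cbind(col, col, 1L - col)  # r^2 = 1 among all three
  x <- toy_matrix(g)
  panel <- data.frame(sample = x$samples,
                      pop = rep(c("P1", "P2"), each = 10),
                      super_pop = rep(c("G1", "G2"), each = 10))
  m <- ld_matrix(x, 1:3)
  expect_true(all(m == 1))
  for (grp in c("G1", "G2", "ALL")) {
    f12 <- c(allele_frequency(x, 1, panel, grp), allele_frequency(x, 2, panel, grp))
    expect_equal(f12[1], f12[2])
  }
  tab <- frequency_table(x, 1:2, panel)
  expect_equal(tab$G1[1], tab$G1[2])
  expect_equal(tab$G2[1], tab$G2[2])
})

test_that("ld_block returns the min-max envelope of linked sites", {
  set.seed(9)
  col <- rbinom(30, 1, 0.4)
  noise <- matrix(rbinom(30 * 3, 1, 0.5), ncol = 3)
  g <- cbind(noise[, 1], col, noise[, 2], col, noise[, 3])
  x <- toy_matrix(g, pos = c(100, 250, 300, 900, 1200))
  blk <- ld_block(x, 2, threshold = 0.8)
  expect_s3_class(blk, "hap_block")
  expect_setequal(blk$member_sites$pos, c(250, 900))
  expect_equal(blk$span_start, 250)
  expect_equal(blk$span_end, 900)
  expect_equal(blk$length, 650)
  # index always a member with r^2 = 1
  expect_equal(blk$member_sites$r2[blk$member_sites$pos == 250], 1)
})

test_that("an index with no linked partner yields a singleton block of length 0", {
  set.seed(10)
  g <- cbind(rbinom(40, 1, 0.5), rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))
  x <- toy_matrix(g)
  blk <- ld_block(x, 2, threshold = 0.999)
  expect_equal(nrow(blk$member_sites), 1L)
  expect_equal(blk$length, 0)
  expect_error(ld_block(toy_matrix(cbind(rep(0L, 10), rbinom(10, 1, .5))), 1),
               "monomorphic")
})

test_that("ld_block is invariant to record order in the input VCF", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(region_length = 45000, n_sites = 60,
                                     n_recipient = 20, n_outgroup = 20, seed = 12), dir = dir)
  x <- sim$matrix
  f <- colMeans(x$geno)
  idx <- which(sim$truth$site_class == "archaic_derived" & f > 0 & f < 1)[1]
  index_key <- archhap:::site_key(x$sites)[idx]
  blk <- ld_block(x, index_key)
  # shuffle the VCF body: ingest normalizes to ascending position order
  lines <- readLines(sim$files$vcf)
  hdr <- grepl("^#", lines)
  set.seed(1)
  shuffled <- c(lines[hdr], sample(lines[!hdr]))
  f2 <- file.path(dir, "shuffled.vcf")
  writeLines(shuffled, f2)
  blk_p <- ld_block(read_phased_vcf(f2), index_key)
  expect_equal(blk_p$span_start, blk$span_start)
  expect_equal(blk_p$span_end, blk$span_end)
  expect_setequal(blk_p$member_sites$pos, blk$member_sites$pos)
})

test_that("block detection recovers a planted fixed-length tract", {
  sim <- simulate_dataset(sim_config(n_sites = 400, tract_length = 50000,
                                     admix_fraction = 0.1, seed = 2))
  x <- sim$matrix
  f <- colMeans(x$geno)
  cand <- which(sim$truth$site_class == "archaic_derived" & f > 0 & f < 1)
  in_tract <- x$sites$pos[cand] >= sim$truth$tract[1] &
    x$sites$pos[cand] <= sim$truth$tract[2]
  idx <- cand[in_tract][1]
  blk <- ld_block(x, idx, threshold = 0.8)
  # spacing between adjacent sites bounds the achievable resolution
  spacing <- max(diff(x$sites$pos))
  expect_gte(blk$span_start, sim$truth$tract[1] - spacing)
  expect_lte(blk$span_end, sim$truth$tract[2] + spacing)
  expect_gte(blk$span_end - blk$span_start, 0.5 * diff(sim$truth$tract))
})
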