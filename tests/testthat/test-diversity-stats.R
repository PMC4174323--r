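test_that("segregating sites match per-column allele enumeration", {
  expect_equal(segregating_sites(matrix(0L, 4, 10)), 0L)
  expect_equal(segregating_sites(matrix(c(0L, 1L), ncol = 1)), 1L)
  for (seed in c(11, 12, 13)) {
    m <- rand_codes(6, 50, seed, na_rate = 0.1)
    expect_equal(segregating_sites(m), oracle_segregating_sites(m))
  }
})

test_that("nucleotide diversity equals haplotype pair enumeration", {
  # two diploids 0 and 2: four haplotypes, 4 of 6 pairs differ
  one_site <- matrix(c(0L, 2L), ncol = 1,
                     dimnames = list(c("a", "b"), NULL))
  expect_equal(nucleotide_diversity(one_site, L = 1), 4 / 6)
  # monomorphic window
  expect_equal(nucleotide_diversity(matrix(2L, 3, 5), L = 100), 0)
  # random slice vs O(n^2) oracle
  for (seed in c(21, 22)) {
    m <- rand_codes(8, 100, seed, na_rate = 0.05)
    skipped <- sum(colSums(!is.na(m)) < 2)
    expect_equal(nucleotide_diversity(m, L = 100),
                 oracle_pi_total(m) / (100 - skipped),
                 tolerance = 1e-12)
  }
})

test_that("Watterson's theta follows S / (a1 * L)", {
  expect_equal(watterson_theta(0, 10, 1e4), 0)
  a1_4 <- 1 + 1 / 2 + 1 / 3
  expect_equal(watterson_theta(5, 4, 1e4), 5 / a1_4 / 1e4, tolerance = 1e-12)
  expect_equal(watterson_theta(7, 12, 2e4),
               watterson_theta(7, 12, 1e4) / 2)
  expect_error(watterson_theta(5, 4, 0), "positive")
})

test_that("Tajima's D agrees with an independent implementation", {
  expect_true(is.na(tajimas_d(matrix(0L, 6, 20))))          # S = 0
  # fixed 6-sample window
  fixed <- matrix(c(0L, 0L, 1L, 0L, 2L, 0L,
                    1L, 1L, 0L, 0L, 0L, 1L,
                    2L, 2L, 2L, 1L, 2L, 2L,
                    0L, 1L, 0L, 0L, 0L, 0L,
                    1L, 0L, 1L, 2L, 1L, 0L), nrow = 6,
                  dimnames = list(paste0("s", 1:6), NULL))
  expect_equal(tajimas_d(fixed), oracle_tajima_d(fixed), tolerance = 1e-12)
  for (seed in c(31, 32, 33)) {
    m <- rand_codes(10, 40, seed)
    expect_equal(tajimas_d(m), oracle_tajima_d(m), tolerance = 1e-12)
  }
  # below the informativeness floor
  two_sites <- matrix(c(0L, 1L, 0L, 0L, 1L, 0L, 2L, 0L), nrow = 4,
                      dimnames = list(paste0("s", 1:4), NULL))
  expect_true(is.na(tajimas_d(two_sites, s_min = 3L)))
  expect_false(is.na(tajimas_d(two_sites, s_min = 2L)))
})

test_that("het ratio counts heterozygous calls per accession", {
  codes <- matrix(c(1L, 1L, 1L, 1L, 1L,
                    1L, 1L, 1L, 0L, 2L,
                    rep(NA_integer_, 5)), nrow = 3, byrow = TRUE,
                  dimnames = list(c("allhet", "mix", "empty"), NULL))
  sites <- data.frame(contig = "c", pos = 1:5,
                      ref = "A", alt = "G")
  gm <- genotype_matrix(codes, sites)
  expect_equal(het_ratio(gm, "allhet"), 1.0)
  expect_equal(het_ratio(gm, "mix"), 3 / 5)
  expect_true(is.na(het_ratio(gm, "empty")))
  expect_error(het_ratio(gm, "ghost"), "not present")
})

test_that("inbreeding lowers expected heterozygosity by (1 - F)", {
  set.seed(404)
  het_frac <- function(f) {
    h <- replicate(200, {
      G <- sweepscan:::simulate_window_genotypes(
        8, theta = 2e-3, L = 5e3, inbreeding_f = f)
      if (length(G) == 0) return(NA_real_)
      mean(G == 1L)
    })
    mean(h, na.rm = TRUE)
  }
  h0 <- het_frac(0)
  h9 <- het_frac(0.9)
  expect_lt(h9, h0)
  expect_lt(h9, 0.35 * h0)  # well below the outbred level, ~(1-F) scale
})

test_that("F = 1 forces every genotype homozygous", {
  set.seed(7)
  G <- sweepscan:::simulate_window_genotypes(6, theta = 3e-3, L = 1e4,
                                             inbreeding_f = 1)
  expect_true(all(G %in% c(0L, 2L)))
})

test_that("ld_r2 is the squared dosage correlation", {
  x <- c(0, 0, 1, 1, 2, 2, 0, 2)
  y <- c(0, 0, 1, 1, 2, 2, 2, 0)
  codes <- matrix(as.integer(c(x, y)), ncol = 2,
                  dimnames = list(paste0("s", 1:8), NULL))
  sites <- data.frame(contig = "c", pos = c(100L, 200L),
                      ref = "A", alt = "G")
  gm <- genotype_matrix(codes, sites)
  # hand-computed squared Pearson correlation
  n <- 8
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  expect_equal(ld_r2(gm, 1, 2, maf_min = 0), sxy^2 / (sxx * syy),
               tolerance = 1e-12)
  # identical vectors
  gm2 <- genotype_matrix(matrix(as.integer(c(x, x)), ncol = 2,
                                dimnames = list(paste0("s", 1:8), NULL)),
                         sites)
  expect_equal(ld_r2(gm2, 1, 2, maf_min = 0), 1.0)
  # constant vector is undefined
  gm3 <- genotype_matrix(matrix(as.integer(c(x, rep(1, 8))), ncol = 2,
                                dimnames = list(paste0("s", 1:8), NULL)),
                         sites)
  expect_true(is.na(ld_r2(gm3, 1, 2, maf_min = 0)))
})

test_that("ld_decay finds the haplotype block scale and respects symmetry", {
  # perfect LD everywhere: half-decay undefined
  x <- c(0L, 0L, 1L, 2L, 2L, 1L, 0L, 2L)
  codes <- matrix(rep(x, 5), ncol = 5,
                  dimnames = list(paste0("s", 1:8), NULL))
  sites <- data.frame(contig = "c", pos = c(100L, 5000L, 9000L, 15000L, 22000L),
                      ref = "A", alt = "G")
  gm <- genotype_matrix(codes, sites)
  curve <- ld_decay(gm, rownames(codes), max_dist = 5e4, bin_width = 1000,
                    maf_min = 0)
  expect_true(is.na(curve$half_decay_distance))
  expect_equal(curve$max_r2, 1.0)
  # block-copy cohorts: half-decay within [0.5B, 2B] in most seeds
  B <- 4000
  hd <- vapply(1:20, function(seed) {
    set.seed(seed)
    L <- 40000L
    n_sites <- 120L
    pos <- sort(sample.int(L, n_sites))
    block <- (pos - 1L) %/% B
    G <- sweepscan:::simulate_window_genotypes(
      12, theta = 0, L = L, S = n_sites, block = block)
    keep <- colSums(G) > 0 & colSums(G) < 24
    rownames(G) <- sprintf("s%02d", 1:12)
    gmb <- genotype_matrix(G[, keep, drop = FALSE],
                           data.frame(contig = "c", pos = pos[keep],
                                      ref = "A", alt = "G"))
    ld_decay(gmb, rownames(G), max_dist = 2e4,
             bin_width = 1000, maf_min = 0.1)$half_decay_distance
  }, numeric(1))
  expect_true(mean(hd >= 0.5 * B & hd <= 2 * B, na.rm = TRUE) >= 0.8)
  # invariance to sample order permutation
  set.seed(5)
  m <- rand_codes(10, 30, 50)
  sites2 <- data.frame(contig = "c",
                       pos = sort(sample.int(3e4, 30)),
                       ref = "A", alt = "G")
  gmp <- genotype_matrix(m, sites2)
  perm <- sample(rownames(m))
  c1 <- ld_decay(gmp, rownames(m), 1e4, 1000, 0.1)
  c2 <- ld_decay(gmp, perm, 1e4, 1000, 0.1)
  expect_equal(c1$bins$mean_r2, c2$bins$mean_r2)
})

test_that("dosage PCA has the covariance eigenstructure", {
  m <- rand_codes(10, 50, 77)
  sites <- data.frame(contig = "c", pos = seq_len(50) * 10L,
                      ref = "A", alt = "G")
  gm <- genotype_matrix(m, sites)
  p <- pca_genotypes(gm)
  # full reconstruction of the centered covariance
  V <- eigen(p$covariance, symmetric = TRUE)$vectors
  recon <- V %*% diag(eigen(p$covariance, symmetric = TRUE)$values) %*% t(V)
  expect_equal(recon, unname(p$covariance), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(p$eigenvalues) <= 1e-10))
  # duplicate samples get identical coordinates
  m2 <- rbind(m, dup = m[1, ])
  rownames(m2) <- c(rownames(m), "dup")
  p2 <- pca_genotypes(genotype_matrix(m2, sites))
  expect_equal(p2$scores["dup", 1:3], p2$scores[1, 1:3],
               ignore_attr = TRUE, tolerance = 1e-9)
  # invariance (up to sign, fixed by the loading rule) to site order:
  # permute the dosage columns, keep the (irrelevant) coordinates
  perm <- sample(ncol(m))
  gm_perm <- genotype_matrix(m[, perm], sites)
  p3 <- pca_genotypes(gm_perm)
  expect_equal(abs(p3$scores[, 1]), abs(p$scores[, 1]), tolerance = 1e-9)
  # degenerate input
  expect_error(pca_genotypes(genotype_matrix(
    matrix(1L, 3, 2, dimnames = list(c("a", "b", "c"), NULL)),
    data.frame(contig = "c", pos = c(1L, 2L), ref = "A", alt = "G"))),
    "monomorphic")
})
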