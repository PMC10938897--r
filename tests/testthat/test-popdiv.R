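test_that("variant filtering applies both rules, is idempotent and monotone", {
  ## 10 samples; MAF 0.05 with no missing is retained
  g <- matrix(0L, nrow = 10, ncol = 1)
  g[1, 1] <- 1L  # 1 alt allele among 20 -> MAF 0.05
  m <- genotype_matrix(g)
  expect_equal(filter_variants(m)$log$status, "pass")
  ## hand-built 5-site toy: MAFs {0, .005, .05, .25, .5}, missing {0,0,.4,0,0}
  mk_site <- function(maf, miss, n = 100) {
    alt <- round(maf * 2 * n)
    v <- c(rep(1L, alt), rep(0L, 2 * n - alt))
    g <- v[1:n] + v[(n + 1):(2 * n)]
    g[seq_len(round(miss * n))] <- NA_integer_
    g
  }
  set.seed(1)
  gm <- cbind(mk_site(0, 0), mk_site(0.005, 0), mk_site(0.05, 0.4),
              mk_site(0.25, 0), mk_site(0.5, 0))
  m5 <- genotype_matrix(gm)
  out <- filter_variants(m5)
  expect_equal(sum(out$log$status == "pass"), 2)
  expect_equal(which(out$log$status == "pass"), c(4L, 5L))
  ## order preserved, idempotent
  again <- filter_variants(out$matrix)
  expect_identical(again$matrix$geno, out$matrix$geno)
  ## tightening thresholds never increases survivors
  n_pass <- function(maf, miss) sum(filter_variants(m5, maf, miss)$log$status == "pass")
  expect_lte(n_pass(0.05, 0.3), n_pass(0.01, 0.3))
  expect_lte(n_pass(0.01, 0.1), n_pass(0.01, 0.5))
  ## all-missing site logged distinctly
  m6 <- genotype_matrix(cbind(c(NA, NA, NA), c(0L, 1L, 2L)))
  expect_equal(filter_variants(m6)$log$status[1], "all_missing")
})

test_that("nucleotide diversity matches hand enumeration and scaling", {
  ## 3 samples with pairwise differences {1, 2, 3} over 10 sites -> 0.2
  seqs <- c(a = "AAAAAAAAAA", b = "CAAAAAAAAA", c = "CCCAAAAAAA")
  ## diffs: a-b = 1, a-c = 3, b-c = 2 -> mean 2 -> pi 0.2
  expect_equal(nucleotide_diversity(seqs), 0.2)
  expect_equal(nucleotide_diversity(seqs[c(2, 3, 1)]), 0.2)  # order invariant
  expect_equal(nucleotide_diversity(seqs, n_sites_total = 20), 0.1)  # halves
  expect_equal(nucleotide_diversity(c(x = "ACGT", y = "ACGT")), 0)
  ## genotype-matrix route with missing data, pairwise-complete
  g <- rbind(a = c(0L, 0L, 2L), b = c(2L, NA, 2L))
  expect_equal(nucleotide_diversity(genotype_matrix(g), n_sites_total = 30),
               (1 * 3 / 2) / 30)
  ## heterozygous dosages: expected allele difference 1/2
  gh <- rbind(a = c(0L), b = c(1L))
  expect_equal(nucleotide_diversity(genotype_matrix(gh), n_sites_total = 1), 0.5)
})

test_that("neighbor joining matches the 3-taxon closed form and clamps", {
  D <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.05, 0.15, 0.25), tolerance = 1e-9)
  ## clone pair -> zero-length cherry
  D2 <- matrix(c(0, 0, .3, 0, 0, .3, .3, .3, 0), 3,
               dimnames = list(c("c1", "c2", "o"), c("c1", "c2", "o")))
  tr2 <- suppressMessages(nj_tree(D2))
  bl2 <- tr2$edge.length[match(match(c("c1", "c2"), tr2$tip.label), tr2$edge[, 2])]
  expect_equal(unname(bl2), c(0, 0))
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3")
})

test_that("NJ reconstructs random additive 6-taxon trees exactly", {
  set.seed(2)
  for (i in 1:5) {
    tr <- ape::rtree(6)
    D <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(D[order(rownames(D)), order(colnames(D))])
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0, ignore_attr = TRUE)
    Drec <- ape::cophenetic.phylo(rec)
    expect_equal(Drec[rownames(D), colnames(D)], D, tolerance = 1e-8)
  }
})

test_that("distance-matrix permutation gives an isomorphic NJ tree", {
  set.seed(3)
  tr <- ape::rtree(5)
  D <- ape::cophenetic.phylo(tr)
  p <- sample(5)
  t1 <- nj_tree(D)
  t2 <- nj_tree(D[p, p])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("PCA separates clonal clusters and is stable to duplicated samples", {
  set.seed(4)
  block <- function(base, n) matrix(rep(base, each = n), nrow = n)
  g <- rbind(block(c(rep(2L, 20), rep(0L, 20)), 5),
             block(c(rep(0L, 20), rep(2L, 20)), 5))
  noise <- matrix(rbinom(length(g), 1, 0.01) * 2L, nrow = nrow(g))
  g <- pmin(g + noise, 2L)
  rownames(g) <- paste0("s", 1:10)
  pc <- pca_genotypes(genotype_matrix(g))
  expect_gt(pc$explained[1], 0.99)
  expect_true(all(sign(pc$scores[1:5, 1]) != sign(pc$scores[6:10, 1])))
  ## duplicated sample gets identical coordinates
  g2 <- rbind(g, s11 = g[1, ])
  pc2 <- pca_genotypes(genotype_matrix(g2))
  expect_equal(unname(pc2$scores["s11", ]), unname(pc2$scores["s1", ]), tolerance = 1e-8)
  ## 3x3 hand-computed eigen case
  gm <- rbind(a = c(0L, 2L), b = c(2L, 0L), c = c(0L, 0L))
  pc3 <- pca_genotypes(genotype_matrix(gm))
  K <- tcrossprod(scale(rbind(c(0, 2), c(2, 0), c(0, 0)),
                        center = c(2 / 3, 2 / 3), scale = FALSE) /
                    rep(sqrt(2 * (1 / 3) * (2 / 3)), each = 3)) / 2
  expect_equal(sort(pc3$eigenvalues, decreasing = TRUE),
               sort(eigen(K)$values[eigen(K)$values > 1e-10], decreasing = TRUE),
               tolerance = 1e-8)
})

test_that("plastome comparison is exact on engineered cases", {
  s <- strrep("ACGTTGCA", 2000)
  expect_equal(compare_plastomes(s, s)$snp_count, 0)
  expect_equal(compare_plastomes(s, s)$indel_count, 0)
  ## a single deleted base: (0 SNPs, 1 indel of length 1)
  s2 <- paste0(substr(s, 1, 7000), substr(s, 7002, nchar(s)))
  d <- compare_plastomes(s, s2)
  expect_equal(d$snp_count, 0)
  expect_equal(d$indel_count, 1)
  expect_equal(d$indel_lengths, 1L)
  expect_error(compare_plastomes("", s), "empty")
})
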