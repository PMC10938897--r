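test_that("find_homologs counts family pairs, excludes self, and is symmetric", {
  genes <- data.frame(
    id = paste0("g", 1:10), chrom = "c1", rank = 0:9, strand = "+",
    family = c("A", "A", "B", "B", "B", "C", "D", "E", "F", "G"))
  sub <- genes[genes$family != "B" | genes$id %in% c("g3", "g4"), ]
  sub$rank <- seq_len(nrow(sub)) - 1L
  gA <- new_genome(sub)
  ## one shared family with 2 copies in A and 3 in B -> 6 cross pairs
  gsub <- genes; gsub$id <- paste0("h", 1:10)
  gB <- new_genome(gsub)
  h <- find_homologs(gA, gB, mode = "family")
  expect_equal(sum(h$geneA %in% c("g3", "g4")), 2 * 3)
  ## disjoint families -> empty
  g2 <- genes; g2$family <- paste0("Z", 1:10); g2$id <- paste0("k", 1:10)
  expect_equal(nrow(find_homologs(gA, new_genome(g2), mode = "family")), 0)
  ## self comparison: no gene paired with itself
  hs <- find_homologs(gA, mode = "family")
  expect_false(any(hs$geneA == hs$geneB))
  ## symmetry of the pair set
  hAB <- find_homologs(gA, gB, mode = "family")
  hBA <- find_homologs(gB, gA, mode = "family")
  expect_setequal(paste(hAB$geneA, hAB$geneB), paste(hBA$geneB, hBA$geneA))
  expect_error(find_homologs(gA, new_genome(genes[0, ])), "empty")
})

test_that("a perfect diagonal chains into one block", {
  b <- chain_collinear(diagonal_anchors(100))
  expect_length(b, 1)
  expect_equal(nrow(b[[1]]$anchors), 100)
  expect_equal(b[[1]]$orientation, "same")
})

test_that("the max-gap rule joins at 50 and splits at 51", {
  run2 <- function(gap) {
    a <- rbind(diagonal_anchors(10),
               within(diagonal_anchors(10), {
                 rankA <- rankA + 10 + gap; rankB <- rankB + 10 + gap
                 geneA <- paste0(geneA, "x"); geneB <- paste0(geneB, "x")
               }))
    chain_collinear(a, max_gap = 50, min_block = 5)
  }
  expect_length(run2(50), 1)   # gap of exactly 50 intervening ranks joins
  expect_length(run2(51), 2)   # 51 splits
})

test_that("chaining equals exhaustive search over monotone chains", {
  set.seed(7)
  for (rep in 1:25) {
    m <- sample(4:12, 1)
    a <- data.frame(geneA = paste0("a", 1:m), geneB = paste0("b", 1:m),
                    score = 1, chromA = "c1", rankA = sample(0:11, m),
                    chromB = "c2", rankB = sample(0:11, m))
    max_gap <- sample(c(2, 5, 50), 1)
    blocks <- chain_collinear(a, max_gap = max_gap, min_block = 1)
    got <- max(vapply(blocks, function(b) b$score, numeric(1)))
    expect_equal(got, oracle_best_chain_score(a, max_gap), tolerance = 1e-9)
  }
})

test_that("chaining is symmetric under swapping the two genomes", {
  set.seed(8)
  a <- data.frame(geneA = paste0("a", 1:20), geneB = paste0("b", 1:20),
                  score = 1, chromA = "c1", rankA = sample(0:24, 20),
                  chromB = "c2", rankB = sample(0:24, 20))
  swapped <- data.frame(geneA = a$geneB, geneB = a$geneA, score = a$score,
                        chromA = a$chromB, rankA = a$rankB,
                        chromB = a$chromA, rankB = a$rankA)
  b1 <- chain_collinear(a, min_block = 3)
  b2 <- chain_collinear(swapped, min_block = 3)
  key1 <- sort(vapply(b1, function(b) paste(sort(paste(b$anchors$geneA, b$anchors$geneB)),
                                            collapse = ";"), character(1)))
  key2 <- sort(vapply(b2, function(b) paste(sort(paste(b$anchors$geneB, b$anchors$geneA)),
                                            collapse = ";"), character(1)))
  expect_identical(key1, key2)
})

test_that("increasing max_gap never decreases the anchors placed in blocks", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 30
    a <- diagonal_anchors(n)
    jitter <- sample(0:6, n, replace = TRUE)
    a$rankB <- a$rankB + cumsum(jitter)
    a$rankA <- a$rankA + cumsum(sample(0:6, n, replace = TRUE))
    placed <- vapply(c(5, 10, 20, 50), function(gap) {
      sum(vapply(chain_collinear(a, max_gap = gap, min_block = 2),
                 function(b) nrow(b$anchors), integer(1)))
    }, numeric(1))
    expect_true(all(diff(placed) >= 0))
  }
})

test_that("inverted runs are found and compete with the same orientation", {
  a <- diagonal_anchors(20)
  a$rankB <- 19 - a$rankB  # pure antidiagonal
  b <- chain_collinear(a)
  expect_length(b, 1)
  expect_equal(b[[1]]$orientation, "inverted")
  expect_equal(nrow(b[[1]]$anchors), 20)
})

test_that("dotplot table round-trips blocks and keeps the empty shape", {
  blocks <- fix_tetraploid_blocks()
  tab <- dotplot_table(blocks)
  expect_equal(nrow(tab), sum(vapply(blocks, function(b) nrow(b$anchors), integer(1))))
  back <- blocks_from_table(tab)
  expect_equal(length(back), length(blocks))
  for (i in seq_along(blocks)) {
    expect_equal(back[[i]]$anchors$geneA, blocks[[i]]$anchors$geneA)
    expect_equal(back[[i]]$anchors$rankB, blocks[[i]]$anchors$rankB)
    expect_equal(back[[i]]$orientation, blocks[[i]]$orientation)
  }
  expect_equal(nrow(dotplot_table(structure(list(), class = "synteny_blocks"))), 0)
})

test_that("reciprocal best hits recover one-to-one orthologs and drop ties", {
  anc <- simulate_ancestor(2, 15, 5, 40, seed = 91)
  ## two genomes with modest divergence, ids renamed
  mk <- function(suffix, d) {
    g <- anc
    g$genes$id <- paste0(g$genes$id, suffix)
    g$genes$cds <- vapply(g$genes$cds, mutate_synonymous, "", d = d)
    g
  }
  set.seed(92)
  gA <- mk("_x", 0.05); gB <- mk("_y", 0.05)
  rbh <- reciprocal_best_hits(list(X = gA, Y = gB), min_score = 0.1)
  expect_equal(nrow(rbh), 30)
  expect_identical(sub("_x$", "", rbh$X), sub("_y$", "", rbh$Y))
  ## duplicating a gene with an identical copy creates a tie -> excluded
  gB2 <- gB
  dup <- gB2$genes[1, ]
  dup$id <- "dup_y"; dup$rank <- max(gB2$genes$rank[gB2$genes$chrom == dup$chrom]) + 1L
  gB2$genes <- rbind(gB2$genes, dup)
  gB2 <- new_genome(gB2$genes)
  rbh2 <- reciprocal_best_hits(list(X = gA, Y = gB2), min_score = 0.1)
  expect_false(gB$genes$id[1] %in% rbh2$Y)
  expect_equal(nrow(rbh2), 29)
  expect_error(reciprocal_best_hits(list(X = gA)), ">= 2 genomes")
})

test_that("ortholog depth ratio reflects the WGD algebra", {
  ## identical diploids -> 1:1
  anc <- simulate_ancestor(2, 20, 6, 30, seed = 93)
  a <- anc; a$genes$id <- paste0(a$genes$id, "_a")
  b <- anc; b$genes$id <- paste0(b$genes$id, "_b")
  h <- find_homologs(a, b, mode = "family", self = FALSE)
  h <- h[sub("_a$", "", h$geneA) == sub("_b$", "", h$geneB), ]  # true orthologs
  blocks <- chain_collinear(h, min_block = 5)
  expect_equal(unname(ortholog_depth_ratio(blocks)), c(1, 1))
  ## A doubled twice vs B once -> 4:2 on ledger-perfect anchors
  dupA <- evolve(anc, list(ev_wgd(2, time = 20, tag = "p"),
                           ev_wgd(2, time = 10, tag = "q")))
  dupB <- evolve(anc, list(ev_wgd(2, time = 20, tag = "p")))
  ga <- dupA$genome; ga$genes$id <- paste0(ga$genes$id, "_a")
  gb <- dupB$genome; gb$genes$id <- paste0(gb$genes$id, "_b")
  locus_a <- setNames(unname(dupA$ledger$locus), paste0(names(dupA$ledger$locus), "_a"))
  locus_b <- setNames(unname(dupB$ledger$locus), paste0(names(dupB$ledger$locus), "_b"))
  h2 <- find_homologs(ga, gb, mode = "family", self = FALSE)
  h2 <- h2[locus_a[h2$geneA] == locus_b[h2$geneB], ]
  b42 <- chain_collinear(h2, min_block = 5)
  expect_equal(unname(ortholog_depth_ratio(b42)), c(4, 2))
})
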