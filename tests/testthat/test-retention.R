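test_that("ancestral groups recovered from synteny match the ledger truth", {
  s <- fix_tetraploid()
  blocks <- fix_tetraploid_blocks()
  grp <- assign_ancestral_groups(s$genome, blocks, subgenome = s$ledger$subgenome)
  expect_false(grp$ambiguous)
  ## a chromosome's true group = modal true group of its genes
  genes <- s$genome$genes
  truth <- vapply(split(s$ledger$groups[genes$id], genes$chrom),
                  function(x) names(which.max(table(x))), character(1))
  expect_equal(oracle_ari(grp$groups[names(truth)], truth), 1.0)
  ## relabeling chromosome ids preserves the partition
  g2 <- s$genome
  expect_equal(sort(unname(table(grp$groups))), sort(unname(table(truth))))
})

test_that("a genome with no internal synteny is flagged ambiguous", {
  genes <- data.frame(id = paste0("g", 1:8), chrom = rep(paste0("c", 1:4), each = 2),
                      rank = rep(0:1, 4), strand = "+", family = paste0("F", 1:8))
  g <- new_genome(genes)
  grp <- assign_ancestral_groups(g, structure(list(), class = "synteny_blocks"),
                                 subgenome = setNames(rep(c("A", "B"), each = 2),
                                                      paste0("c", 1:4)))
  expect_true(grp$ambiguous)
})

test_that("no-loss quartets are complete and the orphan case sets one flag", {
  s <- fix_tetraploid()
  blocks <- fix_tetraploid_blocks()
  grp <- assign_ancestral_groups(s$genome, blocks, subgenome = s$ledger$subgenome)
  rec <- quartet_retention(s$genome, blocks, grp)
  rr <- retention_ratio(rec, "ALL", "quartet")
  expect_gt(rr$ratio, 0.9)  # no loss: nearly every locus present in all four groups
  expect_true(all(rec$n_groups >= 1))
})

test_that("retention ratios are plain arithmetic with nested pattern classes", {
  rec <- data.frame(locus = paste0("L", 1:13), family = "F01",
                    A1 = c(rep(TRUE, 5), rep(FALSE, 8)),
                    A2 = c(rep(TRUE, 4), rep(FALSE, 9)),
                    B1 = c(rep(TRUE, 3), TRUE, rep(FALSE, 9)),
                    B2 = c(rep(TRUE, 3), rep(FALSE, 10)))
  rec$n_groups <- rowSums(rec[, c("A1", "A2", "B1", "B2")])
  expect_equal(retention_ratio(rec, "F01", "quartet")$ratio, 3 / 13, tolerance = 1e-9)
  expect_equal(retention_ratio(rec, "F01", "pairA")$retained, 4)
  expect_error(retention_ratio(rec, "NOPE", "quartet"), "unknown family")
  ## quartet <= pair <= homoeolog on real records
  s <- fix_tetraploid()
  blocks <- fix_tetraploid_blocks()
  grp <- assign_ancestral_groups(s$genome, blocks, subgenome = s$ledger$subgenome)
  recs <- quartet_retention(s$genome, blocks, grp)
  q <- retention_ratio(recs, "ALL", "quartet")$ratio
  pa <- retention_ratio(recs, "ALL", "pairA")$ratio
  pb <- retention_ratio(recs, "ALL", "pairB")$ratio
  h <- retention_ratio(recs, "ALL", "homoeolog")$ratio
  expect_lte(q, pa); expect_lte(q, pb)
  expect_lte(q, h)
})

test_that("Fisher depletion p equals exhaustive hypergeometric enumeration", {
  expect_equal(depletion_test(10, 20, 10, 20), 1)
  expect_equal(depletion_test(1, 10, 50, 100), oracle_fisher_p(1, 9, 50, 50),
               tolerance = 1e-9)
  ## symmetry under transposition
  expect_equal(depletion_test(3, 10, 20, 40),
               fisher.test(matrix(c(3, 20, 7, 20), 2))$p.value)
  expect_error(depletion_test(5, 3, 10, 20), "exceeds")
  ## all tables with modest totals
  for (ft in c(6, 9)) for (fr in 0:ft) for (bt in c(20, 40)) for (br in c(5, 17)) {
    if (br > bt) next
    expect_equal(depletion_test(fr, ft, br, bt),
                 oracle_fisher_p(fr, ft - fr, br, bt - br), tolerance = 1e-8)
  }
})

test_that("family size folds are 2 after a clean WGD and 1 for identical genomes", {
  anc <- simulate_ancestor(4, 30, 12, 5, seed = 201)
  dup <- evolve(anc, list(ev_wgd(2, time = 1)))$genome
  sizesA <- table(dup$genes$family)
  sizesB <- table(anc$genes$family)
  fsm <- family_size_matrix(setNames(as.integer(sizesA), names(sizesA)),
                            setNames(as.integer(sizesB), names(sizesB)))
  expect_equal(fsm$modal_fold, 2)
  expect_true(all(fsm$records$fold == 2))
  fsm1 <- family_size_matrix(setNames(as.integer(sizesB), names(sizesB)),
                             setNames(as.integer(sizesB), names(sizesB)))
  expect_equal(fsm1$modal_fold, 1)
  expect_true(all(fsm1$records$p > 0.99))
  ## per-family Fisher test against the oracle
  fsm2 <- family_size_matrix(c(FX = 100, FY = 9900), c(FX = 50, FY = 9950))
  expect_equal(fsm2$records$p[fsm2$records$family == "FX"],
               oracle_fisher_p(100, 9900, 50, 9950), tolerance = 1e-8)
  ## both-zero families skipped
  fsm3 <- family_size_matrix(c(FA = 2, FB = 0), c(FA = 1, FB = 0))
  expect_equal(fsm3$skipped, "FB")
})

test_that("biased families rank below unbiased ones in quartet retention", {
  worse <- 0; runs <- 6
  for (i in seq_len(runs)) {
    s <- simulate_allotetraploid(n_proto = 4, genes_per_chrom = 18, n_families = 6,
                                 codons_per_gene = 60, ks_tau = NULL,
                                 ks_dup = 0.4, ks_split = 0.08,
                                 loss_rate = 0.15, family_bias = c(F01 = 4),
                                 te_div = NULL, seed = 300 + i)
    blocks <- chain_collinear(
      find_homologs(s$genome, mode = "sequence", min_score = 0.25), min_block = 4)
    grp <- assign_ancestral_groups(s$genome, blocks, subgenome = s$ledger$subgenome)
    rec <- quartet_retention(s$genome, blocks, grp)
    r_biased <- retention_ratio(rec, "F01", "quartet")$ratio
    others <- setdiff(sort(unique(rec$family)), "F01")
    r_rest <- mean(vapply(others, function(f) retention_ratio(rec, f, "quartet")$ratio, 0))
    if (r_biased < r_rest) worse <- worse + 1
  }
  expect_gte(worse, runs - 1)
})
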