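test_that("simulate_ancestor builds the requested genome and rejects bad counts", {
  g <- simulate_ancestor(8, 100, 20, 100, seed = 1)
  expect_equal(n_genes(g), 800)
  expect_length(chromosomes(g), 8)
  expect_true(all(nchar(g$genes$cds) == 300))
  expect_false(any(vapply(g$genes$cds, function(x) {
    any(polyevolve:::GENETIC_CODE_1[polyevolve:::split_codons(x)] == "*")
  }, logical(1))))
  g1 <- simulate_ancestor(1, 1, 1, 1, seed = 1)
  expect_equal(n_genes(g1), 1)
  expect_equal(nchar(g1$genes$cds), 3)
  expect_error(simulate_ancestor(0, 10, 2, 10), "positive integer")
  expect_error(simulate_ancestor(2, -1, 2, 10), "positive integer")
})

test_that("same seed gives byte-identical output files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    s <- simulate_allotetraploid(n_proto = 2, genes_per_chrom = 6,
                                 codons_per_gene = 20, te_copies = 3, seed = 77)
    write_genome(s$genome, d, "g")
    write_ledger(s$ledger, d, "t")
  }
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("WGD duplicates every locus and chromosome", {
  g <- simulate_ancestor(8, 10, 5, 10, seed = 2)
  out <- evolve(g, list(ev_wgd(2, time = 10)), seed = 3)
  expect_length(chromosomes(out$genome), 16)
  expect_equal(n_genes(out$genome), 160)
  desc_per_locus <- table(out$ledger$locus)
  expect_true(all(desc_per_locus == 2))
})

test_that("the printed karyotype trajectory collapses 8 chromosomes to 4", {
  g <- simulate_ancestor(8, 6, 3, 5, seed = 4)
  chs <- chromosomes(g)
  hist <- list(ev_wgd(2, time = 100, tag = "w"))
  c16 <- c(chs, paste0(chs, "_w2"))
  hist <- c(hist, list(ev_fission(c16[1], 3, time = 50)))
  c17 <- c(c16[1], paste0(c16[1], "f"), c16[-1])
  leads <- c17[c(1, 6, 10, 14)]
  groups <- split(c17, rep(1:4, c(5, 4, 4, 4)))
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]][-1]) hist <- c(hist, list(ev_fusion(groups[[gi]][1], m, time = 50)))
  }
  out <- evolve(g, hist, seed = 5)
  expect_length(chromosomes(out$genome), 4)  # 8*2 + 1 - 13
  expect_equal(n_genes(out$genome), 96)      # no gene lost in rearrangement
})

test_that("fission and fusion reject invalid targets", {
  g <- simulate_ancestor(2, 10, 2, 5, seed = 1)
  expect_error(evolve(g, list(ev_fission("nope", 5))), "nonexistent")
  expect_error(evolve(g, list(ev_fission("chr01", 0))), "interior")
  expect_error(evolve(g, list(ev_fission("chr01", 10))), "interior")
  expect_error(evolve(g, list(ev_fusion("chr01", "nope"))), "nonexistent")
  expect_error(evolve(g, list(ev_fusion("chr01", "chr02", time = 1),
                              ev_wgd(2, time = 5))), "non-increasing")
})

test_that("chromosome-count conservation holds over random histories", {
  set.seed(42)
  for (rep in 1:8) {
    g <- simulate_ancestor(sample(3:6, 1), 12, 4, 5)
    k <- sample(2:3, 1)
    out <- evolve(g, list(ev_wgd(k, time = 30, tag = "w")))
    gen <- out$genome
    n_fis <- 0L; n_fus <- 0L
    for (step in 1:6) {
      chs <- chromosomes(gen)
      sizes <- table(gen$genes$chrom)[chs]
      if (runif(1) < 0.5 && any(sizes >= 3)) {
        ch <- sample(chs[sizes >= 3], 1)
        bp <- sample(seq_len(sizes[[ch]] - 1L), 1)
        gen <- evolve(gen, list(ev_fission(ch, bp, time = 0)))$genome
        n_fis <- n_fis + 1L
      } else if (length(chs) >= 2) {
        pick <- sample(chs, 2)
        gen <- evolve(gen, list(ev_fusion(pick[1], pick[2], flipB = runif(1) < 0.5,
                                          time = 0)))$genome
        n_fus <- n_fus + 1L
      }
    }
    expect_length(chromosomes(gen),
                  length(chromosomes(g)) * k + n_fis - n_fus)
  }
})

test_that("gene-lineage conservation: survivors plus losses equal loci times k", {
  g <- simulate_ancestor(4, 15, 6, 10, seed = 11)
  out <- evolve(g, list(ev_wgd(2, time = 10),
                        ev_loss(0.3, time = 0, allow_extinction = TRUE)), seed = 12)
  expect_equal(length(out$ledger$locus) + nrow(out$ledger$losses), 60 * 2)
  ## survivors' ranks still consecutive
  expect_silent(validate_genome(out$genome))
})

test_that("family-biased loss realizes the expected per-family loss fraction", {
  ## per-gene Bernoulli with bias multiplier: family F01 at 2 x 0.25 = 0.5
  losses <- 0; total <- 0
  set.seed(21)
  for (rep in 1:10) {
    g <- simulate_ancestor(2, 40, 4, 5, family_skew = 1)
    out <- evolve(g, list(ev_loss(0.25, family_bias = c(F01 = 2), time = 0,
                                  allow_extinction = TRUE)))
    n_f1 <- sum(g$genes$family == "F01")
    lost <- sum(out$ledger$losses$family == "F01")
    losses <- losses + lost; total <- total + n_f1
  }
  p_hat <- losses / total
  se <- sqrt(0.5 * 0.5 / total)
  expect_lt(abs(p_hat - 0.5), 4 * se)
})

test_that("loss protects the last copy of a locus unless extinction is allowed", {
  g <- simulate_ancestor(2, 20, 3, 5, seed = 31)
  out <- evolve(g, list(ev_wgd(2, time = 5), ev_loss(0.95, time = 0)), seed = 32)
  expect_true(all(table(out$ledger$locus) >= 1))
  expect_equal(length(unique(out$ledger$locus)), 40)
})

test_that("expected pairwise Ks tracks duplication age across five epochs", {
  ## regression of ledger-truth Ks on event age: slope 2 * rate, intercept 0
  rate <- 0.002
  ages <- c(50, 100, 150, 200, 250)
  g <- simulate_ancestor(1, 4, 2, 10, seed = 41)
  hist <- c(list(ev_seq(rate, time = 300)),
            lapply(seq_along(ages), function(i) {
              ev_wgd(2, time = rev(ages)[i], tag = paste0("w", i))
            }))
  out <- evolve(g, hist, seed = 42)
  ev <- out$ledger$events
  wgd <- ev[ev$type == "wgd", ]
  fit <- lm(expected_pair_ks ~ time, data = wgd)
  expect_equal(unname(coef(fit)[2]), 2 * rate, tolerance = 1e-8)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-8)
  ## and the realized NG86 Ks of one young duplicate pair lands near truth
  ids <- out$genome$genes$id
  base <- ids[1]
  young <- paste0(base, ".w5", "2")
  expect_true(young %in% ids)
  expect_equal(true_ks(out$ledger, base, young), 2 * rate * 50)
})

test_that("make_allotetraploid sets 2n, subgenome truth, and homoeolog Ks", {
  anc <- simulate_ancestor(8, 10, 5, 30, seed = 51)
  tet <- make_allotetraploid(anc, anc, divergence = 0)
  expect_match(tet$genome$ploidy_note, "2n = 4x = 32")
  expect_length(chromosomes(tet$genome), 16)
  expect_setequal(unique(unname(tet$ledger$subgenome)), c("A", "B"))
  ## zero divergence: all homoeolog Ks are exactly 0
  cds <- setNames(tet$genome$genes$cds, tet$genome$genes$id)
  ids_a <- grep("_A$", names(cds), value = TRUE)[1:10]
  ks <- vapply(ids_a, function(i) ng86(cds[[i]], cds[[sub("_A$", "_B", i)]])$Ks, 0)
  expect_true(all(ks == 0))
  ## clashing chromosome ids rejected when renaming is forbidden
  expect_error(make_allotetraploid(anc, anc, suffixes = NULL), "share chromosome ids")
})

test_that("homoeolog Ks mode matches the requested divergence", {
  anc <- simulate_ancestor(2, 60, 5, 100, seed = 61)
  tet <- make_allotetraploid(anc, anc, divergence = 0.1, seed = 62)
  cds <- setNames(tet$genome$genes$cds, tet$genome$genes$id)
  ids_a <- grep("_A$", names(cds), value = TRUE)
  ks <- vapply(ids_a, function(i) ng86(cds[[i]], cds[[sub("_A$", "_B", i)]])$Ks, 0)
  expect_equal(median(ks), 0.1, tolerance = 0.1)
  expect_equal(true_ks(tet$ledger, ids_a[1], sub("_A$", "_B", ids_a[1])), 0.1)
})

test_that("simulated population obeys the pi calibration and clonal structure", {
  ref <- simulate_ancestor(1, 5, 2, 10, seed = 71, chrom_bp = 1000)
  ## theta = 0: identical samples, pi = 0
  p0 <- simulate_population(ref, population_spec(5, theta = 0, n_sites = 1000), seed = 72)
  expect_equal(ncol(p0$geno$geno), 0)
  expect_length(unique(p0$sequences), 1)
  ## forced single difference between 2 samples over 10 sites: pi = 0.1
  gm <- genotype_matrix(rbind(s1 = c(0L), s2 = c(2L)))
  expect_equal(nucleotide_diversity(gm, n_sites_total = 10), 0.1)
  ## theta recovery within sampling error
  spec <- population_spec(10, theta = 0.00144, n_sites = 1e5, n_genotypes = 4)
  ps <- simulate_population(ref, spec, seed = 73)
  pi_hat <- nucleotide_diversity(ps$geno, n_sites_total = ps$n_sites_total)
  ## binomial sampling band: Var(pi_hat) ~ theta / (h * L) summed over draws
  se <- sqrt(0.00144 / 1e5) * 3  # generous 3-se-style band
  expect_lt(abs(pi_hat - 0.00144), 3 * se)
  ## clones identical before missingness
  expect_equal(ps$truth[1, ], ps$truth[2, ])
  expect_error(population_spec(1), "n_samples")
})

test_that("make_plastome_pair produces exactly the requested edits", {
  p0 <- make_plastome_pair(1000, 0, 0, seed = 81)
  expect_identical(p0$a, p0$b)
  p1 <- make_plastome_pair(20000, 0, 1, seed = 82)
  expect_equal(abs(nchar(p1$a) - nchar(p1$b)), 1)
  d1 <- compare_plastomes(p1$a, p1$b)
  expect_equal(d1$snp_count, 0)
  expect_equal(d1$indel_count, 1)
  expect_equal(d1$indel_lengths, 1L)
  p2 <- make_plastome_pair(20000, 3, 2, seed = 83)
  d2 <- compare_plastomes(p2$a, p2$b)
  expect_equal(d2$snp_count, 3)
  expect_equal(d2$indel_count, 2)
  expect_error(make_plastome_pair(100, 50, 60), "exceed")
})
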