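test_that("canonical k-mer counting matches hand counts and strand collapse", {
  p <- kmer_profile(c(c1 = "AAAA"), k = 3)
  expect_equal(unname(p$counts[1, "AAA"]), 2)
  ## reverse complement gives the identical profile
  s <- "ACGTTGCAATTGGCC"
  p1 <- kmer_profile(c(x = s), k = 5)
  p2 <- kmer_profile(c(x = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))), k = 5)
  expect_equal(p1$counts[1, sort(colnames(p1$counts))],
               p2$counts[1, sort(colnames(p2$counts))])
  ## two-chromosome toy against hand-counted table: b = revcomp(a)
  p3 <- kmer_profile(c(a = "AAACA", b = "TGTTT"), k = 3)
  expect_equal(unname(p3$counts["a", ]), unname(p3$counts["b", ]))
  expect_equal(unname(p3$counts["a", c("AAA", "AAC", "ACA")]), c(1, 1, 1))
  expect_error(kmer_profile(c(a = "ACGT"), k = 4), "odd")
  expect_error(kmer_profile(c(a = "ACG"), k = 5), "shortest")
})

test_that("differential k-mers handle disjoint, uniform and enriched content", {
  prof <- kmer_profile(c(a = strrep("ACACACACACA", 4), b = strrep("GTGTGTGTGTG", 4),
                         c = strrep("AAGGAAGGAAGG", 4), d = strrep("CCTTCCTTCCTT", 4)),
                       k = 3)
  part <- c(a = "S1", b = "S1", c = "S2", d = "S2")
  dk <- differential_kmers(prof, part)
  ## every k-mer present in exactly one class is specific to it
  expect_true(all(colSums(prof$counts[c("a", "b"), dk$S1, drop = FALSE]) > 0))
  expect_true(all(colSums(prof$counts[c("c", "d"), dk$S1, drop = FALSE]) == 0))
  ## uniform content -> empty sets
  u <- kmer_profile(c(a = "ACGTACGTAC", b = "ACGTACGTAC"), k = 3)
  dku <- differential_kmers(u, c(a = "S1", b = "S2"))
  expect_length(dku$S1, 0)
  expect_length(dku$S2, 0)
  expect_error(differential_kmers(prof, c(a = "S1", b = "S1", c = "S1", d = "S1")[1:3]),
               "cover")
})

test_that("phasing recovers the true subgenomes exactly on TE-burst tetraploids", {
  s <- fix_tetraploid()
  prof <- kmer_profile(s$genome$chrom_seq, k = 13)
  ph <- phase_subgenomes(prof, seed = 1)
  truth <- s$ledger$subgenome[names(ph$assignment)]
  expect_equal(oracle_ari(ph$assignment, truth), 1.0)
  expect_gt(ph$consistency, 0.8)
  ## order invariance: permuting chromosome input gives the same partition
  perm <- rev(names(s$genome$chrom_seq))
  ph2 <- phase_subgenomes(kmer_profile(s$genome$chrom_seq[perm], k = 13), seed = 1)
  expect_identical(ph$assignment[sort(names(ph$assignment))],
                   ph2$assignment[sort(names(ph2$assignment))])
})

test_that("chromosomes without subgenome-specific k-mers are flagged unphaseable", {
  set.seed(2)
  base <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  seqs <- setNames(rep(base, 8), c(paste0("c", 1:4, "_A"), paste0("c", 1:4, "_B")))
  ph <- phase_subgenomes(kmer_profile(seqs, k = 7), seed = 3)
  expect_lt(ph$consistency, 0.6)
  expect_error(phase_subgenomes(kmer_profile(seqs[1:3], k = 7)), "per subgenome")
})

test_that("PercDiv is exact and landscapes conserve TE copy mass", {
  cons <- strrep("ACGT", 25)
  expect_equal(percdiv(cons, cons), 0)
  copy <- paste0("TCGT", strrep("ACGT", 24))  # one mismatch in 100
  expect_equal(percdiv(copy, cons), 1)
  s <- fix_tetraploid()
  land <- te_divergence_landscape(s$genome$te_copies, s$ledger$te_consensus,
                                  s$ledger$subgenome)
  per_sub <- table(s$ledger$subgenome[s$genome$te_copies$chrom])
  expect_equal(rowSums(land$counts), as.numeric(per_sub[rownames(land$counts)]),
               ignore_attr = TRUE)
  ## burst modes land at the target divergences
  expect_equal(as.numeric(names(which.max(land$counts["A", ]))), 5, tolerance = 1)
  expect_equal(as.numeric(names(which.max(land$counts["B", ]))), 19, tolerance = 1.5)
  expect_error(te_divergence_landscape(s$genome$te_copies[0, ],
                                       s$ledger$te_consensus, s$ledger$subgenome),
               "empty")
})

test_that("copies mutated to 5% divergence fall in the [5,6) bin on average", {
  set.seed(4)
  cons <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  copies <- data.frame(chrom = "c1", family = "TE1",
                       seq = replicate(30, polyevolve:::mutate_percent(cons, 5)))
  land <- te_divergence_landscape(copies, list(TE1 = cons), c(c1 = "A"))
  mode_bin <- as.numeric(names(which.max(land$counts["A", ])))
  expect_equal(mode_bin, 5, tolerance = 1)
})

test_that("the non-overlap bubble matches the burst geometry", {
  s <- fix_tetraploid()
  land <- te_divergence_landscape(s$genome$te_copies, s$ledger$te_consensus,
                                  s$ledger$subgenome)
  iv <- nonoverlap_interval(land, threshold = 0.75)
  expect_length(iv, 2)
  expect_gt(iv[["from"]], 4)   # above the young subA burst at 5%
  expect_lt(iv[["to"]], 20)    # below the old subB burst bulk at 19%
  expect_gt(iv[["to"]] - iv[["from"]], 5)
  ## identical landscapes -> empty interval
  la <- structure(list(counts = land$counts[c(1, 1), ], breaks = land$breaks,
                       bin = land$bin), class = "te_landscape")
  expect_length(nonoverlap_interval(la, threshold = 0.75), 0)
  ## threshold 0 degenerates to the full binned range
  iv0 <- nonoverlap_interval(land, threshold = 0)
  expect_equal(unname(iv0), c(0, 50))
  ## binning mismatch between separate landscapes errors
  l1 <- te_divergence_landscape(s$genome$te_copies, s$ledger$te_consensus,
                                s$ledger$subgenome, bin = 2)
  expect_error(nonoverlap_interval(a = l1, b = land), "mismatch")
})

test_that("majority-rule consensus reconstructs the generating sequence", {
  set.seed(5)
  cons <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  copies <- data.frame(family = "TE1",
                       seq = replicate(21, polyevolve:::mutate_percent(cons, 4)))
  rec <- te_family_consensus(copies)
  expect_gt(100 - percdiv(rec[["TE1"]], cons), 99)
})
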