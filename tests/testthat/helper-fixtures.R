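# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

# a mid-sized allotetraploid without loss (quartets complete)
fix_tetraploid <- function() {
  ## 4 proto chromosomes + lineage WGD -> two 8-chromosome progenitors
  fixture("tetraploid", simulate_allotetraploid(
    n_proto = 4, genes_per_chrom = 20, n_families = 15, codons_per_gene = 80,
    ks_tau = NULL, ks_dup = 0.5, ks_split = 0.08, loss_rate = 0,
    te_div = c(A = 5, B = 19), te_copies = 12, seed = 101))
}

# its within-genome blocks with Ks
fix_tetraploid_blocks <- function() {
  fixture("tetraploid_blocks", {
    s <- fix_tetraploid()
    anchors <- find_homologs(s$genome, mode = "sequence", min_score = 0.25)
    b <- chain_collinear(anchors, min_block = 4)
    block_ks(b, setNames(s$genome$genes$cds, s$genome$genes$id))
  })
}

# simple diagonal anchor table helper
diagonal_anchors <- function(n, chromA = "a1", chromB = "b1", offset = 0,
                             score = 1) {
  data.frame(geneA = paste0("ga", seq_len(n)), geneB = paste0("gb", seq_len(n)),
             score = score, chromA = chromA, rankA = seq_len(n) - 1L,
             chromB = chromB, rankB = seq_len(n) - 1L + offset,
             stringsAsFactors = FALSE)
}
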