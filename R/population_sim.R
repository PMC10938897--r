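#' Specification for a resequenced-population simulation
#'
#' Describes a clonal population: `n_samples` individuals partitioned into
#' `n_genotypes` distinct genotypes (one dominant clone plus singletons by
#' default, mirroring a globally spread clonal weed), with per-site mutation
#' parameter `theta` and a missing-data rate applied after genotyping.
#'
#' @param n_samples number of samples (>= 2).
#' @param theta target expected nucleotide diversity (mean pairwise
#'   differences per site); the per-site mutation probability is calibrated
#'   from the clonal structure so that `E[pi] = theta`.
#' @param n_sites total surveyed sites (monomorphic included).
#' @param n_genotypes number of distinct genotypes (clones share a genotype).
#' @param genotype_sizes optional integer vector of clone sizes summing to
#'   `n_samples`; default gives the first genotype `n_samples - n_genotypes + 1`
#'   members and the rest one each.
#' @param missing_rate per-cell probability of a missing genotype call.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_samples = 10, theta = 0.00144, n_sites = 1e5,
                            n_genotypes = 4, genotype_sizes = NULL,
                            missing_rate = 0) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (is.null(genotype_sizes)) {
    n_genotypes <- min(n_genotypes, n_samples)
    genotype_sizes <- c(n_samples - n_genotypes + 1L, rep(1L, n_genotypes - 1L))
  }
  if (sum(genotype_sizes) != n_samples) {
    stop("genotype_sizes must sum to n_samples", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), theta = theta,
                 n_sites = as.integer(n_sites),
                 genotype_sizes = as.integer(genotype_sizes),
                 missing_rate = missing_rate),
            class = "population_spec")
}

#' Simulate a resequenced population against a reference genome
#'
#' Infinite-sites draw: each surveyed site carries a mutation with a
#' probability calibrated so that the expected nucleotide diversity over all
#' sample pairs equals `theta` given the clonal structure; a mutation is
#' assigned to one genotype (uniformly chosen), whose members all carry the
#' derived allele homozygously. Clonal samples are therefore identical before
#' missing data are injected.
#'
#' @param ref a `genome` whose chromosome sequences provide the reference
#'   (concatenated); if absent, a random reference of `spec$n_sites` bp is
#'   drawn.
#' @param spec a [population_spec()].
#' @param seed RNG seed.
#' @return list with `geno` (a [genotype_matrix()]: samples x polymorphic
#'   sites, dosages 0/2 with `NA` for missing), `sequences` (named character
#'   vector, one haplotype per sample, for FASTA export), `truth` (per-site
#'   mutated genotype), and `n_sites_total`.
#' @export
simulate_population <- function(ref, spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    refseq <- if (!is.null(ref$chrom_seq)) paste(ref$chrom_seq, collapse = "") else ""
    if (nchar(refseq) < spec$n_sites) {
      refseq <- paste0(refseq, random_dna(spec$n_sites - nchar(refseq)))
    }
    refseq <- substr(refseq, 1, spec$n_sites)
    n <- spec$n_samples
    sizes <- spec$genotype_sizes
    G <- length(sizes)
    sample_geno <- rep(seq_len(G), sizes)
    ## calibration: a mutation on genotype g makes n_g * (n - n_g) of the
    ## C(n, 2) sample pairs differ; with genotypes drawn uniformly the
    ## expected per-mutation heterozygosity is their mean
    h_per_mut <- mean(sizes * (n - sizes)) / choose(n, 2)
    mu <- if (h_per_mut > 0) spec$theta / h_per_mut else 0
    if (mu > 1) stop("theta too large for this clonal structure", call. = FALSE)
    n_mut <- rbinom(1, spec$n_sites, mu)
    pos <- sort(sample.int(spec$n_sites, n_mut))
    hit_geno <- sample.int(G, n_mut, replace = TRUE)
    refb <- strsplit(refseq, "", fixed = TRUE)[[1]]
    alt <- vapply(refb[pos], function(b) sample(setdiff(DNA_BASES, b), 1), character(1))
    geno <- matrix(0L, nrow = n, ncol = n_mut,
                   dimnames = list(sprintf("sample%02d", seq_len(n)),
                                   if (n_mut) paste0("site", pos) else NULL))
    for (j in seq_len(n_mut)) geno[sample_geno == hit_geno[j], j] <- 2L
    sequences <- vapply(seq_len(n), function(i) {
      b <- refb
      carry <- geno[i, ] == 2L
      b[pos[carry]] <- alt[carry]
      paste(b, collapse = "")
    }, character(1))
    names(sequences) <- rownames(geno)
    truth <- geno
    if (spec$missing_rate > 0 && length(geno)) {
      geno[matrix(runif(length(geno)) < spec$missing_rate, nrow = n)] <- NA_integer_
    }
    sites <- data.frame(chrom = rep("ref", n_mut), pos = pos,
                        ref = refb[pos], alt = alt, stringsAsFactors = FALSE)
    list(geno = genotype_matrix(geno, sites), sequences = sequences,
         truth = truth, n_sites_total = spec$n_sites,
         sample_genotype = setNames(sample_geno, rownames(geno)))
  })
}

#' Generate a near-identical plastome pair
#'
#' Returns two circularish plastome-like sequences differing by exactly the
#' requested numbers of single-base substitutions and 1-bp indels, placed at
#' well-separated positions so each edit is an isolated event.
#'
#' @param length sequence length in bp (> 0).
#' @param n_snps,n_indels numbers of substitutions and 1-bp indels.
#' @param seed RNG seed.
#' @param min_spacing minimum distance between edit positions.
#' @return `list(a = , b = )` character sequences.
#' @examples
#' p <- make_plastome_pair(10000, 0, 1, seed = 1)
#' nchar(p$a) - nchar(p$b)  # +/- 1
#' @export
make_plastome_pair <- function(length, n_snps = 0, n_indels = 0, seed = NULL,
                               min_spacing = 100) {
  if (length <= 0) stop("length must be > 0", call. = FALSE)
  n_edit <- n_snps + n_indels
  if (n_edit * min_spacing >= length) stop("edits exceed sequence length", call. = FALSE)
  with_seed(seed, {
    a <- random_dna(length)
    if (n_edit == 0) return(list(a = a, b = a))
    ## well-separated interior positions
    slots <- seq(from = min_spacing, to = length - min_spacing,
                 length.out = max(n_edit, 2))
    pos <- sort(sample(round(slots), n_edit))
    kind <- sample(c(rep("snp", n_snps), rep("indel", n_indels)))
    b <- a
    for (i in rev(seq_len(n_edit))) {  # right-to-left keeps positions valid
      p <- pos[i]
      if (kind[i] == "snp") {
        base <- substr(b, p, p)
        substr(b, p, p) <- sample(setdiff(DNA_BASES, base), 1)
      } else if (runif(1) < 0.5) {  # deletion of one base in b
        b <- paste0(substr(b, 1, p - 1), substr(b, p + 1, nchar(b)))
      } else {                      # insertion of one base in b
        b <- paste0(substr(b, 1, p), sample(DNA_BASES, 1), substr(b, p + 1, nchar(b)))
      }
    }
    list(a = a, b = b)
  })
}
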