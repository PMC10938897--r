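#' Detect homologous gene pairs between (or within) genomes
#'
#' Candidate anchors come from shared gene-family labels; in `sequence` mode
#' candidates are additionally scored by coding-sequence k-mer similarity
#' (Jaccard index of 6-mer sets), which separates same-locus copies from
#' remote family co-members. Within-genome comparison (pass the same genome
#' twice, or omit `genomeB`) excludes a gene paired with itself and reports
#' each unordered pair once.
#'
#' @param genomeA,genomeB `genome` objects (`genomeB` defaults to `genomeA`
#'   for a self-comparison).
#' @param mode `"family"` (score 1 for family co-membership) or `"sequence"`
#'   (family candidates scored by CDS k-mer Jaccard similarity).
#' @param min_score anchors below this score are dropped.
#' @param kmer k-mer length for `sequence` scoring.
#' @param self force self-comparison semantics (unordered pairs, no gene
#'   paired with itself); by default inferred from identical gene-id sets.
#' @return data.frame of anchors: `geneA`, `geneB`, `score`, plus resolved
#'   `chromA`, `rankA`, `chromB`, `rankB`.
#' @export
find_homologs <- function(genomeA, genomeB = genomeA, mode = c("family", "sequence"),
                          min_score = 0, kmer = 6, self = NULL) {
  mode <- match.arg(mode)
  if (!n_genes(genomeA) || !n_genes(genomeB)) stop("empty genome", call. = FALSE)
  if (is.null(self)) self <- identical(genomeA$genes$id, genomeB$genes$id)
  ga <- genomeA$genes; gb <- genomeB$genes
  fams <- intersect(unique(ga$family), unique(gb$family))
  fams <- fams[!is.na(fams)]
  pairs <- do.call(rbind, lapply(fams, function(f) {
    ia <- which(ga$family == f); ib <- which(gb$family == f)
    expand.grid(ia = ia, ib = ib, KEEP.OUT.ATTRS = FALSE)
  }))
  if (is.null(pairs) || !nrow(pairs)) {
    return(data.frame(geneA = character(0), geneB = character(0), score = numeric(0),
                      chromA = character(0), rankA = integer(0),
                      chromB = character(0), rankB = integer(0)))
  }
  if (self) pairs <- pairs[pairs$ia < pairs$ib, , drop = FALSE]
  out <- data.frame(geneA = ga$id[pairs$ia], geneB = gb$id[pairs$ib],
                    score = 1, chromA = ga$chrom[pairs$ia], rankA = ga$rank[pairs$ia],
                    chromB = gb$chrom[pairs$ib], rankB = gb$rank[pairs$ib],
                    stringsAsFactors = FALSE)
  if (mode == "sequence") {
    if (anyNA(ga$cds[pairs$ia]) || anyNA(gb$cds[pairs$ib])) {
      stop("sequence mode requires CDS on all candidate genes", call. = FALSE)
    }
    kset <- function(s) unique(substring(s, seq_len(nchar(s) - kmer + 1L),
                                         seq_len(nchar(s) - kmer + 1L) + kmer - 1L))
    ksA <- lapply(setNames(ga$cds, ga$id)[unique(out$geneA)], kset)
    ksB <- lapply(setNames(gb$cds, gb$id)[unique(out$geneB)], kset)
    out$score <- vapply(seq_len(nrow(out)), function(i) {
      a <- ksA[[out$geneA[i]]]; b <- ksB[[out$geneB[i]]]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
  }
  out <- out[out$score > 0 & out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain anchors into collinear synteny blocks
#'
#' Sparse dynamic programming per chromosome pair and orientation: a chain is
#' a run of anchors with strictly increasing ranks on both chromosomes (for
#' the inverted orientation, decreasing on the second), in which the rank gap
#' between consecutive anchors does not exceed `max_gap` intervening genes on
#' either chromosome. Chain score is the sum of anchor scores minus
#' `gap_penalty * gap / 10` per step (gap = the larger of the two rank gaps).
#' Within each chromosome pair the best chain (over both orientations) is
#' extracted, its anchors removed, and the search repeated until no remaining
#' chain reaches `min_block` anchors. Ties are broken toward the chain with
#' the smaller start rank on the first, then the second chromosome.
#'
#' @param anchors data.frame from [find_homologs()] (columns `chromA`,
#'   `rankA`, `chromB`, `rankB`, `score`, and gene ids).
#' @param max_gap maximum intervening (non-collinear) genes between
#'   consecutive anchors (default 50).
#' @param min_block minimum anchors per reported block (default 5).
#' @param gap_penalty score deduction per 10 ranks of gap (default 0.5).
#' @return list of `synteny_block` objects: each has `chromA`, `chromB`,
#'   `orientation` (`"same"`/`"inverted"`), `anchors` (ordered data.frame),
#'   `score`, `median_ks` (`NA` until [block_ks()]).
#' @export
chain_collinear <- function(anchors, max_gap = 50, min_block = 5, gap_penalty = 0.5) {
  if (is.null(anchors) || !nrow(anchors)) return(structure(list(), class = "synteny_blocks"))
  blocks <- list()
  for (key in unique(paste(anchors$chromA, anchors$chromB, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- anchors[anchors$chromA == parts[1] & anchors$chromB == parts[2], , drop = FALSE]
    repeat {
      best <- NULL
      for (orient in c("same", "inverted")) {
        ch <- best_chain(sub, orient, max_gap, gap_penalty)
        if (is.null(ch)) next
        if (is.null(best) || ch$score > best$score + 1e-9 ||
            (abs(ch$score - best$score) <= 1e-9 && chain_before(ch, best))) {
          best <- ch
        }
      }
      if (is.null(best) || nrow(best$anchors) < min_block) break
      blocks[[length(blocks) + 1L]] <- structure(
        list(chromA = parts[1], chromB = parts[2], orientation = best$orientation,
             anchors = best$anchors, score = best$score, median_ks = NA_real_,
             max_gap = max_gap, min_block = min_block),
        class = "synteny_block")
      used <- paste(best$anchors$rankA, best$anchors$rankB) # one anchor per coordinate
      sub <- sub[!(paste(sub$rankA, sub$rankB) %in% used), , drop = FALSE]
      if (!nrow(sub)) break
    }
  }
  ## deterministic output order
  if (length(blocks)) {
    o <- order(vapply(blocks, function(b) b$chromA, character(1)),
               vapply(blocks, function(b) b$chromB, character(1)),
               vapply(blocks, function(b) b$anchors$rankA[1], numeric(1)),
               vapply(blocks, function(b) b$anchors$rankB[1], numeric(1)))
    blocks <- blocks[o]
  }
  structure(blocks, class = "synteny_blocks")
}

chain_before <- function(a, b) {
  sa <- c(a$anchors$rankA[1], a$anchors$rankB[1])
  sb <- c(b$anchors$rankA[1], b$anchors$rankB[1])
  sa[1] < sb[1] || (sa[1] == sb[1] && sa[2] < sb[2])
}

## best-scoring single chain on one chromosome pair and orientation;
## O(m^2) DP over anchors sorted by rankA then rankB
best_chain <- function(sub, orientation, max_gap, gap_penalty) {
  if (!nrow(sub)) return(NULL)
  rb <- if (orientation == "inverted") -sub$rankB else sub$rankB
  o <- order(sub$rankA, rb)
  sub <- sub[o, , drop = FALSE]
  rb <- rb[o]
  m <- nrow(sub)
  score <- sub$score           # best chain score ending at i
  prev <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      gapA <- sub$rankA[i] - sub$rankA[j] - 1L
      gapB <- rb[i] - rb[j] - 1L
      if (gapA < 0L || gapB < 0L) next
      if (sub$rankA[i] == sub$rankA[j] || rb[i] == rb[j]) next  # strict monotone
      if (gapA > max_gap || gapB > max_gap) next
      cand <- score[j] + sub$score[i] - gap_penalty * max(gapA, gapB) / 10
      if (cand > score[i] + 1e-12 ||
          (abs(cand - score[i]) <= 1e-12 && !is.na(prev[i]) &&
           sub$rankA[j] < sub$rankA[prev[i]])) {
        score[i] <- cand
        prev[i] <- j
      }
    }
  }
  end <- which.max(score)
  idx <- end
  while (!is.na(prev[idx[1]])) idx <- c(prev[idx[1]], idx)
  an <- sub[idx, , drop = FALSE]
  rownames(an) <- NULL
  list(anchors = an, score = score[end], orientation = orientation)
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("<synteny_blocks> %d blocks, %d anchors\n", length(x),
              sum(vapply(x, function(b) nrow(b$anchors), integer(1)))))
  invisible(x)
}

#' Flatten synteny blocks to a dotplot table
#'
#' One row per anchor; the round trip through [blocks_from_table()] is
#' lossless up to block scores.
#'
#' @param blocks a `synteny_blocks` list.
#' @return data.frame with columns `chromA`, `rankA`, `geneA`, `chromB`,
#'   `rankB`, `geneB`, `block_id`, `orientation`, `ks`.
#' @export
dotplot_table <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(chromA = character(0), rankA = integer(0), geneA = character(0),
                      chromB = character(0), rankB = integer(0), geneB = character(0),
                      block_id = integer(0), orientation = character(0), ks = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    ks <- if ("ks" %in% names(b$anchors)) b$anchors$ks else NA_real_
    data.frame(chromA = b$chromA, rankA = b$anchors$rankA, geneA = b$anchors$geneA,
               chromB = b$chromB, rankB = b$anchors$rankB, geneB = b$anchors$geneB,
               block_id = i, orientation = b$orientation, ks = ks,
               stringsAsFactors = FALSE)
  }))
}

#' Rebuild synteny blocks from a dotplot table
#' @param tab a data.frame from [dotplot_table()].
#' @return a `synteny_blocks` list.
#' @export
blocks_from_table <- function(tab) {
  blocks <- lapply(split(tab, tab$block_id), function(d) {
    structure(list(chromA = d$chromA[1], chromB = d$chromB[1],
                   orientation = d$orientation[1],
                   anchors = data.frame(geneA = d$geneA, geneB = d$geneB, score = NA_real_,
                                        chromA = d$chromA, rankA = d$rankA,
                                        chromB = d$chromB, rankB = d$rankB,
                                        ks = d$ks, stringsAsFactors = FALSE),
                   score = NA_real_, median_ks = NA_real_),
              class = "synteny_block")
  })
  names(blocks) <- NULL
  structure(blocks, class = "synteny_blocks")
}

#' Reciprocal-best-hit single-copy ortholog sets
#'
#' For every ordered genome pair the best-scoring hit of each gene is found;
#' a set of genes (one per genome) is reported when all pairs are mutually
#' best. Ties for best score exclude the gene (conservative orthology).
#'
#' @param genomes named list of >= 2 `genome` objects.
#' @param mode,min_score,kmer passed to [find_homologs()].
#' @return data.frame with one column per genome, one row per single-copy set.
#' @export
reciprocal_best_hits <- function(genomes, mode = "sequence", min_score = 0, kmer = 6) {
  if (length(genomes) < 2) stop("need >= 2 genomes", call. = FALSE)
  if (is.null(names(genomes))) names(genomes) <- paste0("G", seq_along(genomes))
  gn <- names(genomes)
  best_map <- list()
  for (i in gn) for (j in gn) {
    if (i == j) next
    h <- find_homologs(genomes[[i]], genomes[[j]], mode = mode,
                       min_score = min_score, kmer = kmer, self = FALSE)
    bm <- vapply(split(h, h$geneA), function(d) {
      top <- max(d$score)
      cands <- d$geneB[d$score >= top - 1e-12]
      if (length(cands) == 1L) cands else NA_character_  # tie -> excluded
    }, character(1))
    best_map[[paste(i, j)]] <- bm
  }
  ref <- gn[1]
  sets <- lapply(genomes[[ref]]$genes$id, function(g) {
    members <- setNames(character(length(gn)), gn)
    members[ref] <- g
    for (j in gn[-1]) {
      b <- best_map[[paste(ref, j)]][g]
      if (is.na(b)) return(NULL)
      members[j] <- b
    }
    ## verify mutual bestness over all ordered pairs
    for (i in gn) for (j in gn) {
      if (i == j) next
      b <- best_map[[paste(i, j)]][members[i]]
      if (is.na(b) || b != members[j]) return(NULL)
    }
    members
  })
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (!length(sets)) {
    return(as.data.frame(setNames(rep(list(character(0)), length(gn)), gn)))
  }
  out <- as.data.frame(do.call(rbind, sets), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Modal ortholog-depth ratio between two genomes
#'
#' Counts, for every gene position covered by at least one block, how many
#' blocks cover it; the modal depth on the B side is the typical number of
#' A-copies of a B region and vice versa. Reported as `c(a, b)`, e.g. 4:2
#' when genome A holds four copies of each region against two in genome B.
#'
#' @param blocks a `synteny_blocks` list between genomes A and B.
#' @return named integer vector `c(a = , b = )`.
#' @export
ortholog_depth_ratio <- function(blocks) {
  if (!length(blocks)) stop("no blocks", call. = FALSE)
  depth <- function(side_chrom, side_rank) {
    cover <- list()
    for (b in blocks) {
      ch <- b[[side_chrom]]
      r <- range(b$anchors[[side_rank]])
      cover[[length(cover) + 1L]] <- data.frame(ch = ch, at = seq(r[1], r[2]))
    }
    cov <- do.call(rbind, cover)
    tab <- table(paste(cov$ch, cov$at))
    dt <- table(as.integer(tab))
    as.integer(names(dt)[which.max(dt)])
  }
  c(a = depth("chromB", "rankB"), b = depth("chromA", "rankA"))
}
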