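#' Canonical k-mer profile of chromosome sequences
#'
#' Counts strand-collapsed (canonical: the lexicographic minimum of a k-mer
#' and its reverse complement) k-mers per chromosome and normalizes to
#' per-chromosome frequencies.
#'
#' @param seqs named character vector of chromosome sequences.
#' @param k odd k-mer length (default 13; odd so no k-mer is its own reverse
#'   complement).
#' @return object of class `kmer_profile`: `counts` and `freq` matrices
#'   (chromosomes x k-mers) and `k`.
#' @export
kmer_profile <- function(seqs, k = 13) {
  if (!length(seqs) || any(!nzchar(seqs))) stop("sequences must be non-empty", call. = FALSE)
  if (k %% 2 == 0) stop("k must be odd", call. = FALSE)
  if (k > min(nchar(seqs))) stop("k exceeds the shortest sequence", call. = FALSE)
  seqs <- seqs[order(names(seqs))]
  counts_list <- lapply(seqs, function(s) {
    s <- toupper(s)
    n <- nchar(s) - k + 1L
    mers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    mers <- mers[!grepl("[^ACGT]", mers)]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(mers)))
    table(pmin(mers, rc))
  })
  all_k <- sort(unique(unlist(lapply(counts_list, names), use.names = FALSE)))
  counts <- matrix(0, nrow = length(seqs), ncol = length(all_k),
                   dimnames = list(names(seqs), all_k))
  for (i in seq_along(counts_list)) {
    counts[i, names(counts_list[[i]])] <- as.numeric(counts_list[[i]])
  }
  freq <- counts / pmax(rowSums(counts), 1)
  structure(list(counts = counts, freq = freq, k = k), class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("<kmer_profile> %d chromosomes x %d canonical %d-mers\n",
              nrow(x$counts), ncol(x$counts), x$k))
  invisible(x)
}

#' Subgenome-specific (differential) k-mers
#'
#' A k-mer is specific to a partition class when its mean frequency there is
#' at least `fold_min` times its mean frequency over all other classes
#' (a k-mer absent elsewhere but present in the class qualifies).
#'
#' @param profile a [kmer_profile()].
#' @param partition named character vector, chromosome -> class, covering all
#'   chromosomes of the profile.
#' @param fold_min enrichment fold (default 2).
#' @return named list, class -> character vector of specific k-mers.
#' @export
differential_kmers <- function(profile, partition, fold_min = 2.0) {
  chs <- rownames(profile$freq)
  if (!all(chs %in% names(partition))) stop("partition must cover all chromosomes", call. = FALSE)
  cls <- unique(unname(partition[chs]))
  if (any(vapply(cls, function(cl) sum(partition[chs] == cl), integer(1)) == 0L)) {
    stop("empty partition class", call. = FALSE)
  }
  out <- lapply(cls, function(cl) {
    inside <- chs[partition[chs] == cl]
    outside <- setdiff(chs, inside)
    m_in <- colMeans(profile$freq[inside, , drop = FALSE])
    m_out <- if (length(outside)) colMeans(profile$freq[outside, , drop = FALSE]) else 0
    spec <- m_in > 0 & m_in >= fold_min * m_out
    colnames(profile$freq)[spec]
  })
  names(out) <- cls
  out
}

#' Phase chromosomes into subgenomes by differential k-mers
#'
#' Iterative partition refinement: an initial hierarchical clustering of the
#' k-mer frequency profiles is refined by recomputing class-specific k-mers
#' and reassigning every chromosome to the class whose specific k-mers it is
#' most enriched in, until a fixed point (or `max_iter`). Labels are
#' canonicalized so that subgenome `A` is the class containing the
#' lexicographically smallest chromosome id. The consistency score is the
#' mean, over chromosomes, of the share of specific-k-mer signal supporting
#' the assigned class (1 = unambiguous, 1/n_subgenomes = unphaseable).
#'
#' @param profile a [kmer_profile()].
#' @param n_subgenomes number of subgenomes (default 2); needs at least
#'   `2 * n_subgenomes` chromosomes.
#' @param fold_min enrichment fold for the refinement step.
#' @param max_iter iteration cap; non-convergence is reported via
#'   `converged = FALSE` with the partial result returned.
#' @param seed RNG seed (clustering is deterministic; guards future use).
#' @return list with `assignment` (chromosome -> subgenome label),
#'   `consistency`, `converged`, `iterations`.
#' @export
phase_subgenomes <- function(profile, n_subgenomes = 2, fold_min = 2.0,
                             max_iter = 20, seed = NULL) {
  freq <- profile$freq[order(rownames(profile$freq)), , drop = FALSE]
  chs <- rownames(freq)
  if (length(chs) < 2 * n_subgenomes) {
    stop("need at least 2 chromosomes per subgenome", call. = FALSE)
  }
  with_seed(seed, {
    hc <- hclust(dist(freq), method = "ward.D2")
    part <- setNames(paste0("S", cutree(hc, k = n_subgenomes)), chs)
    converged <- FALSE
    it <- 0L
    score_mat <- NULL
    while (it < max_iter) {
      it <- it + 1L
      dk <- differential_kmers(profile, part, fold_min = fold_min)
      score_mat <- vapply(names(dk), function(cl) {
        if (!length(dk[[cl]])) return(rep(0, length(chs)))
        rowSums(freq[, dk[[cl]], drop = FALSE])
      }, numeric(length(chs)))
      rownames(score_mat) <- chs
      tot <- rowSums(score_mat)
      new_cls <- colnames(score_mat)[max.col(score_mat, ties.method = "first")]
      ## keep the old class where there is no signal at all
      new_cls[tot == 0] <- part[chs][tot == 0]
      new_part <- setNames(new_cls, chs)
      if (length(unique(new_part)) < n_subgenomes) break  # refinement collapsed
      if (identical(unname(new_part[chs]), unname(part[chs]))) {
        converged <- TRUE
        break
      }
      part <- new_part
    }
    ## consistency: share of specific-kmer signal behind each assignment
    tot <- rowSums(score_mat)
    own <- score_mat[cbind(seq_along(chs), match(part[chs], colnames(score_mat)))]
    consistency <- mean(ifelse(tot > 0, own / tot, 1 / n_subgenomes))
    ## canonical labels: A = class of the lexicographically smallest chrom
    lab_pool <- LETTERS
    canon <- setNames(rep(NA_character_, length(unique(part))), unique(part))
    li <- 0L
    for (ch in chs) {
      cl <- part[[ch]]
      if (is.na(canon[[cl]])) {
        li <- li + 1L
        canon[[cl]] <- lab_pool[li]
      }
    }
    assignment <- setNames(unname(canon[part[chs]]), chs)
    list(assignment = assignment, consistency = consistency,
         converged = converged, iterations = it)
  })
}

#' Transposable-element divergence landscape per subgenome
#'
#' Percent divergence (PercDiv) of each TE copy from its family consensus
#' (mismatches over aligned length x 100), binned per subgenome.
#'
#' @param te_copies data.frame with columns `chrom`, `family`, `seq`.
#' @param consensus named list/character: family -> consensus sequence. For
#'   real data a majority-rule consensus per family can be computed with
#'   [te_family_consensus()].
#' @param subgenome named character vector, chromosome -> subgenome label.
#' @param bin bin width in percent (default 1); bins cover [0, 50].
#' @return object of class `te_landscape`: `counts` matrix (subgenome x bin),
#'   `breaks`, `percdiv` (per-copy values), `bin`.
#' @export
te_divergence_landscape <- function(te_copies, consensus, subgenome, bin = 1) {
  if (is.null(te_copies) || !nrow(te_copies)) stop("empty TE set", call. = FALSE)
  pd <- vapply(seq_len(nrow(te_copies)), function(i) {
    cons <- consensus[[te_copies$family[i]]]
    if (is.null(cons)) stop("no consensus for family ", te_copies$family[i], call. = FALSE)
    percdiv(te_copies$seq[i], cons)
  }, numeric(1))
  sg <- unname(subgenome[te_copies$chrom])
  breaks <- seq(0, 50, by = bin)
  labs <- head(breaks, -1)
  groups <- sort(unique(sg[!is.na(sg)]))
  counts <- t(vapply(groups, function(g) {
    v <- pd[!is.na(sg) & sg == g]
    v <- pmin(v, 50 - 1e-9)
    as.numeric(table(cut(v, breaks = breaks, right = FALSE, labels = labs)))
  }, numeric(length(labs))))
  dimnames(counts) <- list(groups, labs)
  structure(list(counts = counts, breaks = breaks, bin = bin,
                 percdiv = data.frame(chrom = te_copies$chrom, family = te_copies$family,
                                      subgenome = sg, percdiv = pd)),
            class = "te_landscape")
}

#' Percent divergence of a TE copy against its consensus
#' @param seq,consensus equal-length sequences (ungapped comparison).
#' @return percent mismatches.
#' @export
percdiv <- function(seq, consensus) {
  if (nchar(seq) != nchar(consensus)) {
    stop("copy and consensus lengths differ (indels are not modelled)", call. = FALSE)
  }
  a <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  100 * sum(a != b) / length(a)
}

#' Majority-rule consensus per TE family
#' @param te_copies data.frame with `family`, `seq` (equal lengths per family).
#' @return named character vector, family -> consensus.
#' @export
te_family_consensus <- function(te_copies) {
  vapply(split(te_copies$seq, te_copies$family), function(seqs) {
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    paste(apply(m, 2, function(col) names(which.max(table(col)))), collapse = "")
  }, character(1))
}

#' Non-overlap ("bubble") interval between two TE landscapes
#'
#' Finds the divergence interval separating the bulk of the younger
#' subgenome's TE copies from the bulk of the older one's: divergence values
#' `d` with at least `threshold` of the younger landscape's mass below `d`
#' and at least `threshold` of the older landscape's mass above `d`. This is
#' the period between the divergence of the diploid progenitors and their
#' merging. Identical landscapes give an empty interval (for any
#' `threshold > 0.5`); `threshold = 0` degenerates to the full binned range.
#'
#' @param landscape a `te_landscape` with both subgenomes, or `NULL` if
#'   passing `a` and `b`.
#' @param a,b alternatively, two single-subgenome `te_landscape`s on the same
#'   binning.
#' @param threshold dominance fraction (default 0.75).
#' @return numeric `c(from, to)` in percent divergence, or `numeric(0)` when
#'   no such interval exists.
#' @export
nonoverlap_interval <- function(landscape = NULL, a = NULL, b = NULL, threshold = 0.75) {
  if (!is.null(landscape)) {
    if (nrow(landscape$counts) != 2) stop("need exactly two subgenomes", call. = FALSE)
    ca <- landscape$counts[1, ]; cb <- landscape$counts[2, ]
    breaks <- landscape$breaks
  } else {
    if (!identical(a$breaks, b$breaks)) stop("binning mismatch", call. = FALSE)
    ca <- colSums(a$counts); cb <- colSums(b$counts)
    breaks <- a$breaks
  }
  if (sum(ca) == 0 || sum(cb) == 0) return(numeric(0))
  fa <- cumsum(ca) / sum(ca)
  fb <- cumsum(cb) / sum(cb)
  ## younger landscape = smaller mean divergence
  mids <- head(breaks, -1) + diff(breaks) / 2
  if (sum(mids * cb) / sum(cb) < sum(mids * ca) / sum(ca)) {
    tmp <- fa; fa <- fb; fb <- tmp
  }
  upper_edges <- breaks[-1]
  lo_ok <- c(0, head(fa, -1)) >= threshold  # younger mass below the bin's lower edge
  hi_ok <- fb <= 1 - threshold              # older mass above the bin's upper edge
  ok <- lo_ok & hi_ok
  if (!any(ok)) return(numeric(0))
  c(from = breaks[which(ok)[1]], to = upper_edges[tail(which(ok), 1)])
}
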