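#' Compare two plastome-scale sequences
#'
#' Anchor-seeded global comparison designed for near-identical organelle
#' genomes: k-mers unique to both sequences are matched and chained
#' (longest collinear subset), and the short stretches between consecutive
#' anchors are aligned globally (Needleman-Wunsch via
#' \code{Biostrings::pairwiseAlignment}). Mismatch columns count as SNPs;
#' each maximal run of gap columns counts as one indel event, with its
#' length recorded.
#'
#' @param seqA,seqB sequences (single characters strings), non-empty.
#' @param k anchor k-mer length (default 21).
#' @param max_segment longest allowed inter-anchor stretch; longer stretches
#'   mean anchoring failed (sequences too divergent) and raise an error
#'   rather than returning a silent partial result.
#' @return object of class `plastome_diff`: `snp_count`, `indel_count`,
#'   `indel_lengths`, `aligned_length`, `n_anchors`.
#' @examples
#' p <- make_plastome_pair(5000, 3, 2, seed = 7)
#' compare_plastomes(p$a, p$b)
#' @export
compare_plastomes <- function(seqA, seqB, k = 21, max_segment = 20000) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence", call. = FALSE)
  seqA <- toupper(seqA); seqB <- toupper(seqB)
  if (identical(seqA, seqB)) {
    return(structure(list(snp_count = 0L, indel_count = 0L, indel_lengths = integer(0),
                          aligned_length = nchar(seqA), n_anchors = NA_integer_),
                     class = "plastome_diff"))
  }
  unique_kmers <- function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1) stop("sequence shorter than anchor k-mer", call. = FALSE)
    mers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    keep <- !(duplicated(mers) | duplicated(mers, fromLast = TRUE))
    setNames(seq_len(n)[keep], mers[keep])
  }
  ua <- unique_kmers(seqA)
  ub <- unique_kmers(seqB)
  shared <- intersect(names(ua), names(ub))
  if (!length(shared) && (nchar(seqA) > 2 * max_segment)) {
    stop("sequences failed to anchor (no shared unique k-mers)", call. = FALSE)
  }
  anchors <- data.frame(a = unname(ua[shared]), b = unname(ub[shared]))
  anchors <- anchors[order(anchors$a), , drop = FALSE]
  ## longest chain increasing in b (a already increasing): classic LIS
  if (nrow(anchors)) {
    idx <- lis_indices(anchors$b)
    anchors <- anchors[idx, , drop = FALSE]
    ## greedy thinning: keep anchors non-overlapping (>= k apart on both
    ## sequences) at a stride that bounds the number of aligned segments
    stride <- max(k, 200L)
    keep <- logical(nrow(anchors))
    last_a <- -stride; last_b <- -stride
    for (i in seq_len(nrow(anchors))) {
      if (anchors$a[i] >= last_a + stride && anchors$b[i] >= last_b + stride) {
        keep[i] <- TRUE
        last_a <- anchors$a[i]; last_b <- anchors$b[i]
      }
    }
    anchors <- anchors[keep, , drop = FALSE]
  }
  snp <- 0L
  indel_lengths <- integer(0)
  aligned <- 0L
  ## walk segments between consecutive anchors (plus the two flanks)
  seg_from_a <- c(1L, anchors$a + k)
  seg_to_a   <- c(anchors$a - 1L, nchar(seqA))
  seg_from_b <- c(1L, anchors$b + k)
  seg_to_b   <- c(anchors$b - 1L, nchar(seqB))
  for (i in seq_along(seg_from_a)) {
    la <- seg_to_a[i] - seg_from_a[i] + 1L
    lb <- seg_to_b[i] - seg_from_b[i] + 1L
    if (la <= 0L && lb <= 0L) next
    if (max(la, lb) > max_segment) {
      stop("sequences failed to anchor (inter-anchor stretch of ",
           max(la, lb), " bp)", call. = FALSE)
    }
    sa <- if (la > 0) substr(seqA, seg_from_a[i], seg_to_a[i]) else ""
    sb <- if (lb > 0) substr(seqB, seg_from_b[i], seg_to_b[i]) else ""
    if (la <= 0L || lb <= 0L) {
      indel_lengths <- c(indel_lengths, max(la, lb, 0L))
      next
    }
    if (identical(sa, sb)) {
      aligned <- aligned + la
      next
    }
    al <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                        gapOpening = 4, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    gap <- pa == "-" | pb == "-"
    snp <- snp + sum(!gap & pa != pb)
    aligned <- aligned + sum(!gap)
    runs <- rle(gap)
    indel_lengths <- c(indel_lengths, runs$lengths[runs$values])
  }
  aligned <- aligned + nrow(anchors) * k
  structure(list(snp_count = as.integer(snp),
                 indel_count = length(indel_lengths),
                 indel_lengths = as.integer(indel_lengths),
                 aligned_length = as.integer(aligned),
                 n_anchors = nrow(anchors)),
            class = "plastome_diff")
}

#' @export
print.plastome_diff <- function(x, ...) {
  cat(sprintf("<plastome_diff> %d SNP(s), %d indel event(s)%s\n",
              x$snp_count, x$indel_count,
              if (x$indel_count) paste0(" (lengths ",
                                        paste(x$indel_lengths, collapse = ","), ")") else ""))
  invisible(x)
}

## indices of one longest strictly increasing subsequence (patience sorting)
lis_indices <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  tails <- integer(0)   # indices of smallest tail per length
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {  # first tail with value >= x[i]
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(length(tails))
  pos <- length(tails)
  i <- tails[pos]
  while (i > 0L) {
    out[pos] <- i
    i <- prev[i]
    pos <- pos - 1L
  }
  out
}
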