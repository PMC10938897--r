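#' Assign polyploid chromosomes to ancestral groups
#'
#' Within each subgenome of an allotetraploid, chromosomes are split into the
#' two groups created by the within-lineage WGD (A1/A2, B1/B2) by maximizing
#' the between-group synteny: WGD-derived blocks connect a chromosome to its
#' duplicate in the other group, so the best bipartition is the one with the
#' largest anchor weight across the cut. All bipartitions are enumerated
#' (chromosome counts per subgenome are small), making the result
#' deterministic; an ambiguity flag is raised when the best and second-best
#' cuts are equal or no within-subgenome synteny exists.
#'
#' @param genome a `genome` with subgenome labels (`genome$subgenome`), or
#'   pass `subgenome` explicitly.
#' @param blocks within-genome `synteny_blocks` (from a self-comparison).
#' @param subgenome optional named chromosome -> subgenome vector overriding
#'   the genome's.
#' @return object of class `ancestral_groups`: named vector `groups`
#'   (chromosome -> `A1`/`A2`/`B1`/`B2`), `ambiguous` flag, per-subgenome cut
#'   scores.
#' @export
assign_ancestral_groups <- function(genome, blocks, subgenome = NULL) {
  sg <- subgenome %||% genome$subgenome
  if (is.null(sg)) stop("subgenome labels required (phase first or pass ledger truth)",
                        call. = FALSE)
  ## anchor weight between chromosome pairs
  w <- list()
  for (b in blocks) {
    key <- paste(sort(c(b$chromA, b$chromB)), collapse = "\r")
    w[[key]] <- (w[[key]] %||% 0) + nrow(b$anchors)
  }
  pair_weight <- function(c1, c2) w[[paste(sort(c(c1, c2)), collapse = "\r")]] %||% 0
  groups <- character(0)
  ambiguous <- FALSE
  scores <- list()
  for (s in sort(unique(unname(sg)))) {
    chs <- sort(intersect(chromosomes(genome), names(sg)[sg == s]))
    n <- length(chs)
    if (n < 2) {
      groups[chs] <- paste0(s, "1")
      next
    }
    ## enumerate bipartitions (first chromosome fixed in side 1); ambiguous
    ## when several structurally distinct partitions achieve the best cut
    best <- NULL; second <- -Inf; n_optimal <- 0L
    for (mask in 0:(2^(n - 1) - 1)) {
      side <- c(TRUE, as.logical(bitwAnd(2^(0:(n - 2)), mask)))
      if (all(side) || !any(side)) next
      cut <- 0
      for (i in which(side)) for (j in which(!side)) {
        cut <- cut + pair_weight(chs[i], chs[j])
      }
      if (is.null(best) || cut > best$cut) {
        second <- if (is.null(best)) -Inf else best$cut
        best <- list(cut = cut, side = side)
        n_optimal <- 1L
      } else if (cut == best$cut) {
        n_optimal <- n_optimal + 1L
        second <- cut
      } else if (cut > second) {
        second <- cut
      }
    }
    if (is.null(best) || best$cut == 0 || n_optimal > 1L) ambiguous <- TRUE
    g1 <- chs[best$side]; g2 <- chs[!best$side]
    ## group 1 = side containing the lexicographically smallest chromosome
    if (min(g2) < min(g1)) { tmp <- g1; g1 <- g2; g2 <- tmp }
    groups[g1] <- paste0(s, "1")
    groups[g2] <- paste0(s, "2")
    scores[[s]] <- c(best = best$cut, second = second)
  }
  structure(list(groups = groups, ambiguous = ambiguous, scores = scores),
            class = "ancestral_groups")
}

#' @export
print.ancestral_groups <- function(x, ...) {
  cat("<ancestral_groups>", if (x$ambiguous) "(ambiguous!)" else "", "\n")
  print(table(x$groups))
  invisible(x)
}

#' Homoeolog quartet retention records
#'
#' Enumerates ancestral loci as connected components of the anchor graph over
#' all genes (block anchors as edges; genes without anchors are orphan loci)
#' and flags, per locus, in which ancestral groups a syntenic copy survives.
#' Presence is per group, not copy number.
#'
#' @param genome the polyploid `genome`.
#' @param blocks within-genome `synteny_blocks`.
#' @param groups an `ancestral_groups` object (or named chromosome -> group
#'   vector); must cover every chromosome appearing in the blocks.
#' @return data.frame, one row per locus: `locus`, `family`, logical `A1`,
#'   `A2`, `B1`, `B2` (or the group labels in use), `n_groups`.
#' @export
quartet_retention <- function(genome, blocks, groups) {
  grp <- if (inherits(groups, "ancestral_groups")) groups$groups else groups
  tab <- dotplot_table(blocks)
  bad <- setdiff(unique(c(tab$chromA, tab$chromB)), names(grp))
  if (length(bad)) stop("groups do not cover chromosomes: ",
                        paste(head(bad, 3), collapse = ", "), call. = FALSE)
  genes <- genome$genes
  ## union-find over gene ids
  parent <- seq_len(nrow(genes))
  names(parent) <- genes$id
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(tab)) {
    ia <- match(tab$geneA, genes$id)
    ib <- match(tab$geneB, genes$id)
    for (e in seq_along(ia)) {
      ra <- find(ia[e]); rb <- find(ib[e])
      if (ra != rb) parent[ra] <- rb
    }
  }
  comp <- vapply(seq_len(nrow(genes)), find, numeric(1))
  glabels <- sort(unique(unname(grp)))
  gene_grp <- unname(grp[genes$chrom])
  recs <- lapply(split(seq_len(nrow(genes)), comp), function(idx) {
    fam <- names(which.max(table(genes$family[idx])))
    present <- glabels %in% gene_grp[idx]
    c(list(locus = genes$id[idx[1]], family = fam),
      setNames(as.list(present), glabels),
      list(n_groups = sum(present)))
  })
  out <- do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Retention ratio for a pattern class
#'
#' @param records data.frame from [quartet_retention()].
#' @param family a family label, or `"ALL"` for the genome-wide background.
#' @param pattern `"quartet"` (all four groups retained), `"pairA"` (A1 and
#'   A2), `"pairB"` (B1 and B2), or `"homoeolog"` (at least one copy in each
#'   subgenome).
#' @return list with `retained`, `total`, `ratio`.
#' @export
retention_ratio <- function(records, family = "ALL",
                            pattern = c("quartet", "pairA", "pairB", "homoeolog")) {
  pattern <- match.arg(pattern)
  if (!identical(family, "ALL")) {
    if (!family %in% records$family) stop("unknown family: ", family, call. = FALSE)
    records <- records[records$family == family, , drop = FALSE]
  }
  hit <- switch(pattern,
    quartet = records$A1 & records$A2 & records$B1 & records$B2,
    pairA = records$A1 & records$A2,
    pairB = records$B1 & records$B2,
    homoeolog = (records$A1 | records$A2) & (records$B1 | records$B2))
  list(retained = sum(hit), total = nrow(records),
       ratio = if (nrow(records)) sum(hit) / nrow(records) else NA_real_)
}

#' Fisher's exact depletion/enrichment test for a family's retention
#'
#' Two-sided exact hypergeometric test (minimum-likelihood two-siding, the
#' `stats::fisher.test` convention) of a family's retained/lost counts
#' against the genome-wide background.
#'
#' @param family_retained,family_total family counts.
#' @param background_retained,background_total background counts.
#' @return p-value.
#' @export
depletion_test <- function(family_retained, family_total,
                           background_retained, background_total) {
  if (family_retained > family_total || background_retained > background_total) {
    stop("retained exceeds total", call. = FALSE)
  }
  m <- matrix(c(family_retained, family_total - family_retained,
                background_retained, background_total - background_retained),
              nrow = 2)
  fisher.test(m)$p.value
}

#' Gene-family size comparison between two genomes
#'
#' Per-family sizes, fold changes (query over reference), the binned
#' fold-change distribution with its mode, and a per-family 2x2 Fisher test
#' of the family's share of genes in the two genomes.
#'
#' @param sizesA named integer vector: family sizes in the query genome.
#' @param sizesB named integer vector: family sizes in the reference genome.
#' @return object of class `family_size_matrix`: data.frame `records`
#'   (`family`, `sizeA`, `sizeB`, `fold`, `p`), `modal_fold`, `skipped`
#'   (families absent from both).
#' @export
family_size_matrix <- function(sizesA, sizesB) {
  fams <- sort(union(names(sizesA), names(sizesB)))
  a <- setNames(rep(0L, length(fams)), fams); a[names(sizesA)] <- sizesA
  b <- setNames(rep(0L, length(fams)), fams); b[names(sizesB)] <- sizesB
  skipped <- fams[a == 0 & b == 0]
  keep <- !(a == 0 & b == 0)
  fams <- fams[keep]; a <- a[keep]; b <- b[keep]
  totA <- sum(a); totB <- sum(b)
  fold <- ifelse(b > 0, a / b, NA_real_)
  p <- vapply(seq_along(fams), function(i) {
    fisher.test(matrix(c(a[i], totA - a[i], b[i], totB - b[i]), nrow = 2))$p.value
  }, numeric(1))
  records <- data.frame(family = fams, sizeA = unname(a), sizeB = unname(b),
                        fold = unname(fold), p = p, stringsAsFactors = FALSE)
  folds <- round(fold[!is.na(fold)], 2)
  modal_fold <- if (length(folds)) as.numeric(names(which.max(table(folds)))) else NA_real_
  structure(list(records = records, modal_fold = modal_fold, skipped = skipped),
            class = "family_size_matrix")
}

#' @export
print.family_size_matrix <- function(x, ...) {
  cat(sprintf("<family_size_matrix> %d families, modal fold change %.2f\n",
              nrow(x$records), x$modal_fold))
  invisible(x)
}
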