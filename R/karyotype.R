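#' Karyotype bookkeeping: chromosome count after WGD, fissions and fusions
#'
#' `C = k * n + fissions - fusions`, the additive conservation every declared
#' history must satisfy. A non-positive result signals an inconsistent
#' history and is an error.
#'
#' @param n starting (proto-)chromosome number.
#' @param k WGD multiplier product along the trajectory (1 = none).
#' @param fissions,fusions event counts (>= 0).
#' @return resulting chromosome count (integer).
#' @examples
#' event_bookkeeping(8, 2, 1, 13)  # 4, the intermediate karyotype
#' @export
event_bookkeeping <- function(n, k, fissions, fusions) {
  stopifnot(n >= 1, k >= 1, fissions >= 0, fusions >= 0)
  C <- k * n + fissions - fusions
  if (C <= 0) {
    stop(sprintf("inconsistent history: %d*%d + %d - %d = %d chromosomes",
                 k, n, fissions, fusions, C), call. = FALSE)
  }
  as.integer(C)
}

#' Infer fission and fusion counts from a chromosome painting
#'
#' Given a painting with `S` total proto-chromosome segments over `C` extant
#' chromosomes, and a declared origin of `n` proto-chromosomes with WGD
#' multiplier `k`: `fissions = S - k * n` and `fusions = S - C`. Negative
#' values signal a history inconsistent with the painting. When a fission's
#' fragments later re-fuse the counts are minimal, not exact.
#'
#' @param painting a `proto_painting` (or a list with `S` and `C`).
#' @param n declared proto-chromosome number.
#' @param k declared WGD multiplier product.
#' @return list with `fissions`, `fusions`, `S`, `C`.
#' @export
infer_events <- function(painting, n, k) {
  S <- painting$S
  C <- painting$C
  fissions <- S - k * n
  fusions <- S - C
  if (fissions < 0) {
    stop(sprintf("painting has %d segments, fewer than k*n = %d: inconsistent history",
                 S, k * n), call. = FALSE)
  }
  if (fusions < 0) stop("segment count below chromosome count", call. = FALSE)
  list(fissions = as.integer(fissions), fusions = as.integer(fusions),
       S = as.integer(S), C = as.integer(C))
}

#' Paint extant chromosomes by proto-chromosome
#'
#' Cross-genome synteny blocks among >= 3 genomes are used to (i) split every
#' chromosome into atomic intervals at block boundaries, (ii) cluster the
#' intervals into proto-chromosomes as connected components of the
#' block-linkage graph ([infer_proto_chromosomes()]), and (iii) merge
#' neighbouring intervals with the same proto label, yielding segments that
#' tile each chromosome. Intervals untouched by any qualifying block are
#' absorbed into the preceding labelled segment (or the following one at a
#' chromosome start), so the segment count reflects proto ancestry, not
#' coverage gaps.
#'
#' @param block_sets named list of `synteny_blocks`, one per genome pair, with
#'   names `"G1|G2"` naming the two genomes (blocks' A side = first name).
#' @param genomes named list of the `genome` objects involved.
#' @param min_segment minimum anchors for a block to contribute (default 5).
#' @return named list of `proto_painting` objects (one per genome), each with
#'   `segments` (chrom, start, end, proto, orientation), `S`, `C`, and
#'   `proto_levels`.
#' @export
paint_chromosomes <- function(block_sets, genomes, min_segment = 5) {
  if (length(genomes) < 3) stop("need >= 3 genomes for proto inference", call. = FALSE)
  gn <- names(genomes)
  ## collect qualifying block intervals per genome side
  entries <- list()  # per block: two (genome, chrom, lo, hi) sides + id
  bid <- 0L
  for (key in names(block_sets)) {
    pair <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (!all(pair %in% gn)) stop("block set ", key, " names unknown genomes", call. = FALSE)
    for (b in block_sets[[key]]) {
      if (nrow(b$anchors) < min_segment) next
      bid <- bid + 1L
      entries[[length(entries) + 1L]] <- data.frame(
        block = bid, genome = pair, chrom = c(b$chromA, b$chromB),
        lo = c(min(b$anchors$rankA), min(b$anchors$rankB)),
        hi = c(max(b$anchors$rankA), max(b$anchors$rankB)),
        orientation = b$orientation, stringsAsFactors = FALSE)
    }
  }
  if (!length(entries)) stop("no qualifying blocks", call. = FALSE)
  ent <- do.call(rbind, entries)
  ## atomic intervals per chromosome from block boundary ranks
  atoms <- list()
  for (g in gn) {
    for (ch in chromosomes(genomes[[g]])) {
      ng <- sum(genomes[[g]]$genes$chrom == ch)
      e <- ent[ent$genome == g & ent$chrom == ch, , drop = FALSE]
      cuts <- sort(unique(c(0L, e$lo, e$hi + 1L, ng)))
      cuts <- cuts[cuts >= 0 & cuts <= ng]
      for (i in seq_len(length(cuts) - 1L)) {
        atoms[[length(atoms) + 1L]] <- data.frame(
          genome = g, chrom = ch, start = cuts[i], end = cuts[i + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, atoms)
  atoms$atom <- seq_len(nrow(atoms))
  ## link atoms through blocks: two atoms are linked when a block's two side
  ## intervals overlap both
  parent <- seq_len(nrow(atoms))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  atoms_of <- function(g, ch, lo, hi) {
    atoms$atom[atoms$genome == g & atoms$chrom == ch &
               atoms$start <= hi & atoms$end > lo]
  }
  for (b in unique(ent$block)) {
    e <- ent[ent$block == b, , drop = FALSE]
    a1 <- atoms_of(e$genome[1], e$chrom[1], e$lo[1], e$hi[1])
    a2 <- atoms_of(e$genome[2], e$chrom[2], e$lo[2], e$hi[2])
    both <- c(a1, a2)
    for (x in both[-1]) unite(both[1], x)
  }
  comp <- vapply(atoms$atom, find, numeric(1))
  ## proto labels: components ordered by their first (genome, chrom, start)
  ord <- order(atoms$genome, atoms$chrom, atoms$start)
  first_seen <- comp[ord][!duplicated(comp[ord])]
  ## only components supported by at least one block get a proto label
  linked <- unique(comp[duplicated(comp) | duplicated(comp, fromLast = TRUE)])
  labels <- setNames(rep(NA_character_, length(first_seen)), first_seen)
  li <- 0L
  for (cp in first_seen) {
    if (cp %in% linked) {
      li <- li + 1L
      labels[as.character(cp)] <- sprintf("P%02d", li)
    }
  }
  atoms$proto <- unname(labels[as.character(comp)])
  ## per genome: absorb unlabelled atoms, merge same-proto neighbours
  paintings <- lapply(gn, function(g) {
    segs <- list()
    for (ch in chromosomes(genomes[[g]])) {
      a <- atoms[atoms$genome == g & atoms$chrom == ch, , drop = FALSE]
      a <- a[order(a$start), , drop = FALSE]
      ## absorb NA atoms into the previous labelled atom (or next at start)
      lab <- a$proto
      for (i in seq_along(lab)) {
        if (is.na(lab[i])) lab[i] <- if (i > 1) lab[i - 1] else NA
      }
      for (i in rev(seq_along(lab))) {
        if (is.na(lab[i])) lab[i] <- if (i < length(lab)) lab[i + 1] else NA
      }
      a$proto <- lab
      ## merge runs of equal label
      run <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)] |
                        (is.na(lab[-1]) != is.na(lab[-length(lab)]))))
      for (r in unique(run)) {
        at <- a[run == r, , drop = FALSE]
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = ch, start = min(at$start), end = max(at$end),
          proto = at$proto[1], orientation = "same", stringsAsFactors = FALSE)
      }
    }
    segments <- do.call(rbind, segs)
    structure(list(genome = g, segments = segments,
                   S = nrow(segments), C = length(chromosomes(genomes[[g]])),
                   proto_levels = sort(unique(segments$proto))),
              class = "proto_painting")
  })
  names(paintings) <- gn
  paintings
}

#' @export
print.proto_painting <- function(x, ...) {
  cat(sprintf("<proto_painting> %s: %d segments on %d chromosomes, %d proto labels\n",
              x$genome, x$S, x$C, length(x$proto_levels)))
  invisible(x)
}

#' Infer the proto-chromosome set from paintings
#'
#' The proto-chromosomes are the distinct labels shared across the painted
#' genomes (connected components of the cross-genome block-linkage graph).
#' Reports the count and, per proto, its composition across genomes.
#'
#' @param paintings list of `proto_painting` objects from
#'   [paint_chromosomes()].
#' @return list with `n_proto`, `protos` (labels), `composition` (data.frame
#'   proto x genome segment counts).
#' @export
infer_proto_chromosomes <- function(paintings) {
  labs <- sort(unique(unlist(lapply(paintings, function(p) p$segments$proto))))
  labs <- labs[!is.na(labs)]
  comp <- do.call(rbind, lapply(paintings, function(p) {
    t <- table(factor(p$segments$proto, levels = labs))
    as.data.frame.matrix(t(as.matrix(t)))
  }))
  rownames(comp) <- vapply(paintings, function(p) p$genome, character(1))
  list(n_proto = length(labs), protos = labs, composition = comp)
}

#' Validate a table of karyotype trajectories
#'
#' Each row declares a lineage transition (`n`, `k`, `fissions`, `fusions`,
#' expected `C`); rows are checked against [event_bookkeeping()]. Rows that
#' fail (non-positive or mismatching counts) are reported by identity.
#'
#' @param rows data.frame with columns `lineage`, `n`, `k`, `fissions`,
#'   `fusions`, `C`.
#' @return list with `table` (validated rows, `C_computed` added) and
#'   `rejected` (failing rows with a `reason` column).
#' @export
trajectory_table <- function(rows) {
  if (!nrow(rows)) {
    return(list(table = cbind(rows, C_computed = integer(0)),
                rejected = cbind(rows, reason = character(0))))
  }
  res <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, , drop = FALSE]
    C <- tryCatch(event_bookkeeping(r$n, r$k, r$fissions, r$fusions),
                  error = function(e) conditionMessage(e))
    if (is.character(C)) return(list(ok = FALSE, row = r, reason = C))
    if (!is.null(r$C) && !is.na(r$C) && C != r$C) {
      return(list(ok = FALSE, row = r,
                  reason = sprintf("declared C = %d but bookkeeping gives %d", r$C, C)))
    }
    r$C_computed <- C
    list(ok = TRUE, row = r)
  })
  ok <- vapply(res, function(x) x$ok, logical(1))
  tab <- if (any(ok)) do.call(rbind, lapply(res[ok], function(x) x$row)) else NULL
  rej <- if (any(!ok)) {
    do.call(rbind, lapply(res[!ok], function(x) cbind(x$row, reason = x$reason)))
  } else NULL
  list(table = tab, rejected = rej)
}
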