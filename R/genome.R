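#' Gene-ordered genome container
#'
#' A `genome` holds ordered, stranded genes on named chromosomes, optional
#' chromosome nucleotide sequences, optional subgenome labels, and an optional
#' table of transposable-element (TE) copies. It is the universal substrate for
#' synteny detection, Ks estimation, subgenome phasing and karyotype analysis.
#'
#' @param genes data.frame with columns `id` (unique gene id), `chrom`
#'   (chromosome id), `rank` (0-based order along the chromosome), `strand`
#'   (`"+"` or `"-"`), `family` (gene-family label or `NA`), and optionally
#'   `cds` (in-frame coding sequence, length divisible by 3, or `NA`).
#' @param chrom_seq optional named character vector of chromosome nucleotide
#'   sequences (names are chromosome ids).
#' @param subgenome optional named character vector mapping chromosome ids to
#'   subgenome labels (e.g. `"A"`/`"B"`); `NA` for unassigned.
#' @param te_copies optional data.frame of TE copies with columns `chrom`,
#'   `start`, `end` (0-based half-open on `chrom_seq`), `family`, `seq`.
#' @param ploidy_note free-text note on ploidy (e.g. `"2n = 4x = 32"`).
#' @return An object of class `genome`.
#' @examples
#' g <- simulate_ancestor(2, 10, 4, 20, seed = 1)
#' g
#' n_genes(g)
#' @export
new_genome <- function(genes, chrom_seq = NULL, subgenome = NULL,
                       te_copies = NULL, ploidy_note = "") {
  need <- c("id", "chrom", "rank", "strand", "family")
  if (!all(need %in% names(genes))) {
    stop("`genes` must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"cds" %in% names(genes)) genes$cds <- rep(NA_character_, nrow(genes))
  genes$id <- as.character(genes$id)
  genes$chrom <- as.character(genes$chrom)
  genes$rank <- as.integer(genes$rank)
  genes <- genes[order(match(genes$chrom, unique(genes$chrom)), genes$rank), , drop = FALSE]
  rownames(genes) <- NULL
  g <- structure(list(
    genes = genes,
    chrom_seq = chrom_seq,
    subgenome = subgenome,
    te_copies = te_copies,
    ploidy_note = ploidy_note
  ), class = "genome")
  validate_genome(g)
  g
}

#' Validate genome invariants
#'
#' Checks that gene ids are unique genome-wide and that ranks within every
#' chromosome are consecutive from 0.
#' @param g a `genome`
#' @return `g`, invisibly; errors on violation.
#' @export
validate_genome <- function(g) {
  genes <- g$genes
  if (anyDuplicated(genes$id)) stop("gene ids not unique genome-wide", call. = FALSE)
  for (ch in unique(genes$chrom)) {
    r <- sort(genes$rank[genes$chrom == ch])
    if (!identical(r, seq_along(r) - 1L)) {
      stop("ranks on chromosome ", ch, " are not consecutive from 0", call. = FALSE)
    }
  }
  if (!is.null(g$chrom_seq) && is.null(names(g$chrom_seq))) {
    stop("chrom_seq must be named by chromosome id", call. = FALSE)
  }
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  ch <- chromosomes(x)
  cat(sprintf("<genome> %d genes on %d chromosomes", nrow(x$genes), length(ch)))
  if (!is.null(x$subgenome)) {
    sg <- table(x$subgenome[ch], useNA = "no")
    if (length(sg)) cat(sprintf(" [subgenomes: %s]",
                                paste(names(sg), sg, sep = "=", collapse = " ")))
  }
  if (nzchar(x$ploidy_note)) cat(" |", x$ploidy_note)
  cat("\n")
  invisible(x)
}

#' Chromosome ids of a genome
#' @param g a `genome`
#' @return character vector of chromosome ids in storage order.
#' @export
chromosomes <- function(g) unique(g$genes$chrom)

#' Number of genes in a genome
#' @param g a `genome`
#' @return integer count.
#' @export
n_genes <- function(g) nrow(g$genes)

## fast gene id -> (chrom, rank) lookup table
gene_index <- function(g) {
  idx <- g$genes[, c("id", "chrom", "rank")]
  rownames(idx) <- idx$id
  idx
}

## renumber ranks 0..n-1 per chromosome preserving current order
renumber_ranks <- function(genes) {
  genes <- genes[order(match(genes$chrom, unique(genes$chrom)), genes$rank), , drop = FALSE]
  genes$rank <- unlist(lapply(split(seq_len(nrow(genes)), genes$chrom)[unique(genes$chrom)],
                              function(i) seq_along(i) - 1L), use.names = FALSE)
  rownames(genes) <- NULL
  genes
}
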