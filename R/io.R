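#' Write genome artifacts to plain-text files
#'
#' Exports the standard file set for a simulated or analysed genome: CDS and
#' chromosome FASTA, gene BED (0-based half-open spans synthesized from gene
#' ranks at a fixed per-gene pitch), GFF3 (1-based, gene features only),
#' gene-family TSV, and TE-copy BED + family TSV when present.
#'
#' @param g a `genome`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param gene_pitch bp per gene rank used to synthesize BED/GFF coordinates.
#' @return invisibly, the named vector of files written.
#' @export
write_genome <- function(g, dir, prefix = "genome", gene_pitch = 1000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  genes <- g$genes
  ## CDS FASTA
  has_cds <- !is.na(genes$cds)
  if (any(has_cds)) {
    f <- file.path(dir, paste0(prefix, ".cds.fasta"))
    writeLines(paste0(">", genes$id[has_cds], "\n", genes$cds[has_cds]), f)
    files["cds_fasta"] <- f
  }
  if (!is.null(g$chrom_seq)) {
    f <- file.path(dir, paste0(prefix, ".chrom.fasta"))
    writeLines(paste0(">", names(g$chrom_seq), "\n", unname(g$chrom_seq)), f)
    files["chrom_fasta"] <- f
  }
  start <- genes$rank * gene_pitch
  end <- start + nchar(ifelse(is.na(genes$cds), 300L, nchar(genes$cds)))
  bed <- data.frame(genes$chrom, start, end, genes$id, 0L, genes$strand)
  f <- file.path(dir, paste0(prefix, ".genes.bed"))
  write.table(bed, f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  files["bed"] <- f
  gff <- data.frame(genes$chrom, "polyevolve", "gene", start + 1L, end, ".",
                    genes$strand, ".",
                    paste0("ID=", genes$id, ";family=", genes$family))
  f <- file.path(dir, paste0(prefix, ".genes.gff3"))
  writeLines(c("##gff-version 3",
               apply(gff, 1, paste, collapse = "\t")), f)
  files["gff3"] <- f
  f <- file.path(dir, paste0(prefix, ".families.tsv"))
  write.table(data.frame(gene_id = genes$id, family = genes$family), f,
              sep = "\t", quote = FALSE, row.names = FALSE)
  files["families"] <- f
  if (!is.null(g$te_copies) && nrow(g$te_copies)) {
    f <- file.path(dir, paste0(prefix, ".te.bed"))
    write.table(g$te_copies[, c("chrom", "start", "end", "family")], f,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    files["te_bed"] <- f
  }
  if (!is.null(g$subgenome)) {
    f <- file.path(dir, paste0(prefix, ".subgenomes.tsv"))
    write.table(data.frame(chrom = names(g$subgenome), subgenome = unname(g$subgenome)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["subgenomes"] <- f
  }
  invisible(files)
}

#' Write a truth ledger to TSV files
#' @param ledger a `truth_ledger`.
#' @param dir output directory.
#' @param prefix file prefix.
#' @return invisibly, files written.
#' @export
write_ledger <- function(ledger, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, paste0(prefix, ".lineage.tsv"))
  write.table(data.frame(gene_id = names(ledger$locus), locus = unname(ledger$locus),
                         lineage = unname(ledger$lineage[names(ledger$locus)]),
                         group = if (!is.null(ledger$groups))
                           unname(ledger$groups[names(ledger$locus)]) else NA),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["lineage"] <- f
  f <- file.path(dir, paste0(prefix, ".events.tsv"))
  write.table(ledger$events, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["events"] <- f
  f <- file.path(dir, paste0(prefix, ".losses.tsv"))
  write.table(ledger$losses, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["losses"] <- f
  invisible(files)
}

#' Write a genotype matrix as TSV and minimal VCF 4.2
#'
#' The TSV is sites x samples with `./.` for missing calls; the VCF encodes
#' the same dosages as unphased diploid genotypes.
#'
#' @param m a [genotype_matrix()].
#' @param dir output directory.
#' @param prefix file prefix.
#' @return invisibly, files written.
#' @export
write_genotypes <- function(m, dir, prefix = "population") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- m$geno
  gt_code <- function(v) {
    ifelse(is.na(v), "./.", c("0/0", "0/1", "1/1")[v + 1L])
  }
  gm <- gt_code(g)  # samples x sites, character
  tsv <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos, t(gm))
  colnames(tsv) <- c("chrom", "pos", rownames(g))
  f_tsv <- file.path(dir, paste0(prefix, ".genotypes.tsv"))
  write.table(tsv, f_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ref <- if ("ref" %in% names(m$sites)) m$sites$ref else "A"
  alt <- if ("alt" %in% names(m$sites)) m$sites$alt else "T"
  body <- cbind(m$sites$chrom, m$sites$pos, ".", ref, alt, ".", "PASS", ".", "GT",
                t(gm))
  f_vcf <- file.path(dir, paste0(prefix, ".vcf"))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t"),
               apply(body, 1, paste, collapse = "\t")), f_vcf)
  invisible(c(tsv = f_tsv, vcf = f_vcf))
}

#' Read a genotype matrix from the TSV written by [write_genotypes()]
#' @param path TSV path.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  sites <- d[, c("chrom", "pos")]
  gt <- as.matrix(d[, -(1:2), drop = FALSE])
  dec <- matrix(match(gt, c("0/0", "0/1", "1/1")) - 1L, nrow = nrow(gt))
  geno <- t(dec)
  rownames(geno) <- colnames(gt)
  genotype_matrix(geno, sites)
}

#' Write anchors or a dotplot table as TSV
#' @param tab data.frame (anchors or [dotplot_table()] output).
#' @param path file path.
#' @param params optional named list recorded as `## key=value` header lines
#'   (e.g. the `max_gap`/`min_block` used).
#' @return invisibly, `path`.
#' @export
write_synteny_tsv <- function(tab, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf("## %s=%s", names(params), unlist(params)), con)
  }
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
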