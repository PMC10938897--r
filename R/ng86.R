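## Nei-Gojobori (1986) Ka/Ks estimation.
##
## Site counting uses the per-codon synonymous fraction averaged over both
## sequences; observed differences in multi-hit codons are averaged over all
## minimal substitution pathways, excluding pathways that pass through a stop
## codon (falling back to all pathways when every one is blocked, the standard
## NG86 convention). Multiple hits are corrected with Jukes-Cantor,
## d = -(3/4) log(1 - 4 p / 3); pairs where the correction is undefined are
## flagged `saturated` rather than clamped.

GENETIC_CODE_1 <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

SENSE_CODONS <- names(GENETIC_CODE_1)[GENETIC_CODE_1 != "*"]

.ng86_cache <- new.env(parent = emptyenv())

## synonymous site count of one codon: sum over positions of the fraction of
## the three possible single-base changes that are synonymous; changes to stop
## codons count as nonsynonymous (original NG86 convention)
codon_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_1[[codon]]
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    n_syn <- 0
    for (b in setdiff(DNA_BASES, base)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GENETIC_CODE_1[[mut]] == aa) n_syn <- n_syn + 1
    }
    s <- s + n_syn / 3
  }
  s
}

## average (synonymous, nonsynonymous) observed differences between two sense
## codons over all minimal substitution pathways, skipping stop intermediates
codon_pair_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  paths <- if (nd == 1L) list(pos) else {
    perms <- if (nd == 2L) list(pos, rev(pos)) else {
      out <- list()
      for (i in 1:3) for (j in setdiff(1:3, i)) out[[length(out) + 1L]] <- pos[c(i, j, setdiff(1:3, c(i, j)))]
      out
    }
    perms
  }
  step_counts <- function(order) {
    cur <- a
    sdiff <- 0; ndiff <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (GENETIC_CODE_1[[nxt]] == "*") return(NULL)
      if (GENETIC_CODE_1[[nxt]] == GENETIC_CODE_1[[cur]]) sdiff <- sdiff + 1 else ndiff <- ndiff + 1
      cur <- nxt
    }
    c(sdiff, ndiff)
  }
  res <- lapply(paths, step_counts)
  ok <- res[!vapply(res, is.null, logical(1))]
  if (!length(ok)) ok <- lapply(paths, function(order) { # all blocked: keep all
    cur <- a; sdiff <- 0; ndiff <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (GENETIC_CODE_1[[nxt]] != "*" && GENETIC_CODE_1[[nxt]] == GENETIC_CODE_1[[cur]]) sdiff <- sdiff + 1 else ndiff <- ndiff + 1
      cur <- nxt
    }
    c(sdiff, ndiff)
  })
  m <- colMeans(do.call(rbind, ok))
  c(sd = m[1], nd = m[2])
}

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tab)) return(.ng86_cache$tab)
  codons <- SENSE_CODONS
  syn_sites <- vapply(codons, codon_syn_sites, numeric(1))
  n <- length(codons)
  sd_tab <- matrix(0, n, n, dimnames = list(codons, codons))
  nd_tab <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- codon_pair_diffs(codons[i], codons[j])
    sd_tab[i, j] <- d[["sd"]]
    nd_tab[i, j] <- d[["nd"]]
  }
  .ng86_cache$tab <- list(syn_sites = syn_sites, sd = sd_tab, nd = nd_tab)
  .ng86_cache$tab
}

jc_correct <- function(p) {
  arg <- 1 - 4 * p / 3
  ifelse(arg <= 0, NA_real_, -0.75 * log(arg))
}

#' Nei-Gojobori (NG86) Ka/Ks for a pair of coding sequences
#'
#' Counts synonymous and nonsynonymous sites and differences by the NG86
#' method and applies the Jukes-Cantor multiple-hit correction. Pairs whose
#' synonymous (or nonsynonymous) proportion exceeds the correctable range are
#' flagged saturated and get `NA` for the corresponding rate.
#'
#' @param cdsA,cdsB in-frame coding sequences of equal length (no internal
#'   stop codons; a trailing stop is rejected too).
#' @return one-row data.frame with columns `S`, `N` (site counts), `Sd`, `Nd`
#'   (observed differences), `ps`, `pn`, `Ks`, `Ka`, `saturated`.
#' @examples
#' a <- strrep("TTT", 10)
#' b <- paste0("TTC", strrep("TTT", 9))
#' ng86(a, b)$Ks  # ~0.383
#' @export
ng86 <- function(cdsA, cdsB) {
  if (nchar(cdsA) != nchar(cdsB)) stop("sequences differ in length", call. = FALSE)
  ca <- split_codons(toupper(cdsA))
  cb <- split_codons(toupper(cdsB))
  if (any(GENETIC_CODE_1[ca] == "*") || any(GENETIC_CODE_1[cb] == "*")) {
    stop("stop codon in coding sequence", call. = FALSE)
  }
  tab <- ng86_tables()
  sA <- sum(tab$syn_sites[ca]); sB <- sum(tab$syn_sites[cb])
  S <- (sA + sB) / 2
  N <- length(ca) * 3 - S
  ij <- cbind(match(ca, SENSE_CODONS), match(cb, SENSE_CODONS))
  Sd <- sum(tab$sd[ij]); Nd <- sum(tab$nd[ij])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(ps); Ka <- jc_correct(pn)
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
             Ks = Ks, Ka = Ka, saturated = is.na(Ks))
}

#' NG86 over many gene pairs
#'
#' @param pairs data.frame with columns `geneA`, `geneB`.
#' @param cds named character vector (or list) mapping gene ids to CDS.
#' @return `pairs` with NG86 columns appended.
#' @export
ng86_pairs <- function(pairs, cds) {
  if (!nrow(pairs)) {
    return(cbind(pairs, data.frame(S = numeric(0), N = numeric(0), Sd = numeric(0),
                                   Nd = numeric(0), ps = numeric(0), pn = numeric(0),
                                   Ks = numeric(0), Ka = numeric(0), saturated = logical(0))))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ng86(cds[[pairs$geneA[i]]], cds[[pairs$geneB[i]]])
  }))
  cbind(pairs, res)
}
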