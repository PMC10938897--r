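#' @importFrom stats median rbinom rpois runif setNames cutree as.dist approx
#'   dist hclust quantile sd var fisher.test
#' @importFrom utils head tail write.table read.table
#' @importFrom mclust mclustBIC Mclust
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a fixed RNG seed without disturbing the global stream
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a per-stage child seed
#'
#' Deterministically maps a parent seed and a stage tag to a bounded integer
#' seed, so independent pipeline stages get independent but reproducible
#' random streams from one top-level seed.
#'
#' @param seed parent integer seed (or `NULL` for none).
#' @param tag character stage label.
#' @return an integer seed below 2^31, or `NULL`.
#' @export
child_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483399L) + 1L
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer (got %s)", name,
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(as.integer(x))
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  vapply(x, function(s) {
    s <- chartr("ACGTacgt", "TGCAtgca", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## split a sequence string into codon triplets
split_codons <- function(s) {
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}
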