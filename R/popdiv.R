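#' Genotype matrix container
#'
#' Samples x sites matrix of unphased diploid dosages (0/1/2, `NA` missing)
#' with per-site metadata (chromosome, 1-based position as in VCF, ref/alt).
#'
#' @param geno samples x sites integer matrix (rownames = sample ids).
#' @param sites data.frame with one row per site (`chrom`, `pos`, optionally
#'   `ref`, `alt`).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites = NULL) {
  geno <- as.matrix(geno)
  if (nrow(geno) < 2) stop("need at least 2 samples", call. = FALSE)
  if (is.null(sites)) {
    sites <- data.frame(chrom = rep("chr1", ncol(geno)),
                        pos = seq_len(ncol(geno)))
  }
  if (nrow(sites) != ncol(geno)) stop("sites/geno dimension mismatch", call. = FALSE)
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) stop("genotypes must be 0/1/2 or NA", call. = FALSE)
  structure(list(geno = geno, sites = sites), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites (%.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

site_stats <- function(m) {
  g <- m$geno
  n_miss <- colSums(is.na(g))
  n_called <- nrow(g) - n_miss
  af <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1))
  data.frame(maf = pmin(af, 1 - af),
             missing = n_miss / nrow(g),
             all_missing = n_called == 0)
}

#' Filter variant sites by minor allele frequency and missing rate
#'
#' A site is removed iff its minor allele frequency (over non-missing allele
#' calls) is below `maf_min` or its missing rate exceeds `missing_max`; sites
#' with all calls missing are removed and logged distinctly. Order is
#' preserved and the operation is idempotent.
#'
#' @param m a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param missing_max maximum per-site missing rate (default 0.30).
#' @return list with `matrix` (filtered [genotype_matrix()]) and `log`
#'   (per-site data.frame: `maf`, `missing`, `status` in
#'   `pass`/`low_maf`/`high_missing`/`all_missing`).
#' @export
filter_variants <- function(m, maf_min = 0.01, missing_max = 0.30) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  st <- site_stats(m)
  status <- ifelse(st$all_missing, "all_missing",
            ifelse(st$missing > missing_max, "high_missing",
            ifelse(st$maf < maf_min, "low_maf", "pass")))
  keep <- status == "pass"
  log <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                    maf = st$maf, missing = st$missing, status = status,
                    stringsAsFactors = FALSE)
  list(matrix = structure(list(geno = m$geno[, keep, drop = FALSE],
                               sites = m$sites[keep, , drop = FALSE]),
                          class = "genotype_matrix"),
       log = log)
}

## expected allele difference between two dosage genotypes: probability that
## one allele drawn from each differs
dosage_diff <- function(gi, gj) (gi * (2 - gj) + gj * (2 - gi)) / 4

#' Nucleotide diversity (pi)
#'
#' Mean pairwise difference per site over all unordered sample pairs. For a
#' genotype matrix the per-site difference between two samples is the
#' probability that one allele drawn from each differs
#' (`(gi (2 - gj) + gj (2 - gi)) / 4`); missing data are handled
#' pairwise-complete, rescaling each pair's observed polymorphic sites to the
#' full polymorphic count. For aligned sequences it is the per-site mismatch
#' count. The denominator is `n_sites_total`, the number of surveyed sites
#' including monomorphic ones.
#'
#' @param m a [genotype_matrix()] or character vector of >= 2 equal-length
#'   aligned sequences.
#' @param n_sites_total total surveyed sites; defaults to the matrix site
#'   count (or alignment length).
#' @return pi (numeric).
#' @examples
#' g <- genotype_matrix(rbind(a = c(0L, 0L), b = c(2L, 0L)))
#' nucleotide_diversity(g, n_sites_total = 10)  # 0.1
#' @export
nucleotide_diversity <- function(m, n_sites_total = NULL) {
  if (is.character(m)) {
    if (length(m) < 2) stop("need >= 2 sequences", call. = FALSE)
    L <- unique(nchar(m))
    if (length(L) != 1) stop("sequences must be aligned to equal length", call. = FALSE)
    n_sites_total <- n_sites_total %||% L
    mat <- do.call(rbind, strsplit(toupper(m), "", fixed = TRUE))
    pairs <- utils::combn(nrow(mat), 2)
    d <- apply(pairs, 2, function(p) sum(mat[p[1], ] != mat[p[2], ]))
    return(mean(d) / n_sites_total)
  }
  stopifnot(inherits(m, "genotype_matrix"))
  g <- m$geno
  S <- ncol(g)
  n_sites_total <- n_sites_total %||% S
  if (n_sites_total < S) stop("n_sites_total below polymorphic site count", call. = FALSE)
  if (S == 0) return(0)
  pairs <- utils::combn(nrow(g), 2)
  pair_pi <- apply(pairs, 2, function(p) {
    gi <- g[p[1], ]; gj <- g[p[2], ]
    ok <- !is.na(gi) & !is.na(gj)
    if (!any(ok)) stop("a sample pair has no comparable sites", call. = FALSE)
    sum(dosage_diff(gi[ok], gj[ok])) * (S / sum(ok))
  })
  mean(pair_pi) / n_sites_total
}

#' Pairwise p-distance matrix
#'
#' Mean expected allele difference per comparable site between every pair of
#' samples (or per-site mismatch fraction for sequences).
#'
#' @param m a [genotype_matrix()] or character vector of aligned sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(m) {
  if (is.character(m)) {
    mat <- do.call(rbind, strsplit(toupper(m), "", fixed = TRUE))
    n <- nrow(mat)
    ids <- names(m) %||% paste0("s", seq_len(n))
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- mean(mat[i, ] != mat[j, ])
    }
    return(D)
  }
  stopifnot(inherits(m, "genotype_matrix"))
  g <- m$geno
  n <- nrow(g)
  D <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    gi <- g[i, ]; gj <- g[j, ]
    ok <- !is.na(gi) & !is.na(gj)
    D[i, j] <- D[j, i] <- if (any(ok)) mean(dosage_diff(gi[ok], gj[ok])) else NA_real_
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Q-criterion neighbor joining (via \pkg{ape}); negative branch
#' lengths are clamped to zero with a note.
#'
#' @param D symmetric distance matrix (>= 3 samples).
#' @return an \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3) stop("need >= 3 samples for a tree", call. = FALSE)
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    message(sum(tr$edge.length < 0), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Principal component analysis of a genotype matrix
#'
#' Eigendecomposition of the sample covariance of genotypes centered at twice
#' the allele frequency and scaled by `sqrt(2 p (1 - p))` per site (the
#' standard genotype scaling). Missing calls are mean-imputed. The sign of
#' each component is fixed so that the coordinate of largest magnitude is
#' positive.
#'
#' @param m a [genotype_matrix()] (ideally post-filter).
#' @param n_components components to return (default all informative ones).
#' @return list with `scores` (samples x components), `eigenvalues`,
#'   `explained` (fraction of variance per component).
#' @export
pca_genotypes <- function(m, n_components = NULL) {
  stopifnot(inherits(m, "genotype_matrix"))
  g <- m$geno
  if (ncol(g) < 1) stop("no sites", call. = FALSE)
  p <- colMeans(g, na.rm = TRUE) / 2
  X <- g
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- 2 * p[j]
  denom <- sqrt(pmax(2 * p * (1 - p), 1e-12))
  Z <- sweep(sweep(X, 2, 2 * p, "-"), 2, denom, "/")
  K <- tcrossprod(Z) / ncol(Z)
  eig <- eigen(K, symmetric = TRUE)
  keep <- which(eig$values > 1e-10)
  if (!is.null(n_components)) keep <- head(keep, n_components)
  scores <- eig$vectors[, keep, drop = FALSE] %*% diag(sqrt(pmax(eig$values[keep], 0)),
                                                       nrow = length(keep))
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_along(keep)))
  list(scores = scores, eigenvalues = eig$values[keep],
       explained = eig$values[keep] / sum(pmax(eig$values, 0)))
}
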