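# Independent oracles used to cross-check the package implementations.

# ---- NG86 oracle: pathway enumeration written against Biostrings' genetic
# code table (independent code source), scalar and unvectorized on purpose.
oracle_codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- sub("U", "T", names(gc), fixed = TRUE)  # already DNA, safe no-op
  gc
})

oracle_translate <- function(codon) unname(oracle_codon_table[codon])

oracle_syn_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_translate(mut) != "*" &&
          oracle_translate(mut) == oracle_translate(codon)) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_pair_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  walk <- function(order) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (oracle_translate(nxt) == "*") return(NULL)
      if (oracle_translate(nxt) == oracle_translate(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms(pos), walk))
  if (!length(res)) {  # every pathway crosses a stop: count all, stops as nonsyn
    res <- lapply(perms(pos), function(order) {
      cur <- a; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (oracle_translate(nxt) != "*" &&
            oracle_translate(nxt) == oracle_translate(cur)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  colMeans(do.call(rbind, res))
}

oracle_ng86 <- function(cdsA, cdsB) {
  ca <- substring(cdsA, seq(1, nchar(cdsA), 3), seq(3, nchar(cdsA), 3))
  cb <- substring(cdsB, seq(1, nchar(cdsB), 3), seq(3, nchar(cdsB), 3))
  S <- (sum(vapply(ca, oracle_syn_sites, 0)) + sum(vapply(cb, oracle_syn_sites, 0))) / 2
  N <- length(ca) * 3 - S
  d <- rowSums(vapply(seq_along(ca), function(i) oracle_pair_diffs(ca[i], cb[i]),
                      numeric(2)))
  ps <- d[1] / S; pn <- d[2] / N
  jc <- function(p) if (1 - 4 * p / 3 <= 0) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = d[1], Nd = d[2], ps = ps, pn = pn, Ks = jc(ps), Ka = jc(pn))
}

random_sense_cds <- function(n_codons) {
  sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# ---- brute-force best monotone chain (both orientations), naive recursion
oracle_best_chain_score <- function(anchors, max_gap, gap_penalty = 0.5) {
  best <- -Inf
  for (dir in c(1, -1)) {
    rb <- dir * anchors$rankB
    o <- order(anchors$rankA, rb)
    ra <- anchors$rankA[o]; rbo <- rb[o]; sc <- anchors$score[o]
    m <- length(ra)
    extend <- function(i, cur) {
      best <<- max(best, cur)
      if (i == m) return()
      for (j in (i + 1):m) {
        gapA <- ra[j] - ra[i] - 1
        gapB <- rbo[j] - rbo[i] - 1
        if (ra[j] == ra[i] || rbo[j] == rbo[i]) next
        if (gapA < 0 || gapB < 0 || gapA > max_gap || gapB > max_gap) next
        extend(j, cur + sc[j] - gap_penalty * max(gapA, gapB) / 10)
      }
    }
    for (i in seq_len(m)) extend(i, sc[i])
  }
  best
}

# ---- exhaustive two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  # margins fixed; k = entry in cell (1,1)
  m <- a + b; n <- c + d; kcol <- a + c
  ks <- max(0, kcol - n):min(m, kcol)
  probs <- vapply(ks, function(k) {
    exp(lchoose(m, k) + lchoose(n, kcol - k) - lchoose(m + n, kcol))
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---- adjusted Rand index between two labelings
oracle_ari <- function(x, y) mclust::adjustedRandIndex(x, y)
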