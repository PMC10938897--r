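## Calibration of the synonymous-walk clock against NG86.
##
## The simulator's substitution process is a continuous-time walk on the
## synonymous single-step codon graph (each neighbour at rate 1/3, so a codon
## with s synonymous sites mutates at rate s, i.e. unit rate per synonymous
## site). The NG86 + Jukes-Cantor estimator applied to that process is not
## exactly unbiased: two-fold degenerate sites saturate toward an observed
## difference of 1/2 on a site measure of 1/3, above the 3/4 saturation JC
## assumes, so the estimated Ks inflates with divergence. The exact expected
## estimate is computable from the walk's generator (symmetric, so by
## eigendecomposition); the simulator uses its inverse to spend the event
## time that makes the expected *estimated* Ks equal the nominal Ks. All
## ledger truths are therefore on the scale NG86 reports.

syn_walk_eigen <- function() {
  if (!is.null(.ng86_cache$walk)) return(.ng86_cache$walk)
  nbr <- syn_neighbor_table()
  n <- length(SENSE_CODONS)
  Q <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  for (c1 in SENSE_CODONS) {
    for (c2 in nbr[[c1]]) Q[c1, c2] <- 1 / 3
  }
  diag(Q) <- -rowSums(Q)
  e <- eigen(Q, symmetric = TRUE)
  .ng86_cache$walk <- e
  e
}

## expected NG86 Ks estimate for a codon pair whose branches each walked
## event time t from a uniform sense-codon start
expected_ng86_ks <- function(t_branch) {
  e <- syn_walk_eigen()
  tab <- ng86_tables()
  P <- e$vectors %*% (exp(e$values * t_branch) * t(e$vectors))
  n <- length(SENSE_CODONS)
  J <- (P %*% P) / n               # joint codon distribution of the pair
  ESd <- sum(J * tab$sd)
  marg <- colSums(P) / n           # marginal composition at time t
  ES <- sum(marg * tab$syn_sites)
  jc_correct(ESd / ES)
}

## event time per branch needed for an expected estimated pair Ks; cached
## monotone grid inversion
event_time_for_ks <- function(ks_pair) {
  if (is.null(.ng86_cache$calib)) {
    tg <- seq(0, 2.5, by = 0.01)
    kg <- vapply(tg, expected_ng86_ks, numeric(1))
    ok <- !is.na(kg)
    .ng86_cache$calib <- list(t = tg[ok], ks = kg[ok])
  }
  cal <- .ng86_cache$calib
  if (any(ks_pair > max(cal$ks))) {
    stop("requested Ks beyond the calibrated (unsaturated) range of ",
         round(max(cal$ks), 2), call. = FALSE)
  }
  stats::approx(cal$ks, cal$t, xout = ks_pair, rule = 2)$y
}
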