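#' Simulate an ancestral gene-ordered genome
#'
#' Builds a diploid-like ancestor with `n_chrom` chromosomes each carrying
#' `genes_per_chrom` genes. Genes are assigned to `n_families` families by a
#' skewed (geometric-decay) size distribution, and each gene receives a coding
#' sequence of `codons_per_gene` sense codons drawn uniformly (no internal
#' stops). A random background chromosome sequence is generated so that later
#' transposable-element bursts have a substrate.
#'
#' @param n_chrom,genes_per_chrom,n_families,codons_per_gene positive integers.
#' @param seed RNG seed (same seed gives identical genomes).
#' @param family_skew decay of the family-size distribution: family `i` gets
#'   probability proportional to `family_skew^i`; 1 gives equal sizes.
#' @param chrom_bp background chromosome sequence length in bp (per
#'   chromosome); set 0 to skip sequence generation.
#' @return a [new_genome()] object.
#' @examples
#' g <- simulate_ancestor(8, 100, 20, 100, seed = 1)
#' n_genes(g)  # 800
#' @export
simulate_ancestor <- function(n_chrom, genes_per_chrom, n_families,
                              codons_per_gene, seed = NULL,
                              family_skew = 0.9, chrom_bp = genes_per_chrom * 150L) {
  stopifnot_scalar_count(n_chrom, "n_chrom")
  stopifnot_scalar_count(genes_per_chrom, "genes_per_chrom")
  stopifnot_scalar_count(n_families, "n_families")
  stopifnot_scalar_count(codons_per_gene, "codons_per_gene")
  with_seed(seed, {
    n <- n_chrom * genes_per_chrom
    fam_p <- family_skew^seq_len(n_families)
    fam_p <- fam_p / sum(fam_p)
    fams <- sprintf("F%02d", seq_len(n_families))
    genes <- data.frame(
      id = sprintf("g%05d", seq_len(n)),
      chrom = rep(sprintf("chr%02d", seq_len(n_chrom)), each = genes_per_chrom),
      rank = rep(seq_len(genes_per_chrom) - 1L, n_chrom),
      strand = sample(c("+", "-"), n, replace = TRUE),
      family = sample(fams, n, replace = TRUE, prob = fam_p),
      cds = vapply(seq_len(n), function(i) {
        paste(sample(SENSE_CODONS, codons_per_gene, replace = TRUE), collapse = "")
      }, character(1)),
      stringsAsFactors = FALSE
    )
    chrom_seq <- NULL
    if (chrom_bp > 0) {
      chrom_seq <- setNames(
        vapply(seq_len(n_chrom), function(i) random_dna(chrom_bp), character(1)),
        sprintf("chr%02d", seq_len(n_chrom)))
    }
    new_genome(genes, chrom_seq = chrom_seq)
  })
}

## synonymous single-step neighbours of each sense codon (cached)
syn_neighbor_table <- function() {
  if (!is.null(.ng86_cache$nbr)) return(.ng86_cache$nbr)
  nbr <- lapply(SENSE_CODONS, function(codon) {
    aa <- GENETIC_CODE_1[[codon]]
    out <- character(0)
    for (pos in 1:3) for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (GENETIC_CODE_1[[mut]] == aa) out <- c(out, mut)
    }
    out
  })
  names(nbr) <- SENSE_CODONS
  .ng86_cache$nbr <- nbr
  nbr
}

#' Apply synonymous-site substitutions to a coding sequence
#'
#' Poisson substitution process restricted to synonymous changes: the expected
#' number of substitutions per synonymous site is `d`. Each event picks a codon
#' with probability proportional to its synonymous site count and replaces it
#' with a random synonymous single-step neighbour, so repeated hits saturate
#' naturally and the Jukes-Cantor correction in [ng86()] recovers `d`.
#'
#' @param cds in-frame coding sequence.
#' @param d expected substitutions per synonymous site.
#' @return mutated coding sequence.
#' @export
mutate_synonymous <- function(cds, d) {
  if (d <= 0) return(cds)
  nbr <- syn_neighbor_table()
  codons <- split_codons(cds)
  w <- vapply(nbr[codons], length, integer(1)) / 3
  S <- sum(w)
  if (S <= 0) return(cds)
  n_ev <- rpois(1, d * S)
  for (e in seq_len(n_ev)) {
    i <- sample.int(length(codons), 1, prob = w)
    codons[i] <- sample(nbr[[codons[i]]], 1)
    w[i] <- length(nbr[[codons[i]]]) / 3
  }
  paste(codons, collapse = "")
}

## mutate every CDS in a genes table by d expected subs per synonymous site
mutate_genome_cds <- function(genes, d) {
  if (d <= 0) return(genes)
  has <- !is.na(genes$cds)
  genes$cds[has] <- vapply(genes$cds[has], mutate_synonymous, character(1), d = d)
  genes
}

## per-base Bernoulli substitution toward a target percent divergence
mutate_percent <- function(seq, percent) {
  if (percent <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(b)) < percent / 100
  if (any(hit)) {
    b[hit] <- vapply(b[hit], function(x) sample(setdiff(DNA_BASES, x), 1), character(1))
  }
  paste(b, collapse = "")
}

#' Evolve a genome through an event history
#'
#' Applies WGDs, fissions, fusions, inversions, loss epochs, TE bursts and
#' sequence-divergence epochs in order (oldest first) and returns the evolved
#' genome together with a [truth_ledger] recording gene lineages, losses and
#' the expected Ks separating copies born at each duplication. Between events,
#' coding sequences accumulate synonymous substitutions at the current clock
#' rate, so that copies duplicated at time `T` are separated by an expected
#' `2 * rate * T` substitutions per synonymous site.
#'
#' @param genome a [new_genome()] object.
#' @param history list of events from the [events] constructors, oldest first.
#' @param seed RNG seed.
#' @param ledger optionally, an existing ledger to extend (used internally).
#' @param end_time stop accumulating sequence divergence at this age (Mya);
#'   default 0 runs the clock to the present. Useful when a later stage (e.g.
#'   a progenitor merge) supplies the remaining divergence itself.
#' @return `list(genome = ..., ledger = ...)`.
#' @examples
#' g <- simulate_ancestor(8, 20, 5, 30, seed = 1)
#' ev <- evolve(g, list(ev_wgd(2, time = 10)), seed = 2)
#' length(chromosomes(ev$genome))  # 16
#' @export
evolve <- function(genome, history, seed = NULL, ledger = NULL, end_time = 0) {
  validate_genome(genome)
  validate_history(history)
  if (is.null(ledger)) {
    ids <- genome$genes$id
    ledger <- new_ledger(setNames(ids, ids), setNames(ids, ids))
  }
  ## the full rate schedule is declared in the history, so the nominal
  ## divergence-to-present D(t) is known upfront; sequence evolution spends
  ## event time F(t) = KsExp^-1(2 D(t)) so that the *estimated* (NG86) Ks of a
  ## pair split at t is the nominal 2 D(t) (see ks_calibration.R)
  sched <- do.call(rbind, lapply(history, function(e) {
    if (e$type == "seq") data.frame(time = e$time, rate = e$rate) else NULL
  }))
  Ft <- if (is.null(sched) || all(sched$rate == 0)) {
    function(t) 0
  } else {
    function(t) event_time_for_ks(2 * cumulative_divergence(sched, t))
  }
  with_seed(seed, {
    st <- list(genes = genome$genes, chrom_seq = genome$chrom_seq,
               te = genome$te_copies, ledger = ledger,
               rate = 0, t_now = if (length(history)) history[[1]]$time else 0,
               n_events = nrow(ledger$events),
               rate_changes = data.frame(time = numeric(0), rate = numeric(0)))
    for (e in history) {
      ## accumulate sequence divergence between the previous event and this one
      d_ev <- Ft(st$t_now) - Ft(e$time)
      if (d_ev > 0) st$genes <- mutate_genome_cds(st$genes, d_ev)
      st$t_now <- e$time
      st <- apply_event(st, e)
    }
    d_ev <- Ft(st$t_now) - Ft(end_time)
    if (d_ev > 0) st$genes <- mutate_genome_cds(st$genes, d_ev)
    ## fill in expected pairwise Ks for every duplication event now that the
    ## whole rate schedule is known
    todo <- which(is.na(st$ledger$events$expected_pair_ks))
    st$ledger$events$expected_pair_ks[todo] <- vapply(todo, function(i) {
      2 * cumulative_divergence(st$rate_changes, st$ledger$events$time[i])
    }, numeric(1))
    out <- new_genome(renumber_ranks(st$genes), chrom_seq = st$chrom_seq,
                      subgenome = genome$subgenome, te_copies = st$te,
                      ploidy_note = genome$ploidy_note)
    list(genome = out, ledger = st$ledger)
  })
}

## integral of the substitution rate from time t (Mya) to the present
cumulative_divergence <- function(rate_changes, t) {
  if (!nrow(rate_changes)) return(0)
  ## rate_changes: rate active from `time` until the next (more recent) change
  rc <- rate_changes[order(-rate_changes$time), , drop = FALSE]
  bounds <- c(rc$time, 0)
  total <- 0
  for (i in seq_len(nrow(rc))) {
    hi <- min(bounds[i], t)
    lo <- bounds[i + 1]
    if (hi > lo) total <- total + rc$rate[i] * (hi - lo)
  }
  total
}

log_event <- function(st, type, detail = "") {
  st$n_events <- st$n_events + 1L
  id <- sprintf("e%03d", st$n_events)
  st$ledger$events <- rbind(st$ledger$events, data.frame(
    event_id = id, type = type, time = st$t_now, expected_pair_ks = NA_real_,
    detail = detail, stringsAsFactors = FALSE))
  list(st = st, id = id)
}

apply_event <- function(st, e) {
  switch(e$type,
    seq = {
      le <- log_event(st, "seq", sprintf("rate=%g", e$rate))
      st <- le$st
      st$rate <- e$rate
      st$rate_changes <- rbind(st$rate_changes, data.frame(time = e$time, rate = e$rate))
      st
    },
    wgd = apply_wgd(st, e),
    fission = apply_fission(st, e),
    fusion = apply_fusion(st, e),
    inversion = apply_inversion(st, e),
    loss = apply_loss(st, e),
    te_burst = apply_te_burst(st, e),
    stop("unknown event type: ", e$type, call. = FALSE)
  )
}

apply_wgd <- function(st, e) {
  le <- log_event(st, "wgd", sprintf("k=%d", e$k))
  st <- le$st; id <- le$id
  tag <- e$tag %||% id
  genes <- st$genes
  base_locus <- unname(st$ledger$locus[genes$id])
  base_lineage <- unname(st$ledger$lineage[genes$id])
  copies <- lapply(seq_len(e$k), function(ci) {
    g <- genes
    tok <- paste0(id, ":", ci)
    if (ci > 1L) {
      g$chrom <- paste0(g$chrom, "_", tag, ci)
      g$id <- paste0(g$id, ".", tag, ci)
    }
    st$ledger$locus[g$id] <<- base_locus
    st$ledger$lineage[g$id] <<- paste0(base_lineage, "|", tok)
    g
  })
  ## copy-1 genes keep their ids, so no ledger entry goes stale
  st$genes <- do.call(rbind, copies)
  if (!is.null(st$chrom_seq)) {
    cs <- st$chrom_seq
    for (ci in seq_len(e$k)[-1]) {
      add <- setNames(cs, paste0(names(cs), "_", tag, ci))
      st$chrom_seq <- c(st$chrom_seq, add)
    }
  }
  if (!is.null(st$te) && nrow(st$te)) {
    te <- st$te
    for (ci in seq_len(e$k)[-1]) {
      t2 <- te
      t2$chrom <- paste0(t2$chrom, "_", tag, ci)
      st$te <- rbind(st$te, t2)
    }
  }
  st
}

apply_fission <- function(st, e) {
  genes <- st$genes
  on_ch <- genes$chrom == e$chrom
  if (!any(on_ch)) stop("fission of nonexistent chromosome: ", e$chrom, call. = FALSE)
  n <- sum(on_ch)
  if (e$breakpoint <= 0L || e$breakpoint >= n) {
    stop("fission breakpoint must be interior (got ", e$breakpoint,
         " on a chromosome of ", n, " genes)", call. = FALSE)
  }
  le <- log_event(st, "fission", sprintf("%s@%d", e$chrom, e$breakpoint))
  st <- le$st
  new_id <- paste0(e$chrom, "f")
  while (new_id %in% unique(st$genes$chrom)) new_id <- paste0(new_id, "f")
  move <- on_ch & genes$rank >= e$breakpoint
  genes$chrom[move] <- new_id
  st$genes <- renumber_ranks(genes)
  if (!is.null(st$chrom_seq) && e$chrom %in% names(st$chrom_seq)) {
    s <- st$chrom_seq[[e$chrom]]
    cut <- max(1L, round(nchar(s) * e$breakpoint / n))
    st$chrom_seq[[e$chrom]] <- substr(s, 1L, cut)
    st$chrom_seq[[new_id]] <- substr(s, cut + 1L, nchar(s))
    if (!is.null(st$te) && nrow(st$te)) {
      on_te <- st$te$chrom == e$chrom
      right <- on_te & st$te$start >= cut
      st$te$chrom[right] <- new_id
      st$te$start[right] <- st$te$start[right] - cut
      st$te$end[right] <- st$te$end[right] - cut
      st$te <- st$te[!(on_te & !right & st$te$end > cut), , drop = FALSE] # straddlers dropped
    }
  }
  st
}

apply_fusion <- function(st, e) {
  genes <- st$genes
  chs <- unique(genes$chrom)
  if (!(e$chromA %in% chs)) stop("fusion of nonexistent chromosome: ", e$chromA, call. = FALSE)
  if (!(e$chromB %in% chs)) stop("fusion of nonexistent chromosome: ", e$chromB, call. = FALSE)
  le <- log_event(st, "fusion", sprintf("%s+%s%s", e$chromA, e$chromB,
                                        if (isTRUE(e$flipB)) " (flipped)" else ""))
  st <- le$st
  nA <- sum(genes$chrom == e$chromA)
  onB <- genes$chrom == e$chromB
  if (isTRUE(e$flipB)) {
    nB <- sum(onB)
    genes$rank[onB] <- nB - 1L - genes$rank[onB]
    genes$strand[onB] <- ifelse(genes$strand[onB] == "+", "-", "+")
  }
  genes$rank[onB] <- genes$rank[onB] + nA
  genes$chrom[onB] <- e$chromA
  st$genes <- renumber_ranks(genes)
  if (!is.null(st$chrom_seq) && all(c(e$chromA, e$chromB) %in% names(st$chrom_seq))) {
    sB <- st$chrom_seq[[e$chromB]]
    LA <- nchar(st$chrom_seq[[e$chromA]]); LB <- nchar(sB)
    if (isTRUE(e$flipB)) sB <- revcomp(sB)
    st$chrom_seq[[e$chromA]] <- paste0(st$chrom_seq[[e$chromA]], sB)
    st$chrom_seq <- st$chrom_seq[names(st$chrom_seq) != e$chromB]
    if (!is.null(st$te) && nrow(st$te)) {
      onTB <- st$te$chrom == e$chromB
      if (any(onTB)) {
        if (isTRUE(e$flipB)) {
          s0 <- st$te$start[onTB]; e0 <- st$te$end[onTB]
          st$te$start[onTB] <- LB - e0
          st$te$end[onTB] <- LB - s0
          st$te$seq[onTB] <- revcomp(st$te$seq[onTB])
        }
        st$te$start[onTB] <- st$te$start[onTB] + LA
        st$te$end[onTB] <- st$te$end[onTB] + LA
        st$te$chrom[onTB] <- e$chromA
      }
    }
  }
  st
}

apply_inversion <- function(st, e) {
  genes <- st$genes
  on_ch <- genes$chrom == e$chrom
  if (!any(on_ch)) stop("inversion on nonexistent chromosome: ", e$chrom, call. = FALSE)
  n <- sum(on_ch)
  if (e$from < 0L || e$to >= n || e$from > e$to) {
    stop("invalid inversion interval [", e$from, ",", e$to, "]", call. = FALSE)
  }
  le <- log_event(st, "inversion", sprintf("%s[%d,%d]", e$chrom, e$from, e$to))
  st <- le$st
  inside <- on_ch & genes$rank >= e$from & genes$rank <= e$to
  genes$rank[inside] <- e$to - (genes$rank[inside] - e$from)
  genes$strand[inside] <- ifelse(genes$strand[inside] == "+", "-", "+")
  st$genes <- renumber_ranks(genes)
  st
}

apply_loss <- function(st, e) {
  le <- log_event(st, "loss", sprintf("rate=%g", e$rate))
  st <- le$st; id <- le$id
  genes <- st$genes
  mult <- rep(1, nrow(genes))
  if (!is.null(e$family_bias)) {
    m <- e$family_bias[genes$family]
    mult[!is.na(m)] <- m[!is.na(m)]
  }
  p <- pmin(1, e$rate * mult)
  die <- runif(nrow(genes)) < p
  if (!isTRUE(e$allow_extinction)) {
    loci <- unname(st$ledger$locus[genes$id])
    for (lc in unique(loci[die])) {
      at <- which(loci == lc)
      if (all(die[at])) die[sample(at, 1)] <- FALSE  # protect one survivor
    }
  }
  if (any(die)) {
    st$ledger$losses <- rbind(st$ledger$losses, data.frame(
      gene_id = genes$id[die], locus = unname(st$ledger$locus[genes$id[die]]),
      family = genes$family[die], event_id = id, stringsAsFactors = FALSE))
    st$ledger$lineage <- st$ledger$lineage[setdiff(names(st$ledger$lineage), genes$id[die])]
    st$ledger$locus <- st$ledger$locus[setdiff(names(st$ledger$locus), genes$id[die])]
    st$genes <- renumber_ranks(genes[!die, , drop = FALSE])
  }
  fl <- setNames(rep(1, length(unique(genes$family))), sort(unique(genes$family)))
  if (!is.null(e$family_bias)) fl[names(e$family_bias)] <- e$family_bias
  st$ledger$family_loss <- fl
  st
}

apply_te_burst <- function(st, e) {
  if (is.null(st$chrom_seq)) stop("TE burst requires chromosome sequences", call. = FALSE)
  le <- log_event(st, "te_burst", sprintf("%s div=%g%%", e$family, e$target_div))
  st <- le$st
  if (is.null(st$ledger$te_consensus)) st$ledger$te_consensus <- list()
  if (is.null(st$ledger$te_consensus[[e$family]])) {
    st$ledger$te_consensus[[e$family]] <- random_dna(e$length)
  }
  cons <- st$ledger$te_consensus[[e$family]]
  if (is.null(st$te)) {
    st$te <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                        family = character(0), seq = character(0),
                        true_div = numeric(0), stringsAsFactors = FALSE)
  }
  for (ch in names(st$chrom_seq)) {
    for (ci in seq_len(e$copies_per_chrom)) {
      copy <- mutate_percent(cons, e$target_div)
      L <- nchar(copy)
      pos <- sample.int(nchar(st$chrom_seq[[ch]]), 1)  # insert after `pos`
      s <- st$chrom_seq[[ch]]
      st$chrom_seq[[ch]] <- paste0(substr(s, 1, pos), copy, substr(s, pos + 1, nchar(s)))
      ## shift previously recorded copies lying beyond the insertion point
      on_ch <- st$te$chrom == ch & st$te$start >= pos
      st$te$start[on_ch] <- st$te$start[on_ch] + L
      st$te$end[on_ch] <- st$te$end[on_ch] + L
      st$te <- rbind(st$te, data.frame(chrom = ch, start = pos, end = pos + L,
                                       family = e$family, seq = copy,
                                       true_div = e$target_div, stringsAsFactors = FALSE))
    }
  }
  st
}
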