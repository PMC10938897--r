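#' Merge two progenitor genomes into an allotetraploid
#'
#' Combines two progenitors (descended from one simulated ancestor, so they
#' share ancestral locus ids) into a single genome with subgenome labels set
#' to the truth. Optionally applies an additional divergence pulse to each
#' progenitor first, so that homoeologous copies are separated by an expected
#' synonymous divergence of `divergence` (half accumulated on each branch).
#'
#' @param progA,progB progenitor genomes.
#' @param ledgerA,ledgerB their truth ledgers (from [evolve()]); if `NULL`, a
#'   fresh ledger treating each gene as its own locus is created.
#' @param divergence expected homoeolog Ks between the two subgenomes
#'   (`0` for identical progenitors).
#' @param suffixes length-2 character; chromosome and gene ids of the two
#'   progenitors are suffixed with these subgenome labels before merging.
#'   Set `NULL` to forbid renaming, in which case clashing chromosome ids are
#'   an error.
#' @param split_time age of the progenitor split in Mya (bookkeeping only).
#' @param seed RNG seed for the divergence pulse.
#' @return `list(genome = ..., ledger = ...)`; the genome's `ploidy_note`
#'   reports the somatic chromosome number `2n = 2 * (nA + nB)`.
#' @examples
#' anc <- simulate_ancestor(8, 10, 5, 30, seed = 1)
#' tet <- make_allotetraploid(anc, anc, divergence = 0)
#' tet$genome$ploidy_note  # "2n = 4x = 32"
#' @export
make_allotetraploid <- function(progA, progB, ledgerA = NULL, ledgerB = NULL,
                                divergence = 0, suffixes = c("A", "B"),
                                split_time = NA_real_, seed = NULL) {
  fresh <- function(g) {
    ids <- g$genes$id
    new_ledger(setNames(ids, ids), setNames(ids, ids))
  }
  if (is.null(ledgerA)) ledgerA <- fresh(progA)
  if (is.null(ledgerB)) ledgerB <- fresh(progB)
  if (is.null(suffixes)) {
    clash <- intersect(chromosomes(progA), chromosomes(progB))
    if (length(clash)) {
      stop("progenitors share chromosome ids (", paste(head(clash, 3), collapse = ", "),
           "...); pass `suffixes` to rename", call. = FALSE)
    }
    suffixes <- c("", "")
  }
  rename <- function(g, led, suf, side) {
    old_ids <- g$genes$id
    new_ids <- if (nzchar(suf)) paste0(old_ids, "_", suf) else old_ids
    map <- setNames(new_ids, old_ids)
    genes <- g$genes
    genes$id <- new_ids
    if (nzchar(suf)) genes$chrom <- paste0(genes$chrom, "_", suf)
    led2 <- led
    names(led2$locus) <- unname(map[names(led$locus)])
    names(led2$lineage) <- unname(map[names(led$lineage)])
    led2$lineage <- paste0(unname(led2$lineage), "|esplit:", side)
    names(led2$lineage) <- names(led2$locus)
    cs <- g$chrom_seq
    if (!is.null(cs) && nzchar(suf)) names(cs) <- paste0(names(cs), "_", suf)
    te <- g$te_copies
    if (!is.null(te) && nrow(te) && nzchar(suf)) te$chrom <- paste0(te$chrom, "_", suf)
    list(genes = genes, ledger = led2, chrom_seq = cs, te = te)
  }
  with_seed(seed, {
    a <- rename(progA, ledgerA, suffixes[1], "A")
    b <- rename(progB, ledgerB, suffixes[2], "B")
    if (divergence > 0) {
      ## per-branch event time calibrated so the expected estimated (NG86)
      ## homoeolog Ks equals `divergence`
      d_branch <- event_time_for_ks(divergence)
      a$genes <- mutate_genome_cds(a$genes, d_branch)
      b$genes <- mutate_genome_cds(b$genes, d_branch)
    }
    genes <- rbind(a$genes, b$genes)
    if (anyDuplicated(genes$id)) {
      stop("gene ids clash between progenitors after renaming", call. = FALSE)
    }
    ledger <- merge_ledgers(a$ledger, b$ledger)
    ledger$events <- rbind(ledger$events, data.frame(
      event_id = "esplit", type = "split", time = split_time,
      expected_pair_ks = divergence, detail = "progenitor divergence",
      stringsAsFactors = FALSE))
    chrom_seq <- c(a$chrom_seq, b$chrom_seq)
    te <- rbind(a$te, b$te)
    subg <- c(setNames(rep("A", length(unique(a$genes$chrom))), unique(a$genes$chrom)),
              setNames(rep("B", length(unique(b$genes$chrom))), unique(b$genes$chrom)))
    ledger$subgenome <- subg
    n_hap <- length(unique(genes$chrom))
    g <- new_genome(genes, chrom_seq = chrom_seq, subgenome = subg, te_copies = te,
                    ploidy_note = sprintf("2n = 4x = %d", 2L * n_hap))
    list(genome = g, ledger = ledger)
  })
}

#' Simulate a full allotetraploid study system
#'
#' Convenience wrapper reproducing the nested-WGD architecture of an
#' allotetraploid with two 8-chromosome subgenomes: a proto ancestor of
#' `n_proto` chromosomes undergoes an ancient shared WGD (the dating anchor),
#' karyotype rearrangements down to an intermediate state, a lineage-specific
#' WGD creating the within-subgenome ancestral groups (A1/A2 and B1/B2), a
#' progenitor split with subgenome-specific TE bursts and family-biased gene
#' loss, and finally the tetraploidizing merge.
#'
#' @param n_proto proto-chromosome number of the ancestor (default 8).
#' @param genes_per_chrom genes per proto chromosome.
#' @param n_families,codons_per_gene see [simulate_ancestor()].
#' @param ks_tau,ks_dup,ks_split expected Ks separating copies born at the
#'   ancient shared WGD, the lineage-specific WGD, and the progenitor split.
#'   Set `ks_tau = NULL` to skip the ancient round (faster; two nested epochs
#'   instead of three).
#' @param loss_rate per-copy loss probability in the post-merge fractionation
#'   epoch; `family_bias` multiplies it per family.
#' @param te_div divergence targets (percent) for the subgenome-specific TE
#'   bursts, named `A` and `B`.
#' @param te_copies TE copies inserted per chromosome and burst.
#' @param rate synonymous substitution rate per site per My (the clock tying
#'   Ks to time; ages of the simulated events are `ks / (2 * rate)`).
#' @param seed RNG seed.
#' @return `list(genome, ledger)`; `ledger$groups` maps every gene to its true
#'   ancestral group and `ledger$subgenome` every chromosome to its subgenome.
#' @export
simulate_allotetraploid <- function(n_proto = 8, genes_per_chrom = 25,
                                    n_families = 20, codons_per_gene = 100,
                                    ks_tau = 1.5, ks_dup = 0.7, ks_split = 0.1,
                                    loss_rate = 0, family_bias = NULL,
                                    te_div = c(A = 5, B = 19), te_copies = 20,
                                    rate = 0.0025, seed = NULL) {
  with_seed(seed, {
    anc <- simulate_ancestor(n_proto, genes_per_chrom, n_families, codons_per_gene)
    t_dup <- ks_dup / (2 * rate)
    t_split <- ks_split / (2 * rate)
    chs <- chromosomes(anc)
    history <- list()
    if (!is.null(ks_tau)) {
      t_tau <- ks_tau / (2 * rate)
      t_r1 <- (t_tau + t_dup) / 2   # age of the post-tau rearrangement batch
      history <- c(history, list(ev_seq(rate, time = t_tau + 1),
                                 ev_wgd(2, time = t_tau, tag = "t")))
      ## collapse the doubled karyotype (2 * n_proto chromosomes) to an
      ## intermediate state of n_proto / 2 chromosomes: 1 fission followed by
      ## (2 * n_proto + 1) - n_proto / 2 fusions (for n_proto = 8: 1 + 13,
      ## reaching the n = 4 intermediate)
      c16 <- c(chs, paste0(chs, "_t2"))
      history <- c(history, list(ev_fission(c16[1], max(1L, genes_per_chrom %/% 2L),
                                            time = t_r1)))
      c17 <- c(c16[1], paste0(c16[1], "f"), c16[-1])
      n_int <- max(1L, n_proto %/% 2L)
      grp <- rep(seq_len(n_int), length.out = length(c17))
      grp <- sort(grp)
      leads <- character(n_int)
      fi <- 0L
      for (gi in seq_len(n_int)) {
        members <- c17[grp == gi]
        leads[gi] <- members[1]
        for (m in members[-1]) {
          fi <- fi + 1L
          history <- c(history, list(ev_fusion(members[1], m, flipB = fi %% 2L == 0L,
                                               time = t_r1)))
        }
      }
    } else {
      history <- c(history, list(ev_seq(rate, time = t_dup + 1)))
      leads <- chs
    }
    ## lineage-specific duplication creating the A1/A2 (and B1/B2) groups
    history <- c(history, list(ev_wgd(2, time = t_dup, tag = "d")))
    ## a few balanced post-duplication rearrangements (translocation-style
    ## fission+fusion pairs and inversions) so extant chromosomes are mosaics
    t_r2 <- (t_dup + t_split) / 2
    dup_chs <- c(leads, paste0(leads, "_d2"))
    if (length(dup_chs) >= 4 && genes_per_chrom >= 6) {
      ## hub translocations: every copy-1 chromosome beyond the first donates
      ## its tail to the first, so each ancestral group forms one connected
      ## synteny bundle and the group partition is identifiable
      tail_len <- max(3L, genes_per_chrom %/% 4L)
      half <- length(dup_chs) %/% 2L
      for (i in 2:half) {
        history <- c(history, list(
          ev_fission(dup_chs[i], genes_per_chrom - tail_len, time = t_r2),
          ev_fusion(dup_chs[1], paste0(dup_chs[i], "f"),
                    flipB = i %% 2L == 0L, time = t_r2)))
      }
      history <- c(history, list(
        ev_inversion(dup_chs[2], 1L, max(2L, genes_per_chrom %/% 3L), time = t_r2)))
    }
    pre <- evolve(anc, history, end_time = t_split)
    tet <- make_allotetraploid(pre$genome, pre$genome,
                               ledgerA = pre$ledger, ledgerB = pre$ledger,
                               divergence = ks_split, split_time = t_split)
    g <- tet$genome; ledger <- tet$ledger
    ## subgenome-specific TE bursts at distinct divergence levels
    if (!is.null(te_div) && !is.null(g$chrom_seq)) {
      for (sg in names(te_div)) {
        sg_chs <- names(ledger$subgenome)[ledger$subgenome == sg]
        te_now <- g$te_copies
        if (is.null(te_now)) {
          te_now <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                               family = character(0), seq = character(0),
                               true_div = numeric(0), stringsAsFactors = FALSE)
        }
        sub_st <- list(genes = g$genes, chrom_seq = g$chrom_seq[sg_chs],
                       te = te_now[te_now$chrom %in% sg_chs, , drop = FALSE],
                       ledger = ledger, rate = 0, t_now = 0,
                       n_events = nrow(ledger$events),
                       rate_changes = data.frame(time = numeric(0), rate = numeric(0)))
        sub_st <- apply_te_burst(sub_st, ev_te_burst(paste0("TE_", sg), te_copies,
                                                     te_div[[sg]], time = 0))
        ledger <- sub_st$ledger
        g$chrom_seq[sg_chs] <- sub_st$chrom_seq[sg_chs]
        g$te_copies <- rbind(te_now[!(te_now$chrom %in% sg_chs), , drop = FALSE], sub_st$te)
      }
    }
    ## post-merge fractionation with family-biased loss
    if (loss_rate > 0) {
      post <- evolve(g, list(ev_loss(loss_rate, family_bias = family_bias, time = 0)),
                     ledger = ledger)
      g <- post$genome
      ledger <- post$ledger
      ledger$subgenome <- tet$ledger$subgenome
    }
    ledger$groups <- true_groups(g, ledger)
    list(genome = g, ledger = ledger)
  })
}

## true ancestral group (A1/A2/B1/B2) of every gene: subgenome from the
## progenitor split token, 1/2 from the copy index at the most recent
## within-progenitor WGD
true_groups <- function(genome, ledger) {
  lin <- ledger$lineage[genome$genes$id]
  side <- ifelse(grepl("\\|esplit:A", lin), "A",
                 ifelse(grepl("\\|esplit:B", lin), "B", NA))
  ## copy index of the last wgd token before the split token
  wgd_tok <- regmatches(lin, gregexpr("e[0-9]+:[0-9]+", lin))
  copy <- vapply(wgd_tok, function(t) {
    if (!length(t)) return(NA_character_)
    sub("^.*:", "", t[length(t)])
  }, character(1))
  grp <- ifelse(is.na(side) | is.na(copy), NA_character_, paste0(side, copy))
  setNames(grp, genome$genes$id)
}
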