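#' Truth ledger of a simulated genome
#'
#' Records the lineage of every surviving gene (descendant to ancestral locus),
#' the event log with times, logged gene losses, the true subgenome of every
#' chromosome and the true ancestral group of every gene (after
#' [make_allotetraploid()]), per-family loss rates, and the expected synonymous
#' divergence (Ks) separating copies born at each duplication event.
#'
#' @name truth_ledger
NULL

new_ledger <- function(locus, lineage) {
  structure(list(
    locus = locus,          # gene id -> ancestral locus id
    lineage = lineage,      # gene id -> lineage string "locus|e1:2|..."
    events = data.frame(event_id = character(0), type = character(0),
                        time = numeric(0), expected_pair_ks = numeric(0),
                        detail = character(0), stringsAsFactors = FALSE),
    losses = data.frame(gene_id = character(0), locus = character(0),
                        family = character(0), event_id = character(0),
                        stringsAsFactors = FALSE),
    subgenome = NULL,       # chromosome -> subgenome truth
    groups = NULL,          # gene id -> ancestral group (A1/A2/B1/B2)
    family_loss = NULL      # family -> effective loss multiplier
  ), class = "truth_ledger")
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat(sprintf("<truth_ledger> %d surviving genes, %d loci, %d events, %d losses\n",
              length(x$locus), length(unique(x$locus)), nrow(x$events), nrow(x$losses)))
  invisible(x)
}

## event id (oldest shared->first differing token) separating two lineages
divergence_event <- function(ledger, geneA, geneB) {
  la <- strsplit(ledger$lineage[[geneA]], "|", fixed = TRUE)[[1]]
  lb <- strsplit(ledger$lineage[[geneB]], "|", fixed = TRUE)[[1]]
  if (la[1] != lb[1]) return(NA_character_)  # different ancestral loci
  n <- min(length(la), length(lb))
  for (i in seq_len(n)[-1]) {
    if (la[i] != lb[i]) return(sub(":.*$", "", la[i]))
  }
  NA_character_
}

#' Ledger-truth expected Ks between two paralogous genes
#'
#' Looks up the duplication (or progenitor-split) event at which the two gene
#' lineages diverged and returns the expected pairwise synonymous divergence
#' accumulated since then (2 x rate x age under the simulation's clock).
#'
#' @param ledger a `truth_ledger`
#' @param geneA,geneB gene ids present in the ledger
#' @return expected Ks (numeric), or `NA` if the genes do not share a locus.
#' @export
true_ks <- function(ledger, geneA, geneB) {
  ev <- divergence_event(ledger, geneA, geneB)
  if (is.na(ev)) return(NA_real_)
  i <- match(ev, ledger$events$event_id)
  if (is.na(i)) return(NA_real_)
  ledger$events$expected_pair_ks[i]
}

## merge two ledgers after renaming (used by make_allotetraploid)
merge_ledgers <- function(la, lb) {
  out <- new_ledger(c(la$locus, lb$locus), c(la$lineage, lb$lineage))
  ev <- rbind(la$events, lb$events)
  out$events <- ev[!duplicated(ev$event_id), , drop = FALSE]
  out$losses <- rbind(la$losses, lb$losses)
  out$family_loss <- c(la$family_loss, lb$family_loss)
  out
}
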