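#' Event constructors for genome-evolution histories
#'
#' An event history is an ordered list of events, oldest first, with times in
#' millions of years ago (Mya) non-increasing toward the present. Events are
#' applied by [evolve()].
#'
#' @name events
#' @param k WGD multiplier (>= 2): every chromosome is copied `k` times.
#' @param time event age in Mya (>= 0).
#' @param chrom,chromA,chromB chromosome ids.
#' @param breakpoint 0-based gene rank at which a fission splits a chromosome;
#'   genes with rank `< breakpoint` stay, the rest move to a new chromosome.
#'   Must be interior (neither 0 nor the gene count).
#' @param flipB logical; if `TRUE` the second chromosome is reversed
#'   (gene order and strands, sequence reverse-complemented) before fusion.
#' @param from,to inclusive 0-based rank interval to invert.
#' @param rate for `ev_loss`: per-gene loss probability per epoch; for
#'   `ev_seq`: expected synonymous substitutions per synonymous site per My
#'   from this time toward the present.
#' @param family_bias named numeric vector of per-family multipliers applied
#'   to the base loss rate (families absent get multiplier 1).
#' @param allow_extinction if `FALSE` (default) the last surviving copy of an
#'   ancestral locus is protected from loss.
#' @param family TE family label.
#' @param copies_per_chrom TE copies inserted per chromosome.
#' @param target_div target percent divergence of inserted copies from the
#'   family consensus (per-base Bernoulli mismatches).
#' @param length TE consensus length in bp (generated on first burst of a
#'   family).
#' @return a list describing the event, for use in a history list.
NULL

#' @rdname events
#' @param tag short label used to suffix duplicated chromosome and gene ids
#'   (defaults to the event id); distinct WGDs must carry distinct tags.
#' @export
ev_wgd <- function(k = 2, time = 0, tag = NULL) {
  stopifnot(k >= 2, k == floor(k), time >= 0)
  list(type = "wgd", k = as.integer(k), time = time, tag = tag)
}

#' @rdname events
#' @export
ev_fission <- function(chrom, breakpoint, time = 0) {
  list(type = "fission", chrom = chrom, breakpoint = as.integer(breakpoint), time = time)
}

#' @rdname events
#' @export
ev_fusion <- function(chromA, chromB, flipB = FALSE, time = 0) {
  list(type = "fusion", chromA = chromA, chromB = chromB, flipB = flipB, time = time)
}

#' @rdname events
#' @export
ev_inversion <- function(chrom, from, to, time = 0) {
  list(type = "inversion", chrom = chrom, from = as.integer(from), to = as.integer(to), time = time)
}

#' @rdname events
#' @export
ev_loss <- function(rate, family_bias = NULL, time = 0, allow_extinction = FALSE) {
  stopifnot(rate >= 0)
  list(type = "loss", rate = rate, family_bias = family_bias, time = time,
       allow_extinction = allow_extinction)
}

#' @rdname events
#' @export
ev_te_burst <- function(family, copies_per_chrom, target_div, length = 500, time = 0) {
  stopifnot(copies_per_chrom >= 1, target_div >= 0, target_div <= 100)
  list(type = "te_burst", family = family, copies_per_chrom = as.integer(copies_per_chrom),
       target_div = target_div, length = as.integer(length), time = time)
}

#' @rdname events
#' @export
ev_seq <- function(rate, time = 0) {
  stopifnot(rate >= 0)
  list(type = "seq", rate = rate, time = time)
}

validate_history <- function(history) {
  if (!length(history)) return(invisible(history))
  times <- vapply(history, function(e) e$time, numeric(1))
  if (any(diff(times) > 1e-9)) {
    stop("event times must be non-increasing toward the present (oldest first)",
         call. = FALSE)
  }
  invisible(history)
}
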