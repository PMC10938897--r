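#' Fill per-anchor and per-block Ks into synteny blocks
#'
#' Runs [ng86()] on every anchor pair and stores the per-anchor Ks plus the
#' block median over non-saturated anchors. Blocks whose anchors are all
#' saturated keep `median_ks = NA` and are flagged.
#'
#' @param blocks a `synteny_blocks` list.
#' @param cds named character vector (or list) mapping gene ids to CDS.
#' @return the blocks with `anchors$ks`, `median_ks` and `all_saturated` set.
#' @export
block_ks <- function(blocks, cds) {
  out <- lapply(blocks, function(b) {
    miss <- setdiff(c(b$anchors$geneA, b$anchors$geneB), names(cds))
    if (length(miss)) stop("missing CDS for: ", paste(head(miss, 3), collapse = ", "),
                           call. = FALSE)
    est <- ng86_pairs(b$anchors[, c("geneA", "geneB")], cds)
    b$anchors$ks <- est$Ks
    b$anchors$ka <- est$Ka
    ok <- !est$saturated
    b$median_ks <- if (any(ok)) median(est$Ks[ok]) else NA_real_
    b$all_saturated <- !any(ok)
    b
  })
  structure(out, class = "synteny_blocks")
}

#' Extract all anchor Ks values from blocks
#' @param blocks blocks processed by [block_ks()].
#' @param drop_saturated drop `NA` (saturated) values (default `TRUE`).
#' @return numeric vector of Ks values.
#' @export
anchor_ks_values <- function(blocks, drop_saturated = TRUE) {
  v <- unlist(lapply(blocks, function(b) b$anchors$ks), use.names = FALSE)
  if (drop_saturated) v <- v[!is.na(v)]
  v
}

#' Fit peaks to a Ks distribution
#'
#' Gaussian mixture on log-transformed Ks with the component count chosen by
#' BIC (equal- and unequal-variance one-dimensional models). Peak locations
#' are reported back-transformed as the component centres `exp(mu)` (the
#' lognormal median/geometric mean), with the lognormal mode
#' `exp(mu - sigma^2)` alongside, sorted ascending; weights sum to 1.
#'
#' @param ks numeric vector of Ks values (>= 2 required; >= 50 recommended).
#' @param ks_max values above this are discarded before fitting (default 3).
#' @param max_components maximum mixture components (default 4).
#' @param seed RNG seed (the fit itself is deterministic given the data; the
#'   seed guards any future stochastic initialisation).
#' @return object of class `ks_peaks`: data.frame `peaks` with `location`,
#'   `mode`, `weight`, `sigma_log`, plus `n`, `G`, `bic`.
#' @export
fit_ks_peaks <- function(ks, ks_max = 3.0, max_components = 4, seed = NULL) {
  ks <- ks[!is.na(ks) & ks > 0 & ks <= ks_max]
  if (length(ks) < 2) stop("need >= 2 positive Ks values", call. = FALSE)
  with_seed(seed, {
    bic <- mclust::mclustBIC(log(ks), G = seq_len(max_components),
                             modelNames = c("E", "V"), verbose = FALSE)
    fit <- mclust::Mclust(log(ks), x = bic, verbose = FALSE)
    mu <- fit$parameters$mean
    sig2 <- fit$parameters$variance$sigmasq
    if (length(sig2) == 1L) sig2 <- rep(sig2, length(mu))
    w <- fit$parameters$pro
    o <- order(mu)
    peaks <- data.frame(location = exp(mu[o]),
                        mode = exp(mu[o] - sig2[o]),
                        weight = w[o],
                        sigma_log = sqrt(sig2[o]))
    rownames(peaks) <- NULL
    structure(list(peaks = peaks, n = length(ks), G = fit$G, bic = fit$bic,
                   model = fit$modelName), class = "ks_peaks")
  })
}

#' @export
print.ks_peaks <- function(x, ...) {
  cat(sprintf("<ks_peaks> %d component(s) fitted to %d values (model %s)\n",
              x$G, x$n, x$model))
  print(x$peaks, digits = 4)
  invisible(x)
}

#' Date Ks peaks against an anchored calibration
#'
#' Linear molecular-clock scaling: a peak at `mu_i` is dated to
#' `(mu_i / mu_anchor) * [T_min, T_max]`, propagating only the anchor's
#' interval. The transform is scale-free: multiplying all Ks by a constant
#' leaves the dates unchanged.
#'
#' @param peaks a `ks_peaks` object (or numeric vector of peak locations).
#' @param anchor_peak index of the anchor peak among the locations.
#' @param t_min,t_max calibration interval of the anchor event in Mya
#'   (0 < t_min <= t_max).
#' @return data.frame with `peak`, `ks`, `t_min`, `t_max` per peak.
#' @export
anchored_dating <- function(peaks, anchor_peak, t_min, t_max) {
  if (!(t_min > 0 && t_min <= t_max)) stop("need 0 < t_min <= t_max", call. = FALSE)
  locs <- if (inherits(peaks, "ks_peaks")) peaks$peaks$location else as.numeric(peaks)
  if (anchor_peak < 1 || anchor_peak > length(locs)) stop("anchor peak out of range", call. = FALSE)
  mu_a <- locs[anchor_peak]
  if (mu_a <= 0) stop("anchor peak location must be > 0", call. = FALSE)
  data.frame(peak = seq_along(locs), ks = locs,
             t_min = locs / mu_a * t_min, t_max = locs / mu_a * t_max)
}

#' Outgroup-based relative-rate contrast
#'
#' Compares the substitution rates of two lineages A and B via their Ks to a
#' common outgroup over the same ortholog set: `ratio = median(ks_AO) /
#' median(ks_BO)`, with a percentile bootstrap interval over paired ortholog
#' resampling.
#'
#' @param ks_AO,ks_BO equal-length numeric vectors (same ortholog order).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return list with `ratio`, `conf_int`, `n`.
#' @export
relative_rate <- function(ks_AO, ks_BO, n_boot = 1000, conf = 0.95, seed = NULL) {
  if (!length(ks_AO) || !length(ks_BO)) stop("empty Ks sets", call. = FALSE)
  if (length(ks_AO) != length(ks_BO)) stop("ortholog sets differ in length", call. = FALSE)
  ratio <- median(ks_AO) / median(ks_BO)
  ci <- with_seed(seed, {
    n <- length(ks_AO)
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      median(ks_AO[idx]) / median(ks_BO[idx])
    }, numeric(1))
    quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  list(ratio = ratio, conf_int = ci, n = length(ks_AO))
}
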