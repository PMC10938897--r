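## default run configuration; every key here is a recognized config key
default_config <- function() {
  list(
    seed = 1L,
    outdir = "polyevolve_demo",
    ## simulator sizes (study-condition defaults)
    n_proto = 8L, genes_per_chrom = 12L, n_families = 20L, codons_per_gene = 100L,
    ks_tau = 1.5, ks_dup = 0.7, ks_split = 0.1,
    loss_rate = 0.2, family_bias = c(F01 = 4, F02 = 2),
    te_div = c(A = 5, B = 19), te_copies = 20L,
    ## synteny
    max_gap = 50L, min_block = 5L, min_score = 0.12,
    ## Ks fitting / dating
    ks_max = 3.0, max_components = 4L,
    anchor_t_min = 129, anchor_t_max = 146,
    ## phasing
    kmer = 13L, fold_min = 2.0,
    ## TE landscape
    te_bin = 1, bubble_threshold = 0.75,
    ## population
    n_samples = 10L, theta = 0.00144, n_sites = 50000L,
    n_genotypes = 4L, missing_rate = 0.05,
    maf_min = 0.01, missing_max = 0.30,
    plastome_bp = 20000L, plastome_snps = 0L, plastome_indels = 1L,
    ## stage toggles
    run_phasing = TRUE, run_popdiv = TRUE
  )
}

#' Validate and normalize a run configuration
#'
#' Reads a YAML/JSON configuration file (or takes a list), fills in all
#' defaults, and rejects unknown keys and invalid values. All violations are
#' collected and reported together, not first-failure.
#'
#' @param config path to a YAML/JSON file, a list, or `NULL` for defaults.
#' @return the normalized configuration list; errors carry the full list of
#'   violations.
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_config()
  user <- config
  if (is.character(user)) {
    if (!file.exists(user)) stop("config file not found: ", user, call. = FALSE)
    user <- yaml::read_yaml(user)
  }
  user <- user %||% list()
  errors <- character(0)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- defaults
  for (k in intersect(names(user), names(defaults))) {
    v <- user[[k]]
    if (k %in% c("family_bias", "te_div") && is.list(v)) v <- unlist(v)
    cfg[[k]] <- v
  }
  check_pos <- function(keys) {
    for (k in keys) {
      if (!is.numeric(cfg[[k]]) || any(cfg[[k]] < 0) || anyNA(cfg[[k]])) {
        errors <<- c(errors, sprintf("`%s` must be non-negative numeric (got %s)",
                                     k, paste(format(cfg[[k]]), collapse = ",")))
      }
    }
  }
  check_pos(c("ks_dup", "ks_split", "loss_rate", "ks_max", "theta",
              "missing_rate", "te_bin"))
  for (k in c("n_proto", "genes_per_chrom", "n_families", "codons_per_gene",
              "max_gap", "min_block", "kmer", "n_samples", "n_sites",
              "te_copies", "max_components", "plastome_bp")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v)) {
      errors <- c(errors, sprintf("`%s` must be a positive integer (got %s)", k,
                                  paste(format(v), collapse = ",")))
    } else {
      cfg[[k]] <- as.integer(v)
    }
  }
  if (is.numeric(cfg$maf_min) && (cfg$maf_min < 0 || cfg$maf_min > 0.5)) {
    errors <- c(errors, "`maf_min` must be in [0, 0.5]")
  }
  if (is.numeric(cfg$missing_max) && (cfg$missing_max < 0 || cfg$missing_max > 1)) {
    errors <- c(errors, "`missing_max` must be in [0, 1]")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg
}

#' Run the full demonstration pipeline
#'
#' Simulates an allotetraploid study system and runs every analysis stage on
#' it: within-genome synteny, per-anchor Ks and peak fitting, anchored
#' dating, subgenome phasing and TE landscapes, ancestral-group assignment
#' and quartet retention, karyotype bookkeeping, and population diversity
#' with a plastome pair. All artifacts are written under `cfg$outdir` and a
#' manifest of files with MD5 checksums is returned; re-running with the same
#' seed reproduces the checksums.
#'
#' @param seed RNG seed (overrides the config's).
#' @param config configuration (path, list or `NULL`), see
#'   [validate_config()].
#' @return invisibly, a list with `manifest` (data.frame file/md5) and
#'   `summary` (named list of headline numbers per stage).
#' @export
run_demo <- function(seed = NULL, config = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  sim <- stage("simulate", {
    s <- simulate_allotetraploid(
      n_proto = cfg$n_proto, genes_per_chrom = cfg$genes_per_chrom,
      n_families = cfg$n_families, codons_per_gene = cfg$codons_per_gene,
      ks_tau = cfg$ks_tau, ks_dup = cfg$ks_dup, ks_split = cfg$ks_split,
      loss_rate = cfg$loss_rate, family_bias = cfg$family_bias,
      te_div = cfg$te_div, te_copies = cfg$te_copies,
      seed = child_seed(cfg$seed, "simulate"))
    write_genome(s$genome, cfg$outdir, "tetraploid")
    write_ledger(s$ledger, cfg$outdir, "truth")
    s
  })
  g <- sim$genome

  blocks <- stage("synteny", {
    anchors <- find_homologs(g, mode = "sequence", min_score = cfg$min_score)
    b <- chain_collinear(anchors, max_gap = cfg$max_gap, min_block = cfg$min_block)
    write_synteny_tsv(dotplot_table(b), file.path(cfg$outdir, "dotplot.tsv"),
                      params = list(max_gap = cfg$max_gap, min_block = cfg$min_block))
    b
  })
  summary$n_blocks <- length(blocks)

  blocks <- stage("ks", {
    cds <- setNames(g$genes$cds, g$genes$id)
    b <- block_ks(blocks, cds)
    write_synteny_tsv(dotplot_table(b), file.path(cfg$outdir, "dotplot_ks.tsv"))
    b
  })
  peaks <- stage("ks_peaks", {
    p <- fit_ks_peaks(anchor_ks_values(blocks), ks_max = cfg$ks_max,
                      max_components = cfg$max_components,
                      seed = child_seed(cfg$seed, "peaks"))
    jsonlite::write_json(p$peaks, file.path(cfg$outdir, "ks_peaks.json"),
                         digits = NA, auto_unbox = TRUE)
    p
  })
  summary$ks_peaks <- peaks$peaks$location

  dates <- stage("date", {
    anchor <- nrow(peaks$peaks)  # oldest fitted peak anchors the calibration
    d <- anchored_dating(peaks, anchor, cfg$anchor_t_min, cfg$anchor_t_max)
    write.table(d, file.path(cfg$outdir, "dates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    d
  })
  summary$dates <- dates

  phased <- NULL
  if (isTRUE(cfg$run_phasing) && !is.null(g$chrom_seq)) {
    phased <- stage("phase", {
      prof <- kmer_profile(g$chrom_seq, k = cfg$kmer)
      ph <- phase_subgenomes(prof, fold_min = cfg$fold_min,
                             seed = child_seed(cfg$seed, "phase"))
      write.table(data.frame(chrom = names(ph$assignment),
                             subgenome = unname(ph$assignment)),
                  file.path(cfg$outdir, "phasing.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ph
    })
    summary$phasing_consistency <- phased$consistency
    land <- stage("te_landscape", {
      l <- te_divergence_landscape(g$te_copies, sim$ledger$te_consensus,
                                   phased$assignment, bin = cfg$te_bin)
      write.table(data.frame(subgenome = rep(rownames(l$counts), ncol(l$counts)),
                             bin = rep(colnames(l$counts), each = nrow(l$counts)),
                             count = as.vector(l$counts)),
                  file.path(cfg$outdir, "te_landscape.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      l
    })
    summary$te_bubble <- nonoverlap_interval(land, threshold = cfg$bubble_threshold)
  }

  retention <- stage("retention", {
    sg <- if (!is.null(phased)) phased$assignment else sim$ledger$subgenome
    ## screen out blocks older than the two recent polyploidizations so that
    ## loci are resolved at the homoeolog level
    recent <- structure(Filter(function(b) !is.na(b$median_ks) && b$median_ks < 1.0,
                               blocks), class = "synteny_blocks")
    grp <- assign_ancestral_groups(g, recent, subgenome = sg)
    rec <- quartet_retention(g, recent, grp)
    bg <- retention_ratio(rec, "ALL", "quartet")
    fam_rows <- lapply(sort(unique(rec$family)), function(f) {
      rr <- retention_ratio(rec, f, "quartet")
      p <- depletion_test(rr$retained, rr$total,
                          bg$retained - rr$retained, bg$total - rr$total)
      data.frame(family = f, retained = rr$retained, total = rr$total,
                 ratio = rr$ratio, p = p)
    })
    tab <- do.call(rbind, fam_rows)
    write.table(tab, file.path(cfg$outdir, "retention.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(groups = grp, records = rec, table = tab, background = bg)
  })
  summary$quartet_background <- retention$background$ratio

  karyo <- stage("karyotype", {
    C <- event_bookkeeping(cfg$n_proto, 2, 1, cfg$n_proto * 2 + 1 - cfg$n_proto %/% 2)
    data.frame(n = cfg$n_proto, k = 2, C_intermediate = C)
  })
  summary$karyotype_intermediate <- karyo$C_intermediate

  if (isTRUE(cfg$run_popdiv)) {
    pop <- stage("popdiv", {
      spec <- population_spec(n_samples = cfg$n_samples, theta = cfg$theta,
                              n_sites = cfg$n_sites, n_genotypes = cfg$n_genotypes,
                              missing_rate = cfg$missing_rate)
      ps <- simulate_population(g, spec, seed = child_seed(cfg$seed, "pop"))
      write_genotypes(ps$geno, cfg$outdir)
      flt <- filter_variants(ps$geno, cfg$maf_min, cfg$missing_max)
      pi_hat <- nucleotide_diversity(flt$matrix, n_sites_total = ps$n_sites_total)
      D <- pairwise_distance(flt$matrix)
      tr <- nj_tree(D)
      ape::write.tree(tr, file.path(cfg$outdir, "population.nwk"))
      pc <- pca_genotypes(flt$matrix)
      pl <- make_plastome_pair(cfg$plastome_bp, cfg$plastome_snps,
                               cfg$plastome_indels,
                               seed = child_seed(cfg$seed, "plastome"))
      writeLines(c(">haplotypeA", pl$a, ">haplotypeB", pl$b),
                 file.path(cfg$outdir, "plastomes.fasta"))
      pd <- compare_plastomes(pl$a, pl$b)
      list(pi = pi_hat, n_pass = sum(flt$log$status == "pass"),
           plastome = pd, pca = pc)
    })
    summary$pi <- pop$pi
    summary$plastome_snps <- pop$plastome$snp_count
    summary$plastome_indels <- pop$plastome$indel_count
  }

  files <- list.files(cfg$outdir, full.names = TRUE, recursive = TRUE)
  manifest <- data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  write.table(manifest, file.path(cfg$outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest, summary = summary))
}
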