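#' Configuration for the synthetic-data generators
#'
#' The defaults state the simulated world once, scaled down from a plant
#' genome so tests run in seconds: two chromosomes of 3 Mb with a 30%
#' pericentromeric band each, 1,200 genes of which 165 are NLRs and 59 of
#' those form the focal (regulator-controlled) subset, 2,000 TEs placed
#' with a 5x pericentromeric density excess and log-normal lengths, a
#' planted mean excess of 236 TE bp inside NLR gene space, NB counts with
#' dispersion 0.05 and log-uniform means, 3 RNA / 2 ChIP replicates per
#' genotype, and an 8-site minus-strand polyadenylation locus whose
#' read-through drops to 10% downstream of site 6 in the mutant.
#'
#' @param seed master integer seed; stage sub-streams are derived from it so
#'   regenerating one stage never perturbs another (keep below 2^31 - 10^6)
#' @param ... overrides for any default listed above; unknown keys error
#' @return a `synth_config` list
#' @export
synth_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_chrom = 2L,
    chrom_length = 3e6,
    pericentromere_fraction = 0.3,
    n_genes = 1200L,
    n_nlr = 165L,
    n_focal_nlr = 59L,
    gene_length_range = c(1000, 4000),
    n_te = 2000L,
    te_length_meanlog = log(400),
    te_length_sdlog = 0.8,
    te_length_bounds = c(50, 30000),
    te_peri_density_ratio = 5,
    planted_nlr_te_excess_bp = 236,
    planted_zero_fraction = 0.3,
    planted_te_length_meanlog = log(120),
    planted_te_length_sdlog = 0.6,
    n_samples_rna = 3L,
    n_samples_chip = 2L,
    nb_mean_range = c(20, 500),
    nb_dispersion = 0.05,
    libsize_sdlog = 0.15,
    rna_frac_up = 0.09,
    rna_frac_down = 0.07,
    rna_fold_change = 4,
    k9_frac_up = 0.068,
    k9_frac_down = 0.0015,
    k9_fold_change = 2,
    apa_n_sites = 8L,
    apa_drop_site = 6L,
    apa_drop_factor = 0.1,
    apa_wt_depth = 5,
    apa_site_spacing = c(30, 80),
    apa_n_replicates = 3L,
    apa_noise = "poisson",
    apa_noise_sd = 0,
    apa_total_reads = 2e7)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown synth_config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_nlr <= cfg$n_genes, cfg$n_focal_nlr <= cfg$n_nlr,
            cfg$pericentromere_fraction >= 0,
            cfg$pericentromere_fraction <= 1,
            cfg$apa_n_sites >= 2,
            cfg$apa_drop_site >= 2, cfg$apa_drop_site < cfg$apa_n_sites,
            cfg$apa_noise %in% c("none", "poisson"))
  structure(cfg, class = "synth_config")
}

# fixed offsets giving each generator its own RNG sub-stream
stage_seed <- function(cfg, stage) {
  off <- c(annotation = 11L, rna = 23L, chip_k9 = 37L, chip_h3 = 41L,
           input = 43L, apa = 53L)
  cfg$seed + off[[stage]] * 1e4
}

#' Generate a synthetic annotation with planted TE-NLR association
#'
#' Chromosomes are split into a central pericentromeric band
#' (`pericentromere_fraction` of the length) flanked by two arms. Genes are
#' placed uniformly; `n_nlr` random genes are flagged NLR (category "NLR"),
#' and `n_focal_nlr` of those focal. TEs are placed with per-compartment
#' density proportional to `te_peri_density_ratio` in the pericentromere and
#' log-normal lengths. Each NLR gene then receives additional small TE
#' placements inside the still-uncovered parts of its gene space until the
#' union TE bp inside the gene exceeds its pre-planting value by a
#' per-gene target with across-gene mean `planted_nlr_te_excess_bp`
#' (zero-inflated Gamma: a `planted_zero_fraction` share of NLRs carries no
#' intra-genic TE DNA, the rest proportionally more), so the planted excess
#' is exact at flank distance 0 and the background TE density field is
#' never edited.
#'
#' @param config a [synth_config()]
#' @return list: `annotation` ([annotation_set()]), `truth` (list with
#'   per-gene planted TE excess targets)
#' @export
generate_annotation <- function(config) {
  cfg <- config
  with_seed(stage_seed(cfg, "annotation"), {
    chroms <- paste0("Chr", seq_len(cfg$n_chrom))
    chrom_lengths <- stats::setNames(rep(cfg$chrom_length, cfg$n_chrom),
                                     chroms)
    # partition: arms flanking a central pericentromeric band
    peri_len <- round(cfg$chrom_length * cfg$pericentromere_fraction)
    arm_len <- floor((cfg$chrom_length - peri_len) / 2)
    partition <- do.call(rbind, lapply(chroms, function(ch) data.frame(
      chrom = ch,
      start = c(0, arm_len, arm_len + peri_len),
      end = c(arm_len, arm_len + peri_len, cfg$chrom_length),
      label = c("arm", "pericentromere", "arm"),
      stringsAsFactors = FALSE)))
    # genes
    glen <- round(stats::runif(cfg$n_genes, cfg$gene_length_range[1],
                               cfg$gene_length_range[2]))
    if (sum(glen) > 0.8 * cfg$n_chrom * cfg$chrom_length)
      stop("requested genes exceed chromosome capacity")
    gchrom <- sample(chroms, cfg$n_genes, replace = TRUE)
    # non-overlapping placement, uniform conditional on disjointness:
    # split each chromosome's free space into random gaps between genes
    gstart <- numeric(cfg$n_genes)
    for (ch in chroms) {
      idx <- which(gchrom == ch)
      if (!length(idx)) next
      free <- cfg$chrom_length - sum(glen[idx])
      if (free <= 0) stop("requested genes exceed chromosome capacity")
      gaps <- stats::rexp(length(idx) + 1)
      gaps <- floor(gaps / sum(gaps) * free)
      gstart[idx] <- cumsum(gaps[-length(gaps)]) +
        c(0, cumsum(glen[idx])[-length(idx)])
    }
    nlr_idx <- sample.int(cfg$n_genes, cfg$n_nlr)
    focal_idx <- sample(nlr_idx, cfg$n_focal_nlr)
    is_nlr <- seq_len(cfg$n_genes) %in% nlr_idx
    genes <- data.frame(
      id = sprintf("G%04d", seq_len(cfg$n_genes)),
      chrom = gchrom, start = gstart, end = gstart + glen,
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      is_nlr = is_nlr,
      is_focal = seq_len(cfg$n_genes) %in% focal_idx,
      categories = ifelse(is_nlr, "NLR", "other"),
      stringsAsFactors = FALSE)
    # background TE field: compartment chosen with density weighting
    seg <- partition
    seg$weight <- (seg$end - seg$start) *
      ifelse(seg$label == "pericentromere", cfg$te_peri_density_ratio, 1)
    seg_idx <- sample.int(nrow(seg), cfg$n_te, replace = TRUE,
                          prob = seg$weight)
    tlen <- round(pmin(pmax(stats::rlnorm(cfg$n_te, cfg$te_length_meanlog,
                                          cfg$te_length_sdlog),
                            cfg$te_length_bounds[1]),
                       cfg$te_length_bounds[2]))
    tstart <- floor(seg$start[seg_idx] + stats::runif(cfg$n_te) *
                      (seg$end[seg_idx] - seg$start[seg_idx] - 1))
    tend <- pmin(tstart + tlen, cfg$chrom_length)
    tes <- data.frame(
      id = sprintf("TE%05d", seq_len(cfg$n_te)),
      chrom = seg$chrom[seg_idx], start = tstart, end = tend,
      strand = sample(c("+", "-"), cfg$n_te, replace = TRUE),
      superfamily = sample(te_superfamilies, cfg$n_te, replace = TRUE,
                           prob = c(0.45, 0.15, 0.05, 0.25, 0.10)),
      stringsAsFactors = FALSE)
    # planted NLR-proximal excess: fill uncovered gene space to the target
    excess_target <- numeric(cfg$n_genes)
    planted <- list()
    if (cfg$planted_nlr_te_excess_bp > 0) {
      # zero-inflated per-gene targets: not every NLR carries TE DNA in its
      # gene space, but the across-gene mean equals the configured excess
      nz <- stats::runif(length(nlr_idx)) >= cfg$planted_zero_fraction
      scale_nz <- cfg$planted_nlr_te_excess_bp /
        (1 - cfg$planted_zero_fraction) / 2
      targets <- ifelse(nz, round(stats::rgamma(length(nlr_idx), shape = 2,
                                                scale = scale_nz)), 0)
      for (k in seq_along(nlr_idx)) {
        gi <- genes[nlr_idx[k], ]
        cur <- tes[tes$chrom == gi$chrom, c("chrom", "start", "end")]
        if (length(planted)) {
          pl <- do.call(rbind, planted)
          cur <- rbind(cur, pl[pl$chrom == gi$chrom, , drop = FALSE])
        }
        remaining <- min(targets[k],
                         (gi$end - gi$start) -
                           te_bp_in_window(gi, cur, 0, cfg$chrom_length))
        excess_target[nlr_idx[k]] <- remaining
        while (remaining > 0) {
          cov <- cur[cur$end > gi$start & cur$start < gi$end,
                     c("start", "end"), drop = FALSE]
          free <- uncovered_intervals(gi$start, gi$end, cov)
          flen <- free$end - free$start
          pick <- sample.int(nrow(free), 1, prob = flen)
          want <- min(remaining, flen[pick],
                      round(stats::rlnorm(1, cfg$planted_te_length_meanlog,
                                          cfg$planted_te_length_sdlog)))
          want <- max(want, 1)
          s0 <- free$start[pick] +
            floor(stats::runif(1) * (flen[pick] - want + 1))
          newte <- data.frame(chrom = gi$chrom, start = s0, end = s0 + want,
                              stringsAsFactors = FALSE)
          planted[[length(planted) + 1L]] <- newte
          cur <- rbind(cur, newte)
          remaining <- remaining - want
        }
      }
    }
    if (length(planted)) {
      pl <- do.call(rbind, planted)
      tes <- rbind(tes, data.frame(
        id = sprintf("TEP%04d", seq_len(nrow(pl))),
        chrom = pl$chrom, start = pl$start, end = pl$end,
        strand = "+",
        superfamily = sample(te_superfamilies, nrow(pl), replace = TRUE,
                             prob = c(0.45, 0.35, 0.05, 0.1, 0.05)),
        stringsAsFactors = FALSE))
    }
    genes <- genes[order(genes$chrom, genes$start, genes$id), ]
    tes <- tes[order(tes$chrom, tes$start, tes$id), ]
    rownames(genes) <- rownames(tes) <- NULL
    list(annotation = annotation_set(genes, tes, partition, chrom_lengths),
         truth = list(te_excess_target = stats::setNames(
           excess_target, sprintf("G%04d", seq_len(cfg$n_genes)))))
  })
}

# complement of `cov` within [start, end): the still-uncovered sub-intervals
uncovered_intervals <- function(start, end, cov) {
  if (is.null(cov) || nrow(cov) == 0L)
    return(data.frame(start = start, end = end))
  m <- merge_intervals(cov)
  m$start <- pmax(m$start, start); m$end <- pmin(m$end, end)
  m <- m[m$end > m$start, , drop = FALSE]
  if (nrow(m) == 0L) return(data.frame(start = start, end = end))
  s <- c(start, m$end); e <- c(m$start, end)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Generate an NB count matrix with planted differential features
#'
#' Features are all genes plus all TEs of the annotation. Counts are
#' negative-binomial with log-uniform baseline means, per-sample log-normal
#' library-size factors, and the configured fraction of features planted up
#' or down in the mutant by the configured fold change.
#'
#' @param config a [synth_config()]
#' @param annotation an [annotation_set()]
#' @param assay one of `"rna"`, `"chip_k9"`, `"chip_h3"`, `"input"`;
#'   only `rna` and `chip_k9` carry planted differences
#' @return list: `matrix` ([count_matrix()]), `truth` (data frame feature,
#'   status), `size_factors_true`
#' @export
generate_count_matrix <- function(config, annotation, assay) {
  cfg <- config
  stopifnot(assay %in% c("rna", "chip_k9", "chip_h3", "input"))
  n <- if (assay == "rna") cfg$n_samples_rna else cfg$n_samples_chip
  feats <- c(annotation$genes$id, annotation$tes$id)
  with_seed(stage_seed(cfg, if (assay %in% c("rna", "chip_k9")) assay
                       else if (assay == "chip_h3") "chip_h3" else "input"), {
    nf <- length(feats)
    mu <- exp(stats::runif(nf, log(cfg$nb_mean_range[1]),
                           log(cfg$nb_mean_range[2])))
    fr_up <- switch(assay, rna = cfg$rna_frac_up, chip_k9 = cfg$k9_frac_up, 0)
    fr_dn <- switch(assay, rna = cfg$rna_frac_down,
                    chip_k9 = cfg$k9_frac_down, 0)
    fc <- switch(assay, rna = cfg$rna_fold_change,
                 chip_k9 = cfg$k9_fold_change, 1)
    status <- rep("ns", nf)
    n_up <- round(fr_up * nf); n_dn <- round(fr_dn * nf)
    pick <- sample.int(nf, n_up + n_dn)
    status[pick[seq_len(n_up)]] <- "up"
    if (n_dn > 0) status[pick[n_up + seq_len(n_dn)]] <- "down"
    fold <- ifelse(status == "up", fc, ifelse(status == "down", 1 / fc, 1))
    sf <- stats::rlnorm(2 * n, 0, cfg$libsize_sdlog)
    samples <- data.frame(
      sample = paste0(rep(c("WT", "mut"), each = n), "_", assay, "_r",
                      rep(seq_len(n), 2)),
      genotype = rep(c("WT", "mutant"), each = n),
      assay = assay, replicate = rep(seq_len(n), 2),
      stringsAsFactors = FALSE)
    cts <- matrix(0L, nf, 2 * n,
                  dimnames = list(feats, samples$sample))
    for (j in seq_len(2 * n)) {
      mu_j <- mu * sf[j] *
        (if (samples$genotype[j] == "mutant") fold else 1)
      cts[, j] <- stats::rnbinom(nf, mu = mu_j, size = 1 / cfg$nb_dispersion)
    }
    list(matrix = count_matrix(cts, samples),
         truth = data.frame(feature = feats, status = status,
                            stringsAsFactors = FALSE),
         size_factors_true = stats::setNames(sf, samples$sample))
  })
}

#' Generate the alternative-polyadenylation dataset
#'
#' Emulates a minus-strand gene with `apa_n_sites` polyadenylation sites at
#' descending genomic coordinates (numbered 1..n in transcript order, as
#' read off the transcript). WT coverage reads through the whole span at
#' `apa_wt_depth`; mutant coverage downstream (in transcript direction,
#' i.e. at lower genomic coordinates) of the planted drop site is reduced
#' to `apa_drop_factor` of WT. Per-base Poisson sampling (plus optional
#' log-normal multiplicative noise `apa_noise_sd`) gives replicate tracks;
#' `apa_noise = "none"` emits the exact expected depth instead.
#'
#' @param config a [synth_config()]
#' @return list: `tracks` (named list of [coverage_track()] per sample),
#'   `samples` (sample sheet), `sites` ([polya_site_set()]), `truth`
#'   (drop site and factor)
#' @export
generate_apa_dataset <- function(config) {
  cfg <- config
  with_seed(stage_seed(cfg, "apa"), {
    spacing <- round(stats::runif(cfg$apa_n_sites - 1,
                                  cfg$apa_site_spacing[1],
                                  cfg$apa_site_spacing[2]))
    # minus strand: transcript order = descending genomic coordinate
    top <- 9000
    coords <- top - c(0, cumsum(spacing))
    span_start <- min(coords) - 100
    span_end <- max(coords) + 100
    sites <- polya_site_set("APA1", "ChrA", "-", coords)
    nb <- span_end - span_start
    pos <- span_start + seq_len(nb) - 1L
    drop_coord <- coords[cfg$apa_drop_site]
    lam_wt <- rep(cfg$apa_wt_depth, nb)
    lam_mut <- ifelse(pos < drop_coord,
                      cfg$apa_wt_depth * cfg$apa_drop_factor,
                      cfg$apa_wt_depth)
    samples <- data.frame(
      sample = paste0(rep(c("WT", "mut"), each = cfg$apa_n_replicates),
                      "_apa_r", rep(seq_len(cfg$apa_n_replicates), 2)),
      genotype = rep(c("WT", "mutant"), each = cfg$apa_n_replicates),
      assay = "rna", replicate = rep(seq_len(cfg$apa_n_replicates), 2),
      stringsAsFactors = FALSE)
    tracks <- lapply(seq_len(nrow(samples)), function(j) {
      lam <- if (samples$genotype[j] == "WT") lam_wt else lam_mut
      vals <- switch(cfg$apa_noise,
                     none = lam,
                     poisson = {
                       v <- stats::rpois(nb, lam)
                       if (cfg$apa_noise_sd > 0)
                         v <- v * stats::rlnorm(nb, 0, cfg$apa_noise_sd)
                       v
                     })
      coverage_track("ChrA", span_start, vals,
                     total_reads = cfg$apa_total_reads)
    })
    names(tracks) <- samples$sample
    list(tracks = tracks, samples = samples, sites = sites,
         truth = list(drop_site = cfg$apa_drop_site,
                      drop_factor = cfg$apa_drop_factor))
  })
}
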