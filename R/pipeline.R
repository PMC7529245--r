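#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates: synthetic data generation, RNA and H3K9me2 differential
#' calling, replicate QC, joint direction classification, category balance
#' tests, TE-NLR association (curve + nearest-distance test), compartment x
#' superfamily enrichment, and the polyadenylation contrast. All stage
#' tables are written as TSV under `out_dir` together with `summary.tsv`
#' (headline quantities) and `manifest.json` (seed, config hash, package
#' version). Byte-identical for a fixed config and seed.
#'
#' @param config a [synth_config()]; its `seed` drives every stage
#' @param out_dir output directory, created if needed
#' @param padj_max,fc_min differential calling thresholds
#' @param n_resample resampling iterations for the association and
#'   enrichment nulls (kept modest by default for runtime)
#' @param max_d,step association-curve flank grid
#' @return invisibly, a list with all in-memory stage results
#' @export
run_pipeline <- function(config, out_dir, padj_max = 0.05, fc_min = 1.2,
                         n_resample = 200, max_d = 1000, step = 100) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }
  tsv <- function(df, name) {
    utils::write.table(format_num_df(df), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sim <- stage("simulate", {
    ann <- generate_annotation(config)
    rna <- generate_count_matrix(config, ann$annotation, "rna")
    k9 <- generate_count_matrix(config, ann$annotation, "chip_k9")
    apa <- generate_apa_dataset(config)
    write_annotation_gff3(ann$annotation,
                          file.path(out_dir, "annotation.gff3"))
    write_partition_bed(ann$annotation$partition,
                        file.path(out_dir, "partition.bed"))
    write_count_matrix(rna$matrix, file.path(out_dir, "rna_counts.tsv"),
                       file.path(out_dir, "rna_samples.tsv"))
    write_count_matrix(k9$matrix, file.path(out_dir, "k9_counts.tsv"),
                       file.path(out_dir, "k9_samples.tsv"))
    tsv(rna$truth, "rna_truth.tsv")
    tsv(k9$truth, "k9_truth.tsv")
    write_polya_sites(apa$sites, file.path(out_dir, "polya_sites.tsv"))
    for (nm in names(apa$tracks))
      write_bedgraph(apa$tracks[[nm]],
                     file.path(out_dir, paste0("apa_", nm, ".bedgraph")))
    list(ann = ann, rna = rna, k9 = k9, apa = apa)
  })

  diff_one <- function(gen, label) {
    mat <- filter_expressed(gen$matrix)
    sf <- estimate_size_factors(mat)
    res <- call_differential(nb_wald_test(mat, sf),
                             padj_max = padj_max, fc_min = fc_min)
    write_diff_result(res, file.path(out_dir, paste0(label, "_diff.tsv")))
    res
  }
  rna_res <- stage("diff-rna", diff_one(sim$rna, "rna"))
  k9_res <- stage("diff-k9", diff_one(sim$k9, "k9"))

  qc <- stage("qc", {
    q <- rbind(replicate_spearman(sim$rna$matrix),
               replicate_spearman(sim$k9$matrix))
    tsv(q, "qc_spearman.tsv")
    q
  })

  joint <- stage("joint", {
    j <- classify_joint(rna_res, k9_res)
    qd <- as.data.frame(as.table(j$quadrants), stringsAsFactors = FALSE)
    names(qd) <- c("rna_call", "k9_call", "n")
    tsv(qd, "joint_quadrants.tsv")
    j
  })

  genes <- sim$ann$annotation$genes
  balance <- stage("balance", {
    cats <- data.frame(feature = genes$id, category = genes$categories,
                       stringsAsFactors = FALSE)
    b <- category_balance(rna_res, cats)
    tsv(b, "balance.tsv")
    b
  })

  assoc <- stage("te-assoc", {
    tes <- sim$ann$annotation$tes
    cl <- sim$ann$annotation$chrom_lengths
    ac <- association_curve(genes[genes$is_nlr, ], genes[!genes$is_nlr, ],
                            tes, cl, max_d = max_d, step = step,
                            n_resample = n_resample, seed = config$seed)
    tsv(ac$curve, "association_curve.tsv")
    nd <- nearest_distance_ttest(genes[genes$is_focal, ],
                                 genes[genes$is_nlr & !genes$is_focal, ],
                                 tes)
    tsv(data.frame(mean_focal = nd$mean_a, mean_other = nd$mean_b,
                   p = nd$p, n_focal = nd$n_a, n_other = nd$n_b),
        "nearest_te.tsv")
    list(curve = ac, nearest = nd)
  })

  enrich <- stage("enrich", {
    tes <- sim$ann$annotation$tes
    focal_ids <- k9_res$feature[k9_res$call != "ns"]
    focal_tes <- tes[tes$id %in% focal_ids, , drop = FALSE]
    et <- enrichment_table(focal_tes, tes, sim$ann$annotation$partition,
                           n_random = n_resample, seed = config$seed)
    tsv(et, "enrichment.tsv")
    et
  })

  apa_res <- stage("apa", {
    apa <- sim$apa
    cpm <- lapply(apa$tracks, coverage_cpm)
    sc <- segment_counts(apa$tracks, apa$sites)
    du <- differential_segment_usage(sc$counts, apa$samples,
                                     padj_max = padj_max, fc_min = fc_min)
    tsv(cbind(sc$segments, du[, c("log2fc", "p", "padj", "call")]),
        "apa_segments.tsv")
    wt <- combine_and_subtract(cpm[apa$samples$genotype == "WT"])
    mut <- combine_and_subtract(cpm[apa$samples$genotype == "mutant"])
    drop <- detect_drop_site(wt, mut, apa$sites)
    list(segments = sc, usage = du, drop_site = drop)
  })

  summary_df <- stage("report", {
    s <- write_report(list(rna = rna_res, k9 = k9_res, balance = balance,
                           assoc = assoc, apa = apa_res))
    tsv(s, "summary.tsv")
    s
  })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   package = "k9balance",
                   version = as.character(utils::packageVersion("k9balance")),
                   thresholds = list(padj_max = padj_max, fc_min = fc_min),
                   n_resample = n_resample, max_d = max_d, step = step)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))

  invisible(list(sim = sim, rna = rna_res, k9 = k9_res, qc = qc,
                 joint = joint, balance = balance, assoc = assoc,
                 enrich = enrich, apa = apa_res, summary = summary_df))
}

#' Consolidated headline summary
#'
#' One row per headline quantity: up/down counts and percentage split for
#' RNA, up/down counts for K9, the NLR balance chi-square p, the focal vs
#' background mean TE-bp difference at distance 0, and the detected
#' polyadenylation drop site.
#'
#' @param stage_outputs named list with any of `rna`, `k9`, `balance`,
#'   `assoc`, `apa` stage results (as produced inside [run_pipeline()])
#' @return data frame: `metric`, `value`
#' @export
write_report <- function(stage_outputs) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(metric = metric,
                                             value = value,
                                             stringsAsFactors = FALSE)
  if (!is.null(stage_outputs$rna)) {
    up <- sum(stage_outputs$rna$call == "up")
    dn <- sum(stage_outputs$rna$call == "down")
    add("rna_n_up", up); add("rna_n_down", dn)
    if (up + dn > 0) {
      pr <- proportion_summary(up, dn)
      add("rna_percent_up", pr$percent_up)
      add("rna_percent_down", pr$percent_down)
    }
  }
  if (!is.null(stage_outputs$k9)) {
    add("k9_n_up", sum(stage_outputs$k9$call == "up"))
    add("k9_n_down", sum(stage_outputs$k9$call == "down"))
  }
  if (!is.null(stage_outputs$balance)) {
    b <- stage_outputs$balance
    nlr <- b[b$category == "NLR", , drop = FALSE]
    if (nrow(nlr) == 1L) {
      add("nlr_up", nlr$up); add("nlr_down", nlr$down)
      add("nlr_balance_chisq_p", nlr$p)
    }
  }
  if (!is.null(stage_outputs$assoc)) {
    cv <- stage_outputs$assoc$curve$curve
    add("te_bp_diff_d0", cv$mean_focal[1] - cv$mean_background[1])
    add("nearest_te_p", stage_outputs$assoc$nearest$p)
  }
  if (!is.null(stage_outputs$apa)) {
    add("apa_drop_site", as.numeric(stage_outputs$apa$drop_site))
  }
  if (!length(rows))
    return(data.frame(metric = character(0), value = numeric(0)))
  do.call(rbind, rows)
}
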