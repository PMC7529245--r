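#' Count matrix with sample metadata
#'
#' Container for per-feature read counts (genes or TEs in rows) across
#' sequencing libraries, with a sample sheet describing genotype
#' (`WT`/`mutant`), assay (`rna`, `chip_k9`, `chip_h3`, `input`) and
#' replicate index.
#'
#' @param counts non-negative numeric matrix, features x samples, with
#'   rownames (feature ids) and colnames (sample ids)
#' @param samples data frame with columns `sample`, `genotype`, `assay`,
#'   `replicate`; rows match `colnames(counts)`
#' @return an object of class `count_matrix`
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)),
            all(c("sample", "genotype", "assay", "replicate") %in%
                  names(samples)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!identical(colnames(counts), as.character(samples$sample)))
    stop("sample sheet rows must match count matrix columns")
  if (!all(samples$genotype %in% c("WT", "mutant")))
    stop("genotype must be 'WT' or 'mutant'")
  structure(list(counts = counts, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$assay), collapse = ", ")))
  invisible(x)
}

#' Remove non-expressed features
#'
#' Drops features whose value is below `min_value` in every library, i.e.
#' keeps a feature when at least one library reaches the threshold. Feature
#' order is preserved.
#'
#' @param mat a [count_matrix()]
#' @param min_value minimum value required in at least one library
#' @return filtered [count_matrix()]
#' @export
filter_expressed <- function(mat, min_value = 1) {
  keep <- apply(mat$counts, 1, function(r) any(r >= min_value))
  count_matrix(mat$counts[keep, , drop = FALSE], mat$samples)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (restricted
#' to rows positive in every sample) of the ratio of the count to the
#' feature's geometric mean across samples.
#'
#' @param mat a [count_matrix()]
#' @return named numeric vector of positive size factors
#' @export
estimate_size_factors <- function(mat) {
  cts <- mat$counts
  pos <- rowSums(cts > 0) == ncol(cts)
  if (!any(pos))
    stop("no feature with positive counts in all samples; ",
         "prefilter with filter_expressed() or check the input")
  lg <- log(cts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - geo)))
  stats::setNames(sf, colnames(cts))
}

#' Negative-binomial Wald test between genotypes
#'
#' Per feature: counts are divided by their size factors, group means are
#' formed with a 0.5 pseudocount, and the mutant/WT log2 fold change is
#' tested with a Wald statistic under the NB variance model
#' `Var(K) = mu + alpha * mu^2`, two-sided normal p.
#'
#' Dispersion (`alpha`) estimation, `dispersion` argument:
#' \describe{
#'   \item{`"pooled"` (default)}{one common dispersion from a moment
#'     regression of the per-feature excess variance `s2 - mu` on `mu^2`
#'     across all features (within-genotype variances, pooled over the two
#'     groups). With 2-3 replicates per group, per-feature estimates carry
#'     only 2-4 degrees of freedom and a normal-reference Wald test on them
#'     is badly anticonservative; pooling restores calibration at the cost
#'     of assuming the features share a dispersion scale.}
#'   \item{`"per-feature"`}{the plain method-of-moments estimate
#'     `(s2 - mu) / mu^2` per feature.}
#' }
#' Either estimate is floored at `1e-8`.
#'
#' @param mat a [count_matrix()] containing both genotypes of one assay
#' @param size_factors named size factors from [estimate_size_factors()]
#' @param dispersion `"pooled"` or `"per-feature"`
#' @return data frame: `feature`, `baseMean`, `log2fc`, `p`, `dispersion`
#' @export
nb_wald_test <- function(mat, size_factors = estimate_size_factors(mat),
                         dispersion = c("pooled", "per-feature")) {
  dispersion <- match.arg(dispersion)
  g <- mat$samples$genotype
  if (!all(c("WT", "mutant") %in% g))
    stop("both genotypes must be present")
  if (min(table(g)) < 2L)
    stop("need >= 2 samples per genotype")
  nc <- sweep(mat$counts, 2, size_factors[colnames(mat$counts)], "/")
  wt <- g == "WT"; mut <- g == "mutant"
  n1 <- sum(wt); n2 <- sum(mut)
  m_wt <- rowMeans(nc[, wt, drop = FALSE])
  m_mut <- rowMeans(nc[, mut, drop = FALSE])
  v_wt <- apply(nc[, wt, drop = FALSE], 1, stats::var)
  v_mut <- apply(nc[, mut, drop = FALSE], 1, stats::var)
  s2 <- (v_wt * (n1 - 1) + v_mut * (n2 - 1)) / (n1 + n2 - 2)
  mu <- (m_wt + m_mut) / 2
  alpha <- if (dispersion == "pooled") {
    rep(max(sum((s2 - mu) * mu^2) / sum(mu^4), 1e-8), length(mu))
  } else {
    pmax((s2 - mu) / pmax(mu, 1e-8)^2, 1e-8)
  }
  m_wt_p <- m_wt + 0.5
  m_mut_p <- m_mut + 0.5
  log2fc <- log2(m_mut_p / m_wt_p)
  # delta method on log2(mean): Var(mean)/ (mean^2 ln(2)^2) per group
  inv_sf_wt <- mean(1 / size_factors[colnames(mat$counts)][wt])
  inv_sf_mut <- mean(1 / size_factors[colnames(mat$counts)][mut])
  var_wt <- (m_wt_p * inv_sf_wt + alpha * m_wt_p^2) / n1
  var_mut <- (m_mut_p * inv_sf_mut + alpha * m_mut_p^2) / n2
  se <- sqrt(var_wt / m_wt_p^2 + var_mut / m_mut_p^2) / log(2)
  p <- 2 * stats::pnorm(-abs(log2fc / se))
  p[se == 0] <- 1
  data.frame(feature = rownames(mat$counts),
             baseMean = mu, log2fc = log2fc, p = p,
             dispersion = alpha,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: order p ascending, scale by m/rank, take the running minimum
#' from the largest rank down, cap at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`
#' @return adjusted p-values in the original order
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(adj, 1)[order(o)]
}

#' Call up / down / ns from test results
#'
#' A feature is `up` when `padj <= padj_max` and its fold change (mutant over
#' WT) is at least `fc_min`; `down` symmetrically; otherwise `ns`. These are
#' the published thresholds (adjusted p 0.05, 1.2-fold).
#'
#' @param results data frame from [nb_wald_test()] (needs `log2fc`, `p`)
#' @param padj_max adjusted-p threshold
#' @param fc_min minimum fold change, must exceed 1
#' @return `diff_result` data frame: `feature`, `baseMean`, `log2fc`, `p`,
#'   `padj`, `call`
#' @export
call_differential <- function(results, padj_max = 0.05, fc_min = 1.2) {
  if (fc_min <= 1) stop("fc_min must exceed 1")
  padj <- bh_adjust(results$p)
  lfc_min <- log2(fc_min)
  call <- ifelse(padj <= padj_max & results$log2fc >= lfc_min, "up",
                 ifelse(padj <= padj_max & results$log2fc <= -lfc_min,
                        "down", "ns"))
  out <- data.frame(feature = results$feature,
                    baseMean = results$baseMean,
                    log2fc = results$log2fc,
                    p = results$p, padj = padj, call = call,
                    stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

#' Spearman correlation between biological replicates
#'
#' For every within-condition (genotype + assay) replicate pair, the Spearman
#' rank correlation of the count profiles, with average ranks for ties.
#' Constant profiles give `NA` for that pair.
#'
#' @param mat a [count_matrix()]
#' @return data frame: `genotype`, `assay`, `rep_a`, `rep_b`, `spearman_r`
#' @export
replicate_spearman <- function(mat) {
  sm <- mat$samples
  out <- list()
  for (key in unique(paste(sm$genotype, sm$assay))) {
    idx <- which(paste(sm$genotype, sm$assay) == key)
    if (length(idx) < 2L) next
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i >= j) next
      a <- mat$counts[, idx[i]]; b <- mat$counts[, idx[j]]
      r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
        stats::cor(a, b, method = "spearman")
      out[[length(out) + 1L]] <- data.frame(
        genotype = sm$genotype[idx[i]], assay = sm$assay[idx[i]],
        rep_a = sm$sample[idx[i]], rep_b = sm$sample[idx[j]],
        spearman_r = r, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    stop("no condition has >= 2 replicates")
  do.call(rbind, out)
}

#' H3K9me2 level relative to histone H3
#'
#' Depth-normalizes each library to counts per million, sums replicates
#' within genotype, and forms the per-feature log ratio
#' `log2((K9 + 0.5) / (H3 + 0.5))` for each genotype. The genotypes are then
#' compared across features with a two-sided Wilcoxon signed-rank test
#' (zero differences dropped; exact distribution up to n = 25 without ties,
#' normal approximation with tie correction otherwise).
#'
#' @param k9_mat,h3_mat [count_matrix()] objects sharing the feature set,
#'   each containing both genotypes
#' @return list: `log_ratio` (data frame feature, WT, mutant, delta),
#'   `p` (signed-rank p), `n_used` (non-zero differences)
#' @export
k9_relative_summary <- function(k9_mat, h3_mat) {
  if (!identical(rownames(k9_mat$counts), rownames(h3_mat$counts)))
    stop("K9 and H3 matrices must share an identical feature set")
  cpm <- function(m) sweep(m, 2, colSums(m), "/") * 1e6
  geno_sum <- function(mat) {
    m <- cpm(mat$counts)
    vapply(c("WT", "mutant"), function(g)
      rowSums(m[, mat$samples$genotype == g, drop = FALSE]),
      numeric(nrow(m)))
  }
  k9 <- geno_sum(k9_mat); h3 <- geno_sum(h3_mat)
  lr <- log2((k9 + 0.5) / (h3 + 0.5))
  delta <- lr[, "mutant"] - lr[, "WT"]
  p <- signed_rank_p(delta)
  list(log_ratio = data.frame(feature = rownames(k9_mat$counts),
                              WT = lr[, "WT"], mutant = lr[, "mutant"],
                              delta = delta, stringsAsFactors = FALSE),
       p = p, n_used = sum(delta != 0))
}

# two-sided Wilcoxon signed-rank p for a vector of paired differences;
# zeros dropped (Wilcoxon's convention); exact null distribution when
# n <= 25 and |d| has no ties, else normal approximation with tie correction
signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L && !anyDuplicated(abs(d))) {
    pl <- stats::psignrank(w, n)
    pg <- stats::psignrank(w - 1, n, lower.tail = FALSE)
    return(min(1, 2 * min(pl, pg)))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Write / read differential results as TSV
#'
#' Stable column order: feature, baseMean, log2fc, p, padj, call.
#'
#' @param res a `diff_result` data frame
#' @param path output TSV
#' @export
write_diff_result <- function(res, path) {
  cols <- c("feature", "baseMean", "log2fc", "p", "padj", "call")
  utils::write.table(format_num_df(res[, cols]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diff_result
#' @param path TSV written by [write_diff_result()]
#' @export
read_diff_result <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("diff_result", "data.frame")
  out
}

# deterministic numeric formatting for text outputs
format_num_df <- function(df, digits = 10) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = digits, format = "g")
  df
}

#' Read a count matrix and its sample sheet
#'
#' The counts TSV has feature ids in the first column and sample ids as the
#' header; the sample sheet TSV has columns `sample`, `genotype`, `assay`,
#' `replicate`.
#'
#' @param counts_path counts TSV
#' @param samples_path sample sheet TSV
#' @return a [count_matrix()]
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  tab <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  sm <- utils::read.table(samples_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  count_matrix(as.matrix(tab), sm[match(colnames(tab), sm$sample), ,
                                  drop = FALSE])
}

#' @rdname read_count_matrix
#' @param mat a [count_matrix()]
#' @export
write_count_matrix <- function(mat, counts_path, samples_path) {
  df <- data.frame(feature = rownames(mat$counts), mat$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mat$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}
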