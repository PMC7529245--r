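# shared fixtures and per-base oracles (all coordinates half-open)

# per-base membership oracle: set of covered base offsets
oracle_bases <- function(df) {
  if (nrow(df) == 0L) return(integer(0))
  unique(unlist(lapply(seq_len(nrow(df)), function(i)
    seq.int(df$start[i], df$end[i] - 1L))))
}

oracle_union_length <- function(df) length(oracle_bases(df))

oracle_overlap_bp <- function(a, b) {
  if (!is.null(a$chrom) && !is.null(b$chrom) && a$chrom[1] != b$chrom[1])
    return(0L)
  length(intersect(seq.int(a$start[1], a$end[1] - 1L),
                   seq.int(b$start[1], b$end[1] - 1L)))
}

random_intervals <- function(n, max_coord = 1e4, chrom = "Chr1") {
  s <- sample.int(max_coord - 2L, n, replace = TRUE)
  len <- sample.int(200L, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = pmin(s + len, max_coord))
}

# minimal hand-built annotation: 2 genes (1 NLR) + 2 TEs on one chromosome
tiny_annotation <- function() {
  genes <- data.frame(
    id = c("g1", "g2"), chrom = "Chr1",
    start = c(99, 500), end = c(200, 700), strand = c("+", "-"),
    is_nlr = c(TRUE, FALSE), is_focal = c(TRUE, FALSE),
    categories = c("NLR", "other"), stringsAsFactors = FALSE)
  tes <- data.frame(
    id = c("t1", "t2"), chrom = "Chr1",
    start = c(249, 760), end = c(300, 900), strand = "+",
    superfamily = c("Gypsy", "Copia"), stringsAsFactors = FALSE)
  partition <- data.frame(chrom = "Chr1", start = c(0, 400, 800),
                          end = c(400, 800, 1000),
                          label = c("arm", "pericentromere", "arm"),
                          stringsAsFactors = FALSE)
  annotation_set(genes, tes, partition, c(Chr1 = 1000))
}

# count matrix from a plain matrix, default 2 genotypes x n reps of one assay
tiny_count_matrix <- function(m, assay = "rna") {
  n <- ncol(m) / 2
  samples <- data.frame(
    sample = paste0(rep(c("WT", "mut"), each = n), "_r", rep(seq_len(n), 2)),
    genotype = rep(c("WT", "mutant"), each = n),
    assay = assay, replicate = rep(seq_len(n), 2),
    stringsAsFactors = FALSE)
  colnames(m) <- samples$sample
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  count_matrix(m, samples)
}

# brute-force BH by its step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# two-sided Fisher exact p by hypergeometric enumeration over one margin
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  xs <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(xs, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided signed-rank p by enumerating all sign assignments
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
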