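#' Per-base coverage track
#'
#' Values over a contiguous half-open interval `[start, start + length(values))`
#' of one chromosome, plus the total mapped reads of the source library
#' (needed for counts-per-million normalization).
#'
#' @param chrom chromosome name
#' @param start 0-based start offset of the first value
#' @param values non-negative numeric vector, one value per base
#' @param total_reads total mapped reads of the library (> 0 for CPM)
#' @return an object of class `coverage_track`
#' @export
coverage_track <- function(chrom, start, values, total_reads = NA_real_) {
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(list(chrom = chrom, start = start, values = as.numeric(values),
                 total_reads = total_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %s:%d-%d (%d bases)\n", x$chrom, x$start,
              x$start + length(x$values), length(x$values)))
  invisible(x)
}

#' Normalize a track to coverage per million mapped reads
#'
#' @param track a [coverage_track()]
#' @return the track with each value scaled by `1e6 / total_reads`
#' @export
coverage_cpm <- function(track) {
  if (is.na(track$total_reads) || track$total_reads <= 0)
    stop("total mapped reads must be positive for CPM normalization")
  coverage_track(track$chrom, track$start,
                 track$values * 1e6 / track$total_reads, total_reads = 1e6)
}

#' Combine replicate tracks and subtract background
#'
#' Averages the (already CPM-normalized) signal replicates, averages the
#' background replicates, subtracts per base, and clamps negative values to
#' zero. With no background tracks the replicate mean is returned.
#'
#' @param tracks_signal list of [coverage_track()] sharing one interval
#' @param tracks_background optional list of background (input) tracks on
#'   the same interval
#' @return a combined [coverage_track()]
#' @export
combine_and_subtract <- function(tracks_signal, tracks_background = list()) {
  all_tr <- c(tracks_signal, tracks_background)
  ref <- all_tr[[1]]
  same <- vapply(all_tr, function(t)
    t$chrom == ref$chrom && t$start == ref$start &&
      length(t$values) == length(ref$values), logical(1))
  if (!all(same)) stop("tracks must share one interval")
  sig <- rowMeans(vapply(tracks_signal, `[[`, numeric(length(ref$values)),
                         "values"))
  if (length(tracks_background)) {
    bg <- rowMeans(vapply(tracks_background, `[[`,
                          numeric(length(ref$values)), "values"))
    sig <- pmax(sig - bg, 0)
  }
  coverage_track(ref$chrom, ref$start, sig, total_reads = 1e6)
}

#' Ordered polyadenylation sites of one gene
#'
#' Sites are numbered 1..n in transcript order: genomic coordinates must be
#' strictly increasing on the plus strand and strictly decreasing on the
#' minus strand (the proximal site carries the lowest transcript number).
#' Coordinates are 0-based positions.
#'
#' @param gene_id gene identifier
#' @param chrom chromosome
#' @param strand `"+"` or `"-"`
#' @param coords genomic coordinates in transcript order
#' @return an object of class `polya_site_set`
#' @export
polya_site_set <- function(gene_id, chrom, strand, coords) {
  if (length(coords) < 2) stop("need at least 2 polyadenylation sites")
  d <- diff(coords)
  if (strand == "+" && !all(d > 0))
    stop("plus-strand site coordinates must be strictly increasing")
  if (strand == "-" && !all(d < 0))
    stop("minus-strand site coordinates must be strictly decreasing")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 coords = as.numeric(coords)),
            class = "polya_site_set")
}

# genomic half-open interval of transcript-order segment k (site k -> k+1);
# the boundary base belongs to the downstream (higher k) side
segment_interval <- function(sites, k) {
  a <- sites$coords[k]; b <- sites$coords[k + 1]
  if (sites$strand == "+") c(start = a, end = b) else c(start = b, end = a)
}

#' Read counts in inter-site segments
#'
#' Sums track values over the genomic interval between each consecutive
#' site pair (in transcript order), for each sample. Segments tile the span
#' between the first and last site, so per sample the segment counts add up
#' to the full-span count.
#'
#' @param tracks named list of [coverage_track()] per sample
#' @param sites a [polya_site_set()]
#' @return list: `counts` (matrix segments x samples), `segments` (data
#'   frame segment, start, end)
#' @export
segment_counts <- function(tracks, sites) {
  n_seg <- length(sites$coords) - 1
  segs <- t(vapply(seq_len(n_seg), function(k) segment_interval(sites, k),
                   numeric(2)))
  seg_df <- data.frame(segment = paste0("s", seq_len(n_seg), "_",
                                        seq_len(n_seg) + 1),
                       start = segs[, "start"], end = segs[, "end"],
                       stringsAsFactors = FALSE)
  cts <- vapply(tracks, function(tr) {
    if (tr$chrom != sites$chrom)
      stop("track chromosome does not match the site set")
    vapply(seq_len(n_seg), function(k) {
      idx <- seq.int(segs[k, "start"] - tr$start + 1,
                     segs[k, "end"] - tr$start)
      if (any(idx < 1) || any(idx > length(tr$values)))
        stop("segment outside the track interval")
      sum(tr$values[idx])
    }, numeric(1))
  }, numeric(n_seg))
  cts <- matrix(cts, nrow = n_seg,
                dimnames = list(seg_df$segment, names(tracks)))
  list(counts = cts, segments = seg_df)
}

#' Differential segment usage between genotypes
#'
#' Applies the package's NB Wald test and BH adjustment to the segment x
#' sample count table; segments play the role of features. Counts are
#' rounded to integers; size factors default to 1 (segment counts of one
#' locus carry no library-composition information).
#'
#' @param seg_counts matrix segments x samples from [segment_counts()]
#' @param samples sample sheet (`sample`, `genotype`, `assay`, `replicate`)
#' @param padj_max,fc_min calling thresholds, as in [call_differential()]
#' @return a `diff_result` data frame, one row per segment
#' @export
differential_segment_usage <- function(seg_counts, samples,
                                       padj_max = 0.05, fc_min = 1.2) {
  if (min(table(samples$genotype)) < 2L)
    stop("need >= 2 replicates per genotype")
  mat <- count_matrix(round(seg_counts[, samples$sample, drop = FALSE]),
                      samples)
  sf <- stats::setNames(rep(1, nrow(samples)), samples$sample)
  res <- nb_wald_test(mat, sf)
  call_differential(res, padj_max = padj_max, fc_min = fc_min)
}

#' Detect the polyadenylation site where mutant read-through drops
#'
#' For each candidate site k (2 .. n-1 in transcript order) the
#' mutant-to-WT mean-coverage ratio is computed over the segment immediately
#' downstream of the site (k to k+1) and over the segment immediately
#' upstream (k-1 to k); the site is called when the downstream ratio falls
#' below `ratio_threshold` times the upstream ratio. The smallest
#' qualifying transcript-order index is returned, `NA` if none. Invariant
#' to global rescaling of either track.
#'
#' @param wt_track,mut_track combined, CPM-normalized [coverage_track()]s
#' @param sites a [polya_site_set()]
#' @param ratio_threshold drop factor threshold in (0, 1)
#' @return integer site index, or `NA_integer_`
#' @export
detect_drop_site <- function(wt_track, mut_track, sites,
                             ratio_threshold = 0.5) {
  n <- length(sites$coords)
  span_mean <- function(tr, ka, kb) {
    a <- sites$coords[ka]; b <- sites$coords[kb]
    lo <- min(a, b); hi <- max(a, b)
    idx <- seq.int(lo - tr$start + 1, hi - tr$start)
    mean(tr$values[idx])
  }
  for (k in 2:(n - 1)) {
    wt_up <- span_mean(wt_track, k - 1, k)
    wt_dn <- span_mean(wt_track, k, k + 1)
    if (wt_up == 0 || wt_dn == 0) {
      warning("zero WT coverage around site ", k, "; site skipped")
      next
    }
    r_up <- span_mean(mut_track, k - 1, k) / wt_up
    r_dn <- span_mean(mut_track, k, k + 1) / wt_dn
    if (r_up > 0 && r_dn / r_up < ratio_threshold) return(k)
  }
  NA_integer_
}

#' bedGraph input/output for coverage tracks
#'
#' Tracks are written as run-length bedGraph blocks (0-based half-open,
#' deterministic ordering) and read back into dense per-base vectors.
#'
#' @param track a [coverage_track()]
#' @param path bedGraph file
#' @export
write_bedgraph <- function(track, path) {
  v <- track$values
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  df <- data.frame(chrom = track$chrom,
                   start = track$start + starts,
                   end = track$start + ends,
                   value = formatC(r$values, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param total_reads total mapped reads to attach to the track
#' @export
read_bedgraph <- function(path, total_reads = NA_real_) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  if (length(unique(df$chrom)) != 1L)
    stop("expected a single-chromosome bedGraph")
  df <- df[order(df$start), ]
  start0 <- df$start[1]
  vals <- numeric(df$end[nrow(df)] - start0)
  for (i in seq_len(nrow(df)))
    vals[(df$start[i] - start0 + 1):(df$end[i] - start0)] <- df$value[i]
  coverage_track(df$chrom[1], start0, vals, total_reads = total_reads)
}

#' Write / read a polyA site set as TSV
#'
#' Four columns: gene, chrom, strand, comma-separated 1-based site
#' coordinates in transcript order (converted to internal 0-based positions
#' on read).
#'
#' @param sites a [polya_site_set()]
#' @param path TSV file
#' @export
write_polya_sites <- function(sites, path) {
  df <- data.frame(gene = sites$gene_id, chrom = sites$chrom,
                   strand = sites$strand,
                   coords = paste(format(sites$coords + 1,
                                         scientific = FALSE, trim = TRUE),
                                  collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polya_sites
#' @export
read_polya_sites <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  polya_site_set(df$gene[1], df$chrom[1], df$strand[1],
                 as.numeric(strsplit(df$coords[1], ",")[[1]]) - 1)
}
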