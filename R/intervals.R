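#' Genomic interval arithmetic
#'
#' All coordinates inside the package are 0-based half-open `[start, end)`,
#' the BED convention. GFF3 input/output converts from/to 1-based inclusive
#' at the boundary (`start <- first - 1`, `end <- last`). Intervals are plain
#' data frames with columns `chrom`, `start`, `end` (and optionally `strand`),
#' so they compose with base R and data-frame tooling without coercion.
#'
#' @param chrom character chromosome name(s)
#' @param start 0-based inclusive start offset(s)
#' @param end exclusive end offset(s)
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded)
#' @return a data frame with columns `chrom`, `start`, `end`, `strand`
#' @examples
#' genomic_interval("Chr1", 0, 100)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  iv <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv), all(c("chrom", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0L) return(invisible(iv))
  if (any(is.na(iv$chrom)) || any(!nzchar(iv$chrom)))
    stop("interval chromosome names must be non-empty")
  if (any(iv$start < 0))
    stop("interval starts must be >= 0")
  bad <- which(iv$end <= iv$start)
  if (length(bad))
    stop(sprintf("invalid interval: end <= start at row %d (start=%s, end=%s)",
                 bad[1], iv$start[bad[1]], iv$end[bad[1]]))
  if ("strand" %in% names(iv) && !all(iv$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(iv)
}

#' Merge intervals into disjoint union
#'
#' Collapses a set of intervals on one chromosome into the minimal sorted,
#' disjoint set covering exactly their union. Touching intervals (`[0,5)`,
#' `[5,9)`) are merged.
#'
#' @param intervals data frame with `start`, `end` (and optionally a single
#'   `chrom` value)
#' @return data frame of disjoint sorted intervals
#' @examples
#' merge_intervals(data.frame(start = c(0, 3), end = c(5, 8)))
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L)
    return(data.frame(start = numeric(0), end = numeric(0)))
  if ("chrom" %in% names(intervals) &&
      length(unique(intervals$chrom)) > 1L)
    stop("merge_intervals requires all intervals on one chromosome")
  o <- order(intervals$start, intervals$end)
  s <- intervals$start[o]; e <- intervals$end[o]
  # running maximum of ends; a new block starts where start > max(previous ends)
  cummax_e <- cummax(e)
  new_block <- c(TRUE, s[-1] > cummax_e[-length(e)])
  grp <- cumsum(new_block)
  out <- data.frame(start = tapply(s, grp, min),
                    end = tapply(cummax_e, grp, max),
                    row.names = NULL)
  if ("chrom" %in% names(intervals))
    out <- cbind(chrom = intervals$chrom[1], out, stringsAsFactors = FALSE)
  out
}

#' Overlap length of two intervals in base pairs
#'
#' @param a,b single intervals (lists or one-row data frames with `chrom`,
#'   `start`, `end`)
#' @return integer overlap; 0 when chromosomes differ or intervals touch
#' @export
interval_overlap_bp <- function(a, b) {
  if (!is.null(a$chrom) && !is.null(b$chrom) && a$chrom[1] != b$chrom[1])
    return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
}

#' Cumulative TE base pairs in a gene window
#'
#' Counts the union (overlaps not double-counted) of TE-annotated base pairs
#' within the gene body extended by `flank_d` on both sides, clamped to the
#' chromosome bounds. Monotone non-decreasing in `flank_d`.
#'
#' @param gene one-row interval (`chrom`, `start`, `end`)
#' @param tes data frame of TE intervals (`chrom`, `start`, `end`)
#' @param flank_d non-negative flank width in bp
#' @param chrom_length optional chromosome length used to clamp the window
#' @return numeric TE base pairs covered in the window
#' @export
te_bp_in_window <- function(gene, tes, flank_d, chrom_length = Inf) {
  if (flank_d < 0) stop("flank_d must be >= 0")
  w_start <- max(0, gene$start[1] - flank_d)
  w_end <- min(chrom_length, gene$end[1] + flank_d)
  tt <- tes[tes$chrom == gene$chrom[1] &
              tes$end > w_start & tes$start < w_end, , drop = FALSE]
  if (nrow(tt) == 0L) return(0)
  m <- merge_intervals(tt[, c("start", "end")])
  sum(pmin(m$end, w_end) - pmax(m$start, w_start))
}

#' Distance to the nearest TE
#'
#' 0 when any TE overlaps the gene; otherwise the minimal boundary-to-boundary
#' gap on the same chromosome; `NA` when no TE shares the chromosome (such
#' genes are excluded from group means downstream).
#'
#' @param gene one-row interval
#' @param tes data frame of TE intervals
#' @return numeric distance in bp, or `NA_real_`
#' @export
nearest_te_distance <- function(gene, tes) {
  tt <- tes[tes$chrom == gene$chrom[1], , drop = FALSE]
  if (nrow(tt) == 0L) return(NA_real_)
  gaps <- pmax(0, pmax(tt$start - gene$end[1], gene$start[1] - tt$end))
  min(gaps)
}

#' Assign an interval to a chromosome compartment
#'
#' A feature is labelled by the compartment segment (arm or pericentromere)
#' containing its midpoint, `floor((start + end) / 2)`; the paper-style
#' analyses give no rule for boundary-straddling features, so the midpoint
#' decides.
#'
#' @param interval one-row interval
#' @param partition data frame with `chrom`, `start`, `end`, `label`
#'   (labels in `c("arm", "pericentromere")`), non-overlapping per chromosome
#' @return `"arm"` or `"pericentromere"`
#' @export
classify_compartment <- function(interval, partition) {
  mid <- floor((interval$start[1] + interval$end[1]) / 2)
  seg <- partition[partition$chrom == interval$chrom[1] &
                     partition$start <= mid & partition$end > mid, , drop = FALSE]
  if (nrow(seg) == 0L)
    stop(sprintf("midpoint %d on %s not covered by the partition",
                 mid, interval$chrom[1]))
  seg$label[1]
}

#' Vectorised compartment assignment
#'
#' @param intervals data frame of intervals
#' @inheritParams classify_compartment
#' @return character vector of labels
#' @export
classify_compartments <- function(intervals, partition) {
  vapply(seq_len(nrow(intervals)), function(i)
    classify_compartment(intervals[i, , drop = FALSE], partition),
    character(1))
}
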