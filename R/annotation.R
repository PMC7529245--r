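#' Annotation container: genes, TEs, compartment partition
#'
#' An `annotation_set` bundles the strand-aware feature annotation one run
#' operates on: protein-coding genes (with NLR and focal-subset flags plus
#' free-form functional category labels), transposable elements (with a
#' superfamily label from the closed vocabulary Gypsy / Copia / LINE / DNA /
#' other), the arm-vs-pericentromere chromosome partition, and chromosome
#' lengths. All coordinates 0-based half-open.
#'
#' @param genes data frame: `id`, `chrom`, `start`, `end`, `strand`,
#'   `is_nlr`, `is_focal`, `categories` (semicolon-joined labels, may be "")
#' @param tes data frame: `id`, `chrom`, `start`, `end`, `strand`,
#'   `superfamily`
#' @param partition data frame: `chrom`, `start`, `end`, `label`
#' @param chrom_lengths named numeric vector of chromosome lengths
#' @return an object of class `annotation_set`
#' @export
annotation_set <- function(genes, tes, partition, chrom_lengths) {
  obj <- structure(list(genes = genes, tes = tes, partition = partition,
                        chrom_lengths = chrom_lengths),
                   class = "annotation_set")
  validate_annotation_set(obj)
  obj
}

te_superfamilies <- c("Gypsy", "Copia", "LINE", "DNA", "other")

validate_annotation_set <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  validate_intervals(x$genes)
  validate_intervals(x$tes)
  if (anyDuplicated(x$genes$id)) stop("duplicate gene ids")
  if (anyDuplicated(x$tes$id)) stop("duplicate TE ids")
  if (!all(x$tes$superfamily %in% te_superfamilies))
    stop("TE superfamily outside the closed vocabulary: ",
         paste(setdiff(x$tes$superfamily, te_superfamilies), collapse = ", "))
  for (df in list(x$genes, x$tes)) {
    if (nrow(df) == 0L) next
    len <- x$chrom_lengths[df$chrom]
    if (any(is.na(len)) || any(df$end > len))
      stop("feature interval outside its chromosome length")
  }
  # partition must tile each chromosome's covered extent without overlap
  for (ch in unique(x$partition$chrom)) {
    p <- x$partition[x$partition$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (any(p$start[-1] < p$end[-nrow(p)]))
      stop("partition segments overlap on ", ch)
    if (!all(p$label %in% c("arm", "pericentromere")))
      stop("partition labels must be 'arm' or 'pericentromere'")
  }
  invisible(x)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "annotation_set: %d genes (%d NLR, %d focal), %d TEs, %d chromosomes\n",
    nrow(x$genes), sum(x$genes$is_nlr), sum(x$genes$is_focal),
    nrow(x$tes), length(x$chrom_lengths)))
  invisible(x)
}

# default mapping from GFF3 types/attributes to package roles
default_feature_config <- function() {
  list(gene_types = "gene",
       te_types = "transposable_element",
       nlr_attr = "is_nlr",
       focal_attr = "is_focal",
       categories_attr = "categories",
       superfamily_attr = "superfamily")
}

#' Read an annotation from GFF3
#'
#' Coordinates convert from GFF3 1-based inclusive to internal half-open.
#' `feature_config` declares which GFF3 `type` values are genes vs TEs and
#' which attribute keys carry the NLR flag, focal flag, category labels and
#' TE superfamily (defaults: `is_nlr`, `is_focal`, `categories`,
#' `superfamily`). Chromosome lengths come from `##sequence-region`
#' directives when present, else from the maximum feature end.
#'
#' @param path GFF3 file
#' @param feature_config optional list overriding the default mapping
#' @param partition optional partition data frame (or from [read_partition_bed()])
#' @return an [annotation_set()]
#' @export
read_annotation_gff3 <- function(path, feature_config = NULL,
                                 partition = NULL) {
  cfg <- utils::modifyList(default_feature_config(),
                           feature_config %||% list())
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$chrom <- as.character(df$seqnames)
  df$start0 <- df$start - 1L            # 1-based inclusive -> half-open
  df$strand <- as.character(df$strand)
  att <- function(d, key, default) {
    if (key %in% names(d)) as.character(d[[key]]) else rep(default, nrow(d))
  }
  gd <- df[df$type %in% cfg$gene_types, , drop = FALSE]
  genes <- data.frame(
    id = as.character(gd$ID),
    chrom = gd$chrom, start = gd$start0, end = gd$end,
    strand = gd$strand,
    is_nlr = att(gd, cfg$nlr_attr, "FALSE") == "TRUE",
    is_focal = att(gd, cfg$focal_attr, "FALSE") == "TRUE",
    categories = ifelse(is.na(att(gd, cfg$categories_attr, "")), "",
                        att(gd, cfg$categories_attr, "")),
    stringsAsFactors = FALSE)
  td <- df[df$type %in% cfg$te_types, , drop = FALSE]
  tes <- data.frame(
    id = as.character(td$ID),
    chrom = td$chrom, start = td$start0, end = td$end,
    strand = td$strand,
    superfamily = att(td, cfg$superfamily_attr, "other"),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start, genes$id), , drop = FALSE]
  tes <- tes[order(tes$chrom, tes$start, tes$id), , drop = FALSE]
  rownames(genes) <- rownames(tes) <- NULL
  # rtracklayer does not surface ##sequence-region; parse the directives
  sl <- read_sequence_regions(path)
  if (!length(sl) && (nrow(genes) || nrow(tes))) {
    sl_t <- tapply(c(genes$end, tes$end), c(genes$chrom, tes$chrom), max)
    sl <- stats::setNames(as.numeric(sl_t), names(sl_t))
  }
  if (is.null(partition)) {
    partition <- if (length(sl))
      data.frame(chrom = names(sl), start = 0, end = as.numeric(sl),
                 label = "arm", stringsAsFactors = FALSE)
    else data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), label = character(0),
                    stringsAsFactors = FALSE)
  }
  annotation_set(genes, tes, partition, sl)
}

#' Write an annotation to GFF3
#'
#' Deterministic output: features sorted by (chrom, start, id), coordinates
#' converted back to 1-based inclusive, flags and labels emitted as GFF3
#' attributes so that a write/read round trip is lossless.
#'
#' @param ann an [annotation_set()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_annotation_gff3 <- function(ann, path) {
  g <- ann$genes[order(ann$genes$chrom, ann$genes$start, ann$genes$id), ,
                 drop = FALSE]
  t <- ann$tes[order(ann$tes$chrom, ann$tes$start, ann$tes$id), ,
               drop = FALSE]
  mk <- function(d, type, mcols) {
    if (nrow(d) == 0L) return(NULL)
    gr <- GenomicRanges::GRanges(
      seqnames = d$chrom,
      ranges = IRanges::IRanges(start = d$start + 1L, end = d$end),
      strand = d$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      c(list(type = type, ID = d$id), mcols))
    gr
  }
  grs <- list(mk(g, "gene", list(is_nlr = ifelse(g$is_nlr, "TRUE", "FALSE"),
                              is_focal = ifelse(g$is_focal, "TRUE", "FALSE"),
                              categories = g$categories)),
              mk(t, "transposable_element",
                 list(superfamily = t$superfamily)))
  grs <- grs[!vapply(grs, is.null, logical(1))]
  if (!length(grs)) {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d",
                         names(ann$chrom_lengths),
                         as.integer(ann$chrom_lengths))), path)
    return(invisible(path))
  }
  gr <- suppressWarnings(do.call(c, grs))
  GenomeInfoDb::seqlevels(gr) <- names(ann$chrom_lengths)
  GenomeInfoDb::seqlengths(gr) <- as.integer(ann$chrom_lengths)
  rtracklayer::export(gr, path, format = "gff3")
  # re-insert ##sequence-region directives (dropped by rtracklayer) and
  # strip the date stamp so output is deterministic
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##date")]
  directives <- sprintf("##sequence-region %s 1 %d",
                        names(ann$chrom_lengths),
                        as.integer(ann$chrom_lengths))
  writeLines(c(lines[1], directives, lines[-1]), path)
  invisible(path)
}

# ##sequence-region <chrom> <first> <last> directives -> named lengths
read_sequence_regions <- function(path) {
  lines <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(trimws(lines), "\\s+")
  stats::setNames(vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
                  vapply(parts, `[`, character(1), 2))
}

#' Read / write an arm-pericentromere partition as BED4
#'
#' BED is 0-based half-open, matching internal coordinates directly; the BED
#' name column carries the compartment label.
#'
#' @param path BED file
#' @return data frame with `chrom`, `start`, `end`, `label`
#' @export
read_partition_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             label = gr$name, stringsAsFactors = FALSE)
}

#' @rdname read_partition_bed
#' @param partition data frame with `chrom`, `start`, `end`, `label`
#' @export
write_partition_bed <- function(partition, path) {
  p <- partition[order(partition$chrom, partition$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = p$chrom,
    ranges = IRanges::IRanges(start = p$start + 1L, end = p$end))
  gr$name <- p$label
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
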