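# -- per-interval counting and the retention index -------------------------

#' Count reads per annotation interval
#'
#' Assigns each read to annotation intervals and tabulates raw and
#' normalized (counts-per-million mapped reads, CPM) counts. The default
#' midpoint rule assigns a read to the unique interval containing its
#' midpoint, so a partitioning annotation receives each read exactly once
#' and boundary-straddling reads are never double counted; `"any"` counts a
#' read toward every interval it overlaps.
#'
#' @param reads Placed-read `GRanges` (or a BED path readable by
#'   [read_reads_bed()]).
#' @param annotation `GRanges` with `id` (and optionally `kind`) metadata,
#'   a `genome_model`, or a BED path.
#' @param assignment_rule `"midpoint"` (default) or `"any"`.
#' @param sample Optional sample label stored with the table.
#' @return A `coverage_table`: a data frame with one row per interval
#'   (`id`, `chrom`, `start` 0-based, `end`, `length`, `kind`, `count`,
#'   `cpm`) and attributes `total_reads` (N, counting only reads on
#'   annotated chromosomes; reads skipped for an unknown chromosome are
#'   tallied in `skipped`), `sample` and `assignment_rule`.
#' @export
count_reads <- function(reads, annotation,
                        assignment_rule = c("midpoint", "any"),
                        sample = NULL) {
  assignment_rule <- match.arg(assignment_rule)
  if (is.character(reads)) reads <- read_reads_bed(reads)
  anno <- as_annotation(annotation)

  known <- as.character(GenomicRanges::seqnames(reads)) %in%
    as.character(GenomeInfoDb::seqlevels(anno))
  n_skip <- sum(!known)
  if (n_skip > 0L) {
    warning(n_skip, " read(s) on chromosomes absent from the annotation ",
            "were skipped", call. = FALSE)
    reads <- reads[known]
  }
  N <- length(reads)

  if (assignment_rule == "midpoint") {
    mid <- GenomicRanges::start(reads) +
      (GenomicRanges::width(reads) - 1L) %/% 2L
    target <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(reads),
      ranges = IRanges::IRanges(start = mid, width = 1L))
    counts <- GenomicRanges::countOverlaps(anno, target)
  } else {
    counts <- GenomicRanges::countOverlaps(anno, reads)
  }

  out <- data.frame(
    id = anno$id,
    chrom = as.character(GenomicRanges::seqnames(anno)),
    start = GenomicRanges::start(anno) - 1L,
    end = GenomicRanges::end(anno),
    length = GenomicRanges::width(anno),
    kind = if (!is.null(anno$kind)) anno$kind else NA_character_,
    count = as.integer(counts),
    cpm = if (N > 0) 1e6 * counts / N else rep(NA_real_, length(counts)),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("coverage_table", "data.frame"),
            total_reads = N, skipped = n_skip, sample = sample,
            assignment_rule = assignment_rule)
}

as_annotation <- function(annotation) {
  if (inherits(annotation, "genome_model")) return(annotation$intervals)
  if (is.character(annotation)) return(read_annotation_bed(annotation))
  stopifnot(methods::is(annotation, "GRanges"))
  if (is.null(annotation$id))
    annotation$id <- as.character(seq_along(annotation))
  if (anyDuplicated(annotation$id))
    stop_param("annotation interval ids must be unique")
  annotation
}

#' Per-IES retention index from a new-MAC and a MIC coverage table
#'
#' The retention index of IES i is the ratio of normalized read counts,
#' new-MAC sample over MIC reference:
#' `RI_i = (n_i^newMAC / N^newMAC) / (n_i^MIC / N^MIC)`.
#' An RI of 0 means complete elimination, 1 full retention; micronuclear
#' contamination of the new-MAC preparation puts a floor of about the
#' contamination fraction under the whole distribution.
#'
#' @param newmac,mic `coverage_table`s over the same annotation.
#' @param normalization `"total"` (counts per million mapped reads, the
#'   default) or `"mds"` (normalize each sample by its MDS-assigned read
#'   count; requires a `kind` column).
#' @return A `retention_table`: data frame of IES rows (`id`, `chrom`,
#'   `start`, `end`, `length`, `n_newmac`, `n_mic`, `ri`) with attribute
#'   `dropped` naming IESs with zero reference count (reported as missing,
#'   never as infinite RI).
#' @export
retention_index <- function(newmac, mic,
                            normalization = c("total", "mds")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(newmac, "coverage_table"),
            inherits(mic, "coverage_table"))
  if (!identical(newmac$id, mic$id) ||
      !identical(newmac$start, mic$start) ||
      !identical(newmac$end, mic$end))
    stop_param("coverage tables were computed over different annotations")

  if (normalization == "total") {
    N_new <- attr(newmac, "total_reads")
    N_mic <- attr(mic, "total_reads")
  } else {
    if (all(is.na(newmac$kind)))
      stop_param("mds normalization requires interval kinds")
    N_new <- sum(newmac$count[newmac$kind == "MDS"])
    N_mic <- sum(mic$count[mic$kind == "MDS"])
  }
  if (N_new <= 0 || N_mic <= 0)
    stop_param("both samples must contain mapped reads")

  is_ies <- if (all(is.na(newmac$kind))) rep(TRUE, nrow(newmac))
            else newmac$kind == "IES"
  idx <- which(is_ies)
  zero_ref <- idx[mic$count[idx] == 0]
  if (length(zero_ref)) {
    message(length(zero_ref), " IES(s) dropped for zero reference count: ",
            paste(utils::head(newmac$id[zero_ref], 5), collapse = ", "),
            if (length(zero_ref) > 5) ", ..." else "")
  }
  keep <- setdiff(idx, zero_ref)
  ri <- (newmac$count[keep] / N_new) / (mic$count[keep] / N_mic)
  out <- data.frame(
    id = newmac$id[keep], chrom = newmac$chrom[keep],
    start = newmac$start[keep], end = newmac$end[keep],
    length = newmac$length[keep],
    n_newmac = newmac$count[keep], n_mic = mic$count[keep],
    ri = ri, stringsAsFactors = FALSE
  )
  structure(out, class = c("retention_table", "data.frame"),
            dropped = newmac$id[zero_ref],
            samples = c(numerator = attr(newmac, "sample") %||% "newMAC",
                        reference = attr(mic, "sample") %||% "MIC"),
            normalization = normalization)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a retention-index distribution
#'
#' Order statistics plus the fraction of IESs below/above user cut points.
#' The default thresholds bracket the bands seen in real data: a
#' contamination-dominated wild-type sample sits mostly in 0.001-0.1,
#' an elimination-defective sample near 1.
#'
#' @param table A `retention_table`.
#' @param thresholds Numeric cut points.
#' @return A list of class `ri_summary` with `n`, `median`, `q1`, `q3`,
#'   `frac_below` and `frac_above` (named by threshold).
#' @export
summarize_ri <- function(table, thresholds = c(0.001, 0.1, 1)) {
  stopifnot(inherits(table, "retention_table"))
  ri <- table$ri[is.finite(table$ri)]
  if (!length(ri)) stop_param("no finite retention indices to summarize")
  qs <- stats::quantile(ri, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    n = length(ri), median = qs[2], q1 = qs[1], q3 = qs[3],
    frac_below = stats::setNames(
      vapply(thresholds, function(t) mean(ri < t), numeric(1)),
      as.character(thresholds)),
    frac_above = stats::setNames(
      vapply(thresholds, function(t) mean(ri > t), numeric(1)),
      as.character(thresholds)),
    thresholds = thresholds
  ), class = "ri_summary")
}

#' @export
print.ri_summary <- function(x, ...) {
  cat(sprintf("retention-index summary over %d IESs\n", x$n))
  cat(sprintf("  median %.4g  [Q1 %.4g, Q3 %.4g]\n", x$median, x$q1, x$q3))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  RI < %-6s : %5.1f%%   RI > %-6s : %5.1f%%\n",
                format(x$thresholds[i]), 100 * x$frac_below[i],
                format(x$thresholds[i]), 100 * x$frac_above[i]))
  invisible(x)
}

#' Write a retention table (or its summary) to TSV
#' @param x A `retention_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_retention_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
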