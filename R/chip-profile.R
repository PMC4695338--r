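# -- fold-enrichment tracks and the modeled-IES metagene -------------------

#' Tile a genome into fixed-width windows
#'
#' @param genome A `genome_model`, or a named vector of chromosome lengths.
#' @param width Window width in bp (default 50).
#' @return A `GRanges` of windows with `id` metadata, tiling each
#'   chromosome (the last window of a chromosome may be shorter).
#' @export
genome_windows <- function(genome, width = 50L) {
  sl <- if (inherits(genome, "genome_model"))
    GenomeInfoDb::seqlengths(genome$intervals) else genome
  tiles <- GenomicRanges::tileGenome(sl, tilewidth = width,
                                     cut.last.tile.in.chrom = TRUE)
  tiles$id <- sprintf("win_%06d", seq_along(tiles))
  tiles
}

#' Fold-enrichment track: IP over input on a common window grid
#'
#' Each window's value is `(IP CPM + pseudocount) / (input CPM +
#' pseudocount)`; the pseudocount keeps windows with no input reads finite,
#' and such windows are flagged low-confidence.
#'
#' @param ip,input `coverage_table`s computed with [count_reads()] over the
#'   same window grid.
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return An `enrichment_track`: `GRanges` with `score` (fold enrichment)
#'   and `low_confidence` metadata columns.
#' @export
fold_enrichment <- function(ip, input, pseudocount = 0.5) {
  stopifnot(inherits(ip, "coverage_table"),
            inherits(input, "coverage_table"))
  if (pseudocount < 0) stop_param("pseudocount must be >= 0")
  if (!identical(ip$id, input$id) || !identical(ip$start, input$start) ||
      !identical(ip$chrom, input$chrom))
    stop_param("IP and input tables use different window grids")
  score <- (ip$cpm + pseudocount) / (input$cpm + pseudocount)
  gr <- GenomicRanges::GRanges(
    seqnames = ip$chrom,
    ranges = IRanges::IRanges(start = ip$start + 1L, end = ip$end),
    score = score, low_confidence = input$count == 0L
  )
  S4Vectors::metadata(gr) <- list(pseudocount = pseudocount)
  gr
}

#' Export a fold-enrichment track as bedGraph
#' @param track `GRanges` with a `score` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(track, path) {
  rtracklayer::export(track[, "score"], path, format = "bedGraph")
  invisible(path)
}

#' Compile the modeled-IES metagene profile
#'
#' All IESs in a length class (default the 1-5 kb class, inclusive on both
#' ends) are compiled onto one length-scaled axis: each IES body is
#' rescaled to `body_bins` bins by linear interpolation of the
#' fold-enrichment window values, flanks of `flank_bp` are kept at native
#' scale in `flank_bins` bins, and the per-bin arithmetic mean across loci
#' is reported. Loci whose flanks would overrun a chromosome end are
#' dropped (and counted), keeping bins comparable across loci.
#'
#' @param track An enrichment track from [fold_enrichment()] (windowed
#'   `GRanges` with `score`).
#' @param annotation `GRanges` annotation (with `kind`/`id`), a
#'   `genome_model`, or BED path.
#' @param length_filter Inclusive (min, max) IES length in bp.
#' @param body_bins Number of length-scaled body bins.
#' @param flank_bp Flank width in bp on each side.
#' @param flank_bins Number of native-scale bins per flank.
#' @return A `metagene_profile`: data frame with `bin`, `region`
#'   (`upstream`/`body`/`downstream`), `position` (bin-center label in
#'   relative coordinates) and `mean` fold enrichment; attributes `n_loci`
#'   (loci used) and `n_dropped_flank`.
#' @export
modeled_ies <- function(track, annotation,
                        length_filter = c(1000, 5000),
                        body_bins = 50L, flank_bp = 2000L,
                        flank_bins = 50L) {
  anno <- as_annotation(annotation)
  stopifnot(methods::is(track, "GRanges"), !is.null(track$score))
  ies <- anno[!is.na(anno$kind) & anno$kind == "IES"]
  w <- GenomicRanges::width(ies)
  ies <- ies[w >= length_filter[1] & w <= length_filter[2]]
  if (length(ies) == 0L)
    stop_param("no IES passes the length filter [",
               length_filter[1], ", ", length_filter[2], "] bp")

  sl <- tapply(GenomicRanges::end(track),
               as.character(GenomicRanges::seqnames(track)), max)
  chrom <- as.character(GenomicRanges::seqnames(ies))
  s <- GenomicRanges::start(ies)
  e <- GenomicRanges::end(ies)
  fits <- s - flank_bp >= 1 & e + flank_bp <= sl[chrom]
  n_dropped <- sum(!fits)
  if (n_dropped > 0L)
    message(n_dropped, " IES locus/loci dropped: flank overruns a ",
            "chromosome end")
  ies <- ies[fits]; chrom <- chrom[fits]; s <- s[fits]; e <- e[fits]
  if (length(ies) == 0L)
    stop_param("no IES with complete ", flank_bp, " bp flanks remains")

  # per-chromosome interpolators over window centers
  tr_chrom <- as.character(GenomicRanges::seqnames(track))
  centers <- (GenomicRanges::start(track) + GenomicRanges::end(track)) / 2
  interp <- function(cn, xout) {
    i <- tr_chrom == cn
    stats::approx(centers[i], track$score[i], xout = xout, rule = 2)$y
  }

  n_bins <- 2L * flank_bins + body_bins
  acc <- matrix(0, nrow = length(ies), ncol = n_bins)
  fw <- flank_bp / flank_bins
  for (k in seq_along(ies)) {
    len <- e[k] - s[k] + 1
    up <- s[k] - flank_bp + (seq_len(flank_bins) - 0.5) * fw
    body <- s[k] + (seq_len(body_bins) - 0.5) / body_bins * len
    down <- e[k] + (seq_len(flank_bins) - 0.5) * fw
    acc[k, ] <- interp(chrom[k], c(up, body, down))
  }

  region <- c(rep("upstream", flank_bins), rep("body", body_bins),
              rep("downstream", flank_bins))
  position <- c(-flank_bp + (seq_len(flank_bins) - 0.5) * fw,
                (seq_len(body_bins) - 0.5) / body_bins,
                (seq_len(flank_bins) - 0.5) * fw)
  out <- data.frame(bin = seq_len(n_bins), region = region,
                    position = position, mean = colMeans(acc))
  structure(out, class = c("metagene_profile", "data.frame"),
            n_loci = length(ies), n_dropped_flank = n_dropped,
            body_bins = body_bins, flank_bins = flank_bins,
            flank_bp = flank_bp, length_filter = length_filter)
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("modeled-IES metagene over %d loci (%d dropped for flanks)\n",
              attr(x, "n_loci"), attr(x, "n_dropped_flank")))
  b <- x$region == "body"
  cat(sprintf("  mean fold enrichment: body %.3f, flanks %.3f\n",
              mean(x$mean[b]), mean(x$mean[!b])))
  invisible(x)
}

#' Plot a metagene profile
#' @param x A `metagene_profile`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.metagene_profile <- function(x, ...) {
  fb <- attr(x, "flank_bins"); bb <- attr(x, "body_bins")
  plot(x$bin, x$mean, type = "l", xlab = "bin", ylab = "mean fold enrichment",
       main = sprintf("modeled IES (n = %d)", attr(x, "n_loci")), ...)
  graphics::abline(v = c(fb + 0.5, fb + bb + 0.5), lty = 2, col = "grey40")
  invisible(x)
}

#' Write a metagene profile to TSV
#' @param x A `metagene_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metagene_tsv <- function(x, path) {
  df <- as.data.frame(x)
  df$n_loci <- attr(x, "n_loci")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
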