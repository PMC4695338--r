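# -- placed-read simulation ------------------------------------------------
#
# Reads are emitted as coordinate-resolved records ("placed reads"): a
# GRanges carrying the true genomic origin plus `source` (somatic vs
# contaminant) and `channel` (WGS / IP / input) metadata. No aligner is
# involved; the downstream statistics operate on mapped counts only.

placed_reads <- function(chrom, start, width, source, channel, seqlengths) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, width = width),
    source = source, channel = channel,
    seqlengths = seqlengths
  )
  gr
}

# uniform read placement over whole chromosomes (reads stay within bounds)
uniform_reads <- function(genome, n, read_length) {
  sl <- GenomeInfoDb::seqlengths(genome$intervals)
  eff <- pmax(sl - read_length + 1L, 1L)
  ci <- sample.int(length(sl), n, replace = TRUE, prob = eff)
  start <- floor(stats::runif(n, min = 1, max = eff[ci] + 1))
  list(chrom = names(sl)[ci], start = as.integer(start))
}

# reads placed entirely within sampled annotation intervals, with
# per-interval sampling weight proportional to weight_per_bp * width
interval_reads <- function(genome, n, read_length, weight_per_bp) {
  gr <- genome$intervals
  w <- GenomicRanges::width(gr) * weight_per_bp
  if (all(w == 0) || n == 0L)
    return(list(chrom = character(0), start = integer(0),
                width = integer(0)))
  ii <- sample.int(length(gr), n, replace = TRUE, prob = w)
  ws <- GenomicRanges::start(gr)[ii]
  we <- GenomicRanges::end(gr)[ii]
  iw <- we - ws + 1L
  rl <- pmin(read_length, iw)             # short intervals yield short reads
  start <- ws + floor(stats::runif(n) * (iw - rl + 1L))
  list(chrom = as.character(GenomicRanges::seqnames(gr))[ii],
       start = as.integer(start), width = as.integer(rl))
}

#' Simulate whole-genome sequencing reads from the MIC or a new MAC
#'
#' The MIC reference sample places reads uniformly over the full germline
#' genome. A new-MAC sample is a mixture: a binomially sampled fraction
#' `contamination` of reads comes from intact contaminating MIC genomes
#' (uniform over the whole genome), and the rest from the somatic template,
#' in which each MDS contributes its full length and each IES contributes
#' in proportion to its retained fraction. Somatic reads lie entirely
#' within a single annotation interval, mirroring how reads from the
#' spliced somatic genome map back to germline coordinates: under complete
#' elimination and zero contamination no read can touch IES space.
#'
#' @param genome A `genome_model` from [generate_genome()].
#' @param params A [sim_params()]; `depth`, `read_length`, `contamination`,
#'   `elimination` and `seed` are used. Total reads
#'   `N = round(depth * G / read_length)`.
#' @param sample `"MIC"` or `"newMAC"`.
#' @return A `GRanges` of placed reads with `source` and `channel` metadata.
#' @examples
#' gm <- generate_genome(sim_params(seed = 1, genome_size = 2e5, n_ies = 12))
#' rd <- simulate_wgs(gm, sim_params(seed = 1, genome_size = 2e5,
#'                                   n_ies = 12, depth = 2), "MIC")
#' length(rd)
#' @export
simulate_wgs <- function(genome, params, sample = c("MIC", "newMAC")) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "sim_params"))
  sample <- match.arg(sample)
  rl <- params$read_length
  N <- as.integer(round(params$depth * genome$genome_length / rl))
  sl <- GenomeInfoDb::seqlengths(genome$intervals)
  set.seed(stage_seed(params$seed, paste0("wgs_", sample)))

  if (sample == "MIC") {
    u <- uniform_reads(genome, N, rl)
    return(placed_reads(u$chrom, u$start, rl, "somatic", "WGS", sl))
  }

  retained <- elimination_profile(
    genome, if (is.null(params$elimination)) 0 else params$elimination)
  gr <- genome$intervals
  w <- numeric(length(gr))
  w[gr$kind == "MDS"] <- 1
  w[gr$kind == "IES"] <- retained[gr$id[gr$kind == "IES"]]

  n_contam <- stats::rbinom(1L, N, params$contamination)
  n_som <- N - n_contam
  som <- interval_reads(genome, n_som, rl, w)
  con <- uniform_reads(genome, n_contam, rl)
  placed_reads(
    chrom = c(som$chrom, con$chrom),
    start = c(som$start, con$start),
    width = c(som$width, rep(rl, n_contam)),
    source = c(rep("somatic", n_som), rep("contaminant", n_contam)),
    channel = "WGS", seqlengths = sl
  )
}

#' Simulate a ChIP experiment as weighted read placement
#'
#' Input reads are uniform over the genome; IP reads are placed with
#' per-bp weight `enrichment` on IES bodies and `background` on MDS,
#' normalized to a probability distribution, emulating immunoprecipitation
#' of chromatin marked on IESs.
#'
#' @param genome A `genome_model`.
#' @param params A [sim_params()]; `depth`, `read_length` and `seed` used.
#' @param enrichment Fold weight on IES bodies (>= 0).
#' @param background Fold weight elsewhere (>= 0).
#' @return List with `ip` and `input` placed-read `GRanges`.
#' @export
simulate_chip <- function(genome, params, enrichment = 8, background = 1) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "sim_params"))
  if (enrichment < 0 || background < 0)
    stop_param("enrichment and background must be >= 0")
  if (enrichment == 0 && background == 0)
    stop_param("enrichment and background cannot both be zero")
  rl <- params$read_length
  N <- as.integer(round(params$depth * genome$genome_length / rl))
  sl <- GenomeInfoDb::seqlengths(genome$intervals)
  gr <- genome$intervals
  w <- ifelse(gr$kind == "IES", enrichment, background)

  set.seed(stage_seed(params$seed, "chip_input"))
  u <- uniform_reads(genome, N, rl)
  input <- placed_reads(u$chrom, u$start, rl, "somatic", "input", sl)

  set.seed(stage_seed(params$seed, "chip_ip"))
  ipr <- interval_reads(genome, N, rl, w)
  ip <- placed_reads(ipr$chrom, ipr$start, ipr$width, "somatic", "IP", sl)
  list(ip = ip, input = input)
}

#' Write placed reads to BED6
#'
#' The name field encodes `source:channel:index` so a read set round-trips
#' through plain text.
#'
#' @param reads Placed-read `GRanges`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(reads)),
    start = GenomicRanges::start(reads) - 1L,
    end = GenomicRanges::end(reads),
    name = sprintf("%s:%s:%d", reads$source, reads$channel,
                   seq_along(reads)),
    score = 0L, strand = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read placed reads from BED6
#' @param path BED path as written by [write_reads_bed()] (any BED works;
#'   missing source/channel default to `somatic`/`WGS`).
#' @return Placed-read `GRanges`.
#' @export
read_reads_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) gr$name else rep("somatic:WGS", length(gr))
  parts <- strsplit(nm, ":", fixed = TRUE)
  src <- vapply(parts, function(p) if (length(p) >= 1) p[1] else "somatic",
                character(1))
  chn <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "WGS",
                character(1))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(source = src, channel = chn)
  gr
}

#' Export placed reads as FASTQ (interoperability only)
#'
#' Sequences are extracted from the simulated genome at the read
#' coordinates; base qualities are uniform.
#'
#' @param reads Placed-read `GRanges`.
#' @param genome The `genome_model` the reads were simulated from.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, genome, path) {
  chrom <- as.character(GenomicRanges::seqnames(reads))
  out <- vector("list", length(genome$sequences))
  names(out) <- names(genome$sequences)
  for (cn in names(genome$sequences)) {
    sel <- chrom == cn
    if (!any(sel)) next
    v <- Biostrings::Views(genome$sequences[[cn]],
                           start = GenomicRanges::start(reads)[sel],
                           end = GenomicRanges::end(reads)[sel])
    ss <- Biostrings::DNAStringSet(v)
    names(ss) <- sprintf("%s:%s:%s:%d", reads$source[sel],
                         reads$channel[sel], cn, which(sel))
    out[[cn]] <- ss
  }
  all <- do.call(c, unname(out[!vapply(out, is.null, logical(1))]))
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(all)))
  Biostrings::writeXStringSet(all, path, format = "fastq", qualities = quals)
  invisible(path)
}
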