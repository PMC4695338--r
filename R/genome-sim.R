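#' Simulation parameters for a synthetic micronuclear genome and reads
#'
#' Bundles every knob of the simulator: genome geometry (size, number of
#' chromosomes, number of IESs and the genomic fraction they occupy),
#' sequencing parameters (mean depth, read length), the micronuclear
#' contamination fraction of a new-MAC preparation, and the per-IES
#' elimination status.
#'
#' Defaults follow a desk-scale version of the study system: a 5 Mb genome
#' in which internal eliminated sequences (IESs) occupy one third of the
#' germline genome, 300 IES loci with a 1-5 kb core length class, 20x mean
#' coverage of 50 nt reads, and a 5% contamination fraction (the observed
#' range in real new-MAC preparations is roughly 2%-10%).
#'
#' @param seed Integer seed; all randomness in the simulator derives from it.
#' @param genome_size Total genome length G in bp.
#' @param n_chrom Number of chromosomes (genome split evenly).
#' @param n_ies Number of IES intervals.
#' @param ies_fraction Target fraction of the genome covered by IESs.
#' @param ies_length_range Length-class range (bp) from which raw IES
#'   lengths are drawn before rescaling to hit `ies_fraction`; with the
#'   defaults a sizeable subset of loci stays inside the 1-5 kb class used
#'   by the modeled-IES metagene.
#' @param min_gap Minimum MDS gap (bp) between IESs and to chromosome ends,
#'   so every IES has MDS flanks.
#' @param depth Mean fold-coverage of simulated read sets.
#' @param read_length Read length in bp.
#' @param contamination Fraction `c` in `[0,1]` of new-MAC reads that
#'   originate from intact contaminating MIC genomes.
#' @param elimination Optional named numeric vector mapping IES ids to the
#'   retained fraction in `[0,1]` (0 = fully eliminated, 1 = fully
#'   retained); a scalar is recycled to all IESs when reads are simulated.
#' @return An object of class `sim_params` (a validated list).
#' @seealso [generate_genome()], [simulate_wgs()], [simulate_chip()]
#' @export
sim_params <- function(seed = 1L,
                       genome_size = 5e6,
                       n_chrom = 2L,
                       n_ies = 300L,
                       ies_fraction = 1 / 3,
                       ies_length_range = c(1000L, 5000L),
                       min_gap = 200L,
                       depth = 20,
                       read_length = 50L,
                       contamination = 0.05,
                       elimination = NULL) {
  if (!is.numeric(genome_size) || genome_size < 1000)
    stop_param("genome_size must be at least 1000 bp")
  if (n_ies < 1L) stop_param("n_ies must be >= 1")
  if (length(ies_length_range) != 2L || ies_length_range[1] < 1 ||
      ies_length_range[2] < ies_length_range[1])
    stop_param("ies_length_range must be (min, max) with min >= 1")
  check_fraction(ies_fraction, "ies_fraction")
  check_fraction(contamination, "contamination")
  if (depth <= 0) stop_param("depth must be > 0")
  if (read_length < 1) stop_param("read_length must be >= 1")
  if (!is.null(elimination)) {
    if (any(elimination < 0 | elimination > 1))
      stop_param("elimination retained fractions must lie in [0, 1]")
  }
  structure(list(
    seed = as.integer(seed), genome_size = genome_size,
    n_chrom = as.integer(n_chrom), n_ies = as.integer(n_ies),
    ies_fraction = ies_fraction,
    ies_length_range = as.integer(round(ies_length_range)),
    min_gap = as.integer(min_gap), depth = depth,
    read_length = as.integer(read_length),
    contamination = contamination, elimination = elimination
  ), class = "sim_params")
}

#' Generate a synthetic micronuclear genome partitioned into MDS and IES
#'
#' Builds random chromosome sequences together with an annotation that
#' tiles every chromosome exactly into alternating MAC-destined segments
#' (MDS) and internal eliminated sequences (IES). IES lengths are drawn
#' from `ies_length_range` and rescaled so total IES content matches
#' `ies_fraction` of the genome; every IES is strictly internal, flanked by
#' MDS of at least `min_gap` bp on both sides.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `genome_model`: a list with `sequences`
#'   (a [Biostrings::DNAStringSet]), `intervals` (a
#'   [GenomicRanges::GRanges] with metadata columns `kind` in
#'   `{MDS, IES}` and unique `id`), and `genome_length`.
#' @examples
#' gm <- generate_genome(sim_params(seed = 1, genome_size = 2e5, n_ies = 12))
#' table(gm$intervals$kind)
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  G <- params$genome_size
  n_chrom <- params$n_chrom
  chrom_len <- rep(floor(G / n_chrom), n_chrom)
  chrom_len[n_chrom] <- chrom_len[n_chrom] + (G - sum(chrom_len))
  chrom_names <- sprintf("chr%d", seq_len(n_chrom))

  # apportion IES count across chromosomes in proportion to length
  n_per <- floor(params$n_ies * chrom_len / G)
  rem <- params$n_ies - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L

  target_ies <- round(params$ies_fraction * chrom_len)
  need <- target_ies + (n_per + 1L) * params$min_gap
  if (any(need > chrom_len))
    stop_param("infeasible geometry: requested IES mass plus minimum MDS ",
               "gaps exceeds chromosome length")

  set.seed(params$seed)
  seqs <- character(n_chrom)
  iv <- vector("list", n_chrom)
  ies_counter <- 0L
  mds_counter <- 0L
  for (ci in seq_len(n_chrom)) {
    L <- chrom_len[ci]
    n <- n_per[ci]
    if (n > 0L) {
      raw <- stats::runif(n, params$ies_length_range[1],
                          params$ies_length_range[2])
      len <- pmax(1L, as.integer(round(raw * target_ies[ci] / sum(raw))))
      len[which.max(len)] <- len[which.max(len)] + (target_ies[ci] - sum(len))
      spare <- L - sum(len) - (n + 1L) * params$min_gap
      gaps <- params$min_gap +
        as.integer(stats::rmultinom(1L, spare, rep(1, n + 1L)))
      # 0-based starts of IESs from alternating gap/IES runs
      starts <- integer(n)
      pos <- 0L
      for (k in seq_len(n)) {
        pos <- pos + gaps[k]
        starts[k] <- pos
        pos <- pos + len[k]
      }
      ies_start <- starts           # 0-based inclusive
      ies_end <- starts + len       # 0-based exclusive
      mds_start <- c(0L, ies_end)
      mds_end <- c(ies_start, L)
      keep <- mds_end > mds_start
      iv[[ci]] <- rbind(
        data.frame(chrom = chrom_names[ci], start = ies_start, end = ies_end,
                   kind = "IES",
                   id = sprintf("IES_%04d", ies_counter + seq_len(n))),
        data.frame(chrom = chrom_names[ci], start = mds_start[keep],
                   end = mds_end[keep], kind = "MDS",
                   id = sprintf("MDS_%04d", mds_counter + seq_len(sum(keep))))
      )
      ies_counter <- ies_counter + n
      mds_counter <- mds_counter + sum(keep)
    } else {
      iv[[ci]] <- data.frame(chrom = chrom_names[ci], start = 0L, end = L,
                             kind = "MDS",
                             id = sprintf("MDS_%04d", mds_counter + 1L))
      mds_counter <- mds_counter + 1L
    }
    seqs[ci] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = "")
  }
  ivd <- do.call(rbind, iv)
  ivd <- ivd[order(match(ivd$chrom, chrom_names), ivd$start), ]
  gr <- GenomicRanges::GRanges(
    seqnames = ivd$chrom,
    ranges = IRanges::IRanges(start = ivd$start + 1L, end = ivd$end),
    kind = ivd$kind, id = ivd$id,
    seqlengths = stats::setNames(chrom_len, chrom_names)
  )
  dna <- Biostrings::DNAStringSet(stats::setNames(seqs, chrom_names))
  structure(list(sequences = dna, intervals = gr, genome_length = G,
                 params = params),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  n_ies <- sum(x$intervals$kind == "IES")
  ies_bp <- sum(GenomicRanges::width(
    x$intervals[x$intervals$kind == "IES"]))
  cat("genome_model:", length(x$sequences), "chromosome(s),",
      format(x$genome_length, big.mark = ","), "bp\n")
  cat(sprintf("  %d IESs covering %s bp (%.1f%% of genome)\n",
              n_ies, format(ies_bp, big.mark = ","),
              100 * ies_bp / x$genome_length))
  invisible(x)
}

#' IES ids of a genome model
#' @param genome A `genome_model`.
#' @return Character vector of IES interval ids.
#' @export
ies_ids <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  genome$intervals$id[genome$intervals$kind == "IES"]
}

#' Build a per-IES retained-fraction map
#'
#' @param genome A `genome_model`.
#' @param retained Scalar retained fraction applied to every IES, or a named
#'   vector overriding individual IESs.
#' @return Named numeric vector over all IES ids.
#' @export
elimination_profile <- function(genome, retained = 0) {
  ids <- ies_ids(genome)
  if (length(retained) == 1L && is.null(names(retained))) {
    out <- stats::setNames(rep(check_fraction(retained, "retained"),
                               length(ids)), ids)
    return(out)
  }
  unknown <- setdiff(names(retained), ids)
  if (length(unknown))
    stop_param("unknown IES id(s) in elimination map: ",
               paste(utils::head(unknown, 5), collapse = ", "))
  out <- stats::setNames(rep(0, length(ids)), ids)
  out[names(retained)] <- retained
  out
}

#' Write genome sequences to FASTA
#' @param genome A `genome_model`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequences, path)
  invisible(path)
}

#' Write the MDS/IES annotation to BED6
#'
#' Coordinates are 0-based half-open; the name column carries the interval
#' id, score is 0 and strand ".".
#'
#' @param genome A `genome_model` (or a `GRanges` annotation).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(genome, path) {
  gr <- if (inherits(genome, "genome_model")) genome$intervals else genome
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$id)) gr$id else as.character(seq_along(gr)),
    score = 0L, strand = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an MDS/IES annotation from BED
#'
#' Accepts the BED6 written by [write_annotation_bed()] or any BED with
#' interval names. Interval kind is recovered from the id prefix
#' (`IES`/`MDS`) when present.
#'
#' @param path BED file path.
#' @return A `GRanges` with `id` and `kind` metadata columns.
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  ids <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
  kind <- ifelse(grepl("^IES", ids), "IES",
                 ifelse(grepl("^MDS", ids), "MDS", NA_character_))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(kind = kind, id = ids)
  gr
}
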