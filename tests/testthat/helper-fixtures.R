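# shared small-scale fixtures built in code

small_params <- function(seed = 1, ...) {
  sim_params(seed = seed, genome_size = 1e6, n_chrom = 2, n_ies = 60, ...)
}

small_genome <- function(seed = 1, ...) {
  generate_genome(small_params(seed = seed, ...))
}

# hand-built annotation on one 10 kb chromosome: MDS | IES | MDS
tiny_annotation <- function(ies_start = 4001, ies_end = 6000, len = 10000) {
  GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(
      start = c(1, ies_start, ies_end + 1),
      end = c(ies_start - 1, ies_end, len)),
    kind = c("MDS", "IES", "MDS"),
    id = c("MDS_0001", "IES_0001", "MDS_0002"),
    seqlengths = c(chr1 = len)
  )
}

tiny_reads <- function(start, width = 50, chrom = "chr1",
                       seqlen = 10000) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, width = width),
    source = "somatic", channel = "WGS",
    seqlengths = stats::setNames(seqlen, chrom[1])
  )
}

ies_space_fraction <- function(reads, genome) {
  ies <- genome$intervals[genome$intervals$kind == "IES"]
  mean(GenomicRanges::countOverlaps(reads, ies) > 0)
}
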