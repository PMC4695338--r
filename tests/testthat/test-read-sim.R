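gm <- small_genome(seed = 21)

test_that("read count follows N = depth * G / read_length", {
  p <- small_params(seed = 21, depth = 4)
  rd <- simulate_wgs(gm, p, "MIC")
  expect_equal(length(rd), round(4 * 1e6 / 50))
  expect_true(all(GenomicRanges::start(rd) >= 1))
  sl <- GenomeInfoDb::seqlengths(gm$intervals)
  expect_true(all(GenomicRanges::end(rd) <=
                    sl[as.character(GenomicRanges::seqnames(rd))]))
})

test_that("complete elimination without contamination leaves IES space empty", {
  p <- small_params(seed = 22, depth = 5, contamination = 0,
                    elimination = 0)
  rd <- simulate_wgs(gm, p, "newMAC")
  expect_equal(ies_space_fraction(rd, gm), 0)
  expect_true(all(rd$source == "somatic"))
})

test_that("realized contaminant fraction is binomially close to c", {
  p <- small_params(seed = 23, depth = 10, contamination = 0.05,
                    elimination = 0)
  rd <- simulate_wgs(gm, p, "newMAC")
  realized <- mean(rd$source == "contaminant")
  N <- length(rd)
  expect_lt(abs(realized - 0.05), 3 * sqrt(0.05 * 0.95 / N))
})

test_that("with full elimination, IES-overlap fraction approaches c/3", {
  p <- small_params(seed = 24, depth = 20, contamination = 0.05,
                    elimination = 0)
  rd <- simulate_wgs(gm, p, "newMAC")
  frac <- ies_space_fraction(rd, gm)
  expect_lt(abs(frac - 0.05 / 3), 0.003)
})

test_that("somatic coverage of a fully retained IES matches MDS coverage", {
  p <- small_params(seed = 25, depth = 20, contamination = 0,
                    elimination = 1)
  rd <- simulate_wgs(gm, p, "newMAC")
  cov <- count_reads(rd, gm)
  dens <- cov$count / cov$length
  ies_d <- mean(dens[cov$kind == "IES"])
  mds_d <- mean(dens[cov$kind == "MDS"])
  expect_lt(abs(ies_d / mds_d - 1), 0.05)
})

test_that("partial retention scales IES coverage proportionally", {
  ids <- ies_ids(gm)
  retained <- stats::setNames(rep(c(0.25, 1), length.out = length(ids)),
                              ids)
  p <- small_params(seed = 26, depth = 20, contamination = 0,
                    elimination = retained)
  rd <- simulate_wgs(gm, p, "newMAC")
  cov <- count_reads(rd, gm)
  dens <- cov$count / cov$length
  lo <- mean(dens[cov$id %in% names(retained)[retained == 0.25]])
  hi <- mean(dens[cov$id %in% names(retained)[retained == 1]])
  expect_lt(abs(lo / hi - 0.25), 0.05)
})

test_that("wgs simulation is deterministic given the seed", {
  p <- small_params(seed = 27, depth = 2)
  r1 <- simulate_wgs(gm, p, "MIC")
  r2 <- simulate_wgs(gm, p, "MIC")
  expect_identical(GenomicRanges::start(r1), GenomicRanges::start(r2))
})

test_that("ChIP placement matches the closed-form IES read fraction", {
  p <- small_params(seed = 28, depth = 10)
  ch <- simulate_chip(gm, p, enrichment = 8, background = 1)
  # E=8 on one third of the genome: 8*(1/3) / (8/3 + 2/3) = 0.8
  expect_lt(abs(ies_space_fraction(ch$ip, gm) - 0.8), 0.01)
  expect_lt(abs(ies_space_fraction(ch$input, gm) - 1 / 3), 0.01)
  expect_equal(unique(ch$ip$channel), "IP")
  expect_equal(unique(ch$input$channel), "input")
})

test_that("degenerate ChIP weights behave as specified", {
  p <- small_params(seed = 29, depth = 2)
  none <- simulate_chip(gm, p, enrichment = 0, background = 1)
  expect_equal(ies_space_fraction(none$ip, gm), 0)
  expect_error(simulate_chip(gm, p, enrichment = 0, background = 0),
               "both")
  flat <- simulate_chip(gm, p, enrichment = 1, background = 1)
  expect_lt(abs(ies_space_fraction(flat$ip, gm) - 1 / 3), 0.02)
})

test_that("placed reads round-trip through BED with source and channel", {
  p <- small_params(seed = 30, depth = 0.1, contamination = 0.3,
                    elimination = 0.5)
  rd <- simulate_wgs(gm, p, "newMAC")
  d <- withr::local_tempdir()
  bed <- file.path(d, "reads.bed")
  write_reads_bed(rd, bed)
  back <- read_reads_bed(bed)
  expect_equal(length(back), length(rd))
  expect_equal(back$source, rd$source)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(rd))
})

test_that("FASTQ export carries genome subsequences at read coordinates", {
  p <- small_params(seed = 31, depth = 0.01)
  rd <- simulate_wgs(gm, p, "MIC")
  d <- withr::local_tempdir()
  fq <- file.path(d, "reads.fastq")
  write_reads_fastq(rd, gm, fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_equal(length(back), length(rd))
  one <- back[[1]]
  cn <- strsplit(names(back)[1], ":")[[1]][3]
  idx <- as.integer(strsplit(names(back)[1], ":")[[1]][4])
  ref <- Biostrings::subseq(gm$sequences[[cn]],
                            GenomicRanges::start(rd)[idx],
                            GenomicRanges::end(rd)[idx])
  expect_equal(as.character(one), as.character(ref))
})
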