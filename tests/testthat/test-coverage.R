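test_that("a read fully inside an IES counts toward that IES only", {
  anno <- tiny_annotation()
  cov <- count_reads(tiny_reads(5000), anno)
  expect_equal(cov$count[cov$id == "IES_0001"], 1L)
  expect_equal(sum(cov$count), 1L)
})

test_that("a boundary-straddling read follows the midpoint rule", {
  anno <- tiny_annotation(ies_start = 4001)
  # read 3980-4029: midpoint 4004 lies in the IES
  cov <- count_reads(tiny_reads(3980), anno)
  expect_equal(cov$count[cov$id == "IES_0001"], 1L)
  expect_equal(cov$count[cov$id == "MDS_0001"], 0L)
  # read 3970-4019: midpoint 3994 lies in the upstream MDS
  cov2 <- count_reads(tiny_reads(3970), anno)
  expect_equal(cov2$count[cov2$id == "IES_0001"], 0L)
  expect_equal(cov2$count[cov2$id == "MDS_0001"], 1L)
  # the any-overlap rule counts it toward both
  cov3 <- count_reads(tiny_reads(3970), anno, assignment_rule = "any")
  expect_equal(sum(cov3$count), 2L)
})

test_that("midpoint counts partition uniform reads by genomic fraction", {
  gm <- small_genome(seed = 41)
  rd <- simulate_wgs(gm, small_params(seed = 41, depth = 20), "MIC")
  cov <- count_reads(rd, gm)
  expect_equal(sum(cov$count), length(rd))   # exact partition, N preserved
  ies_frac <- sum(cov$count[cov$kind == "IES"]) / sum(cov$count)
  expect_lt(abs(ies_frac - 1 / 3), 0.01)
})

test_that("reads on unknown chromosomes are skipped with a warning", {
  anno <- tiny_annotation()
  rd <- suppressWarnings(
    c(tiny_reads(5000), tiny_reads(100, chrom = "chrUn", seqlen = 10000)))
  expect_warning(cov <- count_reads(rd, anno), "skipped")
  expect_equal(attr(cov, "total_reads"), 1L)
  expect_equal(attr(cov, "skipped"), 1L)
})

test_that("RI is 1 for identical samples and drops zero-reference IESs", {
  anno <- tiny_annotation()
  rd <- tiny_reads(c(5000, 5100, 200, 9000))
  cov <- count_reads(rd, anno)
  rt <- retention_index(cov, cov)
  expect_equal(rt$ri, 1)
  # zero reference count: IES dropped and logged, never infinite
  mds_only <- count_reads(tiny_reads(c(200, 9000)), anno)
  expect_message(rt2 <- retention_index(cov, mds_only), "zero reference")
  expect_equal(nrow(rt2), 0L)
  expect_equal(attr(rt2, "dropped"), "IES_0001")
})

test_that("RI is invariant to rescaling one sample's counts", {
  gm <- small_genome(seed = 42)
  mic <- count_reads(simulate_wgs(gm, small_params(seed = 42, depth = 5),
                                  "MIC"), gm)
  p <- small_params(seed = 43, depth = 5, contamination = 0.05,
                    elimination = 0.5)
  new <- count_reads(simulate_wgs(gm, p, "newMAC"), gm)
  ri0 <- retention_index(new, mic)$ri
  scaled <- new
  scaled$count <- scaled$count * 7L
  attr(scaled, "total_reads") <- attr(new, "total_reads") * 7L
  expect_equal(retention_index(scaled, mic)$ri, ri0)
})

test_that("annotation mismatch between samples is a hard error", {
  a <- count_reads(tiny_reads(5000), tiny_annotation())
  b <- count_reads(tiny_reads(5000), tiny_annotation(ies_start = 3001))
  expect_error(retention_index(a, b), "different annotations")
})

test_that("MDS normalization rescales the RI floor as expected", {
  # complete elimination at contamination c: total-count RI floor is c;
  # normalizing by MDS counts instead multiplies it by (2/3)/(1 - c/3)
  # (MDS holds 2/3 of MIC reads but nearly all new-MAC reads)
  gm <- small_genome(seed = 44)
  mic <- count_reads(simulate_wgs(gm, small_params(seed = 44, depth = 10),
                                  "MIC"), gm)
  p <- small_params(seed = 45, depth = 10, contamination = 0.05,
                    elimination = 0)
  new <- count_reads(simulate_wgs(gm, p, "newMAC"), gm)
  ri_tot <- median(retention_index(new, mic)$ri)
  ri_mds <- median(retention_index(new, mic, normalization = "mds")$ri)
  expected_ratio <- (2 / 3) / (1 - 0.05 / 3)
  expect_lt(abs(ri_mds / ri_tot - expected_ratio), 0.07)
})

test_that("RI summaries report order statistics and threshold fractions", {
  rt <- structure(
    data.frame(id = c("a", "b", "c"), chrom = "chr1", start = 0,
               end = 1, length = 1, n_newmac = 0, n_mic = 1,
               ri = c(0, 0, 0)),
    class = c("retention_table", "data.frame"))
  s <- summarize_ri(rt)
  expect_equal(s$median, 0)
  expect_equal(unname(s$frac_below[["0.1"]]), 1)
  rt$ri <- numeric(3) * NA
  expect_error(summarize_ri(rt), "finite")
})

test_that("retention tables round-trip through TSV", {
  gm <- small_genome(seed = 46)
  mic <- count_reads(simulate_wgs(gm, small_params(seed = 46, depth = 5),
                                  "MIC"), gm)
  p <- small_params(seed = 47, depth = 5, contamination = 0.05,
                    elimination = 0)
  rt <- retention_index(count_reads(simulate_wgs(gm, p, "newMAC"), gm), mic)
  d <- withr::local_tempdir()
  tsv <- file.path(d, "ri.tsv")
  write_retention_tsv(rt, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(rt))
  expect_equal(back$ri, rt$ri, tolerance = 1e-12)
})
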