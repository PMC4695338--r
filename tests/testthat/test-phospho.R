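fx <- synthetic_pdd1()
muts <- pdd1_mutants(fx)

test_that("the two-study site merge follows inclusion-exclusion", {
  expect_equal(nrow(fx$sites_ms), 31L)
  expect_equal(nrow(fx$sites_prior), 10L)
  expect_equal(nrow(merge_site_sets(fx$sites_ms, fx$sites_prior)), 33L)
  # idempotence and disjoint union
  expect_equal(nrow(merge_site_sets(fx$sites_ms, fx$sites_ms)), 31L)
  a <- phospho_sites(fx$protein, fx$sites_ms$position[1:3], "a")
  b <- phospho_sites(fx$protein, fx$sites_ms$position[4:7], "b")
  expect_equal(nrow(merge_site_sets(a, b)), 7L)
  # shared sites carry merged provenance
  m <- merge_site_sets(fx$sites_ms, fx$sites_prior)
  shared <- intersect(fx$sites_ms$position, fx$sites_prior$position)
  expect_true(all(grepl("\\+", m$provenance[m$position %in% shared])))
})

test_that("inclusion-exclusion holds over random site subsets", {
  pool <- fx$sites_all$position
  set.seed(99)
  for (i in 1:20) {
    pa <- sample(pool, sample(3:20, 1))
    pb <- sample(pool, sample(3:20, 1))
    a <- phospho_sites(fx$protein, pa, "a")
    b <- phospho_sites(fx$protein, pb, "b")
    expect_equal(nrow(merge_site_sets(a, b)),
                 length(union(pa, pb)))
  }
})

test_that("site sets are validated against the sequence", {
  expect_error(phospho_sites(fx$protein, c(1e4)), "outside")
  not_st <- which(!strsplit(fx$protein$sequence, "")[[1]] %in%
                    c("S", "T", "Y"))[1]
  expect_error(phospho_sites(fx$protein, not_st), "Ser/Thr/Tyr")
})

test_that("MIM mutants substitute exactly k N-terminal-most S/T with Glu", {
  for (k in c(10L, 14L, 18L, 22L)) {
    sp <- muts[[sprintf("MIM%d", k)]]
    mut <- apply_mutations(fx$protein, sp)
    expect_equal(nchar(mut$sequence), nchar(fx$protein$sequence))
    pos <- sp$substitutions$position
    expect_length(pos, k)
    expect_true(all(vapply(pos, function(p)
      substr(mut$sequence, p, p), character(1)) == "E"))
    # selection is N-terminal-first from the merged set in NT/HNG regions
    in_reg <- fx$sites_all$position[fx$sites_all$position <= 400 &
                                      !(fx$sites_all$position %in% 71:130) &
                                      !(fx$sites_all$position %in% 231:290)]
    expect_equal(sort(pos), sort(in_reg)[seq_len(k)])
  }
})

test_that("insertions lengthen the chain and shift downstream regions", {
  mut <- apply_mutations(fx$protein, muts[["MIM22+Ins6K"]])
  expect_equal(nchar(mut$sequence), nchar(fx$protein$sequence) + 6L)
  # all six insertions fall in HNG2, which must grow by 6
  w0 <- with(fx$protein$regions, end[region == "HNG2"] -
               start[region == "HNG2"])
  w1 <- with(mut$regions, end[region == "HNG2"] - start[region == "HNG2"])
  expect_equal(w1, w0 + 6L)
  # CSD shifts right unchanged in width
  expect_equal(mut$regions$start[mut$regions$region == "CSD"],
               fx$protein$regions$start[fx$protein$regions$region == "CSD"] + 6L)
  # empty spec is the identity
  same <- apply_mutations(fx$protein, mutant_spec("null"))
  expect_identical(same$sequence, fx$protein$sequence)
  # mismatching 'from' residue is a hard error naming the position
  bad <- mutant_spec("bad", substitutions = data.frame(
    position = 1L, from = "W", to = "A"))
  expect_error(apply_mutations(fx$protein, bad), "mismatch at position")
})

test_that("net charge equals the sum of its per-residue breakdown", {
  rep_ <- net_charge(fx$protein, c("NT", "HNG1", "HNG2"))
  expect_equal(rep_$charge, sum(rep_$breakdown$charge))
  expect_error(net_charge(fx$protein, "NOPE"), "undefined region")
})

test_that("charge deltas of the mutant series follow construction", {
  reg <- c("NT", "HNG1", "HNG2")
  q <- function(p, ...) net_charge(p, reg, ...)$charge
  q_wt <- q(fx$protein)
  q_m22 <- q(apply_mutations(fx$protein, muts$MIM22))
  expect_equal(q_m22 - q_wt, -22)
  q_ins <- q(apply_mutations(fx$protein, muts[["MIM22+Ins6K"]]))
  q_sub <- q(apply_mutations(fx$protein, muts[["MIM22+Sub6K"]]))
  expect_equal(q_ins - q_m22, +6)
  expect_equal(q_sub - q_m22, +6)
  # fully phosphorylated at the 22 mutated sites: -2 per phosphate
  sites22 <- phospho_sites(fx$protein, muts$MIM22$substitutions$position)
  expect_equal(q(fx$protein, phospho = sites22) - q_wt, -44)
  # the milder -1.5 phosphate convention scales accordingly
  expect_equal(net_charge(fx$protein, reg, phospho = sites22,
                          phospho_charge = -1.5)$charge - q_wt, -33)
})

test_that("charge is additive for non-interacting substitution sets", {
  reg <- c("NT", "HNG1", "HNG2")
  q <- function(p) net_charge(p, reg)$charge
  s1 <- muts$MIM10$substitutions
  s2 <- muts$MIM22$substitutions[11:22, ]
  d1 <- q(apply_mutations(fx$protein, mutant_spec("a", s1))) - q(fx$protein)
  d2 <- q(apply_mutations(fx$protein, mutant_spec("b", s2))) - q(fx$protein)
  d12 <- q(apply_mutations(fx$protein, mutant_spec("ab", rbind(s1, s2)))) -
    q(fx$protein)
  expect_equal(d12, d1 + d2)
})

test_that("region charge ignores edits outside the region", {
  q_csd <- function(p) net_charge(p, "CSD")$charge
  expect_equal(q_csd(apply_mutations(fx$protein, muts$MIM22)),
               q_csd(fx$protein))
})

test_that("charge_rank orders the series WT down to MIM22 with ties at +6", {
  rk <- charge_rank(fx$protein, muts)
  expect_equal(rk$delta_vs_wt[rk$name == "WT"], 0)
  expect_equal(rk$delta_vs_wt[match(sprintf("MIM%d", c(10, 14, 18, 22)),
                                    rk$name)],
               c(-10, -14, -18, -22))
  expect_equal(rk$delta_vs_wt[rk$name == "MIM22+Ins6K"], -16)
  expect_equal(rk$delta_vs_wt[rk$name == "MIM22+Sub6K"], -16)
  ord <- rk$charge[match(c("WT", "MIM10", "MIM14", "MIM18", "MIM22"),
                         rk$name)]
  expect_true(all(diff(ord) < 0))
})

test_that("protein FASTA and site TSV loaders round-trip the fixture", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "prot.fa")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(pdd1 = fx$protein$sequence)), fa)
  back <- read_protein_fasta(fa, fx$protein$regions)
  expect_identical(back$sequence, fx$protein$sequence)
  tsv <- file.path(d, "sites.tsv")
  utils::write.table(as.data.frame(fx$sites_all), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sites <- read_sites_tsv(tsv, back)
  expect_equal(nrow(sites), 33L)
})
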