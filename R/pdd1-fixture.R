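# -- synthetic Pdd1p-like fixture ------------------------------------------
#
# The real protein's residue-level phospho-site map and insertion points
# are published only graphically, so the package ships a SYNTHETIC
# Pdd1p-like protein with the correct domain architecture (NT, CD1, HNG1,
# CD2, HNG2, CSD) and a site inventory with the documented bookkeeping: 31
# Ser/Thr sites from one mass-spectrometry study plus a 10-site set from an
# earlier study of which 2 are novel, 33 distinct sites in total, 31 of
# them in the unconserved N-terminal and hinge regions. Positions are
# placeholders; all charge arithmetic is sequence-agnostic, and real
# sequences can be supplied through read_protein_fasta()/read_sites_tsv().

pdd1_site_positions <- function() {
  list(
    nt   = c(5L, 9L, 14L, 22L, 30L, 38L, 46L, 55L, 63L),
    hng1 = c(135L, 141L, 150L, 158L, 166L, 175L, 183L, 192L, 200L, 210L,
             221L),
    hng2 = c(295L, 303L, 312L, 320L, 331L, 340L, 350L, 361L, 372L, 383L,
             395L),
    csd  = c(410L, 442L),
    prior_only = c(221L, 395L),
    prior_shared = c(5L, 14L, 135L, 158L, 200L, 303L, 331L, 410L),
    sub6k = c(298L, 308L, 318L, 328L, 338L, 348L),
    ins6k_after = c(300L, 310L, 325L, 341L, 355L, 370L)
  )
}

#' Synthetic Pdd1p-like protein fixture
#'
#' A 480-residue synthetic HP1-like protein with regions NT (1-70),
#' CD1 (71-130), HNG1 (131-230), CD2 (231-290), HNG2 (291-400) and
#' CSD (401-470), carrying 33 marked Ser/Thr phospho-sites split by
#' provenance into a 31-site mass-spectrometry set and a 10-site prior-study
#' set sharing 8 positions (2 novel). Residue positions are synthetic
#' placeholders, not the real protein's coordinates.
#'
#' @return A list with `protein` (a [protein_record()]), `sites_ms` (31
#'   sites, provenance `"ms"`), `sites_prior` (10 sites, provenance
#'   `"prior"`), and `sites_all` (their 33-site merge).
#' @examples
#' fx <- synthetic_pdd1()
#' nrow(fx$sites_all)
#' @export
synthetic_pdd1 <- function() {
  pp <- pdd1_site_positions()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  # hinge-like composition: mildly enriched for charged/polar residues
  comp <- stats::setNames(rep(1, 20), aa)
  comp[c("K", "E", "D", "N", "Q", "S", "T", "R")] <- 2.2
  seq <- with_seed(20151221L,
                   sample(aa, 480L, replace = TRUE, prob = comp))
  sites <- sort(c(pp$nt, pp$hng1, pp$hng2, pp$csd))
  seq[sites] <- rep(c("S", "T"), length.out = length(sites))
  seq[pp$sub6k] <- rep(c("Q", "N"), each = 3)

  regions <- data.frame(
    region = c("NT", "CD1", "HNG1", "CD2", "HNG2", "CSD"),
    start = c(1L, 71L, 131L, 231L, 291L, 401L),
    end = c(70L, 130L, 230L, 290L, 400L, 470L)
  )
  protein <- protein_record(paste(seq, collapse = ""), regions)
  ms_pos <- setdiff(sites, pp$prior_only)
  prior_pos <- sort(c(pp$prior_only, pp$prior_shared))
  sites_ms <- phospho_sites(protein, ms_pos, "ms")
  sites_prior <- phospho_sites(protein, prior_pos, "prior")
  list(protein = protein, sites_ms = sites_ms, sites_prior = sites_prior,
       sites_all = merge_site_sets(sites_ms, sites_prior))
}

#' Build a phospho-mimic (MIM-k) mutation spec
#'
#' Selects the k N-terminal-most phospho-sites within the unconserved
#' regions (NT, HNG1, HNG2) from a merged site set and substitutes each
#' Ser/Thr with Glu, mimicking the constitutive negative charge of
#' phosphorylation (one -1 Glu per site, deliberately weaker than the -2
#' phosphate).
#'
#' @param protein The parent `protein_record` (must define NT/HNG regions).
#' @param sites A merged `phospho_sites` set.
#' @param k Number of sites to mutate.
#' @param regions Regions from which sites are drawn.
#' @return A `mutant_spec` named `MIMk`.
#' @export
mim_spec <- function(protein, sites, k,
                     regions = c("NT", "HNG1", "HNG2")) {
  stopifnot(inherits(protein, "protein_record"),
            inherits(sites, "phospho_sites"), k >= 1)
  rr <- protein$regions[protein$regions$region %in% regions, ]
  in_reg <- vapply(sites$position, function(p)
    any(p >= rr$start & p <= rr$end), logical(1))
  cand <- sites[in_reg & sites$residue %in% c("S", "T"), ]
  if (nrow(cand) < k)
    stop_param("only ", nrow(cand), " mutable S/T sites in ",
               paste(regions, collapse = "/"), "; cannot build MIM", k)
  sel <- cand[seq_len(k), ]            # sites are stored position-sorted
  mutant_spec(sprintf("MIM%d", k),
              substitutions = data.frame(position = sel$position,
                                         from = sel$residue, to = "E"))
}

#' The standard mutant series of the synthetic Pdd1p fixture
#'
#' MIM10/14/18/22 phospho-mimic mutants plus the two charge-restored MIM22
#' variants: `MIM22+Ins6K` (six Lys insertions in HNG2) and `MIM22+Sub6K`
#' (six Gln/Asn-to-Lys substitutions in HNG2).
#'
#' @param fixture Output of [synthetic_pdd1()] (built fresh by default).
#' @return Named list of `mutant_spec`s.
#' @export
pdd1_mutants <- function(fixture = synthetic_pdd1()) {
  pp <- pdd1_site_positions()
  mims <- lapply(c(10L, 14L, 18L, 22L), function(k)
    mim_spec(fixture$protein, fixture$sites_all, k))
  names(mims) <- sprintf("MIM%d", c(10L, 14L, 18L, 22L))
  m22 <- mims$MIM22
  ins <- mutant_spec("MIM22+Ins6K",
                     substitutions = m22$substitutions,
                     insertions = data.frame(after = pp$ins6k_after,
                                             residues = "K"))
  sub_from <- residues_at(fixture$protein, pp$sub6k)
  sub <- mutant_spec("MIM22+Sub6K",
                     substitutions = rbind(
                       m22$substitutions,
                       data.frame(position = pp$sub6k, from = sub_from,
                                  to = "K")))
  c(mims, list(`MIM22+Ins6K` = ins, `MIM22+Sub6K` = sub))
}
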