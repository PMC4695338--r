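---
title: "Models and methods behind tetelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tetelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetelim)
```

`tetelim` packages the statistics used to quantify programmed DNA
elimination in *Tetrahymena* — the per-IES retention index, ChIP
fold-enrichment metagenes, protein net-charge bookkeeping and equilibrium
RNA-binding fits — together with a simulator that generates inputs with
exactly the structure those statistics assume. This vignette explains the
models, the defaults and the numerical choices, and what the synthetic
data do and do not capture about real sequencing experiments.

## The genome model

A germline (MIC) genome is a set of chromosomes, each tiled exactly into
alternating MAC-destined segments (MDS) and internal eliminated sequences
(IES). The generator draws IES lengths uniformly from `ies_length_range`
(default 1–5 kb, the class compiled by the modeled-IES metagene) and then
rescales them jointly so that total IES content hits `ies_fraction`
(default 1/3, the genomic share of IESs in this organism) to within
integer rounding. The MDS mass is distributed multinomially over the
gaps, with a floor of `min_gap` (default 200 bp) so that no IES touches a
chromosome end or another IES — metagene flanks always exist. A
consequence of the rescaling worth knowing: when `n_ies × mean length`
falls short of the target IES mass, all lengths are inflated
proportionally, so only a subset of loci remains inside the 1–5 kb
metagene class. That mirrors real annotations, where the 1–5 kb class is
likewise a filtered subset.

Defaults are desk-scale: a 5 Mb genome over 2 chromosomes with 300 IESs
at 20× coverage of 50 nt reads runs the full elimination experiment in
seconds. The acceptance script uses exactly this scale; the unit tests
use 1 Mb / 60 IESs, and sampling-noise arguments below are quoted for
those sizes.

## Read simulation

Reads are *placed reads*: coordinate-resolved records with a source
(somatic vs contaminant) and channel (WGS, IP, input). No sequencing
errors, GC bias or mappability structure is modelled and no aligner is
run — the downstream statistics consume mapped counts, and alignment is
orthogonal to them. FASTQ export exists purely for interoperability.

* **MIC reference**: read starts uniform over each chromosome,
  chromosomes weighted by length; reads straddle interval boundaries
  freely, which is what exercises the midpoint assignment rule.
* **New MAC**: each of the `N = depth × G / read_length` reads is
  contaminant with probability `c` (binomial sampling, so the realized
  fraction fluctuates as `sqrt(c(1−c)/N)`); contaminant reads are
  uniform over the whole MIC genome. Somatic reads are drawn from the
  spliced somatic template: each MDS contributes its full length, each
  IES contributes `length × retained fraction`. Somatic reads are placed
  entirely within their source interval, the coordinate-space image of
  reads from a template in which eliminated sequence is simply absent.
  This makes "complete elimination, zero contamination ⇒ zero IES reads"
  exact, at the cost of slightly under-sampling interval edges (a read
  length's worth per interval, < 5% for a 1 kb IES); the elimination-null
  median RI lands at ≈ 0.99 rather than exactly 1 for this reason, well
  inside sampling noise at the scales used.
* **ChIP**: input is uniform; IP reads are placed with per-bp weight
  `enrichment` on IES bodies and `background` elsewhere, normalized to a
  probability distribution. With E = 8 and one third of the genome in
  IESs, the expected IP read share in IES space is
  `8·(1/3) / (8·(1/3) + 1·(2/3)) = 0.8`, a closed form the tests check.

Contamination is defined per *read*, not per cell or genome copy — the
convention under which the count-ratio statistic recovers `c` exactly,
and the only one the data constrain, since real preparations are
quantified only as an approximate percentage. All randomness funnels
through one integer seed, expanded per stage by name (`stage_seed`), so a
partial configuration change does not perturb unrelated stages and every
output file regenerates byte-identically.

## The retention index

`RI_i = (n_i/N)_newMAC / (n_i/N)_MIC`. Choices that matter:

* **Normalization** is by total mapped reads (counts per million). Under
  complete elimination this makes the expected RI equal the contamination
  fraction `c` — the interpretation used when reading wild-type RI
  distributions. An alternative normalization by MDS-assigned counts is
  available (`normalization = "mds"`); it shrinks the floor by the
  predictable factor `(2/3)/(1 − c/3)` and is provided for samples where
  IES retention is so pervasive that total read count itself shifts.
* **Midpoint assignment**: a read counts toward the unique interval
  containing its midpoint. This partitions counts exactly (no double
  counting, `ΣIES + ΣMDS = N`) and is stable at boundaries. Count mode
  and per-bp coverage mode differ only by a length factor that cancels in
  the ratio, so counts are used throughout.
* **Zero reference counts** (possible in principle for a tiny IES at low
  depth) drop the IES with a logged reason; RI is never reported as
  infinite.
* Summary thresholds default to 0.001, 0.1 and 1 — the bands used to
  describe contamination-dominated wild-type samples and
  elimination-defective samples respectively; both are configurable.

## Fold enrichment and the modeled IES

Enrichment is `(IP CPM + ε)/(input CPM + ε)` over fixed windows
(default 50 bp; ε = 0.5 CPM keeps empty input windows finite and flags
them low-confidence). Note the track is input-relative, so a genome
where a third of the bases carry 8-fold weight shows IES windows at
≈ 2.4 and MDS windows at ≈ 0.3: the *ratio* of the two recovers the
simulated 8-fold, and that ratio is what the tests assert.

The modeled IES compiles all loci in an inclusive length class (default
[1000, 5000] bp, a plain reading of "1 to 5 kb") onto one axis: the body
is rescaled to `body_bins` (50) bins by linear interpolation of window
values at bin centres, flanks of `flank_bp` (2000 bp) are kept at native
scale in `flank_bins` (50) bins, and bins are averaged across loci.
Interpolation at bin centres makes the metagene of a constant track
exactly constant — no binning artifacts for any mixture of IES lengths.
Window width, bins, flank width and pseudocount are not constrained by
any published value; the defaults give smooth profiles at 20× depth and
every one is an argument. Loci whose flanks would overrun a chromosome
end are dropped and counted, keeping bins comparable across loci.

## Phospho-sites, mutants and net charge

The residue-level positions of the 33 phosphorylated Ser/Thr sites and of
the six Lys insertion points are published only as figures, so the
package ships a *synthetic* HP1-like protein (480 aa; regions NT, CD1,
HNG1, CD2, HNG2, CSD) whose site inventory reproduces the documented
bookkeeping: a 31-site mass-spectrometry set, a 10-site prior-study set
sharing 8 positions, 33 distinct sites in total, 31 of them in the
unconserved N-terminal and hinge regions. Positions are placeholders and
say so in the documentation; every charge computation is
sequence-agnostic and accepts real sequences via FASTA and site TSVs.

Mutant construction: `MIM-k` substitutes the k N-terminal-most merged
sites within NT/HNG1/HNG2 with Glu (the selection order is a package
convention — the published mutants are drawn, not listed); `+Ins6K`
inserts six lysines in HNG2, shifting downstream regions; `+Sub6K`
mutates six hinge Gln/Asn to Lys. Net charge uses a neutral-pH table
(D/E −1, K/R +1, H 0) with phosphate at −2 per site (−1.5 available,
reflecting partial protonation); a phospho-mimic Glu is deliberately −1,
encoding the fact that Glu only partially mimics phosphate charge. These
conventions give the series its defining arithmetic — MIM22 sits 22
charges below wild type, both charge-restored variants sit at
MIM22 + 6, and full phosphorylation of the same 22 sites would be −44 —
which the tests assert as exact integers.

## Equilibrium binding and K_d estimation

One RNA (concentration R, default 10.4 nM) carries `n_sites` independent,
identical sites with dissociation constant K_d. Per-site occupancy is
`θ = P_free/(K_d + P_free)`; with depletion accounting, P_free solves the
mass balance `P_free = P − n·R·θ`, whose unique root in [0, P] is taken
from the quadratic in closed form. Fraction bound is defined as the
probability an RNA carries ≥ 1 protein, `f = 1 − (1−θ)^n` — the quantity
a gel quantifies when any shifted species counts as bound — and the
shift-class distribution is Binomial(n, θ), the model's account of
multiple band shifts. Hill-type cooperativity is deliberately excluded:
no published fit constrains it, and independent sites already explain
multiple shifts.

Fitting minimizes squared error over `log10(K_d)` on [−2, 5] (positivity
and conditioning across the 0–630 nM ladder): a 0.25-spaced coarse grid
locates the basin, then 1-D golden-section/parabolic optimization
(`stats::optimize`, tol 1e-10) refines it; the objective is smooth and
unimodal in one dimension so this is exact for practical purposes, and
noise-free self-consistency recovers generating constants to ≪ 1%. A
series whose maximum observed fraction bound is below `min_signal`
(default 0.05, a gel quantification floor) returns an explicit
no-binding result carrying the largest probed concentration as a K_d
lower bound — the honest summary for a non-interacting mutant — rather
than a runaway estimate. Bootstrap CIs resample titration points.

## What the simulations do not show

Passing tests on synthetic data demonstrate that the statistics recover
the parameters of the generating model under its assumptions: uniform
read placement, independent reads, exact annotations, binomial
contamination, ideal equilibrium binding. They do not demonstrate
robustness to mappability artifacts, copy-number structure, annotation
error, partial IES boundary usage, gel-quantification bias or
cooperative binding. Real analyses should treat the contamination floor
as sample-specific (estimable as the wild-type median RI itself) and the
metagene defaults as tunable display parameters, not inferences.
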