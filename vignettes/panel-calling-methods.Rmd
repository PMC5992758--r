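---
title: "Methods: somatic calling for noisy targeted panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic calling for noisy targeted panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Setting

`panelcall` targets the hardest common case in clinical cancer panels:
formalin-fixed, paraffin-embedded (FFPE) tumor tissue sequenced deeply over
a small capture design, with no matched normal — only an unmatched pooled
normal as the background sample. Formalin fixation damages DNA and inflates
low-VAF substitution artifacts (classically C>T from cytosine deamination),
with errors that are correlated across nearby positions, strand-asymmetric,
and concentrated near fragment ends. Error rates differ between labs,
platforms and storage times, so the package avoids modelling them
parametrically: candidate extraction and filtering are built on
non-parametric tests, and every rate a filter needs is estimated from the
data being analysed ("internal controls") rather than fixed a priori.

Three callers share this philosophy:

* **SNV/indel** (`call_snvs()`): Fisher-exact extraction against the
  control pileup, then a cascade of noise filters.
* **Fusion** (`call_fusions()`): split-read discovery over local
  alignments, with a virtual-junction rescue step.
* **Copy number** (`call_cnas()`): GC-corrected logR, windowed circular
  binary segmentation (CBS) with a Mann–Whitney statistic, segment
  abortion, bootstrap classification.

# SNV/indel calling

## Extraction

At every covered target position, each non-reference allele key (A/C/G/T,
`ins:<seq>`, `del:<len>`; indels left-aligned and keyed at the preceding
base) with at least `min_alt` (default 3) supporting tumor reads is tested
with a one-sided Fisher exact test on the 2×2 table of tumor alt/ref versus
control alt/ref counts. One-sided because somatic calling is directional:
only enrichment in the tumor is of interest. Candidates are emitted at
`p <= alpha_extract` (default 1e-4). The test is the exact hypergeometric
tail, so it makes no assumption about Phred calibration or error rates —
the reason a non-parametric extraction was chosen over likelihood or
Bayesian callers for FFPE material. There is deliberately **no hard VAF
cutoff** anywhere in the pipeline.

Before extraction, prep filters admit reads to the pileup: mapping quality
at least `min_mapq` (default 20), base quality at least `min_baseq`
(default 20, failing bases masked individually), duplicates/secondary/
supplementary records dropped. MQ0 reads are excluded from counts but
their per-site overlap is tallied, because the MQ0 filter needs it.

## The noise-filter cascade

Eight noise filters run for Illumina data, nine for Ion (the BQ-drop
filter applies only to Ion indels). All verdicts are recorded for every
candidate; the reported status is the first failure in the documented
order, and the filters of set 1 are independent given the pileup, so their
internal order cannot change which candidates survive.

1. **Misalignment** — misaligned reads come from elsewhere and carry
   several extra mismatches each. The filter derives a high-mismatch
   threshold from the mismatch counts of non-supporting reads at the same
   site (one above their 99.5th percentile, at least 2) and binomially
   tests the number of supporting reads at or above it against the
   background fraction. Testing the *count of high-mismatch reads* rather
   than the summed mismatch load makes the filter insensitive to ordinary
   sequencing noise on the supporting reads, which matters at depth ~1000
   where even a true variant has dozens of supports.
2. **Strand bias** — one-sided Fisher test of alt fwd/rev against ref
   fwd/rev, in the direction of the observed alt imbalance; fails only if
   significant *and* the alt strand ratio is more extreme than the ref
   ratio (a skewed site skews both).
3. **Within-long-homopolymer** — fails candidates inside (or, for indels,
   adjacent to) a single-base reference run of ≥ 8 bp (inclusive).
4. **MQ0** — fails when MQ0 overlaps / (MQ0 + counted depth) strictly
   exceeds 0.1.
5. **Read-end call** — FFPE damage and adapter chemistry concentrate
   artifacts near fragment ends; one-sided Fisher on within-5bp-of-end vs
   beyond counts, alt vs ref calls at the same site. Fewer than two alt
   reads pass vacuously.
6. **Surrounded-by-dust** — counts window positions (±10 bp) carrying
   low-VAF third-allele noise (≥ 2 reads and ≥ 2% VAF) and tests the count
   against the panel-wide noisy-position rate with a binomial tail. This
   targets the "noise around the variant" situation typical of damaged
   templates.
7. **Abnormal BQ drop** (Ion indels only) — fails when mean base quality
   downstream of the event on supporting reads drops by more than 10
   relative to upstream.
8. **Second Fisher with mismatch and trim cleaning** — reads whose
   extra-mismatch count exceeds the internal-control cutoff are removed,
   the terminal 5 bp of every remaining read are trimmed from counting, the
   2×2 table is rebuilt from cleaned tumor and control reads and the
   one-sided Fisher test re-run at `alpha_extract`.
9. **VAF-lees** — see below.

After the cascade, the **germline filter** removes candidates matching a
SNP-database site and candidates whose VAF falls in the heterozygous band
[0.40, 0.60] or the homozygous band (0.96, 1] — the pragmatic heuristic for
unmatched calling. It runs last so its verdicts are visible on otherwise
clean calls.

## The VAF-lees model

Even after per-site filtering, a residue ("lees") of low-VAF calls can
survive for no identifiable mechanical reason. The VAF distribution of the
surviving candidates is modelled as a mixture of beta distributions. EM is
run for k = 1..10 components with 5 restarts each (first restart a
deterministic quantile-spread moment initialisation, later restarts
jittered under the run seed); the M-step maximises the weighted beta
likelihood exactly through its sufficient statistics (weighted means of
log x and log(1−x)) by damped Newton, so the observed-data log-likelihood
is non-decreasing. Model selection minimises ICL-BIC
(−2·loglik + ν·log n + 2·entropy, ν = 3k−1), which penalises overlapping
components harder than BIC; ties break toward fewer components. Boundary-
degenerate fits are avoided by clamping shapes to [1e-4, 1e6] rather than
by an extra penalty.

If some component's mean α/(α+β) lies in the configured low band (default
[0.01, 0.03] — a peak of calls at 1–3% VAF), that component is declared the
error component, and every candidate is tested with the exact beta-binomial
upper tail of (alt | depth) under (α, β): calls *consistent* with the error
component (tail p > `alpha_lees`, default 0.05) are removed; calls
significantly above it stay. With fewer than 20 usable VAFs, or no
component in the band, the filter is vacuous — deliberately conservative.

# Fusion calling

Reads are locally aligned (Smith–Waterman via `pairwiseAlignment`; an
external `bwa bwasw` engine is available for realistic reference sizes —
local alignment is used precisely because split reads then fall out of the
aligner directly). The **2map** step keeps reads whose left and right
portions (each ≥ 20 bp) align to two different genes, derives the
breakpoint pair from the junction-side alignment ends, clusters pairs
within ±5 bp and reports the modal breakpoint; reads split across three or
more loci are dropped, as are candidates not touching a user-indicated
gene. The **virtual fusion (VF)** step builds a 2×200 bp junction sequence
from the reference around the clustered breakpoints and rescues reads that
2map missed because one side was too short to seed an alignment: a read
counts if it aligns across the junction nearly full-length (identity
≥ 95%) with at least one base on each side, toward at most one candidate
(best identity; ties dropped). In paired-end mode, discordant mates
mapping cleanly to the two genes within 1 kb of the breakpoints add
`pair_support`; by default pairs corroborate but do not enter the ranking
total, since split evidence pinpoints the junction while pair evidence
only brackets it (configurable).

Candidates are ranked by total support; each candidate's S/N ratio is its
support divided by the best other candidate's (infinite when it is alone),
and normalized support is support over all mapped reads. S/N > 1 means the
true fusion ranks first.

# Copy-number calling

Depths are averaged in ≤ 100 bp bins tiled over the targets (fixed-width
bins within each target; per-bin GC from the reference). LOWESS of depth
on GC (span 2/3, fitted over ≥ 50 usable bins) rescales each bin by
median-depth / fitted-depth, separately in tumor and control. logR is
log2(tumor/control) per bin, median-centered — which assumes the panel is
majority-neutral; a panel dominated by CNAs would shift the baseline. Bins
with zero depth or missing GC are masked; bins whose GC lies outside the
central 98% of the panel's GC distribution are flagged (GC correction is
weakest there, a known failure mode on high-GC regions, and no fix is
attempted).

Each chromosome's bins are split into windows of 500 bins and CBS runs
within each window: the circularised sequence is cut at the arc maximising
the standardized Mann–Whitney statistic (rank-sum of the arc against its
complement, tie-corrected, with continuity correction; arcs shorter than
`min_width` = 3 bins are not candidates), the cut is accepted when its
permutation p (1000 label permutations, early-stopped once `alpha_seg` =
0.01 is unreachable) is significant, and recursion continues on the
pieces. Because the circular test accepts an *arc* rather than each of its
two cuts individually, a split can leave a short flank whose own boundary
was never tested; a pruning pass therefore re-tests every adjacent segment
pair with the same Mann–Whitney rule and merges where it fails to reject.
Neighbouring windows are then compiled the same way: terminal segments
merge when the test finds no evidence their levels differ. The
**abortion rule** discards segments in which more than 30% of bins deviate
from the segment median by more than 0.5 logR — heterogeneous segments are
not trustworthy CNA evidence in FFPE data. Surviving segments are
classified by a bootstrap of the segment median (1000 resamples): AMP when
the 95% interval's lower bound exceeds 0.8, DEL when the upper bound is
below −0.8, otherwise neutral. At tumor purity p the attainable logR
scales as log2(1 + p·(c/2 − 1)), so the defaults correspond to ≥ 4 copies
(resp. homozygous-like loss) at full purity; they are configurable and a
single run seed governs permutations and bootstrap.

# The synthetic-data generators

The generators exist so every stage is testable with no external data, and
their defaults are the conditions the tests use:

* `sim_reference()` — random contigs with controllable GC, one per gene,
  with 200 bp off-target shoulders so coverage does not collapse at target
  edges (as with real capture).
* `sim_snv_reads()` — uniform read starts to a target mean depth (default
  970×, the depth a power calculation for ~1000× panels aims at), constant
  Phred 30 bases, planted variants carried with probability purity × allele
  fraction. FFPE damage is modelled as C>T proposals at rate 3e-3 per base,
  thinned to reference C positions, with 85% of events on forward-
  orientation reads and 3× enrichment in the terminal 5 bp; independent
  substitution error at 1e-3 per base everywhere. These rates were chosen
  once as qualitatively FFPE-like (strand asymmetry, end concentration,
  low-VAF piles) and are documented parameters, not fitted quantities.
* `sim_fusion_reads()` — chimeric reads across a declared junction with
  uniform split positions, optional ±jitter, random-gene-pair noise
  chimeras and plain background reads.
* `sim_depth_profile()` — Poisson depths around piecewise-constant
  copy-number truth with an optional linear GC bias 1 + b·(gc − 0.5).

What the generators do **not** emulate: fragment-size distributions,
sequencer-specific error spectra (no flow-space indel errors), mapping
ambiguity (simulated reads are placed, not realigned), real SNP linkage,
and capture efficiency variation beyond the GC term. Passing tests
therefore demonstrate the statistical machinery under controlled noise,
not performance on any particular instrument or tissue archive.

Sizes used by the test-suite: the dilution-series check runs a 50 kb panel
(25 genes × 2 kb) at ~970× with 50 heterozygous variants at 10% tumor
fraction; mixture recovery uses 20 replicates of n = 1000; segmentation
recovery uses 20 replicates of 120-bin profiles with 30-bin segments.
These were chosen as the smallest sizes at which the statistics being
tested operate in their intended regime.

# Numerical and design choices

* Coordinates are 1-based closed internally (the GRanges/Biostrings
  convention this implementation is built on); BED input and BEDPE output
  are converted at the boundary, VCF/SEG are 1-based.
* Boundary conventions: homopolymer length threshold inclusive; MQ0
  fraction strict; germline heterozygous band closed, homozygous band open
  at 0.96.
* Fisher tails are computed as exact hypergeometric tails (`phyper`);
  beta-binomial tails by direct log-space summation, accurate to well
  below 1e-9 at panel depths.
* EM ties in ICL-BIC break toward smaller k; the EM iteration cap (150)
  binds only for overparameterised k on well-separated data, where the fit
  is discarded by model selection anyway.
* Degenerate inputs: empty read sets produce empty outputs; a constant
  logR series is one segment (the rank statistic is undefined, no split is
  accepted); single-bin segments are never aborted; candidates with no
  control coverage are tested against zeros and flagged.
* Duplicate reads are dropped by flag before pileups and collapsed by
  read name before fusion support counting, so PCR amplification cannot
  inflate evidence.

# Limitations

Unmatched calling cannot separate rare germline variants from somatic ones
beyond the SNP-database and VAF-band heuristics; matched normals remain
preferable when available. The fusion caller only finds fusions touching a
user-indicated gene and does not handle three-way or reciprocal events.
The CNA caller reports relative copy state only — no purity/ploidy
estimation, no allele-specific copy number — and inherits the weakness of
GC correction at extreme GC. The simulators are deliberately simple; see
above for what they do not model.
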