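# panelcall

Somatic SNV/indel, gene-fusion and copy-number calling for deep targeted
sequencing of degraded (FFPE) tumor samples against an **unmatched**
pooled-normal control.

FFPE fixation damages DNA: low-VAF substitution artifacts (classically
C>T), correlated errors around damaged templates, strand asymmetry, and
noise concentrated near fragment ends. Error rates vary by lab, platform
and block age, so `panelcall` avoids parametric error models. Candidates
are extracted with exact non-parametric tests and then scrubbed by filters
whose thresholds are **internal controls estimated from the data being
analysed** — mismatch rates from non-supporting reads, noisy-position
rates from the rest of the panel, an error component fitted to the VAF
distribution itself.

## The three callers

**SNV/indel — `call_snvs()`.** At each covered position, every
non-reference allele with ≥ 3 tumor reads is tested with a one-sided
Fisher exact test on tumor alt/ref vs control alt/ref counts
(`p ≤ 1e-4` to become a candidate; exact hypergeometric tail, no Phred
assumptions, no hard VAF cutoff). Candidates then pass a cascade of eight
noise filters (nine on Ion data): misalignment, strand bias,
within-long-homopolymer, MQ0, read-end call, surrounded-by-dust, abnormal
BQ drop (Ion indels), a second Fisher test after removing high-mismatch
reads and trimming read ends, and the **VAF-lees** filter — the VAF
distribution of surviving calls is fitted as a beta mixture by EM
(k = 1..10, ICL-BIC model selection); if a component peaks at 1–3% VAF it
is declared the error component and calls consistent with its
beta-binomial (upper-tail p > 0.05) are removed as residual "lees".
Finally, likely germline variants are removed: SNP-database matches and
VAFs in [40%, 60%] or above 96%.

**Fusion — `call_fusions()`.** Local (Smith–Waterman) alignment yields
split reads directly: the *2map* step keeps reads whose two portions map
to two different genes (≥ 20 bp each side), clusters breakpoints within
±5 bp, and the *virtual fusion* step rescues reads whose short side could
not seed an alignment by aligning them across a constructed junction
sequence (≥ 95% identity, ≥ 1 base on each side). Discordant mate pairs
corroborate in paired-end mode. Candidates are ranked by support; the S/N
ratio (support over the strongest other candidate, ∞ when alone) above 1
means the true fusion ranks first.

**Copy number — `call_cnas()`.** Binned depths are GC-corrected by LOWESS
in tumor and control, logR = log2(tumor/control) is median-centered, and
each chromosome is segmented by windowed circular binary segmentation
using a standardized Mann–Whitney statistic with permutation p-values,
followed by boundary pruning and window compilation. Segments where > 30%
of bins stray > 0.5 logR from the segment median are *aborted* (too
heterogeneous to trust); the rest are classified AMP/DEL/NEUTRAL by a
bootstrap interval of the segment median against logR ±0.8.

Seeded simulators (`sim_reference()`, `sim_variant_truth()`,
`sim_snv_reads()`, `sim_fusion_reads()`, `sim_depth_profile()`) generate
FFPE-like fixtures with known ground truth, so the whole suite is testable
offline. See the methods vignette
(`vignettes/panel-calling-methods.Rmd`) for the statistical details and
the design rationale.

## Worked example

Plant six heterozygous somatic variants in a 20% purity tumor at 400×
over a small 4-gene panel, with FFPE-like damage, and call against a clean
unmatched normal:

```r
library(panelcall)

sim   <- sim_reference(n_genes = 4, gene_len = 1500, seed = 1)
truth <- sim_variant_truth(sim$reference, sim$genes, n = 6, seed = 2)
tumor <- sim_snv_reads(sim$reference, sim$genes, truth, purity = 0.2,
                       depth = 400, ffpe_rate = 3e-3, seed = 3)
normal <- sim_snv_reads(sim$reference, sim$genes, depth = 400, seed = 4)

res <- call_snvs(tumor, normal, sim$genes, sim$reference)
res$candidates[, c("chrom", "pos", "ref", "alt", "tumor_alt",
                   "tumor_ref", "vaf", "p_fisher", "status")]
#>    chrom   pos    ref    alt tumor_alt tumor_ref        vaf     p_fisher status
#> 1: gene1  1083      T      G        49       385 0.11290323 7.760731e-14   PASS
#> 2: gene1  1185      A      G        52       373 0.12235294 5.696621e-14   PASS
#> 3: gene1  1438      A      C        35       311 0.10115607 3.829457e-12   PASS
#> 4: gene2   853      A      G        42       329 0.11320755 1.881923e-14   PASS
#> 5: gene3  1033      A      T        50       318 0.13586957 6.449680e-17   PASS
#> 6: gene4   602      A      C        31       359 0.07948718 6.759179e-11   PASS
```

All six planted variants come back as `PASS` at VAFs near the expected
10% (purity 0.2 × allele fraction 0.5), each with its extraction Fisher p;
`write_vcf(res, sim$reference, "calls.vcf")` writes them with the full
per-filter verdicts in INFO. FFPE artifact piles and germline-like VAFs
are rejected by the cascade — the same fixtures with shared tumor/control
truth yield zero PASS calls (see `tests/testthat/test-acceptance.R`).

A command-line wrapper with `snv`, `fusion`, `cna` and `simulate`
subcommands is installed as `inst/exec/panelcall` (exit codes: 0 ok,
2 usage, 3 input, 4 runtime).

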