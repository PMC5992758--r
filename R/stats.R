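# Shared test statistics. Fisher one-sided p-values are hypergeometric
# tails computed with phyper (exact); the beta-binomial tail is a direct
# log-space summation, stable up to the depths a capture panel produces.

#' One-sided Fisher exact p for a 2x2 table (enrichment of alt in tumor)
#'
#' Probability of observing `t_alt` or more alt reads in the tumor margin of
#' the table \[tumor alt/ref vs control alt/ref\] under the hypergeometric
#' null. Vectorised over all arguments.
#'
#' @param t_alt,t_ref Tumor alt / ref read counts.
#' @param c_alt,c_ref Control alt / ref read counts.
#' @return p-values in (0, 1].
#' @export
fisher_tail <- function(t_alt, t_ref, c_alt, c_ref) {
  stats::phyper(t_alt - 1, t_alt + c_alt, t_ref + c_ref, t_alt + t_ref,
                lower.tail = FALSE)
}

#' Beta-binomial upper-tail probability
#'
#' P(X >= x) for X ~ BetaBinomial(n, alpha, beta), by direct summation in
#' log space. Used by the VAF-lees filter to ask whether an alt count is
#' larger than the background error component explains.
#'
#' @param x Observed alt count (vectorised).
#' @param n Depth (vectorised).
#' @param alpha,beta Beta shape parameters of the error component.
#' @return Upper-tail probabilities in \[0, 1\].
#' @export
beta_binom_tail <- function(x, n, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  mapply(function(xi, ni) {
    if (xi <= 0) return(1)
    if (xi > ni) return(0)
    k <- xi:ni
    sum(exp(lchoose(ni, k) + lbeta(k + alpha, ni - k + beta) -
              lbeta(alpha, beta)))
  }, x, n)
}

#' Extract variant candidates by Fisher's exact test
#'
#' For every non-reference allele key (A/C/G/T, `ins:<seq>`, `del:<len>`)
#' with at least `min_alt` supporting tumor reads, tests the 2x2 table of
#' tumor alt/ref versus control alt/ref counts (one-sided, enrichment in the
#' tumor) and emits candidates at `p <= alpha_extract`. Sites absent from the
#' control pileup are tested against zero counts and flagged
#' (`control_missing`).
#'
#' @param tumor,control `pileup` objects over the same targets.
#' @param alpha_extract p-value cutoff for emission.
#' @param min_alt Minimum tumor alt reads.
#' @return data.table of candidates: chrom, pos, ref, alt, tumor_alt,
#'   tumor_ref, control_alt, control_ref, vaf, p_fisher, odds_ratio,
#'   control_missing.
#' @export
fisher_extract <- function(tumor, control, alpha_extract = 1e-4,
                           min_alt = 3L) {
  ta <- tumor$alleles
  ts <- tumor$sites
  # alt alleles: anything differing from the reference base at the site
  cand <- merge(ta, ts[, c("chrom", "pos", "ref")], by = c("chrom", "pos"))
  cand <- cand[cand$allele != cand$ref]
  cand[, "tumor_alt" := cand$fwd + cand$rev]
  cand <- cand[cand$tumor_alt >= min_alt]
  if (!nrow(cand)) return(empty_candidates())

  # reference-allele counts in each sample
  tref <- merge(ta, ts[, c("chrom", "pos", "ref")], by = c("chrom", "pos"))
  tref <- tref[tref$allele == tref$ref]
  tref <- tref[, list(chrom = tref$chrom, pos = tref$pos,
                      tumor_ref = tref$fwd + tref$rev)]
  cand <- merge(cand, tref, by = c("chrom", "pos"), all.x = TRUE)
  cand[is.na(cand$tumor_ref), "tumor_ref" := 0L]

  ca <- control$alleles
  calt <- ca[, list(chrom = ca$chrom, pos = ca$pos, allele = ca$allele,
                    control_alt = ca$fwd + ca$rev)]
  cand <- merge(cand, calt, by = c("chrom", "pos", "allele"), all.x = TRUE)
  cs <- control$sites
  cref <- merge(ca, cs[, c("chrom", "pos", "ref")], by = c("chrom", "pos"))
  cref <- cref[cref$allele == cref$ref]
  cref <- cref[, list(chrom = cref$chrom, pos = cref$pos,
                      control_ref = cref$fwd + cref$rev)]
  cand <- merge(cand, cref, by = c("chrom", "pos"), all.x = TRUE)
  cand[, "control_missing" := is.na(cand$control_alt) & is.na(cand$control_ref)]
  cand[is.na(cand$control_alt), "control_alt" := 0L]
  cand[is.na(cand$control_ref), "control_ref" := 0L]

  cand[, "p_fisher" := fisher_tail(cand$tumor_alt, cand$tumor_ref,
                                   cand$control_alt, cand$control_ref)]
  or <- (cand$tumor_alt * pmax(cand$control_ref, 0.5)) /
    (pmax(cand$tumor_ref, 0.5) * pmax(cand$control_alt, 0.5))
  cand[, "odds_ratio" := or]
  cand[, "vaf" := cand$tumor_alt / (cand$tumor_alt + cand$tumor_ref)]
  cand <- cand[cand$p_fisher <= alpha_extract]
  if (any(cand$control_missing)) {
    warning(sum(cand$control_missing),
            " candidate site(s) without control coverage")
  }
  out <- cand[, c("chrom", "pos", "ref", "allele", "tumor_alt", "tumor_ref",
                  "control_alt", "control_ref", "vaf", "p_fisher",
                  "odds_ratio", "control_missing")]
  data.table::setnames(out, "allele", "alt")
  data.table::setorderv(out, c("chrom", "pos", "alt"))
  out[]
}

empty_candidates <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         tumor_alt = integer(), tumor_ref = integer(),
                         control_alt = integer(), control_ref = integer(),
                         vaf = numeric(), p_fisher = numeric(),
                         odds_ratio = numeric(), control_missing = logical())
}
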