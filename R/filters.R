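# The noise-filter cascade. Each filter is a pure function returning a
# verdict (filter name, pass flag, statistic, threshold, detail); the cascade
# runner assembles per-candidate context from the pileups, runs every filter
# (verdicts are independent given the pileup, so all are recorded regardless
# of earlier failures) and sets the candidate status to the first failing
# filter in the documented order, or PASS.
#
# Internal controls: the misalignment, dust and second-Fisher filters compare
# the candidate against error rates estimated from non-supporting reads or
# non-candidate positions of the same sample — nothing about the error
# process is hard-coded.

verdict <- function(filter, passed, statistic = NA_real_,
                    threshold = NA_real_, detail = "") {
  data.table::data.table(filter = filter, passed = passed,
                         statistic = as.numeric(statistic),
                         threshold = as.numeric(threshold), detail = detail)
}

#' Registered noise filters for a platform
#'
#' The Illumina cascade runs eight noise filters; Ion data adds the
#' abnormal-BQ-drop filter (indels only), for nine.
#'
#' @param platform "illumina" or "ion".
#' @return Character vector of filter names in cascade order.
#' @export
noise_filters <- function(platform = c("illumina", "ion")) {
  platform <- match.arg(platform)
  set1 <- c("misalignment", "strand_bias", "homopolymer", "mq0", "read_end",
            "dust")
  if (platform == "ion") set1 <- c(set1, "bq_drop")
  c(set1, "second_fisher", "vaf_lees")
}

#' Strand-bias filter
#'
#' One-sided Fisher test (in the direction of the observed alt imbalance) of
#' alt forward/reverse versus ref forward/reverse counts. Fails when the test
#' is significant and the alt strand ratio is more extreme than the ref
#' strand ratio; zero alt reads pass vacuously.
#'
#' @param alt_fwd,alt_rev,ref_fwd,ref_rev Strand-split read counts.
#' @param alpha Significance cutoff.
#' @return A one-row verdict data.table.
#' @export
filter_strand_bias <- function(alt_fwd, alt_rev, ref_fwd, ref_rev,
                               alpha = 1e-3) {
  if (alt_fwd + alt_rev == 0) {
    return(verdict("strand_bias", TRUE, detail = "no alt reads"))
  }
  p <- min(fisher_tail(alt_fwd, alt_rev, ref_fwd, ref_rev),
           fisher_tail(alt_rev, alt_fwd, ref_rev, ref_fwd))
  alt_ratio <- alt_fwd / (alt_fwd + alt_rev)
  ref_ratio <- if (ref_fwd + ref_rev > 0) ref_fwd / (ref_fwd + ref_rev) else 0.5
  more_extreme <- abs(alt_ratio - 0.5) > abs(ref_ratio - 0.5)
  verdict("strand_bias", !(p <= alpha && more_extreme), p, alpha)
}

#' Misalignment filter
#'
#' Misaligned reads carry several additional mismatches each, because the
#' whole read comes from somewhere else. The filter counts supporting reads
#' whose extra-mismatch load reaches a high-mismatch threshold derived from
#' the non-supporting reads of the same window (an internal control: one
#' above their 99.5th percentile, at least 2) and tests that count against
#' the background fraction of such reads with a binomial tail. Variants
#' whose supporting reads look like the background pass regardless of
#' ordinary sequencing noise.
#'
#' @param supp_extra Integer vector: extra (non-candidate) mismatches per
#'   supporting read.
#' @param bg_mism Integer vector: mismatch counts of non-supporting reads.
#' @param alpha Significance cutoff.
#' @return A one-row verdict data.table.
#' @export
filter_misalignment <- function(supp_extra, bg_mism, alpha = 1e-3) {
  if (!length(bg_mism)) {
    return(verdict("misalignment", TRUE, detail = "insufficient control"))
  }
  if (!length(supp_extra)) {
    return(verdict("misalignment", TRUE, detail = "no alt reads"))
  }
  thr <- max(2, stats::quantile(bg_mism, 0.995, names = FALSE) + 1)
  bg_frac <- (sum(bg_mism >= thr) + 0.5) / (length(bg_mism) + 1)
  x <- sum(supp_extra >= thr)
  p <- stats::pbinom(x - 1, length(supp_extra), min(bg_frac, 1),
                     lower.tail = FALSE)
  verdict("misalignment", p > alpha, p, alpha,
          sprintf("%d/%d high-mismatch (thr=%g), bg=%.3g", x,
                  length(supp_extra), thr, bg_frac))
}

#' Within-long-homopolymer filter
#'
#' Fails a candidate lying in (or, for an indel keyed at the preceding base,
#' immediately adjacent to) a single-base reference run of at least
#' `run_len` bp (inclusive threshold).
#'
#' @param reference DNAStringSet or DNAString.
#' @param chrom,pos Candidate site (1-based).
#' @param run_len Inclusive run-length threshold.
#' @return A one-row verdict data.table.
#' @export
filter_homopolymer <- function(reference, chrom, pos, run_len = 8L) {
  half <- run_len + 2L
  ctx <- as.character(ref_slice(reference, chrom, pos - half, pos + half,
                                truncate = TRUE))
  lo <- max(1L, pos - half)
  r <- rle(strsplit(ctx, "")[[1]])
  ends <- cumsum(r$lengths) + lo - 1L
  starts <- ends - r$lengths + 1L
  # runs covering pos or either neighbour (indels are keyed at the base
  # before the event)
  touching <- starts <= pos + 1L & ends >= pos - 1L
  longest <- if (any(touching)) max(r$lengths[touching]) else 0L
  verdict("homopolymer", longest < run_len, longest, run_len)
}

#' MQ0 filter
#'
#' Fails when the fraction of mapping-quality-zero reads overlapping the
#' site, among MQ0 plus counted reads, strictly exceeds `frac`.
#'
#' @param mq0 MQ0 overlap count at the site.
#' @param depth Counted depth at the site.
#' @param frac Maximum tolerated MQ0 fraction (strict inequality).
#' @return A one-row verdict data.table.
#' @export
filter_mq0 <- function(mq0, depth, frac = 0.1) {
  ratio <- if (mq0 + depth > 0) mq0 / (mq0 + depth) else 0
  verdict("mq0", ratio <= frac, ratio, frac)
}

#' Read-end-call filter
#'
#' Fails when alt calls are significantly concentrated within `end_bp` of a
#' read end compared with ref calls at the same site (one-sided Fisher).
#' Fewer than two alt reads pass vacuously.
#'
#' @param alt_dist,ref_dist Distances (bp) of alt / ref calls from the
#'   nearer read end.
#' @param end_bp Terminal window regarded as a read end.
#' @param alpha Significance cutoff.
#' @return A one-row verdict data.table.
#' @export
filter_read_end <- function(alt_dist, ref_dist, end_bp = 5L, alpha = 1e-3) {
  alt_dist <- alt_dist[!is.na(alt_dist)]
  ref_dist <- ref_dist[!is.na(ref_dist)]
  if (length(alt_dist) < 2) {
    return(verdict("read_end", TRUE, detail = "fewer than 2 alt reads"))
  }
  aw <- sum(alt_dist < end_bp); ab <- length(alt_dist) - aw
  rw <- sum(ref_dist < end_bp); rb <- length(ref_dist) - rw
  p <- fisher_tail(aw, ab, rw, rb)
  verdict("read_end", p > alpha, p, alpha,
          sprintf("alt %d/%d ref %d/%d within %dbp", aw, aw + ab, rw, rw + rb,
                  end_bp))
}

#' Surrounded-by-dust filter
#'
#' Counts window positions (candidate excluded) carrying low-VAF
#' non-reference noise and tests the count against the sample-wide noisy-
#' position rate (internal control) with a binomial tail. A window of size
#' zero passes with a note.
#'
#' @param n_noisy Noisy positions observed in the window.
#' @param n_window Window positions examined.
#' @param bg_rate Sample-wide fraction of noisy positions.
#' @param alpha Significance cutoff.
#' @return A one-row verdict data.table.
#' @export
filter_dust <- function(n_noisy, n_window, bg_rate, alpha = 1e-3) {
  if (n_window == 0) {
    return(verdict("dust", TRUE, detail = "empty window"))
  }
  p <- stats::pbinom(n_noisy - 1, n_window, min(max(bg_rate, 1e-12), 1),
                     lower.tail = FALSE)
  verdict("dust", p > alpha, p, alpha,
          sprintf("%d/%d noisy, bg=%.3g", n_noisy, n_window, bg_rate))
}

#' Abnormal-BQ-drop filter (Ion indels only)
#'
#' Ion indel artifacts often show a collapse of base quality downstream of
#' the event on supporting reads. Applied only when `platform == "ion"` and
#' the candidate is an indel; otherwise records a not-applicable pass.
#'
#' @param platform "illumina" or "ion".
#' @param is_indel Candidate is an insertion/deletion.
#' @param up_mean,down_mean Mean base quality up/downstream of the event on
#'   supporting reads.
#' @param delta Maximum tolerated drop (up - down).
#' @return A one-row verdict data.table.
#' @export
filter_bq_drop <- function(platform, is_indel, up_mean, down_mean,
                           delta = 10) {
  if (platform != "ion" || !is_indel) {
    return(verdict("bq_drop", TRUE, detail = "not applicable"))
  }
  if (is.na(up_mean) || is.na(down_mean)) {
    return(verdict("bq_drop", TRUE, detail = "no flanking bases"))
  }
  drop <- up_mean - down_mean
  verdict("bq_drop", drop <= delta, drop, delta)
}

#' Second Fisher pass with mismatch and trim cleaning
#'
#' Removes reads whose extra-mismatch count exceeds an internal-control
#' cutoff (a high quantile of the mismatch counts of non-supporting tumor
#' reads), excludes calls within `trim_bp` of a read end, recomputes the 2x2
#' table from the cleaned tumor and control reads and re-runs the one-sided
#' Fisher test. Fails when the cleaned p exceeds `alpha_extract` or when no
#' clean support remains.
#'
#' @param cand One-row candidate (list or data.table row) with ref/alt.
#' @param ctx_t,ctx_c [site_read_calls()] tables for tumor and control.
#' @param trim_bp Terminal bases excluded from counting.
#' @param mismatch_quantile Internal-control quantile defining an erroneous
#'   read.
#' @param alpha_extract Fisher cutoff the cleaned table must still meet.
#' @return A one-row verdict data.table with the cleaned p as statistic.
#' @export
second_fisher <- function(cand, ctx_t, ctx_c, trim_bp = 5L,
                          mismatch_quantile = 0.995, alpha_extract = 1e-4) {
  is_indel <- grepl("^(ins|del):", cand$alt)
  supp_t <- supports(ctx_t, cand, is_indel)
  bg <- ctx_t$n_mism[!supp_t & !is.na(ctx_t$base)]
  cutoff <- if (length(bg)) {
    max(2, stats::quantile(bg, mismatch_quantile, names = FALSE))
  } else 2
  extra_t <- ctx_t$n_mism - ifelse(supp_t & !is_indel, 1L, 0L)
  keep_t <- extra_t <= cutoff & !is.na(ctx_t$dist_end) &
    ctx_t$dist_end >= trim_bp
  refcall_t <- !is.na(ctx_t$base) & ctx_t$base == cand$ref & !ctx_t$masked &
    ctx_t$indel == ""
  t_alt <- sum(supp_t & keep_t)
  t_ref <- sum(refcall_t & keep_t)
  if (t_alt == 0) {
    return(verdict("second_fisher", FALSE, 1, alpha_extract,
                   "no clean support"))
  }
  supp_c <- supports(ctx_c, cand, is_indel)
  extra_c <- ctx_c$n_mism - ifelse(supp_c & !is_indel, 1L, 0L)
  keep_c <- extra_c <= cutoff & !is.na(ctx_c$dist_end) &
    ctx_c$dist_end >= trim_bp
  refcall_c <- !is.na(ctx_c$base) & ctx_c$base == cand$ref & !ctx_c$masked &
    ctx_c$indel == ""
  c_alt <- sum(supp_c & keep_c)
  c_ref <- sum(refcall_c & keep_c)
  p2 <- fisher_tail(t_alt, t_ref, c_alt, c_ref)
  verdict("second_fisher", p2 <= alpha_extract, p2, alpha_extract,
          sprintf("cleaned %d/%d vs %d/%d, cutoff=%g", t_alt, t_ref, c_alt,
                  c_ref, cutoff))
}

# which reads in a site context support the candidate allele
supports <- function(ctx, cand, is_indel = grepl("^(ins|del):", cand$alt)) {
  if (is_indel) {
    ctx$indel == cand$alt
  } else {
    !is.na(ctx$base) & ctx$base == cand$alt & !ctx$masked & ctx$indel == ""
  }
}

#' Germline VAF-band and SNP-database filter
#'
#' Removes likely germline variants in unmatched tumor/control calling:
#' candidates whose VAF falls in a heterozygous band (default closed
#' \[0.40, 0.60\]) or homozygous band (default (0.96, 1\], open at the low
#' end), and candidates matching a SNP-database site (same chrom, pos, ref,
#' alt). A band whose upper end reaches 1 is treated as open at the low end,
#' matching the "greater than" phrasing of a homozygous cutoff.
#'
#' @param cands Candidate table with chrom, pos, ref, alt, vaf.
#' @param snp_sites Optional data.frame of known SNPs (chrom, pos, ref, alt),
#'   e.g. parsed from a VCF with [read_snp_vcf()].
#' @param bands List of numeric `c(lo, hi)` VAF bands.
#' @return data.table of verdicts, one row per candidate.
#' @export
germline_filter <- function(cands, snp_sites = NULL,
                            bands = list(c(0.40, 0.60), c(0.96, 1.0))) {
  n <- nrow(cands)
  in_band <- rep(FALSE, n)
  for (b in bands) {
    if (b[2] >= 1) {
      in_band <- in_band | (cands$vaf > b[1] & cands$vaf <= b[2])
    } else {
      in_band <- in_band | (cands$vaf >= b[1] & cands$vaf <= b[2])
    }
  }
  in_snp <- rep(FALSE, n)
  if (!is.null(snp_sites) && nrow(snp_sites)) {
    key <- paste(cands$chrom, cands$pos, cands$ref, cands$alt)
    skey <- paste(snp_sites$chrom, snp_sites$pos, snp_sites$ref,
                  snp_sites$alt)
    in_snp <- key %in% skey
  }
  fail <- in_band | in_snp
  data.table::data.table(
    filter = "germline", passed = !fail, statistic = cands$vaf,
    threshold = NA_real_,
    detail = ifelse(in_snp, "SNP database",
                    ifelse(in_band, "VAF band", "")))
}

#' Parse a minimal SNP-sites VCF
#'
#' Reads chrom/pos/ref/alt from a (possibly multi-allelic) VCF text file for
#' use by [germline_filter()]. Indel records are keyed like candidates
#' (`ins:<seq>` / `del:<len>` at the preceding base).
#'
#' @param path VCF path.
#' @return data.table with chrom, pos, ref, alt.
#' @export
read_snp_vcf <- function(path) {
  if (!file.exists(path)) stop("SNP VCF not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:5)
  recs <- data.table::data.table(chrom = f[[1]], pos = as.integer(f[[2]]),
                                 ref = f[[4]], alt = f[[5]])
  recs <- recs[, list(alt = unlist(strsplit(alt, ",", fixed = TRUE))),
               by = c("chrom", "pos", "ref")]
  snv <- nchar(recs$ref) == 1 & nchar(recs$alt) == 1
  ins <- nchar(recs$ref) == 1 & nchar(recs$alt) > 1
  del <- nchar(recs$ref) > 1 & nchar(recs$alt) == 1
  out <- list(
    recs[snv],
    data.table::data.table(chrom = recs$chrom[ins], pos = recs$pos[ins],
                           ref = recs$ref[ins],
                           alt = paste0("ins:", substring(recs$alt[ins], 2))),
    data.table::data.table(chrom = recs$chrom[del], pos = recs$pos[del],
                           ref = substr(recs$ref[del], 1, 1),
                           alt = paste0("del:", nchar(recs$ref[del]) - 1L)))
  data.table::rbindlist(out)
}
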