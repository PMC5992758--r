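# Copy-number calling from tumor-vs-control binned depth: LOWESS GC
# correction, log2 ratio, windowed circular binary segmentation with a
# standardized Mann-Whitney statistic and permutation p-values, window
# compilation, the segment-abortion rule, and bootstrap AMP/DEL
# classification.

#' Bin read depths over the targets
#'
#' Splits each target into bins of at most `bin_size` bp, computes mean
#' per-base coverage from the reads and the GC fraction from the reference.
#'
#' @param reads Read table (or `prep_filter()` output; only positions are
#'   used).
#' @param targets GRanges.
#' @param reference DNAStringSet.
#' @param bin_size Maximum bin width (bp).
#' @return data.table: chrom, start, end, gc, raw_depth.
#' @export
bin_depths <- function(reads, targets, reference, bin_size = 100L) {
  stopifnot(bin_size >= 1L)
  if (!is.data.frame(reads)) reads <- reads$reads
  cov <- GenomicRanges::coverage(GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$pos, reads$rend)))
  out <- list()
  tg <- data.frame(chrom = as.character(GenomicRanges::seqnames(targets)),
                   start = GenomicRanges::start(targets),
                   end = GenomicRanges::end(targets))
  for (i in seq_len(nrow(tg))) {
    starts <- seq(tg$start[i], tg$end[i], by = bin_size)
    ends <- pmin(starts + bin_size - 1L, tg$end[i])
    chrom <- tg$chrom[i]
    cv <- if (chrom %in% names(cov)) cov[[chrom]] else S4Vectors::Rle(0L, 0)
    if (length(cv) < max(ends)) {
      cv <- c(cv, S4Vectors::Rle(0L, max(ends) - length(cv)))
    }
    dep <- IRanges::viewSums(IRanges::Views(cv, starts, ends)) /
      (ends - starts + 1L)
    gc <- vapply(seq_along(starts), function(b)
      compute_gc(reference, chrom, starts[b], ends[b]), numeric(1))
    out[[i]] <- data.table::data.table(chrom = chrom, start = starts,
                                       end = ends, gc = gc, raw_depth = dep)
  }
  data.table::rbindlist(out)
}

#' LOWESS GC correction of binned depths
#'
#' Fits a LOWESS curve of raw depth on GC over unmasked bins and rescales
#' each bin by `median(depth) / fitted(gc)`. Bins with depth 0 or missing GC
#' are masked; bins whose GC lies outside the central 98% of the panel's GC
#' distribution are flagged `gc_extreme` (correction there leans on few
#' observations).
#'
#' @param bins data.table with gc and raw_depth.
#' @param span LOWESS smoother span.
#' @param min_bins Minimum unmasked bins required to fit.
#' @return Copy of `bins` with corrected_depth, masked and gc_extreme
#'   columns.
#' @export
lowess_gc_correct <- function(bins, span = 2 / 3, min_bins = 50L) {
  b <- data.table::as.data.table(data.table::copy(bins))
  b[, "masked" := b$raw_depth <= 0 | is.na(b$gc)]
  ok <- !b$masked
  if (sum(ok) < min_bins) {
    stop("only ", sum(ok), " usable bins (< ", min_bins,
         "); disable GC correction or supply more bins")
  }
  fit <- stats::lowess(b$gc[ok], b$raw_depth[ok], f = span)
  fitted <- stats::approx(fit$x, fit$y, xout = b$gc, rule = 2,
                          ties = mean)$y
  med <- stats::median(b$raw_depth[ok])
  corr <- b$raw_depth * med / pmax(fitted, med * 0.01)
  b[, "corrected_depth" := ifelse(b$masked, NA_real_, corr)]
  qs <- stats::quantile(b$gc[ok], c(0.01, 0.99), names = FALSE)
  b[, "gc_extreme" := !is.na(b$gc) & (b$gc < qs[1] | b$gc > qs[2])]
  b[]
}

#' Compute the logR series from matched tumor/control bins
#'
#' `log2(tumor corrected / control corrected)` per bin, median-centered
#' (assumes a majority-neutral panel; the offset is kept as an attribute).
#' Bins masked in either sample, or with zero depth, get `NA`.
#'
#' @param tumor,control Bin tables from [lowess_gc_correct()] (a
#'   `corrected_depth` column is required; identical binning enforced).
#' @return data.table: chrom, start, end, gc, tumor_depth, control_depth,
#'   logr; attribute `center_offset`.
#' @export
compute_logr <- function(tumor, control) {
  if (nrow(tumor) != nrow(control) ||
      !all(tumor$chrom == control$chrom & tumor$start == control$start &
           tumor$end == control$end)) {
    stop("tumor and control bin grids differ; bin both samples identically")
  }
  t_c <- tumor$corrected_depth
  c_c <- control$corrected_depth
  raw <- log2(t_c / c_c)
  raw[!is.finite(raw)] <- NA_real_
  offset <- stats::median(raw, na.rm = TRUE)
  out <- data.table::data.table(chrom = tumor$chrom, start = tumor$start,
                                end = tumor$end, gc = tumor$gc,
                                tumor_depth = t_c, control_depth = c_c,
                                logr = raw - offset)
  data.table::setattr(out, "center_offset", offset)
  out
}

# --- circular binary segmentation ------------------------------------------

# max standardized Mann-Whitney statistic over all arcs of the circularized
# sequence; returns NULL for a constant series
mw_max_stat <- function(x, min_width = 3L) {
  n <- length(x)
  if (n < 2L || length(unique(x)) == 1L) return(NULL)
  r <- rank(x)
  mw_max_from_ranks(r, n, tie_term(x), min_width)
}

tie_term <- function(x) {
  t <- table(x)
  sum(t^3 - t)
}

# arc-length-dependent constants shared by every permutation
mw_consts <- function(n, ties, min_width) {
  idx <- 0:n
  m <- outer(idx, idx, FUN = function(a, b) b - a)
  valid <- m >= min_width & (n - m) >= min_width
  if (!any(valid)) return(NULL)
  corr <- (n + 1) - ties / (n * (n - 1))
  v <- m * (n - m) / 12 * corr
  list(E = m * (n + 1) / 2, sd = sqrt(pmax(v, 1e-12)), valid = valid, n = n)
}

mw_stat_from_ranks <- function(r, cn) {
  S <- c(0, cumsum(r))
  W <- outer(S, S, FUN = function(a, b) b - a)   # W[i+1, j+1] = S[j] - S[i]
  z <- (abs(W - cn$E) - 0.5) / cn$sd
  z[!cn$valid] <- -Inf
  best <- which.max(z)
  n <- cn$n
  j <- (best - 1L) %/% (n + 1L)        # column (0-based) -> j
  i <- (best - 1L) %% (n + 1L)         # row -> i
  list(stat = z[best], i = i, j = j)
}

mw_max_from_ranks <- function(r, n, ties, min_width) {
  cn <- mw_consts(n, ties, min_width)
  if (is.null(cn)) return(NULL)
  mw_stat_from_ranks(r, cn)
}

# permutation p-value of the max statistic; stops early once the split can
# no longer reach `alpha`
mw_perm_p <- function(x, obs, n_perm, min_width, alpha = 1) {
  n <- length(x)
  r <- rank(x)
  cn <- mw_consts(n, tie_term(x), min_width)
  if (is.null(cn)) return(1)
  limit <- floor(alpha * (n_perm + 1L))  # hits above this cannot pass
  hits <- 0L
  for (b in seq_len(n_perm)) {
    st <- mw_stat_from_ranks(sample(r), cn)
    if (st$stat >= obs) {
      hits <- hits + 1L
      if (hits > limit) return((hits + 1L) / (b + 1L))
    }
  }
  (hits + 1L) / (n_perm + 1L)
}

# recursive CBS on a numeric vector; returns start indices of segments
cbs_recurse <- function(x, n_perm, alpha, min_width) {
  n <- length(x)
  if (n < 2L * min_width) return(list(c(1L, n)))
  st <- mw_max_stat(x, min_width)
  if (is.null(st)) return(list(c(1L, n)))
  p <- mw_perm_p(x, st$stat, n_perm, min_width, alpha)
  if (p > alpha) return(list(c(1L, n)))
  cuts <- sort(unique(c(st$i, st$j)))
  cuts <- cuts[cuts > 0L & cuts < n]
  if (!length(cuts)) return(list(c(1L, n)))
  bounds <- c(0L, cuts, n)
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L
    hi <- bounds[k + 1L]
    sub <- cbs_recurse(x[lo:hi], n_perm, alpha, min_width)
    out <- c(out, lapply(sub, function(s) s + lo - 1L))
  }
  out
}

#' Segment a logR series with windowed CBS
#'
#' Splits each chromosome's unmasked bins into windows of `window_size`
#' bins, runs circular binary segmentation within each window (change-points
#' maximize the standardized Mann-Whitney statistic between the two arcs;
#' splits accepted at permutation `p <= alpha_seg`), then merges segments
#' across window borders when a Mann-Whitney test finds no evidence their
#' levels differ ([compile_windows()]).
#'
#' @param series logR table from [compute_logr()].
#' @param window_size Window size in bins.
#' @param n_perm Permutations per split test.
#' @param alpha_seg Split acceptance level.
#' @param min_width Minimum segment width in bins.
#' @return data.table of segments: chrom, start, end, bin_count,
#'   median_logr, plus hidden bin-index columns used downstream.
#' @export
cbs_segment <- function(series, window_size = 500L, n_perm = 1000L,
                        alpha_seg = 0.01, min_width = 3L) {
  s <- series[!is.na(series$logr)]
  out <- list()
  for (chr in unique(s$chrom)) {
    sc <- s[s$chrom == chr]
    n <- nrow(sc)
    win_start <- seq(1L, n, by = window_size)
    segs <- list()
    for (w in seq_along(win_start)) {
      lo <- win_start[w]
      hi <- min(lo + window_size - 1L, n)
      pieces <- cbs_recurse(sc$logr[lo:hi], n_perm, alpha_seg, min_width)
      for (p in pieces) {
        segs[[length(segs) + 1L]] <- data.table::data.table(
          window = w, bin_lo = p[1] + lo - 1L, bin_hi = p[2] + lo - 1L)
      }
    }
    segs <- data.table::rbindlist(segs)
    data.table::setorderv(segs, "bin_lo")
    segs <- compile_windows(segs, sc$logr, alpha_seg)
    segs <- prune_segments(segs, sc$logr, alpha_seg)
    segs[, "chrom" := chr]
    segs[, "start" := sc$start[segs$bin_lo]]
    segs[, "end" := sc$end[segs$bin_hi]]
    segs[, "bin_count" := segs$bin_hi - segs$bin_lo + 1L]
    segs[, "median_logr" := vapply(seq_len(nrow(segs)), function(k)
      stats::median(sc$logr[segs$bin_lo[k]:segs$bin_hi[k]]), numeric(1))]
    out[[length(out) + 1L]] <- segs
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("chrom", "start", "end", "bin_count",
                                 "median_logr"))
  res
}

#' Compile window-level segments into chromosome segments
#'
#' Merges the terminal segments of neighbouring windows when a Mann-Whitney
#' test between their logR values fails to reject at `alpha_seg` — i.e. the
#' window border alone split them, not a level change.
#'
#' @param segs data.table with window, bin_lo, bin_hi (one chromosome).
#' @param x Numeric logR vector the bin indices refer to.
#' @param alpha_seg Rejection level below which segments stay separate.
#' @return data.table with merged bin_lo/bin_hi (window column dropped).
#' @export
compile_windows <- function(segs, x, alpha_seg = 0.01) {
  k <- 1L
  segs <- data.table::copy(segs)
  while (k < nrow(segs)) {
    a <- segs[k]
    b <- segs[k + 1L]
    if (a$window != b$window) {
      xa <- x[a$bin_lo:a$bin_hi]
      xb <- x[b$bin_lo:b$bin_hi]
      p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
      if (is.na(p) || p > alpha_seg) {
        segs[k, "bin_hi" := b$bin_hi]
        segs[k, "window" := b$window]  # allow chaining across borders
        segs <- segs[-(k + 1L)]
        next
      }
    }
    k <- k + 1L
  }
  segs[, "window" := NULL]
  segs[]
}

# per-boundary pruning: the circular cut accepts an arc, not each of its
# two cuts individually, so a split can leave a short flank whose own
# boundary was never tested; re-test every adjacent pair with the same
# Mann-Whitney rule and merge where it fails to reject
prune_segments <- function(segs, x, alpha_seg = 0.01) {
  segs <- data.table::copy(segs)
  k <- 1L
  while (k < nrow(segs)) {
    xa <- x[segs$bin_lo[k]:segs$bin_hi[k]]
    xb <- x[segs$bin_lo[k + 1L]:segs$bin_hi[k + 1L]]
    p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
    if (is.na(p) || p > alpha_seg) {
      segs[k, "bin_hi" := segs$bin_hi[k + 1L]]
      segs <- segs[-(k + 1L)]
      if (k > 1L) k <- k - 1L  # the merged segment may now join its left
      next
    }
    k <- k + 1L
  }
  segs
}

#' Flag excessively heterogeneous segments (abortion rule)
#'
#' A segment is aborted when the fraction of its bins deviating from the
#' segment median by more than `dev_delta` exceeds `dev_frac`; aborted
#' segments are excluded from AMP/DEL classification. Single-bin segments
#' are never aborted (the fraction rule is vacuous there).
#'
#' @param segs Segment table from [cbs_segment()].
#' @param series logR table the segments refer to.
#' @param dev_delta Deviation threshold (logR units).
#' @param dev_frac Maximum tolerated deviating fraction (strict >).
#' @return Segment table with an `aborted` column.
#' @export
abort_segments <- function(segs, series, dev_delta = 0.5, dev_frac = 0.3) {
  s <- series[!is.na(series$logr)]
  segs <- data.table::copy(segs)
  ab <- vapply(seq_len(nrow(segs)), function(k) {
    xs <- s$logr[s$chrom == segs$chrom[k]][segs$bin_lo[k]:segs$bin_hi[k]]
    if (length(xs) < 2L) return(FALSE)
    mean(abs(xs - stats::median(xs)) > dev_delta) > dev_frac
  }, logical(1))
  segs[, "aborted" := ab]
  segs[]
}

#' Bootstrap amplification/deletion classification
#'
#' Resamples a segment's bin logR values with replacement and classifies by
#' the bootstrap interval of the median: AMP when the lower bound exceeds
#' `amp_logr`, DEL when the upper bound is below `del_logr`, otherwise
#' NEUTRAL. Segments with fewer than 3 bins are NEUTRAL (insufficient bins).
#'
#' @param x Numeric logR values of the segment's bins.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param amp_logr,del_logr Classification thresholds.
#' @param conf Interval coverage.
#' @return list with state, boot_lo, boot_hi.
#' @export
bootstrap_classify <- function(x, n_boot = 1000L, amp_logr = 0.8,
                               del_logr = -0.8, conf = 0.95) {
  stopifnot(n_boot >= 100L)
  if (length(x) < 3L) {
    return(list(state = "NEUTRAL", boot_lo = NA_real_, boot_hi = NA_real_,
                detail = "insufficient bins"))
  }
  meds <- vapply(seq_len(n_boot), function(b)
    stats::median(sample(x, length(x), replace = TRUE)), numeric(1))
  a <- (1 - conf) / 2
  lo <- stats::quantile(meds, a, names = FALSE)
  hi <- stats::quantile(meds, 1 - a, names = FALSE)
  state <- if (lo > amp_logr) "AMP" else if (hi < del_logr) "DEL" else
    "NEUTRAL"
  list(state = state, boot_lo = lo, boot_hi = hi, detail = "")
}

#' Call copy-number alterations from binned tumor/control depths
#'
#' Full pipeline: GC correction of both samples, logR computation, windowed
#' CBS, segment abortion, and bootstrap classification. The RNG seed in the
#' config governs permutations and bootstrap draws.
#'
#' @param tumor_bins,control_bins Bin tables (chrom, start, end, gc,
#'   raw_depth) on an identical grid, e.g. from [bin_depths()] or
#'   [sim_depth_profile()].
#' @param config [default_config()] list.
#' @param gc_correct Apply LOWESS GC correction (disable for pre-corrected
#'   input).
#' @return list with `segments` (chrom, start, end, bin_count, median_logr,
#'   aborted, boot_lo, boot_hi, state) and `bins` (per-bin gc, raw,
#'   corrected, logr).
#' @export
call_cnas <- function(tumor_bins, control_bins, config = default_config(),
                      gc_correct = TRUE) {
  if (gc_correct) {
    tb <- lowess_gc_correct(tumor_bins, span = config$lowess_span,
                            min_bins = config$min_gc_bins)
    cb <- lowess_gc_correct(control_bins, span = config$lowess_span,
                            min_bins = config$min_gc_bins)
  } else {
    tb <- data.table::as.data.table(data.table::copy(tumor_bins))
    cb <- data.table::as.data.table(data.table::copy(control_bins))
    tb[, "corrected_depth" := ifelse(tb$raw_depth > 0, tb$raw_depth,
                                     NA_real_)]
    cb[, "corrected_depth" := ifelse(cb$raw_depth > 0, cb$raw_depth,
                                     NA_real_)]
  }
  series <- compute_logr(tb, cb)
  with_seed(config$seed, {
    segs <- cbs_segment(series, window_size = config$cbs_window,
                        n_perm = config$cbs_nperm,
                        alpha_seg = config$alpha_seg,
                        min_width = config$cbs_min_width)
    segs <- abort_segments(segs, series, dev_delta = config$abort_delta,
                           dev_frac = config$abort_frac)
    s <- series[!is.na(series$logr)]
    cls <- lapply(seq_len(nrow(segs)), function(k) {
      if (segs$aborted[k]) {
        return(list(state = "ABORTED", boot_lo = NA_real_,
                    boot_hi = NA_real_))
      }
      xs <- s$logr[s$chrom == segs$chrom[k]][segs$bin_lo[k]:segs$bin_hi[k]]
      bootstrap_classify(xs, n_boot = config$n_boot,
                         amp_logr = config$amp_logr,
                         del_logr = config$del_logr, conf = config$boot_conf)
    })
    segs[, "boot_lo" := vapply(cls, function(z) z$boot_lo, numeric(1))]
    segs[, "boot_hi" := vapply(cls, function(z) z$boot_hi, numeric(1))]
    segs[, "state" := vapply(cls, function(z) z$state, character(1))]
    segs[, c("bin_lo", "bin_hi") := NULL]
    list(segments = segs[], bins = series)
  })
}

#' Write segments in SEG format
#'
#' Tab-separated SEG-like table (1-based coordinates) with the bootstrap
#' bounds, abortion flag and state, plus a config echo header.
#'
#' @param result Output of [call_cnas()].
#' @param path Output path.
#' @param sample Sample name for the first column.
#' @param config Optional config echoed into the header.
#' @return Invisibly, `path`.
#' @export
write_seg <- function(result, path, sample = "tumor", config = NULL) {
  hdr <- "sample\tchrom\tstart\tend\tbin_count\tmedian_logr\tstate\tboot_lo\tboot_hi\taborted"
  if (!is.null(config)) hdr <- c(paste0("#config=", config_echo(config)), hdr)
  s <- result$segments
  rows <- sprintf("%s\t%s\t%d\t%d\t%d\t%.4f\t%s\t%s\t%s\t%s", sample,
                  s$chrom, s$start, s$end, s$bin_count, s$median_logr,
                  s$state, format(s$boot_lo, digits = 4),
                  format(s$boot_hi, digits = 4), s$aborted)
  writeLines(c(hdr, rows), path)
  invisible(path)
}
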