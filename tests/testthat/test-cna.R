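# GC correction, logR, CBS segmentation, abortion and bootstrap
# classification.

test_that("bin_depths tiles targets and averages coverage", {
  ref <- tiny_ref(strrep("ACGT", 250))  # 1000 bp
  tg <- tiny_targets(ref, 101L, 400L)   # one 300 bp exon
  rd <- make_reads("chr1", rep(seq(81L, 380L, by = 3L), each = 1),
                   strrep("A", 50))
  rd$seq <- vapply(rd$pos, function(p)
    as.character(Biostrings::subseq(ref[["chr1"]], p, p + 49L)), "")
  bins <- bin_depths(rd, tg, ref, bin_size = 100L)
  expect_equal(nrow(bins), 3L)
  expect_equal(bins$start, c(101L, 201L, 301L))
  expect_equal(bins$end, c(200L, 300L, 400L))
  # ~1 read per 3 bp, 50 bp reads -> ~16.7x
  expect_true(all(abs(bins$raw_depth - 50 / 3) < 2))
  expect_true(all(bins$gc == 0.5))

  none <- bin_depths(rd[0], tg, ref, bin_size = 100L)
  expect_true(all(none$raw_depth == 0))
})

test_that("GC correction is a near-identity on unbiased depth", {
  prof <- sim_depth_profile(300, base_depth = 200, gc_bias = 0, seed = 41)
  cor_b <- lowess_gc_correct(prof$tumor)
  ok <- !cor_b$masked
  rel <- abs(cor_b$corrected_depth[ok] - cor_b$raw_depth[ok]) /
    cor_b$raw_depth[ok]
  expect_lt(stats::median(rel), 0.02)
})

test_that("a planted linear GC bias is flattened", {
  prof <- sim_depth_profile(500, base_depth = 100, gc_bias = 2, seed = 42)
  cor_b <- lowess_gc_correct(prof$tumor)
  ok <- !cor_b$masked
  rho_before <- stats::cor(prof$tumor$raw_depth[ok], prof$tumor$gc[ok],
                           method = "spearman")
  rho_after <- stats::cor(cor_b$corrected_depth[ok], cor_b$gc[ok],
                          method = "spearman")
  expect_gt(abs(rho_before), 0.5)
  expect_lt(abs(rho_after), 0.1)
})

test_that("too few bins for LOWESS is an explicit error", {
  prof <- sim_depth_profile(10, base_depth = 100, seed = 43)
  expect_error(lowess_gc_correct(prof$tumor), "usable bins")
})

test_that("logR follows the log2 convention with median centering", {
  bins <- data.table::data.table(chrom = "chr1", start = 1:100, end = 1:100,
                                 gc = 0.5, corrected_depth = 100)
  t2 <- data.table::copy(bins)
  expect_true(all(compute_logr(t2, bins)$logr == 0))

  # tumor doubled on a minority of bins against a neutral majority
  t2$corrected_depth[1:20] <- 200
  lr <- compute_logr(t2, bins)
  expect_equal(lr$logr[1:20], rep(1, 20))
  expect_equal(lr$logr[21:100], rep(0, 80))

  t2$corrected_depth[5] <- NA_real_
  expect_true(is.na(compute_logr(t2, bins)$logr[5]))

  bad <- data.table::copy(bins)[1:50]
  expect_error(compute_logr(t2, bad), "grids differ")
})

run_cbs <- function(logr, cfg = default_config(cbs_nperm = 500L), seed = 1L) {
  series <- data.table::data.table(chrom = "chr1",
                                   start = seq_along(logr) * 10L - 9L,
                                   end = seq_along(logr) * 10L,
                                   logr = logr)
  panelcall:::with_seed(seed, {
    segs <- cbs_segment(series, window_size = cfg$cbs_window,
                        n_perm = cfg$cbs_nperm, alpha_seg = cfg$alpha_seg,
                        min_width = cfg$cbs_min_width)
    abort_segments(segs, series, cfg$abort_delta, cfg$abort_frac)
  })
}

test_that("CBS leaves i.i.d. noise unsegmented in most replicates", {
  ok <- 0L
  for (r in 1:5) {
    x <- panelcall:::with_seed(200 + r, rnorm(100, 0, 0.1))
    segs <- run_cbs(x, seed = r)
    if (nrow(segs) == 1L) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("CBS recovers a planted step within two bins", {
  x <- panelcall:::with_seed(211, c(rnorm(50, 0, 0.2), rnorm(50, 1, 0.2)))
  segs <- run_cbs(x)
  expect_equal(nrow(segs), 2L)
  expect_lte(abs(segs$bin_hi[1] - 50L), 2L)
  expect_lt(abs(segs$median_logr[1] - 0), 0.15)
  expect_lt(abs(segs$median_logr[2] - 1), 0.15)
})

test_that("a constant series yields a single segment", {
  segs <- run_cbs(rep(0.4, 60))
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$bin_count, 60L)
})

test_that("segments always partition the unmasked bins", {
  for (r in 1:3) {
    x <- panelcall:::with_seed(300 + r,
      c(rnorm(40, 0, 0.2), rnorm(30, 1, 0.2), rnorm(40, -1, 0.2)))
    segs <- run_cbs(x, seed = r)
    segs <- segs[order(segs$bin_lo)]
    expect_equal(segs$bin_lo[1], 1L)
    expect_equal(segs$bin_hi[nrow(segs)], length(x))
    if (nrow(segs) > 1) {
      expect_true(all(segs$bin_lo[-1] == segs$bin_hi[-nrow(segs)] + 1L))
    }
  }
})

test_that("window borders are compiled away on flat signal but real
           breakpoints at borders survive", {
  cfg <- default_config(cbs_window = 50L, cbs_nperm = 500L)
  flat <- panelcall:::with_seed(221, rnorm(100, 0, 0.2))
  expect_equal(nrow(run_cbs(flat, cfg)), 1L)

  step <- panelcall:::with_seed(222, c(rnorm(50, 0, 0.2), rnorm(50, 1.5, 0.2)))
  segs <- run_cbs(step, cfg)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$bin_hi[1], 50L)
})

test_that("the abortion rule flags heterogeneous segments by fraction", {
  series <- data.table::data.table(chrom = "chr1", start = 1:100, end = 1:100,
                                   logr = rep(1, 100))
  segs <- data.table::data.table(window = 1L, bin_lo = 1L, bin_hi = 100L,
                                 chrom = "chr1", start = 1L, end = 100L,
                                 bin_count = 100L, median_logr = 1)
  expect_false(abort_segments(segs, series, 0.5, 0.3)$aborted)

  series$logr[1:40] <- series$logr[1:40] + c(1, -1)  # 40% deviating by 1
  segs$median_logr <- stats::median(series$logr)
  expect_true(abort_segments(segs, series, 0.5, 0.3)$aborted)

  one <- data.table::data.table(window = 1L, bin_lo = 1L, bin_hi = 1L,
                                chrom = "chr1", start = 1L, end = 1L,
                                bin_count = 1L, median_logr = 5)
  expect_false(abort_segments(one, series, 0.5, 0.3)$aborted)
})

test_that("bootstrap classification follows the interval rules", {
  expect_equal(bootstrap_classify(rep(0, 50))$state, "NEUTRAL")
  b <- bootstrap_classify(rep(1, 50), amp_logr = 0.8)
  expect_equal(b$state, "AMP")
  expect_equal(b$boot_lo, 1)
  expect_equal(b$boot_hi, 1)
  short <- bootstrap_classify(c(0.1, 0.2))
  expect_equal(short$state, "NEUTRAL")
  expect_match(short$detail, "insufficient")

  del_ok <- 0L
  for (r in 1:5) {
    x <- panelcall:::with_seed(400 + r, rnorm(50, -2, 0.2))
    st <- panelcall:::with_seed(r, bootstrap_classify(x, del_logr = -1))
    if (st$state == "DEL") del_ok <- del_ok + 1L
  }
  expect_equal(del_ok, 5L)
})

test_that("raising amp_logr never creates a new AMP call (monotone)", {
  n_amp_lo <- 0L
  for (r in 1:8) {
    x <- panelcall:::with_seed(500 + r,
                               rnorm(30, runif(1, 0.5, 1.1), 0.3))
    lo <- panelcall:::with_seed(r, bootstrap_classify(x, amp_logr = 0.6))
    hi <- panelcall:::with_seed(r, bootstrap_classify(x, amp_logr = 0.9))
    expect_false(hi$state == "AMP" && lo$state != "AMP")
    n_amp_lo <- n_amp_lo + (lo$state == "AMP")
  }
  expect_gt(n_amp_lo, 0L)  # the comparison is not vacuous
})

test_that("the full CNA pipeline recovers planted AMP and DEL segments", {
  segments <- data.frame(start_bin = c(1L, 151L, 201L, 351L, 401L),
                         end_bin = c(150L, 200L, 350L, 400L, 500L),
                         logr = c(0, 1, 0, -2, 0))
  prof <- sim_depth_profile(500, segments, base_depth = 150, gc_bias = 1.5,
                            seed = 61)
  res <- call_cnas(prof$tumor, prof$control,
                   default_config(cbs_window = 250L, cbs_nperm = 500L))
  st <- res$segments
  expect_equal(sum(st$state == "AMP"), 1L)
  expect_equal(sum(st$state == "DEL"), 1L)
  amp <- st[st$state == "AMP"]
  expect_lte(abs(amp$start - prof$tumor$start[151]), 2L * 100L)
  expect_lt(abs(amp$median_logr - 1), 0.2)
})

test_that("same-truth depth profiles give no AMP calls", {
  prof <- sim_depth_profile(400, base_depth = 150, seed = 71)
  res <- call_cnas(prof$tumor, prof$control,
                   default_config(cbs_nperm = 500L))
  expect_equal(sum(res$segments$state == "AMP"), 0L)
})

test_that("SEG output has the documented columns", {
  prof <- sim_depth_profile(200, base_depth = 120, seed = 81)
  res <- call_cnas(prof$tumor, prof$control,
                   default_config(cbs_nperm = 300L))
  path <- withr::local_tempfile(fileext = ".seg")
  write_seg(res, path, config = default_config())
  lines <- readLines(path)
  expect_match(lines[1], "^#config=")
  expect_match(lines[2], "^sample\tchrom\tstart\tend\tbin_count")
  expect_equal(length(lines) - 2L, nrow(res$segments))
})
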