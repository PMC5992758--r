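# The individual noise filters: boundary conventions, degenerate-input
# policy, and agreement with enumeration oracles.

test_that("strand-bias filter fails one-sided imbalance, passes symmetry", {
  v <- filter_strand_bias(20, 0, 50, 50)
  expect_verdict(v, FALSE)
  expect_equal(v$statistic, oracle_fisher(20, 0, 50, 50), tolerance = 1e-12)

  expect_verdict(filter_strand_bias(10, 10, 50, 50), TRUE)
  # no power at n = 1
  v <- filter_strand_bias(1, 0, 5, 5)
  expect_verdict(v, TRUE)
  expect_gt(v$statistic, 1e-3)
  # vacuous with zero alt reads
  expect_verdict(filter_strand_bias(0, 0, 50, 50), TRUE)
  # a skewed ref profile protects an equally skewed alt
  expect_verdict(filter_strand_bias(30, 0, 100, 0), TRUE)
})

test_that("misalignment filter catches high-mismatch support, passes clean", {
  expect_verdict(filter_misalignment(rep(4L, 10), rep(0:1, 50)), FALSE)
  expect_verdict(filter_misalignment(rep(0L, 10), rep(0:1, 50)), TRUE)
  v <- filter_misalignment(rep(4L, 10), integer(0))
  expect_verdict(v, TRUE)
  expect_match(v$detail, "insufficient control")
})

test_that("homopolymer filter uses an inclusive run-length threshold", {
  ref <- tiny_ref(paste0("ACGTACGT", strrep("A", 12), "CGTACGT",
                         strrep("G", 8), "TACGTAC"))
  expect_verdict(filter_homopolymer(ref, "chr1", 14L), FALSE)  # inside 12xA
  expect_verdict(filter_homopolymer(ref, "chr1", 4L), TRUE)    # ACGT context
  expect_verdict(filter_homopolymer(ref, "chr1", 30L), FALSE)  # exactly 8
  # indel keyed at the base before a long run also fails
  expect_verdict(filter_homopolymer(ref, "chr1", 8L), FALSE)
})

test_that("MQ0 filter uses a strict fraction inequality", {
  expect_verdict(filter_mq0(50, 50), FALSE)   # 0.5
  expect_verdict(filter_mq0(0, 100), TRUE)
  expect_verdict(filter_mq0(10, 90), TRUE)    # exactly 0.1 passes
  expect_verdict(filter_mq0(11, 89), FALSE)
})

test_that("read-end filter fails concentrated alt calls", {
  v <- filter_read_end(rep(2L, 10), rep(c(10L, 30L, 50L), 20))
  expect_verdict(v, FALSE)
  expect_equal(v$statistic, oracle_fisher(10, 0, 0, 60), tolerance = 1e-12)
  expect_verdict(filter_read_end(3L, rep(10L, 50)), TRUE)  # single alt read
})

test_that("read-end filter type-I rate is near nominal on null draws", {
  set.seed(31)
  fails <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    dists <- sample(0:74, 60, replace = TRUE)
    alt <- dists[1:12]
    refd <- dists[13:60]
    v <- filter_read_end(alt, refd, alpha = 0.05)
    fails <- fails + !v$passed
  }
  # binomial(200, 0.05) stays below 20 with overwhelming probability
  expect_lt(fails, 20L)
})

test_that("dust filter compares window noise against the internal control", {
  expect_verdict(filter_dust(8, 20, 0.01), FALSE)
  expect_verdict(filter_dust(0, 20, 0.01), TRUE)
  v <- filter_dust(0, 0, 0.01)
  expect_verdict(v, TRUE)
  expect_match(v$detail, "empty window")
})

test_that("BQ-drop filter applies only to Ion indels", {
  v <- filter_bq_drop("illumina", FALSE, 30, 12)
  expect_verdict(v, TRUE)
  expect_match(v$detail, "not applicable")
  expect_verdict(filter_bq_drop("ion", TRUE, 30, 12), FALSE)  # drop 18 > 10
  expect_verdict(filter_bq_drop("ion", TRUE, 30, 29.5), TRUE)
  expect_verdict(filter_bq_drop("ion", FALSE, 30, 12), TRUE)  # SNV exempt
})

make_ctx <- function(base, dist, n_mism, masked = FALSE, indel = "") {
  n <- length(base)
  data.table::data.table(
    qname = sprintf("x%03d", seq_len(n)), base = base,
    qual = rep(30L, n), off = dist + 1L, len = rep(100L, n),
    dist_end = dist, rev = rep(c(FALSE, TRUE), length.out = n),
    n_mism = n_mism, indel = rep_len(indel, n),
    masked = rep_len(masked, n))
}

test_that("second Fisher reproduces the original p when cleaning is a no-op", {
  cand <- list(chrom = "chr1", pos = 50L, ref = "A", alt = "T")
  ctx_t <- make_ctx(rep(c("T", "A"), c(20, 80)), rep(50L, 100),
                    rep(c(1L, 0L), c(20, 80)))
  ctx_c <- make_ctx(rep("A", 100), rep(50L, 100), rep(0L, 100))
  v <- second_fisher(cand, ctx_t, ctx_c, alpha_extract = 1e-4)
  expect_verdict(v, TRUE)
  expect_equal(v$statistic, fisher_tail(20, 80, 0, 100), tolerance = 1e-12)
})

test_that("second Fisher fails when cleaned support loses significance", {
  cand <- list(chrom = "chr1", pos = 50L, ref = "A", alt = "T")
  # 8 of 10 alt reads are high-mismatch and removed by cleaning
  ctx_t <- make_ctx(rep(c("T", "A"), c(10, 200)), rep(50L, 210),
                    c(rep(9L, 8), rep(1L, 2), rep(0L, 200)))
  ctx_c <- make_ctx(rep(c("T", "A"), c(1, 200)), rep(50L, 201),
                    rep(0L, 201))
  v <- second_fisher(cand, ctx_t, ctx_c, alpha_extract = 1e-4)
  expect_verdict(v, FALSE)
  expect_equal(v$statistic, fisher_tail(2, 200, 1, 200), tolerance = 1e-12)
})

test_that("second Fisher fails outright when trimming removes all support", {
  cand <- list(chrom = "chr1", pos = 50L, ref = "A", alt = "T")
  ctx_t <- make_ctx(rep(c("T", "A"), c(5, 50)),
                    c(rep(1L, 5), rep(50L, 50)), rep(0L, 55))
  ctx_c <- make_ctx(rep("A", 50), rep(50L, 50), rep(0L, 50))
  v <- second_fisher(cand, ctx_t, ctx_c, trim_bp = 5L)
  expect_verdict(v, FALSE)
  expect_match(v$detail, "no clean support")
})

test_that("germline filter is exact on the VAF bands", {
  vaf <- c(0.25, 0.399, 0.40, 0.50, 0.60, 0.601, 0.95, 0.96, 0.961, 1.0)
  cands <- data.table::data.table(chrom = "chr1", pos = seq_along(vaf),
                                  ref = "A", alt = "T", vaf = vaf)
  v <- germline_filter(cands)
  expect_equal(v$passed,
               !(vaf >= 0.40 & vaf <= 0.60 | vaf > 0.96))
})

test_that("germline filter removes SNP-database matches", {
  cands <- data.table::data.table(chrom = "chr1", pos = c(10L, 20L),
                                  ref = "A", alt = "T", vaf = 0.25)
  snp <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "T")
  v <- germline_filter(cands, snp)
  expect_equal(v$passed, c(FALSE, TRUE))
  expect_match(v$detail[1], "SNP")
})

test_that("read_snp_vcf parses SNVs and indels into internal allele keys", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\trs1\tA\tT,G\t.\t.\t.",
               "chr1\t200\trs2\tA\tACG\t.\t.\t.",
               "chr1\t300\trs3\tATT\tA\t.\t.\t."), path)
  snp <- read_snp_vcf(path)
  expect_setequal(snp$alt, c("T", "G", "ins:CG", "del:2"))
  expect_equal(snp$pos[snp$alt == "del:2"], 300L)
})

test_that("the cascade registers eight Illumina and nine Ion noise filters", {
  expect_length(noise_filters("illumina"), 8L)
  expect_length(noise_filters("ion"), 9L)
  expect_true("bq_drop" %in% noise_filters("ion"))
  expect_false("bq_drop" %in% noise_filters("illumina"))
  expect_false("germline" %in% noise_filters("illumina"))
})
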