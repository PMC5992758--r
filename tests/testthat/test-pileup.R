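# Prep filters, pileup construction, indel conventions, and equivalence
# with a naive per-read counting oracle.

test_that("prep filters drop unmapped/secondary/duplicate and low-mapq reads", {
  ref <- tiny_ref(strrep("ACGT", 30))
  rd <- make_reads("chr1", rep(1L, 5), rep(substr(strrep("ACGT", 30), 1, 20), 5),
                   flag = c(0L, 4L, 256L, 1024L, 0L),
                   mapq = c(60L, 60L, 60L, 60L, 5L))
  pf <- prep_filter(rd, min_mapq = 20L)
  expect_equal(nrow(pf$reads), 1L)
  expect_equal(pf$reads$qname, "r0001")
  pf2 <- prep_filter(rd, min_mapq = 20L, drop_duplicates = FALSE)
  expect_equal(nrow(pf2$reads), 2L)
})

test_that("MQ0 reads are excluded from counts but tallied per site", {
  ref <- tiny_ref(strrep("A", 60))
  rd <- make_reads("chr1", c(1L, 1L, 11L), rep(strrep("A", 30), 3),
                   mapq = c(60L, 0L, 0L))
  pp <- build_pileups(prep_filter(rd), tiny_targets(ref), ref)
  s <- pp$sites
  expect_equal(s$depth[s$pos == 5], 1L)
  expect_equal(s$mq0[s$pos == 5], 1L)   # one MQ0 read covers pos 5
  expect_equal(s$mq0[s$pos == 15], 2L)  # both MQ0 reads cover pos 15
})

test_that("base-quality masking removes single bases without side effects", {
  ref <- tiny_ref(strrep("ACGT", 10))
  seq <- substr(strrep("ACGT", 10), 1, 12)
  qual <- paste0("??", rawToChar(as.raw(33 + 5)), strrep("?", 9))  # base 3 low
  rd <- make_reads("chr1", c(1L, 1L), c(seq, seq),
                   qual = c(qual, strrep("?", 12)))
  pp <- build_pileups(prep_filter(rd), tiny_targets(ref), ref)
  expect_equal(pp$sites$depth[pp$sites$pos == 3], 1L)  # one masked
  expect_equal(pp$sites$depth[pp$sites$pos == 4], 2L)  # neighbours intact
  a <- pp$alleles
  expect_equal(sum(a[a$pos == 3]$fwd + a[a$pos == 3]$rev), 1L)
})

test_that("a deletion is recorded at the base preceding the event", {
  refseq <- paste0(strrep("ACGT", 15), strrep("TGCA", 15))
  ref <- tiny_ref(refseq)
  seq <- paste0(substr(refseq, 1, 50), substr(refseq, 53, 102))
  rd <- make_reads("chr1", 1L, seq, cigar = "50M2D50M")
  pp <- build_pileups(prep_filter(rd), tiny_targets(ref), ref)
  a <- pp$alleles[grepl("^del:", pp$alleles$allele)]
  expect_equal(nrow(a), 1L)
  expect_equal(a$allele, "del:2")
  expect_lte(a$pos, 50L)  # keyed at (or left-shifted from) the preceding base
})

test_that("indels are left-aligned within homopolymer context", {
  # reference ...ACC AAAAA GTT...: a 1-bp A-deletion anywhere in the run
  # must be keyed at the base before the run
  refseq <- paste0(strrep("CGTA", 5), "CC", "AAAAA", "GTT", strrep("ACGT", 10))
  ref <- tiny_ref(refseq)
  run_start <- 23L  # first A of the run
  # read deletes the LAST A of the run (ref position 27)
  seq <- paste0(substr(refseq, 5, 26), substr(refseq, 28, 55))
  rd <- make_reads("chr1", 5L, seq, cigar = "22M1D28M")
  pp <- build_pileups(prep_filter(rd), tiny_targets(ref), ref)
  a <- pp$alleles[grepl("^del:", pp$alleles$allele)]
  expect_equal(a$pos, run_start - 1L)
})

test_that("pileup counts match the naive per-read oracle on a noisy fixture", {
  sim <- sim_reference(n_genes = 2, gene_len = 300, seed = 3, flank = 50)
  truth <- sim_variant_truth(sim$reference, sim$genes, n = 4, seed = 4,
                             indel_frac = 0.5)
  rd <- sim_snv_reads(sim$reference, sim$genes, truth, purity = 1,
                      depth = 40, read_len = 60L, error_rate = 5e-3,
                      ffpe_rate = 3e-3, seed = 5)
  pp <- build_pileups(prep_filter(rd), sim$genes, sim$reference)
  rdf <- as.data.frame(rd)
  for (i in seq_len(nrow(truth))) {
    want <- oracle_pileup(rdf, sim$reference, truth$chrom[i], truth$pos[i])
    got <- pp$alleles[list(truth$chrom[i], truth$pos[i]), nomatch = NULL]
    for (key in names(want)) {
      row <- got[got$allele == key]
      expect_equal(unname(row$fwd), unname(want[[key]]["fwd"]),
                   label = paste(truth$chrom[i], truth$pos[i], key, "fwd"))
      expect_equal(unname(row$rev), unname(want[[key]]["rev"]),
                   label = paste(truth$chrom[i], truth$pos[i], key, "rev"))
    }
    # and no alleles the oracle does not see
    expect_setequal(got$allele, names(want))
  }
})

test_that("strand-split counts always sum to the allele count", {
  sim <- sim_reference(n_genes = 1, gene_len = 400, seed = 8)
  rd <- sim_snv_reads(sim$reference, sim$genes, depth = 60, read_len = 70L,
                      error_rate = 0.01, seed = 9)
  pp <- build_pileups(prep_filter(rd), sim$genes, sim$reference)
  a <- pp$alleles[!grepl(":", pp$alleles$allele)]
  dep <- a[, list(tot = sum(fwd + rev)), by = c("chrom", "pos")]
  m <- merge(dep, pp$sites, by = c("chrom", "pos"))
  expect_true(all(m$tot == m$depth))
  expect_true(all(a$fwd >= 0 & a$rev >= 0))
})

test_that("site_read_calls reports offsets, end distances and indels", {
  refseq <- strrep("ACGTTGCA", 20)
  ref <- tiny_ref(refseq)
  rd <- make_reads("chr1", c(1L, 11L), c(substr(refseq, 1, 40),
                                         substr(refseq, 11, 50)))
  pp <- build_pileups(prep_filter(rd), tiny_targets(ref), ref)
  ctx <- site_read_calls(pp, "chr1", 12L)
  expect_equal(nrow(ctx), 2L)
  expect_equal(sort(ctx$off), c(2L, 12L))
  expect_equal(sort(ctx$dist_end), c(1L, 11L))
  expect_equal(ctx$base, rep(substr(refseq, 12, 12), 2))
})

test_that("SAM round-trip preserves the read table", {
  sim <- sim_reference(n_genes = 1, gene_len = 200, seed = 13)
  rd <- sim_snv_reads(sim$reference, sim$genes, depth = 15, read_len = 40L,
                      seed = 14)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(rd, path, sim$reference)
  back <- read_sam(path)
  expect_equal(nrow(back), nrow(rd))
  data.table::setorderv(back, c("qname"))
  rd2 <- data.table::copy(rd)
  data.table::setorderv(rd2, c("qname"))
  expect_equal(back$seq, rd2$seq)
  expect_equal(back$pos, rd2$pos)
  expect_equal(back$cigar, rd2$cigar)
})
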