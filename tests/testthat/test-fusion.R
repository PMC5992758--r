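# Split-read fusion detection: local alignment, 2map, virtual-fusion
# rescue, paired-end corroboration and S/N ranking.

fusion_fixture <- function(seed = 5) {
  sim <- sim_reference(n_genes = 4, gene_len = 1500, seed = seed, flank = 0)
  sim
}

test_that("local alignment splits a chimera and rejects an all-N read", {
  sim <- fusion_fixture()
  whole <- as.character(Biostrings::subseq(sim$reference[["gene1"]], 301, 400))
  plain <- align_local(stats::setNames(whole, "plain"), sim$reference)
  expect_equal(nrow(plain), 1L)
  expect_equal(plain$chrom, "gene1")
  expect_equal(plain$ref_start, 301L)
  expect_equal(plain$ref_end, 400L)

  chim <- paste0(
    as.character(Biostrings::subseq(sim$reference[["gene1"]], 926, 1000)),
    as.character(Biostrings::subseq(sim$reference[["gene2"]], 501, 575)))
  segs <- align_local(stats::setNames(chim, "chim"), sim$reference)
  expect_equal(nrow(segs), 2L)
  segs <- segs[order(segs$q_start)]
  expect_equal(segs$chrom, c("gene1", "gene2"))
  # halves are near-disjoint; chance matches may extend an end by a base
  # or two, which the 2map modal clustering absorbs
  expect_lte(abs(segs$q_end[1] - 75L), 2L)
  expect_lte(abs(segs$q_start[2] - 76L), 2L)
  expect_lte(abs(segs$ref_end[1] - 1000L), 2L)
  expect_lte(abs(segs$ref_start[2] - 501L), 2L)

  nn <- align_local(stats::setNames(strrep("N", 100), "nn"), sim$reference)
  expect_equal(nrow(nn), 0L)
})

test_that("2map clusters split reads into one exact-breakpoint candidate", {
  sim <- fusion_fixture()
  fus <- sim_fusion_reads(sim$reference, "gene1", "gene2", 1000L, 501L,
                          n_support = 12L, n_background = 0L, seed = 6)
  segs <- align_local(fus$reads, sim$reference)
  cands <- twomap_step(segs, sim$genes, "gene1")
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$gene_a, "gene1")
  expect_equal(cands$gene_b, "gene2")
  expect_equal(cands$bp_a, 1000L)
  expect_equal(cands$bp_b, 501L)
  expect_equal(cands$split_support, 12L)

  # a read mapping twice within the same gene is not a candidate
  dup <- data.table::data.table(
    qname = "d1", chrom = "gene1", ref_start = c(100L, 600L),
    ref_end = c(160L, 660L), q_start = c(1L, 61L), q_end = c(60L, 120L),
    strand = "+", score = 60)
  expect_equal(nrow(twomap_step(dup, sim$genes, "gene1")), 0L)

  # candidates must touch a user-indicated gene
  expect_equal(nrow(twomap_step(segs, sim$genes, "gene4")), 0L)
  expect_error(twomap_step(segs, sim$genes, character(0)), "user-indicated")
})

test_that("a short-tail chimera is missed by 2map but rescued by VF", {
  sim <- fusion_fixture()
  # main support builds the candidate and its virtual reference
  fus <- sim_fusion_reads(sim$reference, "gene1", "gene2", 1000L, 501L,
                          n_support = 10L, n_background = 0L, seed = 7)
  segs <- align_local(fus$reads, sim$reference)
  cands <- twomap_step(segs, sim$genes, "gene1", min_seg = 20L)
  vref <- build_virtual_fusion(cands[1], sim$reference, flank = 200L)
  expect_equal(attr(vref, "junction"), 200L)
  want <- paste0(
    as.character(Biostrings::subseq(sim$reference[["gene1"]], 801, 1000)),
    as.character(Biostrings::subseq(sim$reference[["gene2"]], 501, 700)))
  expect_equal(as.character(vref), want)

  # 145 + 5 bp chimera: the 5 bp tail cannot seed a second alignment
  shorttail <- paste0(
    as.character(Biostrings::subseq(sim$reference[["gene1"]], 856, 1000)),
    as.character(Biostrings::subseq(sim$reference[["gene2"]], 501, 505)))
  st_segs <- align_local(stats::setNames(shorttail, "st"), sim$reference)
  expect_equal(nrow(twomap_step(st_segs, sim$genes, "gene1", min_seg = 20L)),
               0L)
  reads <- Biostrings::DNAStringSet(c(st = shorttail,
                                      gA = as.character(Biostrings::subseq(
                                        sim$reference[["gene1"]], 101, 250))))
  support <- vf_step(reads, list(vref))
  expect_equal(support, 1L)  # the gene-A-only read does not cross the junction
})

test_that("vf_step requires the virtual references", {
  expect_equal(vf_step(Biostrings::DNAStringSet("ACGT"), list()), integer(0))
  cand0 <- data.table::data.table(gene_a = "g", gene_b = "h", bp_a = 1L,
                                  bp_b = 1L, strand_a = "+", strand_b = "+",
                                  split_support = 0L, qnames = list(character(0)))
  expect_error(build_virtual_fusion(cand0, NULL), "at least one")
})

test_that("paired-end discordant mates corroborate the candidate", {
  sim <- fusion_fixture()
  cand <- data.table::data.table(gene_a = "gene1", gene_b = "gene2",
                                 bp_a = 1000L, bp_b = 501L, strand_a = "+",
                                 strand_b = "+", split_support = 5L)
  seg1 <- data.table::data.table(qname = c("p1", "p2"), chrom = "gene1",
                                 ref_start = c(800L, 100L),
                                 ref_end = c(900L, 200L),
                                 q_start = 1L, q_end = 101L, strand = "+",
                                 score = 100)
  seg2 <- data.table::data.table(qname = c("p1", "p2"), chrom = "gene2",
                                 ref_start = c(550L, 550L),
                                 ref_end = c(650L, 650L),
                                 q_start = 1L, q_end = 101L, strand = "-",
                                 score = 100)
  sup <- paired_end_step(seg1, seg2, cand, sim$genes, window = 300L)
  expect_equal(sup, 1L)  # p2's gene1 mate is 800 bp from the breakpoint

  # both mates in the same gene never count
  seg2same <- data.table::copy(seg1)
  expect_equal(paired_end_step(seg1, seg2same, cand, sim$genes), 0L)
})

test_that("ranking computes S/N and normalized support as documented", {
  cands <- data.table::data.table(
    gene_a = c("A", "A"), gene_b = c("B", "C"), bp_a = c(10L, 20L),
    bp_b = c(30L, 40L), strand_a = "+", strand_b = "+",
    split_support = c(18L, 4L), vf_support = c(2L, 0L))
  r <- rank_candidates(cands, mapped_read_total = 1e6)
  expect_equal(r$total_support, c(20L, 4L))
  expect_equal(r$sn_ratio[1], 5.0)
  expect_equal(r$norm_support[1], 2e-5)

  single <- rank_candidates(cands[1], mapped_read_total = 100)
  expect_identical(single$sn_ratio, Inf)
})

test_that("junction jitter keeps the recovered breakpoint within tolerance", {
  sim <- fusion_fixture(seed = 15)
  fus <- sim_fusion_reads(sim$reference, "gene1", "gene2", 900L, 401L,
                          n_support = 15L, junction_jitter = 2L,
                          n_background = 0L, seed = 16)
  res <- call_fusions(fus$reads, sim$reference, sim$genes, "gene1")
  top <- res$candidates[1]
  expect_lte(abs(top$bp_a - 900L), 5L)
  expect_lte(abs(top$bp_b - 401L), 5L)
  expect_gte(top$total_support, 13L)
})

test_that("support reads are never double-counted across 2map and VF", {
  sim <- fusion_fixture(seed = 25)
  fus <- sim_fusion_reads(sim$reference, "gene1", "gene3", 700L, 301L,
                          n_support = 10L, n_background = 50L, seed = 26)
  res <- call_fusions(fus$reads, sim$reference, sim$genes, "gene1")
  top <- res$candidates[1]
  expect_equal(top$split_support + top$vf_support, top$total_support)
  expect_lte(top$total_support, 10L)  # no background read sneaks in
  expect_equal(top$split_support, length(top$qnames[[1]]))
})
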