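# Fixture builders used across the suite. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# a read table from parallel vectors, with sensible defaults
make_reads <- function(chrom, pos, seq, qual = NULL, flag = 0L, mapq = 60L,
                       cigar = NULL, qname = NULL) {
  n <- length(pos)
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  if (is.null(qual)) qual <- strrep("?", nchar(seq))  # Phred 30
  if (is.null(qname)) qname <- sprintf("r%04d", seq_len(n))
  as_reads(data.frame(qname = qname, flag = rep_len(flag, n),
                      chrom = rep_len(chrom, n), pos = pos,
                      mapq = rep_len(mapq, n),
                      cigar = rep_len(cigar, n), seq = seq,
                      qual = rep_len(qual, n)))
}

# single-contig reference + covering target
tiny_ref <- function(seq, name = "chr1") {
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- name
  ref
}

tiny_targets <- function(ref, start = 1L, end = NULL) {
  if (is.null(end)) end <- Biostrings::width(ref)[1]
  gr <- GenomicRanges::GRanges(names(ref)[1], IRanges::IRanges(start, end))
  gr$label <- names(ref)[1]
  gr
}

# reads tiling a reference slice perfectly (all reference allele)
tile_reads <- function(ref, chrom, start, end, read_len = 50L, n = 20L,
                       flag = NULL) {
  starts <- round(seq(start, max(start, end - read_len + 1L), length.out = n))
  seqs <- vapply(starts, function(s)
    as.character(Biostrings::subseq(ref[[chrom]], s, s + read_len - 1L)),
    character(1))
  if (is.null(flag)) flag <- rep(c(0L, 16L), length.out = n)
  make_reads(chrom, starts, seqs, flag = flag)
}

expect_verdict <- function(v, passed) {
  expect_s3_class(v, "data.table")
  expect_identical(nrow(v), 1L)
  expect_identical(v$passed, passed)
}
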