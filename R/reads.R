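#' @import data.table
#' @importFrom methods is
#' @importFrom stats median quantile rbinom rpois runif rbeta rnorm setNames
#'   p.adjust complete.cases
NULL

# Aligned reads are carried as a data.table with one row per alignment record
# (SAM semantics, 1-based leftmost position):
#   qname, flag, chrom, pos, mapq, cigar, seq, qual (Phred+33 string),
#   mchrom, mpos (mate; "*" / 0 when absent)
# Derived columns added on validation: rend (rightmost ref position), rev
# (logical strand flag).

READ_COLS <- c("qname", "flag", "chrom", "pos", "mapq", "cigar", "seq", "qual")

#' Assemble an aligned-read table
#'
#' Validates and indexes a table of aligned reads (the internal currency of
#' the callers). Most users get these from [read_sam()] or from the
#' simulators.
#'
#' @param df data.frame with columns qname, flag, chrom, pos (1-based), mapq,
#'   cigar, seq, qual; optional mchrom, mpos.
#' @return A keyed data.table with derived `rend` and `rev` columns.
#' @export
as_reads <- function(df) {
  dt <- data.table::as.data.table(df)
  miss <- setdiff(READ_COLS, names(dt))
  if (length(miss)) stop("read table missing column(s): ", paste(miss, collapse = ", "))
  if (!"mchrom" %in% names(dt)) dt[, "mchrom" := "*"]
  if (!"mpos" %in% names(dt)) dt[, "mpos" := 0L]
  bad <- dt$qual != "*" & nchar(dt$seq) != nchar(dt$qual)
  if (any(bad)) stop("seq/qual length mismatch for read ", dt$qname[which(bad)[1]])
  dt[, "pos" := as.integer(dt$pos)]
  dt[, "flag" := as.integer(dt$flag)]
  dt[, "mapq" := as.integer(dt$mapq)]
  rw <- cigar_ref_width(dt$cigar)
  nb <- cigar_read_width(dt$cigar)
  ok <- dt$cigar == "*" | nb == nchar(dt$seq)
  if (!all(ok)) stop("CIGAR inconsistent with read length for read ",
                     dt$qname[which(!ok)[1]])
  dt[, "rend" := dt$pos + as.integer(rw) - 1L]
  dt[, "rev" := bitwAnd(dt$flag, 16L) != 0L]
  data.table::setkey(dt, "chrom", "pos")
  dt[]
}

cigar_ops <- function(cigar) {
  regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
}

# reference bp consumed by each CIGAR (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  vapply(cigar_ops(cigar), function(ops) {
    if (!length(ops)) return(0)
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

# read bases consumed (M/I/S/=/X)
cigar_read_width <- function(cigar) {
  vapply(cigar_ops(cigar), function(ops) {
    if (!length(ops)) return(0)
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    sum(n[op %in% c("M", "I", "S", "=", "X")])
  }, numeric(1))
}

#' Read alignments from a SAM file
#'
#' Parses the mandatory SAM columns into the package's read table. BAM input
#' can be converted with `samtools view -h` or `Rsamtools::asSam()` first;
#' the callers themselves only need the columns kept here.
#'
#' @param path Path to a SAM file (plain text, with or without header).
#' @return A read table (see [as_reads()]).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(as_reads(data.frame(qname = character(), flag = integer(),
                               chrom = character(), pos = integer(),
                               mapq = integer(), cigar = character(),
                               seq = character(), qual = character())))
  }
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:11)
  as_reads(data.frame(
    qname = f[[1]], flag = as.integer(f[[2]]), chrom = f[[3]],
    pos = as.integer(f[[4]]), mapq = as.integer(f[[5]]), cigar = f[[6]],
    mchrom = f[[7]], mpos = as.integer(f[[8]]),
    seq = f[[10]], qual = f[[11]]))
}

#' Write alignments to a SAM file
#'
#' @param reads Read table.
#' @param path Output path.
#' @param reference Optional DNAStringSet used to emit `@SQ` header lines.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(reads, path, reference = NULL) {
  hdr <- "@HD\tVN:1.6\tSO:coordinate"
  if (!is.null(reference)) {
    hdr <- c(hdr, sprintf("@SQ\tSN:%s\tLN:%d", names(reference),
                          Biostrings::width(reference)))
  }
  dt <- data.table::as.data.table(reads)
  data.table::setorderv(dt, c("chrom", "pos"))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                  dt$qname, dt$flag, dt$chrom, dt$pos, dt$mapq, dt$cigar,
                  dt$mchrom, dt$mpos, dt$seq, dt$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Apply the prep filters to a read table
#'
#' Drops unmapped, secondary, supplementary and (by default) duplicate
#' records, removes reads below the mapping-quality floor from counting, and
#' sets aside MQ0 reads so their coverage can be tallied per site (the MQ0
#' noise filter needs the fraction of ambiguously mapped reads even though
#' those reads never contribute allele counts). Base-quality masking happens
#' at pileup time using `min_baseq` carried along here.
#'
#' @param reads Read table.
#' @param min_mapq Minimum mapping quality for a read to be counted.
#' @param min_baseq Minimum base quality for a base call to be counted.
#' @param drop_duplicates Drop records flagged 0x400.
#' @return list with `reads` (counted), `mq0_reads` (mapq == 0 overlaps kept
#'   for the MQ0 tally) and `min_baseq`.
#' @export
prep_filter <- function(reads, min_mapq = 20L, min_baseq = 20L,
                        drop_duplicates = TRUE) {
  stopifnot(min_mapq >= 0, min_baseq >= 0)
  dt <- data.table::as.data.table(reads)
  drop_flags <- 0x4L + 0x100L + 0x800L
  keep <- bitwAnd(dt$flag, drop_flags) == 0L
  if (drop_duplicates) keep <- keep & bitwAnd(dt$flag, 0x400L) == 0L
  dt <- dt[keep]
  mq0 <- dt[dt$mapq == 0L]
  # mapq 0 reads are never counted: they feed the MQ0 tally instead
  pass <- dt[dt$mapq >= min_mapq & dt$mapq > 0L]
  list(reads = pass, mq0_reads = mq0, min_baseq = as.integer(min_baseq))
}

# Phred+33 string -> integer vector
qual_ints <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}
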