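# Pileup construction.
#
# Reads are expanded into (position, base, qual, strand, read-id) tuples per
# target region and aggregated with data.table; reads whose CIGAR is a single
# match block take a fully vectorised path, anything with indels or clips is
# walked individually. The resulting `pileup` object bundles the per-position
# allele counts with the prepped reads themselves, because the noise filters
# need to go back to read level at candidate sites.

#' Build pileups over the capture targets
#'
#' One column per target base covered by at least one counted read, with
#' allele counts split by strand, the MQ0 overlap tally, and per-read
#' mismatch counts used later as internal controls. Indels are left-aligned
#' against the reference and keyed at the base preceding the event
#' (`ins:<seq>` / `del:<len>` allele keys).
#'
#' @param prepped Output of [prep_filter()] (a read table is also accepted
#'   and run through [prep_filter()] with default thresholds).
#' @param targets GRanges of capture targets ([load_targets()]).
#' @param reference DNAStringSet ([read_reference()]).
#' @param max_indel_len Longest indel allele tracked (bp); longer events are
#'   ignored.
#' @return An object of class `pileup`: list with `alleles`
#'   (chrom/pos/allele/fwd/rev counts), `sites` (chrom/pos/ref/depth/mq0),
#'   `reads` (counted reads with an `n_mism` column), `mq0_reads`,
#'   `min_baseq`, `targets`.
#' @export
build_pileups <- function(prepped, targets, reference, max_indel_len = 10L) {
  if (is.data.frame(prepped)) prepped <- prep_filter(prepped)
  reads <- data.table::copy(prepped$reads)
  minq <- prepped$min_baseq
  reads[, "n_mism" := 0L]
  reads[, ".rid" := seq_len(nrow(reads))]

  allele_l <- list()
  site_l <- list()
  tg <- data.frame(chrom = as.character(GenomicRanges::seqnames(targets)),
                   start = GenomicRanges::start(targets),
                   end = GenomicRanges::end(targets))
  for (i in seq_len(nrow(tg))) {
    res <- pileup_region(reads, prepped$mq0_reads, tg$chrom[i], tg$start[i],
                         tg$end[i], reference, minq, max_indel_len)
    if (is.null(res)) next
    allele_l[[length(allele_l) + 1L]] <- res$alleles
    site_l[[length(site_l) + 1L]] <- res$sites
    if (nrow(res$mism)) {
      reads[res$mism$rid, "n_mism" := reads$n_mism[res$mism$rid] + res$mism$n]
    }
  }
  alleles <- data.table::rbindlist(allele_l)
  sites <- data.table::rbindlist(site_l)
  if (!nrow(alleles)) {
    alleles <- data.table::data.table(chrom = character(), pos = integer(),
                                      allele = character(), fwd = integer(),
                                      rev = integer())
    sites <- data.table::data.table(chrom = character(), pos = integer(),
                                    ref = character(), depth = integer(),
                                    mq0 = integer())
  }
  data.table::setkey(alleles, "chrom", "pos")
  data.table::setkey(sites, "chrom", "pos")
  structure(list(alleles = alleles, sites = sites, reads = reads,
                 mq0_reads = prepped$mq0_reads, min_baseq = minq,
                 targets = targets),
            class = "pileup")
}

# expand + count one target region; returns NULL when no read overlaps
pileup_region <- function(reads, mq0_reads, chr, rs, re, reference, minq,
                          max_indel_len) {
  sel <- reads[reads$chrom == chr & reads$pos <= re & reads$rend >= rs]
  if (!nrow(sel)) return(NULL)
  refseq <- as.character(ref_slice(reference, chr, rs, re))
  refv <- as.integer(charToRaw(refseq))
  chrom_seq <- if (is(reference, "DNAStringSet")) reference[[chr]] else reference

  simple <- grepl("^\\d+M$", sel$cigar)
  tup <- list()
  indel_l <- list()
  if (any(simple)) {
    ss <- sel[simple]
    len <- nchar(ss$seq)
    rid <- rep(ss$.rid, len)
    revs <- rep(ss$rev, len)
    off <- sequence(len)
    gpos <- rep(ss$pos, len) + off - 1L
    base <- as.integer(charToRaw(paste(ss$seq, collapse = "")))
    qual <- as.integer(charToRaw(paste(ss$qual, collapse = ""))) - 33L
    tup[[1]] <- data.table::data.table(rid = rid, gpos = gpos, base = base,
                                       qual = qual, rev = revs)
  }
  if (any(!simple)) {
    cs <- sel[!simple]
    for (j in seq_len(nrow(cs))) {
      w <- cigar_walk(cs$cigar[j], cs$pos[j])
      sv <- as.integer(charToRaw(cs$seq[j]))
      qv <- as.integer(charToRaw(cs$qual[j])) - 33L
      if (nrow(w$blocks)) {
        offs <- sequence(w$blocks[, "len"])
        gpos <- rep(w$blocks[, "ref_start"], w$blocks[, "len"]) + offs - 1L
        roff <- rep(w$blocks[, "read_start"], w$blocks[, "len"]) + offs - 1L
        tup[[length(tup) + 1L]] <- data.table::data.table(
          rid = cs$.rid[j], gpos = gpos, base = sv[roff], qual = qv[roff],
          rev = cs$rev[j])
      }
      if (length(w$ins)) {
        for (ev in w$ins) {
          if (ev$len > max_indel_len) next
          s <- substr(cs$seq[j], ev$read_start, ev$read_start + ev$len - 1L)
          la <- left_align_ins(chrom_seq, ev$ref_before, s)
          indel_l[[length(indel_l) + 1L]] <- data.table::data.table(
            gpos = la$pos, allele = paste0("ins:", la$seq), rev = cs$rev[j])
        }
      }
      if (length(w$del)) {
        for (ev in w$del) {
          if (ev$len > max_indel_len) next
          p <- left_align_del(chrom_seq, ev$ref_before, ev$len)
          indel_l[[length(indel_l) + 1L]] <- data.table::data.table(
            gpos = p, allele = paste0("del:", ev$len), rev = cs$rev[j])
        }
      }
    }
  }
  tup <- data.table::rbindlist(tup)
  if (!nrow(tup)) return(NULL)
  tup <- tup[tup$gpos >= rs & tup$gpos <= re]
  if (!nrow(tup)) return(NULL)

  # per-read confident mismatches (internal control for several filters)
  acgt <- tup$base %in% c(65L, 67L, 71L, 84L)
  conf <- tup[tup$qual >= minq & acgt]
  mm <- conf[conf$base != refv[conf$gpos - rs + 1L]]
  mism <- if (nrow(mm)) mm[, list(n = .N), by = "rid"] else
    data.table::data.table(rid = integer(), n = integer())

  cnt <- conf[, list(n = .N), by = c("gpos", "base", "rev")]
  alleles <- data.table::dcast(cnt, gpos + base ~ rev, value.var = "n",
                               fill = 0L)
  fwd <- if ("FALSE" %in% names(alleles)) alleles[["FALSE"]] else 0L
  revc <- if ("TRUE" %in% names(alleles)) alleles[["TRUE"]] else 0L
  alleles <- data.table::data.table(
    chrom = chr, pos = alleles$gpos,
    allele = strsplit(rawToChar(as.raw(alleles$base)), "")[[1]],
    fwd = as.integer(fwd), rev = as.integer(revc))

  if (length(indel_l)) {
    idt <- data.table::rbindlist(indel_l)
    idt <- idt[idt$gpos >= rs & idt$gpos <= re]
    if (nrow(idt)) {
      icnt <- idt[, list(n = .N), by = c("gpos", "allele", "rev")]
      iw <- data.table::dcast(icnt, gpos + allele ~ rev, value.var = "n",
                              fill = 0L)
      ifwd <- if ("FALSE" %in% names(iw)) iw[["FALSE"]] else 0L
      irev <- if ("TRUE" %in% names(iw)) iw[["TRUE"]] else 0L
      alleles <- rbind(alleles, data.table::data.table(
        chrom = chr, pos = iw$gpos, allele = iw$allele,
        fwd = as.integer(ifwd), rev = as.integer(irev)))
    }
  }

  depth <- alleles[!startsWith(alleles$allele, "ins:") &
                   !startsWith(alleles$allele, "del:"),
                   list(depth = sum(fwd + rev)), by = "pos"]

  mq0sel <- mq0_reads[mq0_reads$chrom == chr & mq0_reads$pos <= re &
                      mq0_reads$rend >= rs]
  mq0tab <- NULL
  if (nrow(mq0sel)) {
    st <- pmax(mq0sel$pos, rs)
    en <- pmin(mq0sel$rend, re)
    lens <- en - st + 1L
    mpos <- rep(st, lens) + sequence(lens) - 1L
    mq0tab <- data.table::data.table(pos = mpos)[, list(mq0 = .N), by = "pos"]
  }
  sites <- data.table::data.table(
    chrom = chr, pos = depth$pos,
    ref = strsplit(refseq, "")[[1]][depth$pos - rs + 1L],
    depth = as.integer(depth$depth))
  sites[, "mq0" := 0L]
  if (!is.null(mq0tab)) {
    m <- match(sites$pos, mq0tab$pos)
    hit <- !is.na(m)
    sites[hit, "mq0" := mq0tab$mq0[m[hit]]]
  }
  list(alleles = alleles, sites = sites, mism = mism)
}

# decompose a CIGAR into aligned blocks and indel events
# (ref coordinates 1-based; read coordinates 1-based including soft clips)
cigar_walk <- function(cigar, pos) {
  ops <- cigar_ops(cigar)[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- substr(ops, nchar(ops), nchar(ops))
  rpos <- pos
  qpos <- 1L
  blocks <- list()
  ins <- list()
  del <- list()
  for (k in seq_along(op)) {
    if (op[k] %in% c("M", "=", "X")) {
      blocks[[length(blocks) + 1L]] <- c(ref_start = rpos, read_start = qpos,
                                         len = n[k])
      rpos <- rpos + n[k]; qpos <- qpos + n[k]
    } else if (op[k] == "I") {
      ins[[length(ins) + 1L]] <- list(ref_before = rpos - 1L,
                                      read_start = qpos, len = n[k])
      qpos <- qpos + n[k]
    } else if (op[k] == "D" || op[k] == "N") {
      if (op[k] == "D") {
        del[[length(del) + 1L]] <- list(ref_before = rpos - 1L, len = n[k])
      }
      rpos <- rpos + n[k]
    } else if (op[k] == "S") {
      qpos <- qpos + n[k]
    } # H/P consume nothing we track
  }
  list(blocks = do.call(rbind, blocks) %||% matrix(integer(), 0, 3,
         dimnames = list(NULL, c("ref_start", "read_start", "len"))),
       ins = ins, del = del)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shift a deletion of `len` bp keyed after `p_before` to its leftmost
# equivalent position
left_align_del <- function(chrom_seq, p_before, len) {
  cs <- as.character(chrom_seq)
  while (p_before >= 1L &&
         substr(cs, p_before + len, p_before + len) ==
         substr(cs, p_before, p_before)) {
    p_before <- p_before - 1L
  }
  max(p_before, 1L)
}

# shift an insertion (sequence s after p_before) leftwards, rotating s
left_align_ins <- function(chrom_seq, p_before, s) {
  cs <- as.character(chrom_seq)
  L <- nchar(s)
  while (p_before >= 1L && substr(cs, p_before, p_before) == substr(s, L, L)) {
    s <- paste0(substr(cs, p_before, p_before), substr(s, 1L, L - 1L))
    p_before <- p_before - 1L
  }
  list(pos = max(p_before, 1L), seq = s)
}

#' Per-read calls at one site
#'
#' Read-level view the noise filters operate on: for every counted read
#' overlapping `pos`, the base call (NA inside a deletion), its quality,
#' read offset, distance from the nearer read end, strand, the read's
#' confident mismatch count, and any indel allele keyed at this position.
#'
#' @param pp A `pileup` object.
#' @param chrom,pos Site (1-based).
#' @return data.table, one row per overlapping read.
#' @export
site_read_calls <- function(pp, chrom, pos) {
  chr <- chrom
  p <- pos
  sel <- pp$reads[pp$reads$chrom == chr & pp$reads$pos <= p &
                  pp$reads$rend >= p]
  if (!nrow(sel)) {
    return(data.table::data.table(qname = character(), base = character(),
                                  qual = integer(), off = integer(),
                                  len = integer(), dist_end = integer(),
                                  rev = logical(), n_mism = integer(),
                                  indel = character(), masked = logical()))
  }
  len <- nchar(sel$seq)
  off <- rep(NA_integer_, nrow(sel))
  indel <- rep("", nrow(sel))
  simple <- grepl("^\\d+M$", sel$cigar)
  off[simple] <- pos - sel$pos[simple] + 1L
  for (j in which(!simple)) {
    w <- cigar_walk(sel$cigar[j], sel$pos[j])
    for (b in seq_len(nrow(w$blocks))) {
      bs <- w$blocks[b, ]
      if (pos >= bs["ref_start"] && pos < bs["ref_start"] + bs["len"]) {
        off[j] <- unname(bs["read_start"] + (pos - bs["ref_start"]))
        break
      }
    }
    for (ev in w$ins) {
      if (ev$ref_before == pos) indel[j] <- paste0("ins:", substr(
        sel$seq[j], ev$read_start, ev$read_start + ev$len - 1L))
    }
    for (ev in w$del) {
      if (ev$ref_before == pos) indel[j] <- paste0("del:", ev$len)
    }
  }
  base <- ifelse(is.na(off), NA_character_, substr(sel$seq, off, off))
  qch <- ifelse(is.na(off), NA_character_, substr(sel$qual, off, off))
  q <- vapply(qch, function(x) {
    if (is.na(x) || !nzchar(x)) NA_integer_ else utf8ToInt(x) - 33L
  }, integer(1), USE.NAMES = FALSE)
  data.table::data.table(
    qname = sel$qname, base = base, qual = q, off = off, len = len,
    dist_end = pmin(off - 1L, len - off), rev = sel$rev,
    n_mism = sel$n_mism, indel = indel,
    masked = !is.na(q) & q < pp$min_baseq)
}
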