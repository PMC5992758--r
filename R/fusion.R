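# DNA gene-fusion detection: split-read ("2map") discovery, virtual-fusion
# rescue of reads whose alignment on one side is too short, optional
# discordant-pair corroboration, and S/N ranking. Local alignment runs
# in-process on Biostrings::pairwiseAlignment (Smith-Waterman); an external
# `bwa bwasw` engine can be substituted for real-sized references.

fusion_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3,
                                           baseOnly = FALSE)
}

#' Local-align reads against a reference, reporting split segments
#'
#' Each read yields zero, one or two local alignments: the best-scoring
#' local hit over all contigs and both orientations, then (if the unaligned
#' prefix or suffix is at least `min_tail` bp) a second hit for the
#' remainder. Coordinates are reported in original read orientation so the
#' 2map step can order segments left/right along the read.
#'
#' @param reads Named DNAStringSet (or character vector) of read sequences.
#' @param reference DNAStringSet of gene/contig sequences.
#' @param min_score Minimum alignment score to report a segment.
#' @param min_tail Minimum unaligned tail length to attempt a second hit.
#' @param engine "sw" (in-process, default) or "bwa" (external `bwa bwasw`;
#'   requires the binary on PATH and writes temporary FASTA files).
#' @return data.table: qname, chrom, ref_start, ref_end, q_start, q_end,
#'   strand, score.
#' @export
align_local <- function(reads, reference, min_score = 25, min_tail = 15L,
                        engine = c("sw", "bwa")) {
  engine <- match.arg(engine)
  if (is.character(reads)) {
    reads <- Biostrings::DNAStringSet(reads)
    if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  }
  if (!length(reads)) return(empty_segments())
  if (engine == "bwa") return(align_local_bwa(reads, reference, min_score))
  segs <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    segs[[i]] <- align_read_sw(reads[[i]], names(reads)[i], reference,
                               min_score, min_tail)
  }
  out <- data.table::rbindlist(segs)
  if (!nrow(out)) return(empty_segments())
  out
}

empty_segments <- function() {
  data.table::data.table(qname = character(), chrom = character(),
                         ref_start = integer(), ref_end = integer(),
                         q_start = integer(), q_end = integer(),
                         strand = character(), score = numeric())
}

# best local hit of `pattern` (a DNAString) over contigs x orientations
best_local_hit <- function(pattern, reference, min_score) {
  L <- length(pattern)
  if (L == 0 || Biostrings::letterFrequency(
        Biostrings::DNAStringSet(pattern), "ACGT")[1, 1] == 0) {
    return(NULL)
  }
  sm <- fusion_submat()
  best <- NULL
  for (ct in names(reference)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pattern else
        Biostrings::reverseComplement(pattern)
      aln <- Biostrings::pairwiseAlignment(
        pat, reference[[ct]], type = "local", substitutionMatrix = sm,
        gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(aln)
      if (sc < min_score) next
      if (is.null(best) || sc > best$score) {
        ps <- IRanges::start(Biostrings::pattern(aln))
        pe <- IRanges::end(Biostrings::pattern(aln))
        if (strand == "-") {
          tmp <- ps
          ps <- L - pe + 1L
          pe <- L - tmp + 1L
        }
        best <- list(chrom = ct,
                     ref_start = IRanges::start(Biostrings::subject(aln)),
                     ref_end = IRanges::end(Biostrings::subject(aln)),
                     q_start = ps, q_end = pe, strand = strand, score = sc)
      }
    }
  }
  best
}

align_read_sw <- function(read, qname, reference, min_score, min_tail) {
  L <- length(read)
  hit1 <- best_local_hit(read, reference, min_score)
  if (is.null(hit1)) return(NULL)
  segs <- list(hit1)
  # realign whichever unaligned tail is longest
  pre <- hit1$q_start - 1L
  suf <- L - hit1$q_end
  if (max(pre, suf) >= min_tail) {
    if (pre >= suf) {
      tail_rng <- c(1L, hit1$q_start - 1L)
    } else {
      tail_rng <- c(hit1$q_end + 1L, L)
    }
    piece <- Biostrings::subseq(read, tail_rng[1], tail_rng[2])
    hit2 <- best_local_hit(piece, reference, min_score)
    if (!is.null(hit2)) {
      hit2$q_start <- hit2$q_start + tail_rng[1] - 1L
      hit2$q_end <- hit2$q_end + tail_rng[1] - 1L
      segs[[2]] <- hit2
    }
  }
  data.table::rbindlist(lapply(segs, function(s)
    data.table::data.table(qname = qname, chrom = s$chrom,
                           ref_start = s$ref_start, ref_end = s$ref_end,
                           q_start = s$q_start, q_end = s$q_end,
                           strand = s$strand, score = s$score)))
}

# external engine: bwa bwasw, parsing primary + supplementary SAM records
align_local_bwa <- function(reads, reference, min_score) {
  bwa <- Sys.which("bwa")
  if (!nzchar(bwa)) {
    stop("external aligner engine requested but 'bwa' was not found on PATH")
  }
  td <- tempfile("bwasw")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  rf <- file.path(td, "ref.fa")
  qf <- file.path(td, "reads.fa")
  Biostrings::writeXStringSet(reference, rf)
  Biostrings::writeXStringSet(reads, qf)
  system2(bwa, c("index", rf), stdout = FALSE, stderr = FALSE)
  sam <- system2(bwa, c("bwasw", rf, qf), stdout = TRUE, stderr = FALSE)
  sam <- sam[!startsWith(sam, "@")]
  if (!length(sam)) return(empty_segments())
  f <- data.table::tstrsplit(sam, "\t", fixed = TRUE, keep = 1:10)
  dt <- data.table::data.table(qname = f[[1]], flag = as.integer(f[[2]]),
                               chrom = f[[3]], pos = as.integer(f[[4]]),
                               cigar = f[[6]], seq = f[[10]])
  dt <- dt[bitwAnd(dt$flag, 4L) == 0L]
  if (!nrow(dt)) return(empty_segments())
  rl <- setNames(Biostrings::width(reads), names(reads))
  out <- lapply(seq_len(nrow(dt)), function(j) {
    ops <- cigar_ops(dt$cigar[j])[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    lead <- if (op[1] %in% c("S", "H")) n[1] else 0L
    read_used <- sum(n[op %in% c("M", "I", "=", "X")])
    refw <- sum(n[op %in% c("M", "D", "N", "=", "X")])
    L <- rl[[dt$qname[j]]]
    rev <- bitwAnd(dt$flag[j], 16L) != 0L
    qs <- lead + 1L
    qe <- lead + read_used
    if (rev) {
      tmp <- qs
      qs <- L - qe + 1L
      qe <- L - tmp + 1L
    }
    data.table::data.table(qname = dt$qname[j], chrom = dt$chrom[j],
                           ref_start = dt$pos[j],
                           ref_end = dt$pos[j] + refw - 1L,
                           q_start = qs, q_end = qe,
                           strand = if (rev) "-" else "+",
                           score = read_used)
  })
  data.table::rbindlist(out)
}

# longest-overlap gene assignment; ties -> NA (segment dropped)
assign_gene <- function(segs, genes) {
  gr <- GenomicRanges::GRanges(segs$chrom,
                               IRanges::IRanges(segs$ref_start, segs$ref_end))
  hits <- GenomicRanges::findOverlaps(gr, genes)
  ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                  genes[S4Vectors::subjectHits(hits)])
  dt <- data.table::data.table(q = S4Vectors::queryHits(hits),
                               gene = genes$label[S4Vectors::subjectHits(hits)],
                               w = GenomicRanges::width(ov))
  lab <- rep(NA_character_, nrow(segs))
  if (nrow(dt)) {
    pick <- dt[, {
      mx <- max(w)
      g <- gene[w == mx]
      list(gene = if (length(g) == 1L) g else NA_character_)
    }, by = "q"]
    lab[pick$q] <- pick$gene
  }
  lab
}

#' 2map step: fusion candidates from split reads
#'
#' Reads whose left and right portions (each at least `min_seg` bp) locally
#' align to two different genes imply a junction inside the read. Segment
#' pairs are clustered by breakpoints within `merge_tol` bp; the reported
#' breakpoint of a cluster is the modal value. Candidates not touching a
#' user-indicated gene are discarded, as are reads split across three or
#' more loci.
#'
#' @param segments Alignment table from [align_local()].
#' @param genes GRanges with `label` column (gene intervals).
#' @param user_genes Character vector; at least one gene of a pair must be
#'   listed here.
#' @param min_seg Minimum aligned bp per side.
#' @param merge_tol Breakpoint clustering tolerance (bp).
#' @return data.table of candidates: gene_a, gene_b, bp_a, bp_b, strand_a,
#'   strand_b, split_support, qnames (list column of supporting reads).
#' @export
twomap_step <- function(segments, genes, user_genes, min_seg = 20L,
                        merge_tol = 5L) {
  if (!length(user_genes)) stop("at least one user-indicated gene is required")
  if (!nrow(segments)) return(empty_fusion_candidates())
  segs <- data.table::copy(segments)
  segs[, "gene" := assign_gene(segs, genes)]
  segs <- segs[!is.na(segs$gene)]
  counts <- table(segs$qname)
  two <- names(counts)[counts == 2L]  # 3+ loci reads dropped
  segs <- segs[segs$qname %in% two]
  if (!nrow(segs)) return(empty_fusion_candidates())
  data.table::setorderv(segs, c("qname", "q_start"))
  pairs <- segs[, {
    lef <- .SD[1]; rig <- .SD[2]
    ok <- lef$gene != rig$gene &&
      (lef$q_end - lef$q_start + 1L) >= min_seg &&
      (rig$q_end - rig$q_start + 1L) >= min_seg &&
      rig$q_start > lef$q_end - 5L  # near-disjoint read portions
    if (ok) {
      list(gene_a = lef$gene, gene_b = rig$gene,
           bp_a = if (lef$strand == "+") lef$ref_end else lef$ref_start,
           bp_b = if (rig$strand == "+") rig$ref_start else rig$ref_end,
           strand_a = lef$strand, strand_b = rig$strand)
    } else NULL
  }, by = "qname"]
  if (!nrow(pairs)) return(empty_fusion_candidates())
  pairs <- pairs[pairs$gene_a %in% user_genes | pairs$gene_b %in% user_genes]
  if (!nrow(pairs)) return(empty_fusion_candidates())
  cluster_breakpoints(pairs, merge_tol)
}

empty_fusion_candidates <- function() {
  data.table::data.table(gene_a = character(), gene_b = character(),
                         bp_a = integer(), bp_b = integer(),
                         strand_a = character(), strand_b = character(),
                         split_support = integer(), qnames = list())
}

# greedy clustering of breakpoint pairs within tolerance; modal breakpoint
cluster_breakpoints <- function(pairs, merge_tol) {
  out <- list()
  pairs[, "grp" := paste(pairs$gene_a, pairs$gene_b, pairs$strand_a,
                         pairs$strand_b)]
  for (g in unique(pairs$grp)) {
    sub <- pairs[pairs$grp == g]
    data.table::setorderv(sub, c("bp_a", "bp_b"))
    cl <- integer(nrow(sub))
    cur <- 0L
    for (j in seq_len(nrow(sub))) {
      if (j == 1L || abs(sub$bp_a[j] - sub$bp_a[j - 1L]) > merge_tol ||
          abs(sub$bp_b[j] - sub$bp_b[j - 1L]) > merge_tol) {
        cur <- cur + 1L
      }
      cl[j] <- cur
    }
    for (cc in unique(cl)) {
      s <- sub[cl == cc]
      qn <- unique(s$qname)
      out[[length(out) + 1L]] <- data.table::data.table(
        gene_a = s$gene_a[1], gene_b = s$gene_b[1],
        bp_a = modal_int(s$bp_a), bp_b = modal_int(s$bp_b),
        strand_a = s$strand_a[1], strand_b = s$strand_b[1],
        split_support = length(qn), qnames = list(qn))
    }
  }
  data.table::rbindlist(out)
}

modal_int <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Construct the virtual junction sequence for a candidate
#'
#' `flank` bp ending at the gene-A breakpoint joined to `flank` bp starting
#' at the gene-B breakpoint, with orientations respected (a `-` strand side
#' is reverse-complemented so the junction reads left-to-right). Flanks
#' exceeding contig bounds are truncated with a warning.
#'
#' @param cand One candidate row from [twomap_step()] (needs at least one
#'   supporting split read).
#' @param reference DNAStringSet.
#' @param flank Flank length in bp.
#' @return DNAString with attribute `junction` (offset of the last gene-A
#'   base within the sequence).
#' @export
build_virtual_fusion <- function(cand, reference, flank = 200L) {
  if (!cand$split_support[1] >= 1L) {
    stop("virtual fusion requires at least one supporting split read")
  }
  la <- length(reference[[cand$gene_a]])
  lb <- length(reference[[cand$gene_b]])
  if (cand$strand_a == "+") {
    s <- max(1L, cand$bp_a - flank + 1L)
    if (cand$bp_a - flank + 1L < 1L) {
      warning("gene-A flank truncated at contig start")
    }
    aside <- ref_slice(reference, cand$gene_a, s, cand$bp_a)
  } else {
    e <- min(la, cand$bp_a + flank - 1L)
    if (cand$bp_a + flank - 1L > la) warning("gene-A flank truncated")
    aside <- Biostrings::reverseComplement(
      ref_slice(reference, cand$gene_a, cand$bp_a, e))
  }
  if (cand$strand_b == "+") {
    e <- min(lb, cand$bp_b + flank - 1L)
    if (cand$bp_b + flank - 1L > lb) warning("gene-B flank truncated")
    bside <- ref_slice(reference, cand$gene_b, cand$bp_b, e)
  } else {
    s <- max(1L, cand$bp_b - flank + 1L)
    if (cand$bp_b - flank + 1L < 1L) warning("gene-B flank truncated")
    bside <- Biostrings::reverseComplement(
      ref_slice(reference, cand$gene_b, s, cand$bp_b))
  }
  vf <- Biostrings::xscat(aside, bside)
  attr(vf, "junction") <- length(aside)
  vf
}

#' Virtual-fusion rescue step
#'
#' Aligns reads not already counted by the 2map step against each
#' candidate's virtual junction sequence. A read counts when it aligns
#' nearly full-length (identity at least `identity` over the read) across
#' the junction with at least one base on each side; each read counts toward
#' at most one candidate (best identity, ties dropped).
#'
#' @param reads Named DNAStringSet of reads not assigned by 2map.
#' @param virtual_refs List of virtual junction sequences (from
#'   [build_virtual_fusion()]), one per candidate.
#' @param identity Minimum fraction of read bases matching.
#' @return Integer vector of rescued support per candidate.
#' @export
vf_step <- function(reads, virtual_refs, identity = 0.95) {
  nc <- length(virtual_refs)
  support <- integer(nc)
  if (!nc || !length(reads)) return(support)
  sm <- fusion_submat()
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    L <- length(rd)
    best <- c(cand = NA_integer_, ident = -1)
    tie <- FALSE
    for (k in seq_len(nc)) {
      vf <- virtual_refs[[k]]
      junc <- attr(vf, "junction")
      for (pat in list(rd, Biostrings::reverseComplement(rd))) {
        aln <- Biostrings::pairwiseAlignment(
          pat, vf, type = "global-local", substitutionMatrix = sm,
          gapOpening = 5, gapExtension = 2)
        ident <- Biostrings::nmatch(aln) / L
        if (ident < identity) next
        ss <- IRanges::start(Biostrings::subject(aln))
        se <- IRanges::end(Biostrings::subject(aln))
        if (!(ss <= junc && se >= junc + 1L)) next  # must cross the junction
        if (ident > best["ident"]) {
          best <- c(cand = k, ident = ident)
          tie <- FALSE
        } else if (ident == best["ident"] && !identical(k, best[["cand"]])) {
          tie <- TRUE
        }
      }
    }
    if (!is.na(best[["cand"]]) && !tie) {
      support[best[["cand"]]] <- support[best[["cand"]]] + 1L
    }
  }
  support
}

#' Discordant-pair step (paired-end mode)
#'
#' Pairs whose two mates map cleanly (unsplit) to the two genes of a
#' candidate, with both mates within `window` bp of the candidate
#' breakpoints, corroborate the junction lying between them.
#'
#' @param seg_r1,seg_r2 Alignment tables for R1 and R2 reads (qnames shared
#'   within a pair).
#' @param candidates Candidate table from [twomap_step()].
#' @param genes GRanges with `label`.
#' @param window Maximum distance (bp) from a mate to its breakpoint.
#' @return Integer vector of pair support per candidate.
#' @export
paired_end_step <- function(seg_r1, seg_r2, candidates, genes,
                            window = 1000L) {
  support <- integer(nrow(candidates))
  if (!nrow(candidates) || !nrow(seg_r1) || !nrow(seg_r2)) return(support)
  one_hit <- function(segs) {
    segs <- data.table::copy(segs)
    segs[, "gene" := assign_gene(segs, genes)]
    cnt <- table(segs$qname)
    segs[segs$qname %in% names(cnt)[cnt == 1L] & !is.na(segs$gene)]
  }
  r1 <- one_hit(seg_r1)
  r2 <- one_hit(seg_r2)
  common <- intersect(r1$qname, r2$qname)
  for (qn in common) {
    a <- r1[r1$qname == qn]
    b <- r2[r2$qname == qn]
    if (a$gene == b$gene) next
    for (k in seq_len(nrow(candidates))) {
      cd <- candidates[k]
      m <- (a$gene == cd$gene_a && b$gene == cd$gene_b) ||
        (a$gene == cd$gene_b && b$gene == cd$gene_a)
      if (!m) next
      ga <- if (a$gene == cd$gene_a) a else b
      gb <- if (a$gene == cd$gene_a) b else a
      near_a <- min(abs(c(ga$ref_start, ga$ref_end) - cd$bp_a)) <= window
      near_b <- min(abs(c(gb$ref_start, gb$ref_end) - cd$bp_b)) <= window
      if (near_a && near_b) {
        support[k] <- support[k] + 1L
        break
      }
    }
  }
  support
}

#' Rank fusion candidates
#'
#' Sorts by total support (split + rescued, plus pairs when configured) and
#' computes each candidate's S/N ratio (its support over the best other
#' candidate's, infinite when it is the only one) and normalized support
#' (support over all mapped reads).
#'
#' @param candidates Candidate table with split/vf(/pair) support columns.
#' @param mapped_read_total Total mapped reads in the run.
#' @param count_pairs Include pair support in the ranking total.
#' @return Candidate table ordered by total_support with sn_ratio and
#'   norm_support columns.
#' @export
rank_candidates <- function(candidates, mapped_read_total,
                            count_pairs = FALSE) {
  if (!nrow(candidates)) return(candidates)
  stopifnot(mapped_read_total > 0)
  tot <- candidates$split_support +
    (if ("vf_support" %in% names(candidates)) candidates$vf_support else 0L)
  if (count_pairs && "pair_support" %in% names(candidates)) {
    tot <- tot + candidates$pair_support
  }
  out <- data.table::copy(candidates)
  out[, "total_support" := as.integer(tot)]
  sn <- vapply(seq_len(nrow(out)), function(k) {
    others <- out$total_support[-k]
    if (!length(others) || max(others) == 0) Inf else
      out$total_support[k] / max(others)
  }, numeric(1))
  out[, "sn_ratio" := sn]
  out[, "norm_support" := out$total_support / mapped_read_total]
  data.table::setorderv(out, "total_support", order = -1L)
  out[]
}

#' Call gene fusions from targeted reads
#'
#' Runs the full pipeline: local alignment, 2map split-read discovery,
#' virtual-fusion rescue, optional paired-end corroboration, and ranking.
#'
#' @param reads Named DNAStringSet of read sequences (single-end mode), or a
#'   list with elements `r1` and `r2` for paired-end mode.
#' @param reference DNAStringSet.
#' @param genes GRanges with `label` (gene intervals).
#' @param user_genes Character vector of genes of interest (required).
#' @param config [default_config()] list.
#' @param engine Alignment engine passed to [align_local()].
#' @return list with `candidates` (ranked table incl. virtual_ref column),
#'   `segments` (raw alignments) and `mapped_reads`.
#' @export
call_fusions <- function(reads, reference, genes, user_genes,
                         config = default_config(), engine = "sw") {
  paired <- is.list(reads) && !is(reads, "DNAStringSet")
  if (paired) {
    r1 <- reads$r1
    r2 <- reads$r2
    all_reads <- c(r1, r2)
  } else {
    all_reads <- reads
  }
  segs <- align_local(all_reads, reference, engine = engine)
  mapped <- length(unique(segs$qname))
  cands <- twomap_step(segs, genes, user_genes,
                       min_seg = config$min_seg, merge_tol = config$merge_tol)
  if (nrow(cands)) {
    vrefs <- lapply(seq_len(nrow(cands)), function(k)
      build_virtual_fusion(cands[k], reference, flank = config$vf_flank))
    assigned <- unique(unlist(cands$qnames))
    rest <- all_reads[!names(all_reads) %in% assigned]
    cands[, "vf_support" := vf_step(rest, vrefs,
                                    identity = config$vf_identity)]
    cands[, "virtual_ref" := vapply(vrefs, as.character, character(1))]
    if (paired) {
      s1 <- segs[segs$qname %in% names(r1)]
      s2 <- segs[segs$qname %in% names(r2)]
      cands[, "pair_support" := paired_end_step(s1, s2, cands, genes,
                                                window = config$pair_window)]
    } else {
      cands[, "pair_support" := 0L]
    }
    cands <- rank_candidates(cands, max(mapped, 1L),
                             count_pairs = config$count_pairs_in_ranking)
  }
  list(candidates = cands, segments = segs, mapped_reads = mapped)
}

#' Write fusion candidates as BEDPE
#'
#' Standard BEDPE columns (0-based half-open single-base breakpoint
#' intervals) plus support counts, S/N ratio and normalized support.
#'
#' @param candidates Ranked candidate table from [call_fusions()].
#' @param path Output path.
#' @param config Config echoed into the header comment.
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(candidates, path, config = NULL) {
  hdr <- c("#chrom_a\tstart_a\tend_a\tchrom_b\tstart_b\tend_b\tname\tscore\tstrand_a\tstrand_b\tsplit\tvf\tpairs\tsn_ratio\tnorm_support")
  if (!is.null(config)) hdr <- c(paste0("##config=", config_echo(config)), hdr)
  rows <- character(0)
  if (nrow(candidates)) {
    rows <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t%s\t%s\t%d\t%d\t%d\t%s\t%.3g",
                    candidates$gene_a, candidates$bp_a - 1L, candidates$bp_a,
                    candidates$gene_b, candidates$bp_b - 1L, candidates$bp_b,
                    paste0(candidates$gene_a, "-", candidates$gene_b),
                    candidates$total_support, candidates$strand_a,
                    candidates$strand_b, candidates$split_support,
                    candidates$vf_support, candidates$pair_support,
                    format(candidates$sn_ratio, digits = 4),
                    candidates$norm_support)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
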