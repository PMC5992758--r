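# Seeded generators of FFPE-like fixtures with known ground truth. All
# randomness is confined to a supplied seed (the caller's RNG state is
# restored on exit), so identical arguments give byte-identical fixtures.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate a reference panel of genes
#'
#' Random DNA contigs (one per gene) with controllable per-gene GC content,
#' plus the matching target intervals.
#'
#' @param n_genes Number of genes/contigs.
#' @param gene_len Target interval length(s) in bp (recycled).
#' @param gc Target GC fraction(s) in (0, 1) (recycled).
#' @param seed Integer seed.
#' @param prefix Contig name prefix.
#' @param flank Off-target flank (bp) kept on each side of a gene so read
#'   coverage does not collapse at target edges, as with real capture
#'   shoulders.
#' @return list with `reference` (DNAStringSet) and `genes` (GRanges over
#'   the target interval of each contig, `label` = contig name).
#' @export
sim_reference <- function(n_genes = 10L, gene_len = 2000L, gc = 0.5,
                          seed = 1L, prefix = "gene", flank = 200L) {
  if (n_genes == 0L) {
    warning("n_genes = 0: empty reference")
    return(list(reference = Biostrings::DNAStringSet(),
                genes = GenomicRanges::GRanges()))
  }
  gene_len <- rep_len(as.integer(gene_len), n_genes)
  gc <- rep_len(gc, n_genes)
  flank <- as.integer(flank)
  seqs <- with_seed(seed, {
    vapply(seq_len(n_genes), function(i) {
      p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
      paste(sample(c("A", "C", "G", "T"), gene_len[i] + 2L * flank,
                   replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- paste0(prefix, seq_len(n_genes))
  genes <- GenomicRanges::GRanges(names(ref),
                                  IRanges::IRanges(flank + 1L,
                                                   flank + gene_len))
  genes$label <- names(ref)
  list(reference = ref, genes = genes)
}

#' Write targets as a BED file
#' @param targets GRanges (1-based closed); written 0-based half-open.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(targets, path) {
  lab <- if (!is.null(targets$label)) targets$label else "."
  writeLines(sprintf("%s\t%d\t%d\t%s",
                     as.character(GenomicRanges::seqnames(targets)),
                     GenomicRanges::start(targets) - 1L,
                     GenomicRanges::end(targets), lab), path)
  invisible(path)
}

#' Plant a set of heterozygous somatic variants
#'
#' Draws distinct positions across the targets and assigns SNV alleles
#' (optionally some short indels), each with a cell-level allele fraction
#' (0.5 for a heterozygous variant in a diploid tumor cell).
#'
#' @param reference DNAStringSet.
#' @param targets GRanges.
#' @param n Number of variants.
#' @param seed Integer seed.
#' @param allele_fraction Cell-level allele fraction (default heterozygous).
#' @param indel_frac Fraction of variants planted as 1-3 bp indels.
#' @param min_spacing Minimum bp between planted variants.
#' @return data.table: chrom, pos, ref, alt, af.
#' @export
sim_variant_truth <- function(reference, targets, n = 50L, seed = 1L,
                              allele_fraction = 0.5, indel_frac = 0,
                              min_spacing = 50L) {
  tg <- data.frame(chrom = as.character(GenomicRanges::seqnames(targets)),
                   start = GenomicRanges::start(targets),
                   end = GenomicRanges::end(targets))
  with_seed(seed, {
    picked <- list()
    guard <- 0L
    while (length(picked) < n && guard < 50L * n) {
      guard <- guard + 1L
      i <- sample.int(nrow(tg), 1)
      # stay clear of target edges so full-depth reads cover the site
      lo <- tg$start[i] + 10L
      hi <- tg$end[i] - 10L
      if (hi <= lo) next
      pos <- sample(lo:hi, 1)
      clash <- any(vapply(picked, function(v)
        v$chrom == tg$chrom[i] && abs(v$pos - pos) < min_spacing,
        logical(1)))
      if (clash) next
      refb <- as.character(ref_slice(reference, tg$chrom[i], pos, pos))
      if (!refb %in% c("A", "C", "G", "T")) next
      if (runif(1) < indel_frac) {
        # key indels at their left-aligned position so truth matches calls
        chrom_seq <- reference[[tg$chrom[i]]]
        L <- sample(1:3, 1)
        if (runif(1) < 0.5) {
          ins <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = "")
          la <- left_align_ins(chrom_seq, pos, ins)
          pos <- la$pos
          alt <- paste0("ins:", la$seq)
        } else {
          if (pos + L > tg$end[i]) next
          pos <- left_align_del(chrom_seq, pos, L)
          alt <- paste0("del:", L)
        }
        if (pos < tg$start[i]) next
        refb <- as.character(ref_slice(reference, tg$chrom[i], pos, pos))
      } else {
        alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      }
      picked[[length(picked) + 1L]] <- data.table::data.table(
        chrom = tg$chrom[i], pos = pos, ref = refb, alt = alt,
        af = allele_fraction)
    }
    data.table::rbindlist(picked)
  })
}

#' Simulate targeted capture reads for one sample
#'
#' Uniform read starts per target to a requested mean depth; planted
#' variants appear on a read with probability `purity * af`; FFPE-like
#' damage adds strand-asymmetric C>T substitutions enriched near read ends;
#' independent per-base sequencing error is applied everywhere. With
#' `ffpe_rate = 0` and no variants the sample is a clean control.
#'
#' @param reference DNAStringSet.
#' @param targets GRanges.
#' @param variants Truth table from [sim_variant_truth()], or `NULL`.
#' @param purity Tumor cell fraction scaling planted allele fractions.
#' @param depth Target mean depth.
#' @param read_len Read length (bp).
#' @param error_rate Per-base substitution error rate.
#' @param ffpe_rate Per-base proposal rate of C>T damage (realised rate is
#'   thinned by base composition).
#' @param ffpe_strand_frac Fraction of damage events landing on
#'   forward-orientation reads (strand asymmetry).
#' @param ffpe_end_mult Damage enrichment multiplier within `ffpe_end_bp` of
#'   a read end.
#' @param ffpe_end_bp Terminal window for damage enrichment.
#' @param baseq Constant Phred base quality written to reads.
#' @param mapq Mapping quality written to reads.
#' @param seed Integer seed.
#' @param sample Read-name prefix.
#' @return A read table ([as_reads()]).
#' @export
sim_snv_reads <- function(reference, targets, variants = NULL, purity = 1,
                          depth = 970, read_len = 150L, error_rate = 1e-3,
                          ffpe_rate = 0, ffpe_strand_frac = 0.85,
                          ffpe_end_mult = 3, ffpe_end_bp = 5L, baseq = 30L,
                          mapq = 60L, seed = 1L, sample = "s") {
  stopifnot(purity >= 0, purity <= 1)
  tg <- data.frame(chrom = as.character(GenomicRanges::seqnames(targets)),
                   start = GenomicRanges::start(targets),
                   end = GenomicRanges::end(targets))
  if (depth <= 0) {
    return(as_reads(data.frame(qname = character(), flag = integer(),
                               chrom = character(), pos = integer(),
                               mapq = integer(), cigar = character(),
                               seq = character(), qual = character())))
  }
  with_seed(seed, {
    out <- vector("list", nrow(tg))
    for (i in seq_len(nrow(tg))) {
      chr <- tg$chrom[i]
      clen <- Biostrings::width(reference)[names(reference) == chr]
      lo <- max(1L, tg$start[i] - read_len + 1L)
      hi <- max(min(tg$end[i], clen - read_len + 1L), lo)
      # uniform starts over [lo, hi] give ~`depth` coverage inside the target
      n_reads <- round(depth * (hi - lo + 1L) / read_len)
      if (n_reads == 0) next
      starts <- sample(lo:hi, n_reads, replace = TRUE)
      revs <- runif(n_reads) < 0.5
      seqs <- as.character(Biostrings::extractAt(
        reference[[chr]], IRanges::IRanges(starts, width = read_len)))
      cigars <- rep(paste0(read_len, "M"), n_reads)

      vv <- if (is.null(variants)) NULL else
        variants[variants$chrom == chr &
                 variants$pos >= lo & variants$pos <= tg$end[i]]
      if (!is.null(vv) && nrow(vv)) {
        for (v in seq_len(nrow(vv))) {
          off <- vv$pos[v] - starts + 1L
          over <- off >= 1L & off <= read_len
          carrier <- over & runif(n_reads) < purity * vv$af[v]
          idx <- which(carrier)
          if (!length(idx)) next
          if (grepl("^ins:", vv$alt[v])) {
            insseq <- sub("^ins:", "", vv$alt[v])
            L <- nchar(insseq)
            for (r in idx) {
              o <- off[r]
              if (o >= read_len) next
              keep <- read_len - o - L
              if (keep < 1) next
              seqs[r] <- paste0(substr(seqs[r], 1, o), insseq,
                                substr(seqs[r], o + 1L, o + keep))
              cigars[r] <- paste0(o, "M", L, "I", keep, "M")
            }
          } else if (grepl("^del:", vv$alt[v])) {
            L <- as.integer(sub("^del:", "", vv$alt[v]))
            for (r in idx) {
              o <- off[r]
              if (o >= read_len) next
              tail_len <- read_len - o
              tail_seq <- as.character(ref_slice(
                reference, chr, vv$pos[v] + L + 1L,
                vv$pos[v] + L + tail_len, truncate = TRUE))
              if (nchar(tail_seq) < tail_len) next
              seqs[r] <- paste0(substr(seqs[r], 1, o), tail_seq)
              cigars[r] <- paste0(o, "M", L, "D", tail_len, "M")
            }
          } else {
            substr(seqs[idx], off[idx], off[idx]) <- vv$alt[v]
          }
        }
      }

      # FFPE-like damage: proposal positions end-weighted, accepted at
      # reference C bases only, with strand asymmetry
      if (ffpe_rate > 0) {
        rate <- ifelse(revs, 2 * ffpe_rate * (1 - ffpe_strand_frac),
                       2 * ffpe_rate * ffpe_strand_frac)
        wts <- rep(1, read_len)
        endw <- c(seq_len(ffpe_end_bp), read_len - ffpe_end_bp +
                    seq_len(ffpe_end_bp))
        wts[endw] <- ffpe_end_mult
        n_dam <- rbinom(n_reads, read_len, pmin(rate, 1))
        for (r in which(n_dam > 0)) {
          ps <- sample.int(read_len, n_dam[r], prob = wts)
          for (p in ps) {
            if (substr(seqs[r], p, p) == "C") {
              substr(seqs[r], p, p) <- "T"
            }
          }
        }
      }

      # uniform sequencing error
      if (error_rate > 0) {
        n_err <- rbinom(n_reads, read_len, error_rate)
        mx <- max(n_err)
        r_err <- which(n_err > 0)
        for (round in seq_len(max(mx, 0L))) {
          sel <- r_err[n_err[r_err] >= round]
          if (!length(sel)) break
          ps <- sample.int(read_len, length(sel), replace = TRUE)
          cur <- substr(seqs[sel], ps, ps)
          alt <- vapply(cur, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
            USE.NAMES = FALSE)
          substr(seqs[sel], ps, ps) <- alt
        }
      }

      out[[i]] <- data.frame(
        qname = sprintf("%s_%d_%06d", sample, i, seq_len(n_reads)),
        flag = ifelse(revs, 16L, 0L), chrom = chr, pos = starts,
        mapq = mapq, cigar = cigars, seq = seqs,
        qual = strrep(rawToChar(as.raw(33L + baseq)), nchar(seqs)))
    }
    as_reads(do.call(rbind, out[!vapply(out, is.null, logical(1))]))
  })
}

#' Simulate fusion-spanning reads
#'
#' Chimeric reads across a defined junction (split position uniform along
#' the read), optional per-read junction jitter, scattered random-gene-pair
#' noise chimeras, and plain background reads from the panel genes.
#'
#' @param reference DNAStringSet (from [sim_reference()]).
#' @param gene_a,gene_b Contig names of the fused genes.
#' @param bp_a 1-based position of the last gene-A base before the junction.
#' @param bp_b 1-based position of the first gene-B base after the junction.
#' @param n_support Number of true junction-spanning reads.
#' @param read_len Read length (bp).
#' @param junction_jitter Maximum ± bp shift of the junction per read.
#' @param noise_chimeras Number of random-gene-pair noise reads.
#' @param n_background Plain (non-chimeric) reads drawn uniformly from the
#'   genes.
#' @param min_split Minimum bases on each side of the junction per read.
#' @param seed Integer seed.
#' @return list with `reads` (named DNAStringSet), `truth` (list of planted
#'   junction coordinates) and `n_total` (total simulated reads).
#' @export
sim_fusion_reads <- function(reference, gene_a, gene_b, bp_a, bp_b,
                             n_support = 20L, read_len = 150L,
                             junction_jitter = 0L, noise_chimeras = 0L,
                             n_background = 200L, min_split = 30L,
                             seed = 1L) {
  with_seed(seed, {
    seqs <- character(0)
    nms <- character(0)
    if (n_support > 0) {
      split_at <- sample(min_split:(read_len - min_split), n_support,
                         replace = TRUE)
      jit <- if (junction_jitter > 0) {
        sample(seq(-junction_jitter, junction_jitter), n_support,
               replace = TRUE)
      } else rep(0L, n_support)
      for (r in seq_len(n_support)) {
        ja <- bp_a + jit[r]
        left <- as.character(ref_slice(reference, gene_a,
                                       ja - split_at[r] + 1L, ja))
        right <- as.character(ref_slice(reference, gene_b, bp_b,
                                        bp_b + (read_len - split_at[r]) - 1L))
        seqs <- c(seqs, paste0(left, right))
        nms <- c(nms, sprintf("fus_%04d", r))
      }
    }
    if (noise_chimeras > 0) {
      gn <- names(reference)
      for (r in seq_len(noise_chimeras)) {
        pair <- sample(gn, 2)
        w <- Biostrings::width(reference)[match(pair, gn)]
        s <- sample(min_split:(read_len - min_split), 1)
        pa <- sample(seq(s, w[1] - 1L), 1)
        pb <- sample(seq(1L, w[2] - (read_len - s)), 1)
        left <- as.character(ref_slice(reference, pair[1], pa - s + 1L, pa))
        right <- as.character(ref_slice(reference, pair[2], pb,
                                        pb + (read_len - s) - 1L))
        seqs <- c(seqs, paste0(left, right))
        nms <- c(nms, sprintf("noise_%04d", r))
      }
    }
    if (n_background > 0) {
      gn <- sample(names(reference), n_background, replace = TRUE)
      w <- Biostrings::width(reference)[match(gn, names(reference))]
      st <- vapply(w, function(wi) sample.int(max(wi - read_len + 1L, 1L), 1),
                   integer(1))
      for (r in seq_len(n_background)) {
        seqs <- c(seqs, as.character(ref_slice(reference, gn[r], st[r],
                                               st[r] + read_len - 1L,
                                               truncate = TRUE)))
        nms <- c(nms, sprintf("bg_%05d", r))
      }
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- nms
    list(reads = reads,
         truth = list(gene_a = gene_a, gene_b = gene_b, bp_a = bp_a,
                      bp_b = bp_b, n_support = n_support),
         n_total = length(reads))
  })
}

#' Simulate tumor/control binned depth profiles
#'
#' Piecewise-constant copy-number truth on a tiled bin grid: control depth is
#' Poisson around `base_depth`, tumor depth is Poisson around
#' `base_depth * 2^logR`, both optionally scaled by a linear GC bias
#' `1 + gc_bias * (gc - 0.5)`.
#'
#' @param n_bins Number of bins.
#' @param segments data.frame with `start_bin`, `end_bin`, `logr` tiling
#'   1..n_bins; default one neutral segment.
#' @param base_depth Mean control depth per bin.
#' @param gc_bias Linear GC bias coefficient (0 = none).
#' @param bias_both Apply the GC bias to both samples (TRUE) or tumor only.
#' @param bin_size Bin width in bp (coordinates only).
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return list with `tumor` and `control` bin tables (chrom, start, end,
#'   gc, raw_depth) and `truth` (the segment table).
#' @export
sim_depth_profile <- function(n_bins = 500L, segments = NULL,
                              base_depth = 100, gc_bias = 0,
                              bias_both = TRUE, bin_size = 100L,
                              chrom = "chr1", seed = 1L) {
  if (is.null(segments)) {
    segments <- data.frame(start_bin = 1L, end_bin = n_bins, logr = 0)
  }
  stopifnot(segments$start_bin[1] == 1L,
            segments$end_bin[nrow(segments)] == n_bins)
  with_seed(seed, {
    logr <- rep(segments$logr, segments$end_bin - segments$start_bin + 1L)
    gc <- runif(n_bins, 0.3, 0.7)
    bias <- 1 + gc_bias * (gc - 0.5)
    ctl_mu <- base_depth * (if (bias_both) bias else 1)
    tum_mu <- base_depth * 2^logr * bias
    start <- (seq_len(n_bins) - 1L) * bin_size + 1L
    mk <- function(mu) data.table::data.table(
      chrom = chrom, start = start, end = start + bin_size - 1L, gc = gc,
      raw_depth = rpois(n_bins, mu))
    list(tumor = mk(tum_mu), control = mk(ctl_mu), truth = segments)
  })
}
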