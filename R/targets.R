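#' Load capture-target intervals from a BED file
#'
#' Reads a 3+ column BED file (0-based half-open, the BED convention),
#' validates it, converts to 1-based closed coordinates, sorts by
#' (chrom, start) and merges overlapping or bookended same-chromosome
#' intervals. Labels (column 4, if present) of merged intervals are joined
#' with `","`.
#'
#' @param path Path to a BED file with at least chrom, start, end columns.
#' @return A [GenomicRanges::GRanges] with optional `label` metadata column
#'   and an attribute `target_bp` giving the merged total target size in bp
#'   (also available via [target_size()]).
#' @export
load_targets <- function(path) {
  if (!file.exists(path)) stop("target BED not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no intervals in BED: ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3)) {
    stop("malformed BED line ", idx[which(n_col < 3)[1]],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start0) | is.na(end0) | start0 < 0)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1]], ": non-numeric or negative coordinate")
  }
  empty <- which(end0 <= start0)
  if (length(empty)) {
    stop("invalid BED line ", idx[empty[1]], ": end <= start")
  }
  label <- ifelse(n_col >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA_character_)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  gr$label <- label
  merge_targets(gr)
}

# sort + merge a labelled GRanges; label of a merged run = joined labels
merge_targets <- function(gr) {
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  if (!is.null(gr$label)) {
    red$label <- vapply(red$revmap, function(i) {
      labs <- unique(gr$label[i])
      labs <- labs[!is.na(labs)]
      if (!length(labs)) NA_character_ else paste(labs, collapse = ",")
    }, character(1))
  }
  red$revmap <- NULL
  attr(red, "target_bp") <- sum(GenomicRanges::width(red))
  red
}

#' Total merged target size in bp
#' @param targets GRanges from [load_targets()] (or any GRanges).
#' @return Integer, total bp covered after merging overlaps.
#' @export
target_size <- function(targets) {
  sum(GenomicRanges::width(GenomicRanges::reduce(targets)))
}

#' Load a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' GC fraction of a region
#'
#' (G + C) / (A + C + G + T) over the region; ambiguous bases are excluded
#' from the denominator. An all-ambiguous region returns `NA` (the caller
#' masks such bins).
#'
#' @param reference A DNAStringSet (or single DNAString with `chrom` ignored).
#' @param chrom Contig name.
#' @param start,end 1-based closed coordinates.
#' @return GC fraction in \[0, 1\], or `NA_real_` when no unambiguous base.
#' @export
compute_gc <- function(reference, chrom, start, end) {
  seq <- ref_slice(reference, chrom, start, end)
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) return(NA_real_)
  unname((f[["G"]] + f[["C"]]) / denom)
}

# bounds-checked reference slice, 1-based closed
ref_slice <- function(reference, chrom, start, end, truncate = FALSE) {
  if (is(reference, "DNAStringSet")) {
    if (!chrom %in% names(reference)) stop("contig not in reference: ", chrom)
    seq <- reference[[chrom]]
  } else {
    seq <- reference
  }
  if (truncate) {
    start <- max(1L, start)
    end <- min(length(seq), end)
  }
  if (start < 1L || end > length(seq) || start > end) {
    stop("region ", chrom, ":", start, "-", end, " outside contig bounds (1-",
         length(seq), ")")
  }
  Biostrings::subseq(seq, start, end)
}
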