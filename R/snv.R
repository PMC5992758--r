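# SNV/indel calling: Fisher-exact extraction of tumor-vs-control candidates
# followed by the noise-filter cascade (set 1: per-site filters; set 2:
# second Fisher after read cleaning; set 3: VAF-lees) and the germline
# VAF-band filter. No hard VAF cutoff is applied anywhere.

#' Run the noise-filter cascade on extracted candidates
#'
#' Assembles per-candidate read-level context from the pileups and runs
#' every noise filter, recording all verdicts. The candidate status is PASS
#' or the name of the first failing filter in cascade order
#' ([noise_filters()] then germline).
#'
#' @param cands Candidate table from [fisher_extract()].
#' @param pp_t,pp_c Tumor and control `pileup` objects.
#' @param reference DNAStringSet.
#' @param config [default_config()] list.
#' @param snp_sites Optional SNP table for the germline filter.
#' @return list with `candidates` (cands plus p_fisher2, lees_p, status) and
#'   `verdicts` (long table: candidate index, filter, passed, statistic,
#'   threshold, detail) and `model` (the fitted beta mixture or NULL).
#' @export
run_noise_filters <- function(cands, pp_t, pp_c, reference,
                              config = default_config(), snp_sites = NULL) {
  filters <- noise_filters(config$platform)
  n <- nrow(cands)
  if (!n) {
    empty_v <- data.table::data.table(
      cand = integer(0), filter = character(0), passed = logical(0),
      statistic = numeric(0), threshold = numeric(0), detail = character(0))
    out <- data.table::copy(cands)
    out[, c("p_fisher2", "lees_p", "status") :=
          list(numeric(0), numeric(0), character(0))]
    return(list(candidates = out[], verdicts = empty_v, model = NULL))
  }

  # sample-wide noisy-position rate: the internal control for the dust filter
  dustbg <- dust_noisy_sites(pp_t, cands, config)
  verd <- vector("list", n)
  p2 <- rep(NA_real_, n)
  cand_key <- paste(cands$chrom, cands$pos)

  for (k in seq_len(n)) {
    cd <- cands[k]
    is_indel <- grepl("^(ins|del):", cd$alt)
    ctx_t <- site_read_calls(pp_t, cd$chrom, cd$pos)
    ctx_c <- site_read_calls(pp_c, cd$chrom, cd$pos)
    supp <- supports(ctx_t, cd, is_indel)
    refcall <- !is.na(ctx_t$base) & ctx_t$base == cd$ref & !ctx_t$masked &
      ctx_t$indel == ""
    al <- pp_t$alleles[list(cd$chrom, cd$pos), nomatch = NULL]
    arow <- al[al$allele == cd$alt]
    rrow <- al[al$allele == cd$ref]
    site <- pp_t$sites[list(cd$chrom, cd$pos), nomatch = NULL]

    v <- list()
    supp_extra <- pmax(ctx_t$n_mism[supp] - (if (is_indel) 0L else 1L), 0L)
    v$misalignment <- filter_misalignment(
      supp_extra, ctx_t$n_mism[!supp & !is.na(ctx_t$base)],
      alpha = config$alpha_misalign)
    v$strand_bias <- filter_strand_bias(
      sum(arow$fwd), sum(arow$rev), sum(rrow$fwd), sum(rrow$rev),
      alpha = config$alpha_strand)
    v$homopolymer <- filter_homopolymer(reference, cd$chrom, cd$pos,
                                        run_len = config$homopolymer_len)
    v$mq0 <- filter_mq0(site$mq0, site$depth, frac = config$mq0_frac)
    v$read_end <- filter_read_end(ctx_t$dist_end[supp],
                                  ctx_t$dist_end[refcall],
                                  end_bp = config$read_end_bp,
                                  alpha = config$alpha_read_end)
    win <- dustbg$sites[dustbg$sites$chrom == cd$chrom &
                       abs(dustbg$sites$pos - cd$pos) <= config$dust_window &
                       dustbg$sites$pos != cd$pos]
    win <- win[!paste(win$chrom, win$pos) %in% cand_key]
    v$dust <- filter_dust(sum(win$noisy), nrow(win), dustbg$bg_rate,
                          alpha = config$alpha_dust)
    if (config$platform == "ion") {
      bq <- bq_flanks(pp_t, ctx_t, supp)
      v$bq_drop <- filter_bq_drop(config$platform, is_indel, bq["up"],
                                  bq["down"], delta = config$bq_drop_delta)
    }
    v$second_fisher <- second_fisher(
      cd, ctx_t, ctx_c, trim_bp = config$trim_bp,
      mismatch_quantile = config$mismatch_quantile,
      alpha_extract = config$alpha_extract)
    p2[k] <- v$second_fisher$statistic
    verd[[k]] <- data.table::rbindlist(v)
  }

  # set 3: fit the VAF mixture on candidates still alive after sets 1-2
  alive <- vapply(verd, function(vd) all(vd$passed), logical(1))
  model <- fit_beta_mixture(cands$vaf[alive], k_max = config$lees_kmax,
                            restarts = config$lees_restarts,
                            seed = config$seed, min_n = config$lees_min_n,
                            band = config$lees_band)
  lees <- vaf_lees_filter(cands, model, alpha_lees = config$alpha_lees)
  germ <- germline_filter(cands, snp_sites, bands = config$germline_bands)

  long <- data.table::rbindlist(lapply(seq_len(n), function(k)
    cbind(data.table::data.table(cand = k),
          rbind(verd[[k]], lees[k], germ[k]))))
  order_names <- c(filters, "germline")
  status <- vapply(seq_len(n), function(k) {
    vd <- long[long$cand == k]
    vd <- vd[match(order_names, vd$filter)]
    fail <- which(!vd$passed)
    if (!length(fail)) "PASS" else vd$filter[fail[1]]
  }, character(1))

  out <- data.table::copy(cands)
  out[, "p_fisher2" := p2]
  out[, "lees_p" := lees$statistic]
  out[, "status" := status]
  list(candidates = out[], verdicts = long, model = model)
}

# positions carrying low-VAF non-reference noise, and the panel-wide rate
dust_noisy_sites <- function(pp, cands, config) {
  al <- merge(pp$alleles, pp$sites[, c("chrom", "pos", "ref", "depth")],
              by = c("chrom", "pos"))
  alt <- al[al$allele != al$ref]
  alt[, "cnt" := alt$fwd + alt$rev]
  noisy_pos <- alt[alt$cnt >= config$dust_min_count &
                   alt$cnt / pmax(alt$depth, 1L) >= config$dust_min_vaf,
                   c("chrom", "pos")]
  key <- paste(noisy_pos$chrom, noisy_pos$pos)
  sites <- pp$sites[, c("chrom", "pos")]
  sites <- data.table::copy(sites)
  sites[, "noisy" := paste(sites$chrom, sites$pos) %in% unique(key)]
  non_cand <- !paste(sites$chrom, sites$pos) %in%
    paste(cands$chrom, cands$pos)
  bg_rate <- (sum(sites$noisy[non_cand]) + 0.5) / (sum(non_cand) + 1)
  list(sites = sites, bg_rate = bg_rate)
}

# mean base quality up/downstream of the event on supporting reads
bq_flanks <- function(pp, ctx, supp) {
  idx <- which(supp & !is.na(ctx$off))
  up <- numeric(0); down <- numeric(0)
  for (j in idx) {
    row <- pp$reads[pp$reads$qname == ctx$qname[j]]
    if (!nrow(row)) next
    q <- qual_ints(row$qual[1])
    o <- ctx$off[j]
    if (o >= 1L) up <- c(up, q[seq_len(o)])
    if (o < length(q)) down <- c(down, q[(o + 1L):length(q)])
  }
  c(up = if (length(up)) mean(up) else NA_real_,
    down = if (length(down)) mean(down) else NA_real_)
}

#' Call somatic SNVs and indels
#'
#' Full pipeline: prep filters, pileups over the targets, Fisher-exact
#' candidate extraction, the noise-filter cascade, and the germline filter.
#' The cascade order and count follow the platform (eight noise filters for
#' Illumina, nine for Ion).
#'
#' @param tumor_reads,control_reads Read tables (or SAM paths).
#' @param targets GRanges of capture targets.
#' @param reference DNAStringSet.
#' @param config [default_config()] list.
#' @param snp_sites Optional SNP table (see [read_snp_vcf()]).
#' @return list with `candidates`, `verdicts`, `model`, `config`,
#'   `target_bp`.
#' @export
call_snvs <- function(tumor_reads, control_reads, targets, reference,
                      config = default_config(), snp_sites = NULL) {
  if (is.character(tumor_reads)) tumor_reads <- read_sam(tumor_reads)
  if (is.character(control_reads)) control_reads <- read_sam(control_reads)
  prep_t <- prep_filter(tumor_reads, config$min_mapq, config$min_baseq,
                        config$drop_duplicates)
  prep_c <- prep_filter(control_reads, config$min_mapq, config$min_baseq,
                        config$drop_duplicates)
  pp_t <- build_pileups(prep_t, targets, reference, config$max_indel_len)
  pp_c <- build_pileups(prep_c, targets, reference, config$max_indel_len)
  cands <- fisher_extract(pp_t, pp_c, alpha_extract = config$alpha_extract,
                          min_alt = config$min_alt)
  res <- run_noise_filters(cands, pp_t, pp_c, reference, config, snp_sites)
  res$config <- config
  res$target_bp <- target_size(targets)
  res
}

#' Write calls as VCF v4.2
#'
#' One record per candidate (1-based anchor-base convention for indels);
#' FILTER holds PASS or the first failing filter, INFO carries the counts,
#' VAF, both Fisher p-values, the lees tail p and a compact verdict string.
#'
#' @param result Output of [call_snvs()].
#' @param reference DNAStringSet for contig header lines and indel anchors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(result, reference, path) {
  cands <- result$candidates
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=panelcall_", as.character(utils::packageVersion("panelcall"))),
    paste0("##config=", config_echo(result$config)),
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            Biostrings::width(reference)),
    "##INFO=<ID=TAC,Number=1,Type=Integer,Description=\"Tumor alt count\">",
    "##INFO=<ID=TRC,Number=1,Type=Integer,Description=\"Tumor ref count\">",
    "##INFO=<ID=CAC,Number=1,Type=Integer,Description=\"Control alt count\">",
    "##INFO=<ID=CRC,Number=1,Type=Integer,Description=\"Control ref count\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=PF1,Number=1,Type=Float,Description=\"Fisher p, extraction\">",
    "##INFO=<ID=PF2,Number=1,Type=Float,Description=\"Fisher p after read cleaning\">",
    "##INFO=<ID=LEES_P,Number=1,Type=Float,Description=\"Beta-binomial tail p vs error component\">",
    "##INFO=<ID=VERDICTS,Number=1,Type=String,Description=\"filter:pass flags\">",
    paste0("##FILTER=<ID=", unique(c(noise_filters(result$config$platform),
                                     "germline")),
           ",Description=\"noise filter\">", collapse = "\n"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(cands)) {
    vstr <- vapply(seq_len(nrow(cands)), function(k) {
      vd <- result$verdicts[result$verdicts$cand == k]
      paste(paste0(vd$filter, ":", ifelse(vd$passed, "1", "0")),
            collapse = "|")
    }, character(1))
    refalt <- vcf_ref_alt(cands, reference)
    rows <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\tTAC=%d;TRC=%d;CAC=%d;CRC=%d;VAF=%.4g;PF1=%.4g;PF2=%s;LEES_P=%s;VERDICTS=%s",
      cands$chrom, refalt$pos, refalt$ref, refalt$alt, cands$status,
      cands$tumor_alt, cands$tumor_ref, cands$control_alt,
      cands$control_ref, cands$vaf, cands$p_fisher,
      ifelse(is.na(cands$p_fisher2), ".", sprintf("%.4g", cands$p_fisher2)),
      ifelse(is.na(cands$lees_p), ".", sprintf("%.4g", cands$lees_p)),
      vstr)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# internal allele keys -> VCF REF/ALT with anchor bases for indels
vcf_ref_alt <- function(cands, reference) {
  pos <- cands$pos
  ref <- cands$ref
  alt <- cands$alt
  out_ref <- ref
  out_alt <- alt
  for (k in seq_len(nrow(cands))) {
    if (startsWith(alt[k], "ins:")) {
      out_ref[k] <- ref[k]
      out_alt[k] <- paste0(ref[k], sub("^ins:", "", alt[k]))
    } else if (startsWith(alt[k], "del:")) {
      L <- as.integer(sub("^del:", "", alt[k]))
      deleted <- as.character(ref_slice(reference, cands$chrom[k],
                                        pos[k] + 1L, pos[k] + L))
      out_ref[k] <- paste0(ref[k], deleted)
      out_alt[k] <- ref[k]
    }
  }
  list(pos = pos, ref = out_ref, alt = out_alt)
}
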