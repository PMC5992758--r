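#' Default run configuration
#'
#' Returns the full set of tunable parameters used by the callers, as a named
#' list. Every value can be overridden either programmatically
#' (`default_config(min_mapq = 30)`), or from a `key = value` text file via
#' [read_config()]. All thresholds are echoed into output headers so a run is
#' reproducible from its artifacts alone.
#'
#' Parameter groups:
#' \describe{
#'   \item{prep}{`min_mapq`, `min_baseq` (Phred): read / base admission into
#'     pileups; `drop_duplicates`: drop flagged duplicate reads;
#'     `max_indel_len`: longest indel allele tracked (bp).}
#'   \item{extraction}{`alpha_extract`: one-sided Fisher p cutoff for
#'     emitting a candidate; `min_alt`: minimum tumor alt reads.}
#'   \item{noise filters}{`alpha_strand`, `alpha_misalign`, `alpha_read_end`,
#'     `alpha_dust`: per-filter test cutoffs; `homopolymer_len` (inclusive);
#'     `mq0_frac` (strict >); `read_end_bp`: terminal window treated as a read
#'     end; `dust_window`: half-width in bp; `dust_min_vaf`, `dust_min_count`:
#'     what counts as a noisy neighbouring position; `trim_bp`: terminal bases
#'     trimmed in the second Fisher pass; `mismatch_quantile`: internal-control
#'     quantile above which a read is discarded as erroneous; `bq_drop_delta`:
#'     mean base-quality drop flagging an abnormal profile (Ion indels).}
#'   \item{VAF mixture}{`lees_kmax`, `lees_restarts`, `lees_min_n`,
#'     `lees_band` (low-VAF band locating the error component),
#'     `alpha_lees`: beta-binomial upper-tail cutoff below which a call is
#'     declared to exceed the error component.}
#'   \item{germline}{`germline_bands`: VAF intervals removed as likely
#'     germline (list of `c(lo, hi)`, closed unless noted).}
#'   \item{copy number}{`bin_size`, `lowess_span`, `min_gc_bins`,
#'     `cbs_window`, `cbs_nperm`, `alpha_seg`, `cbs_min_width`,
#'     `abort_delta`, `abort_frac`, `n_boot`, `amp_logr`, `del_logr`,
#'     `boot_conf`.}
#'   \item{fusion}{`min_seg`, `merge_tol`, `vf_flank`, `vf_identity`,
#'     `pair_window`, `count_pairs_in_ranking`.}
#' }
#'
#' @param ... name = value overrides of any default.
#' @return Named list of parameters with class `panelcall_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # prep filters
    min_mapq = 20L,
    min_baseq = 20L,
    drop_duplicates = TRUE,
    max_indel_len = 10L,
    # extraction
    alpha_extract = 1e-4,
    min_alt = 3L,
    # noise filters
    alpha_strand = 1e-3,
    alpha_misalign = 1e-3,
    alpha_read_end = 1e-3,
    alpha_dust = 1e-3,
    homopolymer_len = 8L,
    mq0_frac = 0.1,
    read_end_bp = 5L,
    dust_window = 10L,
    dust_min_vaf = 0.02,
    dust_min_count = 2L,
    trim_bp = 5L,
    mismatch_quantile = 0.995,
    bq_drop_delta = 10,
    platform = "illumina",
    # VAF-lees beta mixture
    lees_kmax = 10L,
    lees_restarts = 5L,
    lees_min_n = 20L,
    lees_band = c(0.01, 0.03),
    alpha_lees = 0.05,
    # germline
    germline_bands = list(c(0.40, 0.60), c(0.96, 1.0)),
    # copy number
    bin_size = 100L,
    lowess_span = 2 / 3,
    min_gc_bins = 50L,
    cbs_window = 500L,
    cbs_nperm = 1000L,
    alpha_seg = 0.01,
    cbs_min_width = 3L,
    abort_delta = 0.5,
    abort_frac = 0.3,
    n_boot = 1000L,
    amp_logr = 0.8,
    del_logr = -0.8,
    boot_conf = 0.95,
    # fusion
    min_seg = 20L,
    merge_tol = 5L,
    vf_flank = 200L,
    vf_identity = 0.95,
    pair_window = 1000L,
    count_pairs_in_ranking = FALSE,
    # global
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "panelcall_config"
  cfg
}

#' Read configuration overrides from a key = value file
#'
#' Lines are `key = value`; blank lines and `#` comments ignored. Values are
#' parsed as R literals where possible (numbers, TRUE/FALSE), otherwise kept
#' as strings. Unknown keys are an error.
#'
#' @param path Path to a config text file.
#' @param base Config to override; defaults to [default_config()].
#' @return A `panelcall_config` list.
#' @export
read_config <- function(path, base = default_config()) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln)
    key <- kv[2]
    if (!key %in% names(base)) stop("unknown configuration key: ", key)
    val <- type.convert(kv[3], as.is = TRUE)
    base[[key]] <- val
  }
  base
}

# one-line `key=value;...` echo of a config for output headers
config_echo <- function(cfg) {
  flat <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.list(v)) v <- unlist(v)
    paste0(k, "=", paste(format(v, trim = TRUE), collapse = ","))
  }, character(1))
  paste(flat, collapse = ";")
}
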