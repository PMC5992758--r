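# Independent oracles, deliberately built on different machinery than the
# implementation (explicit log-factorial enumeration rather than phyper;
# recursive probability ratios rather than lchoose/lbeta summation).

# one-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins
oracle_fisher <- function(t_alt, t_ref, c_alt, c_ref) {
  m1 <- t_alt + c_alt          # alt margin
  m2 <- t_ref + c_ref          # ref margin
  k <- t_alt + t_ref           # tumor margin
  n <- m1 + m2
  lf <- lfactorial
  logp <- function(x) {
    # P(tumor alt = x) given margins
    if (x < 0 || x > m1 || k - x < 0 || k - x > m2) return(-Inf)
    lf(m1) - lf(x) - lf(m1 - x) +
      lf(m2) - lf(k - x) - lf(m2 - k + x) -
      (lf(n) - lf(k) - lf(n - k))
  }
  xs <- t_alt:min(m1, k)
  sum(exp(vapply(xs, logp, numeric(1))))
}

# beta-binomial upper tail by forward recursion on probability ratios
oracle_bb_tail <- function(x, n, a, b) {
  # P(X = 0) = B(a, n + b) / B(a, b)
  logp0 <- lbeta(a, n + b) - lbeta(a, b)
  logp <- logp0
  total <- 0
  if (x <= 0) return(1)
  for (k in 0:(n - 1)) {
    if (k >= x) total <- total + exp(logp)
    # P(k+1)/P(k) = (n-k)(a+k) / ((k+1)(b+n-k-1))
    logp <- logp + log(n - k) + log(a + k) - log(k + 1) - log(b + n - k - 1)
  }
  if (n >= x) total <- total + exp(logp)
  total
}

# naive per-read pileup counter: walks every read base by base
oracle_pileup <- function(reads, reference, chrom, pos, min_baseq = 20L) {
  counts <- list()
  bump <- function(key, rev) {
    cur <- counts[[key]]
    if (is.null(cur)) cur <- c(fwd = 0L, rev = 0L)
    cur[if (rev) "rev" else "fwd"] <- cur[if (rev) "rev" else "fwd"] + 1L
    counts[[key]] <<- cur
  }
  for (j in seq_len(nrow(reads))) {
    rd <- reads[j, ]
    if (rd$chrom != chrom) next
    ops <- regmatches(rd$cigar, gregexpr("\\d+[MIDNSHP=X]", rd$cigar))[[1]]
    nn <- as.integer(sub(".$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    rpos <- rd$pos
    qpos <- 1L
    for (i in seq_along(op)) {
      if (op[i] %in% c("M", "=", "X")) {
        if (pos >= rpos && pos < rpos + nn[i]) {
          o <- qpos + (pos - rpos)
          b <- substr(rd$seq, o, o)
          q <- utf8ToInt(substr(rd$qual, o, o)) - 33L
          if (q >= min_baseq && b %in% c("A", "C", "G", "T")) {
            bump(b, bitwAnd(rd$flag, 16L) != 0L)
          }
        }
        rpos <- rpos + nn[i]; qpos <- qpos + nn[i]
      } else if (op[i] == "I") {
        if (rpos - 1L == pos) {
          bump(paste0("ins:", substr(rd$seq, qpos, qpos + nn[i] - 1L)),
               bitwAnd(rd$flag, 16L) != 0L)
        }
        qpos <- qpos + nn[i]
      } else if (op[i] == "D") {
        if (rpos - 1L == pos) {
          bump(paste0("del:", nn[i]), bitwAnd(rd$flag, 16L) != 0L)
        }
        rpos <- rpos + nn[i]
      } else if (op[i] == "S") {
        qpos <- qpos + nn[i]
      } else if (op[i] == "N") {
        rpos <- rpos + nn[i]
      }
    }
  }
  counts
}
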