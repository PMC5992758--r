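# Beta-mixture model of the VAF distribution. The EM here is exact: the
# M-step maximises the weighted beta log-likelihood through its sufficient
# statistics (weighted means of log x and log(1-x)), so each iteration can
# only increase the observed-data log-likelihood. Model selection over
# k = 1..k_max uses ICL-BIC (BIC plus twice the classification entropy),
# with ties broken toward fewer components.

#' Fit a beta mixture to variant allele frequencies
#'
#' Fits mixtures with 1..`k_max` beta components by EM (multiple seeded
#' restarts per k) and returns the model minimising ICL-BIC. The component
#' whose mean lies in the low-VAF `band` — a peak of calls at suspiciously
#' low frequency — is marked as the error component used by
#' [vaf_lees_filter()].
#'
#' @param vafs Numeric vector of VAFs in (0, 1).
#' @param k_max Largest number of components tried.
#' @param restarts EM restarts per k (first restart deterministic
#'   quantile-spread, later ones jittered).
#' @param seed Integer seed governing restarts; `NULL` leaves the RNG alone.
#' @param min_n Below this many observations no model is fitted and `NULL`
#'   is returned (the lees filter is then disabled).
#' @param band Low-VAF interval locating the error component.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return An object of class `beta_mixture` (fields `k`, `weights`,
#'   `shapes` (k x 2 matrix), `loglik`, `icl_bic`, `error_component`
#'   (index or `NA`), `all_k`), or `NULL` when `length(vafs) < min_n`.
#' @export
fit_beta_mixture <- function(vafs, k_max = 10L, restarts = 5L, seed = NULL,
                             min_n = 20L, band = c(0.01, 0.03),
                             max_iter = 150L, tol = 1e-7) {
  x <- vafs[is.finite(vafs)]
  eps <- 1e-6
  x <- pmin(pmax(x, eps), 1 - eps)
  if (length(x) < min_n) return(NULL)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(x)
  best <- NULL
  all_k <- list()
  for (k in seq_len(k_max)) {
    best_k <- NULL
    for (r in seq_len(restarts)) {
      init <- init_beta_mixture(x, k, jitter = r > 1)
      fit <- tryCatch(em_fit(x, k, init, max_iter, tol),
                      error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best_k) || fit$loglik > best_k$loglik) best_k <- fit
    }
    if (is.null(best_k)) next
    nu <- 3L * k - 1L
    z <- best_k$z
    ent <- -sum(ifelse(z > 0, z * log(z), 0))
    icl <- -2 * best_k$loglik + nu * log(n) + 2 * ent
    all_k[[k]] <- data.frame(k = k, loglik = best_k$loglik, icl_bic = icl)
    if (is.null(best) || icl < best$icl_bic) {
      best <- list(k = k, weights = best_k$weights, shapes = best_k$shapes,
                   loglik = best_k$loglik, icl_bic = icl)
    }
  }
  if (is.null(best)) return(NULL)
  means <- best$shapes[, 1] / rowSums(best$shapes)
  in_band <- which(means >= band[1] & means <= band[2])
  err <- if (length(in_band)) in_band[which.max(best$weights[in_band])] else
    NA_integer_
  structure(c(best, list(error_component = err, n = n, band = band,
                         all_k = do.call(rbind, all_k))),
            class = "beta_mixture")
}

#' @export
print.beta_mixture <- function(x, ...) {
  cat("Beta mixture: k =", x$k, " ICL-BIC =", format(x$icl_bic), "\n")
  means <- x$shapes[, 1] / rowSums(x$shapes)
  for (i in seq_len(x$k)) {
    cat(sprintf("  comp %d: w=%.3f alpha=%.3g beta=%.3g mean=%.4f%s\n", i,
                x$weights[i], x$shapes[i, 1], x$shapes[i, 2], means[i],
                if (identical(i, as.integer(x$error_component))) "  [error]"
                else ""))
  }
  invisible(x)
}

# quantile-spread method-of-moments initialisation
init_beta_mixture <- function(x, k, jitter = FALSE) {
  probs <- (seq_len(k) - 0.5) / k
  if (jitter) probs <- pmin(pmax(probs + runif(k, -0.4 / k, 0.4 / k)), 0.99)
  probs <- pmax(probs, 0.01)
  mu <- as.numeric(quantile(x, probs, names = FALSE))
  v <- max(stats::var(x) / max(k, 2), 1e-6)
  shapes <- t(vapply(mu, function(m) {
    v_i <- min(v, 0.9 * m * (1 - m))
    nu <- m * (1 - m) / v_i - 1
    c(max(m * nu, 0.05), max((1 - m) * nu, 0.05))
  }, numeric(2)))
  list(weights = rep(1 / k, k), shapes = shapes)
}

# EM iteration loop; monotone in observed-data log-likelihood. The beta
# log-density is assembled from precomputed log(x)/log1p(-x) so an E-step is
# two outer products.
em_fit <- function(x, k, init, max_iter = 150L, tol = 1e-7) {
  n <- length(x)
  w <- init$weights
  sh <- init$shapes
  lx <- log(x)
  lx1 <- log1p(-x)
  prev <- -Inf
  trace <- numeric(0)
  z <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    ld <- outer(lx, sh[, 1] - 1) + outer(lx1, sh[, 2] - 1)
    ld <- sweep(ld, 2, log(w) - lbeta(sh[, 1], sh[, 2]), "+")
    m <- ld[cbind(seq_len(n), max.col(ld))]
    p <- exp(ld - m)
    rs <- rowSums(p)
    loglik <- sum(log(rs) + m)
    z <- p / rs
    trace <- c(trace, loglik)
    if (is.finite(prev) && loglik - prev < tol * (abs(prev) + 1)) break
    prev <- loglik
    # M-step: exact weighted MLE through sufficient statistics
    nk <- colSums(z)
    w <- nk / n
    for (j in seq_len(k)) {
      if (nk[j] < 1e-8) next
      sl <- sum(z[, j] * lx) / nk[j]
      sl1 <- sum(z[, j] * lx1) / nk[j]
      sh[j, ] <- beta_weighted_mle(sl, sl1, sh[j, ])
    }
  }
  list(weights = w, shapes = sh, loglik = loglik, z = z, trace = trace,
       iter = it)
}

# maximise a*sl + b*sl1 - log B(a, b) over a, b > 0 by damped Newton on the
# sufficient-statistic equations; the step is only taken when it improves
# the objective, so the surrounding EM remains monotone
beta_weighted_mle <- function(sl, sl1, start) {
  f <- function(a, b) a * sl + b * sl1 - lbeta(a, b)
  a <- max(start[1], 1e-4)
  b <- max(start[2], 1e-4)
  f0 <- f(a, b)
  for (it in 1:8) {
    dab <- digamma(a + b)
    g1 <- sl - digamma(a) + dab
    g2 <- sl1 - digamma(b) + dab
    if (abs(g1) + abs(g2) < 1e-8) break
    g <- c(g1, g2)
    tab <- trigamma(a + b)
    h11 <- -trigamma(a) + tab
    h22 <- -trigamma(b) + tab
    det <- h11 * h22 - tab * tab
    step <- if (is.finite(det) && abs(det) > 1e-300) {
      -c(h22 * g1 - tab * g2, -tab * g1 + h11 * g2) / det
    } else g
    lam <- 1
    improved <- FALSE
    for (h in 1:20) {
      a1 <- a + lam * step[1]
      b1 <- b + lam * step[2]
      if (a1 > 1e-6 && b1 > 1e-6) {
        f1 <- f(a1, b1)
        if (is.finite(f1) && f1 >= f0) {
          a <- a1; b <- b1
          improved <- f1 > f0 + 1e-12
          f0 <- f1
          break
        }
      }
      lam <- lam / 2
    }
    if (!improved && sum(abs(g)) < 1e-8) break
    if (!improved) break
  }
  pmin(pmax(c(a, b), 1e-4), 1e6)
}

#' VAF-lees filter
#'
#' Tests each candidate's alt count against the beta-binomial implied by the
#' fitted error component: a call whose upper-tail probability exceeds
#' `alpha_lees` is consistent with background error ("lees") and fails;
#' calls significantly above the error component pass. With no model or no
#' error component every candidate passes vacuously.
#'
#' @param cands Candidate table with tumor_alt, tumor_ref.
#' @param model A `beta_mixture` from [fit_beta_mixture()], or `NULL`.
#' @param alpha_lees Upper-tail cutoff.
#' @return data.table of verdicts, one per candidate, with the tail p as
#'   statistic.
#' @export
vaf_lees_filter <- function(cands, model, alpha_lees = 0.05) {
  n <- nrow(cands)
  if (is.null(model) || is.na(model$error_component)) {
    return(data.table::data.table(
      filter = rep("vaf_lees", n), passed = rep(TRUE, n),
      statistic = rep(NA_real_, n), threshold = rep(alpha_lees, n),
      detail = rep("no error component", n)))
  }
  sh <- model$shapes[model$error_component, ]
  p <- beta_binom_tail(cands$tumor_alt, cands$tumor_alt + cands$tumor_ref,
                       sh[1], sh[2])
  data.table::data.table(filter = "vaf_lees", passed = p <= alpha_lees,
                         statistic = p, threshold = alpha_lees,
                         detail = sprintf("err a=%.3g b=%.3g", sh[1], sh[2]))
}
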