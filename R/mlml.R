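## Joint (5mC, 5hmC) estimation from paired BS/oxBS counts by constrained
## binomial maximum likelihood, in closed form.
##
## Model: the BS unconverted fraction estimates p_m + p_h (both marks
## resist bisulfite); the oxBS unconverted fraction estimates p_m (5hmC is
## oxidized and converted). The joint likelihood
##   Binom(k_bs; n_bs, p_m + p_h) * Binom(k_ox; n_ox, p_m)
## is maximized over the simplex {p_m, p_h >= 0, p_m + p_h <= 1}. The
## interior solution is the naive subtraction; when that leaves the
## simplex (naive p_h < 0) the constrained maximum is on the boundary
## p_h = 0, where both arms measure the same quantity and the MLE pools
## the counts.

#' Per-site joint (5mC, 5hmC) maximum-likelihood estimate
#'
#' Vectorized closed-form constrained MLE. Without a conversion model:
#' interior solution p_m = k_ox/n_ox, p_h = k_bs/n_bs - k_ox/n_ox when
#' nonnegative; otherwise the boundary solution p_h = 0 with pooled
#' p_m = (k_bs + k_ox)/(n_bs + n_ox) and the conflict flag set.
#'
#' With a \code{\link{conversion_model}}, the arm-specific unconverted-read
#' probabilities are first inverted (moment correction) so the estimates
#' are unbiased under imperfect conversion; results outside the simplex
#' are projected back with the conflict flag set (the boundary p_h = 0
#' estimate again pools both arms, which under the corrected model still
#' measure the same linear function of p_m).
#'
#' @param k_bs,n_bs unconverted/total read counts in the BS arm.
#' @param k_ox,n_ox unconverted/total read counts in the oxBS arm.
#' @param model optional \code{\link{conversion_model}} for conversion-error
#'   correction (NULL = raw beta scale, the convention of standard
#'   MLML-style pipelines).
#' @return data.table with columns p_m, p_h, conflict.
#' @export
mlml_site <- function(k_bs, n_bs, k_ox, n_ox, model = NULL) {
  if (any(n_bs <= 0) || any(n_ox <= 0))
    stopf("mlml_site: coverage must be positive in both arms")
  if (any(k_bs > n_bs) || any(k_ox > n_ox) || any(k_bs < 0) || any(k_ox < 0))
    stopf("mlml_site: counts must satisfy 0 <= k <= n")
  b_bs <- k_bs / n_bs
  b_ox <- k_ox / n_ox
  if (is.null(model)) {
    t_hat <- b_bs
    m_hat <- b_ox
    pooled <- (k_bs + k_ox) / (n_bs + n_ox)
  } else {
    stopifnot(inherits(model, "conversion_model"))
    c_bs <- model$c_bs; c_ox <- model$c_ox; e_m <- model$e_m
    ## BS arm: q = t(1 - e_m) + (1 - t)(1 - c_bs)
    t_hat <- (b_bs - (1 - c_bs)) / (c_bs - e_m)
    ## oxBS arm given t: q = p_m[(1-e_m)-(1-c_ox)] + t(1-c_ox) + (1-t)(1-c_bs)
    t_cl <- clamp01(t_hat)
    m_hat <- (b_ox - t_cl * (1 - c_ox) - (1 - t_cl) * (1 - c_bs)) /
      (c_ox - e_m)
    pooled <- ((k_bs + k_ox) / (n_bs + n_ox) - (1 - c_bs)) / (c_bs - e_m)
  }
  p_h_naive <- t_hat - m_hat
  conflict <- (p_h_naive < 0) | (m_hat < 0) | (t_hat > 1) | (t_hat < 0) |
    (m_hat > 1)
  p_m <- clamp01(m_hat)
  p_h <- clamp01(pmin(p_h_naive, 1 - p_m))
  ## boundary p_h = 0: pool both arms for p_m
  low <- p_h_naive < 0
  p_m[low] <- clamp01(pooled[low])
  p_h[low] <- 0
  data.table::data.table(p_m = p_m, p_h = p_h, conflict = conflict)
}

## joint log-likelihood of (p_m, p_h) given the four counts (raw scale);
## used by the likelihood-dominance checks
mlml_loglik <- function(p_m, p_h, k_bs, n_bs, k_ox, n_ox) {
  t <- pmin(pmax(p_m + p_h, 1e-12), 1 - 1e-12)
  m <- pmin(pmax(p_m, 1e-12), 1 - 1e-12)
  k_bs * log(t) + (n_bs - k_bs) * log(1 - t) +
    k_ox * log(m) + (n_ox - k_ox) * log(1 - m)
}

#' Joint (5mC, 5hmC) track from paired BS and oxBS count tables
#'
#' Inner-joins the two arms on (chrom, pos), keeps only sites with at
#' least \code{min_cov} coverage in BOTH arms, and applies
#' \code{\link{mlml_site}} to each site.
#'
#' @param bs,ox count tables (chrom, pos, k, n, optionally sample_id) for
#'   the same sample's two arms.
#' @param min_cov per-arm coverage threshold (default 10).
#' @param model optional \code{\link{conversion_model}}.
#' @return data.table: chrom, pos, p_m, p_h, n_bs, n_ox, conflict.
#' @export
mlml_track <- function(bs, ox, min_cov = 10L, model = NULL) {
  bs <- data.table::as.data.table(bs)
  ox <- data.table::as.data.table(ox)
  if ("sample_id" %in% names(bs) && "sample_id" %in% names(ox)) {
    sb <- unique(bs$sample_id); so <- unique(ox$sample_id)
    if (length(sb) == 1L && length(so) == 1L && sb != so)
      stopf("mlml_track: arms come from different samples ('%s' vs '%s')",
            sb, so)
  }
  j <- merge(bs[, .(chrom, pos, k_bs = k, n_bs = n)],
             ox[, .(chrom, pos, k_ox = k, n_ox = n)],
             by = c("chrom", "pos"))
  j <- j[n_bs >= min_cov & n_ox >= min_cov]
  data.table::setorder(j, chrom, pos)
  if (nrow(j) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  p_m = numeric(), p_h = numeric(),
                                  n_bs = integer(), n_ox = integer(),
                                  conflict = logical()))
  est <- mlml_site(j$k_bs, j$n_bs, j$k_ox, j$n_ox, model = model)
  out <- cbind(j[, .(chrom, pos)], est, j[, .(n_bs, n_ox)])
  data.table::setcolorder(out, c("chrom", "pos", "p_m", "p_h",
                                 "n_bs", "n_ox", "conflict"))
  out[]
}

#' Pool read counts across replicate libraries of one arm
#'
#' Sums k and n per site over a list of per-sample count tables; used to
#' estimate group-level (5mC, 5hmC) at higher effective depth.
#'
#' @param counts_list list of count tables (chrom, pos, k, n).
#' @return one count table with pooled k, n.
#' @export
pool_counts <- function(counts_list) {
  x <- data.table::rbindlist(
    lapply(counts_list, function(d)
      data.table::as.data.table(d)[, .(chrom, pos, k, n)]))
  out <- x[, .(k = sum(k), n = sum(n)), by = .(chrom, pos)]
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Genome-wide mark occupancy summary
#'
#' Fraction of CpG sites "bearing" each mark (estimate strictly above the
#' calling threshold tau) and the co-occupancy percentages: how many 5mC
#' sites also carry 5hmC and vice versa.
#'
#' @param est a \code{\link{mlml_track}} result.
#' @param tau calling threshold in \[0, 1) (default 0: any positive
#'   estimated level counts).
#' @return list with pct_m, pct_h, pct_h_in_m, pct_m_in_h (percentages).
#' @export
occupancy_summary <- function(est, tau = 0) {
  assert_scalar_number(tau, "tau", 0, 1 - 1e-12)
  m <- est$p_m > tau
  h <- est$p_h > tau
  pct <- function(x) 100 * mean(x)
  list(pct_m = pct(m), pct_h = pct(h),
       pct_h_in_m = if (any(m)) 100 * sum(m & h) / sum(m) else 0,
       pct_m_in_h = if (any(h)) 100 * sum(m & h) / sum(h) else 0)
}
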