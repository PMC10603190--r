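## Differential (hydroxy)methylated region calling: recursive binary
## segmentation of the per-site group-mean-difference signal, rank tests
## on candidate regions, BH FDR, and the published threshold sets.

#' Site-by-sample beta matrix
#'
#' Assembles per-sample tracks into one matrix keyed by (chrom, pos),
#' keeping only sites present (covered) in every sample.
#'
#' @param tracks named list (sample_id -> data.table with chrom, pos and a
#'   value column).
#' @param groups named character vector sample_id -> "tumor"/"normal".
#' @param value name of the value column (e.g. "beta" or "p_h").
#' @return list with \code{sites} (chrom, pos), \code{beta} (matrix sites
#'   x samples) and \code{groups} (factor along columns).
#' @export
beta_matrix <- function(tracks, groups, value = "beta") {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (!all(names(tracks) %in% names(groups)))
    stopf("every track needs a group label")
  long <- data.table::rbindlist(lapply(names(tracks), function(s) {
    d <- data.table::as.data.table(tracks[[s]])
    if (!value %in% names(d)) stopf("track '%s' has no column '%s'", s, value)
    data.table::data.table(chrom = d$chrom, pos = d$pos,
                           sample_id = s, value = d[[value]])
  }))
  wide <- data.table::dcast(long, chrom + pos ~ sample_id, value.var = "value")
  wide <- wide[stats::complete.cases(wide)]
  data.table::setorder(wide, chrom, pos)
  mat <- as.matrix(wide[, !c("chrom", "pos")])
  mat <- mat[, names(tracks), drop = FALSE]
  list(sites = wide[, .(chrom, pos)], beta = mat,
       groups = factor(unname(groups[names(tracks)]),
                       levels = c("tumor", "normal")))
}

#' Published threshold sets for DMRs and DhMRs
#'
#' Modality "m" (5mC): |delta beta| > 0.2, more than 10 CpGs, CpG density
#' > 2 percent, FDR < 0.001. Modality "h" (5hmC): |delta beta| > 0.1, at
#' least 5 CpGs, FDR < 0.05 (no density filter).
#'
#' @param modality "m" or "h".
#' @return list with delta, n_cpg_min, density, q.
#' @export
dmr_thresholds <- function(modality = c("m", "h")) {
  modality <- match.arg(modality)
  if (modality == "m")
    list(delta = 0.2, n_cpg_min = 11L, density = 0.02, q = 0.001)
  else
    list(delta = 0.1, n_cpg_min = 5L, density = NULL, q = 0.05)
}

#' Candidate regions by recursive binary segmentation
#'
#' Works on the per-site difference of group means (tumor - normal).
#' Sites are first split into runs wherever consecutive CpGs are more than
#' \code{max_gap} bp apart (bounding region extent); within a run, a
#' segment is emitted as a candidate as soon as its mean |difference|
#' exceeds \code{delta_min}, otherwise it is split at the boundary that
#' maximizes the between-segment difference of mean delta beta (leftmost
#' on ties) and both halves are processed recursively. Recursion stops
#' below \code{min_cpg} sites.
#'
#' @param bm a \code{\link{beta_matrix}}.
#' @param modality "m" or "h" (sets default delta_min / min_cpg).
#' @param delta_min,min_cpg segmentation controls; default to the modality
#'   filter floors.
#' @param max_gap maximum intra-region CpG gap in bp (default 300).
#' @return data.table of candidates: chrom, start, end, first (row index),
#'   last, n_cpg.
#' @export
dmr_segment <- function(bm, modality = c("m", "h"), delta_min = NULL,
                        min_cpg = NULL, max_gap = 300L) {
  modality <- match.arg(modality)
  th <- dmr_thresholds(modality)
  delta_min <- delta_min %||% th$delta
  min_cpg <- min_cpg %||% th$n_cpg_min
  sites <- bm$sites
  if (is.unsorted(order(sites$chrom, sites$pos)) ||
      any(sites[, diff(pos) <= 0, by = chrom]$V1))
    stopf("dmr_segment: sites must be sorted by (chrom, pos) and unique")
  grp <- bm$groups
  d <- rowMeans(bm$beta[, grp == "tumor", drop = FALSE]) -
    rowMeans(bm$beta[, grp == "normal", drop = FALSE])

  out <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    runs <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    for (r in unique(runs)) {
      ri <- idx[runs == r]
      out <- c(out, segment_run(d, ri, delta_min, min_cpg))
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), first = integer(),
                                  last = integer(), n_cpg = integer()))
  cand <- data.table::rbindlist(lapply(out, function(ix)
    data.table::data.table(first = ix[1L], last = ix[2L])))
  cand[, `:=`(chrom = sites$chrom[first],
              start = sites$pos[first],
              end = sites$pos[last] + 2L,
              n_cpg = last - first + 1L)]
  data.table::setorder(cand, chrom, start)
  cand[, .(chrom, start, end, first, last, n_cpg)]
}

## iterative (explicit-stack) binary segmentation over global row indices.
## A segment whose mean |difference| passes delta_min is emitted unless the
## best split exposes a (large-enough) child with a clearly higher mean --
## a refinement margin of delta_min/4 keeps implanted blocks intact while
## shedding diluting flanks.
segment_run <- function(d, ri, delta_min, min_cpg) {
  res <- list()
  margin <- delta_min / 4
  stack <- list(c(ri[1L], ri[length(ri)]))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1L]; hi <- seg[2L]
    n <- hi - lo + 1L
    if (n < min_cpg) next
    dd <- d[lo:hi]
    md <- abs(mean(dd))
    if (n < 2L) {
      if (md > delta_min) res[[length(res) + 1L]] <- c(lo, hi)
      next
    }
    cs <- cumsum(dd)
    kk <- seq_len(n - 1L)
    lmean <- cs[kk] / kk
    rmean <- (cs[n] - cs[kk]) / (n - kk)
    score <- abs(lmean - rmean)
    k <- which.max(score)  # leftmost maximum: deterministic tie-break
    best_child <- max(if (k >= min_cpg) abs(lmean[k]) else -Inf,
                      if (n - k >= min_cpg) abs(rmean[k]) else -Inf)
    if (md > delta_min && best_child <= md + margin) {
      res[[length(res) + 1L]] <- refine_segment(d, lo, hi, min_cpg)
      next
    }
    stack[[length(stack) + 1L]] <- c(lo + k, hi)
    stack[[length(stack) + 1L]] <- c(lo, lo + k - 1L)
  }
  res
}

## boundary refinement of an emitted candidate: exhaustive scan over all
## sub-intervals of >= min_cpg sites; among those within REFINE_EPS of the
## best mean |difference|, the longest (leftmost on ties) wins, so a
## coherent implanted block is kept whole while flanks that dilute the
## mean by more than REFINE_EPS are shed.
## Very long segments (> 400 sites) fall back to greedy end-trimming.
REFINE_EPS <- 0.02

refine_segment <- function(d, lo, hi, min_cpg) {
  n <- hi - lo + 1L
  if (n <= min_cpg) return(c(lo, hi))
  if (n > 400L) return(trim_greedy(d, lo, hi, min_cpg))
  dd <- d[lo:hi]
  cs <- c(0, cumsum(dd))
  best <- -Inf; rows <- list()
  for (len in min_cpg:n) {
    i <- seq_len(n - len + 1L)
    m <- abs((cs[i + len] - cs[i]) / len)
    best <- max(best, max(m))
    rows[[len]] <- m
  }
  for (len in n:min_cpg) {           # longest first
    m <- rows[[len]]
    j <- which(m >= best - REFINE_EPS)
    if (length(j))
      return(c(lo + j[1L] - 1L, lo + j[1L] + len - 2L))
  }
  c(lo, hi)
}

trim_greedy <- function(d, lo, hi, min_cpg) {
  repeat {
    n <- hi - lo + 1L
    if (n <= min_cpg) break
    cur <- abs(mean(d[lo:hi]))
    drop_l <- abs(mean(d[(lo + 1L):hi]))
    drop_r <- abs(mean(d[lo:(hi - 1L)]))
    if (max(drop_l, drop_r) <= cur + 1e-12) break
    if (drop_l >= drop_r) lo <- lo + 1L else hi <- hi - 1L
  }
  c(lo, hi)
}

#' Test candidate regions and apply the modality's filters
#'
#' Per candidate, computes per-sample region-mean beta, the group delta
#' beta (tumor - normal), and a two-group Mann-Whitney p-value; q-values
#' are Benjamini-Hochberg over all candidates of the modality, and the
#' full threshold set of \code{\link{dmr_thresholds}} is then applied.
#'
#' The region statistic is configurable: \code{"pooled"} (default) ranks
#' all CpG-by-sample values of the region between groups, the convention
#' of segmentation callers in this field, which can reach small p-values
#' from few samples; \code{"sample_means"} is the exact Mann-Whitney on
#' per-sample region means (at 4 vs 4 its smallest two-sided p is
#' 2/70, so stringent FDR cutoffs are unattainable -- see the vignette).
#'
#' @param candidates a \code{\link{dmr_segment}} result.
#' @param bm the \code{\link{beta_matrix}} the candidates were derived from.
#' @param modality "m" or "h".
#' @param thresholds list as from \code{\link{dmr_thresholds}} (defaulted).
#' @param region_stat "pooled" or "sample_means".
#' @param density_denom "bp" (n_cpg per bp, default) or "dyads" (per
#'   possible CpG dyad, i.e. length/2).
#' @return data.table of regions passing all filters: chrom, start, end,
#'   modality, n_cpg, mean_tumor, mean_normal, delta_beta, p_value,
#'   q_value, direction, cpg_density.
#' @export
dmr_test <- function(candidates, bm, modality = c("m", "h"),
                     thresholds = NULL,
                     region_stat = c("pooled", "sample_means"),
                     density_denom = c("bp", "dyads")) {
  modality <- match.arg(modality)
  region_stat <- match.arg(region_stat)
  density_denom <- match.arg(density_denom)
  th <- thresholds %||% dmr_thresholds(modality)
  cand <- data.table::as.data.table(candidates)
  empty <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    modality = character(), n_cpg = integer(), mean_tumor = numeric(),
    mean_normal = numeric(), delta_beta = numeric(), p_value = numeric(),
    q_value = numeric(), direction = character(), cpg_density = numeric())
  if (nrow(cand) == 0L) return(empty)
  grp <- bm$groups
  tum <- which(grp == "tumor"); nor <- which(grp == "normal")
  stats_list <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rows <- cand$first[i]:cand$last[i]
    sub <- bm$beta[rows, , drop = FALSE]
    sm <- colMeans(sub)
    if (all(is.na(sm[tum])) || all(is.na(sm[nor]))) {
      warnf("candidate %s:%d-%d dropped: one group entirely missing",
            cand$chrom[i], cand$start[i], cand$end[i])
      next
    }
    p <- if (region_stat == "pooled")
      mwu_exact(as.vector(sub[, tum]), as.vector(sub[, nor]))$p.value
    else
      mwu_exact(sm[tum], sm[nor])$p.value
    stats_list[[i]] <- data.table::data.table(
      i = i, mean_tumor = mean(sm[tum]), mean_normal = mean(sm[nor]),
      p_value = p)
  }
  st <- data.table::rbindlist(stats_list)
  if (nrow(st) == 0L) return(empty)
  st[, q_value := bh_adjust(p_value)]
  res <- cbind(cand[st$i, .(chrom, start, end, n_cpg)], st[, !"i"])
  res[, modality := modality]
  res[, delta_beta := mean_tumor - mean_normal]
  res[, direction := ifelse(delta_beta > 0, "up", "down")]
  denom <- if (density_denom == "bp") (res$end - res$start)
           else (res$end - res$start) / 2
  res[, cpg_density := n_cpg / denom]
  keep <- abs(res$delta_beta) > th$delta &
    res$n_cpg >= th$n_cpg_min &
    res$q_value < th$q
  if (!is.null(th$density)) keep <- keep & res$cpg_density > th$density
  out <- res[keep]
  data.table::setorder(out, chrom, start)
  out[, .(chrom, start, end, modality, n_cpg, mean_tumor, mean_normal,
          delta_beta, p_value, q_value, direction, cpg_density)]
}

#' Segment and test in one call
#'
#' @inheritParams dmr_segment
#' @inheritParams dmr_test
#' @return filtered region set (see \code{\link{dmr_test}}).
#' @export
call_dmrs <- function(bm, modality = c("m", "h"), max_gap = 300L,
                      region_stat = c("pooled", "sample_means"),
                      density_denom = c("bp", "dyads")) {
  modality <- match.arg(modality)
  cand <- dmr_segment(bm, modality, max_gap = max_gap)
  dmr_test(cand, bm, modality, region_stat = match.arg(region_stat),
           density_denom = match.arg(density_denom))
}

#' Promoter-overlapping regions with gene assignment
#'
#' A region is promoter-assigned iff it overlaps a promoter by at least
#' 1 bp (half-open coordinates). A region overlapping several promoters is
#' assigned to all of them; a promoter overlapped by several regions of
#' one modality takes the region with the largest |delta beta|, keeping
#' one direction per gene per modality.
#'
#' @param regions a \code{\link{dmr_test}} result.
#' @param ann a \code{\link{generate_annotation}} result.
#' @return data.table: gene_id, modality, chrom, start, end, delta_beta,
#'   q_value, direction.
#' @export
intersect_promoters <- function(regions, ann) {
  stopifnot(inherits(ann, "toy_annotation"))
  reg <- data.table::as.data.table(regions)
  empty <- data.table::data.table(
    gene_id = character(), modality = character(), chrom = character(),
    start = integer(), end = integer(), delta_beta = numeric(),
    q_value = numeric(), direction = character())
  if (nrow(reg) == 0L || nrow(ann$genes) == 0L) return(empty)
  prom <- promoter_intervals(ann$genes, ann$promoter_size)
  prom[, end := as.integer(pmin(end, ann$chrom_sizes[chrom]))]
  check_intervals(prom, ann$chrom_sizes, "promoter")
  a <- reg[, .(chrom, start, end, modality, delta_beta, q_value, direction)]
  a[, `:=`(rstart = start, rend = end, end = end - 1L)]
  b <- prom[, .(chrom, start, end = end - 1L, gene_id)]
  data.table::setkey(b, chrom, start, end)
  hits <- data.table::foverlaps(a, b, nomatch = NULL)
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[, .(gene_id, modality, chrom, start = rstart, end = rend,
                   delta_beta, q_value, direction)]
  ## one region per gene per modality: largest |delta beta| wins
  hits[, adb := -abs(delta_beta)]
  data.table::setorder(hits, gene_id, modality, adb)
  out <- hits[, .SD[1L], by = .(gene_id, modality)]
  out[, adb := NULL]
  out[]
}

#' Region density per chromosome
#'
#' @param regions a \code{\link{dmr_test}} result (possibly several
#'   modalities bound together).
#' @param chrom_sizes named chromosome lengths in bp.
#' @return data.table: chrom, modality, n_regions, per_mb.
#' @export
chromosome_distribution <- function(regions, chrom_sizes) {
  reg <- data.table::as.data.table(regions)
  mods <- if (nrow(reg)) unique(reg$modality) else c("m", "h")
  grid <- data.table::CJ(chrom = names(chrom_sizes), modality = mods)
  cnt <- if (nrow(reg)) reg[, .(n_regions = .N), by = .(chrom, modality)]
         else data.table::data.table(chrom = character(),
                                     modality = character(),
                                     n_regions = integer())
  out <- cnt[grid, on = c("chrom", "modality")]
  out[is.na(n_regions), n_regions := 0L]
  out[, per_mb := n_regions / (chrom_sizes[chrom] / 1e6)]
  data.table::setorder(out, chrom, modality)
  out[]
}
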