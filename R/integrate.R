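## Integration of promoter 5mC/5hmC calls with gene expression:
## expression filtering, four-way promoter pattern classification,
## unidirectional/bidirectional comparison, 5hmC-stratified fold changes,
## top-gene selection, signature scoring.

UNIDIRECTIONAL <- c("up/up", "down/down")
BIDIRECTIONAL <- c("up/down", "down/up")

#' Filter genes by detection rate
#'
#' Keeps genes with a nonzero count in at least
#' \code{ceiling(min_frac * n_samples)} samples (the "detected in at least
#' 25 percent of all samples" rule).
#'
#' @param expr an \code{\link{simulate_expression}}-style expression table.
#' @param min_frac minimum detection fraction (default 0.25).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(expr, min_frac = 0.25) {
  cnt <- expr$counts
  if (nrow(cnt) == 0L) return(character())
  need <- ceiling(min_frac * ncol(cnt))
  rownames(cnt)[rowSums(cnt > 0) >= need]
}

#' Per-gene log2 fold change of grouped expression
#'
#' log2(mean normalized count in tumor + pseudo) - log2(mean in normal +
#' pseudo); the pseudocount keeps the formula defined at zero.
#'
#' @param expr expression table.
#' @param genes optional subset of gene ids.
#' @param pseudo pseudocount (default 1).
#' @return named numeric vector of log2 fold changes.
#' @export
gene_log2fc <- function(expr, genes = NULL, pseudo = 1) {
  nm <- expr$norm
  if (!is.null(genes)) nm <- nm[rownames(nm) %in% genes, , drop = FALSE]
  tum <- expr$samples$sample_id[expr$samples$group == "tumor"]
  nor <- expr$samples$sample_id[expr$samples$group == "normal"]
  lfc <- log2(rowMeans(nm[, tum, drop = FALSE]) + pseudo) -
    log2(rowMeans(nm[, nor, drop = FALSE]) + pseudo)
  lfc
}

#' Gene-body and promoter 5hmC versus expression
#'
#' Restricted to genes with low promoter methylation (mean 5mC beta below
#' \code{max_prom_m}) to remove the repressive influence of promoter 5mC,
#' genes are split at the median of (a) promoter mean 5hmC and (b)
#' gene-body mean 5hmC; grouped expression (mean normalized count over the
#' genes and samples of each group) is reported for the high and low half
#' of each split. Ties at the median go to the "low" group.
#'
#' @param site_levels data.table with chrom, pos, mC, hmC (across-sample
#'   mean levels).
#' @param expr expression table.
#' @param ann toy annotation.
#' @param max_prom_m promoter 5mC eligibility cutoff (default 0.1).
#' @return data.table: region ("promoter"/"gene_body"), level_group
#'   ("high"/"low"), n_genes, grouped_expression, grouped_expression_tumor,
#'   grouped_expression_normal.
#' @export
genebody_5hmc_analysis <- function(site_levels, expr, ann, max_prom_m = 0.1) {
  stopifnot(inherits(ann, "toy_annotation"))
  lv <- data.table::as.data.table(site_levels)
  tracks <- feature_tracks(ann)
  mean_over <- function(track, col) {
    b <- track[, .(chrom, start, end = end - 1L, gene_id)]
    data.table::setkey(b, chrom, start, end)
    a <- lv[, .(chrom, start = pos, end = pos, val = get(col))]
    h <- data.table::foverlaps(a, b, nomatch = NULL)
    h[, .(v = mean(val)), by = gene_id]
  }
  prom_m <- mean_over(tracks$promoter, "mC")
  prom_h <- mean_over(tracks$promoter, "hmC")
  body_h <- mean_over(tracks$gene_body, "hmC")
  g <- Reduce(function(a, b) merge(a, b, by = "gene_id"),
              list(data.table::setnames(prom_m, "v", "prom_m"),
                   data.table::setnames(prom_h, "v", "prom_h"),
                   data.table::setnames(body_h, "v", "body_h")))
  g <- g[prom_m < max_prom_m & gene_id %in% rownames(expr$norm)]
  if (nrow(g) < 2L)
    stopf("genebody_5hmc_analysis: fewer than 2 eligible genes")
  tum <- expr$samples$sample_id[expr$samples$group == "tumor"]
  nor <- expr$samples$sample_id[expr$samples$group == "normal"]
  grouped <- function(ids) {
    m <- expr$norm[rownames(expr$norm) %in% ids, , drop = FALSE]
    c(all = mean(m), tumor = mean(m[, tum, drop = FALSE]),
      normal = mean(m[, nor, drop = FALSE]))
  }
  split_at <- function(vals) {
    md <- stats::median(vals)
    list(high = g$gene_id[vals > md], low = g$gene_id[vals <= md])
  }
  rows <- list()
  for (rg in c("promoter", "gene_body")) {
    vals <- if (rg == "promoter") g$prom_h else g$body_h
    sp <- split_at(vals)
    for (lg in c("high", "low")) {
      ge <- grouped(sp[[lg]])
      rows[[length(rows) + 1L]] <- data.table::data.table(
        region = rg, level_group = lg, n_genes = length(sp[[lg]]),
        grouped_expression = ge["all"],
        grouped_expression_tumor = ge["tumor"],
        grouped_expression_normal = ge["normal"])
    }
  }
  data.table::rbindlist(rows)
}

#' Four-way promoter modification pattern per gene
#'
#' Joins the promoter-assigned DMR and DhMR tables: genes bearing both
#' marks get one of the four patterns up/up, up/down, down/up, down/down
#' ("<5mC direction>/<5hmC direction>"); genes with one mark are
#' "partial". Unidirectional = both marks change in the same direction.
#'
#' @param pdmr,pdhmr \code{\link{intersect_promoters}} outputs for
#'   modality m and h respectively.
#' @return data.table: gene_id, dm, dhm, delta_m, delta_h, pattern,
#'   directionality.
#' @export
classify_promoters <- function(pdmr, pdhmr) {
  pm <- data.table::as.data.table(pdmr)
  ph <- data.table::as.data.table(pdhmr)
  for (d in list(pm, ph))
    if (nrow(d) && anyDuplicated(d$gene_id))
      stopf("classify_promoters: conflicting duplicate directions for a gene; resolve upstream")
  m <- merge(pm[, .(gene_id, dm = direction, delta_m = delta_beta)],
             ph[, .(gene_id, dhm = direction, delta_h = delta_beta)],
             by = "gene_id", all = TRUE)
  m[is.na(dm), dm := "none"]
  m[is.na(dhm), dhm := "none"]
  m[, pattern := ifelse(dm != "none" & dhm != "none",
                        paste0(dm, "/", dhm), "partial")]
  m[dm == "none" & dhm == "none", pattern := "none"]
  m[, directionality := ifelse(pattern %in% UNIDIRECTIONAL, "unidirectional",
                        ifelse(pattern %in% BIDIRECTIONAL, "bidirectional",
                               "n/a"))]
  m[]
}

#' Pattern counts, percentages, and expression concordance
#'
#' For each 5mC direction: how many genes bear both marks, how many have
#' the matching 5hmC direction, and the percentage (2 decimals). With
#' expression fold changes supplied, also the percentage of
#' up-5mC/up-5hmC genes with reduced expression and of
#' down-5mC/down-5hmC genes with increased expression.
#'
#' @param classes a \code{\link{classify_promoters}} result.
#' @param log2fc optional named per-gene log2 fold changes.
#' @return list with \code{both_marks_total}, \code{by_dm} (data.table)
#'   and \code{concordance} (data.table, if log2fc given).
#' @export
pattern_summary <- function(classes, log2fc = NULL) {
  cl <- data.table::as.data.table(classes)
  both <- cl[dm != "none" & dhm != "none"]
  by_dm <- data.table::rbindlist(lapply(c("up", "down"), function(d) {
    nd <- both[dm == d]
    nm <- nd[dhm == d]
    data.table::data.table(dm = d, n = nrow(nd), n_matching_dhm = nrow(nm),
                           pct_matching = if (nrow(nd))
                             round(100 * nrow(nm) / nrow(nd), 2) else 0)
  }))
  out <- list(both_marks_total = nrow(both), by_dm = by_dm)
  if (!is.null(log2fc)) {
    conc <- data.table::rbindlist(lapply(
      list(c("up/up", "less"), c("down/down", "more")), function(spec) {
        ids <- both[pattern == spec[1]]$gene_id
        lf <- log2fc[names(log2fc) %in% ids]
        hit <- if (spec[2] == "less") sum(lf < 0) else sum(lf > 0)
        data.table::data.table(
          pattern = spec[1], expression_change = spec[2],
          n = length(lf), n_concordant = hit,
          pct_concordant = if (length(lf))
            round(100 * hit / length(lf), 2) else 0)
      }))
    out$concordance <- conc
  }
  out
}

#' Unidirectional versus bidirectional expression comparison
#'
#' Compares per-gene log2 fold changes between up/up and up/down patterns
#' and between down/down and down/up patterns with the exact two-sided
#' Mann-Whitney test (\code{\link{mwu_exact}}; exact for combined n <= 25,
#' normal approximation with continuity correction beyond).
#'
#' @param classes a \code{\link{classify_promoters}} result.
#' @param log2fc named per-gene log2 fold changes.
#' @return data.table: comparison, n_uni, n_bi, median_uni, median_bi,
#'   mean_uni, mean_bi, p_value (NA with a message if a side is empty).
#' @export
compare_pattern_expression <- function(classes, log2fc) {
  cl <- data.table::as.data.table(classes)
  lf_of <- function(p) {
    ids <- cl[pattern == p]$gene_id
    unname(log2fc[names(log2fc) %in% ids])
  }
  pairs <- list(c("up/up", "up/down"), c("down/down", "down/up"))
  rows <- lapply(pairs, function(pr) {
    a <- lf_of(pr[1]); b <- lf_of(pr[2])
    if (!length(a) || !length(b)) {
      message(sprintf("comparison %s vs %s skipped: empty pattern",
                      pr[1], pr[2]))
      p <- NA_real_
    } else p <- mwu_exact(a, b)$p.value
    data.table::data.table(
      comparison = paste(pr[1], "vs", pr[2]),
      n_uni = length(a), n_bi = length(b),
      median_uni = if (length(a)) stats::median(a) else NA_real_,
      median_bi = if (length(b)) stats::median(b) else NA_real_,
      mean_uni = if (length(a)) mean(a) else NA_real_,
      mean_bi = if (length(b)) mean(b) else NA_real_,
      p_value = p)
  })
  data.table::rbindlist(rows)
}

#' Stratify unidirectional genes by 5hmC alteration magnitude
#'
#' Strata on |delta beta| of 5hmC: high (> 0.14), medium (0.12, 0.14\],
#' low (0.10, 0.12\]; genes at or below 0.10 are excluded. Reports the
#' median per-gene log2 fold change per pattern and stratum.
#'
#' @param classes a \code{\link{classify_promoters}} result (unidirectional
#'   genes are selected internally).
#' @param log2fc named per-gene log2 fold changes.
#' @return data.table: pattern, stratum, n, median_log2fc.
#' @export
stratify_by_5hmc <- function(classes, log2fc) {
  cl <- data.table::as.data.table(classes)
  uni <- cl[pattern %in% UNIDIRECTIONAL & !is.na(delta_h)]
  uni[, stratum := hmc_stratum(abs(delta_h))]
  uni <- uni[!is.na(stratum)]
  uni[, log2fc := log2fc[gene_id]]
  out <- uni[!is.na(log2fc),
             .(n = .N, median_log2fc = stats::median(log2fc)),
             by = .(pattern, stratum)]
  out[, stratum := factor(stratum, levels = c("low", "medium", "high"))]
  data.table::setorder(out, pattern, stratum)
  out[]
}

## |delta beta| -> stratum label; boundaries: high > 0.14,
## 0.14 >= medium > 0.12, 0.12 >= low > 0.10
hmc_stratum <- function(adb) {
  ifelse(adb > 0.14, "high",
         ifelse(adb > 0.12, "medium",
                ifelse(adb > 0.10, "low", NA_character_)))
}

#' Top differentially expressed unidirectional genes
#'
#' Eligibility: the unidirectional pattern matching the expression
#' direction ("up"-regulated genes carry down-5mC/down-5hmC, "down"
#' carry up-5mC/up-5hmC) with at least a medium 5hmC alteration
#' (|delta beta| > 0.12). Ranked by |log2FC| descending, ties by gene id.
#'
#' @param classes a \code{\link{classify_promoters}} result.
#' @param log2fc named per-gene log2 fold changes.
#' @param direction "up" (upregulated) or "down" (downregulated).
#' @param k number of genes (default 20); fewer returned with a warning.
#' @return character vector of gene ids.
#' @export
select_top_genes <- function(classes, log2fc, direction = c("up", "down"),
                             k = 20L) {
  direction <- match.arg(direction)
  cl <- data.table::as.data.table(classes)
  want_pattern <- if (direction == "up") "down/down" else "up/up"
  elig <- cl[pattern == want_pattern & !is.na(delta_h) &
               abs(delta_h) > 0.12]
  elig[, log2fc := log2fc[gene_id]]
  elig <- elig[!is.na(log2fc)]
  elig <- if (direction == "up") elig[log2fc > 0] else elig[log2fc < 0]
  elig[, alfc := -abs(log2fc)]
  data.table::setorder(elig, alfc, gene_id)
  if (nrow(elig) < k)
    warnf("select_top_genes: only %d eligible gene(s) for k = %d",
          nrow(elig), k)
  head(elig$gene_id, k)
}

#' Signature score and high/low sample labels
#'
#' Per-sample mean of log2(TPM + 1) over a gene set; samples strictly
#' above the \code{hi_pct} percentile of the score distribution are
#' labelled "high", strictly below the \code{lo_pct} percentile "low"
#' (linear-interpolation percentiles).
#'
#' @param expr expression table (uses \code{expr$tpm}).
#' @param genes non-empty gene set.
#' @param hi_pct,lo_pct percentile cutoffs (default 75/25).
#' @return data.table: sample_id, group, score, label
#'   ("high"/"low"/"mid").
#' @export
signature_score <- function(expr, genes, hi_pct = 75, lo_pct = 25) {
  if (length(genes) == 0L) stopf("signature_score: empty gene set")
  tpm <- expr$tpm[rownames(expr$tpm) %in% genes, , drop = FALSE]
  if (nrow(tpm) == 0L) stopf("signature_score: no gene found in TPM matrix")
  score <- colMeans(log2(tpm + 1))
  hi <- stats::quantile(score, hi_pct / 100, type = 7, names = FALSE)
  lo <- stats::quantile(score, lo_pct / 100, type = 7, names = FALSE)
  data.table::data.table(
    sample_id = names(score), group = expr$samples$group[
      match(names(score), expr$samples$sample_id)],
    score = unname(score),
    label = ifelse(score > hi, "high", ifelse(score < lo, "low", "mid")))
}
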