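## Study-level drivers: simulate a full toy study, run the whole analysis.

#' Simulate a complete toy study
#'
#' Chains the generator: annotation, implant design (paired promoter
#' 5mC/5hmC implants for the configured pattern genes, single-mark
#' promoter implants, background implants), true methylome, one BS and one
#' oxBS library per sample with spike-ins, and pattern-coupled expression.
#' Promoter implants are placed at genes whose promoter carries a CGI so
#' regions have enough CpGs to be callable.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed top-level integer seed (expanded into per-stage child
#'   seeds, recorded in the result).
#' @return list: ann, truth, counts (per sample: list(bs, ox)), spikes,
#'   expr, groups (named vector), config, seeds.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- child_seeds(seed, c("ann", "design", "truth", "libs", "expr"))
  ann <- generate_annotation(config, seeds["ann"])

  design <- with_seed(seeds["design"], design_implants(ann, config))
  truth <- generate_true_methylome(ann, design$implants, config,
                                   seeds["truth"])

  n <- config$n_per_group
  samples <- c(paste0("tumor", seq_len(n)), paste0("normal", seq_len(n)))
  groups <- setNames(rep(c("tumor", "normal"), each = n), samples)
  lib_seeds <- child_seeds(seeds["libs"],
                           as.vector(outer(samples, c("bs", "ox"),
                                           paste, sep = "_")))
  counts <- list(); spikes <- list()
  for (s in samples) for (a in c("bs", "ox")) {
    lib <- simulate_library(truth, config$model, a, s, groups[[s]],
                            depth = config$depth,
                            seed = lib_seeds[[paste(s, a, sep = "_")]],
                            jitter_sd = config$jitter_sd,
                            n_spike_pos = config$n_spike_pos)
    counts[[s]][[a]] <- lib$sites
    spikes[[paste(s, a, sep = "_")]] <- lib$spikes
  }
  expr <- simulate_expression(ann, design$patterns, config$effect,
                              n_per_group = n, seed = seeds["expr"],
                              delta_h = design$delta_h,
                              frac_silent = config$frac_silent)
  list(ann = ann, truth = truth, counts = counts,
       spikes = data.table::rbindlist(spikes), expr = expr,
       groups = groups, config = config, seeds = seeds, seed = seed)
}

## choose pattern genes among CGI-promoter genes and lay out implants
design_implants <- function(ann, config) {
  g <- ann$genes
  pat_counts <- config$patterns
  need <- sum(pat_counts) + config$n_m_only + config$n_h_only
  cand <- which(g$has_cgi)
  if (length(cand) < need)
    stopf("not enough CGI-promoter genes (%d) for the requested implants (%d)",
          length(cand), need)
  cand <- sample(cand)  # shuffled; filled in order, skipping collisions
  pats <- c(rep(names(pat_counts), pat_counts),
            rep(c("m_up", "m_down"), length.out = config$n_m_only),
            rep(c("h_up", "h_down"), length.out = config$n_h_only))

  imp <- list(); dh <- numeric(); patterns <- character()
  placed <- data.table::data.table(chrom = character(), start = integer(),
                                   end = integer())
  pad <- config$implant_pad
  slot <- 1L
  for (ci in cand) {
    if (slot > length(pats)) break
    gi <- g[ci]
    if (gi$strand == "+") {
      s <- gi$tss - ann$promoter_size - pad[1]; e <- gi$tss + pad[2]
    } else {
      s <- gi$tss - pad[2]; e <- gi$tss + ann$promoter_size + pad[1]
    }
    s <- max(0L, s); e <- min(e, ann$chrom_sizes[[gi$chrom]])
    reg <- data.table::data.table(chrom = gi$chrom, start = s, end = e)
    if (overlaps_any(reg, placed)) next  # adjacent promoters would collide
    placed <- rbind(placed, reg)
    p <- pats[slot]; slot <- slot + 1L
    patterns[gi$gene_id] <- p
    dir_m <- if (grepl("^up|^m_up", p)) 1
             else if (grepl("^down|^m_down", p)) -1 else 0
    dir_h <- if (grepl("/up$|^h_up", p)) 1
             else if (grepl("/down$|^h_down", p)) -1 else 0
    if (dir_m != 0)
      imp[[length(imp) + 1L]] <- data.table::data.table(
        chrom = gi$chrom, start = s, end = e, modality = "m",
        delta = dir_m * config$delta_m, gene_id = gi$gene_id)
    if (dir_h != 0) {
      mag <- stats::runif(1, config$delta_h_range[1], config$delta_h_range[2])
      imp[[length(imp) + 1L]] <- data.table::data.table(
        chrom = gi$chrom, start = s, end = e, modality = "h",
        delta = dir_h * mag, gene_id = gi$gene_id)
      dh[gi$gene_id] <- dir_h * mag
    }
  }
  if (slot <= length(pats))
    stopf("could not place all pattern implants without overlap (%d left)",
          length(pats) - slot + 1L)
  ## background implants in gene-free space
  nbg <- config$n_bg_implants
  if (nbg > 0L) {
    gpad <- if (nrow(g)) g[, .(chrom, start = pmax(0L, start - 3000L),
                               end = end + 3000L)] else NULL
    got <- 0L; tries <- 0L
    while (got < nbg && tries < 50L * nbg) {
      tries <- tries + 1L
      ci <- sample(seq_along(ann$chrom_sizes), 1L)
      len <- sample(1000:2000, 1L)
      s <- sample.int(ann$chrom_sizes[ci] - len - 1L, 1L)
      candr <- data.table::data.table(chrom = names(ann$chrom_sizes)[ci],
                                      start = s, end = s + len)
      if (!is.null(gpad) && overlaps_any(candr, gpad)) next
      if (overlaps_any(candr, placed)) next
      placed <- rbind(placed, candr)
      got <- got + 1L
      mod <- if (got %% 2L) "m" else "h"
      mag <- if (mod == "m") config$delta_m
             else stats::runif(1, config$delta_h_range[1],
                               config$delta_h_range[2])
      imp[[length(imp) + 1L]] <- data.table::data.table(
        chrom = candr$chrom, start = candr$start, end = candr$end,
        modality = mod, delta = sample(c(-1, 1), 1L) * mag,
        gene_id = NA_character_)
    }
  }
  list(implants = data.table::rbindlist(imp), patterns = patterns,
       delta_h = dh)
}

#' Run the whole analysis chain on a (simulated) study
#'
#' simulate -> spike-in QC -> beta calling -> joint (5mC, 5hmC)
#' estimation -> DMR/DhMR calling -> promoter intersection -> feature
#' enrichment -> metaprofiles -> expression integration. Everything is
#' driven by one \code{\link{sim_config}} and one seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @param study optionally a pre-built \code{\link{simulate_study}} result
#'   (config/seed then ignored for generation).
#' @return nested list with elements study, qc, tracks, estimates,
#'   site_levels, regions, promoters, enrichment, profiles, occupancy,
#'   integration.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1, study = NULL) {
  study <- study %||% simulate_study(config, seed)
  config <- study$config
  model <- if (isTRUE(config$correct_conversion)) config$model else NULL

  ## QC
  qc <- list(
    conversion = summarize_conversion(conversion_report(study$spikes)),
    depth = depth_summary(data.table::rbindlist(lapply(
      names(study$counts), function(s) {
        data.table::rbindlist(lapply(c("bs", "ox"), function(a)
          data.table::data.table(library = s, arm = a,
                                 depth = mean(study$counts[[s]][[a]]$n))))
      }))))

  ## per-sample tracks
  samples <- names(study$counts)
  beta_bs <- lapply(samples, function(s)
    call_beta(study$counts[[s]]$bs, config$min_cov))
  names(beta_bs) <- samples
  est <- lapply(samples, function(s)
    mlml_track(study$counts[[s]]$bs, study$counts[[s]]$ox,
               min_cov = config$min_cov, model = model))
  names(est) <- samples

  ## matrices and region calling; modality m runs on the deconvolved p_m
  ## track (BS beta alone is p_m + p_h, so opposite 5hmC changes would
  ## partially cancel 5mC changes at bidirectional promoters)
  bm_m <- beta_matrix(est, study$groups, value = "p_m")
  bm_h <- beta_matrix(est, study$groups, value = "p_h")
  cand_m <- dmr_segment(bm_m, "m", max_gap = config$max_gap)
  cand_h <- dmr_segment(bm_h, "h", max_gap = config$max_gap)
  regs_m <- dmr_test(cand_m, bm_m, "m", region_stat = config$region_stat)
  regs_h <- dmr_test(cand_h, bm_h, "h", region_stat = config$region_stat)
  pdmr <- intersect_promoters(regs_m, study$ann)
  pdhmr <- intersect_promoters(regs_h, study$ann)

  enrichment <- list(
    m = if (nrow(cand_m)) feature_enrichment(regs_m, cand_m, study$ann)
        else NULL,
    h = if (nrow(cand_h)) feature_enrichment(regs_h, cand_h, study$ann)
        else NULL)

  ## across-sample mean site levels (overall and per group)
  grp <- study$groups
  common <- Reduce(function(a, b) merge(a, b, by = c("chrom", "pos")),
                   lapply(est, function(d) d[, .(chrom, pos)]))
  est_common <- lapply(est, function(d) merge(d, common,
                                              by = c("chrom", "pos")))
  site_levels <- list(
    all = lvl_from(est_common, samples),
    tumor = lvl_from(est_common, samples[grp[samples] == "tumor"]),
    normal = lvl_from(est_common, samples[grp[samples] == "normal"]))

  gb <- study$ann$genes[, .(chrom, start, end, strand)]
  profiles <- list(
    hmC = lapply(site_levels[c("tumor", "normal")], function(lv)
      binned_profile(lv[, .(chrom, pos, level = hmC)], gb)),
    mC = lapply(site_levels[c("tumor", "normal")], function(lv)
      binned_profile(lv[, .(chrom, pos, level = mC)], gb)))

  occupancy <- lapply(est, occupancy_summary)

  ## integration with expression
  keep <- filter_expressed(study$expr)
  lfc <- gene_log2fc(study$expr, keep)
  classes <- classify_promoters(pdmr[gene_id %in% keep],
                                pdhmr[gene_id %in% keep])
  integration <- list(
    expressed = keep, log2fc = lfc, classes = classes,
    pattern_summary = pattern_summary(classes, lfc),
    comparison = compare_pattern_expression(classes, lfc),
    strata = stratify_by_5hmc(classes, lfc),
    top_up = suppressWarnings(select_top_genes(classes, lfc, "up")),
    top_down = suppressWarnings(select_top_genes(classes, lfc, "down")),
    genebody = tryCatch(
      genebody_5hmc_analysis(site_levels$all, study$expr, study$ann),
      error = function(e) NULL))
  integration$scores <- list(
    top_up = if (length(integration$top_up))
      signature_score(study$expr, integration$top_up) else NULL,
    top_down = if (length(integration$top_down))
      signature_score(study$expr, integration$top_down) else NULL)

  list(study = study, qc = qc,
       tracks = list(beta_bs = beta_bs),
       estimates = est, site_levels = site_levels,
       regions = list(m = regs_m, h = regs_h,
                      candidates_m = cand_m, candidates_h = cand_h),
       promoters = list(pdmr = pdmr, pdhmr = pdhmr),
       enrichment = enrichment, profiles = profiles,
       occupancy = occupancy, integration = integration)
}

## mean site levels over a set of samples (tracks already on common sites)
lvl_from <- function(est_common, samps) {
  pm <- Reduce(`+`, lapply(samps, function(s) est_common[[s]]$p_m)) /
    length(samps)
  ph <- Reduce(`+`, lapply(samps, function(s) est_common[[s]]$p_h)) /
    length(samps)
  data.table::data.table(chrom = est_common[[samps[1]]]$chrom,
                         pos = est_common[[samps[1]]]$pos,
                         mC = pm, hmC = ph)
}
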