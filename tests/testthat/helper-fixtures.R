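# Shared fixtures, built in code at test time.

# small annotation/config for fast unit tests
tiny_config <- function(...) {
  sim_config(chrom_sizes = c(chrT = 3e5), n_genes = 30L,
             n_cgi_intergenic = 5L,
             patterns = c("up/up" = 2L, "down/down" = 2L,
                          "up/down" = 2L, "down/up" = 2L),
             n_m_only = 2L, n_h_only = 2L, n_bg_implants = 2L, ...)
}

# the 20-implant recovery study: 10 5mC implants (delta +/- 0.3) and 10
# 5hmC implants (delta +/- 0.15) at CpG islands of a gene-free genome,
# 4 vs 4 samples at 28x per arm, Table-2-regime conversion chemistry
recovery_study <- function(seed) {
  cfg <- sim_config(chrom_sizes = c(chrA = 5e5, chrB = 5e5), n_genes = 0L,
                    n_cgi_intergenic = 20L)
  seeds <- child_seeds(seed, c("ann", "pick", "truth", "libs"))
  ann <- generate_annotation(cfg, seeds["ann"])
  cgi <- ann$cgis
  stopifnot(nrow(cgi) >= 20L)
  imp <- with_seed(seeds["pick"], {
    pick <- sample(nrow(cgi), 20L)
    data.table::rbindlist(lapply(seq_along(pick), function(i) {
      r <- cgi[pick[i]]
      mod <- if (i <= 10L) "m" else "h"
      mag <- if (mod == "m") 0.3 else 0.15
      data.table::data.table(chrom = r$chrom, start = r$start, end = r$end,
                             modality = mod,
                             delta = sample(c(-1, 1), 1L) * mag)
    }))
  })
  truth <- generate_true_methylome(ann, imp, cfg, seeds["truth"])
  samples <- c(paste0("tumor", 1:4), paste0("normal", 1:4))
  groups <- stats::setNames(rep(c("tumor", "normal"), each = 4L), samples)
  ls <- child_seeds(seeds["libs"],
                    as.vector(outer(samples, c("bs", "ox"), paste,
                                    sep = "_")))
  bs <- list(); ox <- list()
  for (s in samples) {
    bs[[s]] <- simulate_library(truth, cfg$model, "bs", s, groups[[s]],
                                depth = 28,
                                seed = ls[[paste0(s, "_bs")]])$sites
    ox[[s]] <- simulate_library(truth, cfg$model, "ox", s, groups[[s]],
                                depth = 28,
                                seed = ls[[paste0(s, "_ox")]])$sites
  }
  est <- lapply(samples, function(s)
    mlml_track(bs[[s]], ox[[s]], 10L, model = cfg$model))
  names(est) <- samples
  list(cfg = cfg, ann = ann, truth = truth, bs = bs, ox = ox, est = est,
       groups = groups)
}

# sensitivity/precision of a called region set against implant truth
# (same-modality, >= 1 bp overlap)
region_recovery <- function(regions, truth) {
  if (nrow(regions) == 0L)
    return(c(sensitivity = 0, precision = NA_real_))
  tp_t <- vapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i]
    any(regions$modality == r$modality & regions$chrom == r$chrom &
          regions$start < r$end & regions$end > r$start)
  }, logical(1))
  tp_r <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i]
    any(truth$modality == r$modality & truth$chrom == r$chrom &
          truth$start < r$end & truth$end > r$start)
  }, logical(1))
  c(sensitivity = mean(tp_t), precision = mean(tp_r))
}

# published per-library metrics shipped as plain-text package data
example_path <- function(f) {
  p <- system.file("extdata", f, package = "duometh")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", f)
  p
}
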