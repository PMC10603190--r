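test_that("generate_annotation: constraint satisfaction and determinism", {
  cfg <- sim_config(chrom_sizes = c(c1 = 1e6, c2 = 1e6), n_genes = 200L)
  ann <- generate_annotation(cfg, 1)
  g <- ann$genes
  expect_equal(nrow(g), 200L)
  expect_true(all(g$start >= 0 & g$end <= ann$chrom_sizes[g$chrom]))
  expect_true(all(g$end > g$start))
  ## genes non-overlapping within each chromosome
  for (ch in names(ann$chrom_sizes)) {
    gc <- g[chrom == ch][order(start)]
    if (nrow(gc) > 1L)
      expect_true(all(head(gc$end, -1) <= tail(gc$start, -1)))
  }
  ## promoter convention: [TSS - 1000, TSS) on the gene strand
  prom <- duometh:::promoter_intervals(g, ann$promoter_size)
  plus <- g$strand == "+"
  expect_equal(prom$end[plus], g$tss[plus])
  expect_equal(prom$start[plus], pmax(0L, g$tss[plus] - 1000L))
  expect_equal(prom$start[!plus], g$tss[!plus] + 1L)
  ## same seed twice -> identical annotation
  expect_identical(generate_annotation(cfg, 1), ann)
  expect_false(identical(generate_annotation(cfg, 2)$genes, g))
  ## exons within gene bounds
  ex <- merge(ann$exons, g[, .(gene_id, gs = start, ge = end)],
              by = "gene_id")
  expect_true(all(ex$start >= ex$gs & ex$end <= ex$ge))
})

test_that("generate_annotation: degenerate and infeasible configs", {
  cfg0 <- sim_config(chrom_sizes = c(c1 = 1e5), n_genes = 0L,
                     n_cgi_intergenic = 10L)
  ann0 <- generate_annotation(cfg0, 3)
  expect_equal(nrow(ann0$genes), 0L)
  expect_gt(nrow(ann0$cgis), 0L)      # CGIs still emitted
  expect_gt(nrow(ann0$cpgs), 0L)
  ## more gene span than chromosome length -> sizing error
  expect_error(generate_annotation(
    sim_config(chrom_sizes = c(c1 = 2e4), n_genes = 50L), 1), "sizing")
  expect_error(sim_config(chrom_sizes = c(c1 = 5e3)), ">= 10 kb")
})

test_that("true methylome: baselines, simplex, implants, truth table", {
  cfg <- tiny_config()
  ann <- generate_annotation(cfg, 5)
  ## property: simplex conservation across seeds, with and without implants
  for (s in 1:3) {
    tm <- generate_true_methylome(ann, NULL, cfg, s)
    x <- tm$sites
    expect_true(all(x$p_m_normal >= 0 & x$p_h_normal >= 0 &
                      x$p_m_normal + x$p_h_normal <= 1))
    expect_true(all(x$p_m_tumor >= 0 & x$p_h_tumor >= 0 &
                      x$p_m_tumor + x$p_h_tumor <= 1))
    ## no implants: groups identical
    expect_identical(x$p_m_tumor, x$p_m_normal)
  }
  tm <- generate_true_methylome(ann, NULL, cfg, 5)
  ## bimodal 5mC baseline: CGI-low, background-high; 5hmC low
  in_cgi <- duometh:::overlaps_any(
    tm$sites[, .(chrom, start = pos, end = pos + 2L)], ann$cgis)
  expect_lt(mean(tm$sites$p_m_normal[in_cgi]), 0.2)
  expect_gt(mean(tm$sites$p_m_normal[!in_cgi]), 0.6)
  expect_lt(abs(mean(tm$sites$p_h_normal) - 0.05), 0.02)

  ## implant: mean group difference equals the target
  imp <- data.table::data.table(
    chrom = "chrT", start = c(10000L, 60000L), end = c(12000L, 61000L),
    modality = c("m", "h"), delta = c(0.3, -0.15))
  tm2 <- generate_true_methylome(ann, imp, cfg, 6)
  s1 <- tm2$sites[pos >= 10000 & pos < 12000]
  expect_equal(mean(s1$p_m_tumor - s1$p_m_normal), 0.3, tolerance = 0.02)
  s2 <- tm2$sites[pos >= 60000 & pos < 61000]
  expect_equal(mean(s2$p_h_tumor - s2$p_h_normal), -0.15, tolerance = 0.02)
  ## truth table: exact coordinates, direction, CpG counts
  tt <- tm2$implants
  expect_equal(nrow(tt), 2L)
  expect_equal(tt$start, imp$start)
  expect_equal(tt$end, imp$end)
  expect_equal(tt$direction, c("up", "down"))
  expect_equal(tt$n_cpg, c(nrow(s1), nrow(s2)))
  ## infeasible implant errors, naming the region
  bad <- data.table::data.table(chrom = "chrT", start = 10000L,
                                end = 12000L, modality = "m", delta = 0.99)
  expect_error(generate_true_methylome(ann, bad, cfg, 7),
               "infeasible implant chrT:10000")
  ## partially overlapping implant regions are rejected
  ov <- data.table::data.table(
    chrom = "chrT", start = c(10000L, 11000L), end = c(12000L, 13000L),
    modality = c("m", "h"), delta = c(0.2, 0.1))
  expect_error(generate_true_methylome(ann, ov, cfg, 8), "overlap")
})

test_that("simulate_library: closed-form conversion expectations", {
  cfg <- sim_config(chrom_sizes = c(c1 = 1e4), n_genes = 0L,
                    n_cgi_intergenic = 0L)
  ann <- generate_annotation(cfg, 1)
  tm <- generate_true_methylome(ann, NULL, cfg, 1)
  n_sites <- nrow(tm$sites)
  model <- conversion_model(c_bs = 0.9933, c_ox = 0.9652, e_m = 0)

  ## p_m = 1, e_m = 0: all reads unconverted in both arms
  tm$sites[, `:=`(p_m_normal = 1, p_h_normal = 0,
                  p_m_tumor = 1, p_h_tumor = 0)]
  for (a in c("bs", "ox")) {
    lib <- simulate_library(tm, model, a, "s", "normal", depth = 50,
                            seed = 1, jitter_sd = 0)
    expect_equal(sum(lib$sites$k), sum(lib$sites$n))
  }
  ## unmodified site, c_bs = 0.9933: unconverted fraction 0.0067 +/- 3 SE
  tm$sites[, `:=`(p_m_normal = 0, p_h_normal = 0)]
  lib <- simulate_library(tm, model, "bs", "s", "normal", depth = 1e4,
                          seed = 2, jitter_sd = 0)
  frac <- sum(lib$sites$k) / sum(lib$sites$n)
  se <- sqrt(0.0067 * 0.9933 / sum(lib$sites$n))
  expect_lt(abs(frac - 0.0067), 3 * se)
  ## p_h = 1 under oxBS, c_ox = 0.9652: unconverted fraction about 0.0348
  tm$sites[, `:=`(p_m_normal = 0, p_h_normal = 1)]
  lib <- simulate_library(tm, model, "ox", "s", "normal", depth = 1e4,
                          seed = 3, jitter_sd = 0)
  frac <- sum(lib$sites$k) / sum(lib$sites$n)
  expect_equal(frac, 0.0348, tolerance = 3 * sqrt(0.0348 * 0.9652 /
                                                    sum(lib$sites$n)) / 0.0348)
  expect_error(simulate_library(tm, model, "bs", "s", "normal", depth = 0),
               "depth")
})

test_that("arm consistency: expected BS unconverted >= oxBS at every site", {
  ## deterministic closed-form property of the conversion model
  model <- conversion_model()
  set.seed(99)
  p_m <- runif(500)
  p_h <- runif(500) * (1 - p_m)
  q_bs <- duometh:::unconverted_prob(p_m, p_h, model, "bs")
  q_ox <- duometh:::unconverted_prob(p_m, p_h, model, "ox")
  expect_true(all(q_bs >= q_ox - 1e-12))
})

test_that("simulate_expression: effect recovery, null, degenerate", {
  cfg <- sim_config(chrom_sizes = c(c1 = 4e6), n_genes = 400L)
  ann <- generate_annotation(cfg, 11)
  gid <- ann$genes$gene_id
  ## effect recovery: up/up genes at log2FC -2 recovered within +/- 0.5
  pats <- stats::setNames(rep("up/up", 60L), gid[1:60])
  dh <- stats::setNames(rep(0.15, 60L), gid[1:60])
  ex <- simulate_expression(ann, pats, effect_spec(), n_per_group = 4L,
                            seed = 21, delta_h = dh, frac_silent = 0)
  lfc <- gene_log2fc(ex, gid[1:60])
  expect_equal(mean(lfc), -2, tolerance = 0.5)
  ## neutral null: grouped |log2FC| < 0.2 at 1000 genes
  cfg2 <- sim_config(chrom_sizes = c(c1 = 5e6, c2 = 5e6), n_genes = 1000L)
  ann2 <- generate_annotation(cfg2, 12)
  ex0 <- simulate_expression(ann2, NULL, effect_spec(), seed = 22,
                             frac_silent = 0)
  g_t <- mean(ex0$norm[, ex0$samples$group == "tumor"])
  g_n <- mean(ex0$norm[, ex0$samples$group == "normal"])
  expect_lt(abs(log2(g_t + 1) - log2(g_n + 1)), 0.2)
  ## zero genes -> empty table
  ann_empty <- generate_annotation(
    sim_config(chrom_sizes = c(c1 = 1e5), n_genes = 0L), 1)
  ex_e <- simulate_expression(ann_empty, NULL, effect_spec(), seed = 1)
  expect_equal(nrow(ex_e$counts), 0L)
  ## negative dispersion -> config error
  expect_error(effect_spec(dispersion = -1), "dispersion")
})

test_that("study-level determinism: identical seeds, identical outputs", {
  cfg <- tiny_config()
  s1 <- simulate_study(cfg, 17)
  s2 <- simulate_study(cfg, 17)
  expect_identical(s1$truth$sites, s2$truth$sites)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$expr$counts, s2$expr$counts)
  expect_identical(s1$spikes, s2$spikes)
  ## truth-table completeness: every implant recoverable with coordinates
  tt <- s1$truth$implants
  expect_true(all(tt$end > tt$start))
  expect_true(all(tt$modality %in% c("m", "h")))
  expect_true(all(tt[!is.na(gene_id)]$gene_id %in% s1$ann$genes$gene_id))
})
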