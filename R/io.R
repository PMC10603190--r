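## On-disk formats: tab-separated dialects for counts, spike-ins, beta
## tracks (bedGraph-like), regions (BED-like), and JSON configs.

#' Read / write per-CpG count tables
#'
#' Columns: chrom, pos (0-based CpG dyad start), strand, k (unconverted),
#' n (total).
#'
#' @param path file path.
#' @param x count table.
#' @name counts_io
NULL

#' @rdname counts_io
#' @export
read_site_counts <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  need <- c("chrom", "pos", "k", "n")
  if (!all(need %in% names(x)))
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  x
}

#' @rdname counts_io
#' @export
write_site_counts <- function(x, path) {
  keep <- intersect(c("chrom", "pos", "strand", "k", "n"), names(x))
  data.table::fwrite(data.table::as.data.table(x)[, ..keep], path,
                     sep = "\t")
  invisible(path)
}

#' Write a beta track as bedGraph-style TSV
#'
#' Columns chrom, start, end (= start + 2, the CpG dyad), beta, coverage.
#'
#' @param track a \code{\link{call_beta}} result.
#' @param path file path.
#' @export
write_beta_bedgraph <- function(track, path) {
  x <- data.table::as.data.table(track)
  out <- x[, .(chrom, start = pos, end = pos + 2L, beta, coverage)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write a study directory
#'
#' Materializes a \code{\link{simulate_study}} result as plain-text files:
#' per-sample per-arm count TSVs, spike-in counts, annotation (genes,
#' exons, CGIs as BED-like TSV, CpG positions), expression matrices,
#' truth tables, and a JSON metadata file with the seeds.
#'
#' @param study a \code{\link{simulate_study}} result.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  for (s in names(study$counts)) for (a in c("bs", "ox"))
    write_site_counts(study$counts[[s]][[a]],
                      file.path(dir, sprintf("counts_%s_%s.tsv", s, a)))
  fw(study$spikes, "spikes.tsv")
  fw(study$ann$genes, "genes.tsv")
  fw(study$ann$exons, "exons.tsv")
  fw(study$ann$cgis, "cgis.bed.tsv")
  fw(study$ann$cpgs, "cpgs.tsv")
  fw(data.table::data.table(chrom = names(study$ann$chrom_sizes),
                            size = as.integer(study$ann$chrom_sizes)),
     "chrom_sizes.tsv")
  fw(study$truth$sites, "truth_sites.tsv")
  fw(study$truth$implants, "truth_implants.tsv")
  wm <- function(m, f) {
    d <- data.table::as.data.table(m, keep.rownames = "gene_id")
    fw(d, f)
  }
  wm(study$expr$counts, "expr_counts.tsv")
  wm(study$expr$norm, "expr_norm.tsv")
  wm(study$expr$tpm, "expr_tpm.tsv")
  fw(study$expr$samples, "expr_samples.tsv")
  fw(study$expr$genes, "expr_genes.tsv")
  jsonlite::write_json(
    list(seed = study$seed, child_seeds = as.list(study$seeds),
         groups = as.list(study$groups)),
    file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write pipeline result tables
#'
#' @param res a \code{\link{run_pipeline}} result.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) if (!is.null(x) && nrow(x))
    data.table::fwrite(x, file.path(dir, f), sep = "\t")
  fw(res$qc$conversion, "qc_conversion.tsv")
  fw(res$qc$depth$per_arm, "qc_depth.tsv")
  fw(res$regions$m, "dmrs.bed.tsv")
  fw(res$regions$h, "dhmrs.bed.tsv")
  fw(res$promoters$pdmr, "p_dmrs.tsv")
  fw(res$promoters$pdhmr, "p_dhmrs.tsv")
  if (!is.null(res$enrichment$m)) fw(res$enrichment$m, "enrichment_m.tsv")
  if (!is.null(res$enrichment$h)) fw(res$enrichment$h, "enrichment_h.tsv")
  fw(res$integration$classes, "promoter_classes.tsv")
  fw(res$integration$comparison, "pattern_comparison.tsv")
  fw(res$integration$strata, "hmc_strata.tsv")
  ps <- res$integration$pattern_summary
  fw(ps$by_dm, "pattern_summary.tsv")
  if (!is.null(ps$concordance)) fw(ps$concordance, "pattern_concordance.tsv")
  lf <- res$integration$log2fc
  fw(data.table::data.table(gene_id = names(lf), log2fc = unname(lf)),
     "gene_log2fc.tsv")
  writeLines(res$integration$top_up, file.path(dir, "top_genes_up.txt"))
  writeLines(res$integration$top_down, file.path(dir, "top_genes_down.txt"))
  if (!is.null(res$integration$scores$top_up))
    fw(res$integration$scores$top_up, "signature_score_up.tsv")
  if (!is.null(res$integration$scores$top_down))
    fw(res$integration$scores$top_down, "signature_score_down.tsv")
  invisible(dir)
}

#' Load a simulation config from JSON
#'
#' Scalars and vectors override \code{\link{sim_config}} defaults; the
#' nested \code{model} and \code{effect} objects are rebuilt through
#' \code{\link{conversion_model}} / \code{\link{effect_spec}}.
#'
#' @param path JSON file.
#' @return a \code{\link{sim_config}}.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$model))
    raw$model <- do.call(conversion_model, as.list(raw$model))
  if (!is.null(raw$effect)) {
    ef <- as.list(raw$effect)
    if (!is.null(ef$lfc)) ef$lfc <- unlist(ef$lfc)
    raw$effect <- do.call(effect_spec, ef)
  }
  for (nm in c("chrom_sizes", "patterns"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(sim_config, raw)
}
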