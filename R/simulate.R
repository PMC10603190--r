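## Synthetic study generator, part 2: read-count and expression sampling.

## expected unconverted-read probability at a site, given true levels and
## the conversion chemistry. Exposed internally for closed-form checks.
unconverted_prob <- function(p_m, p_h, model, arm) {
  stopifnot(inherits(model, "conversion_model"))
  arm <- match.arg(arm, c("bs", "ox"))
  p_u <- 1 - p_m - p_h
  if (arm == "bs") {
    (p_m + p_h) * (1 - model$e_m) + p_u * (1 - model$c_bs)
  } else {
    p_m * (1 - model$e_m) + p_h * (1 - model$c_ox) + p_u * (1 - model$c_bs)
  }
}

spike_unconverted_prob <- function(class_, model, arm) {
  arm <- match.arg(arm, c("bs", "ox"))
  switch(class_,
    "C"    = 1 - model$c_bs,
    "5mC"  = 1 - model$e_m,
    "5hmC" = if (arm == "bs") 1 - model$e_m else 1 - model$c_ox,
    "5fC"  = if (arm == "bs") 1 - model$c_f_bs else 1 - model$c_f_ox,
    stopf("unknown spike-in class '%s'", class_))
}

#' Simulate one sequencing library (one sample, one protocol arm)
#'
#' Per CpG site, coverage is Poisson(depth) and the unconverted read count
#' is binomial with the arm-specific probability implied by the conversion
#' model: under BS both 5mC and 5hmC resist conversion; under oxBS 5hmC is
#' oxidized and converted at rate c_ox while 5mC still resists. A small
#' truncated-Gaussian between-sample jitter (sd \code{jitter_sd}) is added
#' to the true levels before sampling, then projected back to the simplex.
#' Spike-in control counts for the four pure classes (C, 5mC, 5hmC, 5fC)
#' are emitted alongside.
#'
#' @param truth a \code{\link{generate_true_methylome}} result.
#' @param model a \code{\link{conversion_model}}.
#' @param arm "bs" or "ox".
#' @param sample_id library name.
#' @param group "tumor" or "normal" (selects the truth columns).
#' @param depth mean per-site coverage (> 0).
#' @param seed integer seed.
#' @param jitter_sd between-sample biological variability (sd on the level
#'   scale; 0 disables).
#' @param n_spike_pos spike-in positions per class.
#' @return list with \code{sites} (chrom, pos, strand, k, n plus ids) and
#'   \code{spikes} (library, arm, class, unconverted, total).
#' @export
simulate_library <- function(truth, model, arm, sample_id, group,
                             depth = 28, seed = 1, jitter_sd = 0.02,
                             n_spike_pos = 500L) {
  stopifnot(inherits(truth, "true_methylome"))
  if (depth <= 0) stopf("depth must be > 0")
  arm <- match.arg(arm, c("bs", "ox"))
  group <- match.arg(group, c("tumor", "normal"))
  s <- truth$sites
  p_m <- if (group == "tumor") s$p_m_tumor else s$p_m_normal
  p_h <- if (group == "tumor") s$p_h_tumor else s$p_h_normal
  with_seed(seed, {
    if (jitter_sd > 0) {
      p_m <- clamp01(p_m + stats::rnorm(length(p_m), 0, jitter_sd))
      p_h <- clamp01(p_h + stats::rnorm(length(p_h), 0, jitter_sd))
      p_h <- pmin(p_h, 1 - p_m)
    }
    q <- unconverted_prob(p_m, p_h, model, arm)
    n <- stats::rpois(length(q), depth)
    k <- stats::rbinom(length(q), n, q)
    classes <- c("C", "5mC", "5hmC", "5fC")
    tot <- stats::rpois(4L, n_spike_pos * depth)
    unc <- stats::rbinom(4L, tot, vapply(classes, spike_unconverted_prob,
                                         numeric(1), model = model, arm = arm))
    list(
      sites = data.table::data.table(
        chrom = s$chrom, pos = s$pos, strand = "+", k = k, n = n,
        sample_id = sample_id, group = group, arm = arm),
      spikes = data.table::data.table(
        library = sample_id, arm = arm, class = classes,
        unconverted = unc, total = tot))
  })
}

#' Simulate a gene-by-sample expression table
#'
#' Negative-binomial counts for two groups whose per-gene log2 fold change
#' is set by the gene's promoter modification pattern through an
#' \code{\link{effect_spec}}: unidirectional patterns (up-5mC/up-5hmC,
#' down-5mC/down-5hmC) get larger-magnitude effects than bidirectional
#' ones, and (optionally) the magnitude scales with the gene's 5hmC
#' alteration. Normalized counts are counts per million; TPM additionally
#' divides by gene length.
#'
#' @param ann a \code{\link{generate_annotation}} result.
#' @param patterns named character vector gene_id -> pattern ("up/up",
#'   "down/down", "up/down", "down/up", "m_up", "m_down", "h_up", "h_down",
#'   "neutral"); genes absent from the map are "neutral".
#' @param effect an \code{\link{effect_spec}}.
#' @param n_per_group samples per group.
#' @param seed integer seed.
#' @param delta_h optional named numeric vector gene_id -> signed 5hmC
#'   delta beta (drives the magnitude coupling).
#' @param frac_silent fraction of neutral genes made near-silent (to give
#'   the expression filter something to remove).
#' @return object of class \code{expression_table}: matrices \code{counts},
#'   \code{norm} (CPM), \code{tpm}; \code{samples} (sample_id, group);
#'   \code{genes} (gene_id, length, pattern, delta_h, true_lfc).
#' @export
simulate_expression <- function(ann, patterns = NULL, effect = effect_spec(),
                                n_per_group = 4L, seed = 1, delta_h = NULL,
                                frac_silent = 0.1) {
  stopifnot(inherits(ann, "toy_annotation"), inherits(effect, "effect_spec"))
  g <- ann$genes
  samples <- data.table::data.table(
    sample_id = c(paste0("tumor", seq_len(n_per_group)),
                  paste0("normal", seq_len(n_per_group))),
    group = rep(c("tumor", "normal"), each = n_per_group))
  if (nrow(g) == 0L) {
    empty <- matrix(numeric(), 0, 2L * n_per_group,
                    dimnames = list(NULL, samples$sample_id))
    return(structure(list(counts = empty, norm = empty, tpm = empty,
                          samples = samples,
                          genes = data.table::data.table(
                            gene_id = character(), length = integer(),
                            pattern = character(), delta_h = numeric(),
                            true_lfc = numeric())),
                     class = "expression_table"))
  }
  pat <- rep("neutral", nrow(g))
  names(pat) <- g$gene_id
  if (!is.null(patterns)) {
    unknown <- setdiff(names(patterns), g$gene_id)
    if (length(unknown))
      stopf("patterns for unknown gene(s): %s", paste(unknown, collapse = ","))
    pat[names(patterns)] <- patterns
  }
  bad <- setdiff(unique(pat), names(effect$lfc))
  if (length(bad))
    stopf("no effect size for pattern(s): %s", paste(bad, collapse = ", "))
  dh <- rep(NA_real_, nrow(g)); names(dh) <- g$gene_id
  if (!is.null(delta_h)) dh[names(delta_h)] <- delta_h

  with_seed(seed, {
    lfc <- unname(effect$lfc[pat])
    uni <- pat %in% c("up/up", "down/down")
    if (isTRUE(effect$hmc_coupling)) {
      sc <- abs(dh) / effect$hmc_ref
      lfc <- ifelse(uni & !is.na(dh), lfc * sc, lfc)
    }
    mu <- stats::rlnorm(nrow(g), effect$base_meanlog, effect$base_sdlog)
    silent <- pat == "neutral" &
      stats::runif(nrow(g)) < frac_silent
    mu[silent] <- 0.2
    size <- 1 / effect$dispersion
    nmat <- 2L * n_per_group
    counts <- matrix(0, nrow(g), nmat,
                     dimnames = list(g$gene_id, samples$sample_id))
    for (j in seq_len(nmat)) {
      mj <- if (samples$group[j] == "tumor") mu * 2^lfc else mu
      counts[, j] <- stats::rnbinom(nrow(g), mu = mj, size = size)
    }
    libsize <- colSums(counts)
    libsize[libsize == 0] <- 1
    norm <- sweep(counts, 2, libsize, "/") * 1e6
    lens <- (g$end - g$start) / 1e3
    rate <- sweep(counts, 1, lens, "/")
    rs <- colSums(rate); rs[rs == 0] <- 1
    tpm <- sweep(rate, 2, rs, "/") * 1e6
    structure(list(counts = counts, norm = norm, tpm = tpm,
                   samples = samples,
                   genes = data.table::data.table(
                     gene_id = g$gene_id, length = g$end - g$start,
                     pattern = pat, delta_h = unname(dh),
                     true_lfc = lfc)),
              class = "expression_table")
  })
}

#' @export
print.expression_table <- function(x, ...) {
  cat("expression_table:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}
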