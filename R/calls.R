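## Per-CpG beta calling, coverage filtering, context summaries, 10-kb bins.

#' Call per-CpG beta values with a coverage filter
#'
#' beta = k/n (unconverted over total reads) at each CpG; sites with
#' coverage below \code{min_cov} are dropped (the standard ">= 10-fold"
#' inclusion rule). Records with k > n are malformed and raise an error
#' with the offending row number; duplicated (sample, arm, chrom, pos)
#' records are an input error rather than being merged silently.
#'
#' @param counts data.table with columns chrom, pos, k, n (and optionally
#'   strand, sample_id, group, arm, context).
#' @param min_cov minimum coverage (default 10).
#' @return data.table sorted by (chrom, pos) with beta and coverage
#'   columns, retaining any id columns present.
#' @export
call_beta <- function(counts, min_cov = 10L) {
  x <- data.table::as.data.table(counts)
  need <- c("chrom", "pos", "k", "n")
  if (!all(need %in% names(x)))
    stopf("count table needs columns: %s", paste(need, collapse = ", "))
  if (nrow(x) == 0L) {
    out <- data.table::copy(x)
    out[, `:=`(beta = numeric(0), coverage = integer(0))]
    out[, c("k", "n") := NULL]
    return(out[])
  }
  bad <- which(x$k > x$n | x$k < 0 | x$n < 0)
  if (length(bad))
    stopf("malformed record at line %d: unconverted count exceeds total",
          bad[1L])
  keycols <- intersect(c("sample_id", "arm", "chrom", "pos"), names(x))
  if (anyDuplicated(x, by = keycols))
    stopf("duplicated (sample, arm, position) records in input")
  out <- x[n >= min_cov]
  out[, `:=`(beta = k / n, coverage = n)]
  out[, c("k", "n") := NULL]
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Cytosine-context summary of a beta track
#'
#' Counts of retained (coverage-filtered) sites and the unweighted mean
#' beta per cytosine context (CG/CHG/CHH). Contexts absent from the track
#' get count 0 and a missing mean.
#'
#' @param track a \code{\link{call_beta}} result; if it has no
#'   \code{context} column all sites are treated as CG.
#' @param contexts contexts to report (default CG, CHG, CHH).
#' @return data.table with columns context, n_sites, mean_rate.
#' @export
context_summary <- function(track, contexts = c("CG", "CHG", "CHH")) {
  x <- data.table::as.data.table(track)
  if (!"context" %in% names(x)) x[, context := "CG"]
  known <- c("CG", "CHG", "CHH")
  if (!all(contexts %in% known))
    stopf("unknown context label(s): %s",
          paste(setdiff(contexts, known), collapse = ", "))
  if (any(!x$context %in% known))
    stopf("unknown context label(s) in track: %s",
          paste(setdiff(unique(x$context), known), collapse = ", "))
  got <- x[context %in% contexts,
           .(n_sites = .N, mean_rate = mean(beta)), by = context]
  out <- data.table::data.table(context = contexts)
  out <- got[out, on = "context"]
  out[is.na(n_sites), n_sites := 0L]
  out[]
}

#' Genome-wide binned mean beta
#'
#' Splits each chromosome into fixed-size half-open bins (last bin
#' truncated) and averages beta over the retained sites in each; bins with
#' no site are omitted.
#'
#' @param track a \code{\link{call_beta}} result (or any table with chrom,
#'   pos, beta).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 10 kb).
#' @return data.table with chrom, bin_start, bin_end, n_sites, mean_beta.
#' @export
genome_bins <- function(track, chrom_sizes, bin_size = 1e4) {
  x <- data.table::as.data.table(track)
  if (any(!x$chrom %in% names(chrom_sizes)))
    stopf("track contains chromosomes absent from chrom_sizes")
  x <- x[, .(chrom, pos, beta)]
  x[, bin := floor(pos / bin_size)]
  out <- x[, .(n_sites = .N, mean_beta = mean(beta)), by = .(chrom, bin)]
  out[, `:=`(bin_start = as.integer(bin * bin_size),
             bin_end = as.integer(pmin(bin * bin_size + bin_size,
                                       chrom_sizes[chrom])))]
  out[, bin := NULL]
  data.table::setorder(out, chrom, bin_start)
  out[, .(chrom, bin_start, bin_end, n_sites, mean_beta)]
}
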