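## Spike-in conversion QC and library-level sequencing summaries.

SPIKE_CLASSES <- c("C", "5mC", "5hmC", "5fC")

#' Conversion rate of one spike-in class
#'
#' Percentage of spike-in reads converted (read as T):
#' \code{100 * (total - unconverted) / total}. A class with zero total
#' reads yields NA (a missing-data marker excluded from averages).
#'
#' @param counts data.frame/data.table with columns \code{class},
#'   \code{unconverted}, \code{total} (one library, one arm).
#' @param class spike-in class, one of C, 5mC, 5hmC, 5fC.
#' @return conversion rate in percent, or NA if total is 0.
#' @export
conversion_rate <- function(counts, class) {
  counts <- data.table::as.data.table(counts)
  if (!class %in% SPIKE_CLASSES)
    stopf("unknown spike-in class '%s'", class)
  idx <- which(counts[["class"]] == class)  # outside [] to avoid NSE capture
  row <- counts[idx]
  if (nrow(row) != 1L)
    stopf("expected exactly one row for class '%s'", class)
  if (row$unconverted > row$total || row$total < 0)
    stopf("malformed spike counts: unconverted > total")
  if (row$total == 0) return(NA_real_)
  100 * (row$total - row$unconverted) / row$total
}

#' Per-library conversion-rate report from spike-in counts
#'
#' @param spikes data.table with columns library, arm, class, unconverted,
#'   total (any number of libraries).
#' @return data.table with columns library, arm, class, rate (percent).
#' @export
conversion_report <- function(spikes) {
  spikes <- data.table::as.data.table(spikes)
  need <- c("library", "arm", "class", "unconverted", "total")
  if (!all(need %in% names(spikes)))
    stopf("spike counts need columns: %s", paste(need, collapse = ", "))
  if (any(spikes$unconverted > spikes$total))
    stopf("malformed spike counts: unconverted > total")
  out <- spikes[, .(rate = ifelse(total == 0, NA_real_,
                                  100 * (total - unconverted) / total)),
                by = .(library, arm, class)]
  out[]
}

#' Per-arm class-average conversion rates
#'
#' Arithmetic mean of per-library conversion rates by arm and class,
#' computed at full precision with a display column rounded to 2 decimals.
#' Missing per-library rates (zero-coverage classes) are excluded.
#'
#' @param rates data.table as from \code{\link{conversion_report}}, or a
#'   table of printed per-library rates with the same columns.
#' @return data.table with columns arm, class, n_libraries, average,
#'   average_display.
#' @export
summarize_conversion <- function(rates) {
  rates <- data.table::as.data.table(rates)
  need <- c("library", "arm", "class", "rate")
  if (!all(need %in% names(rates)))
    stopf("rate table needs columns: %s", paste(need, collapse = ", "))
  if (nrow(rates) == 0L) stopf("summarize_conversion: empty input")
  out <- rates[!is.na(rate),
               .(n_libraries = .N, average = mean(rate)),
               by = .(arm, class)]
  if (nrow(out) == 0L) stopf("summarize_conversion: no usable rates")
  out[, average_display := round(average, 2)]
  data.table::setorder(out, arm, class)
  out[]
}

#' Mean sequencing depth per arm
#'
#' Per-library fold depth and the per-arm arithmetic mean. Depths may be
#' given directly (column \code{depth}) or derived from clean base totals
#' as \code{clean_bases / genome_size}.
#'
#' @param libraries data.table with columns library, arm, and either depth
#'   or clean_bases.
#' @param genome_size genome length in bp (required when depths are derived
#'   from clean bases).
#' @return list with \code{per_library} (library, arm, depth) and
#'   \code{per_arm} (arm, mean_depth).
#' @export
depth_summary <- function(libraries, genome_size = NULL) {
  lib <- data.table::as.data.table(libraries)
  if (!"depth" %in% names(lib)) {
    if (!"clean_bases" %in% names(lib))
      stopf("need a 'depth' or 'clean_bases' column")
    if (is.null(genome_size) || genome_size <= 0)
      stopf("genome_size must be > 0 to derive depth from clean bases")
    lib[, depth := clean_bases / genome_size]
  }
  per_arm <- lib[, .(mean_depth = mean(depth)), by = arm]
  list(per_library = lib[, .(library, arm, depth)], per_arm = per_arm[])
}
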