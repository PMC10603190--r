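## Internal helpers: validation, seeding, interval arithmetic.
## All intervals are 0-based, half-open [start, end).

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stopf("'%s' must be a single number in [%s, %s]", name, lo, hi)
  invisible(x)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Derive reproducible child seeds from one top-level seed
#'
#' A single user-facing seed is expanded into named per-stage seeds so that
#' each simulation stage has an independent, recorded random stream. Kept
#' below 2^31 so seeds remain valid R integers.
#'
#' @param seed integer top-level seed.
#' @param labels character vector naming the stages.
#' @return named integer vector of seeds.
#' @export
child_seeds <- function(seed, labels) {
  assert_scalar_number(seed, "seed")
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  setNames(sample.int(.Machine$integer.max - 1L, length(labels)), labels)
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## interval utilities -------------------------------------------------------

check_intervals <- function(x, chrom_sizes = NULL, what = "interval") {
  if (any(x$end <= x$start))
    stopf("%s with end <= start (half-open intervals required)", what)
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[x$chrom]
    if (any(is.na(sz)) || any(x$start < 0) || any(x$end > sz))
      stopf("%s outside chromosome bounds", what)
  }
  invisible(TRUE)
}

## number of overlapping bp between one interval and a set (same chrom assumed)
overlap_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

## does any interval in `a` overlap any in `b` (both data.tables with
## chrom/start/end, half-open)? returns logical vector along `a`.
overlaps_any <- function(a, b) {
  if (nrow(b) == 0L || nrow(a) == 0L) return(rep(FALSE, nrow(a)))
  a2 <- data.table::copy(data.table::as.data.table(a)[, .(chrom, start, end)])
  b2 <- data.table::copy(data.table::as.data.table(b)[, .(chrom, start, end)])
  ## half-open: shrink ends by 1 for the closed-coordinate foverlaps
  a2[, end := end - 1L]
  b2[, end := end - 1L]
  data.table::setkey(b2, chrom, start, end)
  hits <- data.table::foverlaps(a2, b2, which = TRUE, nomatch = NULL)
  out <- rep(FALSE, nrow(a))
  out[unique(hits$xid)] <- TRUE
  out
}

## Benjamini-Hochberg, thin wrapper kept as a named step so the pipeline's
## FDR choice is explicit and testable.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
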