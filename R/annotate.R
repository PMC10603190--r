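## Genomic-feature annotation, 30-bin metaprofiles, observed/expected
## enrichment of differential regions.

## subtract merged intervals `b` from intervals `a` (same chrom assumed
## handled by caller splitting); both data.tables with start/end, half-open
subtract_intervals <- function(a, b) {
  out <- vector("list", 0L)
  for (ch in unique(a$chrom)) {
    ai <- a[chrom == ch]
    bi <- b[chrom == ch]
    if (nrow(bi)) {
      data.table::setorder(bi, start)
      ## merge overlapping b intervals
      merged <- list(); cs <- bi$start[1]; ce <- bi$end[1]
      if (nrow(bi) > 1L) for (j in 2:nrow(bi)) {
        if (bi$start[j] <= ce) ce <- max(ce, bi$end[j])
        else { merged[[length(merged) + 1L]] <- c(cs, ce)
               cs <- bi$start[j]; ce <- bi$end[j] }
      }
      merged[[length(merged) + 1L]] <- c(cs, ce)
      mb <- do.call(rbind, merged)
    } else mb <- NULL
    for (i in seq_len(nrow(ai))) {
      s <- ai$start[i]; e <- ai$end[i]
      if (is.null(mb)) {
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = ch, start = s, end = e)
        next
      }
      cur <- s
      for (j in seq_len(nrow(mb))) {
        bs <- mb[j, 1L]; be <- mb[j, 2L]
        if (be <= cur || bs >= e) next
        if (bs > cur)
          out[[length(out) + 1L]] <- data.table::data.table(
            chrom = ch, start = cur, end = bs)
        cur <- max(cur, be)
      }
      if (cur < e)
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = ch, start = cur, end = e)
    }
  }
  if (!length(out))
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  data.table::rbindlist(out)
}

#' Derived feature tracks of a toy annotation
#'
#' Builds the interval track of every genomic feature used by the
#' profiling and enrichment steps: promoter, 5'UTR, exon, intron, 3'UTR,
#' gene body, 2 kb upstream/downstream flanks, CGI, CGI shore (within
#' 2 kb of a CGI, excluding the island) and CGI shelf (2-4 kb away,
#' excluding the island).
#'
#' @param ann a \code{\link{generate_annotation}} result.
#' @return named list of data.tables (chrom, start, end, and gene_id for
#'   gene-linked tracks).
#' @export
feature_tracks <- function(ann) {
  stopifnot(inherits(ann, "toy_annotation"))
  g <- ann$genes; ex <- ann$exons; sz <- ann$chrom_sizes
  clip <- function(d) {
    d <- d[end > start]
    d[, start := as.integer(pmax(0, start))]
    d[, end := as.integer(pmin(end, sz[chrom]))]
    d[end > start]
  }
  tracks <- list()
  if (nrow(g)) {
    prom <- promoter_intervals(g, ann$promoter_size)
    tracks$promoter <- clip(prom[, .(chrom, start, end, gene_id)])
    tracks$gene_body <- g[, .(chrom, start, end, gene_id)]
    tracks$exon <- ex[, .(chrom, start, end, gene_id)]
    ## introns: per-gene gaps between consecutive exons
    intr <- ex[order(gene_id, start),
               .(chrom = chrom[-.N], start = end[-.N], end = start[-1L]),
               by = gene_id]
    tracks$intron <- intr[end > start, .(chrom, start, end, gene_id)]
    ## UTRs: strand-aware slices of the terminal exons
    utr <- g[, {
      e <- ex[gene_id == .BY$gene_id][order(start)]
      first <- if (strand == "+") e[1L] else e[.N]
      last <- if (strand == "+") e[.N] else e[1L]
      u5len <- min(200L, first$end - first$start)
      u3len <- min(300L, last$end - last$start)
      u5 <- if (strand == "+") c(first$start, first$start + u5len)
            else c(first$end - u5len, first$end)
      u3 <- if (strand == "+") c(last$end - u3len, last$end)
            else c(last$start, last$start + u3len)
      .(chrom = chrom, u5s = u5[1], u5e = u5[2], u3s = u3[1], u3e = u3[2])
    }, by = gene_id]
    tracks$utr5 <- utr[, .(chrom, start = u5s, end = u5e, gene_id)]
    tracks$utr3 <- utr[, .(chrom, start = u3s, end = u3e, gene_id)]
    up <- g[, .(gene_id, chrom,
                start = ifelse(strand == "+", start - 2000L -
                                 ann$promoter_size, end),
                end = ifelse(strand == "+", start,
                             end + 2000L + ann$promoter_size))]
    tracks$upstream2k <- clip(up)
    dn <- g[, .(gene_id, chrom,
                start = ifelse(strand == "+", end, start - 2000L),
                end = ifelse(strand == "+", end + 2000L, start))]
    tracks$downstream2k <- clip(dn)
  }
  cgi <- ann$cgis
  tracks$cgi <- cgi[, .(chrom, start, end)]
  if (nrow(cgi)) {
    shore_raw <- rbind(cgi[, .(chrom, start = start - 2000L, end = start)],
                       cgi[, .(chrom, start = end, end = end + 2000L)])
    tracks$cgi_shore <- clip(subtract_intervals(clip(shore_raw), cgi))
    shelf_raw <- rbind(cgi[, .(chrom, start = start - 4000L,
                               end = start - 2000L)],
                       cgi[, .(chrom, start = end + 2000L,
                               end = end + 4000L)])
    tracks$cgi_shelf <- clip(subtract_intervals(clip(shelf_raw), cgi))
  } else {
    tracks$cgi_shore <- cgi[, .(chrom, start, end)]
    tracks$cgi_shelf <- cgi[, .(chrom, start, end)]
  }
  tracks
}

#' Feature labels of genomic intervals
#'
#' Labels each query interval with every feature it overlaps by at least
#' 1 bp; an interval overlapping no gene-linked feature additionally gets
#' the label "intergenic" (CGI/shore/shelf labels are independent of the
#' gene features).
#'
#' @param intervals data.table with chrom, start, end (half-open).
#' @param ann a \code{\link{generate_annotation}} result.
#' @return data.table with columns idx (row of \code{intervals}) and
#'   feature.
#' @export
annotate_feature <- function(intervals, ann) {
  x <- data.table::as.data.table(intervals)
  check_intervals(x, what = "query interval")
  tracks <- feature_tracks(ann)
  gene_linked <- c("promoter", "gene_body", "exon", "intron", "utr5",
                   "utr3", "upstream2k", "downstream2k")
  hits <- list()
  for (f in names(tracks)) {
    tr <- tracks[[f]]
    if (nrow(tr) == 0L) next
    ov <- overlaps_any(x, tr)
    if (any(ov))
      hits[[f]] <- data.table::data.table(idx = which(ov), feature = f)
  }
  out <- data.table::rbindlist(hits)
  covered <- if (nrow(out))
    unique(out[feature %in% gene_linked]$idx) else integer()
  inter <- setdiff(seq_len(nrow(x)), covered)
  if (length(inter))
    out <- rbind(out, data.table::data.table(idx = inter,
                                             feature = "intergenic"))
  data.table::setorder(out, idx, feature)
  out[]
}

#' Binned metaprofile over a region class
#'
#' Each region body is divided into \code{n_bins} equal bins (regions
#' shorter than \code{n_bins} bp are skipped); optional flanks are divided
#' into \code{flank_bins} equal-bp bins. Site levels are averaged within
#' each bin per region, then across regions (missing bins excluded), and
#' minus-strand regions are flipped so bin 1 is always the 5' end.
#'
#' @param sites data.table with chrom, pos, level.
#' @param regions data.table with chrom, start, end and optionally strand.
#' @param n_bins number of body bins (default 30).
#' @param flank flank size in bp on each side (default 5000; 0 disables).
#' @param flank_bins number of bins per flank (default 50).
#' @return data.table: zone ("upstream", "body", "downstream"), bin
#'   (1-based within zone), mean_level, n_regions.
#' @export
binned_profile <- function(sites, regions, n_bins = 30L, flank = 5000L,
                           flank_bins = 50L) {
  reg <- data.table::as.data.table(regions)
  if (nrow(reg) == 0L) stopf("binned_profile: empty region set")
  if (!"strand" %in% names(reg)) reg[, strand := "+"]
  reg <- reg[end - start >= n_bins]
  if (nrow(reg) == 0L)
    stopf("binned_profile: no region of length >= n_bins bp")
  reg[, region_id := .I]
  s <- data.table::as.data.table(sites)[, .(chrom, pos, level)]
  ## window join
  win <- reg[, .(region_id, chrom, wstart = start - flank,
                 wend = end + flank, start, end, strand)]
  a <- s[, .(chrom, start = pos, end = pos)]
  b <- win[, .(chrom, start = wstart, end = wend - 1L, region_id)]
  data.table::setkey(b, chrom, start, end)
  hits <- data.table::foverlaps(a, b, nomatch = NULL)
  if (nrow(hits) == 0L)
    return(data.table::data.table(zone = character(), bin = integer(),
                                  mean_level = numeric(),
                                  n_regions = integer()))
  hits <- hits[, .(chrom, pos = i.start, region_id)]
  hits <- merge(hits, s, by = c("chrom", "pos"), allow.cartesian = TRUE)
  hits <- merge(hits, win[, .(region_id, start, end, strand)],
                by = "region_id")
  hits[, off := pos - start]
  len <- hits$end - hits$start
  zone <- ifelse(hits$off < 0, "upstream",
                 ifelse(hits$off >= len, "downstream", "body"))
  bin <- integer(nrow(hits))
  upi <- zone == "upstream"
  bin[upi] <- pmin(flank_bins - 1L,
                   floor((hits$off[upi] + flank) / flank * flank_bins))
  bi <- zone == "body"
  bin[bi] <- pmin(n_bins - 1L, floor(hits$off[bi] / len[bi] * n_bins))
  dn <- zone == "downstream"
  bin[dn] <- pmin(flank_bins - 1L,
                  floor((hits$off[dn] - len[dn]) / flank * flank_bins))
  ## strand flip: minus-strand regions read 3'->5' in genomic coordinates
  neg <- hits$strand == "-"
  zz <- zone
  zone[neg & zz == "upstream"] <- "downstream"
  zone[neg & zz == "downstream"] <- "upstream"
  nb <- ifelse(zone == "body", n_bins, flank_bins)
  bin[neg] <- nb[neg] - 1L - bin[neg]
  hits[, `:=`(zone = zone, bin = bin + 1L)]
  per_region <- hits[, .(lv = mean(level)), by = .(region_id, zone, bin)]
  prof <- per_region[, .(mean_level = mean(lv), n_regions = .N),
                     by = .(zone, bin)]
  if (flank <= 0) prof <- prof[zone == "body"]
  prof[, zone := factor(zone, levels = c("upstream", "body", "downstream"))]
  data.table::setorder(prof, zone, bin)
  prof[, zone := as.character(zone)]
  prof[]
}

## two-sided Fisher exact p of the 2x2 table rbind(c(a, b), c(c, d));
## the single significance path used by feature_enrichment
fisher2x2_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Observed/expected enrichment of significant regions per feature
#'
#' The expected frequency is the genome-wide fraction of tested regions
#' that are significant; the observed frequency is the same fraction among
#' regions overlapping the feature; the enrichment ratio is their
#' quotient. Significance of the 2x2 table (significant vs not) x (in
#' feature vs not) is assessed by a two-sided Fisher exact test with
#' Benjamini-Hochberg adjustment across features.
#'
#' @param sig significant region set (rows must be a subset of
#'   \code{universe}).
#' @param universe all tested candidate regions.
#' @param ann a \code{\link{generate_annotation}} result.
#' @param features feature names to report (default: all tracks plus
#'   intergenic).
#' @return data.table: feature, n_feature_sig, n_feature_total, ratio,
#'   p_value, q_value.
#' @export
feature_enrichment <- function(sig, universe, ann, features = NULL) {
  uni <- data.table::as.data.table(universe)
  sg <- data.table::as.data.table(sig)
  if (nrow(uni) == 0L) stopf("feature_enrichment: empty universe")
  key <- intersect(c("chrom", "start", "end", "modality"), names(uni))
  uni[, uid := .I]
  if (nrow(sg)) {
    m <- merge(sg[, ..key], uni[, c(key, "uid"), with = FALSE], by = key)
    if (nrow(m) < nrow(sg))
      stopf("feature_enrichment: significant set is not a subset of the universe")
    sig_ids <- unique(m$uid)
  } else sig_ids <- integer()
  lab <- annotate_feature(uni[, .(chrom, start, end)], ann)
  features <- features %||% c("promoter", "utr5", "exon", "intron", "utr3",
                              "gene_body", "upstream2k", "downstream2k",
                              "cgi", "cgi_shore", "cgi_shelf", "intergenic")
  A <- length(sig_ids); B <- nrow(uni)
  rows <- lapply(features, function(f) {
    in_f <- unique(lab[feature == f]$idx)
    b <- length(in_f)
    a <- length(intersect(in_f, sig_ids))
    if (b == 0L)
      return(data.table::data.table(feature = f, n_feature_sig = 0L,
                                    n_feature_total = 0L, ratio = NA_real_,
                                    p_value = NA_real_))
    ratio <- if (A > 0) (a / b) / (A / B) else NA_real_
    p <- fisher2x2_p(a, b - a, A - a, (B - b) - (A - a))
    data.table::data.table(feature = f, n_feature_sig = a,
                           n_feature_total = b, ratio = ratio, p_value = p)
  })
  out <- data.table::rbindlist(rows)
  out[!is.na(p_value), q_value := bh_adjust(p_value)]
  out[]
}
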