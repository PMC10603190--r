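## Synthetic study generator, part 1: annotation and true methylome.
## Coordinates are 0-based half-open throughout.

#' Generate a toy genome annotation
#'
#' Lays out non-overlapping gene models (with exons, UTRs, promoters) and
#' CpG islands on a small multi-chromosome genome, and places CpG dyad
#' positions densely inside CGIs and sparsely elsewhere. Deterministic for
#' a fixed seed.
#'
#' The promoter convention is \code{[TSS - promoter_size, TSS)} on the gene
#' strand; CGIs are placed around the TSS of a configurable fraction of
#' genes (those are the genes later eligible for promoter implants) plus a
#' few intergenic ones.
#'
#' @param config a \code{\link{sim_config}} (only the genome/annotation
#'   fields are used).
#' @param seed integer seed.
#' @return object of class \code{toy_annotation}: list with
#'   \code{chrom_sizes}, \code{genes}, \code{exons}, \code{cgis},
#'   \code{cpgs}, \code{promoter_size}.
#' @export
generate_annotation <- function(config = sim_config(), seed = 1) {
  sizes <- config$chrom_sizes
  if (any(sizes < 1e4)) stopf("chromosome sizes must be >= 10 kb")
  n_genes <- as.integer(config$n_genes)
  if (n_genes < 0L) stopf("gene count must be >= 0")
  seeds <- child_seeds(seed, c("genes", "cgi", "cpg"))

  margin <- 6000L; min_gap <- 1600L
  genes <- with_seed(seeds["genes"], {
    ## allocate genes to chromosomes proportional to size
    alloc <- floor(n_genes * sizes / sum(sizes))
    rem <- n_genes - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    out <- vector("list", length(sizes))
    gid <- 0L
    for (ci in seq_along(sizes)) {
      k <- alloc[ci]
      if (k == 0L) next
      L <- sizes[ci]
      lens <- sample(seq(config$gene_length[1], config$gene_length[2]), k,
                     replace = TRUE)
      extra <- L - 2 * margin - sum(lens) - (k + 1L) * min_gap
      if (extra < 0)
        stopf("sizing error: %d genes do not fit on %s (%d bp)",
              k, names(sizes)[ci], L)
      u <- sort(stats::runif(k))
      bounds <- floor(c(0, u, 1) * extra)
      gaps <- diff(bounds) + min_gap  # k+1 gaps; last one trails the genes
      starts <- margin + cumsum(gaps[seq_len(k)]) +
        cumsum(c(0L, head(lens, -1L)))
      strand <- sample(c("+", "-"), k, replace = TRUE)
      out[[ci]] <- data.table::data.table(
        gene_id = sprintf("G%04d", gid + seq_len(k)),
        chrom = names(sizes)[ci],
        start = as.integer(starts),
        end = as.integer(starts + lens),
        strand = strand)
      gid <- gid + k
    }
    g <- data.table::rbindlist(out)
    if (nrow(g)) {
      g[, tss := ifelse(strand == "+", start, end - 1L)]
      g[, tts := ifelse(strand == "+", end - 1L, start)]
    } else {
      g <- data.table::data.table(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  strand = character(), tss = integer(),
                                  tts = integer())
    }
    g
  })

  exons <- with_seed(seeds["genes"] + 1L, make_exons(genes, config))

  cgi <- with_seed(seeds["cgi"], {
    make_cgis(genes, sizes, config)
  })
  genes[, has_cgi := FALSE]
  if (nrow(genes)) {
    prom <- promoter_intervals(genes, config$promoter_size)
    ## a gene "has" a promoter CGI if its promoter overlaps one
    genes[, has_cgi := overlaps_any(prom, cgi)]
  }

  cpgs <- with_seed(seeds["cpg"], make_cpgs(sizes, cgi, config))

  structure(list(chrom_sizes = sizes, genes = genes, exons = exons,
                 cgis = cgi, cpgs = cpgs,
                 promoter_size = as.integer(config$promoter_size),
                 seed = as.integer(seed), child_seeds = seeds),
            class = "toy_annotation")
}

make_exons <- function(genes, config) {
  if (nrow(genes) == 0L)
    return(data.table::data.table(gene_id = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  exon_rank = integer()))
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    L <- genes$end[i] - genes$start[i]
    ne <- sample(seq(config$n_exons[1], config$n_exons[2]), 1L)
    nb <- 2L * ne - 2L  # breakpoints between alternating exon/intron blocks
    for (try in 1:100) {
      bp <- if (nb > 0) sort(sample.int(L - 1L, nb)) else integer()
      widths <- diff(c(0L, bp, L))
      if (all(widths >= 40L)) break
    }
    edges <- c(0L, bp, L)
    blk_start <- edges[-length(edges)]
    blk_end <- edges[-1L]
    exon_idx <- seq(1L, 2L * ne - 1L, by = 2L)
    out[[i]] <- data.table::data.table(
      gene_id = genes$gene_id[i], chrom = genes$chrom[i],
      start = genes$start[i] + blk_start[exon_idx],
      end = genes$start[i] + blk_end[exon_idx],
      exon_rank = seq_len(ne))
  }
  data.table::rbindlist(out)
}

make_cgis <- function(genes, sizes, config) {
  res <- list()
  if (nrow(genes)) {
    n_prom <- floor(config$cgi_promoter_frac * nrow(genes))
    pick <- sort(sample.int(nrow(genes), n_prom))
    lens <- sample(seq(config$cgi_length[1], config$cgi_length[2]),
                   length(pick), replace = TRUE)
    ## centered slightly upstream of the TSS so the island covers promoter
    ## and 5' end of the gene
    up <- ifelse(genes$strand[pick] == "+", ceiling(lens * 0.6),
                 floor(lens * 0.4))
    s <- ifelse(genes$strand[pick] == "+",
                genes$tss[pick] - up,
                genes$tss[pick] - (lens - up))
    res$prom <- data.table::data.table(
      chrom = genes$chrom[pick], start = as.integer(s),
      end = as.integer(s + lens))
  }
  ## intergenic CGIs by rejection sampling (must not touch genes nor
  ## other CGIs, with a 500 bp clearance between islands)
  n_int <- as.integer(config$n_cgi_intergenic)
  if (n_int > 0L) {
    got <- 0L; tries <- 0L; acc <- list()
    gpad <- if (nrow(genes))
      data.table::data.table(chrom = genes$chrom,
                             start = pmax(0L, genes$start - 2000L),
                             end = genes$end + 2000L)
    else NULL
    placed <- if (!is.null(res$prom)) data.table::copy(res$prom)
              else data.table::data.table(chrom = character(),
                                          start = integer(),
                                          end = integer())
    while (got < n_int && tries < 50L * n_int) {
      tries <- tries + 1L
      ci <- sample(seq_along(sizes), 1L)
      len <- sample(seq(config$cgi_length[1], config$cgi_length[2]), 1L)
      s <- sample.int(sizes[ci] - len - 2L, 1L)
      cand <- data.table::data.table(chrom = names(sizes)[ci],
                                     start = as.integer(s),
                                     end = as.integer(s + len))
      pad <- data.table::data.table(chrom = cand$chrom,
                                    start = cand$start - 500L,
                                    end = cand$end + 500L)
      if ((!is.null(gpad) && overlaps_any(pad, gpad)) ||
          overlaps_any(pad, placed)) next
      got <- got + 1L
      acc[[got]] <- cand
      placed <- rbind(placed, cand)
    }
    res$int <- data.table::rbindlist(acc)
  }
  cgi <- data.table::rbindlist(res)
  if (nrow(cgi) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer()))
  cgi[, start := pmax(0L, start)]
  cgi[, end := pmin(end, sizes[chrom])]
  data.table::setorder(cgi, chrom, start)
  cgi
}

make_cpgs <- function(sizes, cgi, config) {
  out <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    nm <- names(sizes)[ci]; L <- sizes[ci]
    n_exp <- ceiling(L / config$cpg_spacing_bg * 1.4)
    sp <- 2L + stats::rgeom(n_exp, 1 / (config$cpg_spacing_bg - 1))
    bg <- cumsum(sp)
    bg <- bg[bg < L - 2L]
    isl <- cgi[chrom == nm]
    dense <- integer()
    if (nrow(isl)) {
      for (j in seq_len(nrow(isl))) {
        m <- ceiling((isl$end[j] - isl$start[j]) / config$cpg_spacing_cgi * 1.4)
        sp2 <- 2L + stats::rgeom(m, 1 / (config$cpg_spacing_cgi - 1))
        p <- isl$start[j] + cumsum(sp2)
        dense <- c(dense, p[p < isl$end[j] - 1L])
      }
    }
    pos <- sort(unique(c(bg, dense)))
    out[[ci]] <- data.table::data.table(chrom = nm, pos = as.integer(pos))
  }
  data.table::rbindlist(out)
}

#' @export
print.toy_annotation <- function(x, ...) {
  cat("toy_annotation:", length(x$chrom_sizes), "chromosome(s),",
      sum(x$chrom_sizes), "bp;", nrow(x$genes), "genes;",
      nrow(x$cgis), "CGIs;", nrow(x$cpgs), "CpG sites\n")
  invisible(x)
}

## promoter [TSS - size, TSS) on the gene strand, clipped to the chromosome
promoter_intervals <- function(genes, promoter_size) {
  p <- genes[, .(gene_id, chrom, strand, tss)]
  p[, start := ifelse(strand == "+", tss - promoter_size, tss + 1L)]
  p[, end := ifelse(strand == "+", tss, tss + 1L + promoter_size)]
  p[, start := pmax(0L, as.integer(start))]
  p[, end := as.integer(end)]
  p[, .(gene_id, chrom, start, end, strand)]
}

#' Generate a true methylome with implanted differential regions
#'
#' Draws per-CpG true (p_m, p_h) levels shared by both groups -- 5mC bimodal
#' (low in CGIs, high in background), 5hmC low (mean about 0.05) -- and then
#' applies "implants": regions in which the tumor group's level of one
#' modality is shifted by a target delta beta. Inside an implant the
#' baseline is redrawn from the feasible window so the shifted level stays
#' in the simplex p_m + p_h <= 1 for both groups; an implant with an empty
#' feasible window raises an error naming the region.
#'
#' @param ann a \code{\link{generate_annotation}} result.
#' @param implants data.frame/data.table with columns chrom, start, end,
#'   modality ("m" or "h"), delta (signed target tumor - normal difference),
#'   and optionally gene_id. NULL for no implants.
#' @param config \code{\link{sim_config}} (baseline Beta shapes).
#' @param seed integer seed.
#' @return object of class \code{true_methylome}: \code{sites} (chrom, pos,
#'   p_m_normal, p_h_normal, p_m_tumor, p_h_tumor), \code{implants} truth
#'   table (implant_id, chrom, start, end, modality, delta, direction,
#'   n_cpg, gene_id), \code{chrom_sizes}.
#' @export
generate_true_methylome <- function(ann, implants = NULL,
                                    config = sim_config(), seed = 1) {
  stopifnot(inherits(ann, "toy_annotation"))
  seeds <- child_seeds(seed, c("baseline", "implant"))
  sites <- data.table::copy(ann$cpgs)

  with_seed(seeds["baseline"], {
    in_cgi <- overlaps_any(sites[, .(chrom, start = pos, end = pos + 2L)],
                           ann$cgis)
    pm <- numeric(nrow(sites))
    pm[in_cgi] <- stats::rbeta(sum(in_cgi), config$p_m_cgi[1],
                               config$p_m_cgi[2])
    pm[!in_cgi] <- stats::rbeta(sum(!in_cgi), config$p_m_background[1],
                                config$p_m_background[2])
    ph <- stats::rbeta(nrow(sites), config$p_h_shape[1], config$p_h_shape[2])
    ph <- pmin(ph, (1 - pm) * 0.95)
    sites[, `:=`(p_m_normal = pm, p_h_normal = ph,
                 p_m_tumor = pm, p_h_tumor = ph)]
  })

  truth <- data.table::data.table(
    implant_id = character(), chrom = character(), start = integer(),
    end = integer(), modality = character(), delta = numeric(),
    direction = character(), n_cpg = integer(), gene_id = character())

  if (!is.null(implants) && nrow(implants)) {
    imp <- data.table::as.data.table(implants)
    if (!all(c("chrom", "start", "end", "modality", "delta") %in% names(imp)))
      stopf("implants need columns chrom, start, end, modality, delta")
    if (!"gene_id" %in% names(imp)) imp[, gene_id := NA_character_]
    if (!all(imp$modality %in% c("m", "h")))
      stopf("implant modality must be 'm' or 'h'")
    eps <- 0.02
    ## implant regions must be disjoint unless byte-identical: a partial
    ## overlap would let a later baseline redraw wipe an earlier implant
    iu <- unique(imp[, .(chrom, start, end)])
    if (nrow(iu) > 1L) {
      iu2 <- data.table::copy(iu)[, end := end - 1L]
      data.table::setkey(iu2, chrom, start, end)
      ov <- data.table::foverlaps(iu2, iu2, which = TRUE)
      if (any(ov$xid != ov$yid))
        stopf("implant regions overlap without being identical; merge or separate them")
    }
    with_seed(seeds["implant"], {
      rows <- vector("list", nrow(imp))
      imp[, region_id := paste(chrom, start, end, sep = ":")]
      for (rid in unique(imp$region_id)) {
        sub <- imp[region_id == rid]
        dm <- sum(sub[modality == "m"]$delta)
        dh <- sum(sub[modality == "h"]$delta)
        idx <- sites[, which(chrom == sub$chrom[1] & pos >= sub$start[1] &
                               pos < sub$end[1])]
        if (length(idx)) {
          ## redraw the regional baseline of both marks jointly from the
          ## feasible box so both groups stay in the simplex
          lo_m <- max(eps, -dm + eps); hi_m <- min(1 - eps, 1 - dm - eps)
          lo_h <- max(eps, -dh + eps); hi_h <- min(1 - eps, 1 - dh - eps)
          S <- min(1 - eps, 1 - dm - dh - eps)
          hi_m2 <- min(hi_m, S - lo_h)
          if (hi_m2 <= lo_m || min(hi_h, S - lo_m) <= lo_h)
            stopf("infeasible implant %s (delta_m %+0.2f, delta_h %+0.2f): level would leave the simplex",
                  rid, dm, dh)
          pm <- lo_m + stats::runif(length(idx)) * (hi_m2 - lo_m)
          hih <- pmin(hi_h, S - pm)
          ph <- lo_h + stats::runif(length(idx)) * (hih - lo_h)
          sites[idx, `:=`(p_m_normal = pm, p_m_tumor = pm + dm,
                          p_h_normal = ph, p_h_tumor = ph + dh)]
        }
      }
      for (i in seq_len(nrow(imp))) {
        idx_n <- sites[, sum(chrom == imp$chrom[i] & pos >= imp$start[i] &
                               pos < imp$end[i])]
        rows[[i]] <- data.table::data.table(
          implant_id = sprintf("imp%03d", i), chrom = imp$chrom[i],
          start = as.integer(imp$start[i]), end = as.integer(imp$end[i]),
          modality = imp$modality[i], delta = imp$delta[i],
          direction = if (imp$delta[i] > 0) "up" else "down",
          n_cpg = idx_n, gene_id = imp$gene_id[i])
      }
      truth <- data.table::rbindlist(rows)
    })
  }

  ## invariant check: simplex conservation
  bad <- sites[, p_m_normal < 0 | p_h_normal < 0 |
                 p_m_normal + p_h_normal > 1 |
                 p_m_tumor < 0 | p_h_tumor < 0 | p_m_tumor + p_h_tumor > 1]
  if (any(bad)) stopf("internal error: simplex violated at %d site(s)", sum(bad))

  structure(list(sites = sites, implants = truth,
                 chrom_sizes = ann$chrom_sizes, seed = as.integer(seed)),
            class = "true_methylome")
}

#' @export
print.true_methylome <- function(x, ...) {
  cat("true_methylome:", nrow(x$sites), "CpG sites,",
      nrow(x$implants), "implanted region(s)\n")
  invisible(x)
}
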