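#' Conversion chemistry model
#'
#' Collects the conversion rates that govern how true (5mC, 5hmC) levels
#' translate into unconverted-read probabilities in each protocol arm:
#' \describe{
#'   \item{c_bs}{bisulfite conversion rate of unmodified C (read as T).}
#'   \item{c_ox}{oxidative conversion rate of 5hmC under oxBS (5hmC is
#'     oxidized to 5fC and then converted).}
#'   \item{e_m}{inappropriate (false) conversion rate of 5mC; also used for
#'     5hmC under plain BS, which is protected to a similar degree.}
#'   \item{c_f_bs, c_f_ox}{conversion rate of the 5fC spike-in class under
#'     the BS and oxBS arms.}
#' }
#' Defaults follow the spike-in regime of a typical TrueMethyl-style kit:
#' c_bs = 0.993, c_ox = 0.965, e_m = 0.035, c_f = 0.595 (BS) / 0.922 (oxBS).
#'
#' @param c_bs,c_ox,e_m,c_f_bs,c_f_ox rates in \[0, 1\].
#' @return object of class \code{conversion_model}.
#' @export
conversion_model <- function(c_bs = 0.993, c_ox = 0.965, e_m = 0.035,
                             c_f_bs = 0.595, c_f_ox = 0.922) {
  rates <- c(c_bs = c_bs, c_ox = c_ox, e_m = e_m,
             c_f_bs = c_f_bs, c_f_ox = c_f_ox)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stopf("conversion_model: all rates must lie in [0, 1]")
  structure(as.list(rates), class = "conversion_model")
}

#' Expression effect specification
#'
#' Mean log2 fold changes (tumor vs normal) attached to each promoter
#' modification pattern in the synthetic expression generator. Promoter
#' hyper-methylation represses, so up-5mC/up-5hmC genes get the strongest
#' negative fold change; unidirectional effects are larger in magnitude
#' than bidirectional ones. For unidirectional genes the effect scales
#' linearly with |delta beta| of 5hmC around \code{hmc_ref} when
#' \code{hmc_coupling} is TRUE, so larger 5hmC alterations produce larger
#' expression changes.
#'
#' @param lfc named numeric vector of pattern-level log2 fold changes.
#' @param hmc_ref reference |delta beta| of 5hmC at which the pattern lfc
#'   applies unscaled.
#' @param hmc_coupling logical; scale unidirectional effects by 5hmC
#'   alteration magnitude.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion);
#'   must be positive.
#' @param base_meanlog,base_sdlog log-normal parameters of baseline mean
#'   expression.
#' @return object of class \code{effect_spec}.
#' @export
effect_spec <- function(lfc = c("up/up" = -2, "down/down" = 0.8,
                                "up/down" = -0.5, "down/up" = 0.25,
                                "m_up" = -0.5, "m_down" = 0.25,
                                "h_up" = -0.3, "h_down" = 0.15,
                                "neutral" = 0),
                        hmc_ref = 0.15, hmc_coupling = TRUE,
                        dispersion = 0.1,
                        base_meanlog = log(300), base_sdlog = 1) {
  if (!is.numeric(dispersion) || dispersion <= 0)
    stopf("effect_spec: dispersion must be positive")
  structure(list(lfc = lfc, hmc_ref = hmc_ref, hmc_coupling = hmc_coupling,
                 dispersion = dispersion, base_meanlog = base_meanlog,
                 base_sdlog = base_sdlog),
            class = "effect_spec")
}

#' Default configuration of the synthetic toy study
#'
#' One object holding every tunable of the generator and the pipeline.
#' The defaults define the package's reference "toy study": a 2 x 500 kb
#' genome with 120 non-overlapping genes, paired tumor/normal groups of 4
#' samples sequenced at 28x per arm with realistic conversion chemistry,
#' a bimodal 5mC baseline (CGI-low, background-high) and a low (mean 0.05)
#' 5hmC baseline, 28 promoter "pattern" genes carrying paired 5mC/5hmC
#' implants, single-mark and background implants, and expression whose
#' fold changes depend on the promoter pattern.
#'
#' @param ... overrides of any default element (checked by name).
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    ## genome / annotation
    chrom_sizes       = c(chrTA = 5e5, chrTB = 5e5),
    n_genes           = 120L,
    gene_length       = c(2000L, 6000L),
    n_exons           = c(2L, 5L),
    utr5              = 200L,
    utr3              = 300L,
    promoter_size     = 1000L,
    cgi_promoter_frac = 0.6,
    n_cgi_intergenic  = 15L,
    cgi_length        = c(600L, 1200L),
    cpg_spacing_bg    = 120,
    cpg_spacing_cgi   = 15,
    ## true methylome baselines (Beta shapes)
    p_m_background    = c(7.5, 2.8),
    p_m_cgi           = c(1.5, 20),
    p_h_shape         = c(2, 38),
    ## sequencing
    model             = conversion_model(),
    depth             = 28,
    n_per_group       = 4L,
    jitter_sd         = 0.02,
    min_cov           = 10L,
    correct_conversion = TRUE,
    n_spike_pos       = 500L,
    ## implants
    patterns          = c("up/up" = 7L, "down/down" = 7L,
                          "up/down" = 7L, "down/up" = 7L),
    n_m_only          = 6L,
    n_h_only          = 6L,
    n_bg_implants     = 8L,
    delta_m           = 0.3,
    delta_h_range     = c(0.11, 0.20),
    implant_pad       = c(400L, 200L),  # upstream/downstream of promoter
    ## expression
    effect            = effect_spec(),
    frac_silent       = 0.1,
    ## dmr calling
    max_gap           = 300L,
    region_stat       = "pooled"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stopf("sim_config: unknown option(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (any(cfg$chrom_sizes < 1e4))
    stopf("sim_config: chromosome sizes must be >= 10 kb")
  structure(cfg, class = "sim_config")
}
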