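#' Pipeline configuration
#'
#' Returns the analysis thresholds used throughout the pipeline. Defaults are
#' the conventional values for cis-eQTL MR against a large case-control GWAS:
#' genome-wide significance for instrument extraction, clumping at r^2 < 0.1,
#' a +/- 1 Mb cis window around the TSS, exclusion of the MHC
#' (chr6:25,726,063-33,400,644), colocalization over +/- 500 kb with
#' priors p1 = 1e-4, p2 = 1e-4, p12 = 5e-5 and a PPH4 > 0.8 decision rule
#' (0.7 and 0.9 as reported alternates), +/- 250 kb region grouping for
#' pleiotropy, novelty at r^2 < 0.2 and +/- 250 kb from known loci, and a
#' PheWAS display threshold of p < 5e-5.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `cismr_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(pph4_threshold = 0.9)
#' cfg$clump_r2
pipeline_config <- function(...) {
  cfg <- list(
    p_instrument   = 5e-8,
    clump_r2       = 0.1,
    cis_window     = 1e6,
    mhc_chrom      = "6",
    mhc_start      = 25726063,
    mhc_end        = 33400644,
    coloc_window   = 5e5,
    pph4_threshold = 0.8,
    pph4_alternates = c(0.7, 0.9),
    region_window  = 2.5e5,
    novelty_r2     = 0.2,
    phewas_p       = 5e-5,
    p1             = 1e-4,
    p2             = 1e-4,
    p12            = 5e-5,
    f_min          = 10,
    steiger_alpha  = 0.05,
    cojo_p         = 5e-8,
    collinearity_r2 = 0.9,
    max_signals    = 10,
    # Wakefield prior effect-size variance: sd 0.15 for quantitative traits,
    # 0.2 on the log-odds scale for case-control traits
    W_quant        = 0.15^2,
    W_cc           = 0.2^2,
    maf_min        = 0.01,
    hwe_p_min      = 1e-6,
    bonferroni_alpha = 0.05
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(all(vapply(
    cfg[c("p_instrument", "clump_r2", "cis_window", "coloc_window",
          "pph4_threshold", "region_window", "novelty_r2", "phewas_p",
          "p1", "p2", "p12", "f_min", "cojo_p", "collinearity_r2")],
    function(x) is.numeric(x) && all(x > 0), logical(1))))
  structure(cfg, class = c("cismr_config", "list"))
}

#' Effective sample size of a case-control study
#'
#' `4 / (1/n_case + 1/n_control)`, the standard scaling under which
#' case-control z-scores behave like those of a quantitative trait.
#'
#' @param n_case,n_control case and control counts.
#' @return numeric effective sample size.
#' @export
n_eff_cc <- function(n_case, n_control) 4 / (1 / n_case + 1 / n_control)
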