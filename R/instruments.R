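#' Extract candidate cis-eQTL instruments for a gene
#'
#' Returns the eQTL records within the cis window of the gene's TSS that
#' reach the instrument p-value threshold and lie outside the MHC region.
#' The gene must be annotated and protein-coding (non-protein-coding genes
#' are skipped with a message).
#'
#' @param eqtl a [region_sumstats()] for the gene (quantitative trait).
#' @param annotation gene annotation tibble (`gene_id, chrom, tss,
#'   protein_coding`).
#' @param config a [pipeline_config()].
#' @return tibble of candidate records (possibly empty), or `NULL` when the
#'   gene is skipped.
#' @export
extract_candidates <- function(eqtl, annotation, config = pipeline_config()) {
  stopifnot(inherits(eqtl, "region_sumstats"))
  a <- annotation[annotation$gene_id == eqtl$gene_id, ]
  if (nrow(a) == 0) stop("gene not in annotation: ", eqtl$gene_id)
  if (!a$protein_coding[1]) {
    message("skipping non-protein-coding gene ", eqtl$gene_id)
    return(NULL)
  }
  s <- eqtl$stats
  in_cis <- s$chrom == a$chrom[1] &
    s$pos >= a$tss[1] - config$cis_window & s$pos <= a$tss[1] + config$cis_window
  in_mhc <- s$chrom == config$mhc_chrom &
    s$pos >= config$mhc_start & s$pos <= config$mhc_end
  s[in_cis & !in_mhc & s$pvalue < config$p_instrument, ]
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining variant with the smallest p-value as an
#' index variant and removes all remaining variants with reference-panel
#' r^2 >= `r2_max` against it. Ties on p-value are broken by position, then
#' alleles, so the output is invariant to input ordering. Variants absent
#' from the panel are dropped with a message (their LD cannot be assessed).
#'
#' @param candidates tibble of variant records (needs `rsid, pos, ea, oa,
#'   pvalue`).
#' @param panel a [ref_panel()].
#' @param r2_max clumping threshold (default 0.1).
#' @return the selected rows of `candidates`, in selection order.
#' @export
clump <- function(candidates, panel, r2_max = 0.1) {
  if (is.null(candidates) || nrow(candidates) == 0) return(candidates)
  in_panel <- candidates$rsid %in% panel$variants$rsid
  if (any(!in_panel))
    message(sum(!in_panel), " candidate(s) dropped: absent from LD panel")
  cand <- candidates[in_panel, ]
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(cand$pvalue, cand$pos, cand$ea, cand$oa), ]
  R2 <- ld_corr(panel, cand$rsid)^2
  picked <- integer(0)
  remaining <- seq_len(nrow(cand))
  while (length(remaining)) {
    i <- remaining[1]  # smallest p among remaining (sorted order)
    picked <- c(picked, i)
    remaining <- remaining[R2[remaining, i] < r2_max & remaining != i]
  }
  cand[picked, ]
}

#' Instrument strength F-statistic
#'
#' Single-variant approximation `F = (beta/se)^2`; instruments
#' conventionally require `F > 10`.
#'
#' @param beta,se exposure effect and standard error.
#' @return numeric F.
#' @export
f_statistic <- function(beta, se) (beta / se)^2

#' Steiger directionality test
#'
#' Compares the variance in the exposure explained by a variant,
#' `r2 = z^2 / (z^2 + n)`, with the variance explained in the outcome
#' (using the effective sample size for case-control outcomes). The
#' direction is exposure -> outcome iff `r2_exp > r2_out` (ties resolved
#' against); the p-value is a two-sided z-test on Fisher-z transformed
#' |correlations| with variances `1/(n-3)`.
#'
#' @param z_exp,n_exp exposure z-score and sample size.
#' @param z_out,n_out outcome z-score and (effective) sample size.
#' @return list with `direction` (logical) and `p`.
#' @export
steiger <- function(z_exp, n_exp, z_out, n_out) {
  if (any(c(n_exp, n_out) <= 3)) stop("Steiger test requires n > 3")
  r2_exp <- z_exp^2 / (z_exp^2 + n_exp)
  r2_out <- z_out^2 / (z_out^2 + n_out)
  fz <- function(r2) atanh(sqrt(r2))
  zstat <- (fz(r2_exp) - fz(r2_out)) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(direction = r2_exp > r2_out, p = 2 * pnorm(-abs(zstat)))
}

#' Build cis-eQTL instruments for every gene x dataset
#'
#' Composition of the selection pipeline: extract candidates (significance,
#' cis window, MHC, protein-coding), clump, harmonize to the outcome, then
#' keep variants with `F > f_min` and a significant exposure -> outcome
#' Steiger test. Gene x dataset combinations with no surviving variant are
#' omitted.
#'
#' @param eqtl_list list of [region_sumstats()] eQTL objects (each carries
#'   `gene_id`, `dataset_id`, `cell_type`).
#' @param outcome the outcome [region_sumstats()] (case_control or
#'   quantitative).
#' @param annotation gene annotation tibble.
#' @param panel a [ref_panel()] for LD.
#' @param config a [pipeline_config()].
#' @return tibble, one row per instrumental variant: gene, dataset,
#'   cell_type, rsid, chrom, pos, ea, oa, eaf, exposure and outcome
#'   beta/se/p, n_exp, n_out_eff, F, steiger_dir, steiger_p.
#' @export
build_instruments <- function(eqtl_list, outcome, annotation, panel,
                              config = pipeline_config()) {
  rows <- list()
  for (eqtl in eqtl_list) {
    cand <- extract_candidates(eqtl, annotation, config)
    if (is.null(cand) || nrow(cand) == 0) next
    sel <- clump(cand, panel, r2_max = config$clump_r2)
    if (nrow(sel) == 0) next
    exp_sel <- eqtl
    exp_sel$stats <- eqtl$stats[eqtl$stats$rsid %in% sel$rsid, ]
    h <- harmonize_pair(exp_sel, outcome)
    if (nrow(h) == 0) next
    n_out <- if (outcome$trait_type == "case_control" &&
                 all(!is.na(h$n_case_out)))
      n_eff_cc(h$n_case_out, h$n_control_out) else h$n_out
    Fstat <- f_statistic(h$beta_exp, h$se_exp)
    st <- vapply(seq_len(nrow(h)), function(i)
      unlist(steiger(h$beta_exp[i] / h$se_exp[i], h$n_exp[i],
                     h$beta_out[i] / h$se_out[i], n_out[i])),
      numeric(2))
    rownames(st) <- c("direction", "p")
    keep <- Fstat > config$f_min & st["direction", ] > 0 &
      st["p", ] < config$steiger_alpha
    if (!any(keep)) next
    h <- h[keep, ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene_id = eqtl$gene_id, dataset_id = eqtl$dataset_id,
      cell_type = eqtl$cell_type,
      rsid = h$rsid, chrom = h$chrom, pos = h$pos, ea = h$ea, oa = h$oa,
      eaf = h$eaf_exp,
      beta_exp = h$beta_exp, se_exp = h$se_exp, p_exp = h$p_exp, n_exp = h$n_exp,
      beta_out = h$beta_out, se_out = h$se_out, p_out = h$p_out,
      n_out_eff = n_out[keep],
      F = Fstat[keep], steiger_dir = st["direction", keep] > 0,
      steiger_p = st["p", keep])
  }
  if (!length(rows))
    return(tibble::tibble(gene_id = character(0), dataset_id = character(0)))
  dplyr::bind_rows(rows)
}
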