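#' Fixed-effect meta-analysis of two GWAS (METAL effect-size scheme)
#'
#' Variants shared by the two studies are harmonized to a common effect
#' allele and combined by inverse-variance weighting
#' (`w_i = 1/se_i^2`, `beta = sum(w b)/sum(w)`, `se = 1/sqrt(sum(w))`);
#' variants present in only one study are carried through unchanged. The
#' operation is associative for equal-allele inputs.
#'
#' @param gwas1,gwas2 [region_sumstats()] case-control GWAS on the same
#'   chromosome.
#' @param trait_id label for the result.
#' @return a [region_sumstats()] with combined estimates; column
#'   `n_studies` records how many studies contributed per variant.
#' @export
meta_fixed <- function(gwas1, gwas2, trait_id = "meta") {
  h <- harmonize_pair(gwas1, gwas2)
  if (nrow(h)) {
    w1 <- 1 / h$se_exp^2; w2 <- 1 / h$se_out^2
    beta <- (w1 * h$beta_exp + w2 * h$beta_out) / (w1 + w2)
    se <- 1 / sqrt(w1 + w2)
    n1 <- gwas1$stats[match(h$pos, gwas1$stats$pos), ]
    n2 <- gwas2$stats[match(h$pos, gwas2$stats$pos), ]
    both <- tibble::tibble(
      chrom = h$chrom, pos = h$pos, rsid = h$rsid, ea = h$ea, oa = h$oa,
      eaf = (h$eaf_exp + h$eaf_out) / 2,
      beta = beta, se = se, pvalue = 2 * pnorm(-abs(beta / se)),
      n = n1$n + n2$n,
      n_case = n1$n_case + n2$n_case, n_control = n1$n_control + n2$n_control,
      n_studies = 2L)
  } else both <- NULL
  # single-study variants pass through unchanged; shared positions that
  # failed harmonization (palindromic/irreconcilable) are dropped
  only <- function(g, other) {
    s <- g$stats[!g$stats$pos %in% other$stats$pos, ]
    if (nrow(s) == 0) return(NULL)
    s$n_studies <- 1L
    s
  }
  stats <- dplyr::bind_rows(both, only(gwas1, gwas2), only(gwas2, gwas1))
  if (is.null(stats) || nrow(stats) == 0) stop("meta-analysis produced no variants")
  out <- region_sumstats(stats[setdiff(names(stats), "n_studies")],
                         trait_id = trait_id, trait_type = gwas1$trait_type,
                         validate = FALSE)
  out$stats$n_studies <- stats$n_studies[match(out$stats$pos, stats$pos)]
  out
}

#' Replication MR for prioritized genes
#'
#' Re-selects instruments from a replication eQTL source (same rules as
#' the primary analysis), runs MR against the (meta-analyzed) replication
#' outcome, and reports per gene the estimate, p-value, directional
#' concordance with the primary estimate (sign match), and a flag for the
#' p < 0.1 reporting threshold. Genes with no qualifying cis-eQTL are
#' reported as `"no instrument"`. Primary results are read-only inputs.
#'
#' @param genes tibble with `gene_id` and primary `beta_mr` (one row per
#'   prioritized gene; for genes passing in several datasets supply the
#'   representative estimate).
#' @param repl_eqtl list of replication [region_sumstats()] eQTL objects.
#' @param outcome replication outcome [region_sumstats()] (e.g. from
#'   [meta_fixed()]).
#' @param annotation gene annotation tibble.
#' @param panel a [ref_panel()] for the replication LD.
#' @param config a [pipeline_config()].
#' @param p_report reporting threshold (default 0.1).
#' @return tibble: gene_id, status (`"tested"`/`"no instrument"`),
#'   n_variants, beta_repl, se_repl, p_repl, directionally_concordant,
#'   p_below_report.
#' @export
replicate_mr <- function(genes, repl_eqtl, outcome, annotation, panel,
                         config = pipeline_config(), p_report = 0.1) {
  instr <- build_instruments(repl_eqtl, outcome, annotation, panel, config)
  mr <- mr_analyze(instr)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    m <- mr[mr$gene_id == g, ]
    if (nrow(m) == 0) {
      return(tibble::tibble(gene_id = g, status = "no instrument",
                            n_variants = 0L, beta_repl = NA_real_,
                            se_repl = NA_real_, p_repl = NA_real_,
                            directionally_concordant = NA,
                            p_below_report = NA))
    }
    m <- m[which.min(m$pvalue), ]
    tibble::tibble(gene_id = g, status = "tested",
                   n_variants = m$n_variants,
                   beta_repl = m$beta_mr, se_repl = m$se_mr, p_repl = m$pvalue,
                   directionally_concordant =
                     sign(m$beta_mr) == sign(genes$beta_mr[i]),
                   p_below_report = m$pvalue < p_report)
  })
  dplyr::bind_rows(rows)
}
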