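#' Wald ratio MR estimate
#'
#' `beta = b_out / b_exp`, with the first-order delta-method standard error
#' `se = se_out / |b_exp|` (exposure uncertainty ignored, standard
#' two-sample cis-MR practice) and a two-sided normal p-value.
#'
#' @param b_exp,se_exp exposure association (b_exp must be non-zero).
#' @param b_out,se_out outcome association on the same effect allele.
#' @return list `beta, se, p`.
#' @export
wald_ratio <- function(b_exp, se_exp, b_out, se_out) {
  if (any(b_exp == 0)) stop("Wald ratio undefined for zero exposure effect")
  beta <- b_out / b_exp
  se <- se_out / abs(b_exp)
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)))
}

#' Fixed-effect inverse-variance-weighted meta-analysis of ratio estimates
#'
#' `w_j = 1/se_j^2`; `beta = sum(w beta_j)/sum(w)`; `se = 1/sqrt(sum(w))`.
#' With a single ratio this reduces exactly to that ratio.
#'
#' @param beta,se vectors of variant-level MR estimates and SEs.
#' @return list `beta, se, p`.
#' @export
ivw_fixed <- function(beta, se) {
  stopifnot(length(beta) >= 1, length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s, p = 2 * pnorm(-abs(b / s)))
}

#' Cochran's Q heterogeneity across variant-level estimates
#'
#' `Q = sum(w_j (beta_j - beta_ivw)^2)` against chi-square with k-1 df;
#' `I2 = max(0, (Q - (k-1))/Q)`. Heterogeneous variants are reported, not
#' removed.
#'
#' @param beta,se vectors of variant-level MR estimates and SEs (k >= 2).
#' @return list `Q, Q_p, I2`.
#' @export
cochran_q <- function(beta, se) {
  k <- length(beta)
  stopifnot(k >= 2, length(se) == k)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  list(Q = Q, Q_p = pchisq(Q, df = k - 1, lower.tail = FALSE), I2 = I2)
}

#' Per-(gene, dataset) MR estimates from an instrument table
#'
#' Applies the Wald ratio for single-variant instruments and fixed-effect
#' IVW with Cochran's Q / I2 for multi-variant instruments.
#'
#' @param instruments tibble from [build_instruments()].
#' @return tibble: gene_id, dataset_id, cell_type, method (`wald` or
#'   `ivw_fe`), beta_mr, se_mr, pvalue, n_variants, Q, Q_p, I2 (NA for
#'   single-variant instruments).
#' @export
mr_analyze <- function(instruments) {
  if (nrow(instruments) == 0)
    return(tibble::tibble(gene_id = character(0), dataset_id = character(0)))
  groups <- split(instruments,
                  paste(instruments$gene_id, instruments$dataset_id, sep = "\r"))
  rows <- lapply(groups, function(g) {
    wr <- wald_ratio(g$beta_exp, g$se_exp, g$beta_out, g$se_out)
    k <- nrow(g)
    if (k == 1) {
      tibble::tibble(gene_id = g$gene_id[1], dataset_id = g$dataset_id[1],
                     cell_type = g$cell_type[1], method = "wald",
                     beta_mr = wr$beta, se_mr = wr$se, pvalue = wr$p,
                     n_variants = 1L, Q = NA_real_, Q_p = NA_real_, I2 = NA_real_)
    } else {
      est <- ivw_fixed(wr$beta, wr$se)
      het <- cochran_q(wr$beta, wr$se)
      tibble::tibble(gene_id = g$gene_id[1], dataset_id = g$dataset_id[1],
                     cell_type = g$cell_type[1], method = "ivw_fe",
                     beta_mr = est$beta, se_mr = est$se, pvalue = est$p,
                     n_variants = k, Q = het$Q, Q_p = het$Q_p, I2 = het$I2)
    }
  })
  res <- dplyr::bind_rows(rows)
  res[order(res$gene_id, res$dataset_id), ]
}

#' Dataset-specific Bonferroni significance flags
#'
#' Within each dataset the threshold is `alpha` divided by the number of
#' unique genes tested in that dataset.
#'
#' @param results tibble from [mr_analyze()].
#' @param alpha family-wise error rate (default 0.05).
#' @return `results` with columns `bonf_threshold` and `significant`.
#' @export
bonferroni_flag <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) {
    results$bonf_threshold <- numeric(0); results$significant <- logical(0)
    return(results)
  }
  n_genes <- tapply(results$gene_id, results$dataset_id,
                    function(g) length(unique(g)))
  results$bonf_threshold <- alpha / as.numeric(n_genes[results$dataset_id])
  results$significant <- results$pvalue < results$bonf_threshold
  results
}
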