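# Approximate conditional/joint analysis from marginal summary statistics
# plus a reference LD panel. With D_j = 2*eaf_j*(1-eaf_j)*n_j (the implied
# genotype sum of squares) and B_jk = r_jk*sqrt(D_j*D_k) (the implied
# X'X), joint estimates are the summary-data normal equations
# betaJ = B^{-1} diag(D) b. The implied phenotypic sum of squares per
# variant is y'y_j = D_j*(se_j^2*(n_j-2) + b_j^2), so a single-variant
# joint model reproduces its marginal beta and se exactly.

# Align region summary stats with the panel: keep variants present in the
# panel with reconcilable alleles and consistent allele frequency; return
# stats rows, effect-allele-aligned LD matrix and the D/b/se vectors.
cojo_prep <- function(region, panel, freq_tol = 0.2) {
  s <- region$stats
  idx <- match(s$rsid, panel$variants$rsid)
  by_pos <- is.na(idx)
  if (any(by_pos)) {  # fall back to position matching
    idx[by_pos] <- match(s$pos[by_pos], panel$variants$pos)
  }
  keep <- !is.na(idx)
  pv <- panel$variants[idx[keep], ]
  sk <- s[keep, ]
  same <- sk$ea == pv$ea & sk$oa == pv$oa
  swap <- sk$ea == pv$oa & sk$oa == pv$ea
  ok <- same | swap
  sk <- sk[ok, ]; pv <- pv[ok, ]; same <- same[ok]
  panel_eaf_aligned <- ifelse(same, pv$eaf, 1 - pv$eaf)
  eaf <- ifelse(is.na(sk$eaf), panel_eaf_aligned, sk$eaf)
  fr_ok <- abs(eaf - panel_eaf_aligned) <= freq_tol
  if (any(!fr_ok))
    message(sum(!fr_ok), " variant(s) excluded: allele frequency mismatch with panel")
  sk <- sk[fr_ok, ]; pv <- pv[fr_ok, ]; eaf <- eaf[fr_ok]
  n_drop <- nrow(s) - nrow(sk)
  if (nrow(sk) == 0) stop("no region variants usable with the LD panel")
  R <- ld_corr(panel, pv$rsid, effect_allele = setNames(sk$ea, pv$rsid))
  D <- 2 * eaf * (1 - eaf) * sk$n
  list(stats = sk, panel_rsid = pv$rsid, R = R, D = D,
       b = sk$beta, se = sk$se, n = sk$n,
       yty = D * (sk$se^2 * (sk$n - 2) + sk$beta^2),
       dropped = n_drop)
}

cojo_fit_core <- function(prep, sel) {
  k <- length(sel)
  R <- prep$R[sel, sel, drop = FALSE]
  D <- prep$D[sel]
  off <- abs(R[upper.tri(R)])
  if (k > 1 && any(off^2 >= attr(prep, "collinearity_r2"))) {
    pair <- which(upper.tri(R) & abs(R)^2 >= attr(prep, "collinearity_r2"),
                  arr.ind = TRUE)[1, ]
    stop("collinear selected variants: ",
         prep$stats$rsid[sel[pair[1]]], " and ", prep$stats$rsid[sel[pair[2]]])
  }
  B <- R * tcrossprod(sqrt(D))
  diag(B) <- D
  Db <- D * prep$b[sel]
  betaJ <- unname(drop(solve(B, Db)))
  n <- median(prep$n[sel])
  yty <- median(prep$yty[sel])
  rss <- max(yty - sum(betaJ * Db), yty * 1e-12)
  sigma2 <- rss / (n - k - 1)
  covJ <- sigma2 * solve(B)
  seJ <- unname(sqrt(diag(covJ)))
  list(sel = sel, beta = betaJ, se = seJ,
       p = 2 * pnorm(-abs(betaJ / seJ)), sigma2 = sigma2, B = B, n = n)
}

#' Joint (multi-variant) model from marginal statistics and reference LD
#'
#' Fits the selected variants jointly using the summary-data normal
#' equations (COJO-style): reference LD supplies the genotype
#' cross-products, summary allele frequencies and sample sizes supply the
#' scale. Selected variants with pairwise reference r^2 at or above the
#' collinearity ceiling are an error (naming the offending pair); variants
#' whose allele frequency disagrees with the panel by more than 0.2 are
#' excluded with a message.
#'
#' @param region a [region_sumstats()].
#' @param panel a [ref_panel()].
#' @param ids rsids of the selected variants (must be in region and panel).
#' @param config a [pipeline_config()] (`collinearity_r2`).
#' @return list of class `cojo_model`: `rsid`, `ea`, `beta_marginal`,
#'   `beta_joint`, `se_joint`, `p_joint`, `sigma2`, `n`.
#' @export
cojo_fit <- function(region, panel, ids, config = pipeline_config()) {
  if (anyDuplicated(ids)) stop("collinear selected variants: duplicated id ",
                               ids[duplicated(ids)][1])
  prep <- cojo_prep(region, panel)
  attr(prep, "collinearity_r2") <- config$collinearity_r2
  sel <- match(ids, prep$stats$rsid)
  if (anyNA(sel)) stop("selected variant(s) not usable: ",
                       paste(ids[is.na(sel)], collapse = ", "))
  fit <- cojo_fit_core(prep, sel)
  structure(list(rsid = prep$stats$rsid[sel], ea = prep$stats$ea[sel],
                 beta_marginal = prep$b[sel],
                 beta_joint = fit$beta, se_joint = fit$se, p_joint = fit$p,
                 sigma2 = fit$sigma2, n = fit$n,
                 p_cutoff = config$cojo_p, collinearity_r2 = config$collinearity_r2),
            class = "cojo_model")
}

# Conditional stats of every variant not in C given the model C.
# Conditional beta_j = (D_j b_j - B_jC betaJ_C) / denom_j with
# denom_j = D_j - B_jC B_CC^{-1} B_Cj; the SE uses the variant's own
# marginal residual variance (se_j^2 * D_j), which leaves orthogonal
# variants' statistics exactly unchanged.
cojo_condition_core <- function(prep, C) {
  j <- setdiff(seq_len(nrow(prep$stats)), C)
  if (!length(C)) {
    return(list(idx = j, beta = prep$b[j], se = prep$se[j],
                p = 2 * pnorm(-abs(prep$b[j] / prep$se[j]))))
  }
  sD <- sqrt(prep$D)
  B_CC <- prep$R[C, C, drop = FALSE] * tcrossprod(sD[C])
  diag(B_CC) <- prep$D[C]
  B_jC <- prep$R[j, C, drop = FALSE] * (sD[j] %o% sD[C])
  betaJ_C <- drop(solve(B_CC, prep$D[C] * prep$b[C]))
  M <- B_jC %*% solve(B_CC)
  denom <- unname(prep$D[j] - rowSums(M * B_jC))
  denom <- pmax(denom, prep$D[j] * 1e-10)
  beta <- unname((prep$D[j] * prep$b[j] - drop(B_jC %*% betaJ_C)) / denom)
  se <- unname(sqrt(prep$se[j]^2 * prep$D[j] / denom))
  list(idx = j, beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)))
}

#' Conditional summary statistics given a set of model variants
#'
#' Returns per-variant conditional beta/se/p for every non-conditioning
#' variant, holding the conditioning set in the model. An empty
#' conditioning set is the identity; conditioning on a variant
#' uncorrelated with the rest leaves all statistics unchanged.
#'
#' @param region a [region_sumstats()].
#' @param panel a [ref_panel()].
#' @param ids rsids of the conditioning variants (may be empty).
#' @param config a [pipeline_config()].
#' @return a [region_sumstats()] of the non-conditioning variants with
#'   conditional estimates; attribute `conditioned_on` records `ids`.
#' @export
cojo_condition <- function(region, panel, ids, config = pipeline_config()) {
  prep <- cojo_prep(region, panel)
  C <- match(ids, prep$stats$rsid)
  if (anyNA(C)) stop("conditioning variant(s) not usable: ",
                     paste(ids[is.na(C)], collapse = ", "))
  cond <- cojo_condition_core(prep, C)
  s <- prep$stats[cond$idx, ]
  s$beta <- cond$beta
  s$se <- cond$se
  s$pvalue <- cond$p
  out <- region
  out$stats <- s
  attr(out, "conditioned_on") <- ids
  out
}

#' Stepwise model selection from marginal statistics (COJO-style)
#'
#' Forward selection with backward elimination: seed with the smallest-p
#' variant if below `p_cutoff`; then repeatedly compute every remaining
#' variant's conditional p given the current model, add the smallest if
#' below the cutoff (skipping candidates with reference r^2 >= the
#' collinearity ceiling against any model variant), and after each
#' addition drop any model variant whose joint p rises above the cutoff;
#' iterate to a fixed point. The number of signals is capped at
#' `config$max_signals`.
#'
#' @param region a [region_sumstats()].
#' @param panel a [ref_panel()].
#' @param config a [pipeline_config()].
#' @param p_cutoff selection threshold (default `config$cojo_p`).
#' @return a `cojo_model` (empty `rsid` if nothing is selected).
#' @export
cojo_select <- function(region, panel, config = pipeline_config(),
                        p_cutoff = config$cojo_p) {
  prep <- cojo_prep(region, panel)
  attr(prep, "collinearity_r2") <- config$collinearity_r2
  m <- nrow(prep$stats)
  p_marg <- 2 * pnorm(-abs(prep$b / prep$se))
  model <- integer(0)
  if (min(p_marg) < p_cutoff) model <- which.min(p_marg)
  if (length(model)) {
    for (iter in seq_len(50L)) {
      changed <- FALSE
      if (length(model) < config$max_signals) {
        cond <- cojo_condition_core(prep, model)
        r2max <- apply(prep$R[cond$idx, model, drop = FALSE]^2, 1, max)
        eligible <- r2max < config$collinearity_r2
        if (any(eligible) && min(cond$p[eligible]) < p_cutoff) {
          pick <- cond$idx[eligible][which.min(cond$p[eligible])]
          model <- c(model, pick)
          changed <- TRUE
        }
      }
      repeat {  # backward elimination on joint p-values
        fit <- cojo_fit_core(prep, model)
        if (length(model) <= 1 || all(fit$p < p_cutoff)) break
        model <- model[-which.max(fit$p)]
        changed <- TRUE
      }
      if (!changed) break
    }
  }
  ids <- prep$stats$rsid[model]
  if (!length(ids)) {
    return(structure(list(rsid = character(0), ea = character(0),
                          beta_marginal = numeric(0), beta_joint = numeric(0),
                          se_joint = numeric(0), p_joint = numeric(0),
                          sigma2 = NA_real_, n = NA_real_,
                          p_cutoff = p_cutoff,
                          collinearity_r2 = config$collinearity_r2),
                     class = "cojo_model"))
  }
  cojo_fit(region, panel, ids, config)
}

#' @export
print.cojo_model <- function(x, ...) {
  cat(sprintf("<cojo_model> %d selected signal(s)%s\n", length(x$rsid),
              if (length(x$rsid)) paste0(": ", paste(x$rsid, collapse = ", ")) else ""))
  invisible(x)
}
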