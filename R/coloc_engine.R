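#' Wakefield log approximate Bayes factor
#'
#' For a variant with estimate `beta`, standard error `se` (so `V = se^2`,
#' `z = beta/se`) and prior effect-size variance `W`, the log ABF of
#' association against the null is
#' `0.5 * (log(1 - r) + z^2 * r)` with `r = W/(V + W)`.
#'
#' @param beta,se estimate and standard error (vectorized).
#' @param W prior variance of the true effect.
#' @return numeric vector of log ABFs.
#' @export
wakefield_labf <- function(beta, se, W) {
  V <- se^2
  r <- W / (V + W)
  z2 <- (beta / se)^2
  0.5 * (log1p(-r) + z2 * r)
}

logsumexp <- function(x) {
  x <- x[!is.na(x) & x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Colocalization posteriors from two ABF tracks
#'
#' Enumeration-equivalent posterior probabilities of the five
#' colocalization hypotheses for two traits measured over an identical
#' variant list: H0 no association with either trait; H1/H2 association
#' with one trait only; H3 both traits, different causal variants; H4 a
#' shared causal variant. Per-SNP priors `p1`, `p2` (single-trait) and
#' `p12` (shared) are applied per configuration; all sums are computed in
#' log space.
#'
#' @param labf1,labf2 per-variant log ABFs for the two traits (equal
#'   length, same variant order).
#' @param p1,p2,p12 per-SNP prior probabilities.
#' @return list of class `coloc_result`: `pph0..pph4` (sum to 1),
#'   `n_variants`, `mode` (`"marginal"` unless set downstream),
#'   `conditioned_on` (empty list for marginal).
#' @export
coloc_abf <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4, p12 = 5e-5) {
  m <- length(labf1)
  if (m == 0) stop("colocalization requires at least one shared variant")
  stopifnot(length(labf2) == m)
  S1 <- logsumexp(labf1)
  S2 <- logsumexp(labf2)
  S12 <- logsumexp(labf1 + labf2)
  h <- c(h0 = 0,
         h1 = log(p1) + S1,
         h2 = log(p2) + S2,
         h3 = -Inf,
         h4 = log(p12) + S12)
  if (m >= 2) {
    d <- S12 - (S1 + S2)   # <= 0 since all terms are positive
    h["h3"] <- if (d < -1e-12)
      log(p1) + log(p2) + S1 + S2 + log1p(-exp(d)) else -Inf
  }
  denom <- logsumexp(h)
  post <- exp(h - denom)
  structure(list(pph0 = post[["h0"]], pph1 = post[["h1"]], pph2 = post[["h2"]],
                 pph3 = post[["h3"]], pph4 = post[["h4"]],
                 n_variants = m, mode = "marginal",
                 conditioned_on = list(trait1 = character(0), trait2 = character(0))),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s, %d variants | PPH0-4: %s\n", x$mode,
              x$n_variants,
              paste(sprintf("%.3f", c(x$pph0, x$pph1, x$pph2, x$pph3, x$pph4)),
                    collapse = " ")))
  invisible(x)
}

# Match two summary-stat tables on (pos, reconcilable alleles); returns the
# row indices into each. Orientation does not matter for ABFs.
shared_variant_index <- function(s1, s2) {
  m <- match(s1$pos, s2$pos)
  i1 <- which(!is.na(m)); i2 <- m[i1]
  ok <- (s1$ea[i1] == s2$ea[i2] & s1$oa[i1] == s2$oa[i2]) |
    (s1$ea[i1] == s2$oa[i2] & s1$oa[i1] == s2$ea[i2])
  list(i1 = i1[ok], i2 = i2[ok])
}

#' Colocalization of two regional traits
#'
#' Convenience wrapper: intersects the two traits' variants on position and
#' alleles, builds Wakefield ABF tracks with the trait-appropriate prior
#' variance (`W_quant` for quantitative, `W_cc` for case-control traits),
#' and calls [coloc_abf()].
#'
#' @param ss1,ss2 [region_sumstats()] objects.
#' @param config a [pipeline_config()] (priors and W values).
#' @return a `coloc_result`.
#' @export
coloc_region <- function(ss1, ss2, config = pipeline_config()) {
  idx <- shared_variant_index(ss1$stats, ss2$stats)
  if (!length(idx$i1)) stop("no shared variants between traits")
  W1 <- if (ss1$trait_type == "case_control") config$W_cc else config$W_quant
  W2 <- if (ss2$trait_type == "case_control") config$W_cc else config$W_quant
  l1 <- wakefield_labf(ss1$stats$beta[idx$i1], ss1$stats$se[idx$i1], W1)
  l2 <- wakefield_labf(ss2$stats$beta[idx$i2], ss2$stats$se[idx$i2], W2)
  coloc_abf(l1, l2, config$p1, config$p2, config$p12)
}
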