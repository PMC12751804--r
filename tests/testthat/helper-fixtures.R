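# Small in-code fixture builders shared across tests.

# A summary-stat tibble with sensible defaults, overridable per column.
ss_rows <- function(n = 3, chrom = "1", pos = NULL, rsid = NULL,
                    ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.02,
                    pvalue = NULL, n_samp = 500, n_case = NA, n_control = NA) {
  pos <- pos %||% (1e6 + (seq_len(n) - 1) * 1000)
  rsid <- rsid %||% sprintf("rs%03d", seq_len(n))
  out <- tibble::tibble(chrom = chrom, pos = pos, rsid = rsid,
                        ea = ea, oa = oa, eaf = eaf, beta = beta, se = se,
                        pvalue = pvalue %||% (2 * stats::pnorm(-abs(beta / se))),
                        n = n_samp, n_case = n_case, n_control = n_control)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_region <- function(..., trait_id = "t", trait_type = "quantitative",
                        gene_id = "gene1", dataset_id = "d1", validate = TRUE) {
  region_sumstats(ss_rows(...), trait_id = trait_id, trait_type = trait_type,
                  gene_id = gene_id, dataset_id = dataset_id,
                  cell_type = "cell", validate = validate)
}

# A panel built from an explicit dosage matrix.
make_panel <- function(dosages, chrom = "1", pos = NULL, ea = "A", oa = "G") {
  m <- ncol(dosages)
  ref_panel(tibble::tibble(chrom = chrom,
                           pos = pos %||% (1e6 + (seq_len(m) - 1) * 1000),
                           rsid = sprintf("pv%03d", seq_len(m)),
                           ea = ea, oa = oa),
            dosages)
}

# Independent binomial dosage columns (no LD).
random_panel <- function(n = 500, m = 10, maf = 0.3, seed = 1) {
  set.seed(seed)
  make_panel(matrix(stats::rbinom(n * m, 2, maf), n, m))
}

# Brute-force coloc enumeration over all per-SNP configuration pairs:
# the independent oracle for coloc_abf. Bayes factors are rescaled by
# their per-trait maximum before exponentiating (posteriors are invariant
# once every hypothesis term is divided by the same product), so extreme
# z-scores do not overflow.
enumerate_coloc <- function(labf1, labf2, p1, p2, p12) {
  m1 <- max(labf1); m2 <- max(labf2)
  bf1 <- exp(labf1 - m1); bf2 <- exp(labf2 - m2)
  m <- length(bf1)
  h0 <- exp(-(m1 + m2))
  h1 <- sum(p1 * bf1) * exp(-m2)
  h2 <- sum(p2 * bf2) * exp(-m1)
  h3 <- 0
  for (j in seq_len(m)) for (k in seq_len(m)) if (j != k)
    h3 <- h3 + p1 * p2 * bf1[j] * bf2[k]
  h4 <- sum(p12 * bf1 * bf2)
  u <- c(h0, h1, h2, h3, h4)
  u / sum(u)
}

# Independently coded greedy clumping reference (set semantics, not
# selection-order): smallest p wins, removes r2 >= cutoff neighbours.
greedy_clump_reference <- function(pvals, R2, r2_max) {
  alive <- seq_along(pvals)
  kept <- integer(0)
  while (length(alive) > 0) {
    i <- alive[order(pvals[alive])[1]]
    kept <- c(kept, i)
    alive <- setdiff(alive, c(i, alive[R2[i, alive] >= r2_max]))
  }
  sort(kept)
}

# A cohort with known genotypes, its marginal summary stats via per-variant
# OLS (independent of package internals), and the cohort itself as panel.
make_cohort <- function(n = 2000, m = 20, n_causal = 3, b = 0.12, seed = 1,
                        rho = 0.6) {
  set.seed(seed)
  maf <- runif(m, 0.1, 0.5)
  Z <- matrix(rnorm(2 * n * m), 2 * n)
  for (j in 2:m) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
  H <- sweep(Z, 2, qnorm(maf), "<") * 1
  X <- H[1:n, ] + H[n + 1:n, ]
  causal <- round(seq(2, m - 1, length.out = n_causal))
  y <- X[, causal, drop = FALSE] %*% rep(b, n_causal) + rnorm(n)
  marg <- t(vapply(seq_len(m), function(j) {
    f <- summary(lm(y ~ X[, j]))$coefficients
    c(f[2, 1], f[2, 2])
  }, numeric(2)))
  panel <- make_panel(X)
  region <- region_sumstats(
    tibble::tibble(chrom = "1", pos = panel$variants$pos,
                   rsid = panel$variants$rsid, ea = "A", oa = "G",
                   eaf = colMeans(X) / 2, beta = marg[, 1], se = marg[, 2],
                   pvalue = 2 * pnorm(-abs(marg[, 1] / marg[, 2])), n = n),
    trait_id = "y", validate = FALSE)
  list(X = X, y = y, causal = causal, panel = panel, region = region)
}
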