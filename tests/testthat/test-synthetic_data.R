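test_that("panel simulation is seed-deterministic and respects the block LD targets", {
  spec <- scenario_spec("null", n_variants = 40, n_ref = 800, seed = 21)
  p1 <- simulate_panel(spec)
  p2 <- simulate_panel(spec)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$variants, p2$variants)

  # rho = 0: essentially no LD anywhere at large n_ref
  spec0 <- scenario_spec("null", n_variants = 30, block_size = 10, rho = 0,
                         n_ref = 5000, seed = 22)
  R <- cor(simulate_panel(spec0)$dosages)
  expect_lt(mean(abs(R[upper.tri(R)])), 0.05)

  # across-block LD ~ 0 even at high rho
  spec9 <- scenario_spec("null", n_variants = 40, block_size = 20, rho = 0.9,
                         n_ref = 4000, seed = 23)
  p9 <- simulate_panel(spec9)
  R9 <- cor(p9$dosages)
  expect_lt(mean(abs(R9[1:20, 21:40])), 0.05)
})

test_that("adjacent-variant LD matches a Monte-Carlo oracle of the threshold model", {
  spec <- scenario_spec("null", n_variants = 20, block_size = 20, rho = 0.9,
                        n_ref = 4000, seed = 24)
  panel <- simulate_panel(spec)
  R <- cor(panel$dosages)
  # independent Monte-Carlo oracle: draw correlated latent pairs, threshold
  # at each variant's MAF quantile, correlate the haplotype sums
  oracle_r <- function(rho, maf1, maf2, n = 2e5) {
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    w1 <- rnorm(n); w2 <- rho * w1 + sqrt(1 - rho^2) * rnorm(n)
    cor((z1 < qnorm(maf1)) + (w1 < qnorm(maf1)),
        (z2 < qnorm(maf2)) + (w2 < qnorm(maf2)))
  }
  set.seed(1)
  maf <- panel$gen$maf
  for (j in c(1, 7, 13)) {
    target <- oracle_r(0.9, maf[j], maf[j + 1])
    expect_lt(abs(R[j, j + 1] - target), 0.1)
  }
})

test_that("eQTL summary statistics are calibrated under the null and at known power", {
  # h2 = 0: the anchor variant's p-value is uniform across simulations
  spec0 <- scenario_spec("null", n_variants = 10, block_size = 5, eqtl_h2 = 0,
                         n_eqtl = 200, n_ref = 300, seed = 31)
  panel0 <- simulate_panel(spec0)
  truth0 <- ground_truth(spec0, panel0)
  expect_equal(nrow(truth0$eqtl_causal), 0L)   # no causal variants at all
  expect_equal(nrow(truth0$gwas_causal), 0L)
  ps <- vapply(seq_len(1000), function(r) {
    simulate_eqtl_sumstats(panel0, spec0, truth0, seed = 4000 + r)$stats$pvalue[5]
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)

  # h2 = 0.1, n = 500: causal-variant chi-square has mean ~ 1 + n*h2/(1-h2)
  spec1 <- scenario_spec("shared_causal", n_variants = 10, block_size = 5,
                         eqtl_h2 = 0.1, n_eqtl = 500, n_ref = 300, seed = 32)
  panel1 <- simulate_panel(spec1)
  truth1 <- ground_truth(spec1, panel1)
  chi2 <- vapply(seq_len(300), function(r) {
    s <- simulate_eqtl_sumstats(panel1, spec1, truth1, seed = 5000 + r)$stats
    (s$beta / s$se)[match(truth1$eqtl_causal$rsid, s$rsid)]^2
  }, numeric(1))
  expected <- 1 + 500 * 0.1 / 0.9
  expect_lt(abs(mean(chi2) - expected) / expected, 0.15)

  # same truth, different dataset seeds: same causal ids, different noise
  d1 <- simulate_eqtl_sumstats(panel1, spec1, truth1, dataset_id = "a", seed = 1)
  d2 <- simulate_eqtl_sumstats(panel1, spec1, truth1, dataset_id = "b", seed = 2)
  expect_false(isTRUE(all.equal(d1$stats$beta, d2$stats$beta)))
  top1 <- d1$stats$rsid[which.min(d1$stats$pvalue)]
  r_top <- ld_corr(panel1, c(truth1$eqtl_causal$rsid, top1))
  expect_gt(r_top[1, 2]^2, 0.5)  # top association tags the causal variant
})

test_that("summary-level GWAS z-scores follow the MVN(R lambda, R) model", {
  # R ~ I (rho = 0): null draws are standard normal, causal mean is lambda
  spec <- scenario_spec("shared_causal", n_variants = 30, block_size = 10,
                        rho = 0, n_ref = 4000, n_eff = 70000,
                        gwas_varexp = 5e-4, seed = 41)
  panel <- simulate_panel(spec)
  truth <- ground_truth(spec, panel)
  lam <- sqrt(70000 * 5e-4)
  zc <- zn <- numeric(200)
  for (r in seq_len(200)) {
    s <- simulate_gwas_sumstats(panel, spec, truth, seed = 6000 + r)$stats
    z <- s$beta / s$se
    zc[r] <- z[match(truth$gwas_causal$rsid, s$rsid)]
    zn[r] <- z[1]  # a null variant far from the causal one
  }
  expect_lt(abs(mean(zc) - lam), 0.25)     # E[z_causal] = lambda (R ~ I)
  expect_lt(abs(mean(zn)), 0.25)           # E[z_null] = 0
  expect_lt(abs(sd(zn) - 1), 0.15)

  # LD propagation: E[z_neighbor] = r * lambda
  spec9 <- scenario_spec("shared_causal", n_variants = 20, block_size = 20,
                         rho = 0.9, n_ref = 4000, n_eff = 70000,
                         gwas_varexp = 5e-4, seed = 42)
  panel9 <- simulate_panel(spec9)
  truth9 <- ground_truth(spec9, panel9)
  ci <- match(truth9$gwas_causal$rsid, panel9$variants$rsid)
  r_neigh <- cor(panel9$dosages[, ci], panel9$dosages[, ci + 1])
  zn9 <- vapply(seq_len(200), function(r) {
    s <- simulate_gwas_sumstats(panel9, spec9, truth9, seed = 7000 + r)$stats
    (s$beta / s$se)[ci + 1]
  }, numeric(1))
  expect_lt(abs(mean(zn9) - r_neigh * lam), 0.3)
})

test_that("scenario fixtures round-trip through the I/O layer bit-exactly", {
  dir <- withr::local_tempdir()
  spec <- scenario_spec("vertical_causal", n_variants = 20, block_size = 10,
                        n_ref = 300, n_eqtl = 200, theta = 0.3, seed = 51)
  fx <- make_scenario_fixtures(spec, dir)
  expect_true(all(file.exists(unlist(fx$paths[c("gwas", "genes", "truth")]))))
  eq <- read_sumstats(fx$paths$eqtl[1], trait_id = "e", gene_id = "gene1")
  gw <- read_sumstats(fx$paths$gwas, trait_id = "g", trait_type = "case_control")
  panel <- read_panel(fx$paths$panel)
  panel_re <- simulate_panel(spec)
  gw_re <- simulate_gwas_sumstats(panel_re, spec, fx$truth, seed = spec$seed + 997L)
  expect_identical(gw$stats$beta, unname(gw_re$stats$beta))
  expect_equal(nrow(panel$variants), 20L)
  expect_equal(nrow(eq$stats), 20L)
  # vertical causality: GWAS standardized effects are theta-scaled eQTL effects
  expect_equal(fx$truth$gwas_causal$gamma,
               0.3 * fx$truth$eqtl_causal$beta_std)
  # distinct_causal records a pair at the target r^2
  specd <- scenario_spec("distinct_causal", n_ref = 2000, seed = 52)
  pd <- simulate_panel(specd)
  td <- ground_truth(specd, pd)
  r2 <- ld_corr(pd, c(td$eqtl_causal$rsid, td$gwas_causal$rsid))[1, 2]^2
  expect_false(td$eqtl_causal$rsid == td$gwas_causal$rsid)
  expect_lt(abs(r2 - 0.7), 0.1)
})

test_that("the planted study carries its advertised structure", {
  study <- simulate_study(n_genes = 10, n_shared = 2, n_pleio_pairs = 1,
                          n_ref = 400, n_eqtl = 200, seed = 61)
  expect_equal(length(study$eqtl), 10L)
  expect_equal(study$truth$planted_genes, c("gene01", "gene02"))
  expect_equal(study$truth$pleio_pairs[[1]], c("gene03", "gene04"))
  # pleiotropy pair shares one causal variant, planted genes have their own
  ca <- study$truth$causal
  expect_equal(ca$causal_rsid[ca$gene_id == "gene03"],
               ca$causal_rsid[ca$gene_id == "gene04"])
  expect_true(all(is.na(ca$causal_rsid[ca$gene_id %in% study$truth$null_genes])))
  expect_false(any(ca$disease_causal[ca$gene_id %in% study$truth$null_genes]))
  # one combined panel, unique rsids, sorted positions
  expect_false(anyDuplicated(study$panel$variants$rsid) > 0)
  expect_true(!is.unsorted(study$gwas$stats$pos))
})
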