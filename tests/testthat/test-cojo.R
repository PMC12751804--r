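cfg <- pipeline_config()


test_that("a single-variant joint model reproduces its marginal stats exactly", {
  co <- make_cohort(n = 500, m = 5, n_causal = 1, seed = 2)
  id <- co$region$stats$rsid[3]
  fit <- cojo_fit(co$region, co$panel, id, cfg)
  i <- match(id, co$region$stats$rsid)
  expect_equal(fit$beta_joint, co$region$stats$beta[i], tolerance = 1e-10)
  expect_equal(fit$se_joint, co$region$stats$se[i], tolerance = 1e-10)
})

test_that("joint estimates match exact multiple regression with in-sample LD", {
  worst <- 0
  for (rep in 1:10) {
    co <- make_cohort(n = 2000, m = 20, n_causal = 3, seed = 20 + rep)
    ids <- co$region$stats$rsid[co$causal]
    fit <- cojo_fit(co$region, co$panel, ids, cfg)
    ols <- coef(lm(co$y ~ co$X[, co$causal]))[-1]
    rel <- abs(fit$beta_joint - ols) / pmax(abs(ols), 1e-8)
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 0.05)
})

test_that("orthogonal variants decouple: joint equals marginal, conditioning is a no-op", {
  set.seed(30)
  X <- matrix(rbinom(4000 * 4, 2, 0.4), 4000)    # essentially independent
  panel <- make_panel(X)
  y <- 0.1 * X[, 1] + 0.1 * X[, 3] + rnorm(4000)
  marg <- t(vapply(1:4, function(j) {
    f <- summary(lm(y ~ X[, j]))$coefficients; c(f[2, 1], f[2, 2])
  }, numeric(2)))
  region <- region_sumstats(
    tibble::tibble(chrom = "1", pos = panel$variants$pos,
                   rsid = panel$variants$rsid, ea = "A", oa = "G",
                   eaf = colMeans(X) / 2, beta = marg[, 1], se = marg[, 2],
                   pvalue = 2 * pnorm(-abs(marg[, 1] / marg[, 2])), n = 4000),
    trait_id = "y", validate = FALSE)
  fit <- cojo_fit(region, panel, panel$variants$rsid[c(1, 3)], cfg)
  expect_equal(fit$beta_joint, marg[c(1, 3), 1], tolerance = 0.05)

  # empty conditioning set: identity
  cond0 <- cojo_condition(region, panel, character(0), cfg)
  expect_equal(cond0$stats$beta, region$stats$beta, tolerance = 1e-12)
  expect_equal(cond0$stats$se, region$stats$se, tolerance = 1e-12)

  # conditioning on a variant with r ~ 0 leaves others essentially unchanged
  cond <- cojo_condition(region, panel, panel$variants$rsid[4], cfg)
  keep <- match(cond$stats$rsid, region$stats$rsid)
  expect_equal(cond$stats$beta, region$stats$beta[keep], tolerance = 0.02)
  expect_equal(cond$stats$se, region$stats$se[keep], tolerance = 0.02)
})

test_that("exact orthogonality leaves conditional statistics unchanged to 1e-10", {
  # hand-built panel: variant 3 exactly uncorrelated with 1 and 2 by design
  d1 <- rep(c(0, 1, 2, 1), 100)
  d2 <- rep(c(1, 0, 1, 2), 100)
  d3 <- rep(c(0, 2, 0, 2, 2, 0, 2, 0), 50)       # balanced against both
  stopifnot(abs(cor(d1, d3)) < 1e-12, abs(cor(d2, d3)) < 1e-12)
  panel <- make_panel(cbind(d1, d2, d3))
  region <- region_sumstats(
    tibble::tibble(chrom = "1", pos = panel$variants$pos,
                   rsid = panel$variants$rsid, ea = "A", oa = "G",
                   eaf = colMeans(cbind(d1, d2, d3)) / 2,
                   beta = c(0.2, 0.1, 0.05), se = c(0.04, 0.05, 0.06),
                   pvalue = NA_real_, n = 400),
    trait_id = "y")
  cond <- cojo_condition(region, panel, "pv003", cfg)
  expect_equal(cond$stats$beta, region$stats$beta[1:2], tolerance = 1e-10)
  expect_equal(cond$stats$se, region$stats$se[1:2], tolerance = 1e-10)
})

test_that("collinear or duplicate selections are rejected by name", {
  set.seed(3)
  x <- rbinom(400, 2, 0.3); w <- rbinom(400, 2, 0.4)
  panel <- make_panel(cbind(x, x, w))              # columns 1 and 2 identical
  region <- region_sumstats(
    tibble::tibble(chrom = "1", pos = panel$variants$pos,
                   rsid = panel$variants$rsid, ea = "A", oa = "G",
                   eaf = colMeans(cbind(x, x, w)) / 2,
                   beta = c(0.2, 0.2, 0.1), se = 0.05, pvalue = NA_real_, n = 400),
    trait_id = "y")
  expect_error(cojo_fit(region, panel, c("pv002", "pv002"), cfg), "collinear")
  expect_error(cojo_fit(region, panel, c("pv001", "pv002"), cfg), "collinear")
})

test_that("stepwise selection finds planted signals and respects the cutoff", {
  # no signal below the cutoff: empty model
  spec0 <- scenario_spec("null", eqtl_h2 = 0, n_variants = 40, block_size = 20,
                         n_ref = 1000, seed = 90)
  panel0 <- simulate_panel(spec0)
  truth0 <- ground_truth(spec0, panel0)
  gw0 <- simulate_gwas_sumstats(panel0, spec0, truth0, seed = 91)
  expect_length(cojo_select(gw0, panel0, cfg)$rsid, 0)

  # one strong causal variant: selects it or a tight proxy
  spec1 <- scenario_spec("shared_causal", gwas_varexp = 1.5e-3, n_eff = 70000,
                         n_variants = 60, block_size = 20, n_ref = 1500, seed = 92)
  panel1 <- simulate_panel(spec1)
  truth1 <- ground_truth(spec1, panel1)
  hits <- 0
  for (r in 1:20) {
    gw <- simulate_gwas_sumstats(panel1, spec1, truth1, seed = 900 + r)
    sel <- cojo_select(gw, panel1, cfg)
    if (length(sel$rsid) >= 1) {
      r2 <- ld_corr(panel1, c(truth1$gwas_causal$rsid, sel$rsid))[1, -1]^2
      if (max(r2) > 0.8) hits <- hits + 1
    }
  }
  expect_gte(hits, 18)   # >= 90% of replicates

  # masked secondary: two signals discovered most of the time
  spec2 <- scenario_spec("masked_secondary", n_eff = 70000, seed = 93)
  panel2 <- simulate_panel(spec2)
  truth2 <- ground_truth(spec2, panel2)
  two <- 0
  for (r in 1:20) {
    gw <- simulate_gwas_sumstats(panel2, spec2, truth2, seed = 950 + r)
    if (length(cojo_select(gw, panel2, cfg)$rsid) >= 2) two <- two + 1
  }
  expect_gte(two, 16)    # >= 80% of replicates

  # conditioning on the causal variant deflates its proxies
  gw <- simulate_gwas_sumstats(spec = spec1, panel = panel1, truth = truth1,
                               seed = 999)
  cond <- cojo_condition(gw, panel1, truth1$gwas_causal$rsid, cfg)
  R <- ld_corr(panel1, panel1$variants$rsid)
  ci <- match(truth1$gwas_causal$rsid, panel1$variants$rsid)
  proxies <- panel1$variants$rsid[which(R[ci, ]^2 > 0.5 & seq_len(60) != ci)]
  zc <- abs(cond$stats$beta / cond$stats$se)[match(proxies, cond$stats$rsid)]
  zm <- abs(gw$stats$beta / gw$stats$se)[match(proxies, gw$stats$rsid)]
  expect_lt(mean(zc), 1.5)
  expect_lt(mean(zc), mean(zm))
})
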