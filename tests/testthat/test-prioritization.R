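cfg <- pipeline_config()

test_that("region grouping chains instruments within 250 kb per chromosome", {
  hits <- tibble::tibble(gene_id = c("a", "b"), chrom = "1",
                         pos = c(1.00e6, 1.10e6), rsid = c("r1", "r2"))
  g <- group_regions(hits)
  expect_equal(length(unique(g$region_id)), 1L)       # 100 kb apart: same region
  expect_false(any(g$lone_in_region))

  chain <- tibble::tibble(gene_id = c("a", "b", "c"), chrom = "1",
                          pos = c(1.0e6, 1.2e6, 1.4e6), rsid = paste0("r", 1:3))
  gc <- group_regions(chain)
  expect_equal(length(unique(gc$region_id)), 1L)      # transitive chaining

  far <- tibble::tibble(gene_id = c("a", "b"), chrom = "1",
                        pos = c(1.0e6, 1.6e6), rsid = c("r1", "r2"))
  gf <- group_regions(far)
  expect_equal(length(unique(gf$region_id)), 2L)
  expect_true(all(gf$lone_in_region))

  # partition + order invariance
  set.seed(55)
  hs <- tibble::tibble(gene_id = sample(letters[1:6], 12, TRUE),
                       chrom = sample(c("1", "2"), 12, TRUE),
                       pos = sample(seq(1e6, 3e6, 5e4), 12),
                       rsid = paste0("r", 1:12))
  g1 <- group_regions(hs)
  perm <- sample(12)
  g2 <- group_regions(hs[perm, ])
  expect_false(anyNA(g1$region_id))
  expect_equal(g2$region_id, g1$region_id[perm])
})

test_that("pleiotropy is flagged only for regions with multiple passing genes", {
  one <- group_regions(tibble::tibble(gene_id = "a", chrom = "1", pos = 1e6,
                                      rsid = "r1"))
  expect_false(flag_pleiotropy(one)$pleiotropy)
  two <- group_regions(tibble::tibble(gene_id = c("a", "b"), chrom = "1",
                                      pos = c(1e6, 1.05e6), rsid = c("r1", "r2")))
  expect_true(flag_pleiotropy(two)$pleiotropy)
  # the neighbour gene failed coloc, so only one gene enters grouping
  solo <- group_regions(tibble::tibble(gene_id = "a", chrom = "1",
                                       pos = c(1e6, 1.05e6), rsid = c("r1", "r2")))
  expect_false(flag_pleiotropy(solo)$pleiotropy)
})

test_that("novelty requires distance from and low LD with known variants", {
  set.seed(56)
  x <- rbinom(500, 2, 0.3)
  noise <- function() ifelse(runif(500) < 0.15, rbinom(500, 2, 0.3), x)
  panel <- make_panel(cbind(x, noise(), rbinom(500, 2, 0.3)),
                      pos = c(1e6, 1.4e6, 5e6))
  r2 <- ld_corr(panel, c("pv001", "pv002"))[1, 2]^2
  expect_gt(r2, 0.2)
  hits <- tibble::tibble(gene_id = "g", chrom = "1", pos = 1e6, rsid = "pv001")
  # known variant 100 kb away: proximity kills novelty
  expect_false(assess_novelty(hits, tibble::tibble(chrom = "1", pos = 1.1e6),
                              panel)$novel)
  # known variant 400 kb away but in LD (r2 > 0.2): correlation kills novelty
  expect_false(assess_novelty(hits,
                              tibble::tibble(chrom = "1", pos = 1.4e6, rsid = "pv002"),
                              panel)$novel)
  # distant and uncorrelated known variant: novel
  expect_true(assess_novelty(hits,
                             tibble::tibble(chrom = "1", pos = 5e6, rsid = "pv003"),
                             panel)$novel)
  # no known variants anywhere: novel
  expect_true(assess_novelty(hits, tibble::tibble(chrom = character(0),
                                                  pos = numeric(0)), panel)$novel)
  # exclusion list from earlier MR studies overrides position
  expect_false(assess_novelty(hits, tibble::tibble(chrom = character(0),
                                                   pos = numeric(0)), panel,
                              excluded_genes = "g")$novel)
  # monotone: adding known variants can only remove novelty
  k1 <- tibble::tibble(chrom = "1", pos = 5e6, rsid = "pv003")
  k2 <- rbind(k1, tibble::tibble(chrom = "1", pos = 1.1e6, rsid = "x"))
  expect_true(assess_novelty(hits, k1, panel)$novel)
  expect_false(assess_novelty(hits, k2, panel)$novel)
})

test_that("the gene ledger composes passing, lone, novel and concordance", {
  mr <- tibble::tibble(
    gene_id = c("lone", "pleioA", "pleioB", "disc", "disc", "failed"),
    dataset_id = c("d1", "d1", "d1", "d1", "d2", "d1"),
    beta_mr = c(0.3, 0.2, 0.2, 0.4, -0.4, 0.1),
    pvalue = 1e-10, significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  coloc <- tibble::tibble(
    gene_id = c("lone", "pleioA", "pleioB", "disc", "disc"),
    dataset_id = c("d1", "d1", "d1", "d1", "d2"),
    colocalized = TRUE, pph4 = 0.95)
  instruments <- tibble::tibble(
    gene_id = c("lone", "pleioA", "pleioB", "disc", "disc", "failed"),
    dataset_id = c("d1", "d1", "d1", "d1", "d2", "d1"),
    chrom = "1", pos = c(1e6, 3e6, 3.1e6, 6e6, 6.001e6, 9e6),
    rsid = paste0("r", 1:6), p_exp = 1e-9)
  panel <- random_panel(n = 200, m = 6, seed = 57)
  panel$variants$pos <- instruments$pos
  panel$variants$rsid <- instruments$rsid
  colnames(panel$dosages) <- instruments$rsid
  led <- prioritize(mr, coloc, instruments,
                    tibble::tibble(chrom = character(0), pos = numeric(0)),
                    panel, cfg)
  L <- led$ledger
  expect_true(L$prioritized[L$gene_id == "lone"])
  # pleiotropy pair: same region, neither is lone, region flagged
  expect_false(any(L$prioritized[L$gene_id %in% c("pleioA", "pleioB")]))
  expect_true(any(led$regions$pleiotropy))
  # direction-discordant gene across datasets (the opposite-effects pattern)
  expect_false(L$direction_concordant[L$gene_id == "disc"])
  expect_true(L$direction_concordant[L$gene_id == "lone"])
  # non-significant gene is not passing and carries no region
  expect_false(L$passing[L$gene_id == "failed"])
  expect_true(is.na(L$region_id[L$gene_id == "failed"]))
})

test_that("the PheWAS scan queries the top eQTL and gates coloc on the p threshold", {
  spec <- scenario_spec("shared_causal", n_eff = 70000, seed = 104)
  panel <- simulate_panel(spec)
  truth <- ground_truth(spec, panel)
  eq <- simulate_eqtl_sumstats(panel, spec, truth, seed = 3)
  shared_ph <- simulate_gwas_sumstats(panel, spec, truth, trait_id = "ph1", seed = 4)
  null_truth <- truth
  null_truth$gwas_causal <- truth$gwas_causal[0, ]
  null_ph <- simulate_gwas_sumstats(panel, spec, null_truth, trait_id = "ph0", seed = 5)
  gw <- simulate_gwas_sumstats(panel, spec, truth, seed = 6)
  annot <- tibble::tibble(gene_id = "gene1", chrom = "1",
                          tss = 1e6 + 1e5, protein_coding = TRUE)
  instr <- suppressMessages(build_instruments(list(eq), gw, annot, panel,
                                              pipeline_config()))
  hits <- phewas_scan(instr, eq, list(shared = shared_ph, null = null_ph),
                      panel, pipeline_config())
  expect_equal(nrow(hits), 2L)
  sh <- hits[hits$phenotype == "shared", ]
  nu <- hits[hits$phenotype == "null", ]
  expect_true(sh$passes)
  expect_false(nu$passes)
  expect_true(is.na(nu$pph4))          # no coloc attempted below threshold
  expect_equal(unique(hits$rsid), instr$rsid[which.min(instr$p_exp)])
})
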