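test_that("well-formed files read back as written, invalid rows are dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\trsid\tea\toa\teaf\tbeta\tse\tpvalue\tn",
               "1\t100\trs1\tA\tG\t0.2\t0.5\t0.1\t5.7e-07\t500",
               "1\t200\trs2\tC\tA\t0.4\t-0.1\t0.05\t0.0455\t500",
               "1\t300\trs3\tG\tC\t0.1\t0.2\t0.08\t0.0124\t500"), path)
  ss <- read_sumstats(path, trait_id = "t")
  expect_s3_class(ss, "region_sumstats")
  expect_equal(nrow(ss$stats), 3L)
  expect_equal(ss$stats$rsid, c("rs1", "rs2", "rs3"))

  # one row with se = 0 violates the invariant and is dropped with a message
  writeLines(c("chrom\tpos\trsid\tea\toa\teaf\tbeta\tse\tpvalue\tn",
               "1\t100\trs1\tA\tG\t0.2\t0.5\t0.1\t5.7e-07\t500",
               "1\t200\trs2\tC\tA\t0.4\t-0.1\t0\t0.0455\t500",
               "1\t300\trs3\tG\tC\t0.1\t0.2\t0.08\t0.0124\t500"), path)
  expect_message(ss2 <- read_sumstats(path, trait_id = "t"), "dropped")
  expect_equal(nrow(ss2$stats), 2L)
  expect_false("rs2" %in% ss2$stats$rsid)
})

test_that("mandatory-column and empty-file failures are fatal, dialects map headers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\trsid\tea\toa\teaf\tbeta\tpvalue\tn",
               "1\t100\trs1\tA\tG\t0.2\t0.5\t5.7e-07\t500"), path)
  expect_error(read_sumstats(path), "mandatory")

  writeLines(c("CHR\tBP\tSNP\tA1\tA2\tFRQ\tB\tSE\tP\tN",
               "1\t100\trs1\tA\tG\t0.2\t0.5\t0.1\t5.7e-07\t500"), path)
  ss <- read_sumstats(path, dialect = c(chrom = "CHR", pos = "BP", rsid = "SNP",
                                        ea = "A1", oa = "A2", eaf = "FRQ",
                                        beta = "B", se = "SE", pvalue = "P", n = "N"))
  expect_equal(ss$stats$beta, 0.5)
})

test_that("write/read round-trips random tables bit-exactly", {
  set.seed(41)
  n <- 40
  stats <- tibble::tibble(
    chrom = "7", pos = as.numeric(sort(sample(1e6:2e6, n))),
    rsid = sprintf("rs%d", seq_len(n)),
    ea = sample(c("A", "C"), n, TRUE), oa = sample(c("G", "T"), n, TRUE),
    eaf = runif(n, 0.01, 0.99), beta = rnorm(n), se = rexp(n) + 1e-4,
    pvalue = runif(n), n = 1234, n_case = NA_real_, n_control = NA_real_)
  ss <- region_sumstats(stats, trait_id = "t", validate = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, path)
  # random p-values are deliberately unrelated to beta/se here, so the
  # validator's consistency warning is expected noise
  back <- suppressWarnings(read_sumstats(path, trait_id = "t"))
  expect_identical(back$stats$beta, ss$stats$beta)
  expect_identical(back$stats$se, ss$stats$se)
  expect_identical(back$stats$eaf, ss$stats$eaf)
  expect_identical(back$stats$pos, ss$stats$pos)
})

test_that("p-values are recomputed when missing and checked when present", {
  s <- ss_rows(n = 2, beta = c(0.2, 0.1), se = c(0.05, 0.05), pvalue = NA_real_)
  ss <- region_sumstats(s, trait_id = "t")
  expect_equal(ss$stats$pvalue, 2 * pnorm(-abs(c(0.2, 0.1) / 0.05)))
  s2 <- ss_rows(n = 1, beta = 0.5, se = 0.05, pvalue = 0.2)  # wildly inconsistent
  expect_warning(region_sumstats(s2, trait_id = "t"), "inconsistent")
})

test_that("harmonization flips swapped alleles and drops ambiguous/irreconcilable pairs", {
  exp <- make_region(n = 3, ea = c("A", "A", "A"), oa = c("G", "T", "G"),
                     beta = 0.5, eaf = 0.3)
  out_stats <- ss_rows(n = 3, ea = c("G", "A", "A"), oa = c("A", "T", "C"),
                       beta = c(-0.2, 0.1, 0.1), eaf = 0.7)
  out <- region_sumstats(out_stats, trait_id = "o", trait_type = "case_control",
                         validate = FALSE)
  expect_message(h <- harmonize_pair(exp, out), "irreconcilable")
  # swapped alleles: outcome beta sign and eaf flip
  expect_equal(nrow(h), 1L)
  expect_equal(h$beta_out, 0.2)
  expect_equal(h$eaf_out, 0.3)
  expect_equal(h$ea, "A")
  # A/T palindromic and A/G-vs-A/C irreconcilable rows were excluded
  expect_equal(unname(attr(h, "dropped")["palindromic"]), 1L)
  expect_equal(unname(attr(h, "dropped")["irreconcilable"]), 1L)
})

test_that("harmonization is involution-safe", {
  set.seed(5)
  exp <- make_region(n = 6, ea = "C", oa = "T", beta = rnorm(6))
  out <- make_region(n = 6, ea = "C", oa = "T", beta = rnorm(6),
                     trait_id = "o")
  h1 <- harmonize_pair(exp, out)
  out2 <- out
  out2$stats$beta <- h1$beta_out
  h2 <- harmonize_pair(exp, out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
})

test_that("panel QC enforces the MAF, HWE and strand-ambiguity rules", {
  set.seed(11)
  n <- 200
  # col1: exact HWE proportions; col2: rare (MAF 0.005); col3: gross HWE
  # violation; col4: healthy; col5: palindromic alleles
  g1 <- c(rep(0, 50), rep(1, 100), rep(2, 50))
  g2 <- c(rep(1, 2), rep(0, 198))
  g3 <- c(rep(2, 180), rep(0, 20))
  g4 <- rbinom(n, 2, 0.4)
  g5 <- rbinom(n, 2, 0.4)
  panel <- ref_panel(tibble::tibble(chrom = "1", pos = 1e6 + 1:5,
                                    rsid = paste0("v", 1:5),
                                    ea = c("A", "A", "A", "A", "A"),
                                    oa = c("G", "G", "G", "G", "T")),
                     cbind(g1, g2, g3, g4, g5))
  expect_equal(hwe_test(50, 100, 50)$chisq, 0)
  expect_equal(hwe_test(50, 100, 50)$p, 1)
  # hand-computed chi-square oracle for 90/0/10 split: p_hat = 0.9,
  # expected (81, 18, 1), chisq = 1 + 18 + 81 = 100
  expect_equal(hwe_test(90, 0, 10)$chisq, 100)
  expect_message(qcd <- panel_qc(panel), "removed")
  expect_equal(qcd$variants$rsid, c("v1", "v4"))   # exact HWE + healthy kept
  # idempotent
  expect_equal(panel_qc(qcd)$variants$rsid, c("v1", "v4"))
})

test_that("LD correlation is allele-aware, symmetric and positive semidefinite", {
  set.seed(3)
  x <- rbinom(300, 2, 0.4)
  panel <- make_panel(cbind(x, x, rbinom(300, 2, 0.4)))
  R <- ld_corr(panel, c("pv001", "pv002", "pv003"))
  expect_equal(R[1, 2], 1)                      # duplicated column
  expect_equal(R, t(R))
  expect_true(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)
  # flipping one variant's effect allele negates its row and column
  Rf <- ld_corr(panel, c("pv001", "pv002", "pv003"),
                effect_allele = c("A", "G", "A"))
  expect_equal(Rf[2, c(1, 3)], -R[2, c(1, 3)])
  expect_equal(Rf[c(1, 3), 2], -R[c(1, 3), 2])
  expect_equal(Rf[2, 2], 1)
  # independent columns at large n: |r| < 0.05 with high probability
  big <- random_panel(n = 10000, m = 6, seed = 8)
  Rb <- ld_corr(big, big$variants$rsid)
  expect_lt(max(abs(Rb[upper.tri(Rb)])), 0.05)
  # zero-variance column is fatal
  panel0 <- make_panel(cbind(x, rep(1, 300)))
  expect_error(ld_corr(panel0, c("pv001", "pv002")), "zero-variance")
})
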