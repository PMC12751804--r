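#!/usr/bin/env Rscript
# Replication arm: METAL-style fixed-effect meta-analysis of the two
# smaller case-control GWAS, instrument re-selection from the whole-blood
# replication eQTL source, MR of the prioritized genes against the
# meta-analyzed outcome, and directional-concordance reporting at the
# p < 0.1 threshold.

suppressPackageStartupMessages(library(cismr))

dat <- "results/study/data"
cfg <- pipeline_config()
panel <- read_panel(file.path(dat, "panel"))
annot <- read_gene_annotation(file.path(dat, "genes.tsv"))
g1 <- read_sumstats(file.path(dat, "gwas_repl1.tsv"), trait_id = "repl1",
                    trait_type = "case_control")
g2 <- read_sumstats(file.path(dat, "gwas_repl2.tsv"), trait_id = "repl2",
                    trait_type = "case_control")
meta <- meta_fixed(g1, g2)
write_sumstats(meta, "results/study/meta_gwas.tsv")
cat(sprintf("meta-analysis: %d variants, %d from both studies\n",
            nrow(meta$stats), sum(meta$stats$n_studies == 2)))

led <- readr::read_tsv("results/study/ledger_pph4_0.8.tsv",
                       col_types = readr::cols())
mr <- readr::read_tsv("results/study/mr.tsv", col_types = readr::cols())
pri <- led$gene_id[led$prioritized]
genes <- dplyr::bind_rows(lapply(pri, function(g) {
  m <- mr[mr$gene_id == g & mr$significant, ]
  tibble::tibble(gene_id = g, beta_mr = m$beta_mr[which.min(m$pvalue)])
}))

repl_eqtl <- lapply(pri, function(g) {
  p <- file.path(dat, sprintf("repl_eqtl_%s.tsv", g))
  if (!file.exists(p)) return(NULL)
  read_sumstats(p, trait_id = g, gene_id = g, dataset_id = "repl_wb",
                cell_type = "whole_blood")
})
repl_eqtl <- Filter(Negate(is.null), repl_eqtl)

tab <- replicate_mr(genes, repl_eqtl, meta, annot, panel, cfg)
readr::write_tsv(tab, "results/study/replication.tsv")
cat(sprintf("%d prioritized gene(s): %d with a replication instrument, %d at p < 0.1, %d directionally concordant\n",
            nrow(tab), sum(tab$status == "tested"),
            sum(tab$p_below_report, na.rm = TRUE),
            sum(tab$directionally_concordant, na.rm = TRUE)))
print(as.data.frame(tab), digits = 3)
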