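#!/usr/bin/env Rscript
# Mendelian randomization per gene x dataset: Wald ratio for one-variant
# instruments, fixed-effect IVW with Cochran's Q / I2 otherwise;
# significance under a per-dataset Bonferroni correction for the number
# of genes tested.

suppressPackageStartupMessages(library(cismr))

instr <- readr::read_tsv("results/study/instruments.tsv",
                         col_types = readr::cols(chrom = readr::col_character(),
                                                 .default = readr::col_guess()))
mr <- bonferroni_flag(mr_analyze(instr))
readr::write_tsv(mr, "results/study/mr.tsv")

cat(sprintf("%d gene-disease association(s) tested, %d MR-significant\n",
            nrow(mr), sum(mr$significant)))
print(as.data.frame(mr[mr$significant,
                       c("gene_id", "method", "beta_mr", "se_mr", "pvalue")]),
      digits = 3)
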