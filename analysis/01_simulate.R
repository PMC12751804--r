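#!/usr/bin/env Rscript
# Build the synthetic study: one chromosome of 50 well-separated cis
# regions sharing an LD reference panel; 3 genes with a causal variant
# shared between expression and disease (the planted discoveries), 2 gene
# pairs whose expressions and the disease are driven by one variant
# (horizontal pleiotropy), 45 null genes; plus a whole-blood-style
# replication eQTL source and two smaller case-control GWAS.

suppressPackageStartupMessages(library(cismr))

out <- "results/study/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260

study <- simulate_study(n_genes = 50, n_shared = 3, n_pleio_pairs = 2,
                        seed = seed, replication = TRUE)

write_panel(study$panel, file.path(out, "panel"))
write_sumstats(study$gwas, file.path(out, "gwas.tsv"))
readr::write_tsv(study$annotation, file.path(out, "genes.tsv"))
readr::write_tsv(study$known_loci, file.path(out, "known_loci.tsv"))
for (g in names(study$eqtl))
  write_sumstats(study$eqtl[[g]], file.path(out, sprintf("eqtl_%s.tsv", g)))
for (g in names(study$repl_eqtl))
  write_sumstats(study$repl_eqtl[[g]], file.path(out, sprintf("repl_eqtl_%s.tsv", g)))
write_sumstats(study$gwas_repl1, file.path(out, "gwas_repl1.tsv"))
write_sumstats(study$gwas_repl2, file.path(out, "gwas_repl2.tsv"))
jsonlite::write_json(study$truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("panel: %d individuals x %d variants\n",
            study$panel$n_ref, nrow(study$panel$variants)))
cat(sprintf("primary GWAS: %d cases / %d controls (n_eff %.0f)\n",
            study$gwas$stats$n_case[1], study$gwas$stats$n_control[1],
            n_eff_cc(study$gwas$stats$n_case[1], study$gwas$stats$n_control[1])))
cat("planted shared-causal genes:",
    paste(study$truth$planted_genes, collapse = ", "), "\n")
cat("pleiotropy pairs:",
    paste(vapply(study$truth$pleio_pairs, paste, "", collapse = "+"),
          collapse = ", "), "\n")
cat("fixtures written under", out, "\n")
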