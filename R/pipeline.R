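# End-to-end orchestration: simulate -> instruments -> mr -> pwcoco ->
# prioritize (-> phewas -> meta/replicate), with a JSON run manifest and
# digest-based stage skipping. Every stage reads its inputs from, and
# writes its outputs to, tab-delimited files under the output directory,
# so re-running with identical config and seed reproduces byte-identical
# tables and unchanged stages are skipped.

# Stable per-stage seed substream: a small polynomial hash of the stage
# name folded into the global seed, kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  (as.numeric(seed) * 1000003 + h) %% 2147483629
}

default_pipeline_config <- function() {
  list(seed = 1,
       study = list(n_genes = 50, n_shared = 3, n_pleio_pairs = 2,
                    n_variants = 40, block_size = 20, rho = 0.9,
                    n_ref = 1500, n_eqtl = 500, eqtl_h2 = 0.15,
                    gwas_varexp = 8e-4, n_case = 18942, n_control = 501638),
       thresholds = list(),
       replication = FALSE,
       phewas = FALSE)
}

read_pipeline_config <- function(config) {
  cfg <- default_pipeline_config()
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  for (nm in names(user)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
      modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
  }
  cfg
}

file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

stage_unchanged <- function(manifest, stage, inputs, outputs) {
  st <- manifest$stages[[stage]]
  if (is.null(st)) return(FALSE)
  cur_in <- file_digests(inputs)
  if (!identical(cur_in[sort(names(cur_in))], st$inputs[sort(names(st$inputs))]))
    return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  cur_out <- file_digests(outputs)
  identical(cur_out[sort(names(cur_out))], st$outputs[sort(names(st$outputs))])
}

#' Run the full pipeline from a single configuration
#'
#' Executes simulate -> instruments -> mr -> pwcoco -> prioritize (and,
#' when enabled, phewas and meta/replicate) in order. Each stage's input
#' and output file digests are recorded in `manifest.json`; on re-runs,
#' stages whose inputs and outputs are unchanged are skipped. All
#' randomness derives from the global seed via per-stage substreams, so an
#' identical config and seed reproduces byte-identical tables.
#'
#' Outputs under `out_dir`: `data/` (simulated fixtures), `instruments.tsv`,
#' `mr.tsv`, `coloc.tsv`, `ledger_pph4_<t>.tsv` for each PPH4 threshold,
#' `regions.tsv`, `summary.txt`, `manifest.json`, and when enabled
#' `phewas.tsv`, `meta_gwas.tsv`, `replication.tsv`.
#'
#' @param config path to a YAML configuration or an equivalent named list.
#'   Recognised fields: `seed`; `study` (arguments of [simulate_study()]);
#'   `thresholds` (overrides for [pipeline_config()]); `replication`,
#'   `phewas` (logical stage switches).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  acfg <- do.call(pipeline_config, cfg$thresholds)
  dir.create(file.path(out_dir, "data"), recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  cfg_digest <- tools::md5sum(
    {tf <- tempfile(); writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tf); tf})[[1]]
  if (!identical(manifest$config_digest, cfg_digest)) manifest$stages <- list()
  manifest$config_digest <- cfg_digest
  manifest$seed <- cfg$seed
  manifest$tool_version <- as.character(utils::packageVersion("cismr"))

  record <- function(stage, inputs, outputs) {
    manifest$stages[[stage]] <<- list(inputs = file_digests(inputs),
                                      outputs = file_digests(outputs))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  log_stage <- function(stage, skipped = FALSE) {
    message(sprintf("[%s] %s%s", format(Sys.time(), "%H:%M:%S"), stage,
                    if (skipped) " (skipped: inputs unchanged)" else ""))
  }
  dat <- file.path(out_dir, "data")
  paths <- list(
    panel = file.path(dat, "panel"),
    panel_files = file.path(dat, c("panel.variants.tsv", "panel.dosages.tsv")),
    gwas = file.path(dat, "gwas.tsv"),
    genes = file.path(dat, "genes.tsv"),
    known = file.path(dat, "known_loci.tsv"),
    truth = file.path(dat, "ground_truth.json"),
    instruments = file.path(out_dir, "instruments.tsv"),
    mr = file.path(out_dir, "mr.tsv"),
    coloc = file.path(out_dir, "coloc.tsv"),
    regions = file.path(out_dir, "regions.tsv"),
    summary = file.path(out_dir, "summary.txt"))

  ## stage: simulate -----------------------------------------------------
  study_args <- cfg$study
  study_args$seed <- stage_seed(cfg$seed, "simulate")
  study_args$replication <- isTRUE(cfg$replication)
  n_genes <- study_args$n_genes %||% 50
  eqtl_paths <- file.path(dat, sprintf("eqtl_gene%02d.tsv", seq_len(n_genes)))
  repl_paths <- if (isTRUE(cfg$replication))
    c(file.path(dat, sprintf("repl_eqtl_gene%02d.tsv", seq_len(n_genes))),
      file.path(dat, c("gwas_repl1.tsv", "gwas_repl2.tsv"))) else character(0)
  sim_out <- c(paths$panel_files, paths$gwas, paths$genes, paths$known,
               paths$truth, eqtl_paths, repl_paths)
  if (stage_unchanged(manifest, "simulate", character(0), sim_out)) {
    log_stage("simulate", skipped = TRUE)
  } else {
    log_stage("simulate")
    study <- do.call(simulate_study, study_args)
    write_panel(study$panel, paths$panel)
    write_sumstats(study$gwas, paths$gwas)
    readr::write_tsv(study$annotation, paths$genes, progress = FALSE)
    readr::write_tsv(study$known_loci, paths$known, progress = FALSE)
    for (g in names(study$eqtl))
      write_sumstats(study$eqtl[[g]], file.path(dat, sprintf("eqtl_%s.tsv", g)))
    if (isTRUE(cfg$replication)) {
      for (g in names(study$repl_eqtl))
        write_sumstats(study$repl_eqtl[[g]],
                       file.path(dat, sprintf("repl_eqtl_%s.tsv", g)))
      write_sumstats(study$gwas_repl1, file.path(dat, "gwas_repl1.tsv"))
      write_sumstats(study$gwas_repl2, file.path(dat, "gwas_repl2.tsv"))
    }
    jsonlite::write_json(study$truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    record("simulate", character(0), sim_out)
  }

  ## shared inputs read back from disk ------------------------------------
  panel <- read_panel(paths$panel)
  annot <- read_gene_annotation(paths$genes)
  gwas <- read_sumstats(paths$gwas, trait_id = "disease",
                        trait_type = "case_control")
  read_eqtl <- function(path) {
    g <- sub("^(repl_)?eqtl_(.*)\\.tsv$", "\\2", basename(path))
    read_sumstats(path, trait_id = g, trait_type = "quantitative",
                  dataset_id = if (grepl("^repl_", basename(path))) "repl_wb" else "ds1",
                  cell_type = if (grepl("^repl_", basename(path))) "whole_blood" else "cell1",
                  gene_id = g)
  }
  eqtl_list <- lapply(eqtl_paths[file.exists(eqtl_paths)], read_eqtl)

  ## stage: instruments ---------------------------------------------------
  instr_in <- c(sim_out)
  if (stage_unchanged(manifest, "instruments", instr_in, paths$instruments)) {
    log_stage("instruments", skipped = TRUE)
  } else {
    log_stage("instruments")
    instr <- suppressMessages(
      build_instruments(eqtl_list, gwas, annot, panel, acfg))
    readr::write_tsv(instr, paths$instruments, progress = FALSE)
    record("instruments", instr_in, paths$instruments)
  }
  instr <- readr::read_tsv(paths$instruments,
                           col_types = readr::cols(chrom = readr::col_character(),
                                                   .default = readr::col_guess()),
                           progress = FALSE)

  ## stage: mr -------------------------------------------------------------
  if (stage_unchanged(manifest, "mr", paths$instruments, paths$mr)) {
    log_stage("mr", skipped = TRUE)
  } else {
    log_stage("mr")
    mr <- bonferroni_flag(mr_analyze(instr), alpha = acfg$bonferroni_alpha)
    readr::write_tsv(mr, paths$mr, progress = FALSE)
    record("mr", paths$instruments, paths$mr)
  }
  mr <- readr::read_tsv(paths$mr, col_types = readr::cols(), progress = FALSE)

  ## stage: pwcoco ----------------------------------------------------------
  if (stage_unchanged(manifest, "pwcoco", c(paths$mr, paths$instruments), paths$coloc)) {
    log_stage("pwcoco", skipped = TRUE)
  } else {
    log_stage("pwcoco")
    sig <- mr[mr$significant, ]
    eqtl_by_gene <- setNames(eqtl_list,
                             vapply(eqtl_list, function(e) e$gene_id, character(1)))
    rows <- lapply(seq_len(nrow(sig)), function(i) {
      g <- sig$gene_id[i]; d <- sig$dataset_id[i]
      iv <- instr[instr$gene_id == g & instr$dataset_id == d, ]
      center <- iv$pos[which.min(iv$p_exp)]
      pw <- tryCatch(pwcoco(eqtl_by_gene[[g]], gwas, panel, acfg,
                            center_pos = center),
                     error = function(e) NULL)
      if (is.null(pw)) return(NULL)
      tibble::tibble(gene_id = g, dataset_id = d,
                     mode = pw$best$mode,
                     cond1 = paste(pw$best$conditioned_on$trait1, collapse = ","),
                     cond2 = paste(pw$best$conditioned_on$trait2, collapse = ","),
                     pph0 = pw$best$pph0, pph1 = pw$best$pph1,
                     pph2 = pw$best$pph2, pph3 = pw$best$pph3,
                     pph4 = pw$best$pph4, n_variants = pw$best$n_variants)
    })
    coloc <- dplyr::bind_rows(rows)
    if (nrow(coloc) == 0)
      coloc <- tibble::tibble(gene_id = character(0), dataset_id = character(0),
                              mode = character(0), cond1 = character(0),
                              cond2 = character(0), pph0 = numeric(0),
                              pph1 = numeric(0), pph2 = numeric(0),
                              pph3 = numeric(0), pph4 = numeric(0),
                              n_variants = integer(0))
    readr::write_tsv(coloc, paths$coloc, progress = FALSE)
    record("pwcoco", c(paths$mr, paths$instruments), paths$coloc)
  }
  coloc <- readr::read_tsv(paths$coloc, col_types = readr::cols(), progress = FALSE)

  ## stage: prioritize -------------------------------------------------------
  thresholds <- sort(unique(c(acfg$pph4_threshold, acfg$pph4_alternates)))
  ledger_paths <- file.path(out_dir, sprintf("ledger_pph4_%.1f.tsv", thresholds))
  known <- readr::read_tsv(paths$known,
                           col_types = readr::cols(chrom = readr::col_character()),
                           progress = FALSE)
  pri_in <- c(paths$mr, paths$coloc, paths$instruments, paths$known)
  pri_out <- c(ledger_paths, paths$regions, paths$summary)
  if (stage_unchanged(manifest, "prioritize", pri_in, pri_out)) {
    log_stage("prioritize", skipped = TRUE)
  } else {
    log_stage("prioritize")
    ledgers <- list()
    for (ti in seq_along(thresholds)) {
      thr <- thresholds[ti]
      coloc_t <- coloc
      coloc_t$colocalized <- coloc_t$pph4 >= thr
      led <- prioritize(mr, coloc_t, instr, known, panel,
                        modifyList(acfg, list(pph4_threshold = thr)))
      ledgers[[ti]] <- led
      readr::write_tsv(led$ledger, ledger_paths[ti], progress = FALSE)
      if (thr == acfg$pph4_threshold)
        readr::write_tsv(led$regions, paths$regions, progress = FALSE)
    }
    writeLines(pipeline_summary(mr, coloc, ledgers, thresholds), paths$summary)
    record("prioritize", pri_in, pri_out)
  }

  ## optional stages -----------------------------------------------------------
  if (isTRUE(cfg$replication)) {
    run_replication_stage(out_dir, paths, dat, annot, panel, acfg,
                          manifest, record, log_stage, instr, coloc, mr)
  }
  if (isTRUE(cfg$phewas)) {
    run_phewas_stage(out_dir, paths, dat, panel, acfg, manifest, record,
                     log_stage, instr, mr, coloc, eqtl_list, gwas,
                     isTRUE(cfg$replication))
  }
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_summary <- function(mr, coloc, ledgers, thresholds) {
  per_dataset <- lapply(split(mr, mr$dataset_id), function(d) {
    sprintf("dataset %s: %d gene(s) tested, %d MR-significant",
            d$dataset_id[1], length(unique(d$gene_id)),
            length(unique(d$gene_id[d$significant])))
  })
  main <- which.min(abs(thresholds - 0.8))
  led <- ledgers[[main]]$ledger
  c("pipeline summary",
    "================",
    sprintf("associations tested: %d", nrow(mr)),
    sprintf("unique genes tested: %d", length(unique(mr$gene_id))),
    sprintf("MR-significant associations: %d", sum(mr$significant)),
    sprintf("colocalization runs: %d", nrow(coloc)),
    unlist(per_dataset),
    vapply(seq_along(thresholds), function(ti) {
      l <- ledgers[[ti]]$ledger
      sprintf("PPH4 >= %.1f: %d gene(s) pass MR+coloc, %d prioritized (lone and novel)",
              thresholds[ti], sum(l$passing), sum(l$prioritized))
    }, character(1)),
    sprintf("pleiotropic regions (PPH4 >= %.1f): %d", thresholds[main],
            sum(ledgers[[main]]$regions$pleiotropy)))
}

run_replication_stage <- function(out_dir, paths, dat, annot, panel, acfg,
                                  manifest, record, log_stage, instr, coloc, mr) {
  meta_path <- file.path(out_dir, "meta_gwas.tsv")
  repl_path <- file.path(out_dir, "replication.tsv")
  g1p <- file.path(dat, "gwas_repl1.tsv"); g2p <- file.path(dat, "gwas_repl2.tsv")
  repl_eqtl_paths <- list.files(dat, "^repl_eqtl_.*\\.tsv$", full.names = TRUE)
  ins <- c(g1p, g2p, repl_eqtl_paths, paths$mr, paths$coloc)
  if (stage_unchanged(manifest, "replicate", ins, c(meta_path, repl_path))) {
    log_stage("replicate", skipped = TRUE)
    return(invisible(NULL))
  }
  log_stage("replicate")
  g1 <- read_sumstats(g1p, trait_id = "repl1", trait_type = "case_control")
  g2 <- read_sumstats(g2p, trait_id = "repl2", trait_type = "case_control")
  meta <- meta_fixed(g1, g2)
  write_sumstats(meta, meta_path)
  led <- readr::read_tsv(file.path(out_dir, sprintf("ledger_pph4_%.1f.tsv",
                                                    acfg$pph4_threshold)),
                         col_types = readr::cols(), progress = FALSE)
  pri <- led$gene_id[led$prioritized]
  genes <- dplyr::bind_rows(lapply(pri, function(g) {
    m <- mr[mr$gene_id == g & mr$significant, ]
    tibble::tibble(gene_id = g, beta_mr = m$beta_mr[which.min(m$pvalue)])
  }))
  if (nrow(genes)) {
    repl_eqtl <- lapply(repl_eqtl_paths, function(p) {
      g <- sub("^repl_eqtl_(.*)\\.tsv$", "\\1", basename(p))
      read_sumstats(p, trait_id = g, trait_type = "quantitative",
                    dataset_id = "repl_wb", cell_type = "whole_blood", gene_id = g)
    })
    repl_eqtl <- repl_eqtl[vapply(repl_eqtl, function(e)
      e$gene_id %in% genes$gene_id, logical(1))]
    tab <- suppressMessages(
      replicate_mr(genes, repl_eqtl, meta, annot, panel, acfg))
  } else {
    tab <- tibble::tibble(gene_id = character(0), status = character(0))
  }
  readr::write_tsv(tab, repl_path, progress = FALSE)
  record("replicate", ins, c(meta_path, repl_path))
  invisible(NULL)
}

run_phewas_stage <- function(out_dir, paths, dat, panel, acfg, manifest, record,
                             log_stage, instr, mr, coloc, eqtl_list, gwas,
                             replication) {
  phewas_path <- file.path(out_dir, "phewas.tsv")
  ins <- c(paths$mr, paths$coloc, paths$instruments)
  if (stage_unchanged(manifest, "phewas", ins, phewas_path)) {
    log_stage("phewas", skipped = TRUE)
    return(invisible(NULL))
  }
  log_stage("phewas")
  led <- readr::read_tsv(file.path(out_dir, sprintf("ledger_pph4_%.1f.tsv",
                                                    acfg$pph4_threshold)),
                         col_types = readr::cols(), progress = FALSE)
  phen <- list(disease = gwas)
  if (replication) {
    phen$disease_repl1 <- read_sumstats(file.path(dat, "gwas_repl1.tsv"),
                                        trait_id = "repl1", trait_type = "case_control")
  }
  eqtl_by_gene <- setNames(eqtl_list,
                           vapply(eqtl_list, function(e) e$gene_id, character(1)))
  rows <- lapply(led$gene_id[led$prioritized], function(g) {
    iv <- instr[instr$gene_id == g, ]
    if (nrow(iv) == 0) return(NULL)
    hits <- phewas_scan(iv, eqtl_by_gene[[g]], phen, panel, acfg)
    if (nrow(hits)) hits$gene_id <- g
    hits
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0)
    tab <- tibble::tibble(gene_id = character(0), rsid = character(0),
                          phenotype = character(0))
  readr::write_tsv(tab, phewas_path, progress = FALSE)
  record("phewas", ins, phewas_path)
  invisible(NULL)
}
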