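#' Group passing results into genomic regions
#'
#' Single-linkage clustering of instrumental-variant positions per
#' chromosome: two results share a region iff they are connected by a chain
#' of instrument positions each at most `window` apart. The grouping is a
#' partition and is invariant to input order.
#'
#' @param hits tibble with one row per instrumental variant of a passing
#'   result: columns `gene_id, chrom, pos`.
#' @param window chaining distance (default 250 kb).
#' @return `hits` with columns `region_id` and `lone_in_region`
#'   (TRUE iff the region contains a single unique gene).
#' @export
group_regions <- function(hits, window = 2.5e5) {
  if (nrow(hits) == 0) {
    hits$region_id <- character(0); hits$lone_in_region <- logical(0)
    return(hits)
  }
  ord <- order(hits$chrom, hits$pos)
  h <- hits[ord, ]
  new_cluster <- c(TRUE, h$chrom[-1] != h$chrom[-nrow(h)] |
                     diff(h$pos) > window)
  cluster <- cumsum(new_cluster)
  h$region_id <- sprintf("chr%s_r%02d", h$chrom, cluster)
  n_genes <- tapply(h$gene_id, h$region_id, function(g) length(unique(g)))
  h$lone_in_region <- as.vector(n_genes[h$region_id]) == 1
  h[match(seq_len(nrow(hits)), ord), ]  # restore input order
}

#' Flag regions exhibiting horizontal pleiotropy
#'
#' A region is flagged iff two or more unique genes pass MR and
#' colocalization within it (only passing results take part in grouping).
#'
#' @param regions output of [group_regions()].
#' @return tibble: `region_id`, `n_genes`, `pleiotropy`.
#' @export
flag_pleiotropy <- function(regions) {
  if (nrow(regions) == 0)
    return(tibble::tibble(region_id = character(0), n_genes = integer(0),
                          pleiotropy = logical(0)))
  n_genes <- tapply(regions$gene_id, regions$region_id,
                    function(g) length(unique(g)))
  tibble::tibble(region_id = names(n_genes),
                 n_genes = as.integer(n_genes),
                 pleiotropy = as.integer(n_genes) >= 2)
}

#' Novelty assessment against known loci
#'
#' A gene is novel iff every instrumental variant of every passing result
#' is both uncorrelated (reference r^2 < `r2_max`) with and distant
#' (> `window` bp) from every known variant, and the gene is not on the
#' supplied exclusion list (genes reported by earlier MR studies). Known
#' variants absent from the panel contribute only the distance rule.
#'
#' @param hits tibble with `gene_id, chrom, pos, rsid` per instrumental
#'   variant of a passing result.
#' @param known tibble of known genome-wide-significant variants
#'   (`chrom, pos`, optionally `rsid`).
#' @param panel a [ref_panel()] for LD with known variants.
#' @param r2_max correlation ceiling (default 0.2).
#' @param window distance window (default 250 kb).
#' @param excluded_genes character vector of genes named by prior MR
#'   studies (non-novel regardless of position).
#' @return tibble: `gene_id`, `novel`.
#' @export
assess_novelty <- function(hits, known, panel, r2_max = 0.2, window = 2.5e5,
                           excluded_genes = character(0)) {
  genes <- unique(hits$gene_id)
  novel <- setNames(rep(TRUE, length(genes)), genes)
  novel[genes %in% excluded_genes] <- FALSE
  if (nrow(known) > 0) {
    known_in_panel <- if ("rsid" %in% names(known))
      intersect(known$rsid, panel$variants$rsid) else character(0)
    for (g in genes) {
      if (!novel[g]) next
      hv <- hits[hits$gene_id == g, ]
      for (i in seq_len(nrow(hv))) {
        k_same <- known[known$chrom == hv$chrom[i], ]
        if (nrow(k_same) && any(abs(k_same$pos - hv$pos[i]) <= window)) {
          novel[g] <- FALSE; break
        }
        if (length(known_in_panel) && hv$rsid[i] %in% panel$variants$rsid) {
          r <- ld_corr(panel, c(hv$rsid[i], known_in_panel))[1, -1]
          if (any(r^2 >= r2_max)) { novel[g] <- FALSE; break }
        }
      }
    }
  }
  tibble::tibble(gene_id = genes, novel = as.vector(novel))
}

#' Build the per-gene ledger and prioritize
#'
#' Combines MR results, colocalization calls and instruments into the
#' per-gene rollup: passing results (MR-significant and colocalized) are
#' grouped into regions, flagged for horizontal pleiotropy, assessed for
#' novelty, and a gene is prioritized iff it passes, is the lone result in
#' its region, and is novel. Direction concordance across passing datasets
#' is reported (FALSE iff MR effect signs differ).
#'
#' @param mr tibble from [bonferroni_flag()].
#' @param coloc tibble with `gene_id, dataset_id, colocalized, pph4`
#'   (one row per MR-significant gene x dataset, from [pwcoco()] runs).
#' @param instruments tibble from [build_instruments()].
#' @param known known-locus tibble (`chrom, pos`, optional `rsid`).
#' @param panel a [ref_panel()].
#' @param config a [pipeline_config()].
#' @param excluded_genes genes named by prior MR studies.
#' @return list of class `gene_ledger`: `ledger` (per-gene tibble:
#'   gene_id, n_tested, n_significant, n_colocalized, passing, region_id,
#'   lone_in_region, pleiotropy, novel, direction_concordant,
#'   prioritized), `regions` (from [flag_pleiotropy()]), `hits` (per
#'   passing instrumental variant with region assignment).
#' @export
prioritize <- function(mr, coloc, instruments, known, panel,
                       config = pipeline_config(),
                       excluded_genes = character(0)) {
  key <- function(d) paste(d$gene_id, d$dataset_id, sep = "\r")
  pass_pairs <- key(coloc)[coloc$colocalized]
  mr$passing <- mr$significant & key(mr) %in% pass_pairs
  hits <- instruments[key(instruments) %in% key(mr)[mr$passing],
                      c("gene_id", "dataset_id", "chrom", "pos", "rsid")]
  hits <- group_regions(hits, window = config$region_window)
  regions <- flag_pleiotropy(hits)
  nov <- assess_novelty(hits, known, panel, r2_max = config$novelty_r2,
                        window = config$region_window,
                        excluded_genes = excluded_genes)
  per_gene <- lapply(split(mr, mr$gene_id), function(g) {
    pg <- g[g$passing, ]
    tibble::tibble(
      gene_id = g$gene_id[1],
      n_tested = nrow(g),
      n_significant = sum(g$significant),
      n_colocalized = nrow(pg),
      passing = nrow(pg) > 0,
      direction_concordant = if (nrow(pg))
        length(unique(sign(pg$beta_mr))) == 1 else NA)
  })
  ledger <- dplyr::bind_rows(per_gene)
  gene_region <- unique(hits[c("gene_id", "region_id", "lone_in_region")])
  ledger <- dplyr::left_join(ledger, gene_region, by = "gene_id")
  ledger <- dplyr::left_join(ledger, regions[c("region_id", "pleiotropy")],
                             by = "region_id")
  ledger <- dplyr::left_join(ledger, nov, by = "gene_id")
  ledger$prioritized <- ledger$passing &
    !is.na(ledger$lone_in_region) & ledger$lone_in_region &
    !is.na(ledger$novel) & ledger$novel
  structure(list(ledger = ledger, regions = regions, hits = hits),
            class = "gene_ledger")
}

#' @export
print.gene_ledger <- function(x, ...) {
  cat(sprintf("<gene_ledger> %d gene(s): %d passing, %d prioritized, %d region(s) (%d pleiotropic)\n",
              nrow(x$ledger), sum(x$ledger$passing),
              sum(x$ledger$prioritized), nrow(x$regions),
              sum(x$regions$pleiotropy)))
  invisible(x)
}

#' Phenome-wide scan of an instrumental variant with colocalization
#'
#' For a gene's instrument, queries the variant most strongly associated
#' with expression against a library of phenotype summary statistics. Per
#' phenotype: if the variant's association p-value is below
#' `config$phewas_p`, PWCoCo is run between the eQTL statistics and the
#' phenotype (window +/- `config$coloc_window` around the variant); the
#' hit passes iff both the p-value and PPH4 thresholds are met. The
#' variant-level Wald estimate is reported per higher genetically
#' predicted expression.
#'
#' @param instrument tibble rows from [build_instruments()] for one
#'   gene x dataset (the smallest `p_exp` variant is queried).
#' @param eqtl the gene's eQTL [region_sumstats()].
#' @param phenotypes named list of [region_sumstats()].
#' @param panel a [ref_panel()].
#' @param config a [pipeline_config()].
#' @return tibble: rsid, phenotype, beta, se, p (variant-level), mr_beta,
#'   pph4, colocalized, passes.
#' @export
phewas_scan <- function(instrument, eqtl, phenotypes, panel,
                        config = pipeline_config()) {
  stopifnot(nrow(instrument) >= 1)
  top <- instrument[which.min(instrument$p_exp), ]
  rows <- lapply(names(phenotypes), function(ph) {
    ss <- phenotypes[[ph]]
    i <- which(ss$stats$pos == top$pos)
    if (!length(i)) return(NULL)
    v <- ss$stats[i[1], ]
    flip <- v$ea == top$oa && v$oa == top$ea
    b_out <- if (flip) -v$beta else v$beta
    p <- v$pvalue
    pph4 <- NA_real_; colocalized <- FALSE
    if (p < config$phewas_p) {
      pw <- tryCatch(pwcoco(eqtl, ss, panel, config, center_pos = top$pos),
                     error = function(e) NULL)
      if (!is.null(pw)) { pph4 <- pw$best$pph4; colocalized <- pw$colocalized }
    }
    wr <- wald_ratio(top$beta_exp, top$se_exp, b_out, v$se)
    tibble::tibble(rsid = top$rsid, phenotype = ph,
                   beta = b_out, se = v$se, p = p,
                   mr_beta = wr$beta, pph4 = pph4,
                   colocalized = colocalized,
                   passes = p < config$phewas_p & colocalized)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- tibble::tibble(rsid = character(0), phenotype = character(0),
                          beta = numeric(0), se = numeric(0), p = numeric(0),
                          mr_beta = numeric(0), pph4 = numeric(0),
                          colocalized = logical(0), passes = logical(0))
  out
}
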