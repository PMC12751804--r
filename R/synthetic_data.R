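#' Scenario specification for synthetic data
#'
#' Defines one simulated cis region: an LD-structured genotype panel
#' (blocks of adjacent variants with AR(1) latent correlation `rho`,
#' near-zero LD across blocks), one or more eQTL "cell-type" datasets, and
#' a case-control GWAS that shares (or does not share) causal variants with
#' the eQTLs.
#'
#' Scenarios:
#' * `null` — no disease causal variant, `theta = 0`; causal eQTLs exist
#'   iff `eqtl_h2 > 0`.
#' * `shared_causal` — one variant drives both expression and disease.
#' * `distinct_causal` — expression and disease are driven by two different
#'   variants in LD (target r^2 `distinct_r2`): confounding by LD.
#' * `masked_secondary` — the GWAS carries a strong signal independent of
#'   the eQTL plus a weaker signal shared with it (exercises conditioning).
#' * `horizontal_pleiotropy` — one variant drives two genes' expression and
#'   disease.
#' * `vertical_causal` — variant -> expression -> disease with causal
#'   effect `theta` (log-odds per SD of expression).
#'
#' @param scenario one of the six scenario labels above.
#' @param n_variants variants in the region.
#' @param block_size variants per LD block.
#' @param rho within-block AR(1) latent correlation, `0 <= rho < 1`.
#' @param maf_range range minor-allele frequencies are drawn from.
#' @param n_ref reference-panel individuals.
#' @param n_eqtl eQTL-study sample size per dataset.
#' @param n_datasets number of eQTL datasets (cell types).
#' @param n_causal_eqtl causal cis-eQTL variants per gene.
#' @param eqtl_h2 fraction of expression variance explained by the causal
#'   eQTL(s), `0 <= eqtl_h2 < 1`.
#' @param n_case,n_control GWAS case/control counts (defaults emulate a
#'   large autoimmune-disease GWAS: 18,942 cases, 501,638 controls).
#' @param n_eff optional explicit effective GWAS sample size; when `NULL`,
#'   computed as [n_eff_cc()] from the counts.
#' @param gwas_varexp liability variance explained by each disease causal
#'   variant (non-vertical scenarios).
#' @param mask_varexp liability variance of the masking signal
#'   (`masked_secondary` only).
#' @param theta causal effect of expression on disease liability
#'   (`vertical_causal`; log-odds per SD expression).
#' @param distinct_r2 target LD r^2 between the two causal variants in
#'   `distinct_causal`.
#' @param chrom,pos_start,pos_spacing genomic coordinates of the region.
#' @param seed integer seed; all randomness flows from it.
#' @return a validated list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("null", "shared_causal", "distinct_causal",
                                       "masked_secondary", "horizontal_pleiotropy",
                                       "vertical_causal"),
                          n_variants = 100, block_size = 20, rho = 0.97,
                          maf_range = c(0.05, 0.5), n_ref = 2000,
                          n_eqtl = 500, n_datasets = 1, n_causal_eqtl = 1,
                          eqtl_h2 = 0.1,
                          n_case = 18942, n_control = 501638, n_eff = NULL,
                          gwas_varexp = 5e-4, mask_varexp = 2e-3,
                          theta = 0.3, distinct_r2 = 0.7,
                          chrom = "1", pos_start = 1e6, pos_spacing = 2000,
                          seed = 1) {
  scenario <- match.arg(scenario)
  # the masking scenario models a locus whose secondary signal is itself
  # unambiguously genome-wide significant (z ~ 8), the regime the
  # conditioning step is designed for
  if (scenario == "masked_secondary" && missing(gwas_varexp)) gwas_varexp <- 9e-4
  stopifnot(rho >= 0, rho < 1, eqtl_h2 >= 0, eqtl_h2 < 1,
            n_variants >= block_size, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            n_case > 0, n_control > 0, gwas_varexp >= 0, gwas_varexp < 1)
  if (scenario == "null") theta <- 0
  spec <- list(scenario = scenario, n_variants = n_variants, block_size = block_size,
               rho = rho, maf_range = maf_range, n_ref = n_ref, n_eqtl = n_eqtl,
               n_datasets = n_datasets, n_causal_eqtl = n_causal_eqtl,
               eqtl_h2 = eqtl_h2, n_case = n_case, n_control = n_control,
               n_eff = if (is.null(n_eff)) n_eff_cc(n_case, n_control) else n_eff,
               gwas_varexp = gwas_varexp, mask_varexp = mask_varexp,
               theta = theta, distinct_r2 = distinct_r2,
               chrom = as.character(chrom), pos_start = pos_start,
               pos_spacing = pos_spacing, seed = as.integer(seed))
  structure(spec, class = c("scenario_spec", "list"))
}

# Draw n individuals' dosages from the latent-Gaussian-threshold haplotype
# model described by `gen` (list: maf, blocks, rho). Two independent
# haplotypes per individual; within a block the latent Gaussian is AR(1)
# with parameter rho, across blocks independent, so adjacent-variant LD is
# ~ rho (attenuated by the binary thresholding) and cross-block LD ~ 0.
simulate_genotypes <- function(n, gen) {
  m <- length(gen$maf)
  thr <- qnorm(gen$maf)
  block_start <- rep(FALSE, m)
  block_start[cumsum(c(1, head(gen$blocks, -1)))] <- TRUE
  hap <- function() {
    Z <- matrix(rnorm(2L * n * m), nrow = 2L * n)
    for (j in 2:m) {
      if (!block_start[j])
        Z[, j] <- gen$rho * Z[, j - 1] + sqrt(1 - gen$rho^2) * Z[, j]
    }
    Z
  }
  H <- sweep(hap(), 2, thr, "<") * 1
  H[seq_len(n), ] + H[n + seq_len(n), ]
}

#' Simulate an LD reference panel
#'
#' Draws `n_ref` individuals' dosages under the block-AR(1)
#' latent-Gaussian-threshold haplotype model of the scenario. The returned
#' panel carries its generative parameters (element `gen`) so that
#' independent study cohorts can be drawn from the same population.
#'
#' @param spec a [scenario_spec()].
#' @return a [ref_panel()] with an extra element `gen`.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  m <- spec$n_variants
  nb <- ceiling(m / spec$block_size)
  blocks <- rep(spec$block_size, nb)
  blocks[nb] <- m - spec$block_size * (nb - 1)
  maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
  gen <- list(maf = maf, blocks = blocks, rho = spec$rho)
  dos <- simulate_genotypes(spec$n_ref, gen)
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE), ncol = 2)
  # avoid palindromic and identical pairs so QC keeps everything
  fix <- alleles[, 1] == alleles[, 2] |
    is_palindromic(alleles[, 1], alleles[, 2])
  alleles[fix, 2] <- ifelse(alleles[fix, 1] %in% c("A", "T"), "C", "A")
  variants <- tibble::tibble(
    chrom = spec$chrom,
    pos = spec$pos_start + (seq_len(m) - 1L) * spec$pos_spacing,
    rsid = sprintf("rs%s_%04d", substr(spec$scenario, 1, 3), seq_len(m)),
    ea = alleles[, 1], oa = alleles[, 2])
  p <- ref_panel(variants, dos)
  p$gen <- gen
  p
}

# Pair of variants within the anchor's block whose empirical panel r^2 is
# closest to target; among near-ties (within 0.02) the most separated pair
# is preferred, so the two variants' LD profiles differ as much as the
# target allows.
closest_r2_pair <- function(panel, anchor_idx, target_r2) {
  gen <- panel$gen
  block_id <- rep(seq_along(gen$blocks), gen$blocks)
  blk <- which(block_id == block_id[anchor_idx])
  R2 <- cor(panel$dosages[, blk, drop = FALSE])^2
  pairs <- which(upper.tri(R2), arr.ind = TRUE)
  dev <- abs(R2[pairs] - target_r2)
  near <- which(dev <= min(dev) + 0.02)
  best <- near[which.max(pairs[near, 2] - pairs[near, 1])]
  blk[pairs[best, ]]
}

#' Ground truth of a simulated scenario
#'
#' Chooses the causal variants deterministically from the panel and records
#' them (with standardized effects) before any study noise is drawn.
#'
#' @param spec a [scenario_spec()].
#' @param panel the panel from [simulate_panel()] for this spec.
#' @return list of class `ground_truth`: `scenario`, `eqtl_causal` (tibble
#'   rsid, beta_std), `gwas_causal` (tibble rsid, gamma = liability-scale
#'   standardized effect), `theta`, `shared` (logical).
#' @export
ground_truth <- function(spec, panel) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(panel, "ref_panel"))
  m <- spec$n_variants
  # middle of the central block, away from region edges
  anchor <- floor(m * 0.55)
  partner <- NA_integer_
  if (spec$scenario == "distinct_causal") {
    pair <- closest_r2_pair(panel, anchor, spec$distinct_r2)
    anchor <- pair[1]; partner <- pair[2]
  }
  eqtl_idx <- integer(0)
  if (spec$eqtl_h2 > 0) {
    eqtl_idx <- anchor
    if (spec$n_causal_eqtl > 1) {
      extra <- setdiff(round(seq(m * 0.15, m * 0.85, length.out = spec$n_causal_eqtl)),
                       anchor)
      eqtl_idx <- sort(c(anchor, extra))[seq_len(spec$n_causal_eqtl)]
    }
  }
  beta_std <- numeric(0)
  if (length(eqtl_idx)) {
    u <- rep(1, length(eqtl_idx))
    Rc <- cor(panel$dosages[, eqtl_idx, drop = FALSE])
    beta_std <- u * sqrt(spec$eqtl_h2 / drop(t(u) %*% Rc %*% u))
  }
  gamma_of <- function(varexp) sqrt(varexp)
  gwas <- switch(spec$scenario,
    null = tibble::tibble(rsid = character(0), gamma = numeric(0)),
    shared_causal = tibble::tibble(rsid = panel$variants$rsid[anchor],
                                   gamma = gamma_of(spec$gwas_varexp)),
    distinct_causal = tibble::tibble(rsid = panel$variants$rsid[partner],
                                     gamma = gamma_of(spec$gwas_varexp)),
    masked_secondary = {
      mask <- floor(spec$block_size / 2)  # first block: independent of anchor
      tibble::tibble(rsid = panel$variants$rsid[c(mask, anchor)],
                     gamma = c(gamma_of(spec$mask_varexp), gamma_of(spec$gwas_varexp)))
    },
    horizontal_pleiotropy = tibble::tibble(rsid = panel$variants$rsid[anchor],
                                           gamma = gamma_of(spec$gwas_varexp)),
    vertical_causal = tibble::tibble(rsid = panel$variants$rsid[eqtl_idx],
                                     gamma = spec$theta * beta_std))
  structure(list(
    scenario = spec$scenario,
    eqtl_causal = tibble::tibble(rsid = panel$variants$rsid[eqtl_idx],
                                 beta_std = beta_std),
    gwas_causal = gwas,
    theta = if (spec$scenario == "vertical_causal") spec$theta else 0,
    shared = spec$scenario %in% c("shared_causal", "masked_secondary",
                                  "horizontal_pleiotropy", "vertical_causal")),
    class = c("ground_truth", "list"))
}

#' Simulate per-variant eQTL summary statistics for one dataset
#'
#' Draws an independent cohort of `n_eqtl` individuals from the panel's
#' generative model, forms expression `y = X_causal %*% beta + e` with the
#' causal variants jointly explaining `eqtl_h2` of the variance, and
#' returns the per-variant marginal regression statistics.
#'
#' @param panel panel from [simulate_panel()] (must carry `gen`).
#' @param spec the [scenario_spec()].
#' @param truth a [ground_truth()].
#' @param dataset_id,cell_type,gene_id labels for the output.
#' @param seed seed for this dataset's draws.
#' @return a [region_sumstats()] (quantitative).
#' @export
simulate_eqtl_sumstats <- function(panel, spec, truth, dataset_id = "d1",
                                   cell_type = "cell", gene_id = "gene1",
                                   seed = spec$seed + 1L) {
  stopifnot(!is.null(panel$gen))
  set.seed(seed)
  n <- spec$n_eqtl
  X <- simulate_genotypes(n, panel$gen)
  idx <- match(truth$eqtl_causal$rsid, panel$variants$rsid)
  g <- if (length(idx)) {
    Xc <- scale(X[, idx, drop = FALSE])
    drop(Xc %*% truth$eqtl_causal$beta_std)
  } else 0
  h2 <- if (length(idx)) var(g) else 0
  y <- g + rnorm(n, 0, sqrt(max(1 - h2, 1e-8)))
  marginal_stats_from(X, y, panel$variants, n, trait = list(
    trait_id = paste0(gene_id, "@", dataset_id), trait_type = "quantitative",
    dataset_id = dataset_id, cell_type = cell_type, gene_id = gene_id))
}

# Vectorized per-variant simple linear regression of y on each column of X.
marginal_stats_from <- function(X, y, variants, n, trait) {
  xm <- colMeans(X)
  Sxx <- colSums(X^2) - n * xm^2
  keep <- Sxx > 0
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  Sxy <- drop(crossprod(X, yc))
  b <- Sxy / Sxx
  se2 <- pmax(Syy - b * Sxy, 0) / ((n - 2) * Sxx)
  se <- sqrt(se2)
  stats <- tibble::tibble(
    chrom = variants$chrom, pos = variants$pos, rsid = variants$rsid,
    ea = variants$ea, oa = variants$oa, eaf = xm / 2,
    beta = b, se = se, pvalue = 2 * pnorm(-abs(b / se)), n = n)[keep, ]
  region_sumstats(stats, trait_id = trait$trait_id, trait_type = trait$trait_type,
                  dataset_id = trait$dataset_id, cell_type = trait$cell_type,
                  gene_id = trait$gene_id, validate = FALSE)
}

#' Simulate case-control GWAS summary statistics
#'
#' Summary-level simulation: z-scores are drawn from
#' `z ~ MVN(R lambda, R)` where `R` is the panel LD matrix and
#' `lambda_j = sqrt(n_eff) * gamma_j`, with `gamma_j` the liability-scale
#' standardized effect recorded in the ground truth (zero elsewhere) and
#' `n_eff = 4/(1/n_case + 1/n_control)`. Betas are recovered as `z * se`
#' with `se = 1/sqrt(n_eff * 2 * eaf * (1 - eaf))`. This preserves the
#' LD/z-score structure consumed by colocalization and conditional analysis
#' without simulating hundreds of thousands of individuals.
#'
#' @param panel panel from [simulate_panel()].
#' @param spec the [scenario_spec()].
#' @param truth a [ground_truth()].
#' @param trait_id label.
#' @param seed seed for the z draw.
#' @return a [region_sumstats()] (case_control).
#' @export
simulate_gwas_sumstats <- function(panel, spec, truth, trait_id = "disease",
                                   seed = spec$seed + 2L) {
  set.seed(seed)
  m <- nrow(panel$variants)
  R <- ld_chol(panel)
  lam <- numeric(m)
  idx <- match(truth$gwas_causal$rsid, panel$variants$rsid)
  lam[idx] <- sqrt(spec$n_eff) * truth$gwas_causal$gamma
  z <- unname(drop(R$R %*% lam) + drop(R$L %*% rnorm(m)))
  f <- panel$variants$eaf
  se <- 1 / sqrt(spec$n_eff * 2 * f * (1 - f))
  stats <- tibble::tibble(
    chrom = panel$variants$chrom, pos = panel$variants$pos,
    rsid = panel$variants$rsid, ea = panel$variants$ea, oa = panel$variants$oa,
    eaf = f, beta = z * se, se = se, pvalue = 2 * pnorm(-abs(z)),
    n = spec$n_case + spec$n_control, n_case = spec$n_case,
    n_control = spec$n_control)
  region_sumstats(stats, trait_id = trait_id, trait_type = "case_control",
                  validate = FALSE)
}

# LD matrix of the whole panel plus a PSD square root; caches on the panel
# environment is avoided (panels are plain lists) so callers in loops
# should reuse the returned object where speed matters.
ld_chol <- function(panel) {
  R <- cor(panel$dosages)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 0) {
    message("LD matrix repaired by eigenvalue clipping at 1e-8")
    e$values <- pmax(e$values, 1e-8)
    R <- e$vectors %*% (e$values * t(e$vectors))
    R <- R / sqrt(diag(R) %o% diag(R))
    e <- eigen(R, symmetric = TRUE)
    e$values <- pmax(e$values, 0)
  }
  L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  list(R = R, L = L)
}

#' Write a complete scenario fixture set to disk
#'
#' Writes the reference panel, eQTL summary statistics (one file per
#' dataset), GWAS summary statistics, gene annotation, known-locus list
#' (empty by default) and a `ground_truth.json` sidecar in the package's
#' external formats. For `horizontal_pleiotropy` two genes with nearby TSSs
#' share the causal variant and a dataset is written per gene.
#'
#' @param spec a [scenario_spec()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (named file paths) and `truth`.
#' @export
make_scenario_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- simulate_panel(spec)
  truth <- ground_truth(spec, panel)
  paths <- list(panel = file.path(dir, "panel"))
  write_panel(panel, paths$panel)
  genes <- if (spec$scenario == "horizontal_pleiotropy") c("geneA", "geneB") else "gene1"
  tss <- spec$pos_start + floor(spec$n_variants / 2) * spec$pos_spacing
  annot <- tibble::tibble(gene_id = genes, chrom = spec$chrom,
                          tss = tss + (seq_along(genes) - 1L) * 5e4,
                          protein_coding = TRUE)
  paths$genes <- file.path(dir, "genes.tsv")
  readr::write_tsv(annot, paths$genes, progress = FALSE)
  k <- 0L
  eqtl_paths <- character(0)
  for (g in genes) {
    for (d in seq_len(spec$n_datasets)) {
      k <- k + 1L
      ss <- simulate_eqtl_sumstats(panel, spec, truth,
                                   dataset_id = paste0("ds", d),
                                   cell_type = paste0("cell", d), gene_id = g,
                                   seed = spec$seed + 10L * k)
      p <- file.path(dir, sprintf("eqtl_%s_ds%d.tsv", g, d))
      write_sumstats(ss, p)
      eqtl_paths <- c(eqtl_paths, p)
    }
  }
  paths$eqtl <- eqtl_paths
  gwas <- simulate_gwas_sumstats(panel, spec, truth, seed = spec$seed + 997L)
  paths$gwas <- file.path(dir, "gwas.tsv")
  write_sumstats(gwas, paths$gwas)
  paths$known_loci <- file.path(dir, "known_loci.tsv")
  readr::write_tsv(tibble::tibble(chrom = character(0), pos = numeric(0),
                                  rsid = character(0)),
                   paths$known_loci, progress = FALSE)
  paths$truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(scenario = truth$scenario,
                            eqtl_causal = truth$eqtl_causal,
                            gwas_causal = truth$gwas_causal,
                            theta = truth$theta, shared = truth$shared),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  list(paths = paths, truth = truth)
}

#' Simulate a multi-gene planted study
#'
#' Builds one chromosome with `n_genes` well-separated cis regions sharing
#' a single reference panel: `n_shared` genes with a shared causal variant
#' (expression and disease), `n_pleio_pairs` pairs of genes in one region
#' whose expressions and the disease are all driven by the same variant,
#' and the remainder null genes (no causal eQTL, no disease signal).
#'
#' @param n_genes total genes.
#' @param n_shared planted shared-causal (lone, novel) genes.
#' @param n_pleio_pairs planted horizontal-pleiotropy gene pairs.
#' @param seed master seed.
#' @param n_variants,block_size,rho,maf_range,n_ref,n_eqtl,eqtl_h2,gwas_varexp,n_case,n_control,n_eff
#'   per-region generator settings, as in [scenario_spec()];
#'   `n_variants` is per gene region.
#' @param region_gap base-pair gap between adjacent gene regions.
#' @param replication also simulate a replication arm sharing the causal
#'   structure: a whole-blood-style eQTL source (`n_repl_eqtl` donors) and
#'   two non-overlapping smaller case-control GWAS for meta-analysis.
#' @param n_repl_eqtl,repl1_case,repl1_control,repl2_case,repl2_control
#'   replication arm sample sizes (defaults emulate a 757-donor eQTL study
#'   and GWAS of 6,451/109,410 and 409/482 cases/controls).
#' @return list: `panel`, `eqtl` (list of [region_sumstats()], one per
#'   gene), `gwas`, `annotation`, `known_loci` (empty tibble), `truth`
#'   (list with `planted_genes`, `pleio_pairs`, `causal` tibble); with
#'   `replication = TRUE` also `repl_eqtl`, `gwas_repl1`, `gwas_repl2`.
#' @export
simulate_study <- function(n_genes = 50, n_shared = 3, n_pleio_pairs = 2, seed = 1,
                           n_variants = 40, block_size = 20, rho = 0.9,
                           maf_range = c(0.05, 0.5), n_ref = 1500, n_eqtl = 500,
                           eqtl_h2 = 0.15, gwas_varexp = 8e-4,
                           n_case = 18942, n_control = 501638, n_eff = NULL,
                           region_gap = 2e6, replication = FALSE,
                           n_repl_eqtl = 757, repl1_case = 6451,
                           repl1_control = 109410, repl2_case = 409,
                           repl2_control = 482) {
  stopifnot(n_shared + 2 * n_pleio_pairs <= n_genes)
  n_regions <- n_genes - n_pleio_pairs  # each pleio pair shares one region
  gene_names <- sprintf("gene%02d", seq_len(n_genes))
  planted <- gene_names[seq_len(n_shared)]
  pleio <- if (n_pleio_pairs > 0)
    lapply(seq_len(n_pleio_pairs), function(i)
      gene_names[n_shared + c(2 * i - 1, 2 * i)]) else list()
  null_genes <- setdiff(gene_names, c(planted, unlist(pleio)))

  # region assignment: planted and pleio regions first, then null genes
  region_of <- integer(n_genes); names(region_of) <- gene_names
  r <- 0L
  for (g in planted) { r <- r + 1L; region_of[g] <- r }
  for (pair in pleio) { r <- r + 1L; region_of[pair] <- r }
  for (g in null_genes) { r <- r + 1L; region_of[g] <- r }

  panels <- vector("list", n_regions)
  gwas_parts <- vector("list", n_regions)
  repl1_parts <- vector("list", n_regions)
  repl2_parts <- vector("list", n_regions)
  eqtl <- list()
  repl_eqtl <- list()
  causal <- list()
  annot <- list()
  for (reg in seq_len(n_regions)) {
    genes_here <- names(region_of)[region_of == reg]
    is_planted <- genes_here[1] %in% planted
    is_pleio <- length(genes_here) == 2
    scen <- if (is_planted || is_pleio) "shared_causal" else "null"
    spec <- scenario_spec(scen, n_variants = n_variants, block_size = block_size,
                          rho = rho, maf_range = maf_range, n_ref = n_ref,
                          n_eqtl = n_eqtl,
                          eqtl_h2 = if (scen == "null") 0 else eqtl_h2,
                          n_case = n_case, n_control = n_control, n_eff = n_eff,
                          gwas_varexp = gwas_varexp,
                          pos_start = 1e6 + (reg - 1) * region_gap,
                          seed = (as.numeric(seed) * 131 + reg) %% 2147483629)
    panel <- simulate_panel(spec)
    # region-unique rsids
    panel$variants$rsid <- sprintf("rs%03d_%04d", reg, seq_len(n_variants))
    colnames(panel$dosages) <- panel$variants$rsid
    truth <- ground_truth(spec, panel)
    panels[[reg]] <- panel
    for (gi in seq_along(genes_here)) {
      g <- genes_here[gi]
      eqtl[[g]] <- simulate_eqtl_sumstats(
        panel, spec, truth, dataset_id = "ds1", cell_type = "cell1", gene_id = g,
        seed = (as.numeric(spec$seed) + 7 * gi) %% 2147483629)
      annot[[g]] <- tibble::tibble(
        gene_id = g, chrom = spec$chrom,
        tss = spec$pos_start + floor(n_variants / 2) * spec$pos_spacing + (gi - 1) * 5e4,
        protein_coding = TRUE)
      causal[[g]] <- tibble::tibble(
        gene_id = g, region = reg,
        causal_rsid = if (nrow(truth$eqtl_causal)) truth$eqtl_causal$rsid else NA_character_,
        disease_causal = nrow(truth$gwas_causal) > 0)
    }
    gwas_parts[[reg]] <- simulate_gwas_sumstats(panel, spec, truth,
                                                seed = (as.numeric(spec$seed) + 991) %% 2147483629)$stats
    if (replication) {
      for (gi in seq_along(genes_here)) {
        g <- genes_here[gi]
        spec_r <- spec; spec_r$n_eqtl <- n_repl_eqtl
        repl_eqtl[[g]] <- simulate_eqtl_sumstats(
          panel, spec_r, truth, dataset_id = "repl_wb", cell_type = "whole_blood",
          gene_id = g, seed = (as.numeric(spec$seed) + 37 * gi) %% 2147483629)
      }
      spec_r1 <- spec; spec_r1$n_case <- repl1_case; spec_r1$n_control <- repl1_control
      spec_r1$n_eff <- n_eff_cc(repl1_case, repl1_control)
      repl1_parts[[reg]] <- simulate_gwas_sumstats(
        panel, spec_r1, truth, trait_id = "disease_repl1",
        seed = (as.numeric(spec$seed) + 1993) %% 2147483629)$stats
      spec_r2 <- spec; spec_r2$n_case <- repl2_case; spec_r2$n_control <- repl2_control
      spec_r2$n_eff <- n_eff_cc(repl2_case, repl2_control)
      repl2_parts[[reg]] <- simulate_gwas_sumstats(
        panel, spec_r2, truth, trait_id = "disease_repl2",
        seed = (as.numeric(spec$seed) + 2999) %% 2147483629)$stats
    }
  }
  all_variants <- do.call(rbind, lapply(panels, function(p) p$variants))
  all_dos <- do.call(cbind, lapply(panels, function(p) p$dosages))
  panel <- ref_panel(all_variants[c("chrom", "pos", "rsid", "ea", "oa")], all_dos)
  gwas <- region_sumstats(do.call(rbind, gwas_parts), trait_id = "disease",
                          trait_type = "case_control", validate = FALSE)
  out <- list(panel = panel,
              eqtl = eqtl,
              gwas = gwas,
              annotation = do.call(rbind, annot),
              known_loci = tibble::tibble(chrom = character(0), pos = numeric(0),
                                          rsid = character(0)),
              truth = list(planted_genes = planted, pleio_pairs = pleio,
                           null_genes = null_genes,
                           causal = do.call(rbind, causal)))
  if (replication) {
    out$repl_eqtl <- repl_eqtl
    out$gwas_repl1 <- region_sumstats(do.call(rbind, repl1_parts),
                                      trait_id = "disease_repl1",
                                      trait_type = "case_control", validate = FALSE)
    out$gwas_repl2 <- region_sumstats(do.call(rbind, repl2_parts),
                                      trait_id = "disease_repl2",
                                      trait_type = "case_control", validate = FALSE)
  }
  out
}
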