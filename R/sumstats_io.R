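#' @importFrom stats pnorm pchisq cor var median qnorm rnorm rbinom runif setNames complete.cases
#' @importFrom utils head modifyList
NULL

canonical_cols <- c("chrom", "pos", "rsid", "ea", "oa", "eaf", "beta", "se",
                    "pvalue", "n", "n_case", "n_control")
mandatory_cols <- c("chrom", "pos", "ea", "oa", "beta", "se", "n")

#' Per-region summary statistics container
#'
#' Bundles a table of per-variant associations (one trait, one genomic
#' window) with trait metadata. Effect sizes are additive per copy of the
#' effect allele; for case-control traits `beta` is a log odds ratio.
#'
#' @param stats data frame with columns `chrom, pos, rsid, ea, oa, eaf,
#'   beta, se, pvalue, n` and optionally `n_case, n_control`.
#' @param trait_id trait label.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param dataset_id,cell_type,gene_id optional provenance metadata
#'   (eQTL traits carry `gene_id`).
#' @param validate run [validate_sumstats()] (drops invalid rows, warns on
#'   beta/se vs p inconsistency)?
#' @return an object of class `region_sumstats`: a list with elements
#'   `stats` (tibble sorted by position), `trait_id`, `trait_type`,
#'   `dataset_id`, `cell_type`, `gene_id`.
#' @export
region_sumstats <- function(stats, trait_id, trait_type = c("quantitative", "case_control"),
                            dataset_id = NA_character_, cell_type = NA_character_,
                            gene_id = NA_character_, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stats <- tibble::as_tibble(stats)
  for (col in setdiff(canonical_cols, names(stats))) {
    stats[[col]] <- if (col %in% c("chrom", "rsid", "ea", "oa")) NA_character_ else NA_real_
  }
  stats <- stats[canonical_cols]
  stats$chrom <- as.character(stats$chrom)
  x <- structure(
    list(stats = stats, trait_id = trait_id, trait_type = trait_type,
         dataset_id = dataset_id, cell_type = cell_type, gene_id = gene_id),
    class = "region_sumstats")
  if (validate) x <- validate_sumstats(x) else x$stats <- x$stats[order(x$stats$pos), ]
  x
}

#' @export
print.region_sumstats <- function(x, ...) {
  cat(sprintf("<region_sumstats> trait %s (%s)%s: %d variants, chr%s:%s-%s\n",
              x$trait_id, x$trait_type,
              if (!is.na(x$gene_id)) paste0(" gene ", x$gene_id) else "",
              nrow(x$stats), x$stats$chrom[1],
              format(min(x$stats$pos)), format(max(x$stats$pos))))
  invisible(x)
}

#' Validate and clean a region_sumstats object
#'
#' Enforces the per-variant invariants: `se > 0`, `0 < eaf < 1` (when
#' present), `ea != oa`, alleles in A/C/G/T, finite beta, single chromosome,
#' no duplicate (pos, ea, oa) triples. Rows failing any check are dropped
#' with a message giving the count. Missing p-values are recomputed from
#' beta/se under the two-sided normal approximation; p-values disagreeing
#' with |beta/se| by more than 10% relative on the -log10 scale trigger a
#' warning.
#'
#' @param x a `region_sumstats`.
#' @return the cleaned object, records sorted by position.
#' @export
validate_sumstats <- function(x) {
  s <- x$stats
  if (nrow(s) == 0) stop("no summary-statistic rows")
  ok <- !is.na(s$pos) & !is.na(s$beta) & is.finite(s$beta) &
    !is.na(s$se) & s$se > 0 &
    (is.na(s$eaf) | (s$eaf > 0 & s$eaf < 1)) &
    s$ea %in% c("A", "C", "G", "T") & s$oa %in% c("A", "C", "G", "T") &
    s$ea != s$oa & !is.na(s$n) & s$n > 0
  ok[is.na(ok)] <- FALSE
  dup <- duplicated(s[c("pos", "ea", "oa")])
  ok <- ok & !dup
  if (any(!ok)) message(sum(!ok), " summary-statistic row(s) dropped during validation")
  s <- s[ok, ]
  if (nrow(s) == 0) stop("zero valid summary-statistic rows after validation")
  if (length(unique(s$chrom)) > 1) stop("records span multiple chromosomes")
  z <- abs(s$beta / s$se)
  p_norm <- 2 * pnorm(-z)
  recompute <- is.na(s$pvalue) | s$pvalue <= 0 | s$pvalue > 1
  s$pvalue[recompute] <- p_norm[recompute]
  chk <- !recompute & s$pvalue < 0.5 & p_norm > 0
  if (any(chk)) {
    rel <- abs(log10(s$pvalue[chk]) - log10(p_norm[chk])) /
      pmax(abs(log10(p_norm[chk])), 1)
    if (any(rel > 0.1, na.rm = TRUE)) {
      warning(sum(rel > 0.1, na.rm = TRUE),
              " p-value(s) inconsistent with beta/se by >10% on the -log10 scale")
    }
  }
  x$stats <- s[order(s$pos), ]
  x
}

#' Read per-variant summary statistics
#'
#' Reads a tab-delimited file with header into a [region_sumstats()].
#' Canonical columns are `chrom, pos, rsid, ea, oa, eaf, beta, se, pvalue,
#' n, n_case, n_control`; foreign headers are handled through `dialect`, a
#' named character vector mapping canonical names to file column names.
#' Rows failing type coercion or the type invariants are dropped with a
#' logged count; a missing mandatory column or zero valid rows is fatal.
#'
#' @param path file path.
#' @param trait_id,trait_type,dataset_id,cell_type,gene_id metadata, see
#'   [region_sumstats()].
#' @param dialect optional named character vector, e.g.
#'   `c(chrom = "CHR", pos = "BP", ea = "A1", ...)`.
#' @return a `region_sumstats`.
#' @export
read_sumstats <- function(path, trait_id = basename(path),
                          trait_type = c("quantitative", "case_control"),
                          dataset_id = NA_character_, cell_type = NA_character_,
                          gene_id = NA_character_, dialect = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(raw))
        stop("dialect column not in file: ", dialect[[canon]])
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  missing <- setdiff(mandatory_cols, names(raw))
  if (length(missing)) stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  n0 <- nrow(raw)
  num_cols <- intersect(c("pos", "eaf", "beta", "se", "pvalue", "n", "n_case", "n_control"),
                        names(raw))
  for (col in num_cols) raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  coerced_ok <- rowSums(is.na(raw[intersect(mandatory_cols, num_cols)])) == 0
  if (any(!coerced_ok)) message(sum(!coerced_ok), " row(s) dropped: failed numeric coercion")
  raw <- raw[coerced_ok, ]
  if (nrow(raw) == 0) stop("zero valid rows in ", path)
  region_sumstats(raw, trait_id = trait_id, trait_type = trait_type,
                  dataset_id = dataset_id, cell_type = cell_type, gene_id = gene_id)
}

#' Write summary statistics to a tab-delimited file
#'
#' Inverse of [read_sumstats()]: numeric values round-trip exactly.
#'
#' @param x a `region_sumstats`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "region_sumstats"))
  readr::write_tsv(x$stats, path, progress = FALSE)
  invisible(path)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches two traits' records on (chrom, pos) and expresses the outcome
#' effect on the exposure's effect allele. If the outcome's alleles are
#' swapped relative to the exposure, its beta sign and allele frequency are
#' flipped. Strand-ambiguous (A/T, C/G) variants and allele sets that cannot
#' be reconciled are dropped, with counts in the `dropped` attribute.
#' Harmonizing an already-harmonized pair is a no-op.
#'
#' @param exposure,outcome `region_sumstats` on the same chromosome.
#' @return tibble with one row per shared variant: `chrom, pos, rsid, ea,
#'   oa, eaf_exp, beta_exp, se_exp, p_exp, n_exp` and the corresponding
#'   `_out` columns (plus `n_case_out`, `n_control_out`). Attribute
#'   `dropped` holds counts of palindromic and irreconcilable exclusions.
#' @export
harmonize_pair <- function(exposure, outcome) {
  stopifnot(inherits(exposure, "region_sumstats"), inherits(outcome, "region_sumstats"))
  e <- exposure$stats; o <- outcome$stats
  if (e$chrom[1] != o$chrom[1]) stop("exposure and outcome are on different chromosomes")
  m <- match(e$pos, o$pos)
  keep <- !is.na(m)
  e <- e[keep, ]; o <- o[m[keep], ]
  n_pal <- 0L; n_bad <- 0L
  if (nrow(e)) {
    pal <- is_palindromic(e$ea, e$oa) | is_palindromic(o$ea, o$oa)
    n_pal <- sum(pal)
    e <- e[!pal, ]; o <- o[!pal, ]
  }
  if (nrow(e)) {
    same <- e$ea == o$ea & e$oa == o$oa
    swap <- e$ea == o$oa & e$oa == o$ea
    n_bad <- sum(!(same | swap))
    if (n_bad) message(n_bad, " variant(s) dropped: irreconcilable alleles")
    keep2 <- same | swap
    e <- e[keep2, ]
    o <- o[keep2, ]
    swap <- swap[keep2]
    o$beta[swap] <- -o$beta[swap]
    o$eaf[swap] <- 1 - o$eaf[swap]
    tmp <- o$ea[swap]; o$ea[swap] <- o$oa[swap]; o$oa[swap] <- tmp
  }
  out <- tibble::tibble(
    chrom = e$chrom, pos = e$pos, rsid = e$rsid, ea = e$ea, oa = e$oa,
    eaf_exp = e$eaf, beta_exp = e$beta, se_exp = e$se, p_exp = e$pvalue, n_exp = e$n,
    eaf_out = o$eaf, beta_out = o$beta, se_out = o$se, p_out = o$pvalue, n_out = o$n,
    n_case_out = o$n_case, n_control_out = o$n_control)
  attr(out, "dropped") <- c(palindromic = n_pal, irreconcilable = n_bad)
  out
}

#' Read a gene annotation table
#'
#' BED-like tab-delimited file with header columns `gene_id, chrom, tss,
#' protein_coding` (0/1 or TRUE/FALSE).
#'
#' @param path file path.
#' @return tibble with those columns, `protein_coding` as logical.
#' @export
read_gene_annotation <- function(path) {
  a <- readr::read_tsv(path, col_types = "ccdl", progress = FALSE)
  stopifnot(all(c("gene_id", "chrom", "tss", "protein_coding") %in% names(a)))
  a
}
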