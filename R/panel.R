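#' LD reference panel
#'
#' Holds an ordered variant index and an individuals x variants additive
#' dosage matrix in [0, 2], used for all LD (correlation) queries, clumping,
#' conditional analysis and novelty checks.
#'
#' @param variants data frame with columns `chrom, pos, rsid, ea, oa` and
#'   optionally `eaf` (recomputed from dosages when absent).
#' @param dosages numeric matrix, individuals x variants, columns in the
#'   same order as `variants`; column names set to `rsid`.
#' @return object of class `ref_panel`: list with `variants` (tibble),
#'   `dosages`, `n_ref`.
#' @export
ref_panel <- function(variants, dosages) {
  variants <- tibble::as_tibble(variants)
  stopifnot(ncol(dosages) == nrow(variants),
            all(c("chrom", "pos", "rsid", "ea", "oa") %in% names(variants)))
  if (anyDuplicated(variants$rsid)) stop("duplicate rsids in panel variant index")
  if (min(dosages) < 0 || max(dosages) > 2) stop("dosages must lie in [0, 2]")
  variants$chrom <- as.character(variants$chrom)
  variants$eaf <- colMeans(dosages) / 2
  colnames(dosages) <- variants$rsid
  structure(list(variants = variants, dosages = dosages, n_ref = nrow(dosages)),
            class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d individuals x %d variants (chr %s)\n",
              x$n_ref, nrow(x$variants), paste(unique(x$variants$chrom), collapse = ",")))
  invisible(x)
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' Standard 1-df goodness-of-fit chi-square of observed genotype counts
#' against Hardy-Weinberg proportions at the observed allele frequency.
#'
#' @param n_aa,n_ab,n_bb counts of the three genotype classes.
#' @return list with `chisq` and `p`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(list(chisq = NA_real_, p = NA_real_))
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  e <- c(n * p^2, 2 * n * p * q, n * q^2)
  o <- c(n_aa, n_ab, n_bb)
  if (any(e == 0)) return(list(chisq = 0, p = 1))  # monomorphic
  chisq <- sum((o - e)^2 / e)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Reference-panel quality control
#'
#' Restricts the panel to variants with minor-allele frequency >=
#' `maf_min`, Hardy-Weinberg 1-df chi-square p >= `hwe_p_min` (computed on
#' hard calls, i.e. dosages rounded to the nearest integer), and
#' non-strand-ambiguous alleles (A/T and C/G pairs removed). Idempotent.
#'
#' @param panel a [ref_panel()].
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @return the filtered `ref_panel`; removing every variant is an error.
#' @export
panel_qc <- function(panel, maf_min = 0.01, hwe_p_min = 1e-6) {
  stopifnot(inherits(panel, "ref_panel"))
  f <- panel$variants$eaf
  maf_ok <- pmin(f, 1 - f) >= maf_min
  hard <- round(panel$dosages)
  hwe_p <- vapply(seq_len(ncol(hard)), function(j) {
    g <- hard[, j]
    hwe_test(sum(g == 2), sum(g == 1), sum(g == 0))$p
  }, numeric(1))
  hwe_ok <- is.na(hwe_p) | hwe_p >= hwe_p_min
  amb <- is_palindromic(panel$variants$ea, panel$variants$oa)
  keep <- maf_ok & hwe_ok & !amb
  if (!any(keep)) stop("panel QC removed every variant")
  if (any(!keep)) message(sum(!keep), " panel variant(s) removed by QC")
  out <- panel
  out$variants <- panel$variants[keep, ]
  out$dosages <- panel$dosages[, keep, drop = FALSE]
  out
}

#' LD correlation matrix for a set of panel variants
#'
#' Pearson correlation of dosage columns, optionally re-aligned so each
#' variant's axis points along a caller-specified effect allele (flipping a
#' variant's effect allele negates its row and column).
#'
#' @param panel a [ref_panel()].
#' @param rsids variant identifiers; all must be present in the panel.
#' @param effect_allele optional character vector (parallel to `rsids` or
#'   named by them): where it equals the panel's other allele the variant's
#'   correlations are sign-flipped; any other mismatch is an error.
#' @return symmetric correlation matrix with unit diagonal, dimnames
#'   `rsids`.
#' @export
ld_corr <- function(panel, rsids, effect_allele = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  idx <- match(rsids, panel$variants$rsid)
  if (anyNA(idx)) stop("variant(s) absent from panel: ",
                       paste(rsids[is.na(idx)], collapse = ", "))
  X <- panel$dosages[, idx, drop = FALSE]
  v <- apply(X, 2, var)
  if (any(v == 0)) stop("zero-variance dosage column(s): ",
                        paste(rsids[v == 0], collapse = ", "))
  R <- cor(X)
  if (!is.null(effect_allele)) {
    if (!is.null(names(effect_allele))) effect_allele <- effect_allele[rsids]
    pea <- panel$variants$ea[idx]; poa <- panel$variants$oa[idx]
    flip <- effect_allele == poa
    bad <- !(effect_allele == pea | flip)
    if (any(bad)) stop("effect allele not among panel alleles for: ",
                       paste(rsids[bad], collapse = ", "))
    s <- ifelse(flip, -1, 1)
    R <- R * tcrossprod(s)
  }
  dimnames(R) <- list(rsids, rsids)
  R
}

#' Write / read a reference panel as plain text
#'
#' The on-disk format is two tab-delimited files: `<prefix>.variants.tsv`
#' (the variant index: chrom, pos, rsid, ea, oa, eaf) and
#' `<prefix>.dosages.tsv` (one row per individual, one column per variant,
#' header = rsids).
#'
#' @param panel a [ref_panel()].
#' @param prefix path prefix for the two files.
#' @return `prefix` (write) or a `ref_panel` (read).
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "ref_panel"))
  readr::write_tsv(panel$variants, paste0(prefix, ".variants.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(panel$dosages), paste0(prefix, ".dosages.tsv"),
                   progress = FALSE)
  invisible(prefix)
}

#' @rdname write_panel
#' @export
read_panel <- function(prefix) {
  variants <- readr::read_tsv(paste0(prefix, ".variants.tsv"),
                              col_types = readr::cols(chrom = readr::col_character()),
                              progress = FALSE)
  dos <- as.matrix(readr::read_tsv(paste0(prefix, ".dosages.tsv"),
                                   col_types = readr::cols(.default = readr::col_double()),
                                   progress = FALSE))
  ref_panel(variants, dos)
}

#' Read a reference panel from a VCF file
#'
#' Uses the DS FORMAT field when present, otherwise additive coding of GT.
#' Requires the `vcfR` package. Biallelic SNVs only.
#'
#' @param path VCF path (plain or gzipped).
#' @return a [ref_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF panels requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snv <- fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  fmt <- vcfR::extract.gt(v, element = if ("DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) "DS" else "GT")
  if (all(grepl("[/|]", fmt[!is.na(fmt)][1]))) {
    dos <- matrix(vapply(strsplit(fmt, "[/|]"), function(g) sum(as.numeric(g)), numeric(1)),
                  nrow = nrow(fmt))
  } else {
    dos <- matrix(as.numeric(fmt), nrow = nrow(fmt))
  }
  dos <- t(dos[snv, , drop = FALSE])
  variants <- tibble::tibble(
    chrom = fix$CHROM[snv], pos = as.numeric(fix$POS[snv]),
    rsid = ifelse(is.na(fix$ID[snv]) | fix$ID[snv] == ".",
                  paste0(fix$CHROM[snv], ":", fix$POS[snv]), fix$ID[snv]),
    ea = fix$ALT[snv], oa = fix$REF[snv])
  ref_panel(variants, dos)
}
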