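#' Pairwise conditional colocalization (PWCoCo)
#'
#' Standard colocalization on marginal statistics first; if that does not
#' reach the PPH4 threshold, stepwise signal selection is run on each trait
#' and colocalization is repeated for every combination of marginal and
#' single-signal-isolating conditional statistics (a trait with k >= 2
#' selected signals contributes, besides its marginal track, one track per
#' signal obtained by conditioning on the other k-1 signals). The
#' maximum-PPH4 entry decides colocalization.
#'
#' @param ss1,ss2 [region_sumstats()] objects for the two traits.
#' @param panel a [ref_panel()] providing LD for the conditional step.
#' @param config a [pipeline_config()] (priors, `pph4_threshold`,
#'   `cojo_p`).
#' @param center_pos optional position; when given, both traits are
#'   restricted to `center_pos` +/- `config$coloc_window` first.
#' @return list of class `pwcoco_result`:
#'   `best` (the maximum-PPH4 `coloc_result`),
#'   `grid` (tibble: mode/conditioning per trait, PPH0-4, n_variants),
#'   `colocalized` (`best$pph4 >= config$pph4_threshold`),
#'   `signals1`, `signals2` (selected rsids per trait; empty if the
#'   marginal pass already decided).
#' @export
pwcoco <- function(ss1, ss2, panel, config = pipeline_config(),
                   center_pos = NULL) {
  if (!is.null(center_pos)) {
    ss1 <- window_region(ss1, center_pos, config$coloc_window)
    ss2 <- window_region(ss2, center_pos, config$coloc_window)
  }
  if (nrow(ss1$stats) < 1 || nrow(ss2$stats) < 1 ||
      !length(shared_variant_index(ss1$stats, ss2$stats)$i1))
    stop("colocalization window contains no shared variants")
  marg <- coloc_region(ss1, ss2, config)
  grid <- list(grid_row(marg, "marginal", character(0), "marginal", character(0)))
  best <- marg
  signals1 <- character(0); signals2 <- character(0)
  if (marg$pph4 < config$pph4_threshold) {
    sel1 <- cojo_select(ss1, panel, config)
    sel2 <- cojo_select(ss2, panel, config)
    signals1 <- sel1$rsid; signals2 <- sel2$rsid
    tracks1 <- conditional_tracks(ss1, panel, sel1$rsid, config)
    tracks2 <- conditional_tracks(ss2, panel, sel2$rsid, config)
    for (t1 in tracks1) {
      for (t2 in tracks2) {
        if (t1$mode == "marginal" && t2$mode == "marginal") next
        res <- tryCatch(coloc_region(t1$ss, t2$ss, config), error = function(e) NULL)
        if (is.null(res)) next
        res$mode <- "conditional"
        res$conditioned_on <- list(trait1 = t1$cond, trait2 = t2$cond)
        grid[[length(grid) + 1L]] <- grid_row(res, t1$mode, t1$cond, t2$mode, t2$cond)
        if (res$pph4 > best$pph4) best <- res
      }
    }
  }
  grid <- dplyr::bind_rows(grid)
  structure(list(best = best, grid = grid,
                 colocalized = best$pph4 >= config$pph4_threshold,
                 signals1 = signals1, signals2 = signals2),
            class = "pwcoco_result")
}

window_region <- function(ss, center, half_width) {
  out <- ss
  out$stats <- ss$stats[abs(ss$stats$pos - center) <= half_width, ]
  out
}

grid_row <- function(res, mode1, cond1, mode2, cond2) {
  tibble::tibble(mode1 = mode1, cond1 = paste(cond1, collapse = ","),
                 mode2 = mode2, cond2 = paste(cond2, collapse = ","),
                 pph0 = res$pph0, pph1 = res$pph1, pph2 = res$pph2,
                 pph3 = res$pph3, pph4 = res$pph4, n_variants = res$n_variants)
}

# The marginal track plus, when k >= 2 signals are selected, one track per
# signal conditioning on the other k-1 (isolating that signal). With k <= 1
# the conditional track equals the marginal one and is not duplicated.
conditional_tracks <- function(ss, panel, signal_ids, config) {
  tracks <- list(list(ss = ss, mode = "marginal", cond = character(0)))
  k <- length(signal_ids)
  if (k >= 2) {
    for (i in seq_len(k)) {
      cond <- signal_ids[-i]
      ssc <- tryCatch(cojo_condition(ss, panel, cond, config),
                      error = function(e) NULL)
      if (!is.null(ssc))
        tracks[[length(tracks) + 1L]] <- list(ss = ssc, mode = "conditional",
                                              cond = cond)
    }
  }
  tracks
}

#' @export
print.pwcoco_result <- function(x, ...) {
  cat(sprintf("<pwcoco_result> %s (best PPH4 = %.3f, %d coloc run(s))\n",
              if (x$colocalized) "colocalized" else "not colocalized",
              x$best$pph4, nrow(x$grid)))
  invisible(x)
}
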