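#' Mask wells with too few bead events
#'
#' Wells in which fewer than `min_events` beads of a population were read
#' give unreliable medians; their MFI values are masked (set `NA` in the
#' returned working copy) and excluded from all downstream statistics, never
#' imputed.
#'
#' @param assay an [sba_assay()].
#' @param min_events minimum bead events per well (default 32).
#' @return list: `assay` (the input, untouched), `mfi` (matrix with masked
#'   cells `NA`), `mask` (logical matrix, `TRUE` = masked).
#' @export
filter_bead_counts <- function(assay, min_events = 32) {
  mask <- assay$bead_count < min_events
  mfi <- assay$mfi
  mfi[mask] <- NA_real_
  list(assay = assay, mfi = mfi, mask = mask)
}

#' Flag beads with failed antibody coupling
#'
#' Coupling efficiency is measured per bead (anti-IgG detection on the
#' coupled antibody); beads whose coupling signal falls below the floor are
#' excluded from scoring. Control beads are exempt from flagging.
#'
#' @param coupling named numeric vector of per-bead coupling MFI (names are
#'   antibody ids).
#' @param floor minimum acceptable coupling MFI.
#' @param control_ids antibody ids exempt from the check.
#' @return character vector of failed antibody ids (possibly empty).
#' @export
coupling_qc <- function(coupling, floor = 1000, control_ids = character()) {
  cand <- setdiff(names(coupling), control_ids)
  cand[coupling[cand] < floor]
}

#' Assess construct expression against mock
#'
#' Reproduces the tag-capture expression test: per panel and capture tag,
#' log2-transformed capture-bead MFI (floored at 1 unit) is submitted to a
#' one-way ANOVA over constructs (mock included); if the panel-level ANOVA
#' is significant at `alpha`, each construct is contrasted against mock with
#' Dunnett's multiple comparison test. A construct's expression is
#' *supported* iff its Dunnett p-value is below `alpha` and its mean log2
#' level exceeds the mock mean (direction enforced on top of the two-sided
#' test); otherwise *uncertain*.
#'
#' @param assay an [sba_assay()] (or the `mfi` matrix from
#'   [filter_bead_counts()], with masked cells `NA`).
#' @param samples sample manifest.
#' @param library receptor library (supplies each construct's capture tag).
#' @param capture_beads named character vector mapping tag to capture bead
#'   column, e.g. `c(FLAG = "9001", HA = "9002")`.
#' @param alpha significance level (default 0.05).
#' @return data frame of class `sba_expression`: `gpcr_id`, `panel`, `n`,
#'   `mean_log2`, `mock_mean_log2`, `mean_linear`, `anova_p`, `dunnett_p`,
#'   `status` (`supported`/`uncertain`). Constructs with fewer than two
#'   usable replicates get `NA` p-values and status `uncertain`.
#' @export
assess_expression <- function(assay, samples, library, capture_beads,
                              alpha = 0.05) {
  mfi <- if (inherits(assay, "sba_assay")) assay$mfi else assay
  tag_of <- setNames(library$n_tag, library$gpcr_id)
  out <- list()
  for (p in unique(samples$panel)) {
    psamp <- samples[samples$panel == p, , drop = FALSE]
    tags <- unique(tag_of[setdiff(unique(psamp$construct), MOCK_TOKEN)])
    for (tag in tags) {
      bead <- capture_beads[[tag]]
      if (is.null(bead) || !bead %in% colnames(mfi))
        sba_stop(paste0("no capture bead for tag ", tag), "sba_validation_error")
      cons <- setdiff(unique(psamp$construct), MOCK_TOKEN)
      cons <- cons[tag_of[cons] == tag]
      use <- psamp[psamp$construct %in% c(cons, MOCK_TOKEN), , drop = FALSE]
      y <- log2(pmax(mfi[use$sample_id, bead], 1))
      ylin <- mfi[use$sample_id, bead]
      grp <- use$construct
      keep <- is.finite(y)
      y <- y[keep]; ylin <- ylin[keep]; grp <- grp[keep]
      mock_mean <- mean(y[grp == MOCK_TOKEN])
      n_mock <- sum(grp == MOCK_TOKEN)
      counts <- table(grp)
      testable <- names(counts)[counts >= 2]
      dunnett <- rep(NA_real_, length(cons)); names(dunnett) <- cons
      anova_p <- NA_real_
      test_cons <- intersect(cons, testable)
      if (n_mock >= 2 && length(test_cons) >= 1) {
        sub <- grp %in% c(test_cons, MOCK_TOKEN)
        f <- factor(grp[sub], levels = c(MOCK_TOKEN, test_cons))
        d <- data.frame(y = y[sub], construct = f)
        fit <- aov(y ~ construct, data = d)
        anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
        if (is.finite(anova_p) && anova_p < alpha) {
          gl <- multcomp::glht(fit, linfct = multcomp::mcp(construct = "Dunnett"))
          pv <- with_local_seed(summary(gl)$test$pvalues)
          dunnett[test_cons] <- as.numeric(pv)
        } else {
          dunnett[test_cons] <- 1
        }
      }
      for (g in cons) {
        gy <- y[grp == g]
        supported <- !is.na(dunnett[g]) && dunnett[g] < alpha &&
          mean(gy) > mock_mean
        out[[length(out) + 1L]] <- data.frame(
          gpcr_id = g, panel = p, n = length(gy),
          mean_log2 = mean(gy), mock_mean_log2 = mock_mean,
          mean_linear = mean(ylin[grp == g]),
          anova_p = anova_p, dunnett_p = unname(dunnett[g]),
          status = if (supported) "supported" else "uncertain",
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("sba_expression", "data.frame")
  res
}

#' Per-subfamily expression summary table
#'
#' Counts of receptors per subfamily with the percentage whose expression
#' was supported (one decimal), plus a total row. Subfamilies present in the
#' library but absent from the results are omitted with a warning.
#'
#' @param results an `sba_expression` data frame (or any data frame with
#'   `gpcr_id` and `status`).
#' @param library receptor library (maps id to subfamily).
#' @return data frame: `subfamily`, `n_gpcrs`, `n_expressed`,
#'   `expressed_pct`.
#' @export
expression_summary <- function(results, library) {
  sf_of <- setNames(library$subfamily, library$gpcr_id)
  results <- results[!duplicated(results$gpcr_id), , drop = FALSE]
  sf <- sf_of[results$gpcr_id]
  empty <- setdiff(unique(library$subfamily), unique(sf))
  if (length(empty))
    warning("no expression results for subfamily: ",
            paste(empty, collapse = ", "), "; row omitted")
  rows <- lapply(intersect(SUBFAMILIES, unique(sf)), function(s) {
    k <- sum(sf == s & results$status == "supported")
    n <- sum(sf == s)
    data.frame(subfamily = s, n_gpcrs = n, n_expressed = k,
               expressed_pct = round(100 * k / n, 1), stringsAsFactors = FALSE)
  })
  tot_k <- sum(results$status == "supported"); tot_n <- nrow(results)
  rbind(do.call(rbind, rows),
        data.frame(subfamily = "total", n_gpcrs = tot_n, n_expressed = tot_k,
                   expressed_pct = round(100 * tot_k / tot_n, 1),
                   stringsAsFactors = FALSE))
}
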