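#' Agreement between antibodies sharing a target
#'
#' For every unordered pair of scored antibodies with the same intended
#' target, the Pearson correlation of their robust-Z profiles over the
#' wells both observed (QC-passing in both). Pairs with fewer than three
#' shared wells are skipped with a warning.
#'
#' @param fit an [sba_selectivity()] object.
#' @param profiles per-antibody named value vectors to correlate; defaults
#'   to the fit's robust-Z profiles (each antibody's own scale divided
#'   out); pass raw MFI vectors to correlate on the original scale.
#' @return data frame of class `sba_pairs`: `target_id`, `antibody_a`,
#'   `antibody_b`, `pearson_r`, `n_samples`.
#' @export
pair_correlations <- function(fit, profiles = fit$rz) {
  ann <- fit$annotations
  rows <- list()
  for (tgt in unique(ann$target_id)) {
    abs_t <- ann$antibody_id[ann$target_id == tgt]
    if (length(abs_t) < 2) next
    for (pair in combn(sort(abs_t), 2, simplify = FALSE)) {
      a <- profiles[[pair[1]]]; b <- profiles[[pair[2]]]
      shared <- intersect(names(a)[is.finite(a)], names(b)[is.finite(b)])
      if (length(shared) < 3) {
        warning("pair ", pair[1], "/", pair[2], " skipped: fewer than 3 shared wells")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = tgt, antibody_a = pair[1], antibody_b = pair[2],
        pearson_r = cor(a[shared], b[shared]), n_samples = length(shared),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(target_id = character(), antibody_a = character(),
                         antibody_b = character(), pearson_r = numeric(),
                         n_samples = integer(), stringsAsFactors = FALSE)
  class(out) <- c("sba_pairs", "data.frame")
  out
}

#' Summarize paired-antibody agreement
#'
#' Counts and integer-rounded percentages: targets covered by two or more
#' antibodies, and among those the targets *recognized* (on- or co-target
#' annotation, i.e. the intended receptor detected above threshold) by two
#' or more of their antibodies; plus the mean and median pair correlation.
#'
#' @param pairs an `sba_pairs` table from [pair_correlations()].
#' @param annotations the `annotations` data frame of the fit (needs
#'   `antibody_id`, `target_id`, `category`).
#' @return list: `n_targets`, `n_multi`, `pct_multi`, `n_recognized_multi`,
#'   `pct_recognized`, `mean_r`, `median_r`. Percentages are `NA` when the
#'   denominator is zero.
#' @export
pair_summary <- function(pairs, annotations) {
  n_targets <- length(unique(annotations$target_id))
  per_target <- table(annotations$target_id)
  multi <- names(per_target)[per_target >= 2]
  n_multi <- length(multi)
  recog <- annotations$category %in% c("on_target", "co_target")
  n_rec <- sum(vapply(multi, function(tgt)
    sum(recog & annotations$target_id == tgt) >= 2, logical(1)))
  list(n_targets = n_targets,
       n_multi = n_multi,
       pct_multi = if (n_targets > 0) as.integer(round(100 * n_multi / n_targets))
                   else NA_integer_,
       n_recognized_multi = if (n_multi > 0) n_rec else NA_integer_,
       pct_recognized = if (n_multi > 0) as.integer(round(100 * n_rec / n_multi))
                        else NA_integer_,
       mean_r = if (nrow(pairs)) mean(pairs$pearson_r) else NA_real_,
       median_r = if (nrow(pairs)) median(pairs$pearson_r) else NA_real_)
}
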