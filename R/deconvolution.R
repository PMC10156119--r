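## Karlin-Altschul parameters for BLOSUM62 with affine gap 11/1
## (protein-search convention); only the E < 1 decision boundary feeds the
## pipeline, exact parity with any BLAST release is a non-goal.
KA_PARAMS <- list(lambda = 0.267, K = 0.041)

#' Optimal local alignment with an E-value
#'
#' Smith-Waterman local alignment with affine gaps (via
#' `Biostrings::pairwiseAlignment`), scored with a substitution matrix, and
#' an expectation value from Karlin-Altschul statistics:
#' `E = K * m * n * exp(-lambda * S)` with `(K, lambda)` fixed constants for
#' the matrix/gap setting.
#'
#' @param query,subject amino-acid strings (the antigen is the query).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (default 11 / 1).
#' @param ka list with `lambda` and `K`.
#' @return list of class `sba_alignment`: `score` (floored at 0, the empty
#'   alignment), `e_value`, `aligned_span_query`, `aligned_span_subject`
#'   (1-based inclusive), `identity_fraction`.
#' @export
local_align <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1, ka = KA_PARAMS) {
  for (s in c(query, subject)) {
    if (!nzchar(s) || any(!strsplit(toupper(s), "")[[1]] %in% AA_ALPHABET))
      sba_stop("empty sequence or illegal residue in alignment input",
               "sba_validation_error")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  s <- max(0, Biostrings::score(aln))
  m <- nchar(query); n <- nchar(subject)
  e <- ka$K * m * n * exp(-ka$lambda * s)
  pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
  structure(list(score = s, e_value = e,
                 aligned_span_query = c(Biostrings::start(pat),
                                        Biostrings::end(pat)),
                 aligned_span_subject = c(Biostrings::start(sub),
                                          Biostrings::end(sub)),
                 identity_fraction = if (Biostrings::nchar(aln) > 0)
                   Biostrings::nmatch(aln) / Biostrings::nchar(aln) else 0),
            class = "sba_alignment")
}

#' Off-to-on expression ratio
#'
#' Ratio of mean linear-scale tag-capture levels, off-target over on-target,
#' over QC-passing wells; the literal "twofold line" sits at 2.
#'
#' @param expr an `sba_expression` result (needs `gpcr_id`, `mean_linear`,
#'   `status`).
#' @param on_id,off_id construct ids.
#' @return numeric ratio, or `NA` (with attribute `reason`) when the
#'   on-target level is zero or its expression unsupported.
#' @export
expression_ratio <- function(expr, on_id, off_id) {
  on <- expr[expr$gpcr_id == on_id, , drop = FALSE]
  off <- expr[expr$gpcr_id == off_id, , drop = FALSE]
  if (!nrow(on) || !nrow(off))
    sba_stop(paste0("construct missing from expression results: ",
                    if (!nrow(on)) on_id else off_id), "sba_validation_error")
  if (on$mean_linear[1] <= 0 || on$status[1] != "supported")
    return(structure(NA_real_, reason = "on-target unsupported or zero"))
  off$mean_linear[1] / on$mean_linear[1]
}

#' Annotate the cause of an off-target event
#'
#' Flags: `abundance` if the off/on expression ratio reaches `ratio_cut`
#' (default twofold); `homology` if the antigen-vs-off-target alignment
#' E-value is below `evalue_cut` (default 1); both may co-occur;
#' `promiscuous` iff neither explains the event.
#'
#' @param record list or one-row data frame with `expression_ratio` and
#'   `e_value`.
#' @param ratio_cut,evalue_cut decision boundaries.
#' @return character vector of cause flags.
#' @export
annotate_cause <- function(record, ratio_cut = 2.0, evalue_cut = 1.0) {
  flags <- character()
  if (!is.na(record$expression_ratio) && record$expression_ratio >= ratio_cut)
    flags <- c(flags, "abundance")
  if (!is.na(record$e_value) && record$e_value < evalue_cut)
    flags <- c(flags, "homology")
  if (!length(flags)) flags <- "promiscuous"
  flags
}

#' Build the cross-reactivity event table
#'
#' One row per (antibody, off-target) event of a selectivity fit, with the
#' off/on expression ratio, the antigen-vs-off-target local-alignment
#' E-value, the cause flags, and replicate consistency (event above
#' threshold in every QC-passing well containing the off-target).
#'
#' @param fit an [sba_selectivity()] object.
#' @param library receptor library (sequences).
#' @param expr an `sba_expression` result from [assess_expression()].
#' @param ratio_cut,evalue_cut decision boundaries (defaults 2, 1).
#' @return data frame of class `sba_crossreact`: `antibody_id`, `on_target`,
#'   `off_target`, `expression_ratio`, `e_value`, `align_score`,
#'   `n_samples_above`, `n_samples_total`, `consistent`, `cause` (flags
#'   joined by `+`), plus logical `abundance`, `homology`, `promiscuous`.
#' @export
crossreact_table <- function(fit, library, expr, ratio_cut = 2.0,
                             evalue_cut = 1.0) {
  ev <- fit$events
  ab_man <- fit$antibodies
  seq_of <- setNames(library$sequence, library$gpcr_id)
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    ab <- ev$antibody_id[i]
    man <- ab_man[ab_man$antibody_id == ab, ]
    antigen <- substr(seq_of[man$target_id], man$antigen_start, man$antigen_end)
    aln <- local_align(antigen, seq_of[[ev$gpcr_id[i]]])
    ratio <- expression_ratio(expr, man$target_id, ev$gpcr_id[i])
    rec <- list(expression_ratio = as.numeric(ratio), e_value = aln$e_value)
    flags <- annotate_cause(rec, ratio_cut, evalue_cut)
    rows[[length(rows) + 1L]] <- data.frame(
      antibody_id = ab, on_target = man$target_id, off_target = ev$gpcr_id[i],
      expression_ratio = as.numeric(ratio), e_value = aln$e_value,
      align_score = aln$score,
      n_samples_above = ev$n_samples_above[i],
      n_samples_total = ev$n_samples_total[i],
      consistent = ev$n_samples_above[i] == ev$n_samples_total[i],
      cause = paste(flags, collapse = "+"),
      abundance = "abundance" %in% flags,
      homology = "homology" %in% flags,
      promiscuous = "promiscuous" %in% flags,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(antibody_id = character(), on_target = character(),
                         off_target = character(), expression_ratio = numeric(),
                         e_value = numeric(), align_score = numeric(),
                         n_samples_above = integer(), n_samples_total = integer(),
                         consistent = logical(), cause = character(),
                         abundance = logical(), homology = logical(),
                         promiscuous = logical(), stringsAsFactors = FALSE)
  class(out) <- c("sba_crossreact", "data.frame")
  out
}

#' Replicate consistency of an off-target event
#'
#' `consistent` iff every QC-passing well containing the off-target
#' construct lies above the antibody's threshold.
#'
#' @param n_above,n_total wells above threshold / QC-passing wells
#'   containing the off-target.
#' @return logical.
#' @export
replicate_consistency <- function(n_above, n_total) {
  n_total > 0 & n_above == n_total
}
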