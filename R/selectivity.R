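#' Robust Z-scores
#'
#' Scales one antibody's measurement vector by its median and median
#' absolute deviation: `rz_i = (x_i - median(x)) / (1.4826 * MAD(x))` with
#' `MAD = median(|x_i - median(x)|)`. The estimator is resistant to the very
#' outliers (true binding events) it is designed to expose; it is affine
#' invariant, so rescaling an antibody's raw MFI leaves its profile
#' unchanged.
#'
#' @param x numeric vector of at least 3 finite values (NAs are kept as NA
#'   and ignored by the location/scale estimates).
#' @param id optional antibody id used in error messages.
#' @return numeric vector of robust Z-scores, same length as `x`.
#' @export
robust_z <- function(x, id = NULL) {
  ok <- is.finite(x)
  if (sum(ok) < 3)
    sba_stop(paste0("need >= 3 finite values",
                    if (!is.null(id)) paste0(" (antibody ", id, ")")),
             "sba_degenerate_error")
  med <- median(x[ok])
  madv <- median(abs(x[ok] - med))
  if (madv == 0)
    sba_stop(paste0("degenerate distribution (MAD = 0)",
                    if (!is.null(id)) paste0(" for antibody ", id)),
             "sba_degenerate_error")
  (x - med) / (1.4826 * madv)
}

#' Mode of the Gaussian-smoothed score distribution
#'
#' Kernel density estimate (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) evaluated on a fixed 512-point grid spanning
#' `[min(x), max(x)]`; returns the grid point of maximum density. With a
#' dominant negative (non-binding) population the mode sits on that bulk,
#' unmoved by binding outliers in the upper tail.
#'
#' @param x numeric vector (NAs dropped).
#' @return the density peak location (numeric scalar).
#' @export
density_peak <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1L) return(x[1])
  d <- density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Robust SD of the negative population
#'
#' Estimates the spread of the non-binding (negative) population from the
#' lower half of the score distribution only, mirrored around the density
#' peak: `sigma_neg = 1.4826 * median(|r - peak|)` over `{r <= peak}`. True
#' binding inflates only the upper tail, which this estimator never sees;
#' for symmetric data it is consistent for the usual SD.
#'
#' @param x numeric score vector.
#' @param peak the density peak (default computed via [density_peak()]).
#' @return numeric scalar; if fewer than 3 points lie at or below the peak,
#'   falls back to the full-vector MAD-based SD with a warning.
#' @export
negative_sd <- function(x, peak = density_peak(x)) {
  x <- x[is.finite(x)]
  low <- x[x <= peak]
  if (length(low) < 3) {
    warning("fewer than 3 points at or below the density peak; ",
            "falling back to full-vector MAD-based SD")
    return(1.4826 * median(abs(x - median(x))))
  }
  1.4826 * median(abs(low - peak))
}

#' Per-antibody robust-Z profile and selectivity threshold
#'
#' Computes the robust Z-scores of one antibody over its panel's
#' QC-passing wells and derives the antibody-specific selectivity
#' threshold `peak + k * sigma_neg`, where `peak` is the mode of the
#' Gaussian-smoothed score distribution and `sigma_neg` the robust SD of
#' the negative population ([negative_sd()]).
#'
#' @param values named numeric vector of MFI over the antibody's panel
#'   wells (masked wells `NA`).
#' @param k SD multiplier (default 12).
#' @param id antibody id (for error messages).
#' @return list of class `sba_rz_profile`: `antibody_id`, `rz` (named,
#'   NA for masked wells), `median_mfi`, `mad_mfi`, `density_peak`,
#'   `sigma_neg`, `threshold`.
#' @export
rz_profile <- function(values, k = 12, id = NULL) {
  rz <- robust_z(values, id = id)
  ok <- is.finite(values)
  peak <- density_peak(rz[ok])
  sig <- negative_sd(rz[ok], peak)
  structure(list(antibody_id = id %||% NA_character_, rz = rz,
                 median_mfi = median(values[ok]),
                 mad_mfi = median(abs(values[ok] - median(values[ok]))),
                 density_peak = peak, sigma_neg = sig,
                 threshold = peak + k * sig, k = k),
            class = "sba_rz_profile")
}

#' Classify one antibody's selectivity
#'
#' Applies the four-way rule at the antibody's threshold: *on* flag if the
#' mean robust Z-score over wells expressing the intended target exceeds
#' the threshold; *cross* flag if any single well expressing a different
#' construct exceeds it (mock wells can never trigger the cross flag).
#' Categories: on_target (on, no cross), co_target (on and cross),
#' off_target (cross only), no_target (neither).
#'
#' @param profile an `sba_rz_profile`.
#' @param samples sample manifest rows covering the profile's wells.
#' @param target_id intended target construct id.
#' @param threshold override of the profile threshold (used by sweeps).
#' @return list of class `sba_annotation`: `antibody_id`, `category`,
#'   `on_target_mean_rz`, `threshold`, `offtarget_events` (data frame
#'   `gpcr_id`, `n_samples_above`, `n_samples_total`, `max_rz`).
#' @export
classify_antibody <- function(profile, samples, target_id,
                              threshold = profile$threshold) {
  rz <- profile$rz[samples$sample_id]
  ok <- is.finite(rz)
  tgt <- samples$construct == target_id & ok
  if (!any(samples$construct == target_id))
    sba_stop(paste0("no samples expressing target ", target_id,
                    " in the panel (design flaw)"), "sba_design_error")
  if (!any(tgt))
    sba_stop(paste0("all wells of target ", target_id,
                    " are QC-masked for antibody ", profile$antibody_id),
             "sba_design_error")
  on_flag <- mean(rz[tgt]) > threshold
  other <- ok & !tgt & samples$construct != MOCK_TOKEN &
    samples$construct != target_id
  above <- other & rz > threshold
  events <- if (any(above)) {
    g <- samples$construct[above]
    do.call(rbind, lapply(unique(g), function(gg) {
      in_g <- samples$construct == gg & ok
      data.frame(gpcr_id = gg,
                 n_samples_above = sum(above & samples$construct == gg),
                 n_samples_total = sum(in_g),
                 max_rz = max(rz[above & samples$construct == gg]),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(gpcr_id = character(), n_samples_above = integer(),
                    n_samples_total = integer(), max_rz = numeric(),
                    stringsAsFactors = FALSE)
  cross_flag <- nrow(events) > 0
  category <- if (on_flag && !cross_flag) "on_target"
              else if (on_flag && cross_flag) "co_target"
              else if (cross_flag) "off_target" else "no_target"
  structure(list(antibody_id = profile$antibody_id, category = category,
                 on_target_mean_rz = mean(rz[tgt]), threshold = threshold,
                 offtarget_events = events),
            class = "sba_annotation")
}

#' Fit the selectivity model to an assay
#'
#' The package's central fit: for every QC-passing screening antibody,
#' restricts the assay to the wells of the antibody's subfamily panel,
#' masks low-bead-count wells, computes the robust-Z profile and the
#' antibody-specific threshold `peak + k * sigma_neg`, and applies the
#' four-way selectivity classification.
#'
#' @param assay an [sba_assay()].
#' @param antibodies,samples manifests.
#' @param k threshold SD multiplier (default 12).
#' @param min_events bead-count floor per well (default 32).
#' @param coupling optional named coupling-MFI vector; antibodies failing
#'   [coupling_qc()] at `coupling_floor` are excluded from scoring.
#' @param coupling_floor coupling QC floor (default 1000).
#' @param average_tech collapse technical replicates of the same
#'   (construct, biological replicate) to their mean MFI before scoring;
#'   by default they are retained as separate wells, since the
#'   classification rule is stated over wells.
#' @return Object of class `sba_selectivity` with elements `profiles`
#'   (data frame), `rz` (list of named score vectors), `annotations`
#'   (data frame `antibody_id`, `target_id`, `subfamily_panel`, `category`,
#'   `on_target_mean_rz`, `threshold`, `n_offtargets`), `events` (one row
#'   per off-target event), `excluded` (antibody ids failing QC), `mask`,
#'   `k`, and the matched `samples`/`antibodies`.
#' @export
sba_selectivity <- function(assay, antibodies, samples, k = 12,
                            min_events = 32, coupling = NULL,
                            coupling_floor = 1000, average_tech = FALSE) {
  flt <- filter_bead_counts(assay, min_events)
  ctrl_ids <- antibodies$antibody_id[is_control_bead(antibodies)]
  excluded <- if (!is.null(coupling))
    coupling_qc(coupling, coupling_floor, ctrl_ids) else character()
  screen <- antibodies[!is_control_bead(antibodies) &
                         !antibodies$antibody_id %in% excluded, , drop = FALSE]
  profiles <- list(); rzs <- list(); anns <- list(); events <- list()
  for (i in seq_len(nrow(screen))) {
    ab <- screen[i, ]
    psamp <- samples[samples$panel == ab$subfamily_panel, , drop = FALSE]
    vals <- flt$mfi[psamp$sample_id, as.character(ab$bead_id)]
    names(vals) <- psamp$sample_id
    if (average_tech) {
      key <- paste(psamp$construct, psamp$bio_replicate)
      first <- !duplicated(key)
      mvals <- tapply(vals, key, function(v)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
      psamp <- psamp[first, , drop = FALSE]
      vals <- setNames(as.numeric(mvals[key[first]]), psamp$sample_id)
    }
    prof <- rz_profile(vals, k = k, id = ab$antibody_id)
    ann <- classify_antibody(prof, psamp, ab$target_id)
    profiles[[i]] <- data.frame(antibody_id = ab$antibody_id,
                                target_id = ab$target_id,
                                subfamily_panel = ab$subfamily_panel,
                                n = sum(is.finite(vals)),
                                median_mfi = prof$median_mfi,
                                mad_mfi = prof$mad_mfi,
                                density_peak = prof$density_peak,
                                sigma_neg = prof$sigma_neg,
                                threshold = prof$threshold,
                                stringsAsFactors = FALSE)
    rzs[[ab$antibody_id]] <- prof$rz
    anns[[i]] <- data.frame(antibody_id = ab$antibody_id,
                            target_id = ab$target_id,
                            subfamily_panel = ab$subfamily_panel,
                            category = ann$category,
                            on_target_mean_rz = ann$on_target_mean_rz,
                            threshold = ann$threshold,
                            n_offtargets = nrow(ann$offtarget_events),
                            stringsAsFactors = FALSE)
    if (nrow(ann$offtarget_events))
      events[[length(events) + 1L]] <-
        cbind(antibody_id = ab$antibody_id, ann$offtarget_events,
              stringsAsFactors = FALSE)
  }
  structure(list(profiles = do.call(rbind, profiles),
                 rz = rzs,
                 annotations = do.call(rbind, anns),
                 events = if (length(events)) do.call(rbind, events)
                          else data.frame(antibody_id = character(),
                                          gpcr_id = character(),
                                          n_samples_above = integer(),
                                          n_samples_total = integer(),
                                          max_rz = numeric(),
                                          stringsAsFactors = FALSE),
                 excluded = excluded, mask = flt$mask, k = k,
                 samples = samples, antibodies = antibodies,
                 call = match.call()),
            class = "sba_selectivity")
}

#' @export
print.sba_selectivity <- function(x, ...) {
  tab <- table(factor(x$annotations$category,
                      levels = c("on_target", "co_target", "off_target", "no_target")))
  cat("Suspension-bead-array selectivity fit\n")
  cat(sprintf("  %d antibodies scored (k = %g, %d excluded by coupling QC)\n",
              nrow(x$annotations), x$k, length(x$excluded)))
  cat(sprintf("  on-target %d | co-target %d | off-target %d | no-target %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  cat(sprintf("  thresholds (R.Z): %.1f to %.1f (mean %.1f)\n",
              min(x$profiles$threshold), max(x$profiles$threshold),
              mean(x$profiles$threshold)))
  invisible(x)
}

#' @method summary sba_selectivity
#' @export
summary.sba_selectivity <- function(object, ...) {
  s <- summarize_classifications(object$annotations, object$antibodies)
  structure(list(fit = object, summary = s), class = "summary.sba_selectivity")
}

#' @export
print.summary.sba_selectivity <- function(x, ...) {
  print(x$fit)
  cat("\nPer-subfamily classification (percent):\n")
  print(x$summary$table, row.names = FALSE)
  r <- x$summary$remaining
  cat(sprintf("\nOf the non-on-target antibodies: co-target %d%%, off-target %d%%, no-target %d%%\n",
              r[["co_target"]], r[["off_target"]], r[["no_target"]]))
  invisible(x)
}

#' @method plot sba_selectivity
#' @export
plot.sba_selectivity <- function(x, antibody_id = NULL, ...) {
  ids <- antibody_id %||% head(x$annotations$antibody_id, 1)
  ab <- ids[1]
  rz <- x$rz[[ab]]
  ann <- x$annotations[x$annotations$antibody_id == ab, ]
  psamp <- x$samples[match(names(rz), x$samples$sample_id), ]
  grp <- ifelse(psamp$construct == ann$target_id, "target",
                ifelse(psamp$construct == MOCK_TOKEN, "mock", "other"))
  col <- c(target = "forestgreen", other = "grey40", mock = "steelblue")[grp]
  set.seed(1)
  xj <- as.numeric(factor(grp, levels = c("target", "other", "mock"))) +
    runif(length(rz), -0.15, 0.15)
  graphics::plot(xj, rz, col = col, pch = 19, xaxt = "n",
                 xlab = "", ylab = "robust Z-score",
                 main = sprintf("%s (target %s, %s)", ab, ann$target_id,
                                ann$category), ...)
  graphics::axis(1, at = 1:3, labels = c("target", "other", "mock"))
  graphics::abline(h = ann$threshold, lty = 2, col = "red")
  invisible(x)
}

#' Sweep the threshold multiplier
#'
#' Reclassifies every scored antibody over a grid of SD multipliers `k`
#' (thresholds `peak + k * sigma_neg`) and counts the resulting categories.
#' Used to justify the working multiplier: on-target counts peak and the
#' cross-reactive counts plateau as `k` grows.
#'
#' @param fit an [sba_selectivity()] object.
#' @param k_grid numeric vector of multipliers (default `0:20`).
#' @return data frame: `k`, `on_target`, `co_target`, `off_target`,
#'   `no_target`, `cross_reactive` (co + off), `any_above` (antibodies with
#'   any well above threshold).
#' @export
threshold_sweep <- function(fit, k_grid = 0:20) {
  prof <- fit$profiles
  rows <- lapply(k_grid, function(k) {
    cats <- character(nrow(prof)); any_above <- logical(nrow(prof))
    for (i in seq_len(nrow(prof))) {
      ab <- prof$antibody_id[i]
      thr <- prof$density_peak[i] + k * prof$sigma_neg[i]
      psamp <- fit$samples[fit$samples$panel == prof$subfamily_panel[i], ,
                           drop = FALSE]
      p <- structure(list(antibody_id = ab, rz = fit$rz[[ab]], threshold = thr),
                     class = "sba_rz_profile")
      ann <- classify_antibody(p, psamp, prof$target_id[i], threshold = thr)
      cats[i] <- ann$category
      rz <- fit$rz[[ab]][psamp$sample_id]
      any_above[i] <- any(rz > thr, na.rm = TRUE)
    }
    tab <- table(factor(cats, levels = c("on_target", "co_target",
                                         "off_target", "no_target")))
    data.frame(k = k, on_target = as.integer(tab["on_target"]),
               co_target = as.integer(tab["co_target"]),
               off_target = as.integer(tab["off_target"]),
               no_target = as.integer(tab["no_target"]),
               cross_reactive = as.integer(tab["co_target"] + tab["off_target"]),
               any_above = sum(any_above))
  })
  do.call(rbind, rows)
}

#' Summarize selectivity classifications per subfamily
#'
#' Per-subfamily and total counts with one-decimal percentages of the four
#' categories, plus the narrative breakdown of the non-on-target antibodies
#' (integer percentages, rounded from the one-decimal table values).
#'
#' @param annotations the `annotations` data frame of an
#'   [sba_selectivity()] fit (needs `antibody_id`, `category` and, for the
#'   per-subfamily split, `subfamily_panel`).
#' @param antibodies antibody manifest (ignored if `annotations` carries
#'   `subfamily_panel`).
#' @return list: `table` (per-subfamily + total rows with counts and
#'   `*_pct` columns), `remaining` (named integer percentages of co-, off-
#'   and no-target among non-on-target antibodies).
#' @export
summarize_classifications <- function(annotations, antibodies = NULL) {
  if (!"subfamily_panel" %in% names(annotations) && !is.null(antibodies))
    annotations$subfamily_panel <-
      antibodies$subfamily_panel[match(annotations$antibody_id,
                                       antibodies$antibody_id)]
  cats <- c("on_target", "co_target", "off_target", "no_target")
  one <- function(sub, label) {
    n <- nrow(sub)
    counts <- vapply(cats, function(cc) sum(sub$category == cc), integer(1))
    row <- data.frame(subfamily = label, n_abs = n, stringsAsFactors = FALSE)
    for (cc in cats) {
      row[[cc]] <- counts[[cc]]
      row[[paste0(cc, "_pct")]] <- round(100 * counts[[cc]] / n, 1)
    }
    row
  }
  sfs <- intersect(SUBFAMILIES, unique(annotations$subfamily_panel))
  tab <- do.call(rbind, c(
    lapply(sfs, function(s)
      one(annotations[annotations$subfamily_panel == s, , drop = FALSE], s)),
    list(one(annotations, "total"))))
  rem_n <- sum(annotations$category != "on_target")
  remaining <- vapply(c("co_target", "off_target", "no_target"), function(cc) {
    k <- sum(annotations$category == cc)
    if (rem_n == 0) NA_integer_
    else as.integer(round(round(100 * k / rem_n, 1)))
  }, integer(1))
  list(table = tab, remaining = remaining)
}
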