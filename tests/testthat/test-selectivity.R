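test_that("robust Z matches hand arithmetic and its invariances", {
  x <- c(10, 12, 11, 13, 200)            # median 12, MAD 1
  rz <- robust_z(x)
  expect_equal(rz[5], 188 / 1.4826, tolerance = 1e-9)
  expect_equal(rz[2], 0)
  y <- rnorm(20)
  expect_equal(robust_z(3.7 * y + 42), robust_z(y), tolerance = 1e-9)
  expect_error(robust_z(c(5, 5, 5, 5, 9)), "MAD",
               class = "sba_degenerate_error")
  expect_error(robust_z(c(1, 2)), class = "sba_degenerate_error")
})

test_that("density peak tracks the dominant population mode", {
  set.seed(7)
  x <- rnorm(10000)
  expect_lt(abs(density_peak(x)), 0.1)
  expect_equal(density_peak(rep(4.2, 10)), 4.2)
  xb <- c(rnorm(9500), rnorm(500, 50, 1))
  expect_lt(abs(density_peak(xb)), 0.2)
})

test_that("negative-population SD ignores the binding tail", {
  set.seed(7)
  x <- rnorm(10000)
  s <- negative_sd(x)
  expect_gt(s, 0.9); expect_lt(s, 1.1)

  # symmetric data: mirrored upper-tail estimate agrees within 5%
  peak <- density_peak(x)
  upper <- 1.4826 * median(abs(x[x >= peak] - peak))
  expect_lt(abs(negative_sd(x, peak) / upper - 1), 0.05)

  # upper-tail contamination cannot move it (peak held fixed)
  expect_identical(negative_sd(c(x, rep(100, 500)), peak),
                   negative_sd(x, peak))

  # degenerate lower half falls back with a warning
  expect_warning(negative_sd(c(1, 2, 3, 4), peak = 0.5), "falling back")
})

fake_profile <- function(rz, threshold, id = "ab1") {
  structure(list(antibody_id = id, rz = rz, threshold = threshold),
            class = "sba_rz_profile")
}

test_that("the four-way classification rule is applied verbatim", {
  smp <- sample_manifest(paste0("s", 1:8),
                         c("T", "T", "O1", "O1", "O2", "O2", "MOCK", "MOCK"),
                         c(1, 2, 1, 2, 1, 2, 1, 2), 1, "rhodopsin_alpha")
  rz <- setNames(c(30, 30, 1, 0, 2, 1, 0, 0), smp$sample_id)
  expect_equal(classify_antibody(fake_profile(rz, 20), smp, "T")$category,
               "on_target")
  rz2 <- rz; rz2["s3"] <- 25
  ann2 <- classify_antibody(fake_profile(rz2, 20), smp, "T")
  expect_equal(ann2$category, "co_target")
  expect_equal(ann2$offtarget_events$gpcr_id, "O1")
  expect_equal(ann2$offtarget_events$n_samples_above, 1L)
  rz3 <- setNames(c(5, 5, 25, 1, 1, 1, 0, 0), smp$sample_id)
  expect_equal(classify_antibody(fake_profile(rz3, 20), smp, "T")$category,
               "off_target")
  rz4 <- setNames(rep(1, 8), smp$sample_id)
  expect_equal(classify_antibody(fake_profile(rz4, 20), smp, "T")$category,
               "no_target")

  # mock wells can never create an off-target event
  rz5 <- rz; rz5["s7"] <- 100
  expect_equal(classify_antibody(fake_profile(rz5, 20), smp, "T")$category,
               "on_target")

  # a panel without the target is a design flaw, not no_target
  expect_error(classify_antibody(fake_profile(rz, 20), smp, "ZZZ"),
               "design", class = "sba_design_error")

  # masked target wells drop out of the mean
  rz6 <- rz; rz6["s1"] <- NA
  expect_equal(classify_antibody(fake_profile(rz6, 20), smp, "T")$category,
               "on_target")
})

test_that("the fit partitions every scored antibody exactly once", {
  ds <- generate_dataset(tiny_config(seed = 8))
  fit <- suppressWarnings(sba_selectivity(ds$assay, ds$antibodies, ds$samples,
                                          coupling = ds$coupling))
  ann <- fit$annotations
  screen <- ds$antibodies$antibody_id[!is_control_bead(ds$antibodies)]
  expect_setequal(ann$antibody_id, setdiff(screen, fit$excluded))
  expect_true(all(ann$category %in%
                    c("on_target", "co_target", "off_target", "no_target")))
  expect_false(any(duplicated(ann$antibody_id)))
  # on_target implies no recorded off-target events
  on_ids <- ann$antibody_id[ann$category == "on_target"]
  expect_false(any(fit$events$antibody_id %in% on_ids))
})

test_that("rescaling one antibody's raw MFI changes nothing about it", {
  ds <- generate_dataset(tiny_config(seed = 9))
  fit1 <- suppressWarnings(sba_selectivity(ds$assay, ds$antibodies, ds$samples))
  ab <- fit1$annotations$antibody_id[3]
  bead <- as.character(ds$antibodies$bead_id[ds$antibodies$antibody_id == ab])
  ds$assay$mfi[, bead] <- ds$assay$mfi[, bead] * 7.3
  fit2 <- suppressWarnings(sba_selectivity(ds$assay, ds$antibodies, ds$samples))
  i1 <- fit1$annotations$antibody_id == ab
  i2 <- fit2$annotations$antibody_id == ab
  expect_equal(fit2$rz[[ab]], fit1$rz[[ab]], tolerance = 1e-9)
  expect_equal(fit2$annotations$category[i2], fit1$annotations$category[i1])
  expect_equal(fit2$profiles$threshold[fit2$profiles$antibody_id == ab],
               fit1$profiles$threshold[fit1$profiles$antibody_id == ab],
               tolerance = 1e-9)
})

test_that("threshold sweep shrinks the above-threshold sets as k grows", {
  ds <- generate_dataset(tiny_config(seed = 10))
  fit <- suppressWarnings(sba_selectivity(ds$assay, ds$antibodies, ds$samples,
                                          coupling = ds$coupling))
  sw <- threshold_sweep(fit, k_grid = c(0, 2, 4, 8, 12, 16, 20))
  expect_true(all(diff(sw$any_above) <= 0))
  expect_equal(sw$no_target[sw$k == 0], 0)

  # per-antibody: wells above threshold are nested across k
  prof <- fit$profiles
  for (i in seq_len(nrow(prof))) {
    rz <- fit$rz[[prof$antibody_id[i]]]
    sets <- lapply(c(4, 8, 12), function(k) {
      thr <- prof$density_peak[i] + k * prof$sigma_neg[i]
      names(rz)[!is.na(rz) & rz > thr]
    })
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
})

test_that("classification summaries reproduce count-derived percentages", {
  ann <- data.frame(
    antibody_id = sprintf("AB%03d", 1:407),
    subfamily_panel = "rhodopsin_alpha",
    category = rep(c("on_target", "co_target", "off_target", "no_target"),
                   c(248, 15, 31, 113)),
    stringsAsFactors = FALSE)
  s <- summarize_classifications(ann)
  tot <- s$table[s$table$subfamily == "total", ]
  expect_equal(tot$on_target_pct, 60.9)
  expect_equal(tot$co_target_pct, 3.7)
  expect_equal(tot$off_target_pct, 7.6)
  expect_equal(tot$no_target_pct, 27.8)
  expect_equal(unname(s$remaining),
               c(9L, 20L, 71L))   # of the 159 non-on-target antibodies

  ann$category <- "on_target"
  s2 <- summarize_classifications(ann)
  tot2 <- s2$table[s2$table$subfamily == "total", ]
  expect_equal(c(tot2$on_target_pct, tot2$co_target_pct, tot2$off_target_pct,
                 tot2$no_target_pct), c(100.0, 0.0, 0.0, 0.0))
  expect_true(all(is.na(s2$remaining)))
})

test_that("technical-replicate averaging collapses wells before scoring", {
  ds <- generate_dataset(tiny_config(seed = 12, n_tech = 2L))
  fit_sep <- suppressWarnings(sba_selectivity(ds$assay, ds$antibodies,
                                              ds$samples))
  fit_avg <- suppressWarnings(sba_selectivity(ds$assay, ds$antibodies,
                                              ds$samples, average_tech = TRUE))
  ab <- fit_avg$annotations$antibody_id[1]
  panel <- fit_avg$annotations$subfamily_panel[1]
  psamp <- ds$samples[ds$samples$panel == panel, ]
  n_groups <- length(unique(paste(psamp$construct, psamp$bio_replicate)))
  expect_equal(length(fit_avg$rz[[ab]]), n_groups)
  expect_lt(length(fit_avg$rz[[ab]]), length(fit_sep$rz[[ab]]))
  expect_true(all(fit_avg$annotations$category %in%
                    c("on_target", "co_target", "off_target", "no_target")))
})
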