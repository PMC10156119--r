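test_that("generator is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 11)
  expect_identical(simulate_library(cfg), simulate_library(cfg))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("subfamily members share an ancestral segment, subfamilies do not", {
  cfg <- tiny_config(seed = 3, segment_mut_rate = 0)
  lib <- simulate_library(cfg)
  seg <- attr(lib, "segment_info")
  segs <- vapply(seq_len(nrow(lib)), function(i)
    substr(lib$sequence[i], seg$seg_start[i], seg$seg_end[i]), character(1))
  alpha <- lib$subfamily == "rhodopsin_alpha"
  expect_length(unique(segs[alpha]), 1L)       # mutation rate 0: identical
  expect_length(unique(segs[!alpha]), 1L)
  expect_false(segs[alpha][1] == segs[!alpha][1])

  # positive mutation rate: segments similar but not identical
  lib2 <- simulate_library(tiny_config(seed = 3, segment_mut_rate = 0.1))
  seg2 <- attr(lib2, "segment_info")
  segs2 <- vapply(seq_len(nrow(lib2)), function(i)
    substr(lib2$sequence[i], seg2$seg_start[i], seg2$seg_end[i]), character(1))
  expect_gt(length(unique(segs2[lib2$subfamily == "rhodopsin_alpha"])), 1L)
})

test_that("expression model honors failure, spread and fold-change settings", {
  cfg <- tiny_config(seed = 4,
                     failure_prob = c(rhodopsin_alpha = 1, rhodopsin_beta = 1))
  lib <- simulate_library(cfg)
  smp <- build_samples(cfg, lib)
  ex <- simulate_expression(cfg, lib, smp)
  expect_true(all(ex$failed))
  lv_con <- ex$level[smp$construct != "MOCK"]
  lv_mock <- ex$level[smp$construct == "MOCK"]
  # failed constructs are drawn from the mock distribution
  expect_lt(abs(mean(log(lv_con)) - cfg$mock_meanlog), 3 * cfg$expr_sdlog)
  expect_lt(abs(mean(log(lv_mock)) - cfg$mock_meanlog), 3 * cfg$expr_sdlog)

  # zero spread: all replicates of a construct identical
  cfg0 <- tiny_config(seed = 4, expr_sdlog = 0)
  ex0 <- simulate_expression(cfg0, lib, smp)
  g <- lib$gpcr_id[1]
  expect_length(unique(ex0$level[smp$construct == g]), 1L)

  # Monte-Carlo: expressed mean exceeds mock mean by the configured fold
  cfgF <- sba_sim_config(seed = 9,
                         n_gpcrs = c(rhodopsin_alpha = 50L),
                         n_abs = 5L, n_bio = 50L,
                         failure_prob = c(rhodopsin_alpha = 0))
  libF <- simulate_library(cfgF)
  smpF <- build_samples(cfgF, libF)        # 50 x 50 = 2,500 construct draws
  exF <- simulate_expression(cfgF, libF, smpF)
  ratio <- mean(exF$level[smpF$construct != "MOCK"]) /
    exp(cfgF$mock_meanlog + cfgF$expr_sdlog^2 / 2)
  expect_lt(abs(ratio / cfgF$expr_fold - 1), 0.10)
})

test_that("MFI follows the linear-to-saturation noise model", {
  cfg <- tiny_config(seed = 6, noise_sdlog = 0, coupling_fail_prob = 0,
                     dropout_prob = 0)
  ds <- generate_dataset(cfg)
  # noiseless single-binder wells: MFI = b + a_on * level exactly (below cap)
  tr <- ds$truth
  on_abs <- names(tr$class)[tr$class == "on"]
  ab <- on_abs[1]
  bead <- as.character(ds$antibodies$bead_id[ds$antibodies$antibody_id == ab])
  tgt <- ds$antibodies$target_id[ds$antibodies$antibody_id == ab]
  wells <- ds$samples$sample_id[ds$samples$construct == tgt]
  expected <- cfg$background + cfg$a_on * tr$level[wells]
  expect_equal(unname(ds$assay$mfi[wells, bead]), unname(round(expected, 1)),
               tolerance = 1e-6)

  # saturation: enormous affinity caps at S
  cfgS <- tiny_config(seed = 6, noise_sdlog = 0, a_on = 1e7,
                      coupling_fail_prob = 0, dropout_prob = 0)
  dsS <- generate_dataset(cfgS)
  trS <- dsS$truth
  abS <- names(trS$class)[trS$class == "on"][1]
  beadS <- as.character(dsS$antibodies$bead_id[dsS$antibodies$antibody_id == abS])
  tgtS <- dsS$antibodies$target_id[dsS$antibodies$antibody_id == abS]
  wellsS <- dsS$samples$sample_id[dsS$samples$construct == tgtS &
                                    !trS$failed[tgtS]]
  if (length(wellsS))
    expect_true(all(dsS$assay$mfi[wellsS, beadS] == cfgS$saturation))

  # no binders anywhere: every antibody-bead MFI within noise of background
  cfgN <- tiny_config(seed = 6,
                      class_fractions = c(on = 0, co = 0, off = 0, none = 1))
  dsN <- generate_dataset(cfgN)
  screen <- as.character(
    dsN$antibodies$bead_id[!is_control_bead(dsN$antibodies) &
                             !dsN$truth$coupling_failed[dsN$antibodies$antibody_id]])
  m <- dsN$assay$mfi[, screen]
  expect_lt(max(abs(log(m / cfgN$background))), 5 * cfgN$noise_sdlog)
})

test_that("generated datasets are panel-complete and bead counts honor the floor", {
  ds <- generate_dataset(tiny_config(seed = 7, dropout_prob = 0))
  expect_equal(nrow(validate_panel(ds$antibodies, ds$samples, ds$library)), 0)
  expect_true(all(ds$assay$bead_count >= 32))
  ds2 <- generate_dataset(tiny_config(seed = 7, dropout_prob = 0.2))
  expect_true(any(ds2$assay$bead_count < 32))
})

test_that("invalid generator settings are rejected", {
  expect_error(sba_sim_config(class_fractions = c(on = 0.5, co = 0.5,
                                                  off = 0.5, none = 0.5)),
               "sum to 1", class = "sba_config_error")
  expect_error(sba_sim_config(background = 0), class = "sba_config_error")
  expect_error(sba_sim_config(saturation = 50, background = 100),
               class = "sba_config_error")
})

test_that("raising on-target affinity never lowers planted on-target scores", {
  lo <- hi <- numeric(0)
  for (s in 1:20) {
    for (a in c(10, 20)) {
      ds <- generate_dataset(tiny_config(seed = s, a_on = a))
      fit <- suppressWarnings(
        sba_selectivity(ds$assay, ds$antibodies, ds$samples,
                        coupling = ds$coupling))
      ann <- fit$annotations
      pl <- ds$truth$class[ann$antibody_id]
      ok <- pl == "on" & !ds$truth$failed[ann$target_id]
      v <- mean(ann$on_target_mean_rz[ok])
      if (a == 10) lo <- c(lo, v) else hi <- c(hi, v)
    }
  }
  expect_gte(mean(hi), mean(lo))
})
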