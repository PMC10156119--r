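make_expr_fixture <- function(groups, bead = "9001") {
  ## groups: named list construct -> vector of log2 levels (MOCK required)
  ids <- unlist(lapply(names(groups), function(g)
    sprintf("%s_b%d_t1", g, seq_along(groups[[g]]))))
  cons <- rep(names(groups), lengths(groups))
  samples <- sample_manifest(ids, cons, unlist(lapply(groups, seq_along)),
                             1L, "rhodopsin_alpha")
  mfi <- matrix(2^unlist(groups), ncol = 1, dimnames = list(ids, bead))
  lib_ids <- setdiff(names(groups), "MOCK")
  library <- gpcr_library(lib_ids, "rhodopsin_alpha",
                          strrep("A", 10), "FLAG", FALSE)
  list(mfi = mfi, samples = samples, library = library)
}

test_that("bead-count filter masks exactly the under-counted wells", {
  ds <- generate_dataset(tiny_config(seed = 1, dropout_prob = 0))
  f <- filter_bead_counts(ds$assay)
  expect_false(any(f$mask))
  expect_identical(f$mfi, ds$assay$mfi)

  a2 <- ds$assay
  a2$bead_count[2, 3] <- 31L
  f2 <- filter_bead_counts(a2)
  expect_equal(sum(f2$mask), 1L)
  expect_true(is.na(f2$mfi[2, 3]))
  f3 <- filter_bead_counts(a2, min_events = 0)
  expect_false(any(f3$mask))
})

test_that("coupling QC flags precisely the beads below the floor", {
  cp <- c(AB1 = 5000, AB2 = 999, AB3 = 1000, CTRL = 10)
  expect_identical(coupling_qc(cp, floor = 1000, control_ids = "CTRL"), "AB2")
  expect_identical(coupling_qc(cp, floor = 0, control_ids = "CTRL"),
                   character(0))
})

test_that("expression support requires both significance and direction", {
  # construct identical to mock: never supported
  fx <- make_expr_fixture(list(MOCK = c(7, 7.1, 6.9, 7),
                               G1 = c(7, 7.1, 6.9, 7)))
  r <- assess_expression(fx$mfi, fx$samples, fx$library, c(FLAG = "9001"))
  expect_equal(r$status[r$gpcr_id == "G1"], "uncertain")

  # strong overexpression, near-zero spread: supported with tiny p
  set.seed(1)
  fx2 <- make_expr_fixture(list(MOCK = 7 + rnorm(4, 0, 1e-6),
                                G1 = 7 + log2(100) + rnorm(4, 0, 1e-6)))
  r2 <- assess_expression(fx2$mfi, fx2$samples, fx2$library, c(FLAG = "9001"))
  expect_equal(r2$status, "supported")
  expect_lt(r2$dunnett_p, 0.001)

  # significant but BELOW mock: direction gate blocks support
  set.seed(2)
  fx3 <- make_expr_fixture(list(MOCK = 10 + rnorm(4, 0, 0.01),
                                G1 = 7 + rnorm(4, 0, 0.01)))
  r3 <- assess_expression(fx3$mfi, fx3$samples, fx3$library, c(FLAG = "9001"))
  expect_lt(r3$dunnett_p, 0.05)
  expect_equal(r3$status, "uncertain")

  # single replicate: uncertain with NA p-value
  fx4 <- make_expr_fixture(list(MOCK = c(7, 7.1, 6.9, 7),
                                G1 = c(7, 7.05, 7.02, 6.95),
                                G2 = 12))
  r4 <- assess_expression(fx4$mfi, fx4$samples, fx4$library, c(FLAG = "9001"))
  expect_true(is.na(r4$dunnett_p[r4$gpcr_id == "G2"]))
  expect_equal(r4$status[r4$gpcr_id == "G2"], "uncertain")
})

test_that("supported always implies mean log2 level above mock", {
  for (s in 1:3) {
    ds <- generate_dataset(tiny_config(seed = s))
    f <- filter_bead_counts(ds$assay)
    r <- assess_expression(f$mfi, ds$samples, ds$library, CAPTURE_BEADS)
    sup <- r[r$status == "supported", ]
    expect_true(all(sup$mean_log2 > sup$mock_mean_log2))
  }
})

test_that("strong planted expression is recovered when nothing fails", {
  hits <- tot <- 0
  for (s in 1:20) {
    cfg <- tiny_config(seed = s,
                       failure_prob = c(rhodopsin_alpha = 0, rhodopsin_beta = 0))
    ds <- generate_dataset(cfg)
    f <- filter_bead_counts(ds$assay)
    r <- assess_expression(f$mfi, ds$samples, ds$library, CAPTURE_BEADS)
    hits <- hits + sum(r$status == "supported")
    tot <- tot + nrow(r)
  }
  expect_gte(hits / tot, 0.95)
})

test_that("expression summary table is counts-consistent", {
  # the screen's own printed totals regenerate from their counts
  lib <- gpcr_library(sprintf("G%03d", 1:215), "rhodopsin_alpha",
                      strrep("A", 10), "FLAG", FALSE)
  res <- data.frame(gpcr_id = lib$gpcr_id,
                    status = rep(c("supported", "uncertain"), c(182, 33)),
                    stringsAsFactors = FALSE)
  s <- expression_summary(res, lib)
  expect_equal(s$expressed_pct[s$subfamily == "total"], 84.7)

  res$status <- "supported"
  expect_equal(expression_summary(res, lib)$expressed_pct, c(100.0, 100.0))

  # random splits keep round(100 k/n, 1)
  set.seed(10)
  for (i in 1:25) {
    n <- sample(5:300, 1); k <- sample.int(n, 1)
    res2 <- data.frame(gpcr_id = sprintf("H%03d", 1:n),
                       status = rep(c("supported", "uncertain"), c(k, n - k)))
    lib2 <- gpcr_library(res2$gpcr_id, "GSAF", strrep("A", 5), "FLAG", FALSE)
    s2 <- expression_summary(res2, lib2)
    expect_equal(s2$expressed_pct[1], round(100 * k / n, 1))
  }

  # empty subfamily: omitted with a warning
  lib3 <- gpcr_library(c("G1", "G2"), c("rhodopsin_alpha", "other"),
                       strrep("A", 5), "FLAG", FALSE)
  res3 <- data.frame(gpcr_id = "G1", status = "supported")
  expect_warning(s3 <- expression_summary(res3, lib3), "other")
  expect_false("other" %in% s3$subfamily)
})
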