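test_that("structure reader pulls pLDDT from B-factors, PDB and mmCIF alike", {
  st <- build_backbone(3, plddt = c(90, 50, 20))
  dir <- withr::local_tempdir()
  pdb <- file.path(dir, "m.pdb"); cif <- file.path(dir, "m.cif")
  write_structure_pdb(st, pdb)
  write_structure_cif(st, cif)
  a <- read_structure_model(pdb)
  b <- read_structure_model(cif)
  expect_equal(unname(a$plddt), c(90, 50, 20))
  expect_equal(unname(b$plddt), c(90, 50, 20))
  expect_equal(a$atoms[, c("resno", "elety", "x", "y", "z", "b")],
               b$atoms[, c("resno", "elety", "x", "y", "z", "b")],
               tolerance = 1e-6)

  # two chains rejected
  lines <- readLines(pdb)
  bad <- sub("^(ATOM  .{15})A", "\\1B", lines[4:6])
  writeLines(c(lines[1:3], bad, "END"), file.path(dir, "two.pdb"))
  expect_error(read_structure_model(file.path(dir, "two.pdb")),
               "single-chain", class = "sba_structure_error")

  # multiple models: first used with a warning
  writeLines(c("MODEL     1", lines[1:9], "ENDMDL",
               "MODEL     2", lines[1:9], "ENDMDL", "END"),
             file.path(dir, "multi.pdb"))
  expect_warning(m <- read_structure_model(file.path(dir, "multi.pdb")),
                 "first model")
  expect_equal(unname(m$plddt), c(90, 50, 20))
})

test_that("Shrake-Rupley matches closed-form sphere geometry", {
  # isolated atom: 4 pi (r + probe)^2
  a1 <- shrake_rupley_sasa(matrix(c(0, 0, 0), 1), 1.4)
  expect_lt(abs(a1 / (4 * pi * 2.8^2) - 1), 0.005)

  # two atoms far apart: no occlusion
  a2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.4, 1.4))
  expect_equal(a2, rep(a1, 2), tolerance = 1e-9)

  # two equal overlapping spheres at distance d: accessible area
  # per sphere = 2 pi R (R + d/2), R = r + probe
  R <- 2.8; d <- 2.0
  a3 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(1.4, 1.4))
  expect_lt(max(abs(a3 / (2 * pi * R * (R + d / 2)) - 1)), 0.02)

  # lattice-resolution convergence: 240 vs 960 points within 3 %
  set.seed(4)
  xyz <- matrix(rnorm(30, sd = 3), ncol = 3)
  c240 <- shrake_rupley_sasa(xyz, 1.7, n_points = 240)
  c960 <- shrake_rupley_sasa(xyz, 1.7, n_points = 960)
  expect_lt(max(abs(c240 - c960) / (4 * pi * (1.7 + 1.4)^2)), 0.03)
})

test_that("relative SASA normalizes and clips", {
  expect_equal(relative_sasa(c(129, 0), c("ALA", "ALA")), c(1, 0))
  expect_warning(r <- relative_sasa(130, "ALA"), "clipped")
  expect_equal(unname(r), 1)
})

test_that("dihedral secondary structure hits the canonical regions", {
  helix <- build_backbone(12, phi = -57, psi = -47)
  ss_h <- assign_secondary_structure(helix)
  expect_true(all(ss_h[3:10] == "helix"))

  sheet <- build_backbone(12, phi = -139, psi = 135)
  ss_s <- assign_secondary_structure(sheet)
  expect_true(all(ss_s[3:10] == "sheet"))

  tiny <- build_backbone(2, phi = -57, psi = -47)
  expect_true(all(assign_secondary_structure(tiny) == "coil"))

  # generated dihedrals round-trip through the measurement
  d <- backbone_dihedrals(helix)
  expect_equal(d$phi[5], -57, tolerance = 0.5)
  expect_equal(d$psi[5], -47, tolerance = 0.5)
})

test_that("antigen profiles aggregate over the span only", {
  st <- build_backbone(30, phi = -57, psi = -47, plddt = 70)
  res <- residue_annotations(st, n_points = 240)
  pr <- antigen_profile(res, 5, 20, antibody_id = "ab")
  expect_equal(pr$mean_plddt, 70)
  expect_equal(pr$length, 16L)
  expect_equal(pr$helix + pr$sheet + pr$coil, 1, tolerance = 1e-9)
  expect_true(pr$complete)

  # fully coil span
  st2 <- simulate_pseudo_structure(20, exposed = TRUE)
  res2 <- residue_annotations(st2, n_points = 240)
  pr2 <- antigen_profile(res2, 3, 10, antibody_id = "ab2")
  expect_equal(c(pr2$helix, pr2$sheet, pr2$coil), c(0, 0, 1))

  # length-1 span: one-hot fractions
  pr3 <- antigen_profile(res2, 4, 4)
  expect_equal(pr3$length, 1L)
  expect_setequal(c(pr3$helix, pr3$sheet, pr3$coil), c(0, 0, 1))

  # span outside the model: flagged incomplete
  expect_warning(pr4 <- antigen_profile(res2, 15, 40, antibody_id = "ab4"),
                 "incomplete")
  expect_false(pr4$complete)
})

test_that("group comparisons use the right tests and degrade sanely", {
  prof <- function(len, sasa, n, cls)
    data.frame(antibody_id = paste0(cls, seq_len(n)), length = len,
               mean_plddt = 70, mean_rel_sasa = sasa,
               helix = 0.5, sheet = 0.2, coil = 0.3, complete = TRUE,
               stringsAsFactors = FALSE)
  # identical groups: rank-sum p ~ 1, t-test exactly 1 on constant metrics
  p1 <- rbind(prof(1:10, 0.5, 10, "a"), prof(1:10, 0.5, 10, "b"))
  g1 <- compare_groups(p1, rep(c("a", "b"), each = 10))
  lenrow <- g1$pairwise[g1$pairwise$metric == "length", ]
  expect_gt(lenrow$p, 0.9)
  expect_equal(g1$pairwise$p[g1$pairwise$metric == "mean_rel_sasa"], 1)

  # three identical groups: Kruskal-Wallis p ~ 1
  p3 <- rbind(prof(1:10, 0.5, 10, "a"), prof(1:10, 0.5, 10, "b"),
              prof(1:10, 0.5, 10, "c"))
  g3 <- compare_groups(p3, rep(c("a", "b", "c"), each = 10))
  expect_gt(g3$omnibus$p, 0.99)

  # strong separation: t-test power
  set.seed(2)
  pa <- prof(50, 0.5, 50, "a"); pa$mean_rel_sasa <- rnorm(50, 0, 1)
  pb <- prof(50, 0.5, 50, "b"); pb$mean_rel_sasa <- rnorm(50, 5, 1)
  g2 <- compare_groups(rbind(pa, pb), rep(c("a", "b"), each = 50))
  row <- g2$pairwise[g2$pairwise$metric == "mean_rel_sasa", ]
  expect_lt(row$p, 1e-10)
  expect_equal(row$test, "t")
})
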