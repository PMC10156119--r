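## van der Waals radii (Angstrom) by element; default carbon-like
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

## per-residue maximum accessible surface areas (Angstrom^2), theoretical
## values of Tien et al. 2013 (PLoS ONE 8:e80635), used to normalize
## absolute SASA to relative SASA
SASA_MAX_TIEN2013 <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Read a predicted structure model (PDB or mmCIF)
#'
#' Parses a single-chain model and returns its atoms with the per-residue
#' confidence (pLDDT) read from the B-factor field, the convention of
#' predicted-structure repositories. Multi-model files use the first model
#' with a warning; multi-chain files are rejected.
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @return list of class `sba_structure`: `atoms` (data frame `resno`,
#'   `resid`, `elety`, `elem`, `x`, `y`, `z`, `b`), `plddt` (named by
#'   residue number; `NA` where B-factors are missing), `resno`, `resid`.
#' @export
read_structure_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    suppressWarnings(bio3d::read.cif(path))
  } else {
    lines <- readLines(path)
    models <- grep("^MODEL ", lines)
    if (length(models) > 1) {
      warning("multi-model file; using the first model")
      endm <- grep("^ENDMDL", lines)[1]
      tmp <- tempfile(fileext = ".pdb")
      writeLines(c(lines[seq(models[1] + 1L, endm - 1L)], "END"), tmp)
      path <- tmp
    }
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  }
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain[!is.na(at$chain)])
  if (length(chains) > 1)
    sba_stop(paste0("expected a single-chain model, found chains: ",
                    paste(chains, collapse = ", ")), "sba_structure_error")
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(resno = at$resno, resid = at$resid,
                      elety = trimws(at$elety), elem = trimws(elem),
                      x = at$x, y = at$y, z = at$z, b = at$b,
                      stringsAsFactors = FALSE)
  resno <- unique(atoms$resno)
  plddt <- vapply(resno, function(r) {
    sub <- atoms[atoms$resno == r, ]
    ca <- sub$b[sub$elety == "CA"]
    v <- if (length(ca)) ca[1] else mean(sub$b)
    if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else v
  }, numeric(1))
  structure(list(atoms = atoms, plddt = setNames(plddt, resno),
                 resno = resno,
                 resid = setNames(atoms$resid[match(resno, atoms$resno)],
                                  resno)),
            class = "sba_structure")
}

## deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point sampling: each atom is expanded by the probe
#' radius, covered with a deterministic quasi-uniform point lattice, and
#' the accessible area is the unoccluded point fraction times the expanded
#' sphere area.
#'
#' @param coords numeric matrix (atoms x 3).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius (default 1.4, water).
#' @param n_points lattice points per atom (default 960).
#' @return numeric vector of per-atom accessible areas (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) == 1) radii <- rep(radii, n)
  stopifnot(length(radii) == n)
  pts <- fibonacci_sphere(n_points)
  er <- radii + probe
  out <- numeric(n)
  d2 <- as.matrix(dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (er[i] + er)^2 & seq_len(n) != i)
    sphere <- pts * er[i]
    sphere <- sweep(sphere, 2, coords[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dx <- sphere[, 1] - coords[j, 1]
        dy <- sphere[, 2] - coords[j, 2]
        dz <- sphere[, 3] - coords[j, 3]
        free <- free & (dx * dx + dy * dy + dz * dz > er[j]^2)
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    out[i] <- frac * 4 * pi * er[i]^2
  }
  out
}

#' Relative solvent accessibility
#'
#' Divides per-residue absolute SASA by the residue-type maximum
#' (theoretical values of Tien et al. 2013 by default) and clips to
#' `[0, 1]` (with a warning when rounding pushes a value above 1).
#'
#' @param abs_sasa numeric per-residue absolute SASA.
#' @param residue_types three-letter residue codes, recycled names of
#'   `max_table`.
#' @param max_table named numeric normalization table.
#' @return numeric vector in `[0, 1]` (`NA` for unknown residue types).
#' @export
relative_sasa <- function(abs_sasa, residue_types,
                          max_table = SASA_MAX_TIEN2013) {
  mx <- max_table[toupper(residue_types)]
  rel <- unname(abs_sasa / mx)
  if (any(rel > 1, na.rm = TRUE))
    warning("relative SASA above 1 clipped (rounding/unusual geometry)")
  pmin(pmax(rel, 0), 1)
}

## signed dihedral angle (degrees) from four points
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Backbone dihedral angles
#'
#' `phi` (C- N CA C) and `psi` (N CA C N+) per residue from the backbone
#' N/CA/C atoms; `NA` at chain termini or where backbone atoms are missing.
#'
#' @param structure an `sba_structure`.
#' @return data frame `resno`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(structure) {
  at <- structure$atoms
  get <- function(r, ety) {
    row <- at[at$resno == r & at$elety == ety, , drop = FALSE]
    if (nrow(row)) as.numeric(row[1, c("x", "y", "z")]) else NULL
  }
  resno <- structure$resno
  phi <- psi <- rep(NA_real_, length(resno))
  for (i in seq_along(resno)) {
    r <- resno[i]
    N <- get(r, "N"); CA <- get(r, "CA"); C <- get(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1) {
      Cm <- get(resno[i - 1], "C")
      if (!is.null(Cm)) phi[i] <- dihedral_angle(Cm, N, CA, C)
    }
    if (i < length(resno)) {
      Np <- get(resno[i + 1], "N")
      if (!is.null(Np)) psi[i] <- dihedral_angle(N, CA, C, Np)
    }
  }
  data.frame(resno = resno, phi = phi, psi = psi)
}

#' Three-state secondary structure from backbone dihedrals
#'
#' A lightweight dihedral-based assignment: residues falling in the helical
#' region of the Ramachandran plane (`phi` in (-100, -30), `psi` in
#' (-80, -5)) in runs of at least 4 are `helix`; residues in the extended
#' region (`phi` in (-180, -90), `psi` in (90, 180) or below -150) in runs
#' of at least 3 are `sheet`; everything else (including termini and
#' residues with missing backbone) is `coil`. This intentionally replaces
#' hydrogen-bond-based DSSP logic: only three-state fractions feed the
#' downstream statistics, and precomputed per-residue strings can be
#' supplied instead wherever profiles are built.
#'
#' @param structure an `sba_structure` (or a data frame from
#'   [backbone_dihedrals()]).
#' @return character vector (`"helix"`, `"sheet"`, `"coil"`) named by
#'   residue number.
#' @export
assign_secondary_structure <- function(structure) {
  di <- if (inherits(structure, "sba_structure")) backbone_dihedrals(structure)
        else structure
  in_helix <- !is.na(di$phi) & !is.na(di$psi) &
    di$phi > -100 & di$phi < -30 & di$psi > -80 & di$psi < -5
  in_sheet <- !is.na(di$phi) & !is.na(di$psi) &
    di$phi > -180 & di$phi < -90 & (di$psi > 90 | di$psi < -150)
  keep_runs <- function(flag, min_len) {
    r <- rle(flag)
    r$values <- r$values & r$lengths >= min_len
    inverse.rle(r)
  }
  ss <- rep("coil", nrow(di))
  ss[keep_runs(in_helix, 4L)] <- "helix"
  ss[keep_runs(in_sheet, 3L) & ss == "coil"] <- "sheet"
  setNames(ss, di$resno)
}

#' Per-residue annotation of a structure model
#'
#' Combines pLDDT, absolute and relative SASA, and the three-state
#' secondary structure for each residue.
#'
#' @param structure an `sba_structure`.
#' @param probe,n_points SASA parameters (see [shrake_rupley_sasa()]).
#' @param ss optional precomputed per-residue secondary structure (named
#'   character, `helix`/`sheet`/`coil`), bypassing the dihedral assignment.
#' @return data frame of class `sba_residues`: `residue_index` (1-based
#'   position in the chain), `resno`, `resid`, `plddt`, `abs_sasa`,
#'   `rel_sasa`, `ss_class`.
#' @export
residue_annotations <- function(structure, probe = 1.4, n_points = 960,
                                ss = NULL) {
  at <- structure$atoms
  radii <- unname(VDW_RADII[at$elem])
  radii[is.na(radii)] <- 1.70
  area <- shrake_rupley_sasa(as.matrix(at[, c("x", "y", "z")]), radii,
                             probe = probe, n_points = n_points)
  abs_sasa <- vapply(structure$resno,
                     function(r) sum(area[at$resno == r]), numeric(1))
  if (is.null(ss)) ss <- assign_secondary_structure(structure)
  out <- data.frame(residue_index = seq_along(structure$resno),
                    resno = structure$resno,
                    resid = unname(structure$resid),
                    plddt = unname(structure$plddt),
                    abs_sasa = abs_sasa,
                    rel_sasa = relative_sasa(abs_sasa,
                                             unname(structure$resid)),
                    ss_class = unname(ss[as.character(structure$resno)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("sba_residues", "data.frame")
  out
}

#' Antigen feature profile
#'
#' Means and secondary-structure fractions of the residue annotations over
#' the antigen span only (1-based inclusive coordinates on the native
#' sequence). Spans reaching outside the model's resolved residues are
#' flagged incomplete.
#'
#' @param residues an `sba_residues` data frame.
#' @param antigen_start,antigen_end antigen span.
#' @param antibody_id carried through to the output.
#' @return one-row data frame: `antibody_id`, `length`, `mean_plddt`,
#'   `mean_rel_sasa`, `helix`, `sheet`, `coil` (fractions summing to 1),
#'   `complete`.
#' @export
antigen_profile <- function(residues, antigen_start, antigen_end,
                            antibody_id = NA_character_) {
  span <- antigen_start:antigen_end
  hit <- residues[match(span, residues$resno), , drop = FALSE]
  complete <- !anyNA(hit$resno)
  hit <- hit[!is.na(hit$resno), , drop = FALSE]
  if (!nrow(hit)) {
    warning("antigen span entirely outside the model for ", antibody_id)
    return(data.frame(antibody_id = antibody_id,
                      length = length(span), mean_plddt = NA_real_,
                      mean_rel_sasa = NA_real_, helix = NA_real_,
                      sheet = NA_real_, coil = NA_real_, complete = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (!complete)
    warning("antigen span partially outside the model for ", antibody_id,
            "; profile flagged incomplete")
  fr <- prop.table(table(factor(hit$ss_class,
                                levels = c("helix", "sheet", "coil"))))
  data.frame(antibody_id = antibody_id,
             length = antigen_end - antigen_start + 1L,
             mean_plddt = mean(hit$plddt),
             mean_rel_sasa = mean(hit$rel_sasa, na.rm = TRUE),
             helix = as.numeric(fr["helix"]), sheet = as.numeric(fr["sheet"]),
             coil = as.numeric(fr["coil"]), complete = complete,
             stringsAsFactors = FALSE)
}

#' Compare antigen features between selectivity classes
#'
#' Antigen length is compared with a Kruskal-Wallis omnibus test followed
#' by pairwise two-sided Wilcoxon rank-sum tests; the structural metrics
#' (mean pLDDT, mean relative SASA, secondary-structure fractions) with
#' independent two-sample Student's t tests between classes. Incomplete
#' profiles are excluded with a warning.
#'
#' @param profiles data frame of [antigen_profile()] rows.
#' @param classes per-profile class labels (e.g. `on_target`, `off_target`,
#'   `no_target`).
#' @return list: `omnibus` (data frame, Kruskal-Wallis on length),
#'   `pairwise` (one row per metric and class pair: statistic, p, group
#'   means, sds and sizes).
#' @export
compare_groups <- function(profiles, classes) {
  classes <- as.character(classes)
  if ("complete" %in% names(profiles) && any(!profiles$complete)) {
    warning(sum(!profiles$complete),
            " incomplete antigen profile(s) excluded from group statistics")
    keep <- profiles$complete
    profiles <- profiles[keep, , drop = FALSE]
    classes <- classes[keep]
  }
  lv <- unique(classes)
  omnibus <- data.frame(metric = "length", test = "kruskal_wallis",
                        statistic = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE)
  if (length(lv) >= 2) {
    kw <- kruskal.test(profiles$length, factor(classes))
    omnibus$statistic <- unname(kw$statistic); omnibus$p <- kw$p.value
  }
  metrics <- c("length", "mean_plddt", "mean_rel_sasa", "helix", "sheet", "coil")
  rows <- list()
  for (m in metrics) {
    for (pair in if (length(lv) >= 2) combn(lv, 2, simplify = FALSE) else list()) {
      xa <- profiles[[m]][classes == pair[1]]
      xb <- profiles[[m]][classes == pair[2]]
      xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
      if (length(xa) < 2 || length(xb) < 2) next
      tst <- if (m == "length") {
        w <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE, correct = TRUE))
        list(stat = unname(w$statistic), p = w$p.value, name = "wilcoxon")
      } else {
        if (sd(xa) == 0 && sd(xb) == 0 && mean(xa) == mean(xb))
          list(stat = 0, p = 1, name = "t")
        else {
          tt <- t.test(xa, xb, var.equal = TRUE)
          list(stat = unname(tt$statistic), p = tt$p.value, name = "t")
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group_a = pair[1], group_b = pair[2], test = tst$name,
        statistic = tst$stat, p = tst$p,
        mean_a = mean(xa), sd_a = sd(xa), n_a = length(xa),
        mean_b = mean(xb), sd_b = sd(xb), n_b = length(xb),
        stringsAsFactors = FALSE)
    }
  }
  list(omnibus = omnibus,
       pairwise = if (length(rows)) do.call(rbind, rows)
                  else data.frame())
}

## ---- synthetic structure fixtures ----------------------------------------

#' Write a structure as a minimal PDB file
#' @param structure an `sba_structure` (or compatible `atoms` data frame).
#' @param path output path.
#' @export
write_structure_pdb <- function(structure, path) {
  at <- if (inherits(structure, "sba_structure")) structure$atoms else structure
  lines <- vapply(seq_len(nrow(at)), function(i) {
    nm <- at$elety[i]
    nm4 <- if (nchar(nm) < 4) paste0(" ", sprintf("%-3s", nm)) else substr(nm, 1, 4)
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, nm4, substr(at$resid[i], 1, 3), "A",
            at$resno[i], at$x[i], at$y[i], at$z[i], 1.0, at$b[i], at$elem[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## place atom D from A,B,C with bond length r (C-D), angle theta (B-C-D,
## degrees) and torsion chi (A-B-C-D, degrees): natural extension reference
nerf_place <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- -chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal poly-alanine backbone from dihedrals
#'
#' Constructs N/CA/C backbone coordinates with standard bond geometry and
#' the requested `(phi, psi)` per residue (`omega` fixed trans). Useful for
#' secondary-structure fixtures: `phi = -57, psi = -47` gives an ideal
#' alpha helix, `phi = -139, psi = 135` an extended strand.
#'
#' @param n_res number of residues.
#' @param phi,psi backbone dihedrals in degrees (recycled).
#' @param plddt B-factor value stored per residue (recycled).
#' @return an `sba_structure`.
#' @export
build_backbone <- function(n_res, phi = -57, psi = -47, plddt = 90) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  plddt <- rep_len(plddt, n_res)
  ## bond lengths / angles: N-CA 1.458, CA-C 1.525, C-N 1.329;
  ## N-CA-C 111.2, CA-C-N 116.6, C-N-CA 121.7
  coords <- list(N1 = c(0, 0, 0), CA1 = c(1.458, 0, 0))
  ang <- 111.2 * pi / 180
  coords$C1 <- coords$CA1 + 1.525 * c(-cos(ang), sin(ang), 0)
  atoms <- list(
    data.frame(resno = 1L, elety = c("N", "CA", "C"), stringsAsFactors = FALSE))
  xyz <- rbind(coords$N1, coords$CA1, coords$C1)
  for (i in 2:n_res) {
    prevN <- xyz[nrow(xyz) - 2, ]; prevCA <- xyz[nrow(xyz) - 1, ]
    prevC <- xyz[nrow(xyz), ]
    N <- nerf_place(prevN, prevCA, prevC, 1.329, 116.6, psi[i - 1])
    CA <- nerf_place(prevCA, prevC, N, 1.458, 121.7, 180)   # omega trans
    C <- nerf_place(prevC, N, CA, 1.525, 111.2, phi[i])
    xyz <- rbind(xyz, N, CA, C)
    atoms[[i]] <- data.frame(resno = as.integer(i), elety = c("N", "CA", "C"),
                             stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, atoms)
  at$resid <- "ALA"
  at$elem <- substr(at$elety, 1, 1)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at$b <- plddt[at$resno]
  structure(list(atoms = at[, c("resno", "resid", "elety", "elem",
                                "x", "y", "z", "b")],
                 plddt = setNames(plddt, seq_len(n_res)),
                 resno = seq_len(n_res),
                 resid = setNames(rep("ALA", n_res), seq_len(n_res))),
            class = "sba_structure")
}

#' Simulate a pseudo-structure with exposed or buried residues
#'
#' One pseudo-atom per residue: *exposed* structures are extended chains
#' (every residue solvent accessible, low pLDDT, i.e. disordered-like);
#' *buried* structures pack the residues on a compact cubic lattice (core
#' residues occluded, high pLDDT). A coarse stand-in for predicted models
#' when exercising the group statistics; labelled synthetic throughout.
#'
#' @param n_res residues.
#' @param exposed logical.
#' @param plddt_mean,plddt_sd per-residue confidence distribution.
#' @param jitter coordinate noise (Angstrom).
#' @return an `sba_structure` (single `CA` pseudo-atom per residue).
#' @export
simulate_pseudo_structure <- function(n_res, exposed = TRUE,
                                      plddt_mean = if (exposed) 55 else 90,
                                      plddt_sd = 5, jitter = 0.3) {
  if (exposed) {
    xyz <- cbind(3.8 * seq_len(n_res), 0, 0)
  } else {
    side <- ceiling(n_res^(1 / 3))
    g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
    g <- g[order(rowSums((g - (side + 1) / 2)^2)), ][seq_len(n_res), ]
    xyz <- 3.8 * as.matrix(g)
  }
  xyz <- xyz + matrix(rnorm(3 * n_res, 0, jitter), ncol = 3)
  b <- pmin(100, pmax(0, rnorm(n_res, plddt_mean, plddt_sd)))
  at <- data.frame(resno = seq_len(n_res), resid = "ALA", elety = "CA",
                   elem = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   b = b, stringsAsFactors = FALSE)
  structure(list(atoms = at, plddt = setNames(b, seq_len(n_res)),
                 resno = seq_len(n_res),
                 resid = setNames(rep("ALA", n_res), seq_len(n_res))),
            class = "sba_structure")
}
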