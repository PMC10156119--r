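# shared fixtures and independent oracles for the suite

tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               n_gpcrs = c(rhodopsin_alpha = 3L, rhodopsin_beta = 3L),
               n_abs = 10L,
               failure_prob = c(rhodopsin_alpha = 0.1, rhodopsin_beta = 0.1))
  do.call(sba_sim_config, utils::modifyList(args, list(...)))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# brute-force affine-gap Smith-Waterman (three-state DP, empty alignment 0);
# gap of length k costs open + k * ext
sw_oracle <- function(q, s, mat = blosum62, open = 11, ext = 1) {
  qa <- strsplit(q, "")[[1]]; sa <- strsplit(s, "")[[1]]
  m <- length(qa); n <- length(sa)
  M <- matrix(0, m + 1, n + 1)
  X <- Y <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 1:m) for (j in 1:n) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    M[i + 1, j + 1] <- max(0, mat[qa[i], sa[j]] +
                             max(M[i, j], X[i, j], Y[i, j]))
    best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
  }
  best
}

rand_peptide <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

# permutation oracle for Dunnett-style max-|t| contrasts against mock:
# single-step p per group = Pr(max_j |T_j*| >= |t_g|) over label permutations
dunnett_perm <- function(y, grp, mock = "MOCK", B = 1e5, seed = 42) {
  set.seed(seed)
  groups <- setdiff(unique(grp), mock)
  n <- length(y)
  G <- vapply(c(mock, groups), function(g) as.numeric(grp == g),
              numeric(n))
  ng <- colSums(G)
  k <- ncol(G)
  tstat <- function(yv) {
    mu <- crossprod(G, yv) / ng
    ssw <- sum(yv^2) - sum(ng * mu^2)
    s2 <- ssw / (n - k)
    (mu[-1] - mu[1]) / sqrt(s2 * (1 / ng[-1] + 1 / ng[1]))
  }
  t_obs <- tstat(y)
  P <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  YP <- matrix(y[P], n, B)
  MU <- crossprod(G, YP) / ng                       # k x B
  SSW <- colSums(YP^2) - colSums(MU^2 * ng)
  S2 <- SSW / (n - k)
  TT <- abs(sweep(MU[-1, , drop = FALSE], 2, MU[1, ])) /
    sqrt(outer(1 / ng[-1] + 1 / ng[1], S2))
  maxT <- apply(TT, 2, max)
  p <- vapply(abs(t_obs), function(t0) (sum(maxT >= t0) + 1) / (B + 1),
              numeric(1))
  setNames(p, groups)
}

# minimal mmCIF writer for parity fixtures
write_structure_cif <- function(structure, path) {
  at <- structure$atoms
  hdr <- c("data_synthetic", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.label_asym_id",
           "_atom_site.label_entity_id", "_atom_site.label_seq_id",
           "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
           "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
           "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
           "_atom_site.pdbx_PDB_model_num")
  rows <- vapply(seq_len(nrow(at)), function(i)
    sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 %.2f ? %d %s A %s 1",
            i, at$elem[i], at$elety[i], at$resid[i], at$resno[i],
            at$x[i], at$y[i], at$z[i], at$b[i], at$resno[i], at$resid[i],
            at$elety[i]), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# capture-bead map used throughout (generator control beads)
CAPTURE_BEADS <- c(FLAG = "9001", HA = "9002")
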