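#' Configuration for the synthetic SBA experiment generator
#'
#' Collects every knob of the generative model in one validated object. The
#' defaults describe a screen of the kind the package targets: per-subfamily
#' panels of overexpressed receptors measured in four biological replicates
#' against mock (empty-vector) lysates, antigens of 54 +/- 26 residues
#' (truncated to 20--150), per-subfamily expression failure rates averaging
#' ~15%, planted antibody class fractions {on 0.61, co 0.04, off 0.08,
#' none 0.27}, a linear-to-saturation signal model with multiplicative
#' lognormal noise, and cross-reactivity planted through two mechanisms:
#' sequence homology (a shared, lightly mutated subfamily segment carrying
#' the antigen) and relative abundance (a dissimilar off-target expressed
#' several-fold higher).
#'
#' @param seed integer seed; every generator operation is deterministic
#'   given it.
#' @param n_gpcrs named integer vector, receptors per subfamily panel.
#' @param n_abs number of screening antibodies to plant.
#' @param protein_length residues per synthetic receptor.
#' @param shared_segment_length,segment_mut_rate length of the common
#'   within-subfamily segment and its per-residue mutation rate.
#' @param antigen_len_mean,antigen_len_sd,antigen_len_range antigen length
#'   distribution (normal, truncated to the range), in residues.
#' @param n_bio,n_tech,n_mock biological/technical replicates per construct
#'   and mock wells per panel.
#' @param mock_meanlog,expr_fold,expr_sdlog lognormal abundance model:
#'   mock-like level `exp(mock_meanlog)`, expressed constructs `expr_fold`
#'   above it, lognormal sd `expr_sdlog`.
#' @param failure_prob named per-subfamily probability that a construct
#'   fails to express (level drawn from the mock distribution).
#' @param a_on,a_cross on-target and planted cross-reactive affinities
#'   (MFI units per abundance unit).
#' @param background,saturation background MFI `b` and detector cap `S`
#'   (arbitrary units), with `S > b > 0`.
#' @param noise_sdlog sd of the multiplicative lognormal measurement noise.
#' @param tag_affinity affinity of the anti-tag capture control beads.
#' @param coupling_mfi,coupling_fail_mfi,coupling_fail_prob,coupling_floor
#'   coupling-efficiency signal for sound and failed beads, the failure
#'   probability, and the QC floor.
#' @param class_fractions named fractions of planted antibody classes
#'   `c(on=, co=, off=, none=)`, summing to 1.
#' @param crossreact_mode `"mixed"`, `"homology"` or `"abundance"`: which
#'   mechanism(s) drive planted cross-reactivity.
#' @param homology_fraction in mixed mode, fraction of cross-reactive
#'   antibodies planted via the homology mechanism.
#' @param abundance_boost expression fold applied to abundance-mechanism
#'   off-target constructs.
#' @param bead_count_mean,bead_count_floor,dropout_prob bead-count model:
#'   counts are `floor + Poisson(mean - floor)` except for dropout wells,
#'   uniform below the floor.
#' @param ha_prob_gsaf probability that a GSAF-panel construct carries an
#'   HA (rather than FLAG) N-tag.
#' @return A validated list of class `sba_sim_config`.
#' @export
sba_sim_config <- function(seed = 1L,
                           n_gpcrs = c(rhodopsin_alpha = 5L, rhodopsin_beta = 4L,
                                       rhodopsin_gamma = 4L, rhodopsin_delta = 4L,
                                       GSAF = 4L, other = 3L),
                           n_abs = 40L,
                           protein_length = 300L,
                           shared_segment_length = 90L,
                           segment_mut_rate = 0.05,
                           antigen_len_mean = 54, antigen_len_sd = 26,
                           antigen_len_range = c(20L, 150L),
                           n_bio = 4L, n_tech = 1L, n_mock = 4L,
                           mock_meanlog = 0, expr_fold = 100, expr_sdlog = 0.35,
                           failure_prob = c(rhodopsin_alpha = 0.07,
                                            rhodopsin_beta = 0.13,
                                            rhodopsin_gamma = 0.15,
                                            rhodopsin_delta = 0.26,
                                            GSAF = 0.18, other = 0.25),
                           a_on = 10, a_cross = 5,
                           background = 100, saturation = 60000,
                           noise_sdlog = 0.15,
                           tag_affinity = 10,
                           coupling_mfi = 20000, coupling_fail_mfi = 200,
                           coupling_fail_prob = 0.02, coupling_floor = 1000,
                           class_fractions = c(on = 0.61, co = 0.04,
                                               off = 0.08, none = 0.27),
                           crossreact_mode = c("mixed", "homology", "abundance"),
                           homology_fraction = 0.5,
                           abundance_boost = 4,
                           bead_count_mean = 100, bead_count_floor = 32,
                           dropout_prob = 0.01,
                           ha_prob_gsaf = 0.4) {
  cfg <- as.list(environment())
  cfg$crossreact_mode <- match.arg(crossreact_mode)
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9)
    sba_stop("class_fractions must sum to 1", "sba_config_error")
  if (!all(names(cfg$class_fractions) == c("on", "co", "off", "none")))
    sba_stop("class_fractions must be named on, co, off, none", "sba_config_error")
  if (!(cfg$saturation > cfg$background && cfg$background > 0))
    sba_stop("need saturation > background > 0", "sba_config_error")
  if (any(c(cfg$expr_sdlog, cfg$noise_sdlog) < 0))
    sba_stop("spread parameters must be non-negative", "sba_config_error")
  if (any(!names(cfg$n_gpcrs) %in% SUBFAMILIES))
    sba_stop("n_gpcrs names must be subfamilies", "sba_config_error")
  miss <- setdiff(names(cfg$n_gpcrs), names(cfg$failure_prob))
  if (length(miss))
    sba_stop(paste0("failure_prob missing for: ", paste(miss, collapse = ", ")),
             "sba_config_error")
  class(cfg) <- "sba_sim_config"
  cfg
}

rand_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

subfam_prefix <- c(rhodopsin_alpha = "RA", rhodopsin_beta = "RB",
                   rhodopsin_gamma = "RG", rhodopsin_delta = "RD",
                   GSAF = "GS", other = "OT")

#' Simulate a receptor library
#'
#' Random amino-acid sequences; members of a subfamily share a common
#' ancestral segment, independently mutated per member at
#' `segment_mut_rate`, so sequence-homology-driven cross-reactivity can be
#' planted and later recovered by alignment. The segment position of each
#' member is recorded in the `segment_info` attribute.
#'
#' @param config an [sba_sim_config()].
#' @return An `sba_library` with a `segment_info` attribute
#'   (`gpcr_id`, `seg_start`, `seg_end`).
#' @export
simulate_library <- function(config) {
  set.seed(config$seed)
  L <- config$protein_length
  SL <- config$shared_segment_length
  rows <- list(); seginfo <- list()
  for (sf in names(config$n_gpcrs)) {
    n <- config$n_gpcrs[[sf]]
    if (n == 0L) next
    ancestor <- rand_aa(SL)
    for (i in seq_len(n)) {
      id <- sprintf("GPR%s%02d", subfam_prefix[[sf]], i)
      seg <- mutate_seq(ancestor, config$segment_mut_rate)
      seg_start <- sample.int(L - SL + 1L, 1L)
      body <- rand_aa(L)
      sequence <- paste0(substr(body, 1L, seg_start - 1L), seg,
                         substr(body, seg_start + SL, L))
      n_tag <- if (sf == "GSAF" && runif(1) < config$ha_prob_gsaf) "HA" else "FLAG"
      rows[[length(rows) + 1L]] <-
        data.frame(gpcr_id = id, subfamily = sf, sequence = sequence,
                   n_tag = n_tag, orphan = runif(1) < 0.2,
                   stringsAsFactors = FALSE)
      seginfo[[length(seginfo) + 1L]] <-
        data.frame(gpcr_id = id, seg_start = seg_start,
                   seg_end = seg_start + SL - 1L, stringsAsFactors = FALSE)
    }
  }
  r <- do.call(rbind, rows)
  lib <- gpcr_library(r$gpcr_id, r$subfamily, r$sequence, r$n_tag, r$orphan)
  attr(lib, "segment_info") <- do.call(rbind, seginfo)
  lib
}

## truncated-normal antigen length
draw_antigen_length <- function(config, upper_cap = Inf) {
  lo <- config$antigen_len_range[1]
  hi <- min(config$antigen_len_range[2], upper_cap)
  repeat {
    x <- round(rnorm(1, config$antigen_len_mean, config$antigen_len_sd))
    if (x >= lo && x <= hi) return(as.integer(x))
    if (hi <= lo) return(as.integer(lo))
  }
}

#' Plant screening antibodies and their ground-truth classes
#'
#' Assigns targets round-robin over the library (so most targets receive
#' more than one antibody), draws each antibody's class from
#' `class_fractions`, places its antigen on the intended target, and plants
#' affinities: on-target antibodies bind only their target; co-/off-target
#' antibodies additionally (or instead) bind one same-panel off-target,
#' through the homology mechanism (antigen inside the shared segment) or the
#' abundance mechanism (dissimilar antigen, off-target construct boosted
#' `abundance_boost`-fold); no-binders bind nothing.
#'
#' @param config an [sba_sim_config()].
#' @param library output of [simulate_library()].
#' @return list with the antibody manifest (`antibodies`, including the four
#'   control beads) and the truth ledger fields (`class`, `mechanism`,
#'   `off_target`, `affinities`, `expr_boost`, `coupling`, `coupling_failed`).
#' @export
plant_antibodies <- function(config, library) {
  set.seed(config$seed + 1L)
  seginfo <- attr(library, "segment_info")
  n <- config$n_abs
  tgt_idx <- rep(seq_len(nrow(library)), length.out = n)
  classes <- sample(names(config$class_fractions), n, replace = TRUE,
                    prob = config$class_fractions)
  mech_pool <- switch(config$crossreact_mode,
                      homology = "homology", abundance = "abundance", "mixed")
  ## finalize classes first: co/off need a same-panel partner
  for (i in seq_len(n)) {
    if (!classes[i] %in% c("co", "off")) next
    sf <- library$subfamily[tgt_idx[i]]
    if (sum(library$subfamily == sf) < 2L)
      classes[i] <- if (classes[i] == "co") "on" else "none"
  }
  ## intended targets of cross-reactive antibodies: never choose them as
  ## abundance off-targets, or their boost would cancel that antibody's
  ## own off/on expression ratio
  protected <- unique(library$gpcr_id[tgt_idx[classes %in% c("co", "off")]])
  rows <- list()
  mechanism <- setNames(rep(NA_character_, n), sprintf("AB%03d", seq_len(n)))
  off_target <- mechanism
  affinities <- vector("list", n)
  expr_boost <- setNames(rep(1, nrow(library)), library$gpcr_id)
  for (i in seq_len(n)) {
    ab <- sprintf("AB%03d", i)
    tgt <- library[tgt_idx[i], ]
    sf_members <- library$gpcr_id[library$subfamily == tgt$subfamily]
    partners <- setdiff(sf_members, tgt$gpcr_id)
    cls <- classes[i]
    seg <- seginfo[seginfo$gpcr_id == tgt$gpcr_id, ]
    if (cls %in% c("co", "off")) {
      mech <- if (mech_pool == "mixed") {
        if (runif(1) < config$homology_fraction) "homology" else "abundance"
      } else mech_pool
      pool <- if (mech == "abundance") setdiff(partners, protected) else partners
      if (!length(pool)) pool <- partners
      off <- if (length(pool) == 1L) pool else sample(pool, 1L)
      mechanism[ab] <- mech
      off_target[ab] <- off
      if (mech == "homology") {
        len <- draw_antigen_length(config, upper_cap = config$shared_segment_length)
        a_start <- seg$seg_start + sample.int(config$shared_segment_length - len + 1L, 1L) - 1L
      } else {
        len <- draw_antigen_length(config)
        a_start <- place_outside_segment(config$protein_length, seg, len)
        expr_boost[off] <- config$abundance_boost
      }
      aff <- if (cls == "co") setNames(c(config$a_on, config$a_cross),
                                       c(tgt$gpcr_id, off))
             else setNames(config$a_cross, off)
    } else {
      len <- draw_antigen_length(config)
      a_start <- sample.int(config$protein_length - len + 1L, 1L)
      aff <- if (cls == "on") setNames(config$a_on, tgt$gpcr_id) else numeric(0)
    }
    classes[i] <- cls
    affinities[[i]] <- aff
    rows[[length(rows) + 1L]] <-
      data.frame(antibody_id = ab, bead_id = i, target_id = tgt$gpcr_id,
                 subfamily_panel = tgt$subfamily, antigen_start = a_start,
                 antigen_end = a_start + len - 1L, source = "synthetic",
                 stringsAsFactors = FALSE)
  }
  names(affinities) <- sprintf("AB%03d", seq_len(n))
  ctrl <- data.frame(antibody_id = c("CTRL_FLAG", "CTRL_HA", "CTRL_1D4", "CTRL_COUPLING"),
                     bead_id = 9001:9004,
                     target_id = c("anti-FLAG", "anti-HA", "anti-1D4", "coupling-control"),
                     subfamily_panel = "other",
                     antigen_start = NA_integer_, antigen_end = NA_integer_,
                     source = "control", stringsAsFactors = FALSE)
  manifest <- validate_antibody_manifest(rbind(do.call(rbind, rows), ctrl))
  failed_coupling <- runif(n) < config$coupling_fail_prob
  coupling <- setNames(ifelse(failed_coupling, config$coupling_fail_mfi,
                              config$coupling_mfi) * rlnorm(n, 0, config$noise_sdlog),
                       sprintf("AB%03d", seq_len(n)))
  coupling <- c(coupling, setNames(rep(config$coupling_mfi, 4), ctrl$antibody_id))
  list(antibodies = manifest,
       class = setNames(classes, sprintf("AB%03d", seq_len(n))),
       mechanism = mechanism, off_target = off_target,
       affinities = affinities, expr_boost = expr_boost,
       coupling = coupling,
       coupling_failed = setNames(failed_coupling, sprintf("AB%03d", seq_len(n))))
}

place_outside_segment <- function(L, seg, len) {
  left_ok <- seg$seg_start - 1L >= len
  right_ok <- L - seg$seg_end >= len
  if (!left_ok && !right_ok) return(sample.int(L - len + 1L, 1L)) # give up: overlap
  side <- if (left_ok && right_ok) sample(c("l", "r"), 1L) else if (left_ok) "l" else "r"
  if (side == "l") sample.int(seg$seg_start - len, 1L)
  else seg$seg_end + sample.int(L - seg$seg_end - len + 1L, 1L)
}

#' Build the sample manifest for a simulated experiment
#'
#' Each construct gets `n_bio` biological x `n_tech` technical replicate
#' wells in its subfamily panel; each panel additionally carries `n_mock`
#' mock (empty-vector) wells.
#'
#' @inheritParams plant_antibodies
#' @return An `sba_samples` manifest.
#' @export
build_samples <- function(config, library) {
  rows <- list()
  for (i in seq_len(nrow(library))) {
    g <- library[i, ]
    for (b in seq_len(config$n_bio)) for (t in seq_len(config$n_tech))
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = sprintf("%s_b%d_t%d", g$gpcr_id, b, t),
                   construct = g$gpcr_id, bio_replicate = b, tech_replicate = t,
                   panel = g$subfamily, stringsAsFactors = FALSE)
  }
  for (sf in unique(library$subfamily))
    for (b in seq_len(config$n_mock))
      rows[[length(rows) + 1L]] <-
        data.frame(sample_id = sprintf("%s_MOCK_b%d_t1", subfam_prefix[[sf]], b),
                   construct = MOCK_TOKEN, bio_replicate = b, tech_replicate = 1L,
                   panel = sf, stringsAsFactors = FALSE)
  df <- do.call(rbind, rows)
  sample_manifest(df$sample_id, df$construct, df$bio_replicate,
                  df$tech_replicate, df$panel)
}

#' Simulate construct abundance per well
#'
#' Expressed constructs draw a lognormal level `expr_fold` (times any
#' abundance boost) above the mock-like level; constructs failing expression
#' (per-subfamily probability) draw from the mock distribution itself, so
#' they are indistinguishable from mock in expectation. One level is drawn
#' per biological replicate; technical replicates share it. Mock wells draw
#' a mock-like residual level that no antibody can bind.
#'
#' @inheritParams plant_antibodies
#' @param samples output of [build_samples()].
#' @param boost optional named per-construct expression multiplier (from the
#'   truth ledger's abundance planting).
#' @return list: `level` (named per sample), `failed` (named logical per
#'   construct).
#' @export
simulate_expression <- function(config, library, samples, boost = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(boost)) boost <- setNames(rep(1, nrow(library)), library$gpcr_id)
  failed <- setNames(runif(nrow(library)) <
                       config$failure_prob[library$subfamily],
                     library$gpcr_id)
  level <- setNames(numeric(nrow(samples)), samples$sample_id)
  for (g in c(library$gpcr_id, MOCK_TOKEN)) {
    idx <- which(samples$construct == g)
    if (!length(idx)) next
    if (g == MOCK_TOKEN) {
      level[idx] <- rlnorm(length(idx), config$mock_meanlog, config$expr_sdlog)
      next
    }
    ml <- if (failed[g]) config$mock_meanlog
          else config$mock_meanlog + log(config$expr_fold * boost[g])
    bio <- samples$bio_replicate[idx]
    draws <- setNames(rlnorm(length(unique(bio)), ml, config$expr_sdlog),
                      unique(bio))
    level[idx] <- draws[as.character(bio)]
  }
  list(level = level, failed = failed)
}

#' Simulate the MFI and bead-count matrices
#'
#' Signal model per antibody bead and well:
#' `MFI = min(S, b + sum_g affinity(ab, g) * level(g, well)) * exp(eps)`,
#' `eps ~ N(0, noise_sdlog^2)`. Anti-tag control beads bind the matching
#' epitope tag of the well's construct with `tag_affinity`; the anti-1D4
#' bead binds every construct (constant C-tag); the coupling-control bead
#' and beads with failed coupling read background. Bead counts sit at
#' `floor + Poisson(mean - floor)` except for dropout wells below the floor.
#'
#' @inheritParams simulate_expression
#' @param truth output of [plant_antibodies()].
#' @param expression output of [simulate_expression()].
#' @return An [sba_assay()] (samples x beads, columns named by bead id).
#' @export
simulate_mfi <- function(config, truth, samples, library, expression) {
  set.seed(config$seed + 3L)
  ab_man <- truth$antibodies
  ns <- nrow(samples); nb <- nrow(ab_man)
  tag_of <- setNames(library$n_tag, library$gpcr_id)
  lvl <- expression$level[samples$sample_id]
  cons <- samples$construct
  signal <- matrix(config$background, ns, nb,
                   dimnames = list(samples$sample_id, as.character(ab_man$bead_id)))
  for (j in seq_len(nb)) {
    ab <- ab_man$antibody_id[j]
    role <- ab_man$target_id[j]
    if (role == "coupling-control") next
    if (role == "anti-FLAG" || role == "anti-HA") {
      tag <- sub("anti-", "", role)
      hit <- cons != MOCK_TOKEN & tag_of[cons] == tag
      signal[hit, j] <- signal[hit, j] + config$tag_affinity * lvl[hit]
    } else if (role == "anti-1D4") {
      hit <- cons != MOCK_TOKEN
      signal[hit, j] <- signal[hit, j] + config$tag_affinity * lvl[hit]
    } else {
      if (isTRUE(truth$coupling_failed[ab])) next
      aff <- truth$affinities[[ab]]
      for (g in names(aff)) {
        hit <- cons == g
        signal[hit, j] <- signal[hit, j] + aff[g] * lvl[hit]
      }
    }
  }
  mfi <- pmin(signal, config$saturation) *
    matrix(rlnorm(ns * nb, 0, config$noise_sdlog), ns, nb)
  extra <- max(config$bead_count_mean - config$bead_count_floor, 0)
  counts <- config$bead_count_floor + matrix(rpois(ns * nb, extra), ns, nb)
  drop <- matrix(runif(ns * nb) < config$dropout_prob, ns, nb)
  if (any(drop))
    counts[drop] <- sample.int(config$bead_count_floor, sum(drop), replace = TRUE) - 1L
  dimnames(counts) <- dimnames(mfi) <- dimnames(signal)
  sba_assay(round(mfi, 1), counts)
}

#' Generate a complete synthetic SBA experiment
#'
#' One call yields a panel-complete dataset (library, manifests, MFI and
#' bead-count matrices, coupling-efficiency vector) together with the
#' ground-truth ledger used by parameter-recovery tests. Deterministic given
#' `config$seed`; the output always passes [validate_panel()].
#'
#' @param config an [sba_sim_config()].
#' @param dir optional directory; when given, all standard files are written
#'   (`library.fasta`, `library_meta.tsv`, `antibodies.tsv`, `samples.tsv`,
#'   `mfi.tsv`, `bead_counts.tsv`, `coupling.tsv`, `truth.json`).
#' @return list of class `sba_dataset` with elements `library`, `antibodies`,
#'   `samples`, `assay`, `coupling`, `truth`, `config`.
#' @export
generate_dataset <- function(config = sba_sim_config(), dir = NULL) {
  library <- simulate_library(config)
  planted <- plant_antibodies(config, library)
  samples <- build_samples(config, library)
  expression <- simulate_expression(config, library, samples,
                                    boost = planted$expr_boost)
  assay <- simulate_mfi(config, planted, samples, library, expression)
  truth <- structure(list(class = planted$class,
                          mechanism = planted$mechanism,
                          off_target = planted$off_target,
                          affinities = planted$affinities,
                          expr_boost = planted$expr_boost,
                          coupling_failed = planted$coupling_failed,
                          failed = expression$failed,
                          level = expression$level),
                     class = "sba_truth")
  ds <- structure(list(library = library, antibodies = planted$antibodies,
                       samples = samples, assay = assay,
                       coupling = planted$coupling, truth = truth,
                       config = config),
                  class = "sba_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a simulated dataset to standard files
#' @param ds an `sba_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gpcr_library(ds$library, p("library.fasta"), p("library_meta.tsv"))
  write_tsv(as.data.frame(ds$antibodies), p("antibodies.tsv"))
  write_tsv(as.data.frame(ds$samples), p("samples.tsv"))
  write_assay(ds$assay, p("mfi.tsv"), p("bead_counts.tsv"))
  write_tsv(data.frame(antibody_id = names(ds$coupling),
                       coupling_mfi = sprintf("%.1f", ds$coupling)),
            p("coupling.tsv"))
  truth <- ds$truth
  jsonlite::write_json(
    list(class = as.list(truth$class), mechanism = as.list(truth$mechanism),
         off_target = as.list(truth$off_target),
         affinities = lapply(truth$affinities, as.list),
         expr_boost = as.list(truth$expr_boost),
         coupling_failed = as.list(truth$coupling_failed),
         failed = as.list(truth$failed), level = as.list(truth$level)),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(ds)
}

#' Read a dataset previously written by [write_dataset()]
#' @param dir directory holding the standard files.
#' @return list with `library`, `antibodies`, `samples`, `assay`, `coupling`
#'   (the truth ledger is not re-read; it is test metadata, not input).
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  library <- read_gpcr_library(p("library.fasta"), p("library_meta.tsv"))
  ab <- validate_antibody_manifest(read_tsv(p("antibodies.tsv")))
  sm <- read_tsv(p("samples.tsv"))
  samples <- sample_manifest(sm$sample_id, sm$construct, sm$bio_replicate,
                             sm$tech_replicate, sm$panel)
  assay <- read_mfi_table(p("mfi.tsv"), p("bead_counts.tsv"), ab, samples)
  cp <- read_tsv(p("coupling.tsv"))
  list(library = library, antibodies = ab, samples = samples, assay = assay,
       coupling = setNames(as.numeric(cp$coupling_mfi), cp$antibody_id))
}
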