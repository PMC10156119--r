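#' Construct an antibody (bead) manifest
#'
#' One row per bead in a panel: the coupled antibody, its intended target (a
#' receptor gene symbol, or a control role for the anti-tag and coupling
#' control beads) and, for screening antibodies, the antigen span used to
#' raise the antibody, as 1-based inclusive residue coordinates on the
#' untagged native target sequence.
#'
#' @param antibody_id character, unique antibody identifiers.
#' @param bead_id integer bead (color code) identifiers, unique within panel.
#' @param target_id intended receptor id, or one of
#'   `"anti-FLAG"`, `"anti-HA"`, `"anti-1D4"`, `"coupling-control"`.
#' @param subfamily_panel panel each bead belongs to; one of
#'   `r paste0('"', SUBFAMILIES, '"', collapse = ", ")`.
#' @param antigen_start,antigen_end 1-based inclusive antigen coordinates
#'   (`NA` for control beads).
#' @param source free-text provenance.
#' @return A `data.frame` with class `sba_antibodies`.
#' @export
antibody_manifest <- function(antibody_id, bead_id, target_id, subfamily_panel,
                              antigen_start = NA_integer_,
                              antigen_end = NA_integer_,
                              source = NA_character_) {
  df <- data.frame(antibody_id = as.character(antibody_id),
                   bead_id = as.integer(bead_id),
                   target_id = as.character(target_id),
                   subfamily_panel = as.character(subfamily_panel),
                   antigen_start = as.integer(antigen_start),
                   antigen_end = as.integer(antigen_end),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_antibody_manifest(df)
}

validate_antibody_manifest <- function(df) {
  if (anyDuplicated(df$bead_id))
    sba_stop(paste0("duplicated bead_id: ",
                    paste(unique(df$bead_id[duplicated(df$bead_id)]), collapse = ", ")),
             "sba_validation_error")
  if (anyDuplicated(df$antibody_id))
    sba_stop("duplicated antibody_id", "sba_validation_error")
  bad_sf <- setdiff(unique(df$subfamily_panel), SUBFAMILIES)
  if (length(bad_sf))
    sba_stop(paste0("unknown subfamily panel: ", paste(bad_sf, collapse = ", ")),
             "sba_validation_error")
  ctrl <- df$target_id %in% CONTROL_ROLES
  span <- !is.na(df$antigen_start) & !is.na(df$antigen_end)
  if (any(ctrl & span))
    sba_stop("control beads must not carry an antigen span", "sba_validation_error")
  bad_span <- span & (df$antigen_start > df$antigen_end | df$antigen_start < 1L)
  if (any(bad_span))
    sba_stop(paste0("invalid antigen span for: ",
                    paste(df$antibody_id[bad_span], collapse = ", ")),
             "sba_validation_error")
  class(df) <- c("sba_antibodies", "data.frame")
  df
}

#' Identify control beads in an antibody manifest
#' @param antibodies an `sba_antibodies` manifest.
#' @return logical vector, `TRUE` for anti-tag and coupling-control beads.
#' @export
is_control_bead <- function(antibodies) antibodies$target_id %in% CONTROL_ROLES

#' Construct a sample manifest
#'
#' One row per well: the expressed construct (`"MOCK"` for empty-vector
#' lysates), biological and technical replicate indices, and the subfamily
#' panel the well belongs to.
#'
#' @param sample_id,construct,bio_replicate,tech_replicate,panel vectors of
#'   equal length; `construct` is a receptor id or `"MOCK"`.
#' @return A `data.frame` with class `sba_samples`.
#' @export
sample_manifest <- function(sample_id, construct, bio_replicate,
                            tech_replicate, panel) {
  df <- data.frame(sample_id = as.character(sample_id),
                   construct = as.character(construct),
                   bio_replicate = as.integer(bio_replicate),
                   tech_replicate = as.integer(tech_replicate),
                   panel = as.character(panel),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    sba_stop("duplicated sample_id", "sba_validation_error")
  key <- paste(df$construct, df$bio_replicate, df$tech_replicate)
  dup <- duplicated(key) & df$construct != MOCK_TOKEN
  if (any(dup))
    sba_stop(paste0("duplicated (construct, bio, tech) triple: ",
                    paste(key[dup], collapse = "; ")), "sba_validation_error")
  bad_sf <- setdiff(unique(df$panel), SUBFAMILIES)
  if (length(bad_sf))
    sba_stop(paste0("unknown panel: ", paste(bad_sf, collapse = ", ")),
             "sba_validation_error")
  class(df) <- c("sba_samples", "data.frame")
  df
}

#' Construct a receptor library
#'
#' @param gpcr_id character receptor ids.
#' @param subfamily subfamily of each receptor.
#' @param sequence amino-acid sequences (untagged native sequence).
#' @param n_tag N-terminal epitope tag, `"FLAG"` or `"HA"`.
#' @param orphan logical, receptor without identified endogenous ligand.
#' @return A `data.frame` with class `sba_library`; the C-terminal tag is the
#'   constant `"1D4"` epitope on every construct.
#' @export
gpcr_library <- function(gpcr_id, subfamily, sequence, n_tag = "FLAG",
                         orphan = FALSE) {
  df <- data.frame(gpcr_id = as.character(gpcr_id),
                   subfamily = as.character(subfamily),
                   sequence = toupper(as.character(sequence)),
                   n_tag = as.character(n_tag),
                   c_tag = "1D4",
                   orphan = as.logical(orphan),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gpcr_id))
    sba_stop(paste0("duplicated gpcr_id: ",
                    paste(unique(df$gpcr_id[duplicated(df$gpcr_id)]), collapse = ", ")),
             "sba_validation_error")
  if (any(!nzchar(df$sequence)))
    sba_stop("empty sequence in library", "sba_validation_error")
  bad <- vapply(strsplit(df$sequence, ""),
                function(x) any(!x %in% AA_ALPHABET), logical(1))
  if (any(bad))
    sba_stop(paste0("illegal residues in sequence of: ",
                    paste(df$gpcr_id[bad], collapse = ", ")),
             "sba_validation_error")
  if (any(!df$n_tag %in% c("FLAG", "HA")))
    sba_stop("n_tag must be FLAG or HA", "sba_validation_error")
  bad_sf <- setdiff(unique(df$subfamily), SUBFAMILIES)
  if (length(bad_sf))
    sba_stop(paste0("unknown subfamily: ", paste(bad_sf, collapse = ", ")),
             "sba_validation_error")
  class(df) <- c("sba_library", "data.frame")
  df
}

#' Assay matrix pair (MFI and bead counts)
#'
#' Couples the median-fluorescence-intensity matrix with the parallel
#' per-well bead (event) count matrix. Rows are samples, columns are beads
#' (named by bead id).
#'
#' @param mfi numeric matrix, samples x beads, non-negative finite.
#' @param bead_count integer matrix of identical shape, non-negative.
#' @return An object of class `sba_assay`.
#' @export
sba_assay <- function(mfi, bead_count) {
  mfi <- as.matrix(mfi)
  bead_count <- as.matrix(bead_count)
  if (!identical(dim(mfi), dim(bead_count)))
    sba_stop("mfi and bead_count shapes differ", "sba_validation_error")
  if (!identical(dimnames(mfi), dimnames(bead_count)))
    sba_stop("mfi and bead_count dimnames differ", "sba_validation_error")
  if (any(!is.finite(mfi)))
    sba_stop("non-finite MFI values", "sba_validation_error")
  if (any(mfi < 0))
    sba_stop("negative MFI values", "sba_validation_error")
  if (any(bead_count < 0))
    sba_stop("negative bead counts", "sba_validation_error")
  if (any(bead_count %% 1 != 0))
    sba_stop("non-integer bead counts", "sba_validation_error")
  storage.mode(bead_count) <- "integer"
  structure(list(mfi = mfi, bead_count = bead_count), class = "sba_assay")
}

#' @export
print.sba_assay <- function(x, ...) {
  cat(sprintf("<sba_assay> %d samples x %d beads; MFI range [%.1f, %.1f]\n",
              nrow(x$mfi), ncol(x$mfi), min(x$mfi), max(x$mfi)))
  invisible(x)
}

#' @export
dim.sba_assay <- function(x) dim(x$mfi)

## ---- readers / writers ----------------------------------------------------

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE,
             fileEncoding = "UTF-8")
}

#' Write / read an assay matrix pair as TSV
#'
#' MFI values are written with one decimal place; bead counts as integers.
#' The first column `sample_id` holds row names; remaining columns are bead
#' ids.
#'
#' @param assay an [sba_assay()] object.
#' @param mfi_path,count_path file paths.
#' @export
write_assay <- function(assay, mfi_path, count_path) {
  fmt <- function(m, digits) {
    df <- data.frame(sample_id = rownames(m), stringsAsFactors = FALSE)
    for (j in colnames(m))
      df[[j]] <- if (is.null(digits)) m[, j] else sprintf("%.1f", m[, j])
    df
  }
  write_tsv(fmt(assay$mfi, 1L), mfi_path)
  write_tsv(fmt(assay$bead_count, NULL), count_path)
  invisible(assay)
}

#' @rdname write_assay
#' @param antibodies,samples manifests used to validate and order the matrix;
#'   unknown bead columns or missing samples are reported as a validation
#'   error naming the offenders.
#' @return `read_mfi_table()` returns an [sba_assay()] ordered per manifests.
#' @export
read_mfi_table <- function(mfi_path, count_path, antibodies, samples) {
  parse_one <- function(path) {
    df <- read_tsv(path)
    if (names(df)[1] != "sample_id")
      sba_stop(paste0("first column of ", path, " must be sample_id"),
               "sba_validation_error")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df$sample_id
    m
  }
  mfi <- parse_one(mfi_path)
  cnt <- parse_one(count_path)
  want_beads <- as.character(antibodies$bead_id)
  unknown <- setdiff(colnames(mfi), want_beads)
  if (length(unknown))
    sba_stop(paste0("bead columns absent from manifest: ",
                    paste(unknown, collapse = ", ")), "sba_validation_error")
  missing_beads <- setdiff(want_beads, colnames(mfi))
  if (length(missing_beads))
    sba_stop(paste0("manifest beads missing from table: ",
                    paste(missing_beads, collapse = ", ")), "sba_validation_error")
  missing_samp <- setdiff(samples$sample_id, rownames(mfi))
  if (length(missing_samp))
    sba_stop(paste0("manifest samples missing from table: ",
                    paste(missing_samp, collapse = ", ")), "sba_validation_error")
  unknown_samp <- setdiff(rownames(mfi), samples$sample_id)
  if (length(unknown_samp))
    sba_stop(paste0("samples absent from manifest: ",
                    paste(unknown_samp, collapse = ", ")), "sba_validation_error")
  mfi <- mfi[samples$sample_id, want_beads, drop = FALSE]
  cnt <- cnt[samples$sample_id, want_beads, drop = FALSE]
  storage.mode(cnt) <- "integer"
  sba_assay(mfi, cnt)
}

#' Read a receptor library from FASTA plus metadata TSV
#'
#' FASTA headers carry the receptor id (first whitespace-separated token);
#' the metadata TSV maps each id to subfamily, N-tag and orphan status.
#' Every FASTA entry must have exactly one metadata row and vice versa.
#'
#' @param fasta_path path to the amino-acid FASTA file.
#' @param meta_path path to a TSV with columns
#'   `gpcr_id, subfamily, n_tag, orphan`.
#' @return An `sba_library` data frame.
#' @export
read_gpcr_library <- function(fasta_path, meta_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    sba_stop(paste0("duplicated FASTA ids: ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "sba_validation_error")
  meta <- read_tsv(meta_path)
  miss_meta <- setdiff(ids, meta$gpcr_id)
  miss_fa <- setdiff(meta$gpcr_id, ids)
  if (length(miss_meta) || length(miss_fa))
    sba_stop(paste0("library/metadata mismatch; missing from metadata: [",
                    paste(miss_meta, collapse = ", "), "]; missing from FASTA: [",
                    paste(miss_fa, collapse = ", "), "]"), "sba_validation_error")
  meta <- meta[match(ids, meta$gpcr_id), ]
  gpcr_library(gpcr_id = ids, subfamily = meta$subfamily,
               sequence = as.character(seqs), n_tag = meta$n_tag,
               orphan = as.logical(meta$orphan))
}

#' Write a receptor library as FASTA plus metadata TSV
#' @param library an `sba_library`.
#' @param fasta_path,meta_path output paths.
#' @export
write_gpcr_library <- function(library, fasta_path, meta_path) {
  lines <- as.vector(rbind(paste0(">", library$gpcr_id), library$sequence))
  writeLines(lines, fasta_path)
  write_tsv(library[, c("gpcr_id", "subfamily", "n_tag", "orphan")], meta_path)
  invisible(library)
}

## ---- panel validation ----------------------------------------------------

#' Cross-validate manifests and library
#'
#' Collects (rather than stopping at) all structural violations: screening
#' antibodies whose intended target is not in the library, non-mock samples
#' whose construct is not in the library, and panels without any mock well.
#'
#' @param antibodies,samples,library the three manifests.
#' @return A `data.frame` with class `sba_validation` (columns `type`,
#'   `offender`, `message`); zero rows means the panel is consistent.
#' @export
validate_panel <- function(antibodies, samples, library) {
  v <- list()
  add <- function(type, offender, message)
    v[[length(v) + 1L]] <<- data.frame(type = type, offender = offender,
                                       message = message, stringsAsFactors = FALSE)
  ab <- antibodies[!is_control_bead(antibodies), , drop = FALSE]
  for (id in unique(setdiff(ab$target_id, library$gpcr_id)))
    add("target_missing", id, paste0("antibody target '", id, "' not in library"))
  smp <- samples[samples$construct != MOCK_TOKEN, , drop = FALSE]
  for (id in unique(setdiff(smp$construct, library$gpcr_id)))
    add("construct_missing", id, paste0("sample construct '", id, "' not in library"))
  for (p in unique(samples$panel)) {
    has_mock <- any(samples$construct[samples$panel == p] == MOCK_TOKEN)
    if (!has_mock) add("no_mock", p, paste0("panel '", p, "' has no mock sample"))
  }
  out <- if (length(v)) do.call(rbind, v)
         else data.frame(type = character(), offender = character(),
                         message = character(), stringsAsFactors = FALSE)
  class(out) <- c("sba_validation", "data.frame")
  out
}

#' @export
print.sba_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("<sba_validation> panel consistent, no violations\n")
  else {
    cat(sprintf("<sba_validation> %d violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x))) cat("  - ", x$message[i], "\n", sep = "")
  }
  invisible(x)
}
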