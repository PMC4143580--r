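#' splicescreen: PCR-based alternative-splicing screens
#'
#' Tools for two-stage PCR screens of alternative-splicing (AS) events:
#' percent-splicing-index (PSI) quantification from capillary-electrophoresis
#' peak tables, a pooled-RNA detection screen, per-subject validation with six
#' intergroup contrasts and FDR correction, association calling, Fisher exact
#' genotype tests, and qBase-style multi-reference qPCR quantification.
#'
#' @keywords internal
#' @importFrom stats dhyper lm median optim p.adjust pt rbinom rlnorm rnorm
#'   runif sd setNames smooth.spline t.test var predict coef plogis qlogis
#' @importFrom utils read.delim write.table
"_PACKAGE"

# ---- enumerations ----------------------------------------------------------

#' Study group labels
#'
#' The four disease-by-genotype groups of the cohort design: healthy donors
#' (HD) and Paget's disease of bone patients (PDB), each stratified by the
#' p62 P392L genotype (wild type or carrier).
#'
#' @return character vector of the four group labels, in canonical order.
#' @export
splice_groups <- function() c("HDwt", "HDP392L", "PDBwt", "PDBP392L")

event_classes <- function() {
  c("cassette_exon", "alt_3prime_site", "alt_5prime_site", "other")
}

event_regions <- function() c("coding", "utr5", "utr3")

#' The six intergroup contrasts of the validation screen
#'
#' Each contrast compares the PSI values of a set of groups A against a set of
#' groups B: all PDB vs all HD, all PDB vs HD wild type, and the four pairwise
#' comparisons that isolate the disease and genotype effects.
#'
#' @return named list; each element has components `A` and `B`, character
#'   vectors of group labels (disjoint by construction).
#' @export
splice_contrasts <- function() {
  list(
    allPDB_vs_allHD  = list(A = c("PDBwt", "PDBP392L"), B = c("HDwt", "HDP392L")),
    allPDB_vs_HDwt   = list(A = c("PDBwt", "PDBP392L"), B = "HDwt"),
    PDBwt_vs_HDwt    = list(A = "PDBwt",                B = "HDwt"),
    PDBwt_vs_HDP392L = list(A = "PDBwt",                B = "HDP392L"),
    PDBwt_vs_PDBP392L = list(A = "PDBwt",               B = "PDBP392L"),
    HDwt_vs_HDP392L  = list(A = "HDwt",                 B = "HDP392L")
  )
}

#' Derive the study group from disease status and genotype
#'
#' @param disease character vector, `"PDB"` or `"HD"`.
#' @param genotype character vector, `"wt"` or `"P392L"`.
#' @return character vector of group labels (see [splice_groups()]).
#' @examples
#' derive_group("PDB", "P392L")  # "PDBP392L"
#' @export
derive_group <- function(disease, genotype) {
  if (!all(disease %in% c("PDB", "HD"))) {
    stop("disease must be 'PDB' or 'HD'; got: ",
         paste(unique(setdiff(disease, c("PDB", "HD"))), collapse = ", "))
  }
  if (!all(genotype %in% c("wt", "P392L"))) {
    stop("genotype must be 'wt' or 'P392L'; got: ",
         paste(unique(setdiff(genotype, c("wt", "P392L"))), collapse = ", "))
  }
  paste0(disease, genotype)
}

# ---- event catalog ---------------------------------------------------------

#' Validate an AS-event catalog
#'
#' Checks the structural invariants of an event catalog: unique event ids,
#' known event classes and regions, positive amplicon sizes with
#' `size_long > size_short`, and an isoform size difference (`delta_nt`)
#' between 10 and 450 nt — the range amenable to end-point PCR with
#' capillary-electrophoresis readout.
#'
#' @param catalog data.frame with columns `event_id`, `gene_symbol`,
#'   `event_class`, `region`, `size_long`, `size_short`, `primer_fwd`,
#'   `primer_rev` (and optionally `delta_nt`, which is checked against
#'   `size_long - size_short` if present).
#' @return the catalog with `delta_nt` filled in, invisibly usable downstream.
#' @export
as_event_catalog <- function(catalog) {
  required <- c("event_id", "gene_symbol", "event_class", "region",
                "size_long", "size_short", "primer_fwd", "primer_rev")
  missing_cols <- setdiff(required, names(catalog))
  if (length(missing_cols) > 0) {
    stop("event catalog is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(catalog$event_id)) {
    stop("duplicate event_id in catalog: ",
         paste(unique(catalog$event_id[duplicated(catalog$event_id)]),
               collapse = ", "))
  }
  if (!all(catalog$event_class %in% event_classes())) {
    stop("unknown event_class: ",
         paste(setdiff(unique(catalog$event_class), event_classes()),
               collapse = ", "))
  }
  if (!all(catalog$region %in% event_regions())) {
    stop("unknown region: ",
         paste(setdiff(unique(catalog$region), event_regions()), collapse = ", "))
  }
  size_long <- suppressWarnings(as.numeric(catalog$size_long))
  size_short <- suppressWarnings(as.numeric(catalog$size_short))
  if (anyNA(size_long) || anyNA(size_short)) {
    bad <- which(is.na(size_long) | is.na(size_short))[1]
    stop(sprintf("malformed amplicon size in catalog row %d (event '%s')",
                 bad, catalog$event_id[bad]))
  }
  if (any(size_short <= 0) || any(size_long <= size_short)) {
    bad <- which(size_short <= 0 | size_long <= size_short)[1]
    stop(sprintf(
      "invalid sizes for event '%s': need size_long > size_short > 0 (got %s/%s)",
      catalog$event_id[bad], size_long[bad], size_short[bad]))
  }
  delta <- size_long - size_short
  if (!is.null(catalog$delta_nt) &&
      !all(is.na(catalog$delta_nt) | catalog$delta_nt == delta)) {
    bad <- which(!is.na(catalog$delta_nt) & catalog$delta_nt != delta)[1]
    stop(sprintf("delta_nt mismatch for event '%s': stated %s, sizes imply %s",
                 catalog$event_id[bad], catalog$delta_nt[bad], delta[bad]))
  }
  if (any(delta < 10 | delta > 450)) {
    bad <- which(delta < 10 | delta > 450)[1]
    stop(sprintf(
      "event '%s' has isoform size difference %d nt; must be within [10, 450]",
      catalog$event_id[bad], as.integer(delta[bad])))
  }
  catalog$size_long <- size_long
  catalog$size_short <- size_short
  catalog$delta_nt <- delta
  rownames(catalog) <- NULL
  catalog
}

#' Read an AS-event catalog from a tab-delimited file
#'
#' @param path path to a UTF-8, tab-delimited file with one header row.
#' @return validated catalog data.frame (see [as_event_catalog()]).
#' @export
read_event_catalog <- function(path) {
  if (!file.exists(path)) stop("event catalog file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(raw) == 0) {
    return(as_event_catalog(raw[, , drop = FALSE])[0, , drop = FALSE])
  }
  tryCatch(as_event_catalog(raw), error = function(e) {
    stop(sprintf("invalid event catalog '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
}

# ---- sample sheet ----------------------------------------------------------

#' Read a sample sheet and derive study groups
#'
#' @param path tab-delimited file with columns `subject_id`, `disease`
#'   (`PDB`/`HD`) and `genotype` (`wt`/`P392L`).
#' @param quiet suppress the per-group count message.
#' @return data.frame with an added `group` column; group counts are reported
#'   via [message()].
#' @export
read_sample_sheet <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("subject_id", "disease", "genotype")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("sample sheet is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  as_sample_sheet(raw, quiet = quiet)
}

#' Validate a subject table and derive groups
#'
#' @param subjects data.frame with `subject_id`, `disease`, `genotype`.
#' @param quiet suppress the per-group count message.
#' @return data.frame with derived `group` column.
#' @export
as_sample_sheet <- function(subjects, quiet = FALSE) {
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  }
  subjects$group <- derive_group(subjects$disease, subjects$genotype)
  counts <- table(factor(subjects$group, levels = splice_groups()))
  if (!quiet) {
    message("sample sheet: ",
            paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                  collapse = ", "))
  }
  rownames(subjects) <- NULL
  subjects
}

# ---- peak tables -----------------------------------------------------------

#' Read a long-format electrophoresis peak table
#'
#' One row per peak: `event_id`, `sample_id`, `size_nt`, `concentration`
#' (arbitrary linear units, uniform within a lane). Optional logical columns
#' `is_pooled` and `is_preamplified` mark detection-screen lanes.
#'
#' @param path tab-delimited file.
#' @return data.frame of peaks.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("event_id", "sample_id", "size_nt", "concentration")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("peak table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) > 0) {
    if (any(!is.finite(raw$size_nt) | raw$size_nt <= 0)) {
      stop_parse(path, which(!is.finite(raw$size_nt) | raw$size_nt <= 0)[1],
                 "peak sizes must be positive")
    }
    if (any(!is.finite(raw$concentration) | raw$concentration < 0)) {
      stop_parse(path,
                 which(!is.finite(raw$concentration) | raw$concentration < 0)[1],
                 "concentrations must be nonnegative")
    }
  }
  if (is.null(raw$is_pooled)) raw$is_pooled <- FALSE
  if (is.null(raw$is_preamplified)) raw$is_preamplified <- FALSE
  raw
}

#' Write a table in the package's tab-delimited convention
#'
#' UTF-8, tab-delimited, one header row, `"."` decimal separator, missing
#' values written as `NA`. Numeric columns are formatted with full double
#' precision so that write-then-read round-trips are lossless.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("failed to write '%s': %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

results_numeric_cols <- function() {
  c("n_A", "n_B", "mean_A", "mean_B", "sd_A", "sd_B", "t_stat", "p", "q")
}

#' Write validation-screen results as a wide per-event table
#'
#' One row per event; for each of the six contrasts a block of columns
#' (`<contrast>.n_A`, ..., `<contrast>.p`, `<contrast>.q`, `<contrast>.status`)
#' in the fixed canonical contrast order — the machine-readable analogue of a
#' published per-event p/q validation table.
#'
#' @param results long data.frame of comparison results as produced by
#'   [run_six_comparisons()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  contrasts <- names(splice_contrasts())
  events <- unique(results$event_id)
  cols <- c(results_numeric_cols(), "status")
  wide <- data.frame(event_id = events, stringsAsFactors = FALSE)
  for (ct in contrasts) {
    sub <- results[results$comparison == ct, , drop = FALSE]
    idx <- match(events, sub$event_id)
    for (cl in cols) {
      val <- sub[[cl]][idx]
      if (cl %in% results_numeric_cols()) val <- as.numeric(val)
      wide[[paste(ct, cl, sep = ".")]] <- val
    }
  }
  write_tsv(wide, path)
}

#' Read back a wide results table into long comparison results
#'
#' Inverse of [write_results_table()]; the round trip is lossless.
#'
#' @param path path written by [write_results_table()].
#' @return long data.frame with one row per event and contrast.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path)
  wide <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  contrasts <- names(splice_contrasts())
  cols <- c(results_numeric_cols(), "status")
  out <- list()
  for (ct in contrasts) {
    block <- data.frame(event_id = wide$event_id,
                        comparison = rep(ct, length(wide$event_id)),
                        stringsAsFactors = FALSE)
    for (cl in cols) {
      col_name <- paste(ct, cl, sep = ".")
      if (!col_name %in% names(wide)) {
        stop(sprintf("results table '%s' lacks column '%s'", path, col_name))
      }
      block[[cl]] <- wide[[col_name]]
    }
    block$n_A <- as.integer(block$n_A)
    block$n_B <- as.integer(block$n_B)
    out[[ct]] <- block
  }
  long <- do.call(rbind, out)
  long <- long[order(match(long$event_id, wide$event_id),
                     match(long$comparison, contrasts)), , drop = FALSE]
  rownames(long) <- NULL
  long
}
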