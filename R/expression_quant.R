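# qBase-style relative qPCR quantification: per-primer efficiencies from
# dilution-series standard curves, efficiency-corrected relative quantities
# (RQ), normalization to the geometric mean of several stable reference
# genes (NF -> CNRQ), and group-level fold-change summaries.

#' Primer efficiency from a dilution-series standard curve
#'
#' Ordinary least squares of Ct on log10 input amount; the per-cycle
#' amplification factor is `E = 10^(-1/slope)`. A perfectly efficient assay
#' (`E = 2`) has slope -3.3219 cycles per 10-fold dilution.
#'
#' @param log10_dilution numeric vector of log10 relative input amounts
#'   (e.g. `0, -1, -2` for a 10-fold series).
#' @param ct corresponding Ct values (replicates allowed: repeat the
#'   dilution value).
#' @return list with `efficiency`, `slope`, `intercept`, `r_squared`.
#' @export
efficiency_from_standard_curve <- function(log10_dilution, ct) {
  if (length(log10_dilution) != length(ct)) {
    stop("log10_dilution and ct must have equal length")
  }
  keep <- !is.na(log10_dilution) & !is.na(ct)
  log10_dilution <- log10_dilution[keep]
  ct <- ct[keep]
  if (length(unique(log10_dilution)) < 3) {
    stop("standard curve needs at least 3 distinct dilution points")
  }
  fit <- stats::lm(ct ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop(sprintf(
      "standard curve slope must be negative (more input, earlier Ct); got %.4g",
      slope))
  }
  # suppressed: lm's "essentially perfect fit" note on exact dilution series
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(efficiency = 10^(-1 / slope), slope = slope,
       intercept = unname(stats::coef(fit)[1]), r_squared = r2)
}

#' Select the best primer pair per gene
#'
#' Candidates failing the melt-curve check (`single_product = FALSE`) are
#' discarded; among the remainder the assay with the lowest mean Ct on the
#' universal reference template wins, ties broken by candidate rank.
#'
#' @param candidates data.frame with columns `gene_symbol`, `candidate_rank`,
#'   `single_product` (logical), `mean_ct_on_universal` and `efficiency`.
#' @return one row per gene (the winning assay), as a data.frame.
#' @export
select_primer_pair <- function(candidates) {
  if (nrow(candidates) == 0) stop("no candidate assays supplied")
  picks <- lapply(split(candidates, candidates$gene_symbol), function(g) {
    valid <- g[g$single_product, , drop = FALSE]
    if (nrow(valid) == 0) {
      stop(sprintf("unable to find a single-product primer pair for gene '%s'",
                   g$gene_symbol[1]))
    }
    valid <- valid[order(valid$mean_ct_on_universal, valid$candidate_rank), ,
                   drop = FALSE]
    valid[1, , drop = FALSE]
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

# mean Ct per gene x sample after dropping failed wells, with a replicate
# spread QC warning
aggregate_ct <- function(ct, qc_max_spread = 0.5) {
  if (!is.null(ct$failed)) ct <- ct[!ct$failed, , drop = FALSE]
  if (nrow(ct) == 0) stop("no usable wells in the Ct table")
  if (any(ct$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  key <- interaction(ct$gene_symbol, ct$sample_id, drop = TRUE)
  spread <- tapply(ct$ct, key, function(x) diff(range(x)))
  wide <- if (any(spread > qc_max_spread, na.rm = TRUE)) {
    names(spread)[which(spread > qc_max_spread)]
  } else character(0)
  if (length(wide) > 0) {
    message("QC: replicate Ct spread exceeds ", qc_max_spread,
            " cycles for ", length(wide), " gene/sample reaction(s)")
  }
  agg <- stats::aggregate(ct["ct"], by = list(gene_symbol = ct$gene_symbol,
                                              sample_id = ct$sample_id),
                          FUN = mean, na.rm = TRUE)
  names(agg)[names(agg) == "ct"] <- "mean_ct"
  agg
}

#' Efficiency-corrected relative quantities (RQ)
#'
#' Replicate Cts are averaged per gene and sample (failed wells dropped; a
#' replicate spread above `qc_max_spread` cycles triggers a QC warning).
#' For each gene the calibrator Ct is the arithmetic mean of the sample-mean
#' Cts over all samples with data, and `RQ = E^(Ct_calibrator - Ct)`. The
#' calibrator choice only rescales each gene by a constant, which cancels in
#' normalization and fold changes.
#'
#' @param ct long Ct table: `gene_symbol`, `sample_id`, `ct`, optional
#'   `replicate` and logical `failed` columns.
#' @param assays data.frame mapping `gene_symbol` to `efficiency` (each in
#'   `(1, 2.2]`).
#' @param qc_max_spread replicate-range warning threshold in cycles.
#' @return long data.frame `gene_symbol`, `sample_id`, `mean_ct`, `rq`; gene
#'   and sample combinations without usable wells are absent (treated as
#'   missing downstream).
#' @export
relative_quantities <- function(ct, assays, qc_max_spread = 0.5) {
  if (any(is.na(assays$efficiency)) || any(assays$efficiency <= 1) ||
      any(assays$efficiency > 2.2)) {
    stop("amplification efficiencies must lie in (1, 2.2]")
  }
  agg <- aggregate_ct(ct, qc_max_spread)
  missing_e <- setdiff(unique(agg$gene_symbol), assays$gene_symbol)
  if (length(missing_e) > 0) {
    stop("no efficiency supplied for gene(s): ",
         paste(missing_e, collapse = ", "))
  }
  eff <- stats::setNames(assays$efficiency, assays$gene_symbol)
  calib <- tapply(agg$mean_ct, agg$gene_symbol, mean)
  agg$rq <- eff[agg$gene_symbol] ^ (calib[agg$gene_symbol] - agg$mean_ct)
  agg <- agg[order(agg$gene_symbol, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Normalize relative quantities to multiple reference genes (CNRQ)
#'
#' Per sample, the normalization factor NF is the geometric mean of the
#' reference-gene RQs; `CNRQ = RQ / NF`. A sample missing any reference-gene
#' RQ gets `NA` for NF and all its CNRQs.
#'
#' @param rq long RQ table from [relative_quantities()].
#' @param reference_genes character vector of reference gene symbols
#'   (nonempty; all must appear in `rq`).
#' @return `rq` with added `nf` and `cnrq` columns.
#' @export
normalize_expression <- function(rq, reference_genes) {
  if (length(reference_genes) == 0) stop("reference gene set is empty")
  missing_refs <- setdiff(reference_genes, unique(rq$gene_symbol))
  if (length(missing_refs) > 0) {
    stop("reference gene(s) absent from RQ table: ",
         paste(missing_refs, collapse = ", "))
  }
  samples <- unique(rq$sample_id)
  nf <- vapply(samples, function(s) {
    ref_rq <- rq$rq[rq$sample_id == s & rq$gene_symbol %in% reference_genes]
    if (length(ref_rq) < length(reference_genes) || anyNA(ref_rq)) {
      return(NA_real_)
    }
    geometric_mean(ref_rq)
  }, numeric(1))
  rq$nf <- nf[match(rq$sample_id, samples)]
  rq$cnrq <- rq$rq / rq$nf
  rq
}

#' Expression contrasts for the candidate-gene study
#'
#' The three group comparisons of the expression analysis: all PDB patients
#' vs wild-type healthy donors, and the genotype effect within each cohort.
#'
#' @return named list of `A`/`B` group-label sets.
#' @export
expression_contrasts <- function() {
  list(
    allPDB_vs_HDwt    = list(A = c("PDBwt", "PDBP392L"), B = "HDwt"),
    PDBP392L_vs_PDBwt = list(A = "PDBP392L",             B = "PDBwt"),
    HDP392L_vs_HDwt   = list(A = "HDP392L",              B = "HDwt")
  )
}

#' Group-level expression summaries and log2 fold changes
#'
#' Per gene and contrast: group means with SEM, the two-sided Student t-test
#' on per-subject CNRQ values, and the fold change computed as the ratio of
#' group means, reported as its base-2 logarithm. A nonpositive group mean
#' leaves the fold change undefined (`NA`, flagged).
#'
#' @param cnrq table from [normalize_expression()].
#' @param subjects sample sheet with `subject_id` and `group`.
#' @param contrasts named list of `A`/`B` group sets
#'   (default [expression_contrasts()]).
#' @param var_equal pooled-variance Student test (default) vs Welch.
#' @return data.frame, one row per gene and contrast: `gene_symbol`,
#'   `comparison`, `n_A`, `n_B`, `mean_A`, `mean_B`, `sem_A`, `sem_B`, `p`,
#'   `log2_fc`, `fc_defined`.
#' @export
group_expression <- function(cnrq, subjects,
                             contrasts = expression_contrasts(),
                             var_equal = TRUE) {
  if (is.null(subjects$group)) subjects <- as_sample_sheet(subjects, quiet = TRUE)
  group_of <- stats::setNames(subjects$group, subjects$subject_id)
  unknown <- setdiff(unique(cnrq$sample_id), names(group_of))
  if (length(unknown) > 0) {
    stop("CNRQ samples not in sample sheet: ", paste(unknown, collapse = ", "))
  }
  genes <- unique(cnrq$gene_symbol)
  rows <- list()
  for (g in genes) {
    gd <- cnrq[cnrq$gene_symbol == g & !is.na(cnrq$cnrq), , drop = FALSE]
    grp <- group_of[gd$sample_id]
    for (ct in names(contrasts)) {
      x <- gd$cnrq[grp %in% contrasts[[ct]]$A]
      y <- gd$cnrq[grp %in% contrasts[[ct]]$B]
      n_A <- length(x); n_B <- length(y)
      if (n_A < 2 || n_B < 2) {
        stop(sprintf("contrast '%s' has fewer than 2 subjects per side for gene '%s'",
                     ct, g))
      }
      tt <- test_comparison(x, y, var_equal = var_equal)
      fc_defined <- tt$mean_A > 0 && tt$mean_B > 0
      rows[[length(rows) + 1]] <- data.frame(
        gene_symbol = g, comparison = ct,
        n_A = n_A, n_B = n_B,
        mean_A = tt$mean_A, mean_B = tt$mean_B,
        sem_A = tt$sd_A / sqrt(n_A), sem_B = tt$sd_B / sqrt(n_B),
        p = tt$p,
        log2_fc = if (fc_defined) log2(tt$mean_A / tt$mean_B) else NA_real_,
        fc_defined = fc_defined,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
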