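# Orchestration: simulate -> detect -> validate -> express, with a
# human-readable markdown run report, plus the packaged-table reanalysis.

pick_pool_members <- function(subjects, pool_size) {
  members <- lapply(splice_groups(), function(g) {
    ids <- subjects$subject_id[subjects$group == g]
    if (length(ids) < pool_size) {
      stop(sprintf("group %s has %d subjects; pool needs %d",
                   g, length(ids), pool_size))
    }
    ids[seq_len(pool_size)]
  })
  stats::setNames(members, splice_groups())
}

#' Run the full synthetic screening pipeline
#'
#' Generates a cohort, simulates the four pooled pre-amplified
#' detection-screen lanes per event and classifies events as
#' active/monoform/no-amplification, simulates per-subject validation lanes
#' for the active events and computes the PSI matrix, runs the six
#' intergroup comparisons with FDR correction and both association-calling
#' rules, and quantifies candidate-gene expression from simulated qPCR data
#' (efficiencies re-estimated from the simulated standard curves). All
#' stage outputs and a markdown report are returned; deterministic given the
#' configuration seed.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   as tab-delimited tables and the report as `report.md`.
#' @param activity_threshold,size_tolerance detection-screen parameters.
#' @param alpha significance level for association calling (inclusive).
#' @param fdr_method `"bh"` or `"storey"`.
#' @return list with `cohort`, `detection`, `psi`, `validation`, `calls`,
#'   `expression`, `report` (character vector of markdown lines).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         activity_threshold = 0.10, size_tolerance = 3,
                         alpha = 0.05, fdr_method = c("bh", "storey")) {
  fdr_method <- match.arg(fdr_method)
  cohort <- generate_cohort(config)
  subjects <- cohort$subjects
  catalog <- cohort$events

  # stage 1: pooled detection screen, one lane per event per group pool
  pools <- pick_pool_members(subjects, config$pool_size)
  pooled_lanes <- list()
  for (i in seq_len(nrow(catalog))) {
    event <- catalog[i, , drop = FALSE]
    for (g in names(pools)) {
      member_psi <- cohort$truth$psi[event$event_id, pools[[g]]]
      pooled_lanes[[length(pooled_lanes) + 1]] <-
        simulate_detection_pool(event, member_psi, config,
                                pool_id = paste0("pool_", g))
    }
  }
  pooled_peaks <- do.call(rbind, pooled_lanes)
  detection <- run_detection_screen(
    catalog, pooled_peaks, pools = paste0("pool_", names(pools)),
    size_tolerance = size_tolerance, activity_threshold = activity_threshold)
  active <- detection$event_id[detection$status == "active" &
                               !is.na(detection$status)]

  # stage 2: per-subject validation of the active events on non-amplified RNA
  validation <- NULL
  calls <- NULL
  psi <- NULL
  if (length(active) > 0) {
    psi <- simulate_psi_matrix(
      cohort$truth$psi[active, , drop = FALSE], config)
    validation <- run_six_comparisons(psi, subjects, fdr_method = fdr_method)
    calls <- list(pdb = call_pdb_associated(validation, alpha = alpha),
                  mutation = call_mutation_associated(validation, alpha = alpha))
  }

  # stage 3: candidate-gene expression with standard-curve efficiencies
  qpcr <- simulate_qpcr(cohort$truth$expression, config)
  eff_fit <- lapply(split(qpcr$dilution, qpcr$dilution$gene_symbol),
                    function(d) efficiency_from_standard_curve(d$log10_dilution, d$ct))
  assays <- data.frame(
    gene_symbol = names(eff_fit),
    efficiency = vapply(eff_fit, `[[`, numeric(1), "efficiency"),
    stringsAsFactors = FALSE)
  rq <- relative_quantities(qpcr$ct, assays)
  cnrq <- normalize_expression(rq, reference_gene_symbols())
  target_cnrq <- cnrq[!cnrq$gene_symbol %in% reference_gene_symbols(), ,
                      drop = FALSE]
  expression <- group_expression(target_cnrq, subjects)

  result <- list(cohort = cohort, detection = detection, psi = psi,
                 validation = validation, calls = calls,
                 expression = expression,
                 parameters = list(activity_threshold = activity_threshold,
                                   size_tolerance = size_tolerance,
                                   alpha = alpha, fdr_method = fdr_method,
                                   seed = config$seed))
  result$report <- render_report(result)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(detection, file.path(out_dir, "detection_status.tsv"))
    if (!is.null(validation)) {
      write_results_table(validation, file.path(out_dir, "validation_results.tsv"))
      for (nm in names(calls)) {
        flat <- calls[[nm]][, c("event_id", "call")]
        write_tsv(flat, file.path(out_dir, paste0("calls_", nm, ".tsv")))
      }
    }
    write_tsv(expression, file.path(out_dir, "expression_summary.tsv"))
    writeLines(result$report, file.path(out_dir, "report.md"))
  }
  result
}

#' Render a markdown run report
#'
#' @param result a [run_pipeline()] result list.
#' @return character vector of markdown lines (no timestamps, so identical
#'   runs render byte-identical reports).
#' @export
render_report <- function(result) {
  par <- result$parameters
  counts <- attr(result$detection, "counts")
  lines <- c(
    "# Alternative-splicing screen report", "",
    "## Parameters",
    sprintf("- seed: %d", par$seed),
    sprintf("- activity threshold: %.3g", par$activity_threshold),
    sprintf("- size tolerance: %.3g nt", par$size_tolerance),
    sprintf("- alpha: %.3g (inclusive)", par$alpha),
    sprintf("- FDR method: %s", par$fdr_method), "",
    "## Detection screen",
    sprintf("- active: %d", counts["active"]),
    sprintf("- monoform: %d", counts["monoform"]),
    sprintf("- no amplification: %d", counts["no_amplification"]),
    sprintf("- no lane data: %d", counts["no_lane"]), "")
  if (!is.null(result$calls)) {
    pdb <- result$calls$pdb
    mut <- result$calls$mutation
    lines <- c(lines, "## Association calls",
               sprintf("- PDB-associated events: %d (%s)",
                       sum(pdb$call == "pdb_associated"),
                       paste(pdb$event_id[pdb$call == "pdb_associated"],
                             collapse = ", ")),
               sprintf("- mutation-associated events: %d (%s)",
                       sum(mut$call == "mutation_associated"),
                       paste(mut$event_id[mut$call == "mutation_associated"],
                             collapse = ", ")), "")
  }
  if (!is.null(result$expression)) {
    sig <- result$expression[result$expression$p <= par$alpha &
                             !is.na(result$expression$p), , drop = FALSE]
    lines <- c(lines, "## Expression",
               sprintf("- gene-by-contrast tests: %d", nrow(result$expression)),
               sprintf("- significant at alpha: %d", nrow(sig)))
    if (nrow(sig) > 0) {
      lines <- c(lines, sprintf("  - %s %s: log2FC = %+.3f, p = %.3g",
                                sig$gene_symbol, sig$comparison, sig$log2_fc,
                                sig$p))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Reanalyze the packaged 21-event validation table
#'
#' Loads the packaged per-event p-value table and applies both
#' association-calling rules, returning the calls with their full audit
#' traces.
#'
#' @param alpha significance level (default 0.05, inclusive).
#' @return list with `pdb` and `mutation` call tables (see
#'   [call_pdb_associated()]), and `pdb_associated` /
#'   `mutation_associated`, the called event id vectors.
#' @export
fixture_reanalysis <- function(alpha = 0.05) {
  fixture <- load_table2_fixture()
  pdb <- call_pdb_associated(fixture, alpha = alpha)
  mut <- call_mutation_associated(fixture, alpha = alpha)
  list(pdb = pdb, mutation = mut,
       pdb_associated = pdb$event_id[pdb$call == "pdb_associated"],
       mutation_associated = mut$event_id[mut$call == "mutation_associated"])
}
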