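# Packaged fixtures: the published 21-event validation table (per-contrast
# p and q values over the whole cohort) and the six-event PSI summary of the
# disease-associated events. Values are transcribed verbatim, including the
# cells printed as "n/a" (encoded NA here).

#' Load the packaged 21-event validation fixture
#'
#' Per-event, per-contrast p and q values for the 21 AS events carried into
#' the whole-cohort validation, as published. Two genes (PIDD, CASC4)
#' contribute two distinct events each, disambiguated by the `.1`/`.2`
#' suffix of `event_id`; a handful of cells are missing (printed "n/a"),
#' reflecting contrasts that could not be computed for those events.
#'
#' @param format `"long"` (default) returns one row per event and contrast
#'   with columns `event_id`, `gene_symbol`, `comparison`, `p`, `q` — the form
#'   consumed by [call_pdb_associated()] and [call_mutation_associated()];
#'   `"wide"` returns one row per event with `<contrast>.p`/`<contrast>.q`
#'   column pairs.
#' @return data.frame (21 events x 6 contrasts in long form: 126 rows).
#' @export
load_table2_fixture <- function(format = c("long", "wide")) {
  format <- match.arg(format)
  path <- system.file("extdata", "table2_validation.tsv",
                      package = "splicescreen", mustWork = TRUE)
  wide <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (format == "wide") return(wide)
  contrasts <- names(splice_contrasts())
  blocks <- lapply(contrasts, function(ct) {
    data.frame(event_id = wide$event_id,
               gene_symbol = wide$gene_symbol,
               comparison = ct,
               p = wide[[paste0(ct, ".p")]],
               q = wide[[paste0(ct, ".q")]],
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, blocks)
  long <- long[order(match(long$event_id, wide$event_id),
                     match(long$comparison, contrasts)), , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' Load the packaged six-event PSI summary fixture
#'
#' Group-level PSI summaries (mean and SD over all PDB subjects and all HD
#' subjects, with the effective sample sizes 19 and 16) for the six AS events
#' associated with Paget's disease of bone, plus the event descriptions
#' (class, region, isoform size difference in nt).
#'
#' @return data.frame with one row per event.
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_psi_summary.tsv",
                      package = "splicescreen", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Effective per-contrast sample sizes of the whole-cohort validation
#'
#' The numbers of analyzable subjects on each side of the six contrasts after
#' per-event attrition (19 PDB vs 16 HD in the all-vs-all contrast, out of
#' 29 and 26 enrolled).
#'
#' @return data.frame with columns `comparison`, `n_A`, `n_B`.
#' @export
validation_contrast_ns <- function() {
  data.frame(
    comparison = names(splice_contrasts()),
    n_A = c(19L, 19L, 12L, 12L, 12L, 11L),
    n_B = c(16L, 11L, 11L, 5L, 7L, 5L),
    stringsAsFactors = FALSE
  )
}
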