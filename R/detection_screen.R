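# Stage 1: the detection screen. Lanes are pooled, pre-amplified PCR
# reactions; peaks are matched to the expected long/short amplicon sizes and
# an event is "active" when both isoforms reach the activity threshold
# (default 10% of the total lane signal) in at least one pool.

#' Match electrophoresis peaks to the two expected isoforms
#'
#' Each peak is assigned to the long isoform if its size lies within
#' `size_tolerance` nt of the expected long amplicon size, to the short
#' isoform likewise, and to the `other` bin otherwise (spurious products,
#' primer dimers). Multiple peaks falling in one window are summed, so total
#' lane signal is conserved across the three bins.
#'
#' @param lane data.frame of peaks with columns `size_nt` and `concentration`
#'   (an empty data.frame is a valid, zero-signal lane).
#' @param event one-row event catalog entry (see [as_event_catalog()]).
#' @param size_tolerance half-width of the matching window in nt; must
#'   satisfy `2 * size_tolerance < delta_nt` so the windows cannot overlap.
#' @return one-row data.frame with `event_id`, `conc_long`, `conc_short`,
#'   `conc_other`.
#' @export
match_peaks <- function(lane, event, size_tolerance = 3) {
  if (size_tolerance <= 0) stop("size_tolerance must be positive")
  delta <- event$size_long - event$size_short
  if (2 * size_tolerance >= delta) {
    stop(sprintf(
      "size_tolerance %.3g too large for event '%s': windows overlap (delta_nt = %d)",
      size_tolerance, event$event_id, as.integer(delta)))
  }
  size <- lane$size_nt %||% numeric(0)
  conc <- lane$concentration %||% numeric(0)
  if (length(size) > 0 && (any(conc < 0) || any(size <= 0))) {
    stop("lane peaks must have positive sizes and nonnegative concentrations")
  }
  in_long <- abs(size - event$size_long) <= size_tolerance
  in_short <- abs(size - event$size_short) <= size_tolerance
  data.frame(
    event_id = event$event_id,
    conc_long = sum(conc[in_long]),
    conc_short = sum(conc[in_short]),
    conc_other = sum(conc[!in_long & !in_short]),
    stringsAsFactors = FALSE
  )
}

#' Classify one event from its per-pool isoform quantities
#'
#' Implements the activity rule of the detection screen: an event is
#' `active` when both isoforms reach at least `activity_threshold` of the
#' lane signal in at least one pool (the boundary is inclusive: exactly 10%
#' counts as detectable). If only one isoform is ever seen the event is
#' `monoform`; if no expected product amplifies in any pool it is
#' `no_amplification` (peaks falling only in the `other` bin do not rescue
#' an event).
#'
#' @param quants data.frame with one row per pool: columns `pool_id`,
#'   `conc_long`, `conc_short`, `conc_other`.
#' @param activity_threshold minimum isoform fraction (default 0.10).
#' @param pools character vector of expected pool ids; defaults to the pools
#'   present, but when given, every listed pool must have a row.
#' @param denominator `"total"` (default) computes isoform fractions over the
#'   total lane signal including unmatched peaks; `"expected"` restricts the
#'   denominator to the long + short isoform signal.
#' @return list with `status` (one of `"active"`, `"monoform"`,
#'   `"no_amplification"`) and `evidence`, the per-pool fraction table.
#' @export
classify_event <- function(quants, activity_threshold = 0.10, pools = NULL,
                           denominator = c("total", "expected")) {
  denominator <- match.arg(denominator)
  if (activity_threshold <= 0 || activity_threshold >= 0.5) {
    stop("activity_threshold must be in (0, 0.5)")
  }
  if (is.null(quants$pool_id)) {
    quants$pool_id <- paste0("pool", seq_len(nrow(quants)))
  }
  if (!is.null(pools)) {
    missing_pools <- setdiff(pools, quants$pool_id)
    if (length(missing_pools) > 0) {
      stop("missing pools: ", paste(missing_pools, collapse = ", "))
    }
    quants <- quants[quants$pool_id %in% pools, , drop = FALSE]
  }
  expected <- quants$conc_long + quants$conc_short
  denom <- if (denominator == "total") expected + quants$conc_other else expected
  frac_long <- ifelse(denom > 0, quants$conc_long / denom, 0)
  frac_short <- ifelse(denom > 0, quants$conc_short / denom, 0)
  evidence <- data.frame(pool_id = quants$pool_id,
                         frac_long = frac_long,
                         frac_short = frac_short,
                         stringsAsFactors = FALSE)
  status <- if (any(frac_long >= activity_threshold &
                    frac_short >= activity_threshold)) {
    "active"
  } else if (any(expected > 0)) {
    "monoform"
  } else {
    "no_amplification"
  }
  list(status = status, evidence = evidence)
}

#' Run the detection screen over an event catalog
#'
#' Matches peaks to isoforms for every event and pooled lane, applies the
#' activity rule, and tallies the per-status counts. Lanes absent from the
#' peak table for a pool are treated as zero-signal lanes (electrophoresis
#' dropout); events with no lane in any pool are reported with `NA` status
#' and a warning rather than silently dropped.
#'
#' @param catalog event catalog (validated by [as_event_catalog()]).
#' @param peaks long-format peak table for the pooled lanes (`event_id`,
#'   `sample_id`, `size_nt`, `concentration`).
#' @param pools pool ids; default: unique `sample_id` values in `peaks`.
#' @param size_tolerance,activity_threshold,denominator see [match_peaks()]
#'   and [classify_event()].
#' @return data.frame with `event_id`, `gene_symbol`, `status`; the
#'   per-status counts are attached as attribute `"counts"` and the per-pool
#'   fraction evidence as attribute `"evidence"` (a long data.frame).
#' @export
run_detection_screen <- function(catalog, peaks, pools = NULL,
                                 size_tolerance = 3, activity_threshold = 0.10,
                                 denominator = c("total", "expected")) {
  denominator <- match.arg(denominator)
  catalog <- as_event_catalog(catalog)
  if (is.null(pools)) pools <- unique(peaks$sample_id)
  if (length(pools) == 0) stop("no pools found in peak table")
  statuses <- character(nrow(catalog))
  evidence <- vector("list", nrow(catalog))
  no_lane <- character(0)
  for (i in seq_len(nrow(catalog))) {
    event <- catalog[i, , drop = FALSE]
    ev_peaks <- peaks[peaks$event_id == event$event_id, , drop = FALSE]
    if (nrow(ev_peaks) == 0) {
      no_lane <- c(no_lane, event$event_id)
      statuses[i] <- NA_character_
      next
    }
    quants <- do.call(rbind, lapply(pools, function(p) {
      lane <- ev_peaks[ev_peaks$sample_id == p, , drop = FALSE]
      q <- match_peaks(lane, event, size_tolerance)
      q$pool_id <- p
      q
    }))
    cls <- classify_event(quants, activity_threshold, pools = pools,
                          denominator = denominator)
    statuses[i] <- cls$status
    ev <- cls$evidence
    ev$event_id <- event$event_id
    evidence[[i]] <- ev
  }
  if (length(no_lane) > 0) {
    warning("events with no lane in any pool: ",
            paste(no_lane, collapse = ", "))
  }
  out <- data.frame(event_id = catalog$event_id,
                    gene_symbol = catalog$gene_symbol,
                    status = statuses,
                    stringsAsFactors = FALSE)
  counts <- c(active = sum(statuses == "active", na.rm = TRUE),
              monoform = sum(statuses == "monoform", na.rm = TRUE),
              no_amplification = sum(statuses == "no_amplification", na.rm = TRUE),
              no_lane = length(no_lane))
  attr(out, "counts") <- counts
  attr(out, "evidence") <- do.call(rbind, evidence[!vapply(evidence, is.null, logical(1))])
  out
}
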