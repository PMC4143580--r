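# Stage 2: the validation screen. Per-subject PSI values are computed from
# non-amplified RNA, compared across the four disease-by-genotype groups in
# six fixed Student t-test contrasts, FDR-corrected per contrast, and
# summarised into disease/mutation association calls with auditable traces.

#' Percent splicing index from isoform concentrations
#'
#' PSI is the long-isoform concentration divided by the summed long + short
#' isoform concentrations. Signal in the `other` bin plays no part: the index
#' is a ratio between the two expected isoforms. When neither isoform
#' amplified the index is undefined (`NA`).
#'
#' @param conc_long,conc_short nonnegative numeric vectors.
#' @return numeric vector of PSI fractions in `[0, 1]`, `NA` where undefined.
#' @examples
#' compute_psi(0.08, 0.92)  # 0.08
#' @export
compute_psi <- function(conc_long, conc_short) {
  if (any(conc_long < 0, na.rm = TRUE) || any(conc_short < 0, na.rm = TRUE)) {
    stop("isoform concentrations must be nonnegative")
  }
  total <- conc_long + conc_short
  ifelse(total > 0, conc_long / total, NA_real_)
}

#' Assemble an events-by-subjects PSI matrix
#'
#' @param quants data.frame with columns `event_id`, `sample_id`,
#'   `conc_long`, `conc_short` (one row per event and subject).
#' @return numeric matrix (rows = events, columns = subjects) with `NA` for
#'   undefined entries; duplicated event/sample pairs are an error.
#' @export
build_psi_matrix <- function(quants) {
  if (anyDuplicated(quants[, c("event_id", "sample_id")])) {
    stop("duplicated event/sample pairs in isoform quantities")
  }
  events <- unique(quants$event_id)
  samples <- unique(quants$sample_id)
  psi <- matrix(NA_real_, nrow = length(events), ncol = length(samples),
                dimnames = list(events, samples))
  psi[cbind(match(quants$event_id, events), match(quants$sample_id, samples))] <-
    compute_psi(quants$conc_long, quants$conc_short)
  psi
}

# pooled-variance two-sample t from summary statistics (closed form); the
# route used both for raw data (after summarising) and for published
# mean/SD/n entries
pooled_t_summary <- function(n_A, mean_A, sd_A, n_B, mean_B, sd_B) {
  df <- n_A + n_B - 2
  sp2 <- ((n_A - 1) * sd_A^2 + (n_B - 1) * sd_B^2) / df
  se <- sqrt(sp2 * (1 / n_A + 1 / n_B))
  if (se == 0) {
    if (mean_A == mean_B) {
      return(list(t = 0, p = 1, df = df, degenerate = FALSE))
    }
    # zero pooled variance with distinct means: evidence is formally
    # unbounded; report the smallest representable p and flag it
    return(list(t = sign(mean_A - mean_B) * Inf, p = .Machine$double.xmin,
                df = df, degenerate = TRUE))
  }
  t <- (mean_A - mean_B) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, p = max(p, .Machine$double.xmin), df = df, degenerate = FALSE)
}

#' Two-sample Student t-test on PSI values
#'
#' Two-sided test of equal group means. The default is the pooled-variance
#' Student test; Welch's unequal-variance form is available with
#' `var_equal = FALSE`. Undefined PSI entries are dropped; if fewer than two
#' defined values remain on either side the result carries
#' `status = "insufficient_n"` and `NA` statistics.
#'
#' @param psi_A,psi_B numeric vectors of PSI fractions (may contain `NA`).
#' @param var_equal pooled-variance Student test (default) vs Welch.
#' @return one-row data.frame with `n_A`, `n_B`, `mean_A`, `mean_B`, `sd_A`,
#'   `sd_B`, `t_stat`, `p`, `status`, `degenerate`.
#' @export
test_comparison <- function(psi_A, psi_B, var_equal = TRUE) {
  psi_A <- psi_A[!is.na(psi_A)]
  psi_B <- psi_B[!is.na(psi_B)]
  n_A <- length(psi_A); n_B <- length(psi_B)
  base <- data.frame(
    n_A = n_A, n_B = n_B,
    mean_A = if (n_A > 0) mean(psi_A) else NA_real_,
    mean_B = if (n_B > 0) mean(psi_B) else NA_real_,
    sd_A = if (n_A > 1) stats::sd(psi_A) else NA_real_,
    sd_B = if (n_B > 1) stats::sd(psi_B) else NA_real_,
    t_stat = NA_real_, p = NA_real_,
    status = "insufficient_n", degenerate = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_A < 2 || n_B < 2) return(base)
  if (var_equal) {
    res <- pooled_t_summary(n_A, base$mean_A, base$sd_A,
                            n_B, base$mean_B, base$sd_B)
    base$t_stat <- res$t
    base$p <- res$p
    base$degenerate <- res$degenerate
  } else {
    if (stats::var(psi_A) == 0 && stats::var(psi_B) == 0) {
      eq <- base$mean_A == base$mean_B
      base$t_stat <- if (eq) 0 else sign(base$mean_A - base$mean_B) * Inf
      base$p <- if (eq) 1 else .Machine$double.xmin
      base$degenerate <- !eq
    } else {
      ht <- stats::t.test(psi_A, psi_B, var.equal = FALSE)
      base$t_stat <- unname(ht$statistic)
      base$p <- max(ht$p.value, .Machine$double.xmin)
    }
  }
  base$status <- "ok"
  base
}

#' Student t-test from published summary statistics
#'
#' Closed-form pooled-variance two-sample t-test computed directly from group
#' sizes, means and SDs — the entry path for re-testing printed group
#' summaries (e.g. PSI means with SD and effective n).
#'
#' @param n_A,mean_A,sd_A,n_B,mean_B,sd_B group summaries.
#' @return one-row data.frame as in [test_comparison()].
#' @export
test_comparison_summary <- function(n_A, mean_A, sd_A, n_B, mean_B, sd_B) {
  if (n_A < 2 || n_B < 2) {
    return(data.frame(n_A = n_A, n_B = n_B, mean_A = mean_A, mean_B = mean_B,
                      sd_A = sd_A, sd_B = sd_B, t_stat = NA_real_,
                      p = NA_real_, status = "insufficient_n",
                      degenerate = FALSE, stringsAsFactors = FALSE))
  }
  res <- pooled_t_summary(n_A, mean_A, sd_A, n_B, mean_B, sd_B)
  data.frame(n_A = n_A, n_B = n_B, mean_A = mean_A, mean_B = mean_B,
             sd_A = sd_A, sd_B = sd_B, t_stat = res$t, p = res$p,
             status = "ok", degenerate = res$degenerate,
             stringsAsFactors = FALSE)
}

# Storey pi0 estimate via the smoother method: pi0(lambda) is fit with a
# cubic smoothing spline over a lambda grid and evaluated at the largest
# lambda. Falls back to pi0 = 1 for very small input sets, where the
# smoother is unstable.
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 10) return(1)
  lambda <- lambda[lambda < max(p)]
  if (length(lambda) < 4) return(1)
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 0), 1)
}

#' False-discovery-rate adjustment (q-values)
#'
#' Benjamini-Hochberg (default): `q_(i) = min_{j >= i} p_(j) * m / j`, capped
#' at 1 and monotone in the p-value ranks. The Storey variant additionally
#' multiplies by a smoother-based estimate of the null proportion pi0, giving
#' (weakly) smaller q-values. `NA` entries are excluded from the adjustment
#' and preserved as `NA` in the output.
#'
#' @param p numeric vector of p-values in `(0, 1]` (may contain `NA`).
#' @param method `"bh"` or `"storey"`.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) stop("p-values must lie in (0, 1]")
  q <- rep(NA_real_, length(p))
  if (!any(ok)) return(q)
  q_bh <- stats::p.adjust(p[ok], method = "BH")
  if (method == "bh") {
    q[ok] <- q_bh
  } else {
    pi0 <- storey_pi0(p[ok])
    q[ok] <- pmin(pi0 * q_bh, 1)
  }
  q
}

#' Run the six intergroup comparisons over a PSI matrix
#'
#' For every event and each of the six fixed contrasts, performs the
#' two-sided Student t-test on the defined per-subject PSI values and
#' attaches q-values computed per contrast column across events (the layout
#' of the published validation table).
#'
#' @param psi events-by-subjects PSI matrix (see [build_psi_matrix()]).
#' @param subjects sample sheet with `subject_id` and `group` columns.
#' @param fdr_method passed to [adjust_fdr()].
#' @param var_equal pooled-variance Student test (default) vs Welch.
#' @return long data.frame, one row per event and contrast, with the columns
#'   of [test_comparison()] plus `event_id`, `comparison`, `q`.
#' @export
run_six_comparisons <- function(psi, subjects, fdr_method = c("bh", "storey"),
                                var_equal = TRUE) {
  fdr_method <- match.arg(fdr_method)
  if (nrow(psi) == 0) stop("PSI matrix is empty")
  if (is.null(subjects$group)) subjects <- as_sample_sheet(subjects, quiet = TRUE)
  unknown <- setdiff(colnames(psi), subjects$subject_id)
  if (length(unknown) > 0) {
    stop("PSI matrix columns not in sample sheet: ",
         paste(unknown, collapse = ", "))
  }
  group_of <- stats::setNames(subjects$group, subjects$subject_id)[colnames(psi)]
  contrasts <- splice_contrasts()
  blocks <- lapply(names(contrasts), function(ct) {
    X <- psi[, group_of %in% contrasts[[ct]]$A, drop = FALSE]
    Y <- psi[, group_of %in% contrasts[[ct]]$B, drop = FALSE]
    block <- group_stat_ttest(X, Y, var_equal = var_equal)
    cbind(data.frame(event_id = rownames(psi), comparison = ct,
                     stringsAsFactors = FALSE), block)
  })
  out <- do.call(rbind, blocks)
  out$q <- NA_real_
  for (ct in names(contrasts)) {
    idx <- out$comparison == ct
    out$q[idx] <- adjust_fdr(out$p[idx], method = fdr_method)
  }
  out <- out[order(match(out$event_id, rownames(psi)),
                   match(out$comparison, names(contrasts))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorized row-wise two-sample t-tests over two events-by-subjects blocks;
# algebraically identical to test_comparison() applied per row
group_stat_ttest <- function(X, Y, var_equal = TRUE) {
  row_stats <- function(M) {
    n <- rowSums(!is.na(M))
    mean <- rowSums(M, na.rm = TRUE) / n
    ss <- rowSums(M^2, na.rm = TRUE) - n * mean^2
    list(n = n, mean = ifelse(n > 0, mean, NA_real_),
         var = ifelse(n > 1, pmax(ss, 0) / (n - 1), NA_real_))
  }
  a <- row_stats(X); b <- row_stats(Y)
  ok <- a$n >= 2 & b$n >= 2
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se <- sqrt(a$var / a$n + b$var / b$n)
    df <- (a$var / a$n + b$var / b$n)^2 /
      ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  }
  diff <- a$mean - b$mean
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  p <- ifelse(is.finite(t), pmax(2 * stats::pt(-abs(t), pmax(df, 1)),
                                 .Machine$double.xmin),
              .Machine$double.xmin)
  p[which(t == 0 & se == 0)] <- 1
  degenerate <- !is.na(se) & se == 0 & !is.na(diff) & diff != 0
  t[!ok] <- NA_real_; p[!ok] <- NA_real_; degenerate[!ok] <- FALSE
  data.frame(
    n_A = a$n, n_B = b$n, mean_A = a$mean, mean_B = b$mean,
    sd_A = sqrt(a$var), sd_B = sqrt(b$var),
    t_stat = t, p = p,
    status = ifelse(ok, "ok", "insufficient_n"),
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

# generic rule engine: each term is list(contrast, direction) where
# direction "significant" requires p <= alpha and "nonsignificant" p > alpha;
# a missing p fails the term either way (it cannot be asserted)
apply_call_rule <- function(results, rule, call_label, alpha) {
  needed <- vapply(rule, `[[`, character(1), "contrast")
  missing_ct <- setdiff(needed, unique(results$comparison))
  if (length(missing_ct) > 0) {
    stop("results lack required contrast(s): ",
         paste(missing_ct, collapse = ", "))
  }
  events <- unique(results$event_id)
  calls <- character(length(events))
  traces <- vector("list", length(events))
  for (i in seq_along(events)) {
    ev <- events[i]
    trace <- do.call(rbind, lapply(rule, function(term) {
      row <- results[results$event_id == ev &
                     results$comparison == term$contrast, , drop = FALSE]
      p <- if (nrow(row) == 1) row$p else NA_real_
      passed <- if (is.na(p)) {
        FALSE
      } else if (term$direction == "significant") {
        p <= alpha
      } else {
        p > alpha
      }
      data.frame(contrast = term$contrast, direction = term$direction,
                 p = p, passed = passed, stringsAsFactors = FALSE)
    }))
    calls[i] <- if (all(trace$passed)) call_label else "none"
    traces[[i]] <- trace
  }
  out <- data.frame(event_id = events, call = calls, stringsAsFactors = FALSE)
  out$rule_trace <- traces
  out
}

#' Call disease-associated AS events
#'
#' An event is called PDB-associated when it is significant (`p <= alpha`) in
#' the three disease contrasts — all PDB vs all HD, PDBwt vs HDwt, and PDBwt
#' vs HDP392L — while the pure genotype contrast among healthy donors
#' (HDwt vs HDP392L) is not significant, i.e. the signal tracks disease, not
#' the mutation. The alpha boundary is inclusive, so a printed p of exactly
#' 0.05 passes. Every call carries a `rule_trace` (a data.frame in a list
#' column) recording each contrast, its p, and whether the check passed, so
#' calls can be audited. A missing p fails its check in either direction.
#'
#' @param results long comparison results (from [run_six_comparisons()] or
#'   [load_table2_fixture()]), needing columns `event_id`, `comparison`, `p`.
#' @param alpha significance level (default 0.05, inclusive).
#' @return data.frame with `event_id`, `call` (`"pdb_associated"`/`"none"`)
#'   and the `rule_trace` list column.
#' @export
call_pdb_associated <- function(results, alpha = 0.05) {
  rule <- list(
    list(contrast = "allPDB_vs_allHD",  direction = "significant"),
    list(contrast = "PDBwt_vs_HDwt",    direction = "significant"),
    list(contrast = "PDBwt_vs_HDP392L", direction = "significant"),
    list(contrast = "HDwt_vs_HDP392L",  direction = "nonsignificant")
  )
  apply_call_rule(results, rule, "pdb_associated", alpha)
}

#' Call mutation-associated AS events
#'
#' An event is called associated with the p62 P392L mutation when the
#' genotype contrast is significant in both disease strata: PDBwt vs
#' PDBP392L and HDwt vs HDP392L (a consistent genotype effect independent of
#' disease status).
#'
#' @inheritParams call_pdb_associated
#' @return data.frame as in [call_pdb_associated()], with call
#'   `"mutation_associated"` or `"none"`.
#' @export
call_mutation_associated <- function(results, alpha = 0.05) {
  rule <- list(
    list(contrast = "PDBwt_vs_PDBP392L", direction = "significant"),
    list(contrast = "HDwt_vs_HDP392L",   direction = "significant")
  )
  apply_call_rule(results, rule, "mutation_associated", alpha)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value conditional on the table margins: the hypergeometric
#' probabilities of all tables with the observed margins are enumerated, and
#' those no more probable than the observed table (up to a relative tolerance
#' guarding against floating-point ties) are summed.
#'
#' @param tab 2x2 matrix of nonnegative integer counts with at least one
#'   nonzero margin.
#' @return the two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be a 2x2 matrix")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(tab) == 0) stop("at least one margin must be nonzero")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- probs[match(tab[1, 1], support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher exact test of mutation-carrier frequency between cohorts
#'
#' Builds the genotype-by-disease 2x2 contingency table (P392L carriers and
#' wild-type subjects among PDB patients and healthy donors) from a sample
#' sheet and applies [fisher_exact_2x2()].
#'
#' @param subjects sample sheet (see [as_sample_sheet()]).
#' @return list with the 2x2 `table` and the two-sided `p`.
#' @export
fisher_mutation_association <- function(subjects) {
  if (is.null(subjects$group)) subjects <- as_sample_sheet(subjects, quiet = TRUE)
  tab <- matrix(
    c(sum(subjects$group == "PDBP392L"), sum(subjects$group == "HDP392L"),
      sum(subjects$group == "PDBwt"), sum(subjects$group == "HDwt")),
    nrow = 2, byrow = TRUE,
    dimnames = list(genotype = c("P392L", "wt"), disease = c("PDB", "HD")))
  list(table = tab, p = fisher_exact_2x2(tab))
}
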