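# Synthetic cohorts with the statistical structure the screen assumes:
# per-subject true PSI drawn from moment-matched logit-normal distributions
# with group-specific mean/SD, multiplicative lognormal electrophoresis
# noise, pooled pre-amplified detection lanes with logit-scale distortion,
# per-event missingness, and qPCR Ct tables with dilution-series standard
# curves. Ground truth is retained for recovery tests.

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: a
#' 55-subject cohort split 16/10/17/12 over the four disease-by-genotype
#' groups; disease effects on the PSI scale of the published events
#' (difference in means 0.06, within-group SD 0.04); electrophoresis
#' concentration noise with CV 0.15, 1 nt size-call jitter and 5% lane
#' dropout; pools of five subjects with zero-mean logit-scale
#' pre-amplification distortion (SD 0.15); a per-event/subject missingness
#' rate of 0.36, matching the published effective sample sizes (19 PDB vs 16
#' HD analyzable out of 29 vs 26 enrolled); and triplicate qPCR Cts at
#' efficiency 2 with 0.15-cycle noise plus a 3-point 10-fold dilution series.
#'
#' @param seed integer RNG seed.
#' @param group_sizes named integer vector over [splice_groups()].
#' @param n_events number of AS events to simulate (used when `psi_truth` is
#'   not supplied).
#' @param psi_truth optional data.frame `event_id`, `group`, `mu`, `sigma`
#'   giving the target mean/SD of true PSI per event and group; by default a
#'   catalog is built in which a third of events carry a disease effect of
#'   `-delta_psi` on the PDB groups and none carry a genotype effect.
#' @param delta_psi,psi_sd,pdb_effect_fraction parameters of the default
#'   truth table.
#' @param concentration_cv lognormal CV of per-peak concentration noise.
#' @param size_jitter_sd SD (nt) of peak size calls around the amplicon size.
#' @param dropout_prob probability a lane yields no peaks.
#' @param spurious_peak_prob probability of one extra low-level off-size peak.
#' @param total_concentration mean total lane signal (arbitrary units).
#' @param pool_size subjects per detection-screen pool.
#' @param preamp_distortion_sd SD of the zero-mean logit-scale
#'   pre-amplification distortion of pooled PSI.
#' @param missing_rate per event-by-subject probability that PSI is
#'   unmeasurable in the validation screen.
#' @param expression_truth optional data.frame `gene_symbol`, `group`,
#'   `mean_level` (positive); defaults to the candidate-gene panel with the
#'   reference genes flat at 1 and disease/genotype effects on the published
#'   scale.
#' @param expression_cv biological lognormal CV of per-subject expression
#'   around its group mean.
#' @param qpcr list: `efficiency` (per-cycle amplification factor, shared
#'   default for all genes), `ct_noise_sd` (cycles), `n_replicates`,
#'   `base_ct` (Ct of the calibrator input), `dilution_log10` (standard-curve
#'   design).
#' @return validated configuration object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       group_sizes = c(HDwt = 16L, HDP392L = 10L,
                                       PDBwt = 17L, PDBP392L = 12L),
                       n_events = 12L,
                       psi_truth = NULL,
                       delta_psi = 0.06,
                       psi_sd = 0.04,
                       pdb_effect_fraction = 1 / 3,
                       concentration_cv = 0.15,
                       size_jitter_sd = 1.0,
                       dropout_prob = 0.05,
                       spurious_peak_prob = 0.02,
                       total_concentration = 10,
                       pool_size = 5L,
                       preamp_distortion_sd = 0.15,
                       missing_rate = 0.36,
                       expression_truth = NULL,
                       expression_cv = 0.15,
                       qpcr = list()) {
  if (!all(splice_groups() %in% names(group_sizes))) {
    stop("group_sizes must name all four groups")
  }
  probs <- c(dropout_prob, spurious_peak_prob, missing_rate,
             pdb_effect_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (pool_size < 1) stop("pool_size must be at least 1")
  if (concentration_cv < 0 || size_jitter_sd < 0 || preamp_distortion_sd < 0 ||
      expression_cv < 0) {
    stop("noise magnitudes must be nonnegative")
  }
  if (psi_sd < 0) stop("psi_sd must be nonnegative")
  qpcr_defaults <- list(efficiency = 2.0, ct_noise_sd = 0.15,
                        n_replicates = 3L, base_ct = 22,
                        dilution_log10 = c(0, -1, -2))
  qpcr <- utils::modifyList(qpcr_defaults, qpcr)
  if (qpcr$efficiency <= 1 || qpcr$efficiency > 2.2) {
    stop("qPCR efficiency must lie in (1, 2.2]")
  }
  if (qpcr$n_replicates < 1) stop("qPCR needs at least one replicate")
  cfg <- list(seed = as.integer(seed),
              group_sizes = group_sizes[splice_groups()],
              n_events = as.integer(n_events),
              psi_truth = psi_truth,
              delta_psi = delta_psi, psi_sd = psi_sd,
              pdb_effect_fraction = pdb_effect_fraction,
              concentration_cv = concentration_cv,
              size_jitter_sd = size_jitter_sd,
              dropout_prob = dropout_prob,
              spurious_peak_prob = spurious_peak_prob,
              total_concentration = total_concentration,
              pool_size = as.integer(pool_size),
              preamp_distortion_sd = preamp_distortion_sd,
              missing_rate = missing_rate,
              expression_truth = expression_truth,
              expression_cv = expression_cv,
              qpcr = qpcr)
  class(cfg) <- "sim_config"
  cfg
}

# ---- logit-normal moment matching -----------------------------------------

# mean and sd of plogis(X), X ~ N(m, s), by numerical integration
logitnorm_moments <- function(m, s) {
  if (s == 0) return(c(mean = inv_logit(m), sd = 0))
  f1 <- function(x) inv_logit(x) * stats::dnorm(x, m, s)
  f2 <- function(x) inv_logit(x)^2 * stats::dnorm(x, m, s)
  mu <- stats::integrate(f1, -Inf, Inf, rel.tol = 1e-10)$value
  m2 <- stats::integrate(f2, -Inf, Inf, rel.tol = 1e-10)$value
  c(mean = mu, sd = sqrt(max(m2 - mu^2, 0)))
}

#' Fit logit-normal parameters to a target PSI mean and SD
#'
#' Finds the location/scale of a logit-normal distribution whose mean and SD
#' on the PSI scale match the requested moments. Infeasible requests (an SD
#' at or beyond the Bernoulli bound `sqrt(mu * (1 - mu))`, which no
#' distribution on `[0, 1]` can exceed) are rejected.
#'
#' @param mu target mean in `(0, 1)`.
#' @param sigma target SD (`>= 0`; 0 gives the degenerate point mass).
#' @return list with `m`, `s` (logit-scale location and scale) and the
#'   achieved `mean` and `sd`.
#' @export
logitnorm_fit <- function(mu, sigma) {
  if (mu <= 0 || mu >= 1) stop("mu must lie strictly inside (0, 1)")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) {
    return(list(m = logit(mu), s = 0, mean = mu, sd = 0))
  }
  if (sigma^2 >= 0.95 * mu * (1 - mu)) {
    stop(sprintf(
      "no logit-normal has mean %.3g with sd %.3g (too close to the Bernoulli bound)",
      mu, sigma))
  }
  # delta-method initial values
  start <- c(logit(mu), log(sigma / (mu * (1 - mu))))
  obj <- function(par) {
    mom <- logitnorm_moments(par[1], exp(par[2]))
    (mom["mean"] - mu)^2 + (mom["sd"] - sigma)^2
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-10) {
    stop(sprintf("logit-normal moment fit failed for mean %.3g, sd %.3g", mu, sigma))
  }
  mom <- logitnorm_moments(fit$par[1], exp(fit$par[2]))
  list(m = fit$par[1], s = exp(fit$par[2]),
       mean = unname(mom["mean"]), sd = unname(mom["sd"]))
}

# ---- default truth tables --------------------------------------------------

default_psi_truth <- function(config) {
  n <- config$n_events
  event_id <- sprintf("EV%03d", seq_len(n))
  baseline <- seq(0.15, 0.70, length.out = max(n, 2))[seq_len(n)]
  n_effect <- round(config$pdb_effect_fraction * n)
  has_effect <- seq_len(n) <= n_effect
  rows <- list()
  for (i in seq_len(n)) {
    for (g in splice_groups()) {
      mu <- baseline[i]
      if (has_effect[i] && g %in% c("PDBwt", "PDBP392L")) {
        mu <- mu - config$delta_psi
      }
      rows[[length(rows) + 1]] <- data.frame(
        event_id = event_id[i], group = g, mu = mu, sigma = config$psi_sd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# candidate-gene panel: three stable reference genes plus six targets with
# disease/genotype effects on the scale of the published group means
default_expression_truth <- function() {
  flat <- function(gene, level = 1) {
    data.frame(gene_symbol = gene, group = splice_groups(),
               mean_level = level, stringsAsFactors = FALSE)
  }
  by_group <- function(gene, hdwt, hdmut, pdbwt, pdbmut) {
    data.frame(gene_symbol = gene, group = splice_groups(),
               mean_level = c(hdwt, hdmut, pdbwt, pdbmut),
               stringsAsFactors = FALSE)
  }
  rbind(
    flat("SF3A1"), flat("PSMC4"), flat("PUM1"),
    by_group("RHOT1", 0.85, 1.02, 0.97, 1.17),
    by_group("LGALS8", 0.94, 0.94, 1.07, 1.07),
    by_group("CASC4", 1.05, 1.39, 1.01, 1.34),
    flat("USP4"), flat("TBC1D25"), flat("PIDD")
  )
}

reference_gene_symbols <- function() c("SF3A1", "PSMC4", "PUM1")

# ---- cohort generation -----------------------------------------------------

random_primer <- function(n, length = 20) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

generate_event_catalog <- function(truth_events) {
  n <- length(truth_events)
  classes <- sample(event_classes(), n, replace = TRUE,
                    prob = c(0.7, 0.15, 0.1, 0.05))
  regions <- sample(event_regions(), n, replace = TRUE, prob = c(0.8, 0.1, 0.1))
  size_short <- sample(80:380, n, replace = TRUE)
  delta <- sample(20:140, n, replace = TRUE)
  as_event_catalog(data.frame(
    event_id = truth_events,
    gene_symbol = paste0("GENE", seq_len(n)),
    event_class = classes,
    region = regions,
    size_long = size_short + delta,
    size_short = size_short,
    primer_fwd = random_primer(n),
    primer_rev = random_primer(n),
    stringsAsFactors = FALSE
  ))
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws the subject table, an event catalog, per-subject true PSI values
#' (logit-normal within each event and group, moment-matched to the
#' configured mean/SD) and per-subject true expression levels. Deterministic
#' given the configuration seed.
#'
#' @param config a [sim_config()] object.
#' @return list with `subjects` (sample sheet), `events` (catalog),
#'   `truth` (list: `psi` events-by-subjects matrix, `expression`
#'   genes-by-subjects matrix), and `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sizes <- config$group_sizes
  groups <- rep(names(sizes), times = sizes)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_along(groups)),
    disease = ifelse(startsWith(groups, "PDB"), "PDB", "HD"),
    genotype = ifelse(endsWith(groups, "P392L"), "P392L", "wt"),
    stringsAsFactors = FALSE
  )
  subjects <- as_sample_sheet(subjects, quiet = TRUE)
  truth_tab <- config$psi_truth %||% default_psi_truth(config)
  events <- unique(truth_tab$event_id)
  catalog <- generate_event_catalog(events)
  # one moment fit per distinct (mu, sigma) pair, reused across cells
  pairs <- unique(truth_tab[, c("mu", "sigma")])
  fits <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    fits[[i]] <- logitnorm_fit(pairs$mu[i], pairs$sigma[i])
  }
  fit_of <- match(paste(truth_tab$mu, truth_tab$sigma),
                  paste(pairs$mu, pairs$sigma))
  psi <- matrix(NA_real_, nrow = length(events), ncol = nrow(subjects),
                dimnames = list(events, subjects$subject_id))
  for (r in seq_len(nrow(truth_tab))) {
    fit <- fits[[fit_of[r]]]
    cols <- subjects$group == truth_tab$group[r]
    n <- sum(cols)
    draw <- if (fit$s == 0) rep(fit$mean, n) else inv_logit(stats::rnorm(n, fit$m, fit$s))
    psi[truth_tab$event_id[r], cols] <- draw
  }
  expr_tab <- config$expression_truth %||% default_expression_truth()
  if (any(expr_tab$mean_level <= 0)) {
    stop("expression truth levels must be positive")
  }
  genes <- unique(expr_tab$gene_symbol)
  expression <- matrix(NA_real_, nrow = length(genes), ncol = nrow(subjects),
                       dimnames = list(genes, subjects$subject_id))
  for (r in seq_len(nrow(expr_tab))) {
    cols <- subjects$group == expr_tab$group[r]
    expression[expr_tab$gene_symbol[r], cols] <-
      expr_tab$mean_level[r] * rlnorm_mean1(sum(cols), config$expression_cv)
  }
  list(subjects = subjects, events = catalog,
       truth = list(psi = psi, expression = expression), config = config)
}

# ---- electrophoresis lanes -------------------------------------------------

empty_lane <- function(event_id, sample_id, is_pooled, is_preamplified) {
  data.frame(event_id = character(0), sample_id = character(0),
             size_nt = numeric(0), concentration = numeric(0),
             is_pooled = logical(0), is_preamplified = logical(0),
             stringsAsFactors = FALSE)
}

#' Simulate one electrophoresis lane for an event
#'
#' Produces the two isoform peaks at the expected amplicon sizes perturbed by
#' size-call jitter, with concentrations `total * (psi, 1 - psi)` each
#' multiplied by independent mean-1 lognormal noise. Because the noise is
#' multiplicative and independent per peak, the measured log-odds of the long
#' isoform equals the true log-odds plus zero-mean Gaussian noise — the noise
#' preserves the isoform ratio in expectation on the log-odds scale. With
#' probability `dropout_prob` the lane is empty; with probability
#' `spurious_peak_prob` an extra low-level off-size peak is added.
#'
#' @param event one-row event catalog entry.
#' @param true_psi true long-isoform fraction, strictly inside (0, 1).
#' @param config a [sim_config()].
#' @param sample_id lane label.
#' @param is_pooled,is_preamplified lane provenance flags.
#' @return peak data.frame (possibly zero rows) in the long peak-table
#'   format.
#' @export
simulate_lane <- function(event, true_psi, config = sim_config(),
                          sample_id = "S1", is_pooled = FALSE,
                          is_preamplified = FALSE) {
  if (is.na(true_psi) || true_psi <= 0 || true_psi >= 1) {
    stop("true_psi must lie strictly inside (0, 1)")
  }
  if (stats::runif(1) < config$dropout_prob) {
    return(empty_lane(event$event_id, sample_id, is_pooled, is_preamplified))
  }
  total <- config$total_concentration
  conc <- total * c(true_psi, 1 - true_psi) * rlnorm_mean1(2, config$concentration_cv)
  size <- c(event$size_long, event$size_short) +
    stats::rnorm(2, 0, config$size_jitter_sd)
  out <- data.frame(event_id = event$event_id, sample_id = sample_id,
                    size_nt = size, concentration = conc,
                    is_pooled = is_pooled, is_preamplified = is_preamplified,
                    stringsAsFactors = FALSE)
  if (stats::runif(1) < config$spurious_peak_prob) {
    out <- rbind(out, data.frame(
      event_id = event$event_id, sample_id = sample_id,
      size_nt = stats::runif(1, 50, 500),
      concentration = stats::runif(1, 0, 0.05 * total),
      is_pooled = is_pooled, is_preamplified = is_preamplified,
      stringsAsFactors = FALSE))
  }
  out
}

#' Simulate a pooled, pre-amplified detection-screen lane
#'
#' The pool's true PSI is the weighted mean of the members' PSI values
#' (equal weights by default, modeling equal RNA mass per subject); a
#' zero-mean logit-scale distortion models pre-amplification bias, and the
#' distorted value drives an ordinary lane simulation flagged as pooled and
#' pre-amplified.
#'
#' @param event one-row event catalog entry.
#' @param member_psi true PSI values of the pooled subjects (at least
#'   `pool_size` members).
#' @param config a [sim_config()].
#' @param pool_id lane label.
#' @param weights optional pooling weights (e.g. expression weighting);
#'   default equal.
#' @return peak data.frame with attributes `pooled_psi` (pre-distortion) and
#'   `distorted_psi`.
#' @export
simulate_detection_pool <- function(event, member_psi, config = sim_config(),
                                    pool_id = "pool1", weights = NULL) {
  if (length(member_psi) < config$pool_size) {
    stop(sprintf("pool needs at least %d members, got %d",
                 config$pool_size, length(member_psi)))
  }
  weights <- weights %||% rep(1, length(member_psi))
  pooled <- sum(weights * member_psi) / sum(weights)
  distorted <- if (config$preamp_distortion_sd > 0) {
    inv_logit(logit(pooled) + stats::rnorm(1, 0, config$preamp_distortion_sd))
  } else {
    pooled
  }
  lane <- simulate_lane(event, distorted, config, sample_id = pool_id,
                        is_pooled = TRUE, is_preamplified = TRUE)
  attr(lane, "pooled_psi") <- pooled
  attr(lane, "distorted_psi") <- distorted
  lane
}

#' Simulate measured PSI values for a whole cohort
#'
#' Fast, vectorized equivalent of simulating one validation lane per event
#' and subject and quantifying it: measured PSI is the true PSI perturbed by
#' the lane's logit-scale concentration noise, and entries are set missing
#' (NA) with probability `missing_rate` (unmeasurable reactions: dropouts,
#' failed amplification, attrition).
#'
#' @param truth_psi events-by-subjects matrix of true PSI.
#' @param config a [sim_config()].
#' @return matrix of the same shape with measured PSI and NAs.
#' @export
simulate_psi_matrix <- function(truth_psi, config = sim_config()) {
  n <- length(truth_psi)
  noise_sd <- lane_logit_noise_sd(config$concentration_cv)
  measured <- inv_logit(logit(truth_psi) + stats::rnorm(n, 0, noise_sd))
  measured[stats::runif(n) < config$missing_rate] <- NA_real_
  measured <- matrix(measured, nrow = nrow(truth_psi),
                     dimnames = dimnames(truth_psi))
  measured
}

# ---- qPCR ------------------------------------------------------------------

#' Simulate a qPCR experiment (Ct table plus standard curves)
#'
#' Threshold cycles follow the exponential amplification model
#' `Ct = Ct0 - log_E(relative input)`: halving the input at efficiency 2
#' raises Ct by exactly one cycle. Each gene-by-sample reaction is run in
#' `n_replicates` wells with independent Gaussian Ct noise, and each gene
#' gets a 10-fold dilution series of one sample for standard-curve
#' efficiency estimation.
#'
#' @param truth_expression genes-by-subjects matrix of positive relative
#'   expression levels (e.g. from [generate_cohort()]).
#' @param config a [sim_config()].
#' @param efficiencies optional named per-gene efficiency vector; defaults to
#'   `config$qpcr$efficiency` for every gene.
#' @return list with `ct` (long table: `gene_symbol`, `sample_id`,
#'   `replicate`, `ct`), `dilution` (long table: `gene_symbol`,
#'   `log10_dilution`, `ct`) and `assays` (`gene_symbol`, `efficiency`,
#'   `is_reference`).
#' @export
simulate_qpcr <- function(truth_expression, config = sim_config(),
                          efficiencies = NULL) {
  if (any(truth_expression <= 0)) {
    stop("expression levels must be positive")
  }
  genes <- rownames(truth_expression)
  samples <- colnames(truth_expression)
  eff <- efficiencies %||%
    stats::setNames(rep(config$qpcr$efficiency, length(genes)), genes)
  if (any(eff <= 1 | eff > 2.2)) stop("efficiencies must lie in (1, 2.2]")
  base_ct <- config$qpcr$base_ct
  nrep <- config$qpcr$n_replicates
  grid <- expand.grid(gene_symbol = genes, sample_id = samples,
                      replicate = seq_len(nrep), stringsAsFactors = FALSE)
  ideal <- base_ct -
    log(truth_expression[cbind(grid$gene_symbol, grid$sample_id)]) /
    log(eff[grid$gene_symbol])
  grid$ct <- ideal + stats::rnorm(nrow(grid), 0, config$qpcr$ct_noise_sd)
  dil <- expand.grid(gene_symbol = genes,
                     log10_dilution = config$qpcr$dilution_log10,
                     stringsAsFactors = FALSE)
  dil$ct <- base_ct - dil$log10_dilution * log(10) / log(eff[dil$gene_symbol]) +
    stats::rnorm(nrow(dil), 0, config$qpcr$ct_noise_sd)
  assays <- data.frame(gene_symbol = genes,
                       efficiency = unname(eff[genes]),
                       is_reference = genes %in% reference_gene_symbols(),
                       stringsAsFactors = FALSE)
  list(ct = grid, dilution = dil, assays = assays)
}
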