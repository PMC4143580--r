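test_that("standard-curve efficiency follows E = 10^(-1/slope)", {
  fit <- efficiency_from_standard_curve(c(0, -1, -2), c(20, 23.3219, 26.6439))
  expect_equal(fit$efficiency, 2, tolerance = 1e-4)
  expect_equal(fit$slope, -3.3219, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  fit2 <- efficiency_from_standard_curve(c(0, -1, -2), 20 - 3.5 * c(0, -1, -2))
  expect_equal(fit2$efficiency, 10^(1 / 3.5), tolerance = 1e-12)

  expect_error(efficiency_from_standard_curve(c(0, -1), c(20, 23)),
               "at least 3")
  expect_error(efficiency_from_standard_curve(c(0, -1, -2), c(20, 19, 18)),
               "negative")
})

test_that("primer-pair selection takes the lowest Ct among clean assays", {
  cands <- data.frame(
    gene_symbol = "RHOT1", candidate_rank = 1:3,
    single_product = c(TRUE, TRUE, TRUE),
    mean_ct_on_universal = c(24.1, 23.2, 25.0),
    efficiency = c(1.95, 1.98, 1.9), stringsAsFactors = FALSE)
  expect_equal(select_primer_pair(cands)$candidate_rank, 2L)

  one <- cands[1, ]
  expect_equal(select_primer_pair(one)$candidate_rank, 1L)

  none <- cands; none$single_product <- FALSE
  expect_error(select_primer_pair(none), "unable to find.*RHOT1")

  tie <- cands; tie$mean_ct_on_universal <- 24
  expect_equal(select_primer_pair(tie)$candidate_rank, 1L)
})

test_that("relative quantities are efficiency powers around the mean-Ct calibrator", {
  ct <- data.frame(gene_symbol = "G1", sample_id = c("S1", "S2"),
                   ct = c(20, 22), stringsAsFactors = FALSE)
  assays <- data.frame(gene_symbol = "G1", efficiency = 2,
                       stringsAsFactors = FALSE)
  rq <- relative_quantities(ct, assays)
  expect_equal(rq$rq[rq$sample_id == "S1"], 2)
  expect_equal(rq$rq[rq$sample_id == "S2"], 0.5)

  expect_error(relative_quantities(ct, data.frame(gene_symbol = "G1",
                                                  efficiency = 1)),
               "\\(1, 2.2\\]")

  # with the arithmetic-mean calibrator, per-gene RQs have geometric mean 1
  set.seed(121)
  ct2 <- expand.grid(gene_symbol = c("G1", "G2"),
                     sample_id = paste0("S", 1:7), stringsAsFactors = FALSE)
  ct2$ct <- runif(nrow(ct2), 18, 26)
  assays2 <- data.frame(gene_symbol = c("G1", "G2"), efficiency = c(2, 1.9))
  rq2 <- relative_quantities(ct2, assays2)
  for (g in c("G1", "G2")) {
    expect_equal(exp(mean(log(rq2$rq[rq2$gene_symbol == g]))), 1)
  }

  # failed wells are dropped; replicates averaged
  ct3 <- data.frame(gene_symbol = "G1", sample_id = "S1",
                    replicate = 1:3, ct = c(20, 20.2, 35),
                    failed = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  rq3 <- relative_quantities(rbind(ct3, data.frame(gene_symbol = "G1",
                                                   sample_id = "S2",
                                                   replicate = 1, ct = 21,
                                                   failed = FALSE)),
                             assays)
  expect_equal(rq3$mean_ct[rq3$sample_id == "S1"], 20.1)
})

test_that("normalization divides by the geometric mean of reference RQs", {
  rq <- data.frame(
    gene_symbol = rep(c("R1", "R2", "R3", "T"), 2),
    sample_id = rep(c("S1", "S2"), each = 4),
    rq = c(1, 1, 1, 3, 2, 2, 2, 4), stringsAsFactors = FALSE)
  cn <- normalize_expression(rq, c("R1", "R2", "R3"))
  expect_equal(cn$nf[cn$sample_id == "S1"], rep(1, 4))
  expect_equal(cn$cnrq[cn$sample_id == "S1" & cn$gene_symbol == "T"], 3)
  expect_equal(cn$nf[cn$sample_id == "S2"], rep(2, 4))
  expect_equal(cn$cnrq[cn$sample_id == "S2" & cn$gene_symbol == "T"], 2)

  expect_error(normalize_expression(rq, character(0)), "empty")
  expect_error(normalize_expression(rq, c("R1", "R9")), "R9")
})

test_that("CNRQ is invariant to per-sample loading shifts", {
  set.seed(131)
  genes <- c("SF3A1", "PSMC4", "PUM1", "T1", "T2")
  ct <- expand.grid(gene_symbol = genes, sample_id = paste0("S", 1:6),
                    stringsAsFactors = FALSE)
  ct$ct <- runif(nrow(ct), 18, 26)
  assays <- data.frame(gene_symbol = genes,
                       efficiency = c(2, 1.9, 1.95, 2, 1.85))
  rq <- relative_quantities(ct, assays)
  base <- normalize_expression(rq, c("SF3A1", "PSMC4", "PUM1"))
  # a loading effect multiplies every gene's RQ of one sample by a constant
  scaled <- rq
  scaled$rq[scaled$sample_id == "S3"] <- scaled$rq[scaled$sample_id == "S3"] * 1.7
  scaled_cn <- normalize_expression(scaled, c("SF3A1", "PSMC4", "PUM1"))
  expect_equal(scaled_cn$cnrq, base$cnrq)
  # equivalently on the Ct scale when all assays share one efficiency
  assays_e2 <- data.frame(gene_symbol = genes, efficiency = 2)
  shifted <- ct
  shifted$ct[shifted$sample_id == "S3"] <-
    shifted$ct[shifted$sample_id == "S3"] + log(1.7) / log(2)
  base2 <- normalize_expression(relative_quantities(ct, assays_e2),
                                c("SF3A1", "PSMC4", "PUM1"))
  shifted2 <- normalize_expression(relative_quantities(shifted, assays_e2),
                                   c("SF3A1", "PSMC4", "PUM1"))
  expect_equal(shifted2$cnrq, base2$cnrq)
})

test_that("with one reference at E = 2, CNRQ ratios equal 2^-ddCt", {
  set.seed(141)
  ct <- expand.grid(gene_symbol = c("REF", "T"), sample_id = paste0("S", 1:5),
                    stringsAsFactors = FALSE)
  ct$ct <- runif(nrow(ct), 18, 26)
  assays <- data.frame(gene_symbol = c("REF", "T"), efficiency = 2)
  cn <- normalize_expression(relative_quantities(ct, assays), "REF")
  ct_of <- function(g, s) ct$ct[ct$gene_symbol == g & ct$sample_id == s]
  for (s in paste0("S", 2:5)) {
    ddct <- (ct_of("T", s) - ct_of("REF", s)) -
      (ct_of("T", "S1") - ct_of("REF", "S1"))
    ratio <- cn$cnrq[cn$gene_symbol == "T" & cn$sample_id == s] /
      cn$cnrq[cn$gene_symbol == "T" & cn$sample_id == "S1"]
    expect_equal(ratio, 2^-ddct, tolerance = 1e-12)
  }
})

test_that("noiseless Cts recover simulated expression up to a per-gene constant", {
  # stable references by construction; targets vary freely across subjects
  cfg <- noiseless_config(seed = 17)
  set.seed(17)
  samples <- paste0("S", 1:10)
  truth <- rbind(
    SF3A1 = rep(1, 10), PSMC4 = rep(1, 10), PUM1 = rep(1, 10),
    T1 = runif(10, 0.5, 2), T2 = runif(10, 0.5, 2))
  colnames(truth) <- samples
  sim <- simulate_qpcr(truth, cfg)
  rq <- relative_quantities(sim$ct, sim$assays)
  cn <- normalize_expression(rq, c("SF3A1", "PSMC4", "PUM1"))
  for (g in c("T1", "T2")) {
    got <- cn$cnrq[cn$gene_symbol == g]
    names(got) <- cn$sample_id[cn$gene_symbol == g]
    ratio <- got / truth[g, names(got)]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  }
})

test_that("group summaries report SEM, Student p and antisymmetric log2 fold changes", {
  subjects <- make_subjects(c(HDwt = 4, HDP392L = 4, PDBwt = 4, PDBP392L = 4))
  cnrq <- data.frame(gene_symbol = "RHOT1",
                     sample_id = subjects$subject_id,
                     cnrq = NA_real_, stringsAsFactors = FALSE)
  # exact group means 1.06 (all PDB) and 0.85 (HDwt)
  cnrq$cnrq[subjects$group %in% c("PDBwt", "PDBP392L")] <-
    vector_with_moments(8, 1.06, 0.05)
  cnrq$cnrq[subjects$group == "HDwt"] <- vector_with_moments(4, 0.85, 0.05)
  cnrq$cnrq[subjects$group == "HDP392L"] <- vector_with_moments(4, 0.9, 0.05)
  res <- group_expression(cnrq, subjects)
  row <- res[res$comparison == "allPDB_vs_HDwt", ]
  expect_equal(row$log2_fc, log2(1.06 / 0.85))
  expect_equal(row$log2_fc, 0.318, tolerance = 1e-2)
  expect_equal(row$sem_A, sd(vector_with_moments(8, 1.06, 0.05)) / sqrt(8))

  # identical groups: no fold change, p = 1
  cnrq2 <- cnrq
  cnrq2$cnrq <- rep(vector_with_moments(4, 1, 0.1), 4)
  res2 <- group_expression(cnrq2, subjects)
  expect_equal(res2$log2_fc, rep(0, 3))
  expect_equal(res2$p, rep(1, 3))

  # antisymmetry under A/B swap
  flipped <- list(HDwt_vs_allPDB = list(A = "HDwt", B = c("PDBwt", "PDBP392L")))
  res3 <- group_expression(cnrq, subjects, contrasts = flipped)
  expect_equal(res3$log2_fc, -row$log2_fc)
  expect_equal(res3$p, row$p)

  # nonpositive group mean leaves the fold change undefined but flagged
  cnrq4 <- cnrq
  cnrq4$cnrq[subjects$group == "HDwt"] <- c(-1, -1, 1, 1)
  res4 <- group_expression(cnrq4, subjects)
  expect_false(res4$fc_defined[res4$comparison == "allPDB_vs_HDwt"])
  expect_true(is.na(res4$log2_fc[res4$comparison == "allPDB_vs_HDwt"]))
})
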