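test_that("PSI is the long-isoform fraction, undefined on zero signal", {
  expect_equal(compute_psi(1, 1), 0.5)
  expect_equal(compute_psi(0.08, 0.92), 0.08)
  expect_true(is.na(compute_psi(0, 0)))
  expect_equal(compute_psi(c(1, 0), c(1, 0)), c(0.5, NA))
  # off-size signal plays no role in the index
  expect_error(compute_psi(-1, 2), "nonnegative")
})

test_that("the Student t-test path agrees with stats::t.test and is symmetric", {
  set.seed(61)
  for (i in 1:20) {
    x <- runif(sample(3:15, 1))
    y <- runif(sample(3:15, 1))
    mine <- test_comparison(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t_stat, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
    swapped <- test_comparison(y, x)
    expect_equal(swapped$t_stat, -mine$t_stat)
    expect_equal(swapped$p, mine$p)

    welch <- test_comparison(x, y, var_equal = FALSE)
    refw <- t.test(x, y)
    expect_equal(welch$p, refw$p.value)
  }

  ident <- test_comparison(c(0.2, 0.3, 0.4), c(0.2, 0.3, 0.4))
  expect_equal(c(ident$t_stat, ident$p), c(0, 1))

  short <- test_comparison(c(0.5, NA, NA), runif(5))
  expect_equal(short$status, "insufficient_n")
  expect_true(is.na(short$p))

  degen <- test_comparison(rep(0.2, 4), rep(0.3, 4))
  expect_true(degen$degenerate)
  expect_lt(degen$p, 1e-300)
})

test_that("summary-statistic entry reproduces the test on moment-matched data", {
  # published-style group summaries: n=19, 0.08 (0.04) vs n=16, 0.14 (0.04)
  mine <- test_comparison_summary(19, 0.08, 0.04, 16, 0.14, 0.04)
  x <- vector_with_moments(19, 0.08, 0.04)
  y <- vector_with_moments(16, 0.14, 0.04)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$t_stat, -4.4207, tolerance = 1e-4)
  expect_equal(mine$p, 1.005e-4, tolerance = 1e-3)
})

test_that("BH q-values follow the step-up formula; Storey shrinks by pi0", {
  # independent oracle: direct step-up evaluation
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(q, 1)[order(o)]
  }
  set.seed(71)
  for (i in 1:20) {
    p <- runif(sample(c(1, 5, 21, 80), 1))
    q <- adjust_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= 0))
    qs <- adjust_fdr(p, method = "storey")
    expect_true(all(qs <= q + 1e-12))
    expect_true(all(diff(qs[order(p)]) >= 0))
  }
  expect_equal(adjust_fdr(0.05), 0.05)
  expect_equal(adjust_fdr(numeric(0)), numeric(0))
  expect_equal(adjust_fdr(c(0.01, NA, 0.5)),
               c(adjust_fdr(c(0.01, 0.5))[1], NA, adjust_fdr(c(0.01, 0.5))[2]))
  expect_error(adjust_fdr(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("run_six_comparisons covers every event-contrast cell", {
  set.seed(81)
  subjects <- make_subjects(c(HDwt = 6, HDP392L = 5, PDBwt = 6, PDBP392L = 5))
  psi <- matrix(runif(21 * nrow(subjects)), nrow = 21,
                dimnames = list(sprintf("EV%02d", 1:21), subjects$subject_id))
  res <- run_six_comparisons(psi, subjects)
  expect_equal(nrow(res), 126L)
  expect_equal(sort(unique(res$comparison)), sort(names(splice_contrasts())))

  # single event: m = 1 within each contrast column, so q equals p
  res1 <- run_six_comparisons(psi[1, , drop = FALSE], subjects)
  expect_equal(res1$q, res1$p)
})

test_that("the vectorized contrast engine matches the scalar test path", {
  set.seed(91)
  subjects <- make_subjects(c(HDwt = 5, HDP392L = 4, PDBwt = 6, PDBP392L = 3))
  psi <- matrix(runif(12 * nrow(subjects)), nrow = 12,
                dimnames = list(sprintf("EV%02d", 1:12), subjects$subject_id))
  psi[sample(length(psi), 40)] <- NA
  psi[3, ] <- NA  # fully missing event
  psi[4, ] <- 0.25  # zero-variance event
  group_of <- setNames(subjects$group, subjects$subject_id)
  for (var_equal in c(TRUE, FALSE)) {
    res <- run_six_comparisons(psi, subjects, var_equal = var_equal)
    for (ct in names(splice_contrasts())) {
      sel <- splice_contrasts()[[ct]]
      for (ev in rownames(psi)) {
        scalar <- test_comparison(psi[ev, group_of %in% sel$A],
                                  psi[ev, group_of %in% sel$B],
                                  var_equal = var_equal)
        row <- res[res$event_id == ev & res$comparison == ct, ]
        expect_equal(row$p, scalar$p)
        expect_equal(row$t_stat, scalar$t_stat)
        expect_equal(row$n_A, scalar$n_A)
        expect_equal(row$sd_A, scalar$sd_A)
        expect_equal(row$status, scalar$status)
      }
    }
  }
})

test_that("association rules reproduce the packaged-table selection", {
  fixture <- load_table2_fixture()
  pdb <- call_pdb_associated(fixture)
  called <- pdb$event_id[pdb$call == "pdb_associated"]
  expect_setequal(called, c("LGALS8.1", "USP4.1", "CASC4.1", "RHOT1.1",
                            "PIDD.1", "TBC1D25.1"))
  # LGALS9 fails the PDBwt vs HDwt stratum despite the global signal
  lg9 <- pdb$rule_trace[[which(pdb$event_id == "LGALS9.1")]]
  expect_false(lg9$passed[lg9$contrast == "PDBwt_vs_HDwt"])
  expect_equal(pdb$call[pdb$event_id == "LGALS9.1"], "none")
  # CASC4 event 1 passes on the inclusive alpha boundary (p = 0.050)
  c4 <- pdb$rule_trace[[which(pdb$event_id == "CASC4.1")]]
  expect_equal(c4$p[c4$contrast == "PDBwt_vs_HDP392L"], 0.050)
  expect_true(c4$passed[c4$contrast == "PDBwt_vs_HDP392L"])

  mut <- call_mutation_associated(fixture)
  expect_equal(sum(mut$call == "mutation_associated"), 0L)
  # the two near-misses each fail exactly one stratum
  for (ev in c("TBC1D25.1", "PIDD.2")) {
    tr <- mut$rule_trace[[which(mut$event_id == ev)]]
    expect_equal(sum(tr$passed), 1L)
  }

  # all-null input yields no calls of either kind
  null_res <- fixture
  null_res$p <- 1
  expect_true(all(call_pdb_associated(null_res)$call == "none"))
  expect_true(all(call_mutation_associated(null_res)$call == "none"))

  expect_error(call_pdb_associated(fixture[fixture$comparison ==
                                             "allPDB_vs_allHD", ]),
               "PDBwt_vs_HDwt")
})

test_that("Fisher exact p matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 7, 7), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(12, 10, 17, 16), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "margin")

  set.seed(101)
  for (i in 1:60) {
    tab <- matrix(rbinom(4, 15, 0.4), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab),
                 fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("carrier frequencies show no genotype-by-disease association", {
  cohort <- generate_cohort(sim_config())
  res <- fisher_mutation_association(cohort$subjects)
  expect_equal(unname(res$table), matrix(c(12, 17, 10, 16), 2))
  expect_equal(res$p, 1)
})
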