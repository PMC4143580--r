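# shared builders for in-code fixtures

tiny_event <- function(event_id = "EV1", gene = "GENE1",
                       size_long = 442, size_short = 300,
                       event_class = "cassette_exon", region = "coding") {
  as_event_catalog(data.frame(
    event_id = event_id, gene_symbol = gene, event_class = event_class,
    region = region, size_long = size_long, size_short = size_short,
    primer_fwd = "ACGTACGTACGTACGTACGT", primer_rev = "TGCATGCATGCATGCATGCA",
    stringsAsFactors = FALSE
  ))
}

# all stochastic components switched off: lanes and Cts become deterministic
noiseless_config <- function(...) {
  sim_config(concentration_cv = 0, size_jitter_sd = 0, dropout_prob = 0,
             spurious_peak_prob = 0, preamp_distortion_sd = 0,
             missing_rate = 0, expression_cv = 0,
             qpcr = list(ct_noise_sd = 0), ...)
}

# a vector with exactly the requested mean and sd (for summary-stat oracles)
vector_with_moments <- function(n, mean, sd) {
  z <- seq_len(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

make_subjects <- function(sizes = c(HDwt = 4, HDP392L = 4, PDBwt = 4,
                                    PDBP392L = 4)) {
  groups <- rep(names(sizes), times = sizes)
  as_sample_sheet(data.frame(
    subject_id = sprintf("S%02d", seq_along(groups)),
    disease = ifelse(startsWith(groups, "PDB"), "PDB", "HD"),
    genotype = ifelse(endsWith(groups, "P392L"), "P392L", "wt"),
    stringsAsFactors = FALSE
  ), quiet = TRUE)
}
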