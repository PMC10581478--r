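# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

donor_hypnograms <- function(n = 6, seed0 = 1000) {
  lapply(seq_len(n), function(i)
    gen_hypnogram(seed = seed0 + i, subject_id = sprintf("hyp%02d", i)))
}

donor_cort_profiles <- function(n = 6, seed0 = 2000) {
  lapply(seq_len(n), function(i)
    gen_cort_profile(seed = seed0 + i, subject_id = sprintf("cort%02d", i)))
}

# small virtual cohort + 2-node model: the scaled configuration used for
# simulation-heavy tests (dt = 1e-3 as in the headline model; cost is
# controlled through the cohort size and the compressed timeline)
tiny_cohort <- function(n_members = 2, seed = 42) {
  assemble_cohort(1, donor_hypnograms(6), donor_cort_profiles(6),
                  target_n = n_members, seed = seed)
}

tiny_model <- function() network_model(n_nodes = 2)

# direct-formula Pearson correlation, independent of stats::cor
pearson_direct <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
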