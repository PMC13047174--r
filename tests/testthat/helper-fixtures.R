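# fixture builders shared across test files; everything is generated in code

# metadata for a complete subjects x timepoints design
make_meta <- function(subjects, n_timepoints, groups) {
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    data.frame(
      sample_id = sprintf("%s_T%02d", subjects[i], seq_len(n_timepoints)),
      subject_id = subjects[i],
      group = groups[i],
      timepoint = seq_len(n_timepoints),
      stringsAsFactors = FALSE
    )
  }))
}

# a small hand-sized counts table matching make_meta sample ids
make_counts <- function(meta, n_features, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nrow(meta) * n_features, 30), nrow(meta), n_features,
    dimnames = list(meta$sample_id, sprintf("F%03d", seq_len(n_features)))
  )
  feature_table(m, mode = "counts")
}

# scaled-down default-volatility cohort used by several qualitative checks
small_cohort <- function(seed, ..., n_subjects = c(toddler = 6, adult = 8)) {
  simulate_cohort(synthetic_config(
    n_subjects = n_subjects, n_features = 120,
    sequencing_depth = 2e4, n_functions = 30, seed = seed, ...
  ))
}
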