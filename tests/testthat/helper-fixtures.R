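# Shared fixtures: everything is generated in code at test time.

# Small 8-channel layout on the 8x9 grid (two columns of four rows).
tiny_layout <- function() {
  electrode_layout(data.frame(channel = paste0("ch", 1:8),
                              row = rep(0:3, 2),
                              col = rep(c(0L, 4L), each = 4L)))
}

# Reduced face-network configuration used throughout the tests; the
# architecture is unchanged, only channel widths shrink.
tiny_face_config <- function(...) {
  face_config(stem_channels = c(8L, 12L), branch_channels = 12L,
              attention_reduction = 4L, block3_channels = 16L,
              classifier_hidden = 32L, ...)
}

# A short synthetic recording set plus its stacked DE samples.
tiny_eeg_samples <- function(n_trials = 12, seed = 301) {
  set.seed(seed)
  proto <- protocol_spec(n_channels = 8L)
  rec <- generate_eeg(proto, class_spec(channels = 1:3), n_trials = n_trials)
  lay <- tiny_layout()
  samples <- unlist(lapply(rec$trials, extract_samples, layout = lay),
                    recursive = FALSE)
  stack_samples(samples)
}

random_simplex <- function(n, d = 2L) {
  m <- matrix(stats::rexp(n * d), n, d)
  m / rowSums(m)
}
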