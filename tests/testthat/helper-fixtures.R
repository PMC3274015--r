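# Expensive fixtures built once per test run and shared across files.
.fixtures <- new.env(parent = emptyenv())

# Full default study: 8 motions x 8 intervals x 6 segments x 2 channels.
default_dataset <- function() {
  if (is.null(.fixtures$dataset)) {
    .fixtures$dataset <- build_dataset(seed = 1)
  }
  .fixtures$dataset
}

# Feature table of the selected operating point: variances of the level-5
# decomposition coefficients (kind k) under the rbio3.1 wavelet.
default_features <- function() {
  if (is.null(.fixtures$features)) {
    .fixtures$features <- compute_features(default_dataset(), "k",
                                           "rbio3.1", 5)
  }
  .fixtures$features
}

# A reduced protocol that keeps the full acquisition chain but shrinks the
# session so chain-level tests stay fast.
tiny_protocol <- function(n_motions = 2L, intervals = 1L, segments = 2L,
                          segment_len = 256L, interval_s = 12) {
  recording_protocol(
    n_motions = n_motions, intervals_per_motion = intervals,
    interval_s = interval_s, segments_per_interval = segments,
    segment_len = segment_len
  )
}

tiny_dataset <- function(seed = 1L, ...) {
  build_dataset(tiny_protocol(...), gyro_spec(), seed = seed)
}

# Orthonormal Haar analysis matrix for a dyadic length, built directly from
# the definition: independent oracle for the filter-bank implementation.
haar_matrix <- function(n) {
  stopifnot(log2(n) %% 1 == 0)
  H <- matrix(1 / sqrt(n), 1, n)
  scale <- 1
  while (scale < n) {
    for (k in 0:(scale - 1)) {
      row <- numeric(n)
      block <- n / scale
      idx <- k * block + seq_len(block)
      row[idx[seq_len(block / 2)]] <- sqrt(scale / n)
      row[idx[(block / 2 + 1):block]] <- -sqrt(scale / n)
      H <- rbind(H, row)
    }
    scale <- scale * 2
  }
  unname(H)
}

fast_opts <- function(max_epochs = 40L) training_options(max_epochs = max_epochs)

with_seed_sample <- function(x, seed) withr::with_seed(as.integer(seed), sample(x))
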