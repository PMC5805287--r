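# Deterministic genome builders for hand-computed fixtures.

# A fully deterministic genome: slot n of every wavelon reads feature n
# (requires n_inputs <= n_features), all switches off, unit weights and
# dilations, zero translations/rotations/shortcuts/bias, all wavelons active.
# Tests overwrite individual fields from here.
blank_genome <- function(n_features = 2L, n_wavelons = 1L,
                         n_inputs = n_features,
                         wavelet_set = "mexican_hat") {
  g <- init_genome(n_features, n_wavelons = n_wavelons, n_inputs = n_inputs,
                   wavelet_set = wavelet_set, seed = 1)
  I <- g$n_inputs; M <- g$n_wavelons
  g$feat <- matrix(rep(seq_len(I), M), I, M)
  g$switch <- matrix(0L, I, M)
  g$w <- matrix(1, I, M)
  g$alpha <- matrix(1, I, M)
  g$beta <- matrix(0, I, M)
  g$rotation <- matrix(0, I, M)
  g$psi <- rep(1L, M)
  g$wt <- rep(1, M)
  g$ot <- rep(1L, M)
  g$a <- rep(0, n_features)
  g$theta <- 0
  g
}

# A classifier that predicts `label` for every record: no active wavelons,
# no shortcuts, bias 1 (output 1 >= 0.5) or 0 (output 0 < 0.5).
const_classifier <- function(label, n_features = 2L) {
  g <- blank_genome(n_features)
  g$ot <- rep(0L, g$n_wavelons)
  g$theta <- as.numeric(label)
  g
}

# A pool of constant classifiers casting the given votes on every record.
const_pool <- function(votes, n_features = 2L) {
  lapply(votes, const_classifier, n_features = n_features)
}

# Tiny all-purpose dataset.
tiny_dataset <- function(n = 8L, n_features = 2L, seed = 1) {
  set.seed(seed)
  wnn_dataset(matrix(rnorm(n * n_features), n, n_features),
              labels = rep_len(c(0L, 1L), n))
}
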