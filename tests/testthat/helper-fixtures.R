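# shared fixtures and independent oracles for the test suite

# a desk-test model small enough for fast forward/backward passes
tiny_model <- function(...) cnn14_config(width_scale = 32, ...)

# 25 frames/s mel front end used with the 4 kHz simulator
tiny_mel <- function() mel_config(sample_rate = 4000, window_s = 0.064,
                                  hop_s = 0.04)

# independent spectral oracle: raw-periodogram band energies via the FFT,
# no shared code with the package's mel pipeline
band_energy <- function(w, lo, hi) {
  x <- w$samples
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) / length(x) * w$sample_rate
  f <- pmin(f, w$sample_rate - f)
  sum(p[f >= lo & f < hi])
}

# murmur-band to low-band energy ratio used to score the simulator's
# stenotic/patent contrast outside the neural pipeline
band_ratio <- function(w, band = c(300, 800)) {
  band_energy(w, band[1], band[2]) / band_energy(w, 0, 200)
}

# best-split threshold accuracy of a 1-d score against binary truth
threshold_accuracy <- function(score, truth) {
  cuts <- sort(unique(score))
  cuts <- c(cuts[1] - 1, (head(cuts, -1) + cuts[-1]) / 2, cuts[length(cuts)] + 1)
  max(vapply(cuts, function(ct) mean((score > ct) == truth), numeric(1)))
}

# naive double-loop InfoNCE oracle, straight from the definition
naive_pair_loss <- function(i, j, Z, tau) {
  csim <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  den <- 0
  for (k in seq_len(nrow(Z)))
    if (k != i) den <- den + exp(csim(Z[i, ], Z[k, ]) / tau)
  -log(exp(csim(Z[i, ], Z[j, ]) / tau) / den)
}

naive_batch_loss <- function(Z, tau) {
  N <- nrow(Z) / 2
  tot <- 0
  for (k in seq_len(N))
    tot <- tot + naive_pair_loss(2 * k - 1, 2 * k, Z, tau) +
      naive_pair_loss(2 * k, 2 * k - 1, Z, tau)
  tot / (2 * N)
}

# exhaustive Mann-Whitney pair-counting AUC oracle (ties get half credit)
paircount_auc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# in-memory batch of synthetic recordings (no disk)
synth_waveforms <- function(n, state, cfg = synth_config(duration = 21),
                            seed0 = 100) {
  lapply(seq_len(n), function(i)
    generate_recording(cfg, state, seed = seed0 + i))
}

# one small on-disk corpus per session, shared across test files
.corpus_cache <- new.env(parent = emptyenv())
small_corpus <- function() {
  if (is.null(.corpus_cache$corp)) {
    cfg <- synth_config(n_patients = 10, recordings_per_patient = 12,
                        stenosis_fraction = 0.8, duration = 21, seed = 42)
    dir <- file.path(tempdir(), "bruitlearn-small-corpus")
    .corpus_cache$corp <- generate_corpus(cfg, dir)
    .corpus_cache$cfg <- cfg
  }
  .corpus_cache$corp
}
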