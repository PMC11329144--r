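#' Log-mel spectrogram configuration
#'
#' The classifier consumes frames x 64 log-mel matrices. Defaults give a frame
#' rate of 100 frames/s (hop 10 ms), so a 10-s clip yields the canonical
#' 1000 x 64 input; a 64 ms Hann window at the simulator's 4 kHz rate is 256
#' samples. The mel filterbank uses HTK-style triangular filters
#' (mel = 2595 log10(1 + f/700), unit peak). Amplitudes are power in dB with
#' an absolute floor.
#'
#' @param sample_rate Sampling rate in Hz the input must match.
#' @param n_mels Number of mel bands; fixed at 64 by the model's input contract.
#' @param window_s Analysis window in seconds (default 0.064).
#' @param hop_s Hop in seconds (default 0.010, i.e. 100 frames/s).
#' @param fmin,fmax Filterbank edges in Hz (defaults 20 and Nyquist).
#' @param log_floor Floor in dB applied after `10 log10(power)` (default -100).
#' @return An object of class `mel_config`.
#' @export
mel_config <- function(sample_rate = 4000, n_mels = 64, window_s = 0.064,
                       hop_s = 0.010, fmin = 20, fmax = sample_rate / 2,
                       log_floor = -100) {
  if (n_mels != 64)
    stop("mel_config: n_mels is fixed at 64 by the model input contract")
  stopifnot(hop_s > 0, window_s > 0, fmin >= 0, fmax > fmin)
  if (fmax > sample_rate / 2)
    stop("mel_config: fmax exceeds Nyquist")
  structure(list(sample_rate = sample_rate, n_mels = n_mels,
                 window_s = window_s, hop_s = hop_s, fmin = fmin, fmax = fmax,
                 log_floor = log_floor),
            class = "mel_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# n_mels x n_bins triangular filterbank over FFT bin center frequencies
mel_filterbank <- function(cfg, nfft) {
  n_bins <- nfft %/% 2 + 1
  bin_freqs <- (0:(n_bins - 1)) * cfg$sample_rate / nfft
  pts <- mel_to_hz(seq(hz_to_mel(cfg$fmin), hz_to_mel(cfg$fmax),
                       length.out = cfg$n_mels + 2))
  fb <- matrix(0, cfg$n_mels, n_bins)
  for (b in seq_len(cfg$n_mels)) {
    lo <- pts[b]; ctr <- pts[b + 1]; hi <- pts[b + 2]
    up <- (bin_freqs - lo) / (ctr - lo)
    down <- (hi - bin_freqs) / (hi - ctr)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-mel spectrogram of a waveform or segment
#'
#' Framing convention: frame `k` (1-based) covers samples starting at
#' `(k - 1) * hop` (0-based), the tail zero-padded, for exactly
#' `floor(n_samples / hop)` frames -- so a 10-s input at 100 frames/s gives
#' exactly 1000 frames and shifting the input by one hop shifts frames by one.
#' The window is Hann, zero-padded to the next power of two for the FFT;
#' power spectra pass through the mel filterbank and `10 log10` with the
#' configured floor. Fully deterministic.
#'
#' @param w A [waveform()] (or segment) at `cfg$sample_rate`.
#' @param cfg A [mel_config()].
#' @return An object of class `mel_spectrogram`: list with `values`
#'   (frames x 64 matrix of floored dB), `frame_rate` (frames/s) and `config`.
#' @export
melspec <- function(w, cfg = mel_config()) {
  stopifnot(inherits(w, "waveform"), inherits(cfg, "mel_config"))
  if (w$sample_rate != cfg$sample_rate)
    stop(sprintf("melspec: waveform at %g Hz but config expects %g Hz",
                 w$sample_rate, cfg$sample_rate))
  x <- w$samples
  n <- length(x)
  if (n < 1) stop("melspec: empty input")
  win <- round(cfg$window_s * cfg$sample_rate)
  hop <- round(cfg$hop_s * cfg$sample_rate)
  nframes <- n %/% hop
  if (nframes < 1) stop("melspec: input shorter than one hop")
  nfft <- 2^ceiling(log2(win))
  xp <- c(x, numeric((nframes - 1) * hop + win - n))
  idx <- outer(seq_len(win), (0:(nframes - 1)) * hop, `+`)
  frames <- matrix(xp[idx], nrow = win)
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / win)
  frames <- frames * hann
  if (nfft > win) frames <- rbind(frames, matrix(0, nfft - win, nframes))
  spec <- stats::mvfft(frames)[seq_len(nfft %/% 2 + 1), , drop = FALSE]
  power <- (Mod(spec) / sum(hann))^2
  fb <- mel_filterbank(cfg, nfft)
  melpow <- fb %*% power                       # n_mels x nframes
  db <- pmax(10 * log10(melpow), cfg$log_floor)
  db[!is.finite(db)] <- cfg$log_floor          # log10(0) -> floor
  structure(list(values = t(db), frame_rate = cfg$sample_rate / hop,
                 config = cfg),
            class = "mel_spectrogram")
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("<mel_spectrogram: %d frames x %d bands @ %g frames/s, range [%.1f, %.1f] dB>\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Cache a mel spectrogram on disk with a JSON sidecar
#'
#' Writes `values` as an RDS next to a small JSON sidecar recording the shape
#' and a hash of the generating config, so stale caches are detectable.
#'
#' @param m A `mel_spectrogram`.
#' @param path Output path (`.rds`); sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_melspec <- function(m, path) {
  stopifnot(inherits(m, "mel_spectrogram"))
  saveRDS(m, path)
  sidecar <- list(frames = nrow(m$values), n_mels = ncol(m$values),
                  frame_rate = m$frame_rate, config_hash = config_hash(m$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
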