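#' Extract a segment of a waveform
#'
#' Segments use 0-based, half-open sample indexing `[start, start + length)`.
#' The returned object materializes its samples and also behaves as a
#' `waveform`, so it can be fed directly to [melspec()].
#'
#' @param w A `waveform`.
#' @param start_sample 0-based first sample.
#' @param length_samples Number of samples.
#' @return An object of class `c("segment", "waveform")` carrying
#'   `start_sample` and `parent_length` alongside the samples.
#' @export
segment <- function(w, start_sample, length_samples) {
  stopifnot(inherits(w, "waveform"))
  n <- length(w$samples)
  start_sample <- as.integer(start_sample)
  length_samples <- as.integer(length_samples)
  if (start_sample < 0 || length_samples < 1 || start_sample + length_samples > n)
    stop("segment: [", start_sample, ", ", start_sample + length_samples,
         ") outside parent of length ", n)
  structure(list(samples = w$samples[(start_sample + 1):(start_sample + length_samples)],
                 sample_rate = w$sample_rate,
                 start_sample = start_sample,
                 parent_length = n),
            class = c("segment", "waveform"))
}

#' Middle segment of a recording
#'
#' Recordings are captured by hand, so their edges carry handling noise; the
#' analysis keeps only a centered window (by default 20 s of a 1-minute
#' recording). The start is `floor((n - L) / 2)` samples, tolerating a 1-sample
#' asymmetry for odd lengths.
#'
#' @param w A `waveform`.
#' @param length_s Segment length in seconds (default 20).
#' @return A `segment` of exactly `floor(length_s * sample_rate)` samples.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * 100 * seq(0, 60, by = 1 / 4000))[1:240000], 4000)
#' s <- middle_segment(w)           # samples [80000, 160000)
#' s$start_sample
middle_segment <- function(w, length_s = 20) {
  stopifnot(inherits(w, "waveform"), length_s > 0)
  L <- floor(length_s * w$sample_rate)
  n <- length(w$samples)
  if (n < L)
    stop(sprintf("middle_segment: recording is %.3f s, shorter than %g s",
                 n / w$sample_rate, length_s))
  segment(w, floor((n - L) / 2), L)
}

#' Random fixed-length crops of a segment
#'
#' Crop start positions are drawn independently and uniformly over the valid
#' range (endpoints included), seeded for reproducibility. This is the audio-
#' domain augmentation used for contrastive pre-training: two crops of the same
#' recording form a positive pair.
#'
#' @param seg A `segment` (or `waveform`).
#' @param crop_s Crop length in seconds.
#' @param k Number of crops (default 2).
#' @param seed Integer seed; same seed gives the same crops.
#' @return List of `k` segments of exactly `floor(crop_s * sample_rate)` samples.
#' @export
random_crops <- function(seg, crop_s, k = 2, seed = 1L) {
  stopifnot(inherits(seg, "waveform"), k >= 1)
  L <- floor(crop_s * seg$sample_rate)
  n <- length(seg$samples)
  if (L > n)
    stop("random_crops: crop longer than segment")
  max_start <- n - L
  starts <- with_seed(seed, floor(runif(k) * (max_start + 1)))
  starts <- pmin(as.integer(starts), max_start)   # guard runif(k) == 1 edge
  w <- waveform(seg$samples, seg$sample_rate)
  lapply(starts, function(s) segment(w, s, L))
}
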