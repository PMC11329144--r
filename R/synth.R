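#' Configuration for the synthetic bruit simulator
#'
#' The simulator emulates the statistical shape of a weekly-monitored
#' hemodialysis AVG cohort: each patient contributes one 1-minute recording per
#' week; a fraction of patients develop a stenosis episode, sound stenotic for
#' 1-3 weeks, receive a PTA intervention, and revert to patent. Acoustically a
#' recording is a cardiac-cycle periodic low-frequency base pulse (< 200 Hz)
#' plus band-limited murmur noise whose gain is high when stenotic and a stated
#' fraction of it when patent, plus white sensor noise.
#'
#' @param n_patients Number of patients (default 45).
#' @param recordings_per_patient Weekly recordings per patient (default 15).
#' @param sample_rate Sampling rate in Hz (default 4000; bruit energy sits well
#'   below 1 kHz).
#' @param duration Recording length in seconds (default 60); must exceed 20 s
#'   so the middle-20-s rule applies.
#' @param stenosis_fraction Probability that a patient's timeline contains a
#'   stenosis episode (default 0.6).
#' @param murmur_band Numeric length-2, murmur noise band in Hz (default
#'   c(300, 800)); `sample_rate` must exceed twice its upper edge.
#' @param murmur_gain Linear amplitude of the murmur when stenotic (default 0.15).
#' @param patent_murmur_frac Fraction of `murmur_gain` retained when patent
#'   (default 0.25): a healthy access still has a soft bruit.
#' @param heart_rate Cardiac frequency in Hz (default 1.2, i.e. 72 bpm).
#' @param noise_sd Standard deviation of additive white noise (default 0.05).
#' @param patient_gain_sd,recording_gain_sd Log-normal jitter (sd on the log
#'   scale) of the murmur gain across patients and across recordings, modelling
#'   anatomical and probe-placement variability (defaults 0.15 and 0.2).
#' @param start_date First recording date (default "2021-01-04").
#' @param seed Integer seed; the whole corpus is a pure function of the config
#'   including this seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 45, recordings_per_patient = 15,
                         sample_rate = 4000, duration = 60,
                         stenosis_fraction = 0.6,
                         murmur_band = c(300, 800), murmur_gain = 0.15,
                         patent_murmur_frac = 0.25,
                         heart_rate = 1.2, noise_sd = 0.05,
                         patient_gain_sd = 0.15, recording_gain_sd = 0.2,
                         start_date = "2021-01-04", seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              recordings_per_patient = as.integer(recordings_per_patient),
              sample_rate = sample_rate, duration = duration,
              stenosis_fraction = stenosis_fraction,
              murmur_band = as.numeric(murmur_band),
              murmur_gain = murmur_gain,
              patent_murmur_frac = patent_murmur_frac,
              heart_rate = heart_rate, noise_sd = noise_sd,
              patient_gain_sd = patient_gain_sd,
              recording_gain_sd = recording_gain_sd,
              start_date = as.Date(start_date), seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$recordings_per_patient >= 1)
  if (cfg$duration <= 20)
    stop("synth_config: duration must exceed 20 s (middle-20-s extraction)")
  if (cfg$sample_rate <= 2 * cfg$murmur_band[2])
    stop("synth_config: sample_rate must exceed twice the murmur band's upper edge")
  if (length(cfg$murmur_band) != 2 || cfg$murmur_band[1] <= 0 ||
      cfg$murmur_band[2] <= cfg$murmur_band[1])
    stop("synth_config: murmur_band must be (low, high) with 0 < low < high")
  if (cfg$murmur_gain < 0 || cfg$noise_sd < 0 || cfg$patent_murmur_frac < 0)
    stop("synth_config: gains must be >= 0")
  if (cfg$stenosis_fraction < 0 || cfg$stenosis_fraction > 1)
    stop("synth_config: stenosis_fraction must be in [0, 1]")
  invisible(cfg)
}

# periodic systolic envelope in [0, 1]: Gaussian bump once per cardiac cycle
cardiac_envelope <- function(t, heart_rate, width = 0.05) {
  cycle <- 1 / heart_rate
  phase <- t %% cycle
  exp(-((phase - 0.3 * cycle)^2) / (2 * width^2))
}

# zero-phase FFT brick-wall band-pass, unit-sd output
bandlimited_noise <- function(n, sample_rate, band) {
  x <- rnorm(n)
  X <- fft(x)
  freqs <- (seq_len(n) - 1) / n * sample_rate
  freqs <- pmin(freqs, sample_rate - freqs)   # fold to [0, Nyquist]
  keep <- freqs >= band[1] & freqs <= band[2]
  X[!keep] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate one synthetic bruit recording
#'
#' Construction: base pulse = Gaussian-enveloped 90 Hz tone repeating at the
#' cardiac rate (all energy well below 200 Hz), plus murmur = band-limited
#' Gaussian noise in `murmur_band`, amplitude-modulated by the cardiac
#' envelope, with gain `murmur_gain` when `truth_state = "stenotic"` and
#' `patent_murmur_frac * murmur_gain` when `"patent"`, plus white noise of sd
#' `noise_sd`. The peak amplitude is normalized to at most 0.9 full scale
#' (signals already below that are left untouched).
#'
#' @param config A [synth_config()].
#' @param truth_state `"stenotic"` or `"patent"`.
#' @param seed Integer seed; same (config, state, seed) gives a bit-identical
#'   waveform.
#' @param gain_multiplier Extra multiplicative murmur gain (used by
#'   [generate_corpus()] for per-patient variability; default 1).
#' @return A [waveform()] of `config$duration` seconds at `config$sample_rate`.
#' @export
generate_recording <- function(config, truth_state, seed, gain_multiplier = 1) {
  validate_synth_config(config)
  truth_state <- match.arg(truth_state, c("stenotic", "patent"))
  n <- floor(config$duration * config$sample_rate)
  t <- (seq_len(n) - 1) / config$sample_rate
  env <- cardiac_envelope(t, config$heart_rate)
  base <- 0.6 * env * sin(2 * pi * 90 * t)
  gain <- config$murmur_gain *
    if (truth_state == "stenotic") 1 else config$patent_murmur_frac
  x <- with_seed(seed, {
    jitter <- exp(rnorm(1, 0, config$recording_gain_sd))
    murmur <- if (gain > 0)
      gain * gain_multiplier * jitter *
        (0.3 + 0.7 * env) * bandlimited_noise(n, config$sample_rate, config$murmur_band)
    else 0
    white <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else 0
    base + murmur + white
  })
  peak <- max(abs(x))
  if (peak > 0.9) x <- x * (0.9 / peak)
  waveform(x, config$sample_rate)
}

#' Generate a synthetic AVG monitoring corpus
#'
#' Builds per-patient weekly timelines. A patient drawn into a stenosis episode
#' sounds stenotic for 1-3 consecutive weeks, receives a PTA event dated 2 days
#' after the last stenotic recording, and reverts to patent; onset weeks are
#' placed so that at least three weekly recordings follow the intervention.
#' WAV files (PCM16 mono), a manifest CSV (`patient_id,timestamp,site,path`),
#' a PTA event CSV (`patient_id,event_date`) and a ground-truth CSV (simulator
#' truth, never used for training labels) are written under `out_dir`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_wavs If `FALSE`, skip waveform synthesis and WAV writing and
#'   produce only the timeline tables (fast path for labeling tests).
#' @return List with `records` (data frame incl. `truth_state`), `events`
#'   (data frame), and the paths `manifest`, `events_csv`, `truth_csv`.
#' @export
generate_corpus <- function(config, out_dir, write_wavs = TRUE) {
  validate_synth_config(config)
  if (config$n_patients < 1) stop("generate_corpus: zero patients")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rpp <- config$recordings_per_patient
  recs <- vector("list", config$n_patients)
  evts <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", i)
    dates <- config$start_date + 7 * (0:(rpp - 1))
    truth <- rep("patent", rpp)
    event_date <- as.Date(character(0))
    tl_seed <- derive_seed(config$seed, "timeline", i)
    tl <- with_seed(tl_seed, {
      has_episode <- runif(1) < config$stenosis_fraction && rpp >= 8
      pgain <- exp(rnorm(1, 0, config$patient_gain_sd))
      pick <- function(x) x[sample.int(length(x), 1)]   # safe for length-1 x
      if (has_episode) {
        dur <- pick(seq_len(min(3, rpp - 6)))
        onset <- pick(seq(3, rpp - 3 - dur))
        list(pgain = pgain, onset = onset, last = onset + dur - 1)
      } else list(pgain = pgain, onset = NA, last = NA)
    })
    if (!is.na(tl$onset)) {
      truth[tl$onset:tl$last] <- "stenotic"
      event_date <- dates[tl$last] + 2
    }
    paths <- file.path(out_dir, sprintf("%s_w%02d.wav", pid, seq_len(rpp)))
    if (write_wavs) {
      for (k in seq_len(rpp)) {
        w <- generate_recording(config, truth[k],
                                seed = derive_seed(config$seed, "recording",
                                                   i * 1000L + k),
                                gain_multiplier = tl$pgain)
        write_wav(w, paths[k])
      }
    }
    recs[[i]] <- data.frame(patient_id = pid, timestamp = dates,
                            site = "arterial", path = paths,
                            truth_state = truth, stringsAsFactors = FALSE)
    if (length(event_date))
      evts[[i]] <- data.frame(patient_id = pid, event_date = event_date,
                              stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  events <- do.call(rbind, evts[!vapply(evts, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(patient_id = character(0),
                         event_date = as.Date(character(0)))
  manifest <- file.path(out_dir, "manifest.csv")
  events_csv <- file.path(out_dir, "events.csv")
  truth_csv <- file.path(out_dir, "truth.csv")
  write.csv(records[, c("patient_id", "timestamp", "site", "path")],
            manifest, row.names = FALSE)
  write.csv(events, events_csv, row.names = FALSE)
  write.csv(records[, c("patient_id", "timestamp", "truth_state")],
            truth_csv, row.names = FALSE)
  list(records = records, events = events, manifest = manifest,
       events_csv = events_csv, truth_csv = truth_csv)
}
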