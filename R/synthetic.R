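#' Acquisition protocol for synthetic recordings
#'
#' The defaults mirror the multimodal acquisition protocol the pipeline
#' targets: 22 subjects, 40 trials each, 63-s trials (3 s preparation +
#' 60 s task) of 32-channel EEG sampled at 128 Hz, with one facial frame
#' every 0.5 s of task.
#'
#' @param n_subjects,n_trials cohort shape.
#' @param prep_seconds,task_seconds trial spans in seconds.
#' @param frame_interval_seconds facial frame sampling interval.
#' @param fs EEG sampling rate in Hz.
#' @param n_channels EEG channel count.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(n_subjects = 22L, n_trials = 40L,
                          prep_seconds = 3, task_seconds = 60,
                          frame_interval_seconds = 0.5, fs = 128,
                          n_channels = 32L) {
  stopifnot(n_subjects >= 1, n_trials >= 1, prep_seconds > 0,
            task_seconds > 0, fs > 0, n_channels >= 1)
  if (abs(task_seconds / frame_interval_seconds -
          round(task_seconds / frame_interval_seconds)) > 1e-9)
    stop("task span must be divisible by the frame interval")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 prep_seconds = prep_seconds, task_seconds = task_seconds,
                 frame_interval_seconds = frame_interval_seconds,
                 fs = fs, n_channels = as.integer(n_channels)),
            class = "protocol_spec")
}

#' Class-effect specification for the generators
#'
#' Defines how the binary class is encoded in the synthetic signals: in
#' EEG, the power of band-limited oscillations on a designated channel
#' subset is multiplied per class; in face images, class 0 shows one
#' compact bright blob (a local-scale cue) while class 1 shows two widely
#' separated blobs (a long-range cue).
#'
#' @param band name of the affected EEG band (see [eeg_bands()]).
#' @param channels integer indices of the affected channels.
#' @param multipliers length-2 positive vector: oscillation amplitude
#'   multiplier for class 0 and class 1, in units of the oscillation's
#'   unit standard deviation.
#' @param noise_sd white-noise standard deviation of the face images.
#' @param eeg_background_sd standard deviation of the pink-noise EEG
#'   background.  The default (2) keeps the background's spectral floor in
#'   every band well above the stop-band leakage of the band-pass filters,
#'   so the class effect stays confined to the designated band.
#' @return A list of class `class_spec`.
#' @export
class_spec <- function(band = "beta", channels = 1:4,
                       multipliers = c(1, 2.5), noise_sd = 0.1,
                       eeg_background_sd = 2) {
  stopifnot(all(multipliers > 0), length(multipliers) == 2L,
            eeg_background_sd > 0)
  structure(list(band = band, channels = as.integer(channels),
                 multipliers = multipliers, noise_sd = noise_sd,
                 eeg_background_sd = eeg_background_sd),
            class = "class_spec")
}

#' Frame and sample counts implied by a protocol
#'
#' @param protocol a [protocol_spec()].
#' @return List: `frames_per_trial`, `frames_per_subject`, `frames_total`,
#'   `samples_per_channel` (time points per trial), `windows_per_trial`
#'   (0.5-s task windows).
#' @export
protocol_frame_counts <- function(protocol = protocol_spec()) {
  fpt <- round(protocol$task_seconds / protocol$frame_interval_seconds)
  list(frames_per_trial = fpt,
       frames_per_subject = fpt * protocol$n_trials,
       frames_total = fpt * protocol$n_trials * protocol$n_subjects,
       samples_per_channel = round(protocol$fs *
         (protocol$prep_seconds + protocol$task_seconds)),
       windows_per_trial = fpt)
}

# 1/f ("pink") noise via spectral shaping: flat-phase white spectrum scaled
# by f^(-1/2) so power falls as 1/f, resembling the EEG background.
pink_noise <- function(n, fs) {
  half <- n %/% 2L
  f <- seq_len(half) * fs / n
  amp <- 1 / sqrt(f)
  spec <- complex(modulus = amp,
                  argument = stats::runif(half, 0, 2 * pi))
  full <- complex(real = numeric(n))
  full[1L + seq_len(half)] <- spec
  if (n %% 2L == 0L)                       # Nyquist bin must be real
    full[1L + half] <- complex(modulus = amp[half], argument = 0)
  ks <- seq_len(if (n %% 2L == 0L) half - 1L else half)
  full[n - ks + 1L] <- Conj(spec[ks])
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

# Band-limited oscillation: random-phase sinusoids in the band interior
# (a 25% margin per edge keeps the class effect out of neighbouring bands
# despite the finite roll-off of any realisable band-pass filter).
band_oscillation <- function(n, fs, low, high, n_components = 3L) {
  t <- seq_len(n) / fs
  m <- 0.25 * (high - low)
  x <- rowSums(vapply(seq_len(n_components), function(i) {
    f <- stats::runif(1, low + m, high - m)
    sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }, numeric(n)))
  x / stats::sd(x)
}

#' Generate synthetic EEG recordings
#'
#' Per trial: a pink-noise background on every channel plus a band-limited
#' oscillation on the designated channels whose amplitude is the class's
#' multiplier; the preparation span carries baseline-only statistics (no
#' class effect).  Labels are balanced and trial order shuffled.
#'
#' @param protocol a [protocol_spec()].
#' @param spec a [class_spec()].
#' @param n_trials trials to generate (defaults to `protocol$n_trials`).
#' @param subject_id identifier stored on the trials.
#' @return List of class `recording_set`: `trials` (list of [eeg_trial()]),
#'   `labels`, `subject_id`.
#' @export
generate_eeg <- function(protocol = protocol_spec(), spec = class_spec(),
                         n_trials = protocol$n_trials, subject_id = "S01") {
  fs <- protocol$fs
  n_prep <- round(fs * protocol$prep_seconds)
  n_task <- round(fs * protocol$task_seconds)
  n_tot <- n_prep + n_task
  bands <- eeg_bands()
  bd <- bands[bands$name == spec$band, ]
  if (nrow(bd) != 1L) stop("unknown band '", spec$band, "'")
  labels <- sample(rep(0:1, length.out = n_trials))
  trials <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    amp <- spec$multipliers[labels[tr] + 1L]
    sig <- matrix(0, protocol$n_channels, n_tot)
    for (ch in seq_len(protocol$n_channels)) {
      x <- pink_noise(n_tot, fs) * spec$eeg_background_sd
      if (ch %in% spec$channels) {
        osc <- band_oscillation(n_task, fs, bd$low, bd$high)
        # class effect confined to the task span; prep stays baseline-only
        x[(n_prep + 1L):n_tot] <- x[(n_prep + 1L):n_tot] + amp * osc
        x[seq_len(n_prep)] <- x[seq_len(n_prep)] +
          spec$multipliers[1L] * band_oscillation(n_prep, fs, bd$low, bd$high)
      }
      sig[ch, ] <- x
    }
    trials[[tr]] <- eeg_trial(sig, fs, protocol$prep_seconds,
                              protocol$task_seconds,
                              label = labels[tr],
                              trial_id = sprintf("%s_T%02d", subject_id, tr))
  }
  structure(list(subject_id = subject_id, trials = trials, labels = labels),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat("Recording set", x$subject_id, ":", length(x$trials), "trials,",
      nrow(x$trials[[1]]$samples), "channels\n")
  invisible(x)
}

gauss_blob <- function(size, cx, cy, sigma, amp = 1) {
  g <- outer(seq_len(size), seq_len(size), function(i, j)
    exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2)))
  amp * g
}

#' Generate synthetic face frames
#'
#' Grayscale frames with class-conditional spatial scale: class 0 frames
#' contain one compact bright blob (a local cue resolvable by a small
#' receptive field), class 1 frames contain two widely separated blobs
#' whose joint detection requires a long-range receptive field.  Pixel
#' values are clipped to `[0, 1]`.
#'
#' @param n number of frames.
#' @param labels optional 0/1 labels (balanced and shuffled by default).
#' @param size image side length (default 48).
#' @param noise_sd additive white-noise standard deviation.
#' @return List with `x` (array `[size, size, n]`) and `y` (labels).
#' @export
generate_faces <- function(n, labels = NULL, size = 48L, noise_sd = 0.1) {
  if (is.null(labels)) labels <- sample(rep(0:1, length.out = n))
  stopifnot(length(labels) == n)
  x <- array(0, c(size, size, n))
  sep <- round(size * 0.42)      # blob separation beyond small-kernel span
  for (i in seq_len(n)) {
    img <- matrix(stats::rnorm(size * size, mean = 0.3, sd = noise_sd),
                  size, size)
    jx <- stats::runif(1, -3, 3); jy <- stats::runif(1, -3, 3)
    if (labels[i] == 0L) {
      img <- img + gauss_blob(size, size / 2 + jx, size / 2 + jy,
                              sigma = 2.2, amp = 0.7)
    } else {
      img <- img + gauss_blob(size, size / 2 - sep / 2 + jx,
                              size / 2 - sep / 2 + jy, sigma = 2.2,
                              amp = 0.35) +
                   gauss_blob(size, size / 2 + sep / 2 + jx,
                              size / 2 + sep / 2 + jy, sigma = 2.2,
                              amp = 0.35)
    }
    x[, , i] <- pmin(pmax(img, 0), 1)
  }
  list(x = x, y = labels)
}

#' Generate complementary synthetic decision pairs
#'
#' A test bed for decision-level fusion: each sample has exactly one
#' reliable modality — a fraction `complementarity` of samples relies on
#' the EEG branch, the rest on the face branch.  The reliable modality's
#' row puts probability mass `acc` on the true class (so its argmax is
#' always correct); the unreliable modality emits the uniform row.  A
#' fusion rule aware of this structure recovers the labels almost
#' perfectly, while either single modality is wrong on roughly half of its
#' unreliable span.
#'
#' @param n number of samples.
#' @param complementarity fraction of samples on which the EEG modality is
#'   the reliable one, in `[0, 1]`.
#' @param acc probability mass the reliable modality assigns to the true
#'   class (> 1/n_classes).
#' @param n_classes number of classes (default 2).
#' @return A labelled [decision_pair()].
#' @export
generate_decisions <- function(n, complementarity = 0.5, acc = 0.85,
                               n_classes = 2L) {
  stopifnot(complementarity >= 0, complementarity <= 1,
            acc > 1 / n_classes, acc <= 1)
  labels <- sample(rep(seq_len(n_classes) - 1L, length.out = n))
  eeg_reliable <- sample(c(rep(TRUE, round(n * complementarity)),
                           rep(FALSE, n - round(n * complementarity))))
  off <- (1 - acc) / (n_classes - 1L)
  p_eeg <- matrix(1 / n_classes, n, n_classes)
  p_face <- matrix(1 / n_classes, n, n_classes)
  for (i in seq_len(n)) {
    row <- rep(off, n_classes)
    row[labels[i] + 1L] <- acc
    if (eeg_reliable[i]) p_eeg[i, ] <- row else p_face[i, ] <- row
  }
  decision_pair(p_eeg, p_face, labels = labels)
}
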