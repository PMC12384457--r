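# Synthetic motor-imagery EEG with the statistical structure the decoder
# exploits: a 1/f (pink) noise floor, a sensorimotor rhythm on every
# electrode, and class-dependent event-related desynchronisation (ERD) —
# attenuation of that rhythm on the electrodes overlying the cortical
# representation contralateral to the imagined movement.

#' Default class-to-electrode ERD layout
#'
#' Mirrors sensorimotor physiology: left-hand imagery attenuates the rhythm
#' over the right motor cortex (C4), right-hand over the left (C3), feet
#' over the vertex (Cz), and tongue bilaterally (C3 and C4 at half
#' strength). Electrodes absent from the montage are skipped.
#'
#' @param montage An [electrode_montage()].
#' @param n_classes 2 (left/right hand) or 4 (left, right, feet, tongue).
#' @param attenuation Amplitude attenuation on the ERD electrodes, in
#'   `[0, 1]` (0 = no class signal, 1 = rhythm fully suppressed).
#' @param band_center Rhythm frequency in Hz (mu band).
#' @return Data frame with columns `class`, `electrode`, `band_center`,
#'   `attenuation`.
#' @export
default_erd_map <- function(montage, n_classes = 4L, attenuation = 0.6,
                            band_center = 11) {
  stopifnot(n_classes %in% c(2L, 4L))
  rows <- list(
    data.frame(class = 0L, electrode = "C4", band_center = band_center,
               attenuation = attenuation),
    data.frame(class = 1L, electrode = "C3", band_center = band_center,
               attenuation = attenuation))
  if (n_classes == 4L) {
    rows <- c(rows, list(
      data.frame(class = 2L, electrode = "Cz", band_center = band_center,
                 attenuation = attenuation),
      data.frame(class = 3L, electrode = c("C3", "C4"),
                 band_center = band_center,
                 attenuation = attenuation / 2)))
  }
  map <- do.call(rbind, rows)
  map[map$electrode %in% montage$names, , drop = FALSE]
}

#' Synthetic-data configuration
#'
#' The defaults emulate the four-class cued paradigm: 22 electrodes,
#' 250 Hz, 4.5 s epochs (1125 samples), 72 trials per class, pink (1/f)
#' background noise and a band-limited rhythm signal-to-noise ratio of 6 dB
#' in the 8-13 Hz mu band, with mild per-subject gain/noise variation.
#'
#' @param n_subjects Number of simulated subjects.
#' @param trials_per_class Trials per class per subject per session.
#' @param n_classes 2 or 4.
#' @param montage An [electrode_montage()].
#' @param fs Sampling rate (Hz).
#' @param epoch_s Epoch duration (s); `fs * epoch_s` must be integral.
#' @param erd_map ERD layout, see [default_erd_map()].
#' @param noise_exponent Spectral slope of the background (1 = pink).
#' @param snr_db Band-limited (8-13 Hz) rhythm-to-noise ratio in dB.
#' @param n_sessions Sessions per subject (session is stamped as metadata).
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_subjects = 1L, trials_per_class = 72L,
                         n_classes = 4L, montage = montage_2a(), fs = 250,
                         epoch_s = 4.5,
                         erd_map = default_erd_map(montage, n_classes),
                         noise_exponent = 1, snr_db = 6, n_sessions = 1L,
                         seed = 1L) {
  if (!(n_classes %in% c(2L, 4L))) stop("n_classes must be 2 or 4")
  if (abs(fs * epoch_s - round(fs * epoch_s)) > 1e-9)
    stop("fs * epoch_s must be an integer sample count")
  if (any(erd_map$attenuation < 0 | erd_map$attenuation > 1))
    stop("attenuation must lie in [0, 1]")
  bad <- setdiff(erd_map$electrode, montage$names)
  if (length(bad) > 0L)
    stop(sprintf("erd_map references electrode(s) absent from the montage: %s",
                 paste(unique(bad), collapse = ", ")))
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_class = as.integer(trials_per_class),
                 n_classes = as.integer(n_classes), montage = montage,
                 fs = fs, epoch_s = epoch_s, erd_map = erd_map,
                 noise_exponent = noise_exponent, snr_db = snr_db,
                 n_sessions = as.integer(n_sessions),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f^alpha noise via spectral shaping, unit variance
pink_noise <- function(n, alpha) {
  half <- n %/% 2L
  f <- seq_len(half)
  amp <- f^(-alpha / 2)
  re <- stats::rnorm(half) * amp
  im <- stats::rnorm(half) * amp
  spec <- complex(real = re, imaginary = im)
  full <- complex(length.out = n)
  full[2L:(half + 1L)] <- spec
  if (n %% 2L == 0L) {
    full[half + 1L] <- complex(real = re[half], imaginary = 0)
    if (half > 1L) full[(half + 2L):n] <- Conj(spec[(half - 1L):1L])
  } else {
    full[(half + 2L):n] <- Conj(spec[half:1L])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1L) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  2 * sum(p[keep])
}

#' Generate labeled synthetic motor-imagery trials
#'
#' Each trial is the sum of (a) per-electrode independent pink noise plus a
#' shared pink source mixed across electrodes by scalp distance (a crude
#' volume-conduction surrogate), and (b) an amplitude-modulated sinusoidal
#' sensorimotor rhythm on every electrode whose amplitude on the trial
#' class's ERD electrodes is multiplied by `1 - attenuation`. The rhythm
#' amplitude is calibrated per channel so that the stated `snr_db` is the
#' band-limited (8-13 Hz) power ratio against that channel's noise. Labels
#' are exactly balanced; the output is deterministic under the
#' configuration seed.
#'
#' @param cfg A [synth_config()].
#' @return A [trial_set()] of
#'   `n_subjects * n_sessions * n_classes * trials_per_class` trials.
#' @export
generate_trials <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  Tn <- as.integer(round(cfg$fs * cfg$epoch_s))
  C <- length(cfg$montage$names)
  per_block <- cfg$n_classes * cfg$trials_per_class
  total <- cfg$n_subjects * cfg$n_sessions * per_block
  data <- array(0, c(total, C, Tn))
  labels <- integer(total); subject <- integer(total); session <- integer(total)

  pos <- cfg$montage$positions
  center <- colMeans(pos)
  dist_c <- sqrt(rowSums(sweep(pos, 2L, center)^2))
  share_w <- exp(-dist_c / 0.3)
  tgrid <- (seq_len(Tn) - 1L) / cfg$fs
  snr_lin <- 10^(cfg$snr_db / 10)

  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    gain <- exp(stats::rnorm(1L, 0, 0.1))
    noise_scale <- exp(stats::rnorm(1L, 0, 0.1))
    for (sess in seq_len(cfg$n_sessions)) {
      block_labels <- rep(seq_len(cfg$n_classes) - 1L,
                          each = cfg$trials_per_class)
      for (y in block_labels) {
        i <- i + 1L
        shared <- pink_noise(Tn, cfg$noise_exponent)
        noise <- matrix(0, C, Tn)
        for (c in seq_len(C))
          noise[c, ] <- noise_scale *
            (pink_noise(Tn, cfg$noise_exponent) + 0.8 * share_w[c] * shared)
        trial <- noise
        ent <- cfg$erd_map[cfg$erd_map$class == y, , drop = FALSE]
        for (c in seq_len(C)) {
          el <- cfg$montage$names[c]
          hit <- which(ent$electrode == el)
          f0 <- if (length(hit) > 0L) ent$band_center[hit[1L]] else 11
          att <- if (length(hit) > 0L) ent$attenuation[hit[1L]] else 0
          pn <- band_power(noise[c, ], cfg$fs, 8, 13)
          amp <- gain * sqrt(2 * pn * snr_lin) * (1 - att)
          env <- 1 + 0.25 * pmax(pmin(smooth_noise(Tn), 2), -2)
          trial[c, ] <- trial[c, ] +
            amp * env * sin(2 * pi * f0 * tgrid + stats::runif(1L, 0, 2 * pi))
        }
        data[i, , ] <- trial
        labels[i] <- y
        subject[i] <- s
        session[i] <- sess
      }
    }
  }
  cls <- if (cfg$n_classes == 2L) c("left_hand", "right_hand")
         else c("left_hand", "right_hand", "feet", "tongue")
  trial_set(data, labels, cfg$fs, subject = subject, session = session,
            class_names = cls, channel_names = cfg$montage$names)
}

# slow random amplitude envelope (moving-average smoothed white noise)
smooth_noise <- function(n, span = 125L) {
  x <- stats::rnorm(n + span)
  k <- rep(1 / span, span)
  y <- stats::filter(x, k, sides = 1L)[(span + 1L):(span + n)]
  as.numeric(y) / stats::sd(y)
}

#' Nearest-centroid band-power oracle classifier
#'
#' An intentionally simple reference decoder: log band power around each
#' ERD electrode's band centre is the feature vector, class centroids are
#' fit with the true labels, and trials are assigned to the nearest
#' centroid. On noise-free separable configurations it is a ceiling check;
#' on null configurations it sits at chance. It is independent of the deep
#' model and serves as a floor/ceiling reference for it.
#'
#' @param trials A [trial_set()].
#' @param erd_map ERD layout (as in [synth_config()]).
#' @param halfwidth Band half-width around each centre (Hz).
#' @return Integer vector of predicted 0-based labels.
#' @export
bandpower_oracle_classify <- function(trials, erd_map, halfwidth = 2.5) {
  feats <- oracle_features(trials, erd_map, halfwidth)
  cents <- lapply(sort(unique(trials$labels)), function(k)
    colMeans(feats[trials$labels == k, , drop = FALSE]))
  dists <- sapply(cents, function(ce)
    rowSums(sweep(feats, 2L, ce)^2))
  (apply(dists, 1L, which.min) - 1L)
}

oracle_features <- function(trials, erd_map, halfwidth = 2.5) {
  keys <- unique(erd_map[, c("electrode", "band_center")])
  ch <- match(keys$electrode, trials$channel_names)
  if (anyNA(ch)) stop("erd_map electrode missing from the trial set")
  n <- n_trials(trials)
  feats <- matrix(0, n, nrow(keys))
  for (j in seq_len(nrow(keys))) {
    for (i in seq_len(n)) {
      feats[i, j] <- log(band_power(trials$data[i, ch[j], ],
                                    trials$fs,
                                    keys$band_center[j] - halfwidth,
                                    keys$band_center[j] + halfwidth))
    }
  }
  feats
}

#' Periodogram of one channel of one trial
#'
#' Plain discrete-Fourier periodogram, returned as a data frame of
#' frequency (Hz) and power, up to the Nyquist frequency.
#'
#' @param trials A [trial_set()].
#' @param trial Trial index (1-based).
#' @param channel Channel index or electrode name.
#' @return Data frame with `freq` and `power`.
#' @export
channel_periodogram <- function(trials, trial = 1L, channel = 1L) {
  if (is.character(channel))
    channel <- match(channel, trials$channel_names)
  x <- trials$data[trial, channel, ]
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1L) * trials$fs / n
  keep <- f <= trials$fs / 2
  data.frame(freq = f[keep], power = p[keep])
}
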