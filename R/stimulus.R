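#' Two-channel stimulus container
#'
#' @param samples Numeric matrix, one column per ear (left, right); a vector
#'   or single column is duplicated diotically.
#' @param fs Sampling rate in Hz.
#' @param annotations Named list of metadata (condition labels, realized
#'   transition time, scaling factors ...).
#' @return An object of class `stimulus`.
#' @export
stimulus <- function(samples, fs, annotations = list()) {
  samples <- as.matrix(samples)
  if (ncol(samples) == 1L) samples <- cbind(samples, samples)
  stopifnot(ncol(samples) == 2L, fs > 0)
  colnames(samples) <- c("left", "right")
  structure(list(samples = samples, fs = fs, annotations = annotations),
            class = "stimulus")
}

raised_cosine_ramp <- function(n) {
  # 0 at sample 1, 1 at sample n
  if (n <= 1L) return(rep(1, n))
  0.5 * (1 - cos(pi * (seq_len(n) - 1) / (n - 1)))
}

#' Gaussian white-noise burst with raised-cosine ramps
#'
#' @param duration Burst duration in seconds.
#' @param ramp On/offset ramp duration in seconds (each).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; identical seeds give identical waveforms.
#' @return Diotic [stimulus()] (identical ears, to be spatialized by
#'   [apply_hrtf()]).
#' @export
noise_burst <- function(duration = 0.5, ramp = 0.01, fs = 44100, seed = 1L) {
  if (2 * ramp >= duration)
    stop("ramps (2 x ", ramp, " s) must fit inside the burst duration")
  n <- round(duration * fs)
  set.seed(seed)
  x <- stats::rnorm(n)
  nr <- round(ramp * fs)
  env <- rep(1, n)
  env[seq_len(nr)] <- raised_cosine_ramp(nr)
  env[n - nr + seq_len(nr)] <- rev(raised_cosine_ramp(nr))
  x <- x * env
  x <- x / max(abs(x))
  stimulus(x, fs, list(kind = "noise_burst", seed = seed))
}

#' Schroeder-phase harmonic tone complex
#'
#' Sum of harmonics `n * f0` inside `[band_lo, band_hi]` with equal
#' amplitudes and phases `phi_n = curvature * pi * n * (n + 1) / N`
#' (N = number of components). Curvature 0.5 spreads energy in time and
#' keeps the crest factor low; curvature 0 gives a pulse train.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param band_lo,band_hi Passband edges in Hz.
#' @param phase_curvature Schroeder phase curvature in `[-1, 1]`.
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return Diotic [stimulus()], peak-normalized.
#' @export
harmonic_complex <- function(f0, band_lo = 1000, band_hi = 16000,
                             phase_curvature = 0.5, duration = 0.6,
                             fs = 44100) {
  stopifnot(f0 > 0, band_lo <= band_hi, abs(phase_curvature) <= 1)
  n_lo <- ceiling(band_lo / f0)
  n_hi <- floor(band_hi / f0)
  if (n_hi < n_lo)
    stop("no harmonic of f0 = ", f0, " Hz falls inside [",
         band_lo, ", ", band_hi, "] Hz")
  harmonics <- seq.int(n_lo, n_hi)
  N <- length(harmonics)
  t <- seq(0, by = 1 / fs, length.out = round(duration * fs))
  phi <- phase_curvature * pi * harmonics * (harmonics + 1) / N
  x <- rowSums(sapply(seq_len(N), function(i)
    sin(2 * pi * harmonics[i] * f0 * t + phi[i])))
  x <- x / max(abs(x))
  stimulus(x, fs, list(kind = "harmonic_complex", f0 = f0,
                       harmonics = harmonics,
                       phase_curvature = phase_curvature))
}

# Minimum-phase FIR (length nfft) realizing a dB magnitude spectrum given on
# arbitrary frequencies; real-cepstrum construction.
min_phase_fir <- function(freqs, mag_db, fs, nfft = 512L) {
  fbin <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  m_db <- stats::approx(freqs, mag_db, xout = fbin, rule = 2)$y
  mag <- 10^(m_db / 20)
  full <- c(mag, rev(mag[2:(nfft / 2)]))
  lmag <- log(pmax(full, 1e-8))
  cep <- Re(stats::fft(lmag, inverse = TRUE)) / nfft
  # fold the cepstrum to make it causal (minimum phase)
  half <- nfft / 2
  cep_mp <- c(cep[1], 2 * cep[2:half], cep[half + 1], rep(0, half - 1))
  H <- exp(stats::fft(cep_mp))
  Re(stats::fft(H, inverse = TRUE)) / nfft
}

#' Filter a stimulus with (possibly manipulated) HRTF magnitude spectra
#'
#' Builds a minimum-phase FIR per ear from the magnitude spectrum of the
#' requested direction and filters each channel. The manipulation chain
#' touches magnitudes only, so phase is reconstructed as minimum phase.
#'
#' @param stim A [stimulus()].
#' @param specs A [magnitude_spectra()] set.
#' @param direction Either a row index into `specs$directions` or a
#'   length-2 numeric `c(lateral, polar)` matched exactly.
#' @param nfft FIR length (samples).
#' @return Spatialized two-channel [stimulus()], same length as input.
#' @export
apply_hrtf <- function(stim, specs, direction, nfft = 512L) {
  stopifnot(inherits(stim, "stimulus"), inherits(specs, "magnitude_spectra"))
  if (length(direction) == 2L && !is.character(direction)) {
    hit <- which(specs$directions$lateral == direction[1] &
                 specs$directions$polar == direction[2])
    if (length(hit) != 1L)
      stop("direction (", direction[1], ", ", direction[2],
           ") not in the set; available:\n",
           paste(sprintf("  (%g, %g)", specs$directions$lateral,
                         specs$directions$polar), collapse = "\n"))
    direction <- hit
  }
  d <- as.integer(direction)
  if (d < 1L || d > nrow(specs$directions)) stop("direction index out of range")
  out <- stim$samples
  for (e in 1:2) {
    h <- min_phase_fir(specs$axis$frequencies, specs$magnitudes[d, e, ],
                       stim$fs, nfft)
    y <- stats::convolve(stim$samples[, e], rev(h), type = "open")
    out[, e] <- y[seq_len(nrow(out))]
  }
  ann <- stim$annotations
  ann$direction <- unlist(specs$directions[d, c("lateral", "polar")])
  stimulus(out, stim$fs, ann)
}

#' Raised-cosine crossfade transition between two correlated stimuli
#'
#' Plays `stimA` up to a jittered onset, then crossfades into `stimB` over
#' `crossfade` seconds with complementary raised-cosine faders (weights sum
#' to 1 at every sample, keeping intensity constant for correlated inputs).
#'
#' @param stimA,stimB [stimulus()] objects with equal `fs` and length.
#' @param onset_nominal Nominal transition onset in seconds.
#' @param jitter Uniform onset jitter half-width in seconds.
#' @param crossfade Crossfade duration in seconds.
#' @param seed Integer seed for the jitter draw.
#' @return [stimulus()] whose annotations record `transition_time` (realized
#'   onset, seconds).
#' @export
make_transition <- function(stimA, stimB, onset_nominal = 0.6,
                            jitter = 0.05, crossfade = 0.01, seed = 1L) {
  stopifnot(inherits(stimA, "stimulus"), inherits(stimB, "stimulus"))
  if (stimA$fs != stimB$fs || nrow(stimA$samples) != nrow(stimB$samples))
    stop("stimuli must share sampling rate and length")
  if (onset_nominal - jitter <= 0) stop("onset_nominal - jitter must be > 0")
  set.seed(seed)
  onset <- onset_nominal + stats::runif(1, -jitter, jitter)
  fs <- stimA$fs
  n <- nrow(stimA$samples)
  i0 <- round(onset * fs)
  nf <- round(crossfade * fs)
  if (i0 + nf > n) stop("transition does not fit inside the stimulus")
  w_in <- raised_cosine_ramp(nf)
  w <- numeric(n)                 # fade-in weight of B
  w[(i0 + 1):(i0 + nf)] <- w_in
  if (i0 + nf < n) w[(i0 + nf + 1):n] <- 1
  out <- (1 - w) * stimA$samples + w * stimB$samples
  ann <- stimA$annotations
  ann$transition_time <- onset
  ann$crossfade <- crossfade
  stimulus(out, fs, ann)
}

#' RMS equalization of a set of stimuli
#'
#' Scales each stimulus by one common per-stimulus factor so its two-channel
#' RMS sits at `target_db` dBFS; the interaural ratio within each stimulus
#' is preserved.
#'
#' @param stims List of [stimulus()] objects.
#' @param target_db Target RMS level in dB full scale (0 dB = RMS 1).
#' @return List of scaled [stimulus()] objects; each records its
#'   `rms_scale` factor in the annotations.
#' @export
rms_equalize <- function(stims, target_db = -20) {
  if (inherits(stims, "stimulus")) stims <- list(stims)
  lapply(stims, function(s) {
    r <- sqrt(mean(s$samples^2))
    if (r == 0) stop("cannot RMS-equalize a silent stimulus")
    g <- 10^(target_db / 20) / r
    s$samples <- s$samples * g
    s$annotations$rms_scale <- g
    s
  })
}
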