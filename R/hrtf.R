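#' Equivalent rectangular bandwidth (ERB) of the auditory filter
#'
#' Glasberg & Moore approximation `ERB(f) = 24.7 * (4.37 * f / 1000 + 1)` Hz.
#'
#' @param f Frequency in Hz (vectorized).
#' @return ERB in Hz.
#' @export
erb <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Frequency axis for magnitude spectra
#'
#' @param frequencies Numeric vector of frequencies in Hz, strictly
#'   increasing, all positive, at least two bins.
#' @return An object of class `freq_axis`.
#' @export
freq_axis <- function(frequencies) {
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) < 2L)
    stop("frequency axis needs at least 2 bins")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be finite and positive")
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing")
  structure(list(frequencies = frequencies), class = "freq_axis")
}

#' Spectral contrast specification
#'
#' Bundles the contrast factor `C` (native = 1, flat = 0, novel = -1) with
#' the manipulation band in Hz.
#'
#' @param C Spectral contrast factor (finite scalar).
#' @param band_lo,band_hi Band edges in Hz, `band_lo < band_hi`.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(C, band_lo = 1000, band_hi = 16000) {
  stopifnot(is.finite(C), band_lo < band_hi, band_lo > 0)
  structure(list(C = C, band_lo = band_lo, band_hi = band_hi),
            class = "contrast_spec")
}

#' Set of per-direction, per-ear HRTF magnitude spectra
#'
#' @param magnitudes Numeric array in dB with dimensions
#'   `(direction, ear, frequency)`; ear order is left, right.
#' @param axis A [freq_axis()] shared by all spectra.
#' @param directions Data frame with columns `lateral` and `polar`
#'   (interaural coordinates, degrees), one row per direction.
#' @return An object of class `magnitude_spectra`.
#' @export
magnitude_spectra <- function(magnitudes, axis, directions) {
  if (!inherits(axis, "freq_axis")) axis <- freq_axis(axis)
  magnitudes <- as.array(magnitudes)
  if (length(dim(magnitudes)) == 2L)  # single direction convenience
    dim(magnitudes) <- c(1L, dim(magnitudes))
  stopifnot(length(dim(magnitudes)) == 3L,
            dim(magnitudes)[3] == length(axis$frequencies),
            dim(magnitudes)[2] == 2L)
  if (any(!is.finite(magnitudes))) stop("magnitudes must be finite")
  directions <- as.data.frame(directions)
  stopifnot(nrow(directions) == dim(magnitudes)[1],
            all(c("lateral", "polar") %in% names(directions)))
  dimnames(magnitudes) <- list(NULL, c("left", "right"), NULL)
  structure(list(magnitudes = magnitudes, axis = axis,
                 directions = directions),
            class = "magnitude_spectra")
}

in_band_idx <- function(axis, spec) {
  which(axis$frequencies >= spec$band_lo & axis$frequencies <= spec$band_hi)
}

#' ERB-derivative frequency weights inside the manipulation band
#'
#' Realizes the across-frequency derivative of the ERB-rate scale,
#' `w(f) = c / ERB(f)`, evaluated at the in-band bins and normalized so the
#' in-band mean weight is 1. Weights decrease with frequency, giving
#' low frequencies (finer auditory resolution) more influence on the
#' weighted spectral mean.
#'
#' @param axis A [freq_axis()].
#' @param band A [contrast_spec()] (only the band edges are used).
#' @return An object of class `erb_weighting` with fields `idx` (in-band bin
#'   indices into the axis) and `weights` (mean-1 weights).
#' @export
erb_weights <- function(axis, band) {
  if (!inherits(axis, "freq_axis")) axis <- freq_axis(axis)
  idx <- in_band_idx(axis, band)
  if (length(idx) < 2L)
    stop("manipulation band [", band$band_lo, ", ", band$band_hi,
         "] Hz intersects the frequency axis on fewer than 2 bins")
  w <- 1 / erb(axis$frequencies[idx])
  w <- w / mean(w)
  structure(list(idx = idx, weights = w, axis = axis), class = "erb_weighting")
}

# Row-stochastic gammatone smoothing matrix on the axis grid.  Kernel at
# centre fc is the 4th-order gammatone power response
# (1 + ((f - fc)/b)^2)^-2 with b set so the kernel's equivalent
# rectangular width equals bandwidth_factor * ERB(fc).
gammatone_kernel_matrix <- function(freqs, bandwidth_factor) {
  K <- outer(freqs, freqs, function(fc, f) {
    bb <- 2 * bandwidth_factor * erb(fc) / pi
    (1 + ((f - fc) / bb)^2)^-2
  })
  K / rowSums(K)
}

#' Gammatone-style spectral smoothing of HRTF magnitude spectra
#'
#' Replaces each dB spectrum by a weighted moving average whose kernel at
#' centre frequency `f` has equivalent rectangular width
#' `bandwidth_factor * ERB(f)`; kernel rows are normalized to unit sum so
#' constant spectra pass through unchanged.
#'
#' @param specs A [magnitude_spectra()] object.
#' @param bandwidth_factor Positive kernel width multiplier (1 = one ERB).
#' @return Smoothed [magnitude_spectra()] on the same axis.
#' @export
smooth_spectrum <- function(specs, bandwidth_factor = 1) {
  stopifnot(inherits(specs, "magnitude_spectra"))
  if (!is.finite(bandwidth_factor) || bandwidth_factor <= 0)
    stop("bandwidth_factor must be positive")
  K <- gammatone_kernel_matrix(specs$axis$frequencies, bandwidth_factor)
  m <- specs$magnitudes
  out <- m
  for (d in seq_len(dim(m)[1]))
    for (e in 1:2)
      out[d, e, ] <- K %*% m[d, e, ]
  specs$magnitudes <- out
  specs
}

#' Spectral-contrast manipulation of HRTF magnitude spectra
#'
#' Applies, per direction and ear and for the in-band bins,
#' `Mc(f) = C * M1(f) + (1 - C) * (1/Nf) * sum_k w(k) * M1(k)`,
#' i.e. an interpolation (0 < C < 1), flattening (C = 0) or inversion
#' (C = -1) of the dB spectrum about its ERB-weighted in-band mean.
#' Out-of-band bins pass through unchanged. The weighted in-band mean is
#' invariant under any `C`.
#'
#' @param specs A [magnitude_spectra()] object.
#' @param spec A [contrast_spec()] carrying `C` and the band.
#' @param w Optional [erb_weights()] on the same axis/band; computed if
#'   missing. Must match the in-band bins of `specs`.
#' @return Manipulated [magnitude_spectra()].
#' @export
spectral_contrast <- function(specs, spec, w = NULL) {
  stopifnot(inherits(specs, "magnitude_spectra"),
            inherits(spec, "contrast_spec"))
  idx <- in_band_idx(specs$axis, spec)
  if (is.null(w)) w <- erb_weights(specs$axis, spec)
  if (!identical(w$idx, idx))
    stop("erb_weights were computed on a different axis/band than `specs`")
  C <- spec$C
  m <- specs$magnitudes
  wn <- w$weights / sum(w$weights)  # mean-1 weights -> convex weights
  for (d in seq_len(dim(m)[1])) {
    for (e in 1:2) {
      s <- m[d, e, idx]
      mu <- sum(wn * s)
      m[d, e, idx] <- C * s + (1 - C) * mu
    }
  }
  specs$magnitudes <- m
  specs
}

#' Build the native / flat / novel cue sets
#'
#' Smooths the measured spectra (gammatone smoothing, done before any
#' contrast manipulation) and applies the spectral contrast with
#' `C = 1, 0, -1` to obtain native, flat and novel cue sets. The flat set is
#' constant across frequency within the band for each (direction, ear)
#' spectrum (one weighted-mean constant per spectrum).
#'
#' @param native A [magnitude_spectra()] object (measured spectra).
#' @param band A [contrast_spec()]; its `C` is ignored, the band is used.
#' @param bandwidth_factor Smoothing bandwidth factor; `NULL` skips smoothing.
#' @return Named list of [magnitude_spectra()]: `native`, `flat`, `novel`.
#' @export
make_cue_sets <- function(native, band = contrast_spec(1),
                          bandwidth_factor = 1) {
  base <- if (is.null(bandwidth_factor)) native
          else smooth_spectrum(native, bandwidth_factor)
  w <- erb_weights(base$axis, band)
  list(
    native = spectral_contrast(base, contrast_spec(1,  band$band_lo, band$band_hi), w),
    flat   = spectral_contrast(base, contrast_spec(0,  band$band_lo, band$band_hi), w),
    novel  = spectral_contrast(base, contrast_spec(-1, band$band_lo, band$band_hi), w)
  )
}

#' Read / write plain-text HRTF spectrum tables
#'
#' Long-format delimited text with columns
#' `frequency, left_dB, right_dB, lateral, polar`.
#'
#' @param path File path.
#' @return `read_spectrum_table()` returns a [magnitude_spectra()] object.
#' @export
read_spectrum_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("frequency", "left_dB", "right_dB", "lateral", "polar")
  if (!all(need %in% names(tab)))
    stop("spectrum table must have columns: ", paste(need, collapse = ", "))
  key <- interaction(tab$lateral, tab$polar, drop = TRUE)
  dirs <- unique(tab[, c("lateral", "polar")])
  freqs <- sort(unique(tab$frequency))
  m <- array(NA_real_, c(nrow(dirs), 2L, length(freqs)))
  for (i in seq_len(nrow(dirs))) {
    sub <- tab[tab$lateral == dirs$lateral[i] & tab$polar == dirs$polar[i], ]
    sub <- sub[order(sub$frequency), ]
    if (!isTRUE(all.equal(sub$frequency, freqs)))
      stop("all directions must share one frequency axis")
    m[i, 1, ] <- sub$left_dB
    m[i, 2, ] <- sub$right_dB
  }
  magnitude_spectra(m, freq_axis(freqs), dirs)
}

#' @rdname read_spectrum_table
#' @param specs A [magnitude_spectra()] object to write.
#' @export
write_spectrum_table <- function(specs, path) {
  stopifnot(inherits(specs, "magnitude_spectra"))
  rows <- do.call(rbind, lapply(seq_len(nrow(specs$directions)), function(i) {
    data.frame(frequency = specs$axis$frequencies,
               left_dB  = specs$magnitudes[i, 1, ],
               right_dB = specs$magnitudes[i, 2, ],
               lateral  = specs$directions$lateral[i],
               polar    = specs$directions$polar[i])
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
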