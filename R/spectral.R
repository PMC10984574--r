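# Multitaper cross-spectra and band-averaged imaginary coherency.
#
# Single-segment, single-taper coherency is degenerate (|C| = 1 at every
# bin), so per-segment estimates use several orthogonal Slepian tapers.

.asrtnet_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the standard symmetric tridiagonal formulation whose
#' eigenvectors are the Slepian sequences. Tapers are normalized to unit
#' energy and cached per `(n, nw, k)`.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (the half-bandwidth is `nw / n` cycles
#'   per sample).
#' @param k Number of tapers; must satisfy `k <= 2 * nw - 1` for good
#'   spectral concentration.
#' @return An `n x k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  n <- assert_count(n, "n", min = 8L)
  k <- assert_count(k, "k")
  if (k > 2 * nw - 1 + 1e-9) {
    warning("k > 2*nw - 1: higher-order tapers have poor concentration",
            call. = FALSE)
  }
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  hit <- .asrtnet_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  w <- nw / n
  t_idx <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  off <- t_idx[-1] * (n - t_idx[-1]) / 2
  m <- diag(diag_main)
  m[cbind(2:n, 1:(n - 1))] <- off
  m[cbind(1:(n - 1), 2:n)] <- off
  ev <- eigen(m, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  tapers <- sweep(tapers, 2, sqrt(colSums(tapers^2)), "/")
  # sign convention: make the mean (symmetric tapers) or initial lobe
  # positive; irrelevant for spectra but keeps output deterministic
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) < 1e-8) s <- tapers[which.max(abs(tapers[, j])), j]
    if (s < 0) tapers[, j] <- -tapers[, j]
  }
  .asrtnet_cache[[key]] <- tapers
  tapers
}

# Multitaper cross-spectral array for one segment.
# x: channels x time. Returns complex array [n_bins, ch, ch] for the
# requested bin indices (1-based FFT bins) plus the bin frequencies.
cross_spectra_segment <- function(x, fs, bins = NULL, nw = 2, k = 3) {
  nch <- nrow(x)
  n <- ncol(x)
  tapers <- dpss_tapers(n, nw, k)
  freq_all <- (0:(n - 1)) * fs / n
  if (is.null(bins)) {
    bins <- seq_len(floor(n / 2) + 1L)
  }
  S <- array(0i, dim = c(length(bins), nch, nch))
  xt <- t(x)
  for (j in seq_len(k)) {
    Fj <- stats::mvfft(xt * tapers[, j])[bins, , drop = FALSE]
    for (b in seq_along(bins)) {
      fb <- Fj[b, ]
      S[b, , ] <- S[b, , ] + outer(fb, Conj(fb))
    }
  }
  list(S = S / k, freq = freq_all[bins], bins = bins)
}

# Normalize a cross-spectral array into coherency; zero-variance channels
# produce zero rows/columns with a warning.
normalize_coherency <- function(S) {
  nb <- dim(S)[1]
  nch <- dim(S)[2]
  C <- array(0i, dim = dim(S))
  warned <- FALSE
  for (b in seq_len(nb)) {
    p <- Re(diag(S[b, , ]))
    bad <- p <= 0
    if (any(bad) && !warned) {
      warning("zero-variance channel(s): their coherencies set to 0",
              call. = FALSE)
      warned <- TRUE
    }
    p[bad] <- 1
    denom <- sqrt(outer(p, p))
    Cb <- S[b, , ] / denom
    Cb[bad, ] <- 0i
    Cb[, bad] <- 0i
    diag(Cb) <- complex(real = as.numeric(!bad))
    C[b, , ] <- Cb
  }
  C
}

#' Imaginary coherency spectrum of one segment
#'
#' Estimates, from multitaper cross-spectra within a single segment, the
#' coherency `C_xy(f) = S_xy(f) / sqrt(S_xx(f) S_yy(f))` for all channel
#' pairs and returns its imaginary part per frequency bin. The imaginary
#' part is insensitive to zero-lag (volume-conducted) coupling: two channels
#' that are scaled copies of each other have `Im C = 0` exactly.
#'
#' @param x Channels x time numeric matrix (one segment).
#' @param fs Sampling rate, Hz.
#' @param nw Taper time-bandwidth product (default 2).
#' @param n_tapers Number of Slepian tapers (default 3).
#' @return List with `freq` (Hz, bins 0..Nyquist) and `im`, a
#'   `[n_bins, ch, ch]` array of `Im C_xy(f)` with zero diagonal.
#' @export
imaginary_coherency <- function(x, fs, nw = 2, n_tapers = 3) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  cs <- cross_spectra_segment(x, fs, bins = NULL, nw = nw, k = n_tapers)
  C <- normalize_coherency(cs$S)
  im <- Im(C)
  for (b in seq_len(dim(im)[1])) {
    diag(im[b, , ]) <- 0
  }
  list(freq = cs$freq, im = im)
}

#' Frequency bands of interest
#'
#' The four analysis bands: theta 4-7 Hz, low alpha 8-10 Hz, high alpha
#' 10-13 Hz and beta 13-30 Hz. The shared printed edge at 10 Hz (and 13 Hz)
#' is resolved half-open — `[8, 10)`, `[10, 13)` — so no bin is counted in
#' two bands; theta and beta are closed intervals.
#'
#' @return Data frame with columns `name`, `lo`, `hi`, `hi_inclusive`.
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("theta", "low_alpha", "high_alpha", "beta"),
    lo = c(4, 8, 10, 13),
    hi = c(7, 10, 13, 30),
    hi_inclusive = c(TRUE, FALSE, FALSE, TRUE)
  )
}

resolve_band <- function(band) {
  if (is.character(band)) {
    bands <- eeg_bands()
    row <- bands[bands$name == band, ]
    if (nrow(row) != 1L) {
      stop(sprintf("unknown band '%s'; use one of %s", band,
                   paste(bands$name, collapse = ", ")), call. = FALSE)
    }
    row
  } else if (is.numeric(band) && length(band) == 2L) {
    data.frame(name = sprintf("[%g,%g]", band[1], band[2]),
               lo = band[1], hi = band[2], hi_inclusive = TRUE)
  } else {
    stop("`band` must be a band name or a numeric (lo, hi) pair",
         call. = FALSE)
  }
}

band_bin_index <- function(freq, band) {
  b <- resolve_band(band)
  sel <- freq >= b$lo & (if (b$hi_inclusive) freq <= b$hi else freq < b$hi)
  which(sel)
}

#' Band-averaged unsigned imaginary coherency
#'
#' Averages `|Im C_xy(f)|` over the frequency bins falling in a band,
#' producing the symmetric channels x channels coherence matrix that the
#' thresholding step consumes. The unsigned magnitude is used so that
#' "strong" coherence does not depend on the direction of the phase lag.
#'
#' @param imcoh Output of [imaginary_coherency()] (list with `freq`, `im`).
#' @param band Band name (see [eeg_bands()]) or numeric `(lo, hi)` pair.
#' @return A channels x channels matrix in `[0, 1]`, zero diagonal, with
#'   attributes `band` and `n_bins`.
#' @export
band_average <- function(imcoh, band) {
  sel <- band_bin_index(imcoh$freq, band)
  if (length(sel) == 0L) {
    stop("band contains no frequency bins at this segment's resolution",
         call. = FALSE)
  }
  m <- apply(abs(imcoh$im[sel, , , drop = FALSE]), c(2, 3), mean)
  diag(m) <- 0
  structure(m, band = resolve_band(band)$name, n_bins = length(sel))
}

#' Band coherence matrices for a set of epochs
#'
#' Computes, for every segment of an `eeg_epochs` object, the band-averaged
#' unsigned imaginary coherency matrix. With `pooled = TRUE` the multitaper
#' cross-spectra are instead averaged across all segments before
#' normalization (the classical multi-segment coherence estimator), yielding
#' a single low-variance matrix: per-segment single-shot estimates carry
#' large sampling noise, which the per-segment thresholding procedure
#' tolerates but edge-recovery analyses do not.
#'
#' @param epochs An `eeg_epochs` object (see [segment_resting()]).
#' @param band Band name or numeric `(lo, hi)`.
#' @param nw,n_tapers Multitaper settings.
#' @param pooled Average cross-spectra across segments before normalizing.
#' @return With `pooled = FALSE` a list of per-segment matrices; otherwise a
#'   single matrix.
#' @export
coherence_matrices <- function(epochs, band = "theta", nw = 2, n_tapers = 3,
                               pooled = FALSE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  n_seg <- d[1]
  n <- d[3]
  freq_all <- (0:(n - 1)) * epochs$fs / n
  bins <- band_bin_index(freq_all[seq_len(floor(n / 2) + 1L)], band)
  if (length(bins) == 0L) {
    stop("band contains no frequency bins at this segment length",
         call. = FALSE)
  }
  if (pooled) {
    acc <- NULL
    for (s in seq_len(n_seg)) {
      cs <- cross_spectra_segment(epochs$data[s, , ], epochs$fs, bins,
                                  nw, n_tapers)
      acc <- if (is.null(acc)) cs$S else acc + cs$S
    }
    C <- normalize_coherency(acc / n_seg)
    m <- apply(abs(Im(C)), c(2, 3), mean)
    diag(m) <- 0
    return(structure(m, band = resolve_band(band)$name,
                     n_bins = length(bins), pooled = TRUE))
  }
  lapply(seq_len(n_seg), function(s) {
    cs <- cross_spectra_segment(epochs$data[s, , ], epochs$fs, bins,
                                nw, n_tapers)
    C <- normalize_coherency(cs$S)
    m <- apply(abs(Im(C)), c(2, 3), mean)
    diag(m) <- 0
    structure(m, band = resolve_band(band)$name, n_bins = length(bins))
  })
}
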