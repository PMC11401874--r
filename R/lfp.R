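#' LFP trace container
#'
#' @param samples voltage samples (uV).
#' @param rate sample rate (Hz).
#' @param trial,channel optional identifiers.
#' @return An object of class \code{lfp_trace}.
#' @export
lfp_trace <- function(samples, rate, trial = NA_integer_, channel = NA_integer_) {
  if (!is.numeric(samples) || length(samples) < 2)
    stop("lfp_trace: samples must be a numeric vector")
  if (!is.numeric(rate) || rate <= 0) stop("lfp_trace: rate must be > 0")
  structure(list(samples = as.numeric(samples), rate = rate,
                 trial = trial, channel = channel),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' Preprocess a raw LFP trace
#'
#' Zero-phase FIR low-pass (Hamming-window design, order 400, applied
#' forward and backward) at the cutoff, then decimation to the target rate.
#' Filtering precedes decimation so the downsampling cannot alias.
#'
#' @param trace an [lfp_trace()] at >= 1 kHz.
#' @param target_rate output rate (Hz); must divide the input rate.
#' @param cutoff low-pass cutoff (Hz).
#' @return The filtered, downsampled [lfp_trace()].
#' @export
preprocess_lfp <- function(trace, target_rate = 1000, cutoff = 300) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (trace$rate < target_rate)
    stop("preprocess_lfp: input rate below the target rate; cannot downsample")
  if (cutoff >= target_rate / 2)
    stop("preprocess_lfp: cutoff must be below the output Nyquist frequency")
  factor <- trace$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("preprocess_lfp: input rate must be an integer multiple of target_rate")
  factor <- round(factor)
  x <- trace$samples
  ord <- min(400, length(x) %/% 3 - 1)
  if (ord < 10) stop("preprocess_lfp: trace too short to filter")
  h <- signal::fir1(ord, cutoff / (trace$rate / 2))
  h <- h / sum(h)   # force exactly unit DC gain
  x <- signal::filtfilt(h, x)
  if (factor > 1) x <- x[seq(1, length(x), by = factor)]
  lfp_trace(x, target_rate, trial = trace$trial, channel = trace$channel)
}

.single_sided_fft <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  n_half <- floor(n / 2) + 1
  freq <- (0:(n_half - 1)) * fs / n
  amp <- Mod(X[1:n_half]) / n
  scale2 <- rep(2, n_half)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[n_half] <- 1
  pow <- (Mod(X[1:n_half]) / n)^2 * scale2   # single-sided power; sums to mean(x^2)
  amp <- amp * scale2                        # single-sided amplitude
  list(freq = freq, amplitude = amp, power = pow)
}

#' Peak-normalized single-sided amplitude spectrum
#'
#' FFT amplitude spectrum of a time window of each trace, averaged across
#' traces (trials/channels), then normalized to its peak value.
#'
#' @param traces an [lfp_trace()] or list of them (equal rate and window
#'   length required).
#' @param window \code{c(start, end)} in ms within each trace; \code{NULL}
#'   uses the whole trace.
#' @return Tibble with \code{freq} (Hz), \code{amplitude} (peak-normalized,
#'   max exactly 1) and \code{raw_amplitude}; attribute \code{rate}.
#' @export
amplitude_spectrum <- function(traces, window = NULL) {
  if (inherits(traces, "lfp_trace")) traces <- list(traces)
  stopifnot(length(traces) > 0, all(vapply(traces, inherits, TRUE, "lfp_trace")))
  fs <- traces[[1]]$rate
  specs <- lapply(traces, function(tr) {
    if (tr$rate != fs) stop("amplitude_spectrum: traces have differing rates")
    x <- tr$samples
    if (!is.null(window)) {
      i1 <- floor(window[1] / 1000 * fs) + 1
      i2 <- floor(window[2] / 1000 * fs)
      if (i1 < 1 || i2 > length(x) || i2 <= i1)
        stop("amplitude_spectrum: window outside the trace")
      x <- x[i1:i2]
    }
    .single_sided_fft(x, fs)
  })
  n <- length(specs[[1]]$freq)
  if (any(vapply(specs, function(s) length(s$freq), 1L) != n))
    stop("amplitude_spectrum: traces have differing window lengths")
  amp <- Reduce(`+`, lapply(specs, `[[`, "amplitude")) / length(specs)
  peak <- max(amp)
  if (peak <= 0) stop("amplitude_spectrum: zero signal")
  out <- tibble::tibble(freq = specs[[1]]$freq, amplitude = amp / peak,
                        raw_amplitude = amp)
  attr(out, "rate") <- fs
  out
}

.lfp_bands <- function() {
  tibble::tibble(band = c("slow", "delta", "theta", "alpha", "beta", "gamma"),
                 f_lo = c(0, 1, 4, 8, 12, 30),
                 f_hi = c(1, 4, 8, 12, 30, 70))
}

#' Band power table
#'
#' Power and normalized amplitude averaged over the canonical frequency
#' bands: slow 0--1, delta 1--4, theta 4--8, alpha 8--12, beta 12--30,
#' gamma 30--70 Hz. Band edges are half-open (\eqn{[lo, hi)}), assigning an
#' edge bin to the lower band. Both the mean per-bin power (power spectral
#' density summary) and the band-integrated power are reported.
#'
#' @param traces an [lfp_trace()] or list of them.
#' @param window optional \code{c(start, end)} ms analysis window.
#' @return Tibble with \code{band}, \code{f_lo}, \code{f_hi},
#'   \code{mean_power}, \code{total_power}, \code{mean_amplitude}
#'   (peak-normalized); attribute \code{total_power} holds the all-frequency
#'   power sum (equal to the window's mean squared signal).
#' @export
band_power <- function(traces, window = NULL) {
  if (inherits(traces, "lfp_trace")) traces <- list(traces)
  fs <- traces[[1]]$rate
  specs <- lapply(traces, function(tr) {
    x <- tr$samples
    if (!is.null(window)) {
      i1 <- floor(window[1] / 1000 * fs) + 1
      i2 <- floor(window[2] / 1000 * fs)
      if (i1 < 1 || i2 > length(x) || i2 <= i1)
        stop("band_power: window outside the trace")
      x <- x[i1:i2]
    }
    .single_sided_fft(x, fs)
  })
  freq <- specs[[1]]$freq
  if (freq[2] - freq[1] > 0.5 + 1e-9)
    stop("band_power: frequency resolution too coarse for the slow band ",
         "(need <= 0.5 Hz; use a longer window)")
  pow <- Reduce(`+`, lapply(specs, `[[`, "power")) / length(specs)
  amp <- Reduce(`+`, lapply(specs, `[[`, "amplitude")) / length(specs)
  peak <- max(amp)
  namp <- if (peak > 0) amp / peak else amp
  bands <- .lfp_bands()
  bands$mean_power <- NA_real_
  bands$total_power <- NA_real_
  bands$mean_amplitude <- NA_real_
  for (k in seq_len(nrow(bands))) {
    sel <- freq >= bands$f_lo[k] & freq < bands$f_hi[k]
    bands$mean_power[k] <- if (any(sel)) mean(pow[sel]) else 0
    bands$total_power[k] <- if (any(sel)) sum(pow[sel]) else 0
    bands$mean_amplitude[k] <- if (any(sel)) mean(namp[sel]) else 0
  }
  attr(bands, "total_power") <- sum(pow)
  bands
}

#' Short-time Fourier spectrogram
#'
#' STFT power map with a Hann window (1-s default) and configurable
#' overlap.
#'
#' @param trace an [lfp_trace()].
#' @param window_s window length (s).
#' @param overlap fractional overlap in \eqn{[0, 1)}.
#' @return List of class \code{lfp_spectrogram}: \code{time} (window-center
#'   s), \code{freq} (Hz), \code{power} (freq x time matrix).
#' @export
lfp_spectrogram <- function(trace, window_s = 1, overlap = 0.5) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (overlap < 0 || overlap >= 1) stop("lfp_spectrogram: overlap must lie in [0, 1)")
  fs <- trace$rate
  L <- round(window_s * fs)
  x <- trace$samples
  if (L > length(x)) stop("lfp_spectrogram: window longer than the trace")
  hop <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hann
  n_half <- floor(L / 2) + 1
  P <- matrix(0, n_half, length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + L - 1)] * w
    s <- .single_sided_fft(seg, fs)
    P[, k] <- s$power
  }
  structure(list(time = (starts - 1 + L / 2) / fs,
                 freq = (0:(n_half - 1)) * fs / L,
                 power = P),
            class = "lfp_spectrogram")
}

#' @export
print.lfp_spectrogram <- function(x, ...) {
  cat(sprintf("<lfp_spectrogram> %d windows x %d frequencies (0-%.0f Hz)\n",
              length(x$time), length(x$freq), max(x$freq)))
  invisible(x)
}
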