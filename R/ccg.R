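#' Spike cross-correlogram
#'
#' Histogram of spike-time differences \eqn{t_B - t_A} over a symmetric lag
#' window. Bins are centered on multiples of the bin width (a zero-centered
#' bin flanked symmetrically), so reversing the roles of A and B mirrors the
#' correlogram about zero lag exactly.
#'
#' @param spikes_a,spikes_b spike-time vectors (ms).
#' @param bin_ms lag bin width (ms).
#' @param window_ms half-width of the lag window (ms).
#' @return Object of class \code{ccg}: \code{lags} (bin centers, ms),
#'   \code{counts}, \code{bin_ms}, \code{window_ms}, \code{n_a},
#'   \code{n_b}, \code{empty} flag, and the two trains (used by the jitter
#'   surrogate in [detect_monosynaptic()]).
#' @export
cross_correlogram <- function(spikes_a, spikes_b, bin_ms = 0.5,
                              window_ms = 25) {
  if (bin_ms <= 0 || window_ms <= 0 || window_ms < bin_ms)
    stop("cross_correlogram: invalid bin or window")
  K <- round(window_ms / bin_ms)
  n_bins <- 2L * K + 1L
  w <- K * bin_ms
  lags <- (-K:K) * bin_ms
  a <- sort(as.numeric(spikes_a)); b <- sort(as.numeric(spikes_b))
  empty <- length(a) == 0 || length(b) == 0
  counts <- integer(n_bins)
  if (!empty) counts <- .ccg_counts(a, b, bin_ms, w, n_bins)
  structure(list(lags = lags, counts = counts, bin_ms = bin_ms,
                 window_ms = w, n_a = length(a), n_b = length(b),
                 empty = empty, spikes_a = a, spikes_b = b),
            class = "ccg")
}

.ccg_counts <- function(a, b, bin_ms, w, n_bins) {
  hw <- w + bin_ms / 2
  lo <- findInterval(a - hw, b)
  hi <- findInterval(a + hw, b, left.open = TRUE)
  k <- pmax(hi - lo, 0L)
  if (sum(k) == 0) return(integer(n_bins))
  idx <- sequence(k) + rep(lo, k)
  d <- b[idx] - rep(a, k)
  bin <- round(d / bin_ms) + (n_bins + 1L) %/% 2L  # zero lag -> center bin
  bin <- bin[bin >= 1 & bin <= n_bins]
  tabulate(bin, nbins = n_bins)
}

#' @export
print.ccg <- function(x, ...) {
  cat(sprintf("<ccg> %d x %d spikes, +/-%g ms at %g ms bins, %d pairs counted\n",
              x$n_a, x$n_b, x$window_ms, x$bin_ms, sum(x$counts)))
  invisible(x)
}

#' Detect a putative monosynaptic connection
#'
#' Tests for a fast, transient increase (excitatory connection) or decrease
#' (inhibitory) in the cross-correlogram at short positive lags (~2 ms; the
#' detection window is 1--4 ms by default). Significance is assessed against
#' a spike-jitter surrogate: train B is jittered uniformly within +/-
#' \code{jitter_ms} many times, destroying millisecond-scale structure while
#' preserving slow comodulation, and the observed maximum (minimum) bin
#' count over the detection window is compared with the surrogate
#' distribution of the same max (min) statistic -- a familywise-calibrated
#' criterion over the window's bins.
#'
#' @param ccg a [cross_correlogram()] result.
#' @param detect_lag \code{c(lo, hi)} lag window (ms) searched for a peak or
#'   trough.
#' @param alpha two-sided significance level.
#' @param n_surrogates number of jitter surrogates.
#' @param jitter_ms jitter half-width (ms).
#' @param min_counts minimum total correlogram count for a decision.
#' @return List of class \code{ccg_detection}: \code{type}
#'   (\code{"excitatory"}, \code{"inhibitory"}, \code{"none"}, or
#'   \code{"undecidable"}), \code{lag} (ms, of the extreme bin),
#'   \code{score} (standardized deviation of the extreme bin from the
#'   surrogate mean), and the surrogate quantile bounds.
#' @export
detect_monosynaptic <- function(ccg, detect_lag = c(1, 4), alpha = 0.01,
                                n_surrogates = 200, jitter_ms = 10,
                                min_counts = 100) {
  stopifnot(inherits(ccg, "ccg"))
  if (ccg$empty || sum(ccg$counts) < min_counts)
    return(structure(list(type = "undecidable", lag = NA_real_,
                          score = NA_real_, bounds = c(NA, NA)),
                     class = "ccg_detection"))
  sel <- ccg$lags >= detect_lag[1] & ccg$lags <= detect_lag[2]
  if (!any(sel)) stop("detect_monosynaptic: detection window outside the correlogram")
  obs <- ccg$counts[sel]
  obs_max <- max(obs); obs_min <- min(obs)

  a <- ccg$spikes_a
  b <- ccg$spikes_b
  smax <- smin <- numeric(n_surrogates)
  n_bins <- length(ccg$counts)
  for (s in seq_len(n_surrogates)) {
    bj <- b + stats::runif(length(b), -jitter_ms, jitter_ms)
    cs <- .ccg_counts(a, sort(bj), ccg$bin_ms, ccg$window_ms, n_bins)[sel]
    smax[s] <- max(cs); smin[s] <- min(cs)
  }
  up <- stats::quantile(smax, 1 - alpha / 2, names = FALSE, type = 1)
  lo <- stats::quantile(smin, alpha / 2, names = FALSE, type = 1)
  exc <- obs_max > up
  inh <- obs_min < lo
  type <- "none"; lag <- NA_real_; score <- NA_real_
  dev_exc <- (obs_max - mean(smax)) / max(stats::sd(smax), 1e-9)
  dev_inh <- (mean(smin) - obs_min) / max(stats::sd(smin), 1e-9)
  if (exc && (!inh || dev_exc >= dev_inh)) {
    type <- "excitatory"
    lag <- ccg$lags[sel][which.max(obs)]
    score <- dev_exc
  } else if (inh) {
    type <- "inhibitory"
    lag <- ccg$lags[sel][which.min(obs)]
    score <- dev_inh
  }
  structure(list(type = type, lag = lag, score = score, bounds = c(lo, up)),
            class = "ccg_detection")
}

#' @export
print.ccg_detection <- function(x, ...) {
  cat(sprintf("<ccg_detection> %s", x$type))
  if (!is.na(x$lag)) cat(sprintf(" at %.2f ms (score %.1f)", x$lag, x$score))
  cat("\n")
  invisible(x)
}
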