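#' Synthetic-session specification
#'
#' Describes a population of statistically realistic units for generating
#' surrogate recordings with known ground truth: log-normal baseline rates
#' (so a realistic tail falls under the 0.5-Hz analysis floor), a bimodal
#' trough-to-peak distribution straddling the 0.5-ms classification
#' boundary, a slow (seconds-scale) sustained rate modulation during
#' photostimulation of the GPCR-like kind, transient visual responses, and a
#' configurable divisive/subtractive gain change of responses presented
#' during photostimulation.
#'
#' The photostimulation modulation rises as \eqn{1 - e^{-(t-t_{on})/\tau}}
#' and is amplitude-calibrated so that the mean rate over the opto-index
#' POST window equals the rate implied by each unit's target opto-index
#' exactly; the realized opto-index therefore equals the target in
#' expectation, whatever the rise time constant.
#'
#' @param n_excitatory,n_inhibitory units per class.
#' @param rate_meanlog,rate_sdlog log-normal baseline-rate parameters
#'   (defaults: median 4 Hz, sdlog 0.6).
#' @param ttp_mean_e,ttp_mean_i,ttp_sd trough-to-peak mixture components
#'   (ms): broad spikes for excitatory units, narrow for inhibitory.
#' @param oi_e,oi_i target opto-index of each class during
#'   photostimulation (scalar, in (-1, 1)).
#' @param rise_tau_ms time constant of the modulation rise (ms).
#' @param amp_meanlog,amp_sdlog log-normal visual-response amplitude
#'   parameters (Hz added over a 600-ms response window).
#' @param gain_divisive,gain_subtractive multiplicative factor \code{d} and
#'   additive offset \code{s} (Hz) applied to the amplitude of stimuli
#'   presented during photostimulation in the \code{V_ph} condition.
#' @param response_ms visual response duration (ms).
#' @param n_trials trials per condition.
#' @param protocol trial timing; defaults to the experimental layout of
#'   [condition_protocol()] (\code{"experimental"} style).
#' @param lfp_exponent 1/f power-law exponent of the LFP background.
#' @param lfp_oscillations list of \code{list(freq, amp, window)} components
#'   added to generated LFP (window \code{NULL} = whole trace).
#' @param lfp_rate LFP sample rate before preprocessing (Hz).
#' @return A \code{synth_spec} list.
#' @export
synth_spec <- function(n_excitatory = 80, n_inhibitory = 20,
                       rate_meanlog = log(4), rate_sdlog = 0.6,
                       ttp_mean_e = 0.85, ttp_mean_i = 0.25, ttp_sd = 0.05,
                       oi_e = 0.3, oi_i = 0.3, rise_tau_ms = 2000,
                       amp_meanlog = log(6), amp_sdlog = 0.5,
                       gain_divisive = 1, gain_subtractive = 0,
                       response_ms = 600, n_trials = 10,
                       protocol = NULL,
                       lfp_exponent = 1, lfp_oscillations = list(),
                       lfp_rate = 20000) {
  if (is.null(protocol))
    protocol <- list(trial_duration = 21000, stim_onsets = 4000 + 3000 * (0:5),
                     stim_duration = 200, photostim_window = c(5800, 13800))
  if (gain_divisive <= 0) stop("synth_spec: gain_divisive must be > 0")
  if (abs(oi_e) >= 1 || abs(oi_i) >= 1)
    stop("synth_spec: target opto-index must lie in (-1, 1)")
  if (n_excitatory + n_inhibitory < 1) stop("synth_spec: need at least one unit")
  structure(list(n_excitatory = n_excitatory, n_inhibitory = n_inhibitory,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 ttp_mean_e = ttp_mean_e, ttp_mean_i = ttp_mean_i,
                 ttp_sd = ttp_sd, oi_e = oi_e, oi_i = oi_i,
                 rise_tau_ms = rise_tau_ms,
                 amp_meanlog = amp_meanlog, amp_sdlog = amp_sdlog,
                 gain_divisive = gain_divisive,
                 gain_subtractive = gain_subtractive,
                 response_ms = response_ms, n_trials = n_trials,
                 protocol = protocol, lfp_exponent = lfp_exponent,
                 lfp_oscillations = lfp_oscillations, lfp_rate = lfp_rate),
            class = "synth_spec")
}

# modulation rise profile on [on, off], exponential decay after off
.mod_profile <- function(t, on, off, tau) {
  out <- numeric(length(t))
  during <- t >= on & t <= off
  after <- t > off
  out[during] <- 1 - exp(-(t[during] - on) / tau)
  if (any(after)) {
    end_val <- 1 - exp(-(off - on) / tau)
    out[after] <- end_val * exp(-(t[after] - off) / tau)
  }
  out
}

# mean of the rise profile over [w1, w2] subset of [on, off] (closed form)
.mod_window_mean <- function(w1, w2, on, tau) {
  f <- function(t) (t - on) + tau * exp(-(t - on) / tau)
  (f(w2) - f(w1)) / (w2 - w1)
}

#' Generate a synthetic spike session with ground truth
#'
#' Draws a unit population from the spec and samples inhomogeneous-Poisson
#' spike trains for the four condition blocks (\code{S}, \code{V},
#' \code{S_ph}, \code{V_ph}) under the spec's protocol timing. Ground truth
#' (class, baseline, response amplitude, target opto-index, gain
#' parameters) is returned alongside, enabling parameter-recovery tests of
#' the analysis stack.
#'
#' Stimuli whose full response window falls inside the photostimulation
#' window have their amplitude transformed as \code{d * a + s} in
#' \code{V_ph}; other stimuli are unchanged.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @return List with \code{session} (a [spike_session()]) and \code{truth}
#'   (tibble of per-unit ground-truth parameters).
#' @export
generate_session <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(as.integer(seed))
  pr <- spec$protocol
  n_e <- spec$n_excitatory; n_i <- spec$n_inhibitory
  n <- n_e + n_i
  pop <- rep(c("E", "I"), c(n_e, n_i))
  base <- stats::rlnorm(n, spec$rate_meanlog, spec$rate_sdlog)
  ttp <- pmax(stats::rnorm(n, ifelse(pop == "E", spec$ttp_mean_e, spec$ttp_mean_i),
                           spec$ttp_sd), 0.01)
  amp <- stats::rlnorm(n, spec$amp_meanlog, spec$amp_sdlog)
  oi <- ifelse(pop == "E", spec$oi_e, spec$oi_i)

  on <- pr$photostim_window[1]; off <- pr$photostim_window[2]
  post_len <- if (off - on < 6000) (off - on) / 2 else 3000
  post_w <- c(off - post_len, off)
  kappa <- .mod_window_mean(post_w[1], post_w[2], on, spec$rise_tau_ms)
  r_post <- base * (1 + oi) / (1 - oi)
  delta <- (r_post - base) / kappa
  if (any(base + pmin(delta, 0) < 0))
    stop("generate_session: infeasible spec (negative rate after modulation)")

  d <- spec$gain_divisive; s_off <- spec$gain_subtractive
  resp_ms <- spec$response_ms
  in_ph <- pr$stim_onsets >= on & pr$stim_onsets + resp_ms <= off
  amp_ph <- outer(amp, rep(1, length(pr$stim_onsets)))
  amp_ph[, in_ph] <- d * amp_ph[, in_ph] + s_off
  if (any(base + pmin(amp_ph, 0) < 0) || any(base + delta + pmin(amp_ph, 0) < 0))
    stop("generate_session: infeasible spec (negative rate after gain change)")

  rate_fun <- function(t, u, condition) {
    r <- rep(base[u], length(t))
    if (grepl("_ph$", condition))
      r <- r + delta[u] * .mod_profile(t, on, off, spec$rise_tau_ms)
    if (grepl("^V", condition)) {
      a_row <- if (condition == "V_ph") amp_ph[u, ] else rep(amp[u], length(pr$stim_onsets))
      for (si in seq_along(pr$stim_onsets)) {
        o <- pr$stim_onsets[si]
        r <- r + a_row[si] * (t >= o & t < o + resp_ms)
      }
    }
    r
  }
  rate_max <- base + pmax(delta, 0) + pmax(apply(amp_ph, 1, max), amp, 0)

  conds <- c("S", "V", "S_ph", "V_ph")
  spikes <- list()
  trial_id <- 0L
  trials <- list()
  dur <- pr$trial_duration
  for (cc in conds) {
    for (k in seq_len(spec$n_trials)) {
      trial_id <- trial_id + 1L
      trials[[trial_id]] <- data.frame(trial = trial_id, condition = cc)
      for (u in seq_len(n)) {
        n_cand <- stats::rpois(1L, rate_max[u] * dur / 1000)
        if (n_cand == 0) next
        tt <- stats::runif(n_cand, 0, dur)
        keep <- stats::runif(n_cand) < rate_fun(tt, u, cc) / rate_max[u]
        tt <- sort(tt[keep])
        if (length(tt) > 0)
          spikes[[length(spikes) + 1L]] <- data.frame(
            unit_id = u, trial = trial_id, condition = cc, t_ms = tt)
      }
    }
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes) else
    data.frame(unit_id = integer(0), trial = integer(0),
               condition = character(0), t_ms = numeric(0))
  units <- tibble::tibble(unit_id = seq_len(n), population = pop,
                          trough_to_peak = ttp, direct = TRUE)
  truth <- tibble::tibble(unit_id = seq_len(n), population = pop,
                          trough_to_peak = ttp, baseline = base,
                          amplitude = amp, target_oi = oi,
                          gain_divisive = d, gain_subtractive = s_off)
  list(session = spike_session(spikes, units, do.call(rbind, trials), pr),
       truth = truth)
}

#' Generate synthetic LFP traces
#'
#' 1/f-coloured Gaussian noise at the spec's raw sample rate with optional
#' embedded band oscillations (optionally gated to a time window), one trace
#' per trial.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed.
#' @param n_trials number of traces.
#' @param duration_ms trace duration (ms).
#' @param noise_sd standard deviation of the coloured background (uV).
#' @return List of [lfp_trace()] objects.
#' @export
generate_lfp <- function(spec, seed = 1L, n_trials = 1, duration_ms = 10000,
                         noise_sd = 1) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(as.integer(seed))
  fs <- spec$lfp_rate
  n <- round(duration_ms / 1000 * fs)
  t_s <- (seq_len(n) - 1) / fs
  lapply(seq_len(n_trials), function(k) {
    x <- if (noise_sd > 0) {
      w <- stats::rnorm(n)
      sp <- stats::fft(w)
      f <- c(1e-3, seq_len(n - 1)) * fs / n  # guard DC
      f <- pmin(f, fs - f + 1e-9)            # mirror for negative freqs
      sp <- sp / f^(spec$lfp_exponent / 2)
      sp[1] <- 0
      y <- Re(stats::fft(sp, inverse = TRUE)) / n
      y / stats::sd(y) * noise_sd
    } else numeric(n)
    for (osc in spec$lfp_oscillations) {
      comp <- osc$amp * sin(2 * pi * osc$freq * t_s + stats::runif(1, 0, 2 * pi))
      if (!is.null(osc$window)) {
        gate <- t_s * 1000 >= osc$window[1] & t_s * 1000 < osc$window[2]
        comp <- comp * gate
      }
      x <- x + comp
    }
    lfp_trace(x, rate = fs, trial = k)
  })
}

#' Generate a synthetically connected spike-train pair
#'
#' Fixture for cross-correlogram analysis. Train A is homogeneous Poisson.
#' For an excitatory connection, train B is independent background plus a
#' Bernoulli(\code{efficacy}) echo of each A spike at a fixed lag. For an
#' inhibitory connection, B is background with spikes falling in
#' \code{lag + c(-1, 1)} ms after any A spike removed (gated suppression).
#'
#' @param rate_a,rate_b base rates (Hz).
#' @param efficacy echo probability (excitatory mode), in \eqn{[0, 1]}.
#' @param lag synaptic lag (ms).
#' @param duration train duration (ms).
#' @param type \code{"excitatory"} or \code{"inhibitory"}.
#' @param seed integer seed.
#' @return List with sorted spike-time vectors \code{A} and \code{B} (ms).
#' @export
generate_connected_pair <- function(rate_a = 20, rate_b = 20, efficacy = 0.3,
                                    lag = 2, duration = 100000,
                                    type = c("excitatory", "inhibitory"),
                                    seed = 1L) {
  type <- match.arg(type)
  if (efficacy < 0 || efficacy > 1)
    stop("generate_connected_pair: efficacy must lie in [0, 1]")
  set.seed(as.integer(seed))
  a <- make_poisson_input(rate_a, duration)
  b <- make_poisson_input(rate_b, duration)
  if (type == "excitatory") {
    echo <- a[stats::runif(length(a)) < efficacy] + lag
    b <- sort(c(b, echo[echo < duration]))
  } else {
    if (length(a) > 0 && length(b) > 0) {
      lo <- a + lag - 1
      idx <- findInterval(b, lo)
      suppressed <- idx >= 1 & (b - lo[pmax(idx, 1)]) <= 2
      b <- b[!suppressed]
    }
  }
  list(A = a, B = b)
}
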