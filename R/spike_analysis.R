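#' Classify units as putative excitatory or inhibitory
#'
#' Waveform-based classification by the trough-to-peak time of the mean
#' spike waveform: narrow-spiking units (trough-to-peak below the boundary)
#' are putative inhibitory, broad-spiking units putative excitatory. A unit
#' exactly at the boundary is assigned to putative excitatory.
#'
#' @param session a [spike_session()] whose \code{units} table carries
#'   \code{trough_to_peak} (ms).
#' @param boundary classification boundary (ms); default 0.5.
#' @return Tibble with \code{unit_id}, \code{trough_to_peak}, \code{class}
#'   (\code{"putative_inhibitory"} / \code{"putative_excitatory"}).
#' @export
classify_units <- function(session, boundary = 0.5) {
  stopifnot(inherits(session, "spike_session"))
  ttp <- session$units$trough_to_peak
  if (is.null(ttp) || anyNA(ttp))
    stop("classify_units: trough_to_peak metadata unavailable")
  if (any(ttp <= 0)) stop("classify_units: trough_to_peak must be > 0")
  tibble::tibble(
    unit_id = session$units$unit_id,
    trough_to_peak = ttp,
    class = ifelse(ttp < boundary, "putative_inhibitory", "putative_excitatory"))
}

#' Bin spike counts and average across trials
#'
#' Spike counts per unit are binned (200-ms frames by default) within each
#' trial and the binned rate traces averaged across all trials of the same
#' condition. A trailing partial bin is dropped.
#'
#' @param session a [spike_session()] with \code{protocol$trial_duration} set.
#' @param bin_ms bin width (ms).
#' @return Tibble with \code{unit_id}, \code{condition}, \code{time} (bin
#'   start, ms), \code{rate} (Hz, trial-averaged), carrying attributes
#'   \code{bin_ms} and \code{protocol}.
#' @export
bin_and_average <- function(session, bin_ms = 200) {
  stopifnot(inherits(session, "spike_session"))
  dur <- session$protocol$trial_duration
  if (is.null(dur)) stop("bin_and_average: protocol$trial_duration is required")
  n_bins <- floor(dur / bin_ms)
  if (n_bins < 1) stop("bin_and_average: trial shorter than one bin")
  conds <- session$conditions
  if (length(conds) == 0) stop("bin_and_average: session has no trials")
  uids <- sort(unique(session$units$unit_id))
  n_trials <- table(factor(session$trials$condition, levels = conds))
  if (any(n_trials == 0)) stop("bin_and_average: condition without trials")

  sp <- session$spikes
  sp <- sp[sp$t_ms >= 0 & sp$t_ms < n_bins * bin_ms, , drop = FALSE]
  bin <- floor(sp$t_ms / bin_ms)
  counts <- table(factor(sp$unit_id, levels = uids),
                  factor(sp$condition, levels = conds),
                  factor(bin, levels = 0:(n_bins - 1)))
  out <- expand.grid(unit_id = uids, condition = conds,
                     time = (0:(n_bins - 1)) * bin_ms,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rate <- as.vector(counts) / as.vector(n_trials)[match(out$condition, conds)] /
    (bin_ms / 1000)
  out <- tibble::as_tibble(out[order(out$unit_id, out$condition, out$time), ])
  attr(out, "bin_ms") <- bin_ms
  attr(out, "protocol") <- session$protocol
  out
}

# mean of a binned trace over a window [from, to); bins fully inside count
.window_mean <- function(time, rate, from, to, bin_ms) {
  sel <- time >= from - 1e-9 & time + bin_ms <= to + 1e-9
  if (!any(sel)) stop("window [", from, ", ", to, ") contains no complete bin")
  mean(rate[sel])
}

#' Exclude low-rate units
#'
#' Units whose baseline firing rate falls below a floor are removed to avoid
#' floor effects in normalized quantities. Baseline is the spontaneous-
#' condition mean rate over a window at the start of the trial.
#'
#' @param session a [spike_session()].
#' @param floor_hz exclusion floor (Hz); units with baseline < floor are
#'   dropped (a unit exactly at the floor is retained).
#' @param baseline_condition condition used for the baseline (default
#'   \code{"S"}).
#' @param baseline_window \code{c(start, end)} ms; default the first 3 s.
#' @return List with \code{session} (filtered) and \code{report}: tibble of
#'   all units with \code{baseline_rate} and \code{excluded} flag.
#' @export
exclude_low_rate <- function(session, floor_hz = 0.5,
                             baseline_condition = "S",
                             baseline_window = c(0, 3000)) {
  stopifnot(inherits(session, "spike_session"))
  uids <- session$units$unit_id
  if (length(uids) == 0) {
    return(list(session = session,
                report = tibble::tibble(unit_id = integer(0),
                                        baseline_rate = numeric(0),
                                        excluded = logical(0))))
  }
  trials_b <- session$trials$trial[session$trials$condition == baseline_condition]
  if (length(trials_b) == 0)
    stop("exclude_low_rate: no trials in baseline condition '", baseline_condition, "'")
  sp <- session$spikes
  sel <- sp$trial %in% trials_b & sp$t_ms >= baseline_window[1] &
    sp$t_ms < baseline_window[2]
  cnt <- table(factor(sp$unit_id[sel], levels = uids))
  base <- as.vector(cnt) / length(trials_b) / diff(baseline_window) * 1000
  keep <- base >= floor_hz
  report <- tibble::tibble(unit_id = uids, baseline_rate = base, excluded = !keep)
  kept_ids <- uids[keep]
  out <- session
  out$units <- session$units[keep, , drop = FALSE]
  out$spikes <- sp[sp$unit_id %in% kept_ids, , drop = FALSE]
  list(session = out, report = report)
}

#' Normalize spontaneous-activity traces
#'
#' Each unit's spontaneous traces (with and without photostimulation) are
#' divided by that unit's mean spontaneous rate over the first 3 s of the
#' control (\code{S}) condition, putting all units on a common relative
#' scale.
#'
#' @param traces binned traces from [bin_and_average()].
#' @param window normalization window \code{c(start, end)} ms in the S trace.
#' @param conditions conditions to normalize (default \code{S} and
#'   \code{S_ph}).
#' @return Traces tibble of the same shape restricted to \code{conditions},
#'   with \code{rate} now in units of the S baseline; attribute
#'   \code{divisors} stores the per-unit baselines.
#' @export
normalize_spontaneous <- function(traces, window = c(0, 3000),
                                  conditions = c("S", "S_ph")) {
  bin_ms <- attr(traces, "bin_ms")
  if (!"S" %in% traces$condition)
    stop("normalize_spontaneous: S-condition trace required")
  uids <- unique(traces$unit_id)
  div <- vapply(uids, function(u) {
    tr <- traces[traces$unit_id == u & traces$condition == "S", ]
    .window_mean(tr$time, tr$rate, window[1], window[2], bin_ms)
  }, 0)
  if (any(div <= 0))
    stop("normalize_spontaneous: zero baseline divisor for unit(s) ",
         paste(uids[div <= 0], collapse = ", "),
         " (apply exclude_low_rate first)")
  out <- traces[traces$condition %in% conditions, , drop = FALSE]
  out$rate <- out$rate / div[match(out$unit_id, uids)]
  attr(out, "bin_ms") <- bin_ms
  attr(out, "protocol") <- attr(traces, "protocol")
  attr(out, "divisors") <- stats::setNames(div, uids)
  out
}

#' Normalize visually evoked traces
#'
#' For each unit, the mean rate over the 1 s preceding the first visual
#' stimulus is subtracted from its evoked traces (\code{V}, \code{V_ph});
#' both are then divided by the first-stimulus response amplitude of the
#' control condition \code{V} (mean of the baseline-subtracted trace over the
#' 600 ms after the first stimulus onset). The control first response is 1 by
#' construction. Units whose control amplitude is not positive cannot be
#' normalized and are dropped with a flag.
#'
#' @param traces binned traces from [bin_and_average()].
#' @param stim_onsets stimulus onset times (ms); default from the traces'
#'   protocol attribute.
#' @param amp_ms amplitude window after onset (ms).
#' @param base_ms baseline window before the first onset (ms).
#' @return List with \code{traces} (normalized \code{V}/\code{V_ph} tibble)
#'   and \code{dropped} (unit ids with non-positive control amplitude).
#' @export
normalize_evoked <- function(traces, stim_onsets = NULL, amp_ms = 600,
                             base_ms = 1000) {
  bin_ms <- attr(traces, "bin_ms")
  proto <- attr(traces, "protocol")
  if (is.null(stim_onsets)) stim_onsets <- proto$stim_onsets
  if (is.null(stim_onsets)) stop("normalize_evoked: stimulus onsets unknown")
  if (!all(c("V") %in% traces$condition))
    stop("normalize_evoked: V-condition trace required")
  on1 <- stim_onsets[1]
  conds <- intersect(c("V", "V_ph"), unique(traces$condition))
  out <- traces[traces$condition %in% conds, , drop = FALSE]
  uids <- unique(out$unit_id)
  amp <- numeric(length(uids))
  for (k in seq_along(uids)) {
    u <- uids[k]
    for (cc in conds) {
      tr <- out$unit_id == u & out$condition == cc
      b <- .window_mean(out$time[tr], out$rate[tr], on1 - base_ms, on1, bin_ms)
      out$rate[tr] <- out$rate[tr] - b
    }
    trv <- out$unit_id == u & out$condition == "V"
    amp[k] <- .window_mean(out$time[trv], out$rate[trv], on1, on1 + amp_ms, bin_ms)
  }
  dropped <- uids[amp <= 0]
  keep <- !(out$unit_id %in% dropped)
  out <- out[keep, , drop = FALSE]
  out$rate <- out$rate / amp[match(out$unit_id, uids)][keep]
  attr(out, "bin_ms") <- bin_ms
  attr(out, "protocol") <- proto
  list(traces = out, dropped = dropped)
}

#' Opto-index
#'
#' Normalized photostimulation effect
#' \deqn{OI = \frac{POST - PRE}{POST + PRE},}
#' bounded in \eqn{[-1, 1]}: +1 an infinite increase from baseline, 0 no
#' change, -1 complete silencing. Undefined (NA) when both rates are zero.
#'
#' @param pre,post firing rates (Hz) before and during photostimulation;
#'   vectorised.
#' @return Numeric vector of opto-index values.
#' @export
opto_index <- function(pre, post) {
  if (any(pre < 0 | post < 0, na.rm = TRUE)) stop("opto_index: rates must be >= 0")
  s <- pre + post
  ifelse(s > 0, (post - pre) / s, NA_real_)
}

#' Per-unit opto-index from spontaneous photostimulation traces
#'
#' PRE is each unit's mean rate over the interval after trial start (3 s by
#' default), POST the mean over the last part of the photostimulation
#' interval (its last 3 s, or half the photostimulation span if that is
#' shorter than 6 s).
#'
#' @param traces binned traces from [bin_and_average()] containing the
#'   photostimulated spontaneous condition.
#' @param condition condition to evaluate (default \code{"S_ph"}).
#' @param pre_window \code{c(start, end)} ms; default \code{c(0, 3000)},
#'   clipped to the photostimulation onset.
#' @param post_window \code{c(start, end)} ms; default derived from the
#'   protocol's photostimulation window as described above.
#' @return Tibble with \code{unit_id}, \code{pre_rate}, \code{post_rate},
#'   \code{oi} (NA where undefined).
#' @export
compute_oi <- function(traces, condition = "S_ph", pre_window = NULL,
                       post_window = NULL) {
  bin_ms <- attr(traces, "bin_ms")
  proto <- attr(traces, "protocol")
  if (!condition %in% traces$condition)
    stop("compute_oi: condition '", condition, "' not present")
  pw <- proto$photostim_window
  if (is.null(post_window)) {
    if (is.null(pw)) stop("compute_oi: post_window or protocol$photostim_window required")
    len <- if (pw[2] - pw[1] < 6000) (pw[2] - pw[1]) / 2 else 3000
    post_window <- c(pw[2] - len, pw[2])
  }
  if (is.null(pre_window)) {
    pre_end <- if (!is.null(pw)) min(3000, pw[1]) else 3000
    pre_window <- c(0, pre_end)
  }
  tr <- traces[traces$condition == condition, , drop = FALSE]
  uids <- unique(tr$unit_id)
  pre <- post <- numeric(length(uids))
  for (k in seq_along(uids)) {
    x <- tr[tr$unit_id == uids[k], ]
    pre[k] <- .window_mean(x$time, x$rate, pre_window[1], pre_window[2], bin_ms)
    post[k] <- .window_mean(x$time, x$rate, post_window[1], post_window[2], bin_ms)
  }
  tibble::tibble(unit_id = uids, pre_rate = pre, post_rate = post,
                 oi = opto_index(pre, post))
}

#' Visual response magnitude
#'
#' Magnitude of the response to each stimulus: mean rate over the 600 ms
#' after stimulus onset minus the mean rate over the 1 s before onset.
#' Operates on binned (raw or normalized) traces.
#'
#' @param traces binned traces from [bin_and_average()] (or normalized ones).
#' @param stim_onsets onset times (ms); default from the protocol attribute.
#' @param conditions conditions to evaluate (default \code{V}, \code{V_ph}
#'   where present).
#' @param amp_ms,base_ms amplitude / baseline window lengths (ms).
#' @return Tibble with \code{unit_id}, \code{condition}, \code{stim}
#'   (1-based stimulus number), \code{magnitude}.
#' @export
response_magnitude <- function(traces, stim_onsets = NULL,
                               conditions = NULL, amp_ms = 600,
                               base_ms = 1000) {
  bin_ms <- attr(traces, "bin_ms")
  proto <- attr(traces, "protocol")
  if (is.null(stim_onsets)) stim_onsets <- proto$stim_onsets
  if (is.null(stim_onsets)) stop("response_magnitude: stimulus onsets unknown")
  if (is.null(conditions))
    conditions <- intersect(c("V", "V_ph"), unique(traces$condition))
  tmax <- max(traces$time) + bin_ms
  if (any(stim_onsets - base_ms < -1e-9) || any(stim_onsets + amp_ms > tmax + 1e-9))
    stop("response_magnitude: amplitude/baseline windows fall outside the trace")
  out <- list()
  for (cc in conditions) {
    tr <- traces[traces$condition == cc, , drop = FALSE]
    for (u in unique(tr$unit_id)) {
      x <- tr[tr$unit_id == u, ]
      for (s in seq_along(stim_onsets)) {
        on <- stim_onsets[s]
        amp <- .window_mean(x$time, x$rate, on, on + amp_ms, bin_ms)
        base <- .window_mean(x$time, x$rate, on - base_ms, on, bin_ms)
        out[[length(out) + 1L]] <- tibble::tibble(
          unit_id = u, condition = cc, stim = s, magnitude = amp - base)
      }
    }
  }
  do.call(rbind, out)
}

#' Stack magnitudes into gain-regression observations
#'
#' Builds the observation table for [fit_gain_regression()]: per unit and
#' condition, \code{r_pre} is the magnitude of the pre-photostimulation
#' stimulus (#1) and \code{r_post} the mean magnitude of the stimuli
#' presented during photostimulation (#2--4 by default); \code{ph} is 0 for
#' the control condition \code{V} and 1 for \code{V_ph}.
#'
#' @param magnitudes tibble from [response_magnitude()].
#' @param post_stims stimulus numbers averaged for \code{r_post}.
#' @return Tibble with \code{unit_id}, \code{ph}, \code{r_pre}, \code{r_post}.
#' @export
gain_observations <- function(magnitudes, post_stims = 2:4) {
  stopifnot(all(c("unit_id", "condition", "stim", "magnitude") %in% names(magnitudes)))
  out <- list()
  for (cc in intersect(c("V", "V_ph"), unique(magnitudes$condition))) {
    m <- magnitudes[magnitudes$condition == cc, ]
    for (u in unique(m$unit_id)) {
      x <- m[m$unit_id == u, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        unit_id = u, ph = as.integer(cc == "V_ph"),
        r_pre = x$magnitude[x$stim == 1],
        r_post = mean(x$magnitude[x$stim %in% post_stims]))
    }
  }
  do.call(rbind, out)
}

#' Divisive/subtractive gain regression
#'
#' Ordinary least squares fit of
#' \deqn{r_{post} = \beta_1 + \beta_2 r_{pre} + \beta_3 \, ph +
#'   \beta_4 \, ph \cdot r_{pre},}
#' where \eqn{ph \in \{0, 1\}} marks photostimulation. \eqn{\beta_3} captures
#' an additive (subtractive) shift of the control relation, \eqn{\beta_4} a
#' slope (divisive) change; the fractional slope change is
#' \eqn{\beta_4 / \beta_2}. Inputs are normalized to the maximum observed
#' value across the pooled data before fitting (so coefficients are scale
#' free), unless \code{normalize = FALSE}.
#'
#' @param r_pre,r_post magnitude firing rates before / during
#'   photostimulation, stacked across both conditions.
#' @param ph 0/1 photostimulation indicator, same length.
#' @param normalize divide all rates by the pooled maximum first.
#' @return Object of class \code{gain_fit}: list with \code{coefficients}
#'   (beta1..beta4), \code{se}, \code{slope_change} (beta4/beta2),
#'   \code{n}, \code{subtractive}/\code{divisive} p-values, and the
#'   underlying \code{lm} fit.
#' @export
fit_gain_regression <- function(r_pre, r_post, ph, normalize = TRUE) {
  if (length(r_pre) != length(r_post) || length(r_pre) != length(ph))
    stop("fit_gain_regression: inputs must have equal length")
  if (!all(ph %in% c(0, 1))) stop("fit_gain_regression: ph must be 0/1")
  if (length(unique(ph)) < 2) stop("fit_gain_regression: both ph levels required")
  if (sum(stats::complete.cases(r_pre, r_post, ph)) < 5)
    stop("fit_gain_regression: too few observations")
  if (normalize) {
    mx <- max(abs(c(r_pre, r_post)))
    if (mx <= 0) stop("fit_gain_regression: degenerate (all-zero) inputs")
    r_pre <- r_pre / mx; r_post <- r_post / mx
  }
  ph <- as.numeric(ph)
  fit <- stats::lm(r_post ~ r_pre + ph + r_pre:ph)
  sm <- summary(fit)
  if (fit$rank < 4) stop("fit_gain_regression: rank-deficient design")
  b <- stats::setNames(coef(fit), c("beta1", "beta2", "beta3", "beta4"))
  se <- stats::setNames(sm$coefficients[, "Std. Error"], names(b))
  pv <- stats::setNames(sm$coefficients[, "Pr(>|t|)"], names(b))
  structure(list(coefficients = b, se = se, p_values = pv,
                 slope_change = unname(b["beta4"] / b["beta2"]),
                 n = length(r_pre), fit = fit),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  b <- x$coefficients; se <- x$se
  cat("<gain_fit> n =", x$n, "\n")
  for (k in 1:4)
    cat(sprintf("  %s = %8.4f +/- %.4f\n", names(b)[k], b[k], se[k]))
  cat(sprintf("  slope change beta4/beta2 = %.1f%%\n", 100 * x$slope_change))
  invisible(x)
}

#' Photostimulation-related response component
#'
#' Pointwise difference between the photostimulated and control evoked
#' traces (V_ph - V) per unit, isolating the photostimulation-related
#' component over time.
#'
#' @param traces binned (typically normalized) traces containing \code{V}
#'   and \code{V_ph}.
#' @return Tibble with \code{unit_id}, \code{time}, \code{diff}.
#' @export
photostim_component <- function(traces) {
  if (!all(c("V", "V_ph") %in% traces$condition))
    stop("photostim_component: V and V_ph traces required")
  v <- traces[traces$condition == "V", ]
  vp <- traces[traces$condition == "V_ph", ]
  v <- v[order(v$unit_id, v$time), ]
  vp <- vp[order(vp$unit_id, vp$time), ]
  if (nrow(v) != nrow(vp) || any(v$unit_id != vp$unit_id) ||
      any(abs(v$time - vp$time) > 1e-9))
    stop("photostim_component: V and V_ph bins are misaligned")
  tibble::tibble(unit_id = v$unit_id, time = v$time, diff = vp$rate - v$rate)
}
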