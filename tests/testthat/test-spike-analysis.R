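test_that("waveform classification applies the trough-to-peak boundary", {
  ses <- spike_session(
    data.frame(unit_id = 1L, trial = 1L, condition = "S", t_ms = 10),
    units = data.frame(unit_id = 1:4,
                       trough_to_peak = c(0.3, 0.8, 0.5, 0.49)),
    trials = data.frame(trial = 1L, condition = "S"),
    protocol = list(trial_duration = 1000))
  cl <- classify_units(ses)
  expect_equal(cl$class, c("putative_inhibitory", "putative_excitatory",
                           "putative_excitatory",   # boundary tie-break
                           "putative_inhibitory"))
  ses$units$trough_to_peak <- NULL
  expect_error(classify_units(ses), "unavailable")
})

test_that("binning and averaging recover constructed rates", {
  # regular 5-Hz unit: every bin reads 5 Hz
  tr <- bin_and_average(regular_session(hz = 5, trial_ms = 2000), bin_ms = 200)
  expect_equal(nrow(tr), 10)
  expect_true(all(tr$rate == 5))
  # one spike in one 200-ms bin of a single trial: 5 Hz there, 0 elsewhere
  ses <- spike_session(
    data.frame(unit_id = 1L, trial = 1L, condition = "S", t_ms = 250),
    units = data.frame(unit_id = 1L, trough_to_peak = 0.8),
    trials = data.frame(trial = 1L, condition = "S"),
    protocol = list(trial_duration = 1000))
  tr1 <- bin_and_average(ses, bin_ms = 200)
  expect_equal(tr1$rate, c(0, 5, 0, 0, 0))
  # trial averaging: 0 and 2 spikes in a bin across two trials -> 5 Hz
  ses2 <- spike_session(
    data.frame(unit_id = 1L, trial = 2L, condition = "S", t_ms = c(250, 260)),
    units = data.frame(unit_id = 1L, trough_to_peak = 0.8),
    trials = data.frame(trial = 1:2, condition = "S"),
    protocol = list(trial_duration = 1000))
  tr2 <- bin_and_average(ses2, bin_ms = 200)
  expect_equal(tr2$rate[2], 5)
  # trailing partial bin is dropped
  ses3 <- regular_session(hz = 5, trial_ms = 2100)
  expect_equal(max(bin_and_average(ses3, bin_ms = 200)$time), 1800)
})

test_that("analysis output is invariant to unit and trial order", {
  sp <- synth_spec(n_excitatory = 6, n_inhibitory = 3, n_trials = 2)
  ses <- generate_session(sp, seed = 8)$session
  shuf <- ses
  set.seed(1)
  shuf$spikes <- shuf$spikes[sample(nrow(shuf$spikes)), ]
  tr_a <- bin_and_average(ses)
  tr_b <- bin_and_average(shuf)
  expect_equal(tr_a, tr_b)
  oi_a <- compute_oi(tr_a)
  oi_b <- compute_oi(tr_b)
  expect_equal(oi_a, oi_b)
})

test_that("low-rate exclusion applies a strict floor on the S baseline", {
  mk <- function(uid, times) data.frame(unit_id = uid, trial = 1L,
                                        condition = "S", t_ms = times)
  ses <- spike_session(
    rbind(mk(1L, 100),                  # 1 spike in the 3-s baseline = 1/3 Hz
          mk(2L, c(500, 1500, 2500))),  # 3 spikes in 3 s = 1 Hz
    units = data.frame(unit_id = 1:2, trough_to_peak = c(0.8, 0.8)),
    trials = data.frame(trial = 1L, condition = "S"),
    protocol = list(trial_duration = 5000))
  ex <- exclude_low_rate(ses, floor_hz = 0.5)
  expect_equal(ex$report$baseline_rate, c(1 / 3, 1))
  expect_true(ex$report$excluded[1])
  expect_false(ex$report$excluded[2])
  expect_equal(ex$session$units$unit_id, 2L)
  # boundary: exactly at the floor is retained ("< floor" excluded)
  ses2 <- spike_session(
    mk(1L, c(400, 1400)),  # 2 spikes in 3 s = 2/3 Hz, exactly at the floor
    units = data.frame(unit_id = 1L, trough_to_peak = 0.8),
    trials = data.frame(trial = 1L, condition = "S"),
    protocol = list(trial_duration = 5000))
  ex2 <- exclude_low_rate(ses2, floor_hz = 2 / 3)
  expect_false(ex2$report$excluded)
  # empty session passes through with an empty report
  ses_empty <- spike_session(
    data.frame(unit_id = integer(0), trial = integer(0),
               condition = character(0), t_ms = numeric(0)),
    units = data.frame(unit_id = integer(0)),
    trials = data.frame(trial = 1L, condition = "S"),
    protocol = list(trial_duration = 1000))
  ex3 <- exclude_low_rate(ses_empty)
  expect_equal(nrow(ex3$report), 0)
})

test_that("spontaneous normalization divides by the S baseline", {
  time <- seq(0, 9800, by = 200)
  proto <- list(trial_duration = 10000, photostim_window = c(3000, 9000))
  df <- rbind(
    data.frame(unit_id = 1L, condition = "S", time = time, rate = 4),
    data.frame(unit_id = 1L, condition = "S_ph", time = time,
               rate = trace_values(time, list(c(0, 3000, 4), c(3000, 10000, 8)))))
  tr <- manual_traces(df, protocol = proto)
  nt <- normalize_spontaneous(tr)
  expect_true(all(nt$rate[nt$condition == "S"] == 1))
  sph <- nt$rate[nt$condition == "S_ph"]
  expect_equal(sort(unique(sph)), c(1, 2))
  # pointwise ratio S_ph/S is preserved by the common divisor
  raw_ratio <- df$rate[df$condition == "S_ph"] / df$rate[df$condition == "S"]
  norm_ratio <- nt$rate[nt$condition == "S_ph"] / nt$rate[nt$condition == "S"]
  expect_equal(norm_ratio, raw_ratio)
  # zero baseline guards
  df0 <- df; df0$rate[df0$condition == "S"] <- 0
  expect_error(normalize_spontaneous(manual_traces(df0, protocol = proto)),
               "divisor")
})

test_that("evoked normalization sets the control first response to one", {
  time <- seq(0, 9800, by = 200)
  proto <- list(trial_duration = 10000, stim_onsets = c(2000, 5000),
                photostim_window = c(3800, 9800))
  resp <- function(amp) trace_values(time, list(c(0, 10000, 2),
                                                c(2000, 2600, 2 + amp),
                                                c(5000, 5600, 2 + amp)))
  # V_ph responses scaled by 0.8 with equal baseline
  df <- rbind(
    data.frame(unit_id = 1L, condition = "V", time = time, rate = resp(5)),
    data.frame(unit_id = 1L, condition = "V_ph", time = time, rate = resp(4)))
  ne <- normalize_evoked(manual_traces(df, protocol = proto))
  v <- ne$traces[ne$traces$condition == "V", ]
  first_amp <- mean(v$rate[v$time >= 2000 & v$time < 2600])
  expect_equal(first_amp, 1)
  vph <- ne$traces[ne$traces$condition == "V_ph", ]
  expect_equal(mean(vph$rate[vph$time >= 5000 & vph$time < 5600]), 0.8)
  # identical V_ph and V give a zero difference trace
  df2 <- df; df2$rate[df2$condition == "V_ph"] <- resp(5)
  ne2 <- normalize_evoked(manual_traces(df2, protocol = proto))
  dtr <- photostim_component(ne2$traces)
  expect_true(all(abs(dtr$diff) < 1e-12))
  # non-positive control amplitude drops the unit with a flag
  df3 <- df; df3$rate[df3$condition == "V"] <- 2
  ne3 <- normalize_evoked(manual_traces(df3, protocol = proto))
  expect_equal(ne3$dropped, 1L)
  expect_equal(nrow(ne3$traces), 0)
})

test_that("opto-index matches the defining identities and windows", {
  expect_equal(opto_index(0, 3), 1)
  expect_equal(opto_index(2, 2), 0)
  expect_equal(opto_index(3, 0), -1)
  expect_equal(opto_index(4, 2), -1 / 3)
  expect_true(is.na(opto_index(0, 0)))
  expect_error(opto_index(-1, 2), ">= 0")
  # antisymmetry and bounds over a grid
  set.seed(1)
  pre <- runif(200, 0, 20); post <- runif(200, 0, 20)
  oi <- opto_index(pre, post)
  expect_true(all(abs(oi) <= 1))
  expect_equal(oi, -opto_index(post, pre))
  # windowed version: PRE over first 3 s, POST over last 3 s of photostim
  time <- seq(0, 20800, by = 200)
  proto <- list(trial_duration = 21000, photostim_window = c(5800, 13800))
  df <- data.frame(unit_id = 1L, condition = "S_ph", time = time,
                   rate = trace_values(time, list(c(0, 5800, 2),
                                                  c(5800, 13800, 6))))
  res <- compute_oi(manual_traces(df, protocol = proto))
  expect_equal(res$pre_rate, 2)
  expect_equal(res$post_rate, 6)
  expect_equal(res$oi, 0.5)
})

test_that("response magnitude is amplitude minus pre-stimulus baseline", {
  time <- seq(0, 5800, by = 200)
  proto <- list(trial_duration = 6000, stim_onsets = 2000)
  flat <- data.frame(unit_id = 1L, condition = "V", time = time, rate = 3)
  m0 <- response_magnitude(manual_traces(flat, protocol = proto))
  expect_equal(m0$magnitude, 0)
  # 10-Hz boxcar covering the full 600-ms window on a 2-Hz baseline
  box <- data.frame(unit_id = 1L, condition = "V", time = time,
                    rate = trace_values(time, list(c(0, 6000, 2), c(2000, 2600, 10))))
  m1 <- response_magnitude(manual_traces(box, protocol = proto))
  expect_equal(m1$magnitude, 8)
  # response confined to the first 200 ms: window-average arithmetic
  short <- data.frame(unit_id = 1L, condition = "V", time = time,
                      rate = trace_values(time, list(c(0, 6000, 2), c(2000, 2200, 10))))
  m2 <- response_magnitude(manual_traces(short, protocol = proto))
  expect_equal(m2$magnitude, (10 * 0.2 + 2 * 0.4) / 0.6 - 2)
  # windows must fit in the trace
  expect_error(response_magnitude(manual_traces(flat, protocol = proto),
                                  stim_onsets = 500), "outside")
})

test_that("gain regression recovers exact constructed coefficients", {
  r_pre <- seq(0.1, 1, length.out = 20)
  # divisive-only change: slope 1.0 -> 0.84
  fit <- suppressWarnings(   # noiseless fixture: lm flags the perfect fit
    fit_gain_regression(c(r_pre, r_pre),
                        c(0.5 + 1.0 * r_pre, 0.5 + 0.84 * r_pre),
                        ph = rep(c(0, 1), each = 20), normalize = FALSE))
  expect_equal(unname(fit$coefficients), c(0.5, 1.0, 0, -0.16), tolerance = 1e-10)
  expect_equal(fit$slope_change, -0.16, tolerance = 1e-10)
  # no photostimulation effect
  fit2 <- suppressWarnings(
    fit_gain_regression(c(r_pre, r_pre), c(2 * r_pre, 2 * r_pre),
                        ph = rep(c(0, 1), each = 20), normalize = FALSE))
  expect_equal(unname(fit2$coefficients[3:4]), c(0, 0), tolerance = 1e-10)
  # purely subtractive shift
  fit3 <- suppressWarnings(
    fit_gain_regression(c(r_pre, r_pre), c(r_pre, r_pre - 0.3),
                        ph = rep(c(0, 1), each = 20), normalize = FALSE))
  expect_equal(unname(fit3$coefficients[3]), -0.3, tolerance = 1e-10)
  expect_equal(unname(fit3$coefficients[4]), 0, tolerance = 1e-10)
  expect_error(fit_gain_regression(r_pre, r_pre, rep(0, 20)), "both ph levels")
})

test_that("photostimulation component subtracts aligned traces", {
  time <- seq(0, 1800, by = 200)
  df <- rbind(data.frame(unit_id = 1L, condition = "V", time = time, rate = 1),
              data.frame(unit_id = 1L, condition = "V_ph", time = time, rate = 1.3))
  d <- photostim_component(manual_traces(df))
  expect_true(all(abs(d$diff - 0.3) < 1e-12))
  # divisive-only gain change dips at stimulus times on a flat background
  proto <- list(trial_duration = 2000, stim_onsets = c(400, 1200))
  resp <- function(gain) trace_values(time, list(c(0, 2000, 2),
                                                 c(400, 1000, 2 + gain * 6),
                                                 c(1200, 1800, 2 + gain * 6)))
  df2 <- rbind(
    data.frame(unit_id = 1L, condition = "V", time = time, rate = resp(1)),
    data.frame(unit_id = 1L, condition = "V_ph", time = time, rate = resp(0.7)))
  d2 <- photostim_component(manual_traces(df2, protocol = proto))
  in_resp <- d2$time >= 400 & d2$time < 1000 | d2$time >= 1200 & d2$time < 1800
  expect_true(all(d2$diff[in_resp] < -1e-9))
  expect_true(all(abs(d2$diff[!in_resp]) < 1e-12))
  # misaligned bins error
  df3 <- df; df3$time[df3$condition == "V_ph"] <- time + 100
  expect_error(photostim_component(manual_traces(df3)), "misaligned")
})

test_that("sessions round-trip through the columnar format", {
  sp <- synth_spec(n_excitatory = 4, n_inhibitory = 2, n_trials = 2)
  ses <- generate_session(sp, seed = 3)$session
  dir <- file.path(tempdir(), "sergain-session-test")
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$spikes$t_ms, ses$spikes$t_ms)
  expect_equal(back$trials$condition, ses$trials$condition)
  expect_equal(back$protocol$photostim_window, ses$protocol$photostim_window)
  expect_equal(bin_and_average(back), bin_and_average(ses),
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
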