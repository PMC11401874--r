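# shared fixtures built in code

# single isolated unit with no background drive
quiet_single_unit <- function() {
  build_network(network_params(N_e = 1, N_i = 0, nu_bkg_e = 0, nu_bkg_i = 0),
                seed = 1)
}

# hand-built session: one unit firing a regular train at `hz` in every trial
regular_session <- function(hz = 5, n_trials = 2, trial_ms = 2000,
                            condition = "S", ttp = 0.8) {
  times <- seq(0, trial_ms - 1e-6, by = 1000 / hz)
  spikes <- do.call(rbind, lapply(seq_len(n_trials), function(k)
    data.frame(unit_id = 1L, trial = k, condition = condition, t_ms = times)))
  spike_session(spikes,
                units = data.frame(unit_id = 1L, trough_to_peak = ttp),
                trials = data.frame(trial = seq_len(n_trials),
                                    condition = condition),
                protocol = list(trial_duration = trial_ms))
}

# binned-trace tibble assembled directly (bypassing spike sampling) so
# normalization/magnitude arithmetic can be checked against exact values
manual_traces <- function(df, bin_ms = 200, protocol = list()) {
  out <- tibble::as_tibble(df)
  attr(out, "bin_ms") <- bin_ms
  attr(out, "protocol") <- protocol
  out
}

# piecewise-constant trace values on a bin grid
trace_values <- function(time, segments) {
  # segments: list of c(from, to, value); later entries override
  v <- numeric(length(time))
  for (s in segments) v[time >= s[1] & time < s[2]] <- s[3]
  v
}

# fine-step reference integrator for one neuron receiving a single
# excitatory alpha-conductance event at t0 (independent of the C++ path)
reference_single_event_peak <- function(np, J, t0, t_end, dt = 0.001) {
  steps <- round(t_end / dt)
  v <- np$E_L
  vmax <- v
  for (s in seq_len(steps)) {
    t <- s * dt
    g <- alpha_kernel(t - t0, J, np$tau_e)
    dv <- (-np$g_L * (v - np$E_L) - g * (v - np$E_e)) / np$C
    v <- v + dt * dv
    if (v > vmax) vmax <- v
  }
  vmax
}
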