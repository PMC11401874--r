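#' Condition protocol
#'
#' Timing of one recording condition. Conditions follow the four-block
#' scheme: \code{S} spontaneous, \code{V} visually evoked, and their
#' photostimulated counterparts \code{S_ph} / \code{V_ph}.
#'
#' Two stock layouts are provided. \code{"experimental"} mirrors the in-vivo
#' protocol: six 200-ms stimuli at a 3-s inter-stimulus interval (first onset
#' 4 s into the trial) and an 8-s photostimulation starting 1.8 s after the
#' first stimulus onset. \code{"model"} is the compact layout used for
#' network simulations: a 1-s settling period (discarded), 2 s pre-stimulus,
#' one 500-ms stimulus, 1 s post, with the perturbation on for the whole
#' analyzed span in photostimulated conditions.
#'
#' @param condition one of \code{"S"}, \code{"V"}, \code{"S_ph"},
#'   \code{"V_ph"}.
#' @param style \code{"model"} or \code{"experimental"} stock timing.
#' @param n_trials trials per condition.
#' @param trial_duration,stim_onsets,stim_duration,photostim_window,settle
#'   overrides of the stock layout (ms; \code{settle} only used by the
#'   simulator and discarded from sessions).
#' @return A \code{condition_protocol} list.
#' @export
condition_protocol <- function(condition = c("S", "V", "S_ph", "V_ph"),
                               style = c("model", "experimental"),
                               n_trials = 5,
                               trial_duration = NULL, stim_onsets = NULL,
                               stim_duration = NULL, photostim_window = NULL,
                               settle = NULL) {
  condition <- match.arg(condition)
  style <- match.arg(style)
  is_ph <- grepl("_ph$", condition)
  is_v <- grepl("^V", condition)
  if (style == "model") {
    def <- list(trial_duration = 3500, stim_onsets = 2000, stim_duration = 500,
                photostim_window = c(0, 3500), settle = 1000)
  } else {
    def <- list(trial_duration = 21000, stim_onsets = 4000 + 3000 * (0:5),
                stim_duration = 200, photostim_window = c(5800, 13800),
                settle = 0)
  }
  p <- list(
    condition = condition,
    trial_duration = if (is.null(trial_duration)) def$trial_duration else trial_duration,
    stim_onsets = if (!is_v) NULL else if (is.null(stim_onsets)) def$stim_onsets else stim_onsets,
    stim_duration = if (is.null(stim_duration)) def$stim_duration else stim_duration,
    photostim_window = if (!is_ph && is.null(photostim_window)) NULL
                       else if (is.null(photostim_window) && is_ph) def$photostim_window
                       else photostim_window,
    settle = if (is.null(settle)) def$settle else settle,
    n_trials = n_trials)
  if (is_ph && is.null(p$photostim_window))
    stop("condition_protocol: photostimulated condition requires a photostim window")
  if (!is_ph && !is.null(p$photostim_window))
    stop("condition_protocol: photostim window set on a non-photostimulated condition")
  if (is_v) {
    if (any(p$stim_onsets < 0) ||
        any(p$stim_onsets + p$stim_duration > p$trial_duration))
      stop("condition_protocol: stimulus epochs must lie inside the trial")
  }
  if (!is.null(p$photostim_window) &&
      (p$photostim_window[1] < 0 || p$photostim_window[2] > p$trial_duration))
    stop("condition_protocol: photostim window must lie inside the trial")
  structure(p, class = "condition_protocol")
}

# deterministic waveform metadata so simulated sessions flow through the
# waveform classifier: broad spikes for E units, narrow for I units
.units_from_network <- function(network, activated) {
  n <- length(network$population)
  tibble::tibble(
    unit_id = seq_len(n),
    population = as.character(network$population),
    trough_to_peak = ifelse(network$population == "E", 0.8, 0.3),
    direct = seq_len(n) %in% activated)
}

#' Run one condition block of the simulated experiment
#'
#' Simulates \code{n_trials} independent trials of one condition and packs
#' the result into a [spike_session()]. The settling period is simulated but
#' discarded; spike times are reported relative to the analyzed span. In
#' photostimulated conditions the perturbation input is on during the
#' protocol's photostimulation window; in \code{V} conditions the visual
#' Poisson input is delivered during each stimulus epoch.
#'
#' @param network a [build_network()] object.
#' @param neuron a [neuron_params()] object.
#' @param protocol a [condition_protocol()].
#' @param perturbation a [perturbation_spec()]; must be \code{"none"} for
#'   conditions without photostimulation.
#' @param seed integer; trial \code{k} uses input seed \code{seed + k - 1}.
#' @param select_seed seed for the activated-unit draw (fixed per network
#'   instance across realizations).
#' @param activated optional explicit activated-unit indices.
#' @param dt integration step (ms).
#' @return A [spike_session()] with ground-truth unit metadata.
#' @export
run_condition <- function(network, neuron = neuron_params(), protocol,
                          perturbation = perturbation_spec("none"),
                          seed = 1L, select_seed = 1L, activated = NULL,
                          dt = 0.1) {
  stopifnot(inherits(protocol, "condition_protocol"))
  is_ph <- grepl("_ph$", protocol$condition)
  if (!is_ph && perturbation$mode != "none")
    stop("run_condition: perturbation supplied for a condition without photostimulation")
  if (is_ph && perturbation$mode == "none")
    stop("run_condition: photostimulated condition requires a perturbation")
  settle <- protocol$settle
  dur <- protocol$trial_duration + settle
  stim <- NULL
  if (!is.null(protocol$stim_onsets))
    stim <- stimulus_spec(onsets = protocol$stim_onsets + settle,
                          duration = protocol$stim_duration,
                          rate = network$params$nu_stim)
  pw <- if (is_ph) protocol$photostim_window + settle else NULL
  if (is_ph && is.null(activated))
    activated <- select_activated(network, perturbation, seed = select_seed)
  if (is.null(activated)) activated <- integer(0)

  sp_all <- list()
  for (k in seq_len(protocol$n_trials)) {
    r <- simulate_network(network, neuron, duration = dur, dt = dt,
                          perturbation = if (is_ph) perturbation else perturbation_spec("none"),
                          activated = activated,
                          perturbation_window = pw,
                          stimulus = stim, seed = seed + k - 1L)
    keep <- r$spikes$t > settle
    sp_all[[k]] <- data.frame(unit_id = r$spikes$unit[keep], trial = k,
                              condition = protocol$condition,
                              t_ms = r$spikes$t[keep] - settle)
  }
  spikes <- do.call(rbind, sp_all)
  trials <- data.frame(trial = seq_len(protocol$n_trials),
                       condition = protocol$condition)
  spike_session(spikes, .units_from_network(network, activated), trials,
                protocol = list(trial_duration = protocol$trial_duration,
                                stim_onsets = protocol$stim_onsets,
                                stim_duration = protocol$stim_duration,
                                photostim_window = protocol$photostim_window))
}

# population/direct-group rates of one run: pre-stimulus baseline and
# evoked magnitude (stimulus-window rate minus pre rate), in Hz
.run_metrics <- function(result, pre_window, stim_window, groups) {
  spk <- result$spikes
  rate_in <- function(ids, w) {
    if (length(ids) == 0) return(NA_real_)
    sum(spk$t > w[1] & spk$t <= w[2] & spk$unit %in% ids) /
      length(ids) / ((w[2] - w[1]) / 1000)
  }
  out <- lapply(groups, function(ids) {
    pre <- rate_in(ids, pre_window)
    ev <- rate_in(ids, stim_window)
    c(baseline = pre, magnitude = ev - pre)
  })
  out
}

#' Sweep the activated fraction of a perturbation mode
#'
#' Runs the simulated visual-stimulation experiment over a grid of activated
#' fractions, aggregating over independent connectivity instances and input
#' realizations. For every (instance, realization) an unperturbed control
#' run shares the input seed of the perturbed runs, so fraction 0 reproduces
#' the control exactly. Reported per fraction, population and
#' direct/indirect group: the percent change of the pre-stimulus baseline
#' rate and of the evoked response magnitude relative to the control run,
#' where group-wise control values are computed over the same units.
#'
#' @param mode \code{"selective_e"}, \code{"selective_i"} or
#'   \code{"systemic"}.
#' @param fractions activated fractions in \eqn{[0, 1]}.
#' @param n_instances connectivity instances (different network seeds).
#' @param n_realizations input realizations per instance.
#' @param net_params,neuron model parameters.
#' @param protocol a \code{"V"}-style [condition_protocol()] providing the
#'   trial layout (single trial per run; defaults to the model layout).
#' @param seed base seed; instance, selection and realization seeds are
#'   derived from it by small offsets.
#' @param rate_scale optional scaling of the mode's per-unit perturbation
#'   rates (used to probe fraction/strength interchangeability).
#' @param dt integration step (ms).
#' @return Object of class \code{sweep_result}: list with \code{runs} (per
#'   run raw metrics), \code{summary} (tibble: fraction, population, direct,
#'   metric, mean, sd, n), \code{fractions}, \code{mode}, provenance fields.
#' @export
sweep_activation_fraction <- function(mode = c("selective_e", "selective_i", "systemic"),
                                      fractions = c(0, 0.25, 0.5),
                                      n_instances = 3, n_realizations = 3,
                                      net_params = network_params(),
                                      neuron = neuron_params(),
                                      protocol = condition_protocol("V", "model", n_trials = 1),
                                      seed = 1L, rate_scale = 1, dt = 0.1) {
  mode <- match.arg(mode)
  if (n_instances < 1 || n_realizations < 1)
    stop("sweep_activation_fraction: need at least one instance and realization")
  if (any(fractions < 0 | fractions > 1))
    stop("sweep_activation_fraction: fractions must lie in [0, 1]")
  settle <- protocol$settle
  pre_w <- c(settle, settle + protocol$stim_onsets[1])
  stim_w <- settle + protocol$stim_onsets[1] + c(0, protocol$stim_duration)
  stim <- stimulus_spec(onsets = protocol$stim_onsets + settle,
                        duration = protocol$stim_duration,
                        rate = net_params$nu_stim)
  dur <- protocol$trial_duration + settle

  rows <- list()
  for (i in seq_len(n_instances)) {
    inst_seed <- seed + i
    net <- build_network(net_params, seed = inst_seed)
    is_e <- net$population == "E"
    ctrl_runs <- lapply(seq_len(n_realizations), function(j)
      simulate_network(net, neuron, duration = dur, dt = dt,
                       stimulus = stim, seed = seed + 1000L * i + j))
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      pert <- perturbation_spec(mode, fraction = f)
      pert$rate_exc_to_e <- pert$rate_exc_to_e * rate_scale
      pert$rate_inh_to_e <- pert$rate_inh_to_e * rate_scale
      pert$rate_exc_to_i <- pert$rate_exc_to_i * rate_scale
      pert$rate_inh_to_i <- pert$rate_inh_to_i * rate_scale
      act <- select_activated(net, pert, seed = inst_seed + 97L * fi)
      groups <- list()
      for (p in c("E", "I")) {
        ids_p <- which(if (p == "E") is_e else !is_e)
        for (d in c(TRUE, FALSE)) {
          ids <- if (d) intersect(ids_p, act) else setdiff(ids_p, act)
          groups[[paste(p, d, sep = ".")]] <- ids
        }
        groups[[paste(p, "all", sep = ".")]] <- ids_p
      }
      for (j in seq_len(n_realizations)) {
        real_seed <- seed + 1000L * i + j
        ctrl <- ctrl_runs[[j]]
        prt <- simulate_network(net, neuron, duration = dur, dt = dt,
                                perturbation = pert, activated = act,
                                stimulus = stim, seed = real_seed)
        mc <- .run_metrics(ctrl, pre_w, stim_w, groups)
        mp <- .run_metrics(prt, pre_w, stim_w, groups)
        for (g in names(groups)) {
          pp <- strsplit(g, ".", fixed = TRUE)[[1]]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            fraction = f, instance = i, realization = j,
            population = pp[1], direct = pp[2],
            n_units = length(groups[[g]]),
            baseline_ctrl = mc[[g]]["baseline"],
            baseline_pert = mp[[g]]["baseline"],
            magnitude_ctrl = mc[[g]]["magnitude"],
            magnitude_pert = mp[[g]]["magnitude"])
        }
      }
    }
  }
  runs <- do.call(rbind, rows)
  runs$baseline_change <- 100 * (runs$baseline_pert - runs$baseline_ctrl) /
    runs$baseline_ctrl
  runs$magnitude_change <- 100 * (runs$magnitude_pert - runs$magnitude_ctrl) /
    abs(runs$magnitude_ctrl)
  long <- rbind(
    tibble::tibble(fraction = runs$fraction, population = runs$population,
                   direct = runs$direct, metric = "baseline_change",
                   value = runs$baseline_change),
    tibble::tibble(fraction = runs$fraction, population = runs$population,
                   direct = runs$direct, metric = "magnitude_change",
                   value = runs$magnitude_change))
  long <- long[is.finite(long$value), , drop = FALSE]
  agg_m <- stats::aggregate(value ~ fraction + population + direct + metric,
                            long, mean)
  agg_s <- stats::aggregate(value ~ fraction + population + direct + metric,
                            long, stats::sd)
  agg_n <- stats::aggregate(value ~ fraction + population + direct + metric,
                            long, length)
  summary <- tibble::as_tibble(agg_m)
  names(summary)[names(summary) == "value"] <- "mean"
  summary$sd <- agg_s$value
  summary$n <- agg_n$value
  structure(list(mode = mode, fractions = fractions, runs = runs,
                 summary = summary, n_instances = n_instances,
                 n_realizations = n_realizations, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> mode %s, fractions {%s}, %d instances x %d realizations\n",
              x$mode, paste(x$fractions, collapse = ", "),
              x$n_instances, x$n_realizations))
  print(x$summary[x$summary$direct == "all", ])
  invisible(x)
}

#' Mean-driven linear-superposition prediction
#'
#' Prediction of the systemic effect under a mean-driven reading of the
#' network, in which the two selective activations superpose linearly: per
#' fraction, population and metric, the predicted percent change is the sum
#' of the selective-E and selective-I percent changes (population-level
#' \code{"all"} groups).
#'
#' @param selE,selI [sweep_activation_fraction()] results for
#'   \code{selective_e} and \code{selective_i} on identical fraction grids.
#' @return Tibble with \code{fraction}, \code{population}, \code{metric},
#'   \code{predicted} (percent change).
#' @export
mean_driven_superposition <- function(selE, selI) {
  stopifnot(inherits(selE, "sweep_result"), inherits(selI, "sweep_result"))
  if (!identical(selE$fractions, selI$fractions))
    stop("mean_driven_superposition: fraction grids differ")
  a <- selE$summary[selE$summary$direct == "all", ]
  b <- selI$summary[selI$summary$direct == "all", ]
  key <- c("fraction", "population", "metric")
  m <- merge(a[, c(key, "mean")], b[, c(key, "mean")], by = key,
             suffixes = c("_selE", "_selI"))
  out <- tibble::as_tibble(m[order(m$metric, m$population, m$fraction), ])
  out$predicted <- out$mean_selE + out$mean_selI
  out
}

#' Conductance and rate comparison: no vs systemic activation
#'
#' Runs the visual-stimulation trial with conductance recording at 0%% and at
#' a given systemic activation fraction, returning population-average
#' excitatory/inhibitory conductance and firing-rate summaries for the
#' pre-stimulus and stimulus windows, plus the full traces.
#'
#' @param net_params,neuron model parameters.
#' @param fraction systemic activated fraction (default 0.5).
#' @param protocol a \code{"V"}-style [condition_protocol()].
#' @param network_seed,seed connectivity / input seeds.
#' @param record_dt trace sampling step (ms).
#' @param dt integration step (ms).
#' @return List of class \code{conductance_comparison} with \code{summary}
#'   (tibble: activation, window, population, G_e, G_i, rate) and
#'   \code{results} (the two \code{sim_result}s with traces).
#' @export
compare_systemic_conductance <- function(net_params = network_params(),
                                         neuron = neuron_params(),
                                         fraction = 0.5,
                                         protocol = condition_protocol("V", "model", n_trials = 1),
                                         network_seed = 1L, seed = 1L,
                                         record_dt = 1, dt = 0.1) {
  net <- build_network(net_params, seed = network_seed)
  settle <- protocol$settle
  stim <- stimulus_spec(onsets = protocol$stim_onsets + settle,
                        duration = protocol$stim_duration,
                        rate = net_params$nu_stim)
  dur <- protocol$trial_duration + settle
  windows <- list(pre = c(settle, settle + protocol$stim_onsets[1]),
                  stim = settle + protocol$stim_onsets[1] + c(0, protocol$stim_duration))
  pert <- perturbation_spec("systemic", fraction = fraction)
  r0 <- simulate_network(net, neuron, duration = dur, dt = dt, stimulus = stim,
                         seed = seed, record_dt = record_dt)
  r1 <- simulate_network(net, neuron, duration = dur, dt = dt, stimulus = stim,
                         perturbation = pert, select_seed = network_seed,
                         seed = seed, record_dt = record_dt)
  s0 <- measure_conductance_and_rate(r0, windows)
  s1 <- measure_conductance_and_rate(r1, windows)
  s0$activation <- 0
  s1$activation <- fraction
  structure(list(summary = tibble::as_tibble(rbind(s0, s1)),
                 results = list(control = r0, activated = r1),
                 windows = windows, fraction = fraction),
            class = "conductance_comparison")
}

#' @export
print.conductance_comparison <- function(x, ...) {
  cat(sprintf("<conductance_comparison> systemic activation 0 vs %.0f%%\n",
              100 * x$fraction))
  print(x$summary)
  invisible(x)
}
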