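#' Choose which units receive the receptor-activation input
#'
#' Uniform random sample without replacement within each population, sized by
#' the perturbation fractions. Selection is controlled by its own seed so that
#' a network instance keeps the same activated set across input realizations.
#'
#' @param network an [build_network()] object.
#' @param perturbation a [perturbation_spec()].
#' @param seed integer seed for the selection draw.
#' @return Integer vector of activated unit indices (possibly empty).
#' @export
select_activated <- function(network, perturbation, seed = 1L) {
  stopifnot(inherits(network, "ei_network"), inherits(perturbation, "perturbation_spec"))
  set.seed(as.integer(seed))
  e_ids <- which(network$population == "E")
  i_ids <- which(network$population == "I")
  n_e <- round(perturbation$fraction_e * length(e_ids))
  n_i <- round(perturbation$fraction_i * length(i_ids))
  act <- c(if (n_e > 0) sample(e_ids, n_e) else integer(0),
           if (n_i > 0) sample(i_ids, n_i) else integer(0))
  sort(act)
}

#' Define a visual-stimulus epoch set
#'
#' @param onsets stimulus onset times (ms).
#' @param duration stimulus duration (ms); the model default is a single
#'   500-ms epoch.
#' @param rate excitatory Poisson rate (Hz) delivered to all units during each
#'   epoch.
#' @return A \code{stimulus_spec} list.
#' @export
stimulus_spec <- function(onsets, duration = 500, rate = 200) {
  stopifnot(is.numeric(onsets), duration > 0, rate >= 0)
  structure(list(onsets = sort(onsets), duration = duration, rate = rate),
            class = "stimulus_spec")
}

#' Simulate the conductance-based E/I network
#'
#' Integrates the membrane equation for every unit with exponential Euler at
#' step \code{dt}, driven by per-unit background Poisson input, optional
#' receptor-activation (perturbation) input to a chosen set of units, and an
#' optional excitatory stimulus train to all units. Recurrent spikes from
#' excitatory (inhibitory) sources enter their targets' excitatory
#' (inhibitory) conductance through the per-connection peak conductance;
#' external events use the population mean peaks \code{J_e} / \code{J_i}.
#'
#' @param network a [build_network()] object.
#' @param neuron a [neuron_params()] object.
#' @param duration simulated time (ms).
#' @param dt integration step (ms); must resolve the synaptic kernels
#'   (\code{dt < tau_e, tau_i}).
#' @param bkg_e,bkg_i background excitatory / inhibitory Poisson rate per unit
#'   (Hz); scalar or length-N vector. Defaults from the network's parameters.
#' @param perturbation a [perturbation_spec()]; \code{"none"} disables it.
#' @param activated integer vector of activated unit indices. If \code{NULL},
#'   chosen by [select_activated()] with \code{select_seed}.
#' @param select_seed seed for the activated-unit draw (per network instance).
#' @param perturbation_window \code{c(start, end)} ms during which the
#'   perturbation input is on; default the whole run.
#' @param stimulus a [stimulus_spec()] or \code{NULL}.
#' @param seed integer seed for all Poisson input realizations.
#' @param v0 initial membrane potential (mV), scalar or per-unit vector;
#'   default \code{E_L}.
#' @param record_dt if not \code{NULL}, record V, G_e, G_i traces for every
#'   unit at this sampling step (ms; a multiple of \code{dt}).
#' @return A \code{sim_result}: list with \code{spikes} (data.frame
#'   \code{unit}, \code{t} in ms), \code{population}, \code{activated},
#'   \code{duration}, \code{dt}, \code{seeds}, and (if recorded)
#'   \code{traces} with \code{time}, \code{V}, \code{G_e}, \code{G_i}
#'   (matrices time x unit).
#' @export
simulate_network <- function(network, neuron = neuron_params(),
                             duration, dt = 0.1,
                             bkg_e = NULL, bkg_i = NULL,
                             perturbation = perturbation_spec("none"),
                             activated = NULL, select_seed = 1L,
                             perturbation_window = NULL,
                             stimulus = NULL,
                             seed = 1L, v0 = NULL,
                             record_dt = NULL) {
  stopifnot(inherits(network, "ei_network"), inherits(neuron, "neuron_params"))
  if (dt <= 0) stop("simulate_network: dt must be > 0")
  if (dt >= neuron$tau_e || dt >= neuron$tau_i)
    stop("simulate_network: dt must be smaller than the synaptic time constants")
  if (duration < 0) stop("simulate_network: duration must be >= 0")
  np <- network$params
  n <- length(network$population)
  is_e <- network$population == "E"
  if (is.null(bkg_e)) bkg_e <- np$nu_bkg_e
  if (is.null(bkg_i)) bkg_i <- np$nu_bkg_i
  bkg_e <- rep_len(bkg_e, n); bkg_i <- rep_len(bkg_i, n)
  if (any(bkg_e < 0) || any(bkg_i < 0))
    stop("simulate_network: background rates must be >= 0")

  if (is.null(activated) && perturbation$mode != "none")
    activated <- select_activated(network, perturbation, seed = select_seed)
  if (is.null(activated)) activated <- integer(0)
  if (is.null(perturbation_window)) perturbation_window <- c(0, duration)

  # piecewise-constant external rates: segment breakpoints
  brk <- c(0, duration)
  if (perturbation$mode != "none" && length(activated) > 0)
    brk <- c(brk, perturbation_window)
  if (!is.null(stimulus))
    brk <- c(brk, stimulus$onsets, stimulus$onsets + stimulus$duration)
  brk <- sort(unique(pmin(pmax(brk, 0), duration)))
  seg_start <- brk[-length(brk)]
  seg_end_ms <- brk[-1]
  n_seg <- length(seg_start)
  if (n_seg == 0) { seg_start <- 0; seg_end_ms <- duration; n_seg <- 1 }

  rate_e <- matrix(bkg_e, n, n_seg)
  rate_i <- matrix(bkg_i, n, n_seg)
  if (perturbation$mode != "none" && length(activated) > 0) {
    in_pw <- seg_start >= perturbation_window[1] & seg_end_ms <= perturbation_window[2]
    act_e <- activated[is_e[activated]]
    act_i <- activated[!is_e[activated]]
    if (any(in_pw)) {
      rate_e[act_e, in_pw] <- rate_e[act_e, in_pw] + perturbation$rate_exc_to_e
      rate_i[act_e, in_pw] <- rate_i[act_e, in_pw] + perturbation$rate_inh_to_e
      rate_e[act_i, in_pw] <- rate_e[act_i, in_pw] + perturbation$rate_exc_to_i
      rate_i[act_i, in_pw] <- rate_i[act_i, in_pw] + perturbation$rate_inh_to_i
    }
  }
  if (!is.null(stimulus)) {
    for (on in stimulus$onsets) {
      in_st <- seg_start >= on & seg_end_ms <= on + stimulus$duration
      if (any(in_st)) rate_e[, in_st] <- rate_e[, in_st] + stimulus$rate
    }
  }

  n_steps <- as.integer(round(duration / dt))
  seg_end_step <- as.integer(round(seg_end_ms / dt))
  seg_end_step[n_seg] <- n_steps
  record_every <- 0L
  if (!is.null(record_dt)) {
    record_every <- as.integer(round(record_dt / dt))
    if (record_every < 1) stop("simulate_network: record_dt must be >= dt")
  }

  set.seed(as.integer(seed))
  raw <- simulate_lif_cpp(network$weights, is_e, unclass(neuron),
                          dt, n_steps, rate_e, rate_i, seg_end_step,
                          np$J_e, np$J_i,
                          rep_len(if (is.null(v0)) neuron$E_L else v0, n),
                          record_every)
  res <- list(
    spikes = data.frame(unit = raw$unit, t = raw$time),
    population = network$population,
    activated = activated,
    duration = duration, dt = dt,
    seeds = list(network = network$seed, select = select_seed, input = seed),
    perturbation = perturbation)
  if (record_every > 0)
    res$traces <- list(time = raw$t_rec, V = raw$V, G_e = raw$G_e, G_i = raw$G_i)
  structure(res, class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  n <- length(x$population)
  cat(sprintf("<sim_result> %d units, %.0f ms at dt = %g ms, %d spikes (%.2f Hz/unit)\n",
              n, x$duration, x$dt, nrow(x$spikes),
              nrow(x$spikes) / n / (x$duration / 1000)))
  invisible(x)
}

#' Window-averaged conductances and firing rates
#'
#' Time-averaged total excitatory and inhibitory conductance and mean firing
#' rate per population within each analysis window, e.g. to contrast the
#' pre-stimulus and stimulus epochs of runs with and without receptor
#' activation.
#'
#' @param result a [simulate_network()] result with traces recorded.
#' @param windows named list of \code{c(start, end)} windows (ms).
#' @return A tibble with columns \code{window}, \code{population},
#'   \code{G_e}, \code{G_i} (nS, mean over units and time), \code{rate} (Hz,
#'   mean over units).
#' @export
measure_conductance_and_rate <- function(result, windows) {
  stopifnot(inherits(result, "sim_result"))
  if (is.null(result$traces))
    stop("measure_conductance_and_rate: traces were not recorded; rerun with record_dt set")
  if (is.null(names(windows)) || any(!nzchar(names(windows))))
    stop("measure_conductance_and_rate: windows must be a named list")
  tr <- result$traces
  pop <- result$population
  out <- list()
  for (wn in names(windows)) {
    w <- windows[[wn]]
    if (w[1] < 0 || w[2] > result$duration || w[2] <= w[1])
      stop("measure_conductance_and_rate: window '", wn, "' outside the simulated span")
    sel <- tr$time > w[1] & tr$time <= w[2]
    dur_s <- (w[2] - w[1]) / 1000
    for (p in levels(pop)[table(pop) > 0]) {
      u <- pop == p
      n_spk <- sum(result$spikes$t > w[1] & result$spikes$t <= w[2] &
                   u[result$spikes$unit])
      out[[length(out) + 1L]] <- tibble::tibble(
        window = wn, population = p,
        G_e = mean(tr$G_e[sel, u, drop = FALSE]),
        G_i = mean(tr$G_i[sel, u, drop = FALSE]),
        rate = n_spk / sum(u) / dur_s)
    }
  }
  do.call(rbind, out)
}
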