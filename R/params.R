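#' Neuron dynamics parameters
#'
#' Parameters of the conductance-based leaky integrate-and-fire neuron
#' \deqn{C \frac{dV_m}{dt} = -g_L (V_m - E_L) - G_e(t)(V_m - E_e) - G_i(t)(V_m - E_i),}
#' with a spike emitted and \eqn{V_m} reset to \code{V_r} whenever
#' \eqn{V_m \ge E_T}. Defaults are the values used for all network
#' simulations in this package.
#'
#' @param C membrane capacitance (pF).
#' @param E_e,E_i reversal potentials of excitatory / inhibitory conductances (mV).
#' @param E_L resting potential (mV).
#' @param E_T spiking threshold voltage (mV).
#' @param g_L leak conductance (nS).
#' @param t_ref absolute refractory period (ms); the membrane is clamped at
#'   \code{V_r} while refractory, synaptic conductances keep evolving.
#' @param tau_e,tau_i synaptic time constants of the excitatory / inhibitory
#'   alpha-function conductance kernels (ms).
#' @param V_r reset voltage (mV).
#' @return An object of class \code{neuron_params} (named list).
#' @seealso [alpha_kernel()], [simulate_network()]
#' @export
neuron_params <- function(C = 120, E_e = 0, E_i = -75, E_L = -70, E_T = -50,
                          g_L = 7.14, t_ref = 2, tau_e = 1, tau_i = 1,
                          V_r = -60) {
  p <- list(C = C, E_e = E_e, E_i = E_i, E_L = E_L, E_T = E_T, g_L = g_L,
            t_ref = t_ref, tau_e = tau_e, tau_i = tau_i, V_r = V_r)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("neuron_params: '", nm, "' must be a single finite number")
  }
  if (g_L <= 0) stop("neuron_params: g_L must be > 0")
  if (C <= 0) stop("neuron_params: C must be > 0")
  if (tau_e <= 0 || tau_i <= 0) stop("neuron_params: synaptic time constants must be > 0")
  if (t_ref < 0) stop("neuron_params: t_ref must be >= 0")
  if (!(E_i < V_r && V_r < E_T && E_T < E_e))
    stop("neuron_params: require E_i < V_r < E_T < E_e")
  structure(p, class = "neuron_params")
}

#' Network architecture and input-rate parameters
#'
#' Sizes, connection probabilities, synaptic peak conductances, and the rates
#' of the homogeneous Poisson inputs driving the network: per-unit excitatory
#' and inhibitory background, and the visual-stimulus input delivered to all
#' units during a stimulus epoch.
#'
#' @param N_e,N_i number of excitatory / inhibitory units.
#' @param CP_e,CP_i probability of each outgoing connection from an excitatory /
#'   inhibitory unit (each potential directed edge is an independent Bernoulli
#'   draw).
#' @param J_e,J_i mean peak excitatory / inhibitory conductance (nS). Recurrent
#'   weights are drawn from Gaussian(J, J/5) and clipped at zero (Dale's law);
#'   external input events use the mean J.
#' @param weight_sd_ratio ratio of the weight standard deviation to its mean.
#' @param nu_bkg_e,nu_bkg_i rate of the excitatory / inhibitory background
#'   Poisson input to every unit (Hz).
#' @param nu_stim rate of the excitatory visual-input Poisson train delivered
#'   to all units during stimulation (Hz).
#' @return An object of class \code{network_params}.
#' @export
network_params <- function(N_e = 160, N_i = 40, CP_e = 0.15, CP_i = 1,
                           J_e = 1, J_i = 3, weight_sd_ratio = 0.2,
                           nu_bkg_e = 970, nu_bkg_i = 220, nu_stim = 200) {
  p <- list(N_e = N_e, N_i = N_i, CP_e = CP_e, CP_i = CP_i, J_e = J_e,
            J_i = J_i, weight_sd_ratio = weight_sd_ratio,
            nu_bkg_e = nu_bkg_e, nu_bkg_i = nu_bkg_i, nu_stim = nu_stim)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("network_params: '", nm, "' must be a single finite number")
  }
  if (N_e < 1 || N_i < 0) stop("network_params: population sizes invalid")
  if (CP_e < 0 || CP_e > 1 || CP_i < 0 || CP_i > 1)
    stop("network_params: connection probabilities must lie in [0, 1]")
  if (J_e < 0 || J_i < 0) stop("network_params: peak conductances must be >= 0")
  if (nu_bkg_e < 0 || nu_bkg_i < 0 || nu_stim < 0)
    stop("network_params: input rates must be >= 0")
  p$N_e <- as.integer(N_e); p$N_i <- as.integer(N_i)
  structure(p, class = "network_params")
}

#' 5-HT2A perturbation specification
#'
#' Describes how receptor activation is injected into the network: which
#' populations contain activated units, what fraction of each is activated,
#' and the extra excitatory/inhibitory Poisson input rates those units
#' receive. Three named modes cover the experiments:
#' \describe{
#'   \item{\code{selective_e}}{extra 50-Hz excitatory drive to activated
#'     excitatory units (receptor activation in pyramidal cells only).}
#'   \item{\code{selective_i}}{extra 100-Hz excitatory drive to activated
#'     inhibitory units -- twice the excitatory-unit rate, reflecting the
#'     somatic vs dendritic receptor localisation.}
#'   \item{\code{systemic}}{extra 29.5-kHz excitatory plus 27-kHz inhibitory
#'     drive to activated units of both populations (joint activation in
#'     pyramidal and PV cells; the balanced, conductance-loading condition).}
#' }
#'
#' @param mode one of \code{"none"}, \code{"selective_e"}, \code{"selective_i"},
#'   \code{"systemic"}.
#' @param fraction_e,fraction_i fraction of each population activated (0--1).
#'   Defaults: the mode's target population(s) get \code{fraction}, others 0.
#' @param fraction convenience scalar applied to the mode's target populations.
#' @param rate_exc_to_e,rate_inh_to_e extra excitatory / inhibitory Poisson
#'   rates (Hz) to activated excitatory units.
#' @param rate_exc_to_i,rate_inh_to_i same for activated inhibitory units.
#' @return An object of class \code{perturbation_spec}.
#' @export
perturbation_spec <- function(mode = c("none", "selective_e", "selective_i", "systemic"),
                              fraction = 1,
                              fraction_e = NULL, fraction_i = NULL,
                              rate_exc_to_e = NULL, rate_inh_to_e = NULL,
                              rate_exc_to_i = NULL, rate_inh_to_i = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("perturbation_spec: fraction must lie in [0, 1]")
  defaults <- switch(mode,
    none        = list(fe = 0,        fi = 0,        ee = 0,     ie = 0, ei = 0,     ii = 0),
    selective_e = list(fe = fraction, fi = 0,        ee = 50,    ie = 0, ei = 0,     ii = 0),
    selective_i = list(fe = 0,        fi = fraction, ee = 0,     ie = 0, ei = 100,   ii = 0),
    systemic    = list(fe = fraction, fi = fraction, ee = 29500, ie = 27000,
                       ei = 29500, ii = 27000))
  s <- list(
    mode          = mode,
    fraction_e    = if (is.null(fraction_e)) defaults$fe else fraction_e,
    fraction_i    = if (is.null(fraction_i)) defaults$fi else fraction_i,
    rate_exc_to_e = if (is.null(rate_exc_to_e)) defaults$ee else rate_exc_to_e,
    rate_inh_to_e = if (is.null(rate_inh_to_e)) defaults$ie else rate_inh_to_e,
    rate_exc_to_i = if (is.null(rate_exc_to_i)) defaults$ei else rate_exc_to_i,
    rate_inh_to_i = if (is.null(rate_inh_to_i)) defaults$ii else rate_inh_to_i)
  for (nm in c("fraction_e", "fraction_i")) {
    v <- s[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) stop("perturbation_spec: ", nm, " must lie in [0, 1]")
  }
  for (nm in c("rate_exc_to_e", "rate_inh_to_e", "rate_exc_to_i", "rate_inh_to_i")) {
    v <- s[[nm]]
    if (!is.numeric(v) || v < 0) stop("perturbation_spec: ", nm, " must be >= 0")
  }
  structure(s, class = "perturbation_spec")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  C = %g pF, g_L = %g nS (tau_m = %.2f ms)\n", x$C, x$g_L, x$C / x$g_L))
  cat(sprintf("  E_L = %g, E_T = %g, V_r = %g, E_e = %g, E_i = %g mV\n",
              x$E_L, x$E_T, x$V_r, x$E_e, x$E_i))
  cat(sprintf("  tau_e = %g ms, tau_i = %g ms, t_ref = %g ms\n", x$tau_e, x$tau_i, x$t_ref))
  invisible(x)
}

#' @export
print.network_params <- function(x, ...) {
  cat("<network_params>\n")
  cat(sprintf("  N_e = %d, N_i = %d; CP_e = %g, CP_i = %g\n", x$N_e, x$N_i, x$CP_e, x$CP_i))
  cat(sprintf("  J_e = %g nS, J_i = %g nS (sd/mean = %g)\n", x$J_e, x$J_i, x$weight_sd_ratio))
  cat(sprintf("  nu_bkg = %g/%g Hz (e/i), nu_stim = %g Hz\n", x$nu_bkg_e, x$nu_bkg_i, x$nu_stim))
  invisible(x)
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf("<perturbation_spec> mode = %s\n", x$mode))
  cat(sprintf("  fractions: E %.2f, I %.2f\n", x$fraction_e, x$fraction_i))
  cat(sprintf("  extra rates to E units: %g Hz exc, %g Hz inh\n", x$rate_exc_to_e, x$rate_inh_to_e))
  cat(sprintf("  extra rates to I units: %g Hz exc, %g Hz inh\n", x$rate_exc_to_i, x$rate_inh_to_i))
  invisible(x)
}
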