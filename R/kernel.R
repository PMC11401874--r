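#' Alpha-function synaptic conductance kernel
#'
#' Conductance time course evoked by a single synaptic event at \code{t = 0}:
#' \deqn{g(t) = \frac{1}{\tau} J \, H(t) \, e^{1 - t/\tau} \, t,}
#' where \eqn{H} is the Heaviside step (\eqn{H(t) = 0} for \eqn{t \le 0}).
#' The kernel rises from zero, peaks at exactly \code{J} when \code{t == tau},
#' and decays exponentially; its time integral is \eqn{J e \tau}.
#'
#' @param t time since the synaptic event (ms); vectorised.
#' @param J peak conductance (nS).
#' @param tau synaptic time constant (ms), > 0.
#' @return Conductance (nS), same length as \code{t}.
#' @examples
#' alpha_kernel(1, J = 3, tau = 1)   # peak: 3 nS
#' @export
alpha_kernel <- function(t, J, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("alpha_kernel: tau must be a single positive number")
  if (!is.numeric(J) || length(J) != 1L || !is.finite(J))
    stop("alpha_kernel: J must be a single finite number")
  ifelse(t > 0, (J / tau) * exp(1 - t / tau) * t, 0)
}

#' Homogeneous Poisson event train
#'
#' Event times of a homogeneous Poisson process on \code{[0, duration)},
#' the model of all external inputs (background, receptor-activation, and
#' visual drive).
#'
#' @param rate event rate (Hz), >= 0.
#' @param duration interval length (ms).
#' @param seed optional integer seed; if supplied the draw is reproducible.
#' @return Sorted numeric vector of event times (ms).
#' @export
make_poisson_input <- function(rate, duration, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("make_poisson_input: rate must be a single number >= 0")
  if (!is.numeric(duration) || duration < 0)
    stop("make_poisson_input: duration must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, rate * duration / 1000)
  sort(stats::runif(n, 0, duration))
}
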