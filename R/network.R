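#' Build a random E/I network
#'
#' Constructs the recurrent connectivity: each potential directed connection
#' from an excitatory (inhibitory) source exists independently with
#' probability \code{CP_e} (\code{CP_i}); self-connections are excluded.
#' Existing weights are peak conductances drawn from
#' Gaussian(\code{J}, \code{J * weight_sd_ratio}) and clipped at zero so that
#' every unit's outgoing synapses keep a single sign (Dale's law): excitatory
#' sources only ever feed the excitatory conductance \eqn{G_e} of their
#' targets, inhibitory sources only \eqn{G_i}.
#'
#' @param net_params a [network_params()] object.
#' @param seed integer seed controlling the connectivity draw.
#' @return An object of class \code{ei_network}: list with \code{weights}
#'   (N x N matrix, nS, rows = sources, cols = targets), \code{population}
#'   (factor \code{"E"}/\code{"I"} per unit, E units first), \code{params},
#'   and \code{seed}.
#' @export
build_network <- function(net_params, seed = 1L) {
  stopifnot(inherits(net_params, "network_params"))
  p <- net_params
  n <- p$N_e + p$N_i
  set.seed(as.integer(seed))
  pop <- factor(rep(c("E", "I"), c(p$N_e, p$N_i)), levels = c("E", "I"))
  cp <- ifelse(pop == "E", p$CP_e, p$CP_i)
  jm <- ifelse(pop == "E", p$J_e, p$J_i)
  W <- matrix(0, n, n)
  for (src in seq_len(n)) {
    exists <- stats::runif(n) < cp[src]
    exists[src] <- FALSE
    k <- sum(exists)
    if (k > 0) {
      w <- stats::rnorm(k, mean = jm[src], sd = jm[src] * p$weight_sd_ratio)
      W[src, exists] <- pmax(w, 0)
    }
  }
  structure(list(weights = W, population = pop, params = p,
                 seed = as.integer(seed)),
            class = "ei_network")
}

#' @export
print.ei_network <- function(x, ...) {
  n <- length(x$population)
  cat(sprintf("<ei_network> %d units (%d E, %d I), %d connections, seed %d\n",
              n, sum(x$population == "E"), sum(x$population == "I"),
              sum(x$weights > 0), x$seed))
  invisible(x)
}
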