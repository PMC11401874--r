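#' Spike-train session container
#'
#' The common currency between the network simulator, the synthetic-session
#' generator, and the analysis stack: spikes organised by unit, trial and
#' condition, with per-unit metadata and the protocol timing needed by the
#' analyses.
#'
#' @param spikes data.frame with columns \code{unit_id} (integer),
#'   \code{trial} (integer), \code{condition} (character, one of the
#'   session's conditions), \code{t_ms} (spike time within the trial, ms).
#' @param units data.frame with \code{unit_id} and optional metadata:
#'   \code{trough_to_peak} (ms, waveform trough-to-peak time),
#'   \code{population} (ground-truth \code{"E"}/\code{"I"}), \code{direct}
#'   (logical, directly receptor-activated).
#' @param trials data.frame with \code{trial}, \code{condition}: every trial
#'   carries exactly one condition label. If \code{NULL}, inferred from
#'   \code{spikes} (only safe if every trial contains spikes).
#' @param protocol list of timing metadata: \code{trial_duration} (ms),
#'   \code{stim_onsets} (ms), \code{stim_duration} (ms),
#'   \code{photostim_window} (\code{c(start, end)} ms, applying to the
#'   \code{*_ph} conditions) -- any may be \code{NULL} when not applicable.
#' @return An object of class \code{spike_session}.
#' @export
spike_session <- function(spikes, units, trials = NULL, protocol = list()) {
  need <- c("unit_id", "trial", "condition", "t_ms")
  if (!all(need %in% names(spikes)))
    stop("spike_session: spikes needs columns ", paste(need, collapse = ", "))
  if (!"unit_id" %in% names(units)) stop("spike_session: units needs unit_id")
  if (is.null(trials)) {
    trials <- unique(spikes[, c("trial", "condition")])
  }
  if (anyDuplicated(trials$trial))
    stop("spike_session: each trial must carry exactly one condition label")
  if (!is.null(protocol$trial_duration) && nrow(spikes) > 0) {
    if (any(spikes$t_ms < 0) || any(spikes$t_ms > protocol$trial_duration))
      stop("spike_session: spike times outside [0, trial_duration]")
  }
  structure(list(spikes = spikes, units = units,
                 trials = trials[order(trials$trial), , drop = FALSE],
                 protocol = protocol,
                 conditions = sort(unique(as.character(trials$condition)))),
            class = "spike_session")
}

#' @export
print.spike_session <- function(x, ...) {
  cat(sprintf("<spike_session> %d units, %d trials, %d spikes\n",
              nrow(x$units), nrow(x$trials), nrow(x$spikes)))
  tab <- table(x$trials$condition)
  cat("  conditions:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$protocol$trial_duration))
    cat(sprintf("  trial duration %g ms", x$protocol$trial_duration))
  if (!is.null(x$protocol$photostim_window))
    cat(sprintf(", photostim %g-%g ms", x$protocol$photostim_window[1],
                x$protocol$photostim_window[2]))
  cat("\n")
  invisible(x)
}

#' Write / read a session in the columnar spike format
#'
#' Plain-text interchange: a spikes CSV (\code{unit_id, trial, condition,
#' t_ms}) plus a units CSV and a JSON-free header line encoding the protocol
#' timing as comment fields in the units file is deliberately avoided --
#' protocol timing travels in a third small CSV of key/value pairs.
#'
#' @param session a [spike_session()].
#' @param dir output directory (created if needed).
#' @return \code{write_session}: the directory, invisibly.
#'   \code{read_session}: the reconstructed [spike_session()].
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "spike_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$units, file.path(dir, "units.csv"), row.names = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  pr <- session$protocol
  keys <- names(pr)
  proto <- data.frame(key = keys,
                      value = vapply(pr, function(v) paste(v, collapse = ";"), ""))
  utils::write.csv(proto, file.path(dir, "protocol.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  units <- utils::read.csv(file.path(dir, "units.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  proto <- utils::read.csv(file.path(dir, "protocol.csv"))
  protocol <- lapply(seq_len(nrow(proto)), function(i)
    as.numeric(strsplit(as.character(proto$value[i]), ";")[[1]]))
  names(protocol) <- proto$key
  spike_session(spikes, units, trials, protocol)
}
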