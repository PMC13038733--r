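#' Parametric neuron response model
#'
#' Generative parameters for the simulator: homogeneous background firing
#' at rate `b`, cosine rate modulation of amplitude `A` locked to the
#' presented stimulus angle with harmonic `k` (1 = azimuthal tuning with
#' one peak per turn, 2 = axial polarization tuning with two peaks per
#' turn), a true preferred angle, optional exponential onset/offset
#' transients, optional opponent inhibition (rate allowed below
#' background, floored at zero) and an optional anticipatory shift `delta`
#' of the peak against the rotation direction.
#'
#' @param background_rate b, impulses/s (>= 0).
#' @param modulation_amplitude A, impulses/s (>= 0).
#' @param harmonic 1 (azimuthal, 360-degree periodic) or 2 (axial,
#'   180-degree periodic).
#' @param true_phi_max preferred angle in degrees, in \[0, 360/harmonic).
#' @param anticipatory_shift delta in degrees (>= 0), applied opposite to
#'   the rotation direction: a clockwise sweep measures the peak at
#'   `true_phi_max - delta`, a counterclockwise sweep at
#'   `true_phi_max + delta`, so the cw/ccw mismatch is `2 delta`.
#' @param onset_amplitude peak rate increment of the lights-on transient,
#'   impulses/s.
#' @param onset_tau decay time constant of the transient, seconds.
#' @param offset_response `"none"`, `"phasic"` (excitatory transient at
#'   lights-off) or `"inhibition"` (transient suppression at lights-off).
#' @param opponent logical; `TRUE` lets the modulation trough fall below
#'   background (clipped at 0), `FALSE` half-wave rectifies it at
#'   background (excitation only).
#' @param label preset/neuron label carried into simulated trains.
#' @return object of class `neuron_model`.
#' @export
neuron_model <- function(background_rate = 10,
                         modulation_amplitude = 10,
                         harmonic = 2,
                         true_phi_max = 0,
                         anticipatory_shift = 0,
                         onset_amplitude = 0,
                         onset_tau = 0.5,
                         offset_response = c("none", "phasic", "inhibition"),
                         opponent = TRUE,
                         label = "model") {
  offset_response <- match.arg(offset_response)
  stopifnot(
    background_rate >= 0, is.finite(background_rate),
    modulation_amplitude >= 0, is.finite(modulation_amplitude),
    harmonic %in% c(1, 2),
    true_phi_max >= 0, true_phi_max < 360 / harmonic,
    anticipatory_shift >= 0,
    onset_amplitude >= 0, onset_tau > 0
  )
  structure(
    list(
      background_rate = background_rate,
      modulation_amplitude = modulation_amplitude,
      harmonic = as.integer(harmonic),
      true_phi_max = true_phi_max,
      anticipatory_shift = anticipatory_shift,
      onset_amplitude = onset_amplitude,
      onset_tau = onset_tau,
      offset_response = offset_response,
      opponent = isTRUE(opponent),
      label = label
    ),
    class = "neuron_model"
  )
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf(
    "<neuron_model '%s': b = %g imp/s, A = %g, k = %d, Phi = %g deg%s%s>\n",
    x$label, x$background_rate, x$modulation_amplitude, x$harmonic,
    x$true_phi_max,
    if (x$anticipatory_shift > 0) sprintf(", delta = %g deg", x$anticipatory_shift) else "",
    if (x$opponent) ", opponent" else ""
  ))
  invisible(x)
}

# Merged lights-on stretches of a protocol: rotation segments plus
# stationary lit intervals, adjacent pieces joined.
.lit_intervals <- function(protocol) {
  iv <- lapply(protocol$segments, function(s) c(s$start_time, s$start_time + s$duration))
  iv <- c(iv, lapply(protocol$stationary_intervals, function(s) c(s$start, s$end)))
  if (!length(iv)) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, iv)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2] + 1e-9) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  out
}

#' Deterministic firing-rate function of the neuron model
#'
#' The instantaneous Poisson intensity lambda(t) driving the simulator.
#' During stimulus-off periods lambda = b. While a segment rotates at
#' angle phi(t) with direction sign s (+1 cw, -1 ccw), the modulation is
#' `m = A cos(k (phi(t) - Phi + s delta) pi/180)`; opponent neurons use
#' `lambda = max(0, b + m)` and non-opponent neurons `lambda = b +
#' max(0, m)`. Each lights-on edge adds an exponential transient
#' `onset_amplitude exp(-(t - t_on)/onset_tau)`; lights-off edges add a
#' phasic or inhibitory transient according to `offset_response`.
#'
#' @param params a [neuron_model()].
#' @param protocol a [stimulus_protocol()].
#' @param t time(s) in seconds (vectorized).
#' @return intensity in impulses/s (>= 0), same length as `t`.
#' @export
rate_function <- function(params, protocol, t) {
  stopifnot(inherits(params, "neuron_model"), inherits(protocol, "stimulus_protocol"))
  t <- as.numeric(t)
  lambda <- rep(params$background_rate, length(t))
  for (seg in protocol$segments) {
    inside <- t >= seg$start_time & t < seg$start_time + seg$duration
    if (!any(inside)) next
    phi <- angle_at_time(seg, t[inside])
    s <- if (seg$direction == "cw") 1 else -1
    m <- params$modulation_amplitude *
      cos(params$harmonic *
            (phi - params$true_phi_max + s * params$anticipatory_shift) * pi / 180)
    lambda[inside] <- if (params$opponent) {
      pmax(0, params$background_rate + m)
    } else {
      params$background_rate + pmax(0, m)
    }
  }
  lit <- .lit_intervals(protocol)
  if (params$onset_amplitude > 0 && nrow(lit)) {
    for (i in seq_len(nrow(lit))) {
      on <- t >= lit[i, 1]
      lambda[on] <- lambda[on] +
        params$onset_amplitude * exp(-(t[on] - lit[i, 1]) / params$onset_tau) *
        (t[on] < lit[i, 2]) # transient acts while the light is on
      if (params$offset_response != "none") {
        post <- t >= lit[i, 2]
        tail <- params$onset_amplitude * exp(-(t[post] - lit[i, 2]) / params$onset_tau)
        lambda[post] <- lambda[post] +
          if (params$offset_response == "phasic") tail else -tail
      }
    }
  }
  pmax(0, lambda)
}

#' Simulate a spike train by inhomogeneous-Poisson thinning
#'
#' Draws candidate events from a homogeneous Poisson process at the
#' envelope rate `lambda_max = b + A + onset_amplitude` over the protocol
#' span and accepts each with probability `lambda(t) / lambda_max`.
#' Reproducible for a fixed seed.
#'
#' @inheritParams rate_function
#' @param seed integer seed for the simulation.
#' @return a [spike_train()] labelled with the model's `label`.
#' @export
simulate_spike_train <- function(params, protocol, seed = NULL) {
  stopifnot(inherits(params, "neuron_model"), inherits(protocol, "stimulus_protocol"))
  if (!is.null(seed)) set.seed(seed)
  spans <- c(
    vapply(protocol$segments, function(s) s$start_time + s$duration, numeric(1)),
    vapply(protocol$off_intervals, `[[`, numeric(1), 2),
    vapply(protocol$stationary_intervals, function(s) s$end, numeric(1))
  )
  t_max <- if (length(spans)) max(spans) else 0
  lambda_max <- params$background_rate + params$modulation_amplitude +
    params$onset_amplitude
  if (lambda_max <= 0 || t_max <= 0) {
    return(spike_train(numeric(0), recording_id = params$label))
  }
  n_cand <- stats::rpois(1, lambda_max * t_max)
  cand <- sort(stats::runif(n_cand, 0, t_max))
  keep <- stats::runif(n_cand) < rate_function(params, protocol, cand) / lambda_max
  spike_train(cand[keep], recording_id = params$label,
              meta = list(model = unclass(params), seed = seed))
}

#' Library of neuron-model presets
#'
#' Named generative presets spanning the response phenomenology seen in
#' sky-compass recordings: strongly opponent axial polarization tuning
#' ("PC4"-like), azimuthal ultraviolet-spot tuning with complete
#' inhibition opposite the preferred azimuth ("PC5_uv"), weak axial
#' tuning on a high background ("PC5_pol"), axial tuning with an
#' anticipatory shift producing a clockwise/counterclockwise mismatch of
#' about 46.6 degrees ("LOXPN1"), an untuned control ("TB1c"), a
#' low-background sparsely firing neuron ("SOC2"), and an opponent
#' azimuthal green-spot responder ("OC2_green"). Background rates and
#' preferred angles follow published per-neuron values; modulation
#' amplitudes are chosen to reproduce the qualitative response classes
#' (an opponent trough at zero requires A >= b).
#'
#' @return named list of [neuron_model()] objects.
#' @export
#' @examples
#' scenario_library()$PC4
scenario_library <- function() {
  list(
    # axial, strongly opponent: trough reaches 0 (A > b)
    PC4 = neuron_model(background_rate = 9.0, modulation_amplitude = 12,
                       harmonic = 2, true_phi_max = 51.8, opponent = TRUE,
                       onset_amplitude = 10, onset_tau = 0.5, label = "PC4"),
    # azimuthal UV response, complete inhibition around the anti-preferred azimuth
    PC5_uv = neuron_model(background_rate = 30.7, modulation_amplitude = 32,
                          harmonic = 1, true_phi_max = 94.3, opponent = TRUE,
                          label = "PC5_uv"),
    # weak axial tuning on a high background
    PC5_pol = neuron_model(background_rate = 30.7, modulation_amplitude = 6,
                           harmonic = 2, true_phi_max = 45.7, opponent = TRUE,
                           label = "PC5_pol"),
    # axial tuning with anticipatory shift: cw/ccw mismatch = 2 * 23.3 = 46.6 deg
    LOXPN1 = neuron_model(background_rate = 13.7, modulation_amplitude = 14,
                          harmonic = 2, true_phi_max = 128.2,
                          anticipatory_shift = 23.3, opponent = TRUE,
                          onset_amplitude = 15, onset_tau = 0.4,
                          offset_response = "phasic", label = "LOXPN1"),
    # untuned control
    TB1c = neuron_model(background_rate = 17.3, modulation_amplitude = 0,
                        harmonic = 2, true_phi_max = 0, opponent = FALSE,
                        label = "TB1c"),
    # very low background, excitation-only axial tuning
    SOC2 = neuron_model(background_rate = 1.0, modulation_amplitude = 8,
                        harmonic = 2, true_phi_max = 24.5, opponent = FALSE,
                        onset_amplitude = 12, onset_tau = 0.5,
                        offset_response = "inhibition", label = "SOC2"),
    # azimuthal green-spot responder with spatial opponency
    OC2_green = neuron_model(background_rate = 9.4, modulation_amplitude = 10,
                             harmonic = 1, true_phi_max = 177.0, opponent = TRUE,
                             onset_amplitude = 8, onset_tau = 0.3,
                             label = "OC2_green")
  )
}

#' Build a standard rotation protocol
#'
#' Constructs a well-formed protocol with a leading off interval, one
#' clockwise and/or counterclockwise rotation block per stimulus kind
#' (blocks of a kind are contiguous; kinds are separated by off gaps) and
#' a trailing off interval.
#'
#' @param stimulus_kinds character vector of stimulus kinds.
#' @param velocities angular velocity per kind, degrees/s (recycled).
#' @param n_turns turns per direction block (recycled over `directions`).
#' @param directions direction blocks per kind, default `c("cw", "ccw")`.
#' @param off_gap duration of off intervals before, between and after
#'   stimuli, seconds (default 30).
#' @param exclude_first_rotation passed to [stimulus_protocol()].
#' @return a [stimulus_protocol()].
#' @export
#' @examples
#' make_protocol() # polarizer, 3 cw + 3 ccw turns at 30 deg/s
make_protocol <- function(stimulus_kinds = "polarizer_blue",
                          velocities = 30,
                          n_turns = 3,
                          directions = c("cw", "ccw"),
                          off_gap = 30,
                          exclude_first_rotation = TRUE) {
  if (any(!is.finite(velocities)) || any(velocities <= 0)) {
    skytuner_error("skytuner_config_error", "angular velocities must be positive")
  }
  velocities <- rep_len(velocities, length(stimulus_kinds))
  n_turns <- rep_len(n_turns, length(directions))
  segments <- list()
  off <- list()
  t <- 0
  for (i in seq_along(stimulus_kinds)) {
    off[[length(off) + 1]] <- c(t, t + off_gap)
    t <- t + off_gap
    for (j in seq_along(directions)) {
      seg <- rotation_segment(stimulus_kinds[i], directions[j], velocities[i],
                              start_time = t, n_turns = n_turns[j])
      segments[[length(segments) + 1]] <- seg
      t <- t + seg$duration
    }
  }
  off[[length(off) + 1]] <- c(t, t + off_gap)
  stimulus_protocol(segments, off_intervals = off,
                    exclude_first_rotation = exclude_first_rotation)
}
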