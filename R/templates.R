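#' Motion identifiers known to the simulator
#'
#' Six trained target motions, two untrained wrist deviations ("unknown"
#' motions used only at test time), and one non-target body movement
#' (elbow flexion).
#'
#' @format Character vector of length 9.
#' @export
MOTION_IDS <- c(
  "Grasp", "Open", "Pronation", "Supination",
  "PalmarFlexion", "Dorsiflexion",
  "RadialFlexion", "UlnarFlexion",
  "ElbowFlexion"
)

#' Construct a motion template
#'
#' A template describes the deterministic part of the two-channel voltage
#' transient evoked by one motion: per channel, a damped sinusoid
#' \eqn{A \, e^{-\lambda t} \sin(2\pi f t)} starting after a channel-specific
#' onset latency and lasting `duration` seconds. Channel 1 is the sensor over
#' the flexor carpi radialis (FCR), channel 2 over the extensor carpi
#' radialis longus (ECRL).
#'
#' @param motion_id One of [MOTION_IDS].
#' @param amplitude Numeric length-2, peak envelope amplitude per channel
#'   (volts, non-negative; at least one channel must be positive).
#' @param polarity Numeric length-2 in `{-1, +1}`, sign of the initial
#'   deflection per channel.
#' @param latency Numeric length-2, onset latency per channel relative to the
#'   cue (seconds, non-negative).
#' @param damping Envelope decay rate \eqn{\lambda} (1/s, positive).
#' @param frequency Oscillation frequency \eqn{f} (Hz, positive).
#' @param duration Transient length (seconds, positive; about 1 s).
#' @return An object of class `motion_template`.
#' @export
motion_template <- function(motion_id, amplitude, polarity, latency,
                            damping = 3, frequency = 2.5, duration = 1) {
  motion_id <- match.arg(motion_id, MOTION_IDS)
  stopifnot(
    length(amplitude) == 2L, all(is.finite(amplitude)), all(amplitude >= 0),
    any(amplitude > 0),
    length(polarity) == 2L, all(polarity %in% c(-1, 1)),
    length(latency) == 2L, all(latency >= 0),
    damping > 0, frequency > 0, duration > 0
  )
  structure(
    list(motion_id = motion_id, amplitude = as.numeric(amplitude),
         polarity = as.numeric(polarity), latency = as.numeric(latency),
         damping = damping, frequency = frequency, duration = duration),
    class = "motion_template"
  )
}

#' Default motion template set
#'
#' Nine templates with pairwise-distinct two-channel signatures. Flexion-type
#' target motions load the FCR channel, extension-type motions the ECRL
#' channel, and forearm rotations load both with opposite polarity. The two
#' unknown wrist deviations get intermediate both-channel signatures, and the
#' non-target elbow flexion a slower, longer, both-channel deflection.
#'
#' @return Named list of [motion_template] objects, one per [MOTION_IDS].
#' @export
default_templates <- function() {
  tpl <- list(
    motion_template("Grasp",         amplitude = c(1.2, 0.3), polarity = c(+1, +1), latency = c(0.15, 0.17)),
    motion_template("Open",          amplitude = c(0.3, 1.2), polarity = c(-1, +1), latency = c(0.17, 0.15)),
    motion_template("Pronation",     amplitude = c(0.9, 0.9), polarity = c(+1, -1), latency = c(0.15, 0.15)),
    motion_template("Supination",    amplitude = c(0.9, 0.9), polarity = c(-1, +1), latency = c(0.16, 0.16)),
    motion_template("PalmarFlexion", amplitude = c(1.4, 0.2), polarity = c(+1, -1), latency = c(0.14, 0.18)),
    motion_template("Dorsiflexion",  amplitude = c(0.2, 1.4), polarity = c(-1, -1), latency = c(0.18, 0.14)),
    motion_template("RadialFlexion", amplitude = c(0.8, 0.8), polarity = c(+1, +1), latency = c(0.15, 0.16)),
    motion_template("UlnarFlexion",  amplitude = c(0.6, 0.6), polarity = c(-1, -1), latency = c(0.16, 0.15)),
    motion_template("ElbowFlexion",  amplitude = c(1.0, 1.0), polarity = c(+1, +1), latency = c(0.20, 0.20),
                    damping = 2.5, frequency = 1.2, duration = 1.4)
  )
  names(tpl) <- vapply(tpl, function(t) t$motion_id, character(1))
  sig <- vapply(tpl, function(t)
    paste(c(t$amplitude, t$polarity, t$latency), collapse = ","), character(1))
  stopifnot(!anyDuplicated(sig))
  tpl
}

#' Sample the deterministic waveform of a template channel
#'
#' @param tmpl A [motion_template].
#' @param channel Channel index (1 = FCR, 2 = ECRL).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of `round(duration * fs)` samples starting at the
#'   channel's onset (latency is not included; the caller places the
#'   waveform in time).
#' @export
template_waveform <- function(tmpl, channel, fs) {
  stopifnot(inherits(tmpl, "motion_template"), channel %in% c(1L, 2L), fs > 0)
  n <- round(tmpl$duration * fs)
  t <- seq_len(n) / fs
  tmpl$amplitude[channel] * tmpl$polarity[channel] *
    exp(-tmpl$damping * t) * sin(2 * pi * tmpl$frequency * t)
}
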