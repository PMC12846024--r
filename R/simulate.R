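#' Specification of one simulated recording session
#'
#' Encodes the experimental protocol: a motion-free resting baseline, then
#' cued trials every `cue_interval` seconds in randomized interleaved order,
#' `trials_per_motion` repetitions of every listed motion. Target motions are
#' used for training and testing; unknown and non-target motions appear only
#' at test time. A configurable fraction of target trials is made ambiguous
#' by blending two target templates or by attenuating the scheduled one.
#'
#' Trial-to-trial variability (multiplicative amplitude jitter and onset
#' latency jitter) emulates the natural variation of motion execution;
#' additive white noise, slow baseline drift and 50 Hz interference emulate
#' the measurement chain.
#'
#' @param trials_per_motion Repetitions of each listed motion (default 50).
#' @param target_motions Six trained motion ids.
#' @param unknown_motions Motions excluded from training, tested only
#'   (default radial/ulnar flexion; set to `character(0)` to omit).
#' @param nontarget_motions Non-target body movements (default elbow flexion).
#' @param cue_interval Seconds between auditory cues (default 2).
#' @param sampling_rate Hz (default 1000).
#' @param noise_sd Additive Gaussian noise SD in volts (default 0.1).
#' @param drift_amplitude,drift_frequency Slow sinusoidal baseline drift
#'   (volts, Hz; default 0.1 V at 0.2 Hz — below the 0.5 Hz high-pass edge).
#' @param powerline_amplitude,powerline_frequency Mains interference
#'   (default 0.05 V at 50 Hz).
#' @param amp_jitter_sd SD of the per-trial multiplicative amplitude factor
#'   (mean 1, truncated to `[0.3, 2]`; default 0.2).
#' @param latency_jitter_sd SD of the per-trial onset shift in seconds
#'   (default 0.03).
#' @param ambiguous_fraction Fraction of target trials rendered ambiguous
#'   (default 0.15).
#' @param ambiguity_mode `"blend"` (convex mix of two target templates,
#'   weight in `[0.35, 0.65]`) or `"attenuate"` (amplitude scaled by a factor
#'   in `[0.2, 0.5]`).
#' @param rest_duration Motion-free baseline before the first cue (seconds,
#'   default 10, minimum 2).
#' @param seed Integer seed; every stochastic element derives from it.
#' @param templates Named list of [motion_template]s covering all listed
#'   motions (default [default_templates()]).
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(trials_per_motion = 50,
                         target_motions = c("Grasp", "Open", "Pronation",
                                            "Supination", "PalmarFlexion",
                                            "Dorsiflexion"),
                         unknown_motions = c("RadialFlexion", "UlnarFlexion"),
                         nontarget_motions = "ElbowFlexion",
                         cue_interval = 2,
                         sampling_rate = 1000,
                         noise_sd = 0.1,
                         drift_amplitude = 0.1,
                         drift_frequency = 0.2,
                         powerline_amplitude = 0.05,
                         powerline_frequency = 50,
                         amp_jitter_sd = 0.2,
                         latency_jitter_sd = 0.03,
                         ambiguous_fraction = 0.15,
                         ambiguity_mode = c("blend", "attenuate"),
                         rest_duration = 10,
                         seed = 1,
                         templates = default_templates()) {
  ambiguity_mode <- match.arg(ambiguity_mode)
  spec <- structure(
    list(trials_per_motion = as.integer(trials_per_motion),
         target_motions = target_motions,
         unknown_motions = unknown_motions,
         nontarget_motions = nontarget_motions,
         cue_interval = cue_interval,
         sampling_rate = sampling_rate,
         noise_sd = noise_sd,
         drift_amplitude = drift_amplitude,
         drift_frequency = drift_frequency,
         powerline_amplitude = powerline_amplitude,
         powerline_frequency = powerline_frequency,
         amp_jitter_sd = amp_jitter_sd,
         latency_jitter_sd = latency_jitter_sd,
         ambiguous_fraction = ambiguous_fraction,
         ambiguity_mode = ambiguity_mode,
         rest_duration = rest_duration,
         seed = as.integer(seed),
         templates = templates),
    class = "session_spec"
  )
  validate_session_spec(spec)
  spec
}

validate_session_spec <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  if (spec$trials_per_motion < 1L)
    stop("invalid session spec: trials_per_motion must be >= 1")
  if (spec$ambiguous_fraction < 0 || spec$ambiguous_fraction > 1)
    stop("invalid session spec: ambiguous_fraction must lie in [0, 1]")
  if (spec$rest_duration < 2)
    stop("invalid session spec: rest_duration must be >= 2 s")
  motions <- session_motions(spec)
  missing <- setdiff(motions, names(spec$templates))
  if (length(missing))
    stop("invalid session spec: no template for motion(s) ",
         paste(missing, collapse = ", "))
  durs <- vapply(spec$templates[motions], function(t)
    t$duration + max(t$latency), numeric(1))
  if (spec$cue_interval < max(durs))
    stop("invalid session spec: cue_interval (", spec$cue_interval,
         " s) is shorter than the longest template (", max(durs), " s)")
  invisible(spec)
}

session_motions <- function(spec) {
  c(spec$target_motions, spec$unknown_motions, spec$nontarget_motions)
}

motion_category <- function(spec, motion) {
  ifelse(motion %in% spec$target_motions, "target",
         ifelse(motion %in% spec$unknown_motions, "unknown", "nontarget"))
}

#' Generate one synthetic two-channel recording session
#'
#' Produces a resting baseline followed by cued trials in seeded random
#' interleaved order. Each trial's deterministic part is its motion template
#' (optionally blended with or attenuated into an ambiguous variant), scaled
#' by per-trial amplitude jitter and shifted by latency jitter; Gaussian
#' noise, sinusoidal drift and 50 Hz interference are added, and the output
#' is clipped to the +/-5 V range of the acquisition chain.
#'
#' @param spec A [session_spec()].
#' @param session_id Optional label stored with the recording.
#' @return An object of class `pvdf_recording`: list with `signal`
#'   (samples x 2 matrix, volts), `fs`, `annotations` (data frame with
#'   `trial_id`, `cue_s`, `onset_s`, `motion`, `category`, `ambiguous`),
#'   `rest_range` (sample index range of the baseline), `session_id`, `spec`.
#' @export
generate_session <- function(spec, session_id = paste0("S", spec$seed)) {
  validate_session_spec(spec)
  withr::with_seed(spec$seed, generate_session_impl(spec, session_id))
}

generate_session_impl <- function(spec, session_id) {
  fs <- spec$sampling_rate
  motions <- rep(session_motions(spec), each = spec$trials_per_motion)
  motions <- motions[sample.int(length(motions))]
  n_trials <- length(motions)
  cues <- spec$rest_duration + (seq_len(n_trials) - 1L) * spec$cue_interval
  total_s <- spec$rest_duration + n_trials * spec$cue_interval + 2
  n <- round(total_s * fs)
  x <- matrix(0, n, 2)

  category <- motion_category(spec, motions)
  is_target <- category == "target"
  n_amb <- floor(spec$ambiguous_fraction * sum(is_target))
  ambiguous <- rep(FALSE, n_trials)
  if (n_amb > 0)
    ambiguous[sample(which(is_target), n_amb)] <- TRUE

  onset <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    tmpl <- spec$templates[[motions[i]]]
    amp_jit <- min(max(stats::rnorm(1, 1, spec$amp_jitter_sd), 0.3), 2)
    lat_jit <- stats::rnorm(1, 0, spec$latency_jitter_sd)
    blend_w <- 1
    tmpl2 <- NULL
    if (ambiguous[i]) {
      if (spec$ambiguity_mode == "blend") {
        other <- sample(setdiff(spec$target_motions, motions[i]), 1)
        tmpl2 <- spec$templates[[other]]
        blend_w <- stats::runif(1, 0.35, 0.65)
      } else {
        amp_jit <- amp_jit * stats::runif(1, 0.2, 0.5)
      }
    }
    for (ch in 1:2) {
      x <- add_waveform(x, ch, tmpl, cues[i] + tmpl$latency[ch] + lat_jit,
                        amp_jit * blend_w, fs)
      if (!is.null(tmpl2))
        x <- add_waveform(x, ch, tmpl2, cues[i] + tmpl2$latency[ch] + lat_jit,
                          amp_jit * (1 - blend_w), fs)
    }
    onset[i] <- cues[i] + min(tmpl$latency) + lat_jit
  }

  tvec <- (seq_len(n) - 1L) / fs
  if (spec$noise_sd > 0)
    x <- x + matrix(stats::rnorm(2L * n, 0, spec$noise_sd), n, 2)
  if (spec$drift_amplitude > 0)
    x <- x + spec$drift_amplitude *
      sin(2 * pi * spec$drift_frequency * tvec + stats::runif(2, 0, 2 * pi)[col(x)])
  if (spec$powerline_amplitude > 0)
    x <- x + spec$powerline_amplitude *
      sin(2 * pi * spec$powerline_frequency * tvec + stats::runif(2, 0, 2 * pi)[col(x)])
  x[x > 5] <- 5
  x[x < -5] <- -5

  ann <- data.frame(
    trial_id = paste0(session_id, "_T", sprintf("%04d", seq_len(n_trials))),
    cue_s = cues, onset_s = onset, motion = motions,
    category = category, ambiguous = ambiguous,
    stringsAsFactors = FALSE
  )
  structure(
    list(signal = x, fs = fs, annotations = ann,
         rest_range = c(1L, as.integer(spec$rest_duration * fs)),
         session_id = session_id, spec = spec),
    class = "pvdf_recording"
  )
}

# returns x with tmpl's channel waveform added starting at time t0
add_waveform <- function(x, ch, tmpl, t0, scale, fs) {
  w <- scale * template_waveform(tmpl, ch, fs)
  i0 <- round(t0 * fs) + 1L
  idx <- i0:(i0 + length(w) - 1L)
  keep <- idx >= 1L & idx <= nrow(x)
  x[idx[keep], ch] <- x[idx[keep], ch] + w[keep]
  x
}

#' @export
print.pvdf_recording <- function(x, ...) {
  cat("<pvdf_recording> ", x$session_id, ": ",
      nrow(x$signal), " samples x 2 ch @ ", x$fs, " Hz, ",
      nrow(x$annotations), " trials (",
      sum(x$annotations$category == "target"), " target, ",
      sum(x$annotations$category == "unknown"), " unknown, ",
      sum(x$annotations$category == "nontarget"), " nontarget)\n", sep = "")
  invisible(x)
}

#' Generate a multi-session study
#'
#' Derives one sub-seed per session from the base spec's seed, applies
#' per-session overrides (e.g. dropping the unknown-motion or non-target
#' protocol from sessions that did not include it), and simulates each
#' session.
#'
#' @param n_sessions Number of sessions (>= 1).
#' @param base_spec A [session_spec()] shared by all sessions.
#' @param overrides Optional list of per-session named lists of spec fields
#'   to replace (length `n_sessions`; `NULL` entries leave the base spec).
#' @return List of `pvdf_recording`s with session ids `S01`, `S02`, ...
#' @seealso [study_overrides()] for the canonical 12-session layout.
#' @export
generate_study <- function(n_sessions, base_spec, overrides = NULL) {
  stopifnot(n_sessions >= 1)
  if (!is.null(overrides) && length(overrides) != n_sessions)
    stop("overrides must have one entry per session")
  sub_seeds <- withr::with_seed(
    base_spec$seed, sample.int(.Machine$integer.max, n_sessions))
  lapply(seq_len(n_sessions), function(i) {
    spec_i <- base_spec
    if (!is.null(overrides) && !is.null(overrides[[i]]))
      spec_i <- utils::modifyList(spec_i, overrides[[i]])
    spec_i$seed <- sub_seeds[i]
    validate_session_spec(spec_i)
    generate_session(spec_i, session_id = sprintf("S%02d", i))
  })
}

#' Per-session overrides for the canonical study layout
#'
#' All sessions run the target-motion protocol; only `unknown_sessions` keep
#' the unknown-motion protocol and only `nontarget_sessions` keep the
#' non-target body-movement protocol (defaults: 7 of 12 and 4 of 12).
#'
#' @param n_sessions Total sessions (default 12).
#' @param unknown_sessions Indices retaining unknown motions (default 1:7).
#' @param nontarget_sessions Indices retaining the non-target movement
#'   (default 9:12).
#' @return List of per-session override lists for [generate_study()].
#' @export
study_overrides <- function(n_sessions = 12, unknown_sessions = 1:7,
                            nontarget_sessions = 9:12) {
  lapply(seq_len(n_sessions), function(i) {
    ov <- list()
    if (!(i %in% unknown_sessions)) ov$unknown_motions <- character(0)
    if (!(i %in% nontarget_sessions)) ov$nontarget_motions <- character(0)
    if (length(ov)) ov else NULL
  })
}

#' Write / read a recording as plain text
#'
#' `write_recording()` stores the signal as a columnar file
#' (`time_s, ch1_V, ch2_V`) plus a sidecar annotation table;
#' `read_recording()` restores the `pvdf_recording` (without the generating
#' spec, which is not needed downstream).
#'
#' @param rec A `pvdf_recording`.
#' @param dir Output directory (created if missing).
#' @return `write_recording()` the directory, invisibly;
#'   `read_recording()` a `pvdf_recording`.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "pvdf_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- data.frame(time_s = (seq_len(nrow(rec$signal)) - 1L) / rec$fs,
                    ch1_V = rec$signal[, 1], ch2_V = rec$signal[, 2])
  meta <- c(paste0("# session_id: ", rec$session_id),
            paste0("# fs_hz: ", rec$fs),
            paste0("# rest_range: ", rec$rest_range[1], " ", rec$rest_range[2]))
  write_csv_with_header(sig, file.path(dir, "signal.csv"), meta)
  write_csv_with_header(rec$annotations, file.path(dir, "annotations.csv"), meta)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  sig_path <- file.path(dir, "signal.csv")
  ann_path <- file.path(dir, "annotations.csv")
  hdr <- readLines(sig_path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key) {
    line <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(line)) stop("missing '", key, "' header in ", sig_path)
    sub(paste0("^# ", key, ": "), "", line[1])
  }
  fs <- as.numeric(get_meta("fs_hz"))
  rest <- as.integer(strsplit(get_meta("rest_range"), " ")[[1]])
  sig <- utils::read.csv(sig_path, comment.char = "#")
  if (!identical(names(sig), c("time_s", "ch1_V", "ch2_V")))
    stop("unexpected columns in ", sig_path)
  ann <- utils::read.csv(ann_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  structure(
    list(signal = cbind(sig$ch1_V, sig$ch2_V), fs = fs, annotations = ann,
         rest_range = rest, session_id = get_meta("session_id"), spec = NULL),
    class = "pvdf_recording"
  )
}
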