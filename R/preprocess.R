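#' Digital conditioning and detection configuration
#'
#' @param highpass_cutoff First-order high-pass cutoff in Hz (default 0.5),
#'   suppressing baseline drift and offset.
#' @param notch_center Notch center frequency in Hz (default 50, mains).
#' @param notch_q Notch quality factor (default 25; second-order biquad).
#' @param downsample_block Samples averaged per output sample (default 10:
#'   1000 Hz -> 100 Hz).
#' @param threshold_k Multiplier `k` in the onset threshold
#'   `theta_i = mean(|rest_i|) + k * sd(|rest_i|)` (default 5).
#' @param threshold_floor Lower bound for thresholds, used when a resting
#'   channel is degenerate (volts, default 1e-6).
#' @param refractory Detection dead time after each event in seconds
#'   (default 1; motions complete within about 1 s and cues are 2 s apart).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(highpass_cutoff = 0.5, notch_center = 50,
                          notch_q = 25, downsample_block = 10,
                          threshold_k = 5, threshold_floor = 1e-6,
                          refractory = 1.0) {
  stopifnot(highpass_cutoff > 0, notch_center > 0, notch_q > 0,
            downsample_block >= 1, threshold_k >= 0, threshold_floor > 0,
            refractory >= 0)
  structure(list(highpass_cutoff = highpass_cutoff,
                 notch_center = notch_center, notch_q = notch_q,
                 downsample_block = as.integer(downsample_block),
                 threshold_k = threshold_k, threshold_floor = threshold_floor,
                 refractory = refractory),
            class = "filter_config")
}

#' Design the digital filters for a given sampling rate
#'
#' First-order Butterworth high-pass (bilinear transform, via
#' [signal::butter()]) followed by a second-order notch biquad at the mains
#' frequency with quality factor `Q` (constrained-zero design: zeros on the
#' unit circle at the notch frequency, poles at radius set by the bandwidth
#' `f0/Q`).
#'
#' @param cfg A [filter_config()].
#' @param fs Sampling rate in Hz; cutoffs must lie below `fs/2`.
#' @return List with elements `highpass` and `notch`, each a list of
#'   numerator `b` and denominator `a` coefficients.
#' @export
design_filters <- function(cfg, fs) {
  stopifnot(cfg$highpass_cutoff < fs / 2, cfg$notch_center < fs / 2)
  hp <- signal::butter(1, cfg$highpass_cutoff / (fs / 2), type = "high")
  w0 <- 2 * pi * cfg$notch_center / fs
  alpha <- sin(w0) / (2 * cfg$notch_q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(highpass = list(b = as.numeric(hp$b), a = as.numeric(hp$a)),
       notch = list(b = b / a[1], a = a / a[1]))
}

#' Magnitude of a digital filter's frequency response
#'
#' Evaluates `|H(e^{j 2 pi f / fs})|` directly from the difference-equation
#' coefficients.
#'
#' @param b,a Filter coefficients.
#' @param freq Frequency in Hz (vectorized).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of magnitudes.
#' @export
filter_response_magnitude <- function(b, a, freq, fs) {
  vapply(freq, function(f) {
    z <- exp(-1i * 2 * pi * f / fs * seq(0, max(length(b), length(a)) - 1))
    Mod(sum(b * z[seq_along(b)]) / sum(a * z[seq_along(a)]))
  }, numeric(1))
}

#' Apply the causal high-pass and notch filters to all channels
#'
#' Filters are applied forward-only (no zero-phase filtering), matching an
#' online controller where future samples are unavailable.
#'
#' @param x Samples-by-channels numeric matrix (or a `pvdf_recording`).
#' @param cfg A [filter_config()].
#' @param fs Sampling rate in Hz (taken from the recording if `x` is one).
#' @return Filtered matrix of the same dimensions (for a recording input, a
#'   recording with filtered signal).
#' @export
apply_digital_filters <- function(x, cfg = filter_config(), fs = NULL) {
  if (inherits(x, "pvdf_recording")) {
    x$signal <- apply_digital_filters(x$signal, cfg, x$fs)
    return(x)
  }
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("signal contains non-finite samples")
  if (is.null(fs)) stop("fs is required for matrix input")
  flt <- design_filters(cfg, fs)
  for (ch in seq_len(ncol(x))) {
    y <- signal::filter(flt$highpass$b, flt$highpass$a, x[, ch])
    x[, ch] <- signal::filter(flt$notch$b, flt$notch$a, y)
  }
  x
}

#' Downsample by block averaging
#'
#' Every block of `block` consecutive samples is replaced by its arithmetic
#' mean; a trailing partial block is discarded.
#'
#' @param x Numeric vector or samples-by-channels matrix.
#' @param block Block length (default 10).
#' @return Downsampled vector/matrix with `floor(n / block)` samples.
#' @export
downsample_signal <- function(x, block = 10) {
  if (block < 1) stop("block must be >= 1")
  block <- as.integer(block)
  if (is.matrix(x)) return(apply(x, 2, downsample_signal, block = block))
  n_out <- length(x) %/% block
  if (n_out == 0) return(numeric(0))
  colMeans(matrix(x[seq_len(n_out * block)], nrow = block))
}

#' Calibrate per-channel detection thresholds from a resting segment
#'
#' `theta_i = mean(|x_i|) + k * sd(|x_i|)` over the motion-free baseline,
#' independently per channel; degenerate (e.g. all-zero) channels fall back
#' to the configured floor so thresholds stay strictly positive.
#'
#' @param rest Resting-segment matrix (samples x channels) at the detection
#'   rate.
#' @param cfg A [filter_config()] (uses `threshold_k`, `threshold_floor`).
#' @param fs Sampling rate of `rest` in Hz (default 100); the segment must
#'   cover at least 2 s.
#' @return Object of class `threshold_set`: list with `theta` (numeric per
#'   channel) and `calibration` (per-channel mean and sd of `|rest|`).
#' @export
estimate_thresholds <- function(rest, cfg = filter_config(), fs = 100) {
  rest <- as.matrix(rest)
  if (nrow(rest) < 2 * fs)
    stop("resting segment too short: need >= 2 s (", 2 * fs, " samples), got ",
         nrow(rest))
  m <- apply(abs(rest), 2, mean)
  s <- apply(abs(rest), 2, stats::sd)
  theta <- pmax(m + cfg$threshold_k * s, cfg$threshold_floor)
  structure(list(theta = theta,
                 calibration = data.frame(channel = seq_along(theta),
                                          mean_abs = m, sd_abs = s)),
            class = "threshold_set")
}

#' Event-driven onset detection
#'
#' An event fires at the first sample index where any channel's absolute
#' value exceeds its threshold; detection is then suppressed for the
#' refractory window. Events too close to the signal edges for a full
#' analysis window (10 samples before, 9 after) are discarded. The same rule
#' serves every motion category.
#'
#' @param x Samples-by-channels matrix at the detection rate (100 Hz).
#' @param thresholds A [estimate_thresholds()] result (or numeric vector of
#'   per-channel thresholds).
#' @param refractory Dead time after each event in seconds.
#' @param fs Sampling rate of `x` in Hz (default 100).
#' @return Data frame with one row per event: `nd` (1-based sample index)
#'   and `channel` (lowest-index channel above threshold at `nd`).
#' @export
detect_onsets <- function(x, thresholds, refractory = 1.0, fs = 100) {
  x <- as.matrix(x)
  theta <- if (inherits(thresholds, "threshold_set")) thresholds$theta
           else as.numeric(thresholds)
  stopifnot(length(theta) == ncol(x), all(theta > 0))
  exceed <- sweep(abs(x), 2, theta, `>`)
  hit <- which(rowSums(exceed) > 0)
  nd <- integer(0); trig <- integer(0)
  dead <- as.integer(round(refractory * fs))
  last <- -Inf
  for (i in hit) {
    if (i - last <= dead) next
    nd <- c(nd, i)
    trig <- c(trig, which(exceed[i, ])[1])
    last <- i
  }
  keep <- nd - 10L >= 1L & nd + 9L <= nrow(x)
  data.frame(nd = nd[keep], channel = trig[keep])
}

#' Extract the windowed feature vector for one detection event
#'
#' Takes the 200 ms analysis window centered on the detection moment
#' (samples `nd - 10` to `nd + 9` inclusive, 20 samples per channel at
#' 100 Hz) and concatenates the channels, channel 1 first, into a single
#' vector of dimension `20 * n_channels` (40 for two channels).
#'
#' @param x Samples-by-channels matrix at 100 Hz.
#' @param nd Detection sample index (1-based).
#' @return Numeric feature vector of length `20 * ncol(x)`.
#' @export
extract_feature <- function(x, nd) {
  x <- as.matrix(x)
  if (nd - 10L < 1L || nd + 9L > nrow(x))
    stop("analysis window [nd-10, nd+9] out of bounds for nd = ", nd)
  as.numeric(x[(nd - 10L):(nd + 9L), ])
}

#' Run the full preprocessing pipeline on a recording
#'
#' Filters at the acquisition rate, downsamples to the detection rate,
#' calibrates thresholds on the resting baseline, detects onsets over the
#' whole recording with one shared rule, matches events to annotated trials
#' (first event with detection time inside `[cue, cue + cue_interval)`), and
#' extracts one feature vector per matched trial.
#'
#' @param rec A `pvdf_recording`.
#' @param cfg A [filter_config()].
#' @param cue_interval Trial window length in seconds (default: from the
#'   recording's spec, else 2).
#' @return Data frame with one row per matched trial: `trial_id`,
#'   `session_id`, `motion`, `category`, `ambiguous`, `t_detect_s`, and
#'   feature columns `z1..z40`. Attributes `n_unmatched_trials` and
#'   `n_spurious_events` count protocol mismatches; `thresholds` records the
#'   calibrated `threshold_set`.
#' @export
extract_trial_features <- function(rec, cfg = filter_config(),
                                   cue_interval = NULL) {
  stopifnot(inherits(rec, "pvdf_recording"))
  if (is.null(cue_interval))
    cue_interval <- if (!is.null(rec$spec)) rec$spec$cue_interval else 2
  filt <- apply_digital_filters(rec$signal, cfg, rec$fs)
  ds <- downsample_signal(filt, cfg$downsample_block)
  fs_ds <- rec$fs / cfg$downsample_block
  rest_ds <- ds[seq(ceiling(rec$rest_range[1] / cfg$downsample_block),
                    rec$rest_range[2] %/% cfg$downsample_block), , drop = FALSE]
  thr <- estimate_thresholds(rest_ds, cfg, fs_ds)
  ev <- detect_onsets(ds, thr, cfg$refractory, fs_ds)
  ev$t_s <- (ev$nd - 1) / fs_ds

  ann <- rec$annotations
  rows <- vector("list", nrow(ann))
  used <- rep(FALSE, nrow(ev))
  for (i in seq_len(nrow(ann))) {
    j <- which(!used & ev$t_s >= ann$cue_s[i] &
                 ev$t_s < ann$cue_s[i] + cue_interval)
    if (!length(j)) next
    j <- j[1]
    used[j] <- TRUE
    z <- extract_feature(ds, ev$nd[j])
    rows[[i]] <- data.frame(
      trial_id = ann$trial_id[i], session_id = rec$session_id,
      motion = ann$motion[i], category = ann$category[i],
      ambiguous = ann$ambiguous[i], t_detect_s = ev$t_s[j],
      t(z), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame()
  } else {
    names(out)[-(1:6)] <- paste0("z", seq_len(20 * ncol(ds)))
    rownames(out) <- NULL
  }
  attr(out, "n_unmatched_trials") <- nrow(ann) - nrow(out)
  attr(out, "n_spurious_events") <- sum(!used)
  attr(out, "thresholds") <- thr
  out
}

#' Extract the numeric feature matrix from a feature data frame
#'
#' @param features Data frame with feature columns `z1..zD`.
#' @return Numeric matrix (trials x D) in column order `z1, z2, ...`.
#' @export
feature_matrix <- function(features) {
  zcols <- grep("^z[0-9]+$", names(features), value = TRUE)
  if (!length(zcols)) stop("no feature columns z1..zD found")
  as.matrix(features[, zcols[order(as.integer(sub("z", "", zcols)))]])
}
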