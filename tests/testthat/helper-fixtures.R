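# Shared fixtures: all synthetic, generated in code.

# Reduced session for fast tests: fewer trials, shorter rest.
small_spec <- function(trials = 8, seed = 42, ...) {
  session_spec(trials_per_motion = trials, rest_duration = 4, seed = seed,
               ...)
}

# Six well-separated Gaussian clusters in 40-D, as a feature data frame.
cluster_features <- function(n_per_class = 25, sep = 6, sd = 0.3,
                             seed = 1, classes = paste0("M", 1:6),
                             category = "target", session_id = "SX") {
  withr::with_seed(seed, {
    centers <- matrix(stats::rnorm(length(classes) * 40), length(classes))
    centers <- sep * centers / sqrt(rowSums(centers^2))
    rows <- lapply(seq_along(classes), function(k) {
      z <- centers[rep(k, n_per_class), ] +
        matrix(stats::rnorm(n_per_class * 40, 0, sd), n_per_class)
      cbind(data.frame(trial_id = sprintf("%s_%s_%03d", session_id,
                                          classes[k], seq_len(n_per_class)),
                       session_id = session_id, motion = classes[k],
                       category = category, ambiguous = FALSE,
                       t_detect_s = NA_real_),
            stats::setNames(as.data.frame(z), paste0("z", 1:40)))
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}

# Hand-built decision data frame for metric oracles.
make_decisions <- function(trial_id, output, mechanism = "test") {
  data.frame(trial_id = trial_id, mechanism = mechanism, output = output,
             rejected = output == "REJECT", stringsAsFactors = FALSE)
}

# One cached small end-to-end session evaluation, shared across test files.
cached_session_eval <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      rec <- generate_session(small_spec(trials = 10, seed = 31))
      val <<- evaluate_session(rec)
    }
    val
  }
})
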