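#' Rejection configuration for the entropy mechanism
#'
#' @param tau Entropy threshold (default 0.7, natural-log units; the
#'   six-class maximum is `log(6) ~ 1.79`).
#' @param log_base Base of the entropy logarithm (default `exp(1)`).
#' @return Object of class `reject_config`.
#' @export
reject_config <- function(tau = 0.7, log_base = exp(1)) {
  stopifnot(tau >= 0, log_base > 1)
  structure(list(tau = tau, log_base = log_base), class = "reject_config")
}

#' Shannon entropy of a class-probability vector
#'
#' `H(p) = -sum_k p_k log(p_k)`, with zero components contributing zero.
#'
#' @param p Probability vector (non-negative, summing to 1 within 1e-6).
#' @param log_base Logarithm base (default natural).
#' @return Entropy in `[0, log(K)]`.
#' @export
shannon_entropy <- function(p, log_base = exp(1)) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("probabilities must be finite and non-negative")
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  pos <- p > 0
  -sum(p[pos] * log(p[pos], base = log_base))
}

new_decision <- function(mechanism, class = NA_character_, rejected,
                         evidence = list()) {
  structure(c(list(mechanism = mechanism,
                   output = if (rejected) "REJECT" else class,
                   rejected = rejected),
              evidence),
            class = "reject_decision")
}

#' @export
print.reject_decision <- function(x, ...) {
  cat("<decision ", x$mechanism, "> ", x$output, "\n", sep = "")
  invisible(x)
}

#' Baseline decision: always emit the argmax class
#'
#' The baseline classifier has no reject option: the class with the maximum
#' one-vs-rest decision value is always emitted (ties resolve to the lowest
#' class index).
#'
#' @param f Numeric vector of K one-vs-rest decision values.
#' @param classes Optional class labels (default `"1".."K"`).
#' @return A `reject_decision` with `output` a class, never `"REJECT"`.
#' @export
decide_baseline <- function(f, classes = as.character(seq_along(f))) {
  if (any(!is.finite(f))) stop("decision values must be finite")
  k <- which.max(f)
  new_decision("baseline", classes[k], rejected = FALSE,
               evidence = list(f = f))
}

#' Entropy-based rejection on MLP probabilities
#'
#' Rejects when the Shannon entropy of the softmax output exceeds the fixed
#' threshold `tau`; otherwise emits the argmax class.
#'
#' @param p Class-probability vector.
#' @param cfg A [reject_config()].
#' @param classes Optional class labels.
#' @return A `reject_decision` with entropy evidence `H`.
#' @export
decide_bpnn_entropy <- function(p, cfg = reject_config(),
                                classes = as.character(seq_along(p))) {
  H <- shannon_entropy(p, cfg$log_base)
  new_decision("bpnn_entropy", classes[which.max(p)], rejected = H > cfg$tau,
               evidence = list(H = H, p = p))
}

#' One-class SVM rejection
#'
#' Accepts (emitting the baseline classifier's predicted class) only when
#' the signed one-class score is strictly positive, i.e. the input lies
#' inside the region learned from target training data; `Delta <= 0` rejects.
#'
#' @param delta Signed one-class score `Delta(z)`.
#' @param predicted_class The baseline classifier's prediction for the same
#'   input.
#' @return A `reject_decision` with score evidence `delta`.
#' @export
decide_ocsvm <- function(delta, predicted_class) {
  if (!is.finite(delta)) stop("one-class score must be finite")
  new_decision("ocsvm", predicted_class, rejected = delta <= 0,
               evidence = list(delta = delta))
}

#' One-vs-rest sign-consistency rejection (OvR-RO)
#'
#' The parameter-free reject option: count the strictly positive one-vs-rest
#' decision values. Exactly one positive sign identifies a single supported
#' class, which is accepted; zero or multiple positive signs indicate an
#' inconsistent decision pattern and the input is rejected. A decision value
#' of exactly zero counts as non-positive. The rule reads nothing but the
#' decision values themselves.
#'
#' @param f Numeric vector of K one-vs-rest decision values.
#' @param classes Optional class labels.
#' @return A `reject_decision` with evidence `n_positive` and the sign
#'   pattern `signs` (character, e.g. `"+--+--"`).
#' @export
decide_ovr_ro <- function(f, classes = as.character(seq_along(f))) {
  if (any(!is.finite(f))) stop("decision values must be finite")
  pos <- f > 0
  n_pos <- sum(pos)
  new_decision("ovr_ro",
               class = if (n_pos == 1) classes[which(pos)] else NA_character_,
               rejected = n_pos != 1,
               evidence = list(f = f, n_positive = n_pos,
                               signs = paste(ifelse(pos, "+", "-"),
                                             collapse = "")))
}

#' Apply one rejection mechanism to a set of trials
#'
#' Computes the mechanism's evidence from the trained bundle and returns one
#' decision row per trial. All mechanisms consume the same feature vectors;
#' the baseline mechanism never rejects.
#'
#' @param bundle A [train_model_bundle()] result.
#' @param features Feature data frame (test trials).
#' @param mechanism One of `"baseline"`, `"ocsvm"`, `"bpnn_entropy"`,
#'   `"ovr_ro"`.
#' @param cfg A [reject_config()] (used by `bpnn_entropy` only).
#' @return Data frame: `trial_id`, `mechanism`, `output` (class or
#'   `"REJECT"`), `rejected`, `n_positive`, `H`, `delta`, `f1..fK`.
#' @export
decide_trials <- function(bundle, features,
                          mechanism = c("baseline", "ocsvm", "bpnn_entropy",
                                        "ovr_ro"),
                          cfg = reject_config()) {
  mechanism <- match.arg(mechanism)
  stopifnot(inherits(bundle, "model_bundle"))
  x <- feature_matrix(features)
  n <- nrow(x)
  K <- length(bundle$classes)
  f <- decision_values(bundle$ovr_svm, x)
  H <- rep(NA_real_, n); delta <- rep(NA_real_, n)
  decisions <- switch(
    mechanism,
    baseline = lapply(seq_len(n), function(i)
      decide_baseline(f[i, ], bundle$classes)),
    ovr_ro = lapply(seq_len(n), function(i)
      decide_ovr_ro(f[i, ], bundle$classes)),
    ocsvm = {
      delta <- ocsvm_score(bundle$ocsvm, x)
      base <- bundle$classes[apply(f, 1, which.max)]
      lapply(seq_len(n), function(i) decide_ocsvm(delta[i], base[i]))
    },
    bpnn_entropy = {
      P <- bpnn_probs(bundle$bpnn, x)
      H <- apply(P, 1, shannon_entropy, log_base = cfg$log_base)
      lapply(seq_len(n), function(i)
        decide_bpnn_entropy(P[i, ], cfg, bundle$classes))
    })
  out <- data.frame(
    trial_id = features$trial_id,
    mechanism = mechanism,
    output = vapply(decisions, `[[`, character(1), "output"),
    rejected = vapply(decisions, `[[`, logical(1), "rejected"),
    n_positive = if (mechanism == "ovr_ro")
      vapply(decisions, `[[`, numeric(1), "n_positive") else rowSums(f > 0),
    H = H, delta = delta,
    stringsAsFactors = FALSE)
  fdf <- as.data.frame(f)
  names(fdf) <- paste0("f", seq_len(K))
  cbind(out, fdf)
}
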