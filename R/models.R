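#' Fixed classifier hyperparameters
#'
#' All hyperparameters are global constants of the pipeline: one
#' configuration serves every session and motion class, with no
#' session-specific or class-specific tuning.
#'
#' @param C SVM regularization parameter (default 16).
#' @param gamma RBF kernel width (default 0.0625).
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(C = 16, gamma = 0.0625) {
  stopifnot(C > 0, gamma > 0)
  structure(list(C = C, gamma = gamma), class = "svm_config")
}

#' @param nu Expected outlier fraction of the one-class SVM (default 0.1).
#' @rdname svm_config
#' @return `ocsvm_config()`: object of class `ocsvm_config`. Its kernel
#'   width is not free: it follows the scale heuristic
#'   `gamma = 1 / (d * Var(z))` with `d` the feature dimension and `Var(z)`
#'   the variance of the flattened training matrix.
#' @export
ocsvm_config <- function(nu = 0.1) {
  stopifnot(nu > 0, nu <= 1)
  structure(list(nu = nu), class = "ocsvm_config")
}

#' @param hidden Hidden-layer width of the MLP (default 25).
#' @param epochs Full-batch training epochs (default 1000).
#' @param lr,beta1,beta2,eps Adam optimizer parameters (defaults 0.001, 0.9,
#'   0.999, 1e-8).
#' @param init Weight initialization: `"uniform01"` draws all weights and
#'   biases from U\[0, 1) (the default), `"symmetric"` from
#'   U\[-0.5, 0.5).
#' @param seed Seed for weight initialization.
#' @rdname svm_config
#' @return `bpnn_config()`: object of class `bpnn_config`.
#' @export
bpnn_config <- function(hidden = 25, epochs = 1000, lr = 0.001,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        init = c("uniform01", "symmetric"), seed = 1) {
  init <- match.arg(init)
  stopifnot(hidden >= 1, epochs >= 1, lr > 0)
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 init = init, seed = as.integer(seed)),
            class = "bpnn_config")
}

#' Stratified train/test split of trial features
#'
#' Only target-category trials are eligible for training; unknown and
#' non-target trials are always routed to the test set. Target trials are
#' split per motion class with a fixed seed so that all classifier backbones
#' share one partition.
#'
#' @param features Feature data frame from [extract_trial_features()].
#' @param fraction Training fraction of each target class, in (0, 1)
#'   (default 0.5).
#' @param seed Integer seed for the partition.
#' @return List with data frames `train` (target trials only) and `test`.
#' @export
split_trials <- function(features, fraction = 0.5, seed = 1) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly in (0, 1): an empty train or test set ",
         "is not a usable partition")
  tgt <- features[features$category == "target", , drop = FALSE]
  counts <- table(tgt$motion)
  if (any(counts < 2))
    stop("every target class needs >= 2 trials to split; got: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(tgt)), tgt$motion), function(ix) {
      sample(ix, floor(fraction * length(ix)))
    }), use.names = FALSE)
  })
  train <- tgt[sort(train_idx), , drop = FALSE]
  test <- features[!(features$trial_id %in% train$trial_id), , drop = FALSE]
  list(train = train, test = test)
}

#' Train the baseline one-vs-rest SVM
#'
#' Six binary RBF SVMs, one per target class against the rest, with the
#' fixed hyperparameters of [svm_config()]. No feature scaling is applied.
#'
#' @param train Training feature data frame (target trials).
#' @param cfg An [svm_config()].
#' @param classes Class label order; defaults to the sorted unique motions
#'   present. Determines the meaning of decision values `f1..fK`.
#' @return Object of class `ovr_svm`.
#' @export
train_ovr_svm <- function(train, cfg = svm_config(), classes = NULL) {
  x <- feature_matrix(train)
  y <- as.character(train$motion)
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(classes) < 2) stop("need >= 2 classes to train a classifier")
  stopifnot(all(y %in% classes))
  fits <- lapply(classes, function(k) {
    yk <- factor(ifelse(y == k, "pos", "rest"), levels = c("pos", "rest"))
    fit <- e1071::svm(x, yk, type = "C-classification", kernel = "radial",
                      cost = cfg$C, gamma = cfg$gamma, scale = FALSE)
    dv <- attr(stats::predict(fit, x[1, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    # libsvm orients the decision function toward the first label it sees
    # in the data; normalize so that positive always means "pos"
    list(fit = fit, sign = if (colnames(dv)[1] == "pos/rest") 1 else -1)
  })
  structure(list(fits = fits, classes = classes, cfg = cfg,
                 train_ids = train$trial_id),
            class = "ovr_svm")
}

#' One-vs-rest decision values
#'
#' @param model An `ovr_svm`.
#' @param x Feature matrix (rows = trials) or single feature vector.
#' @return Matrix (n x K) of decision values `f_k(z)`; `f_k > 0` means class
#'   `k` is supported.
#' @export
decision_values <- function(model, x) UseMethod("decision_values")

#' @export
decision_values.ovr_svm <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  f <- vapply(model$fits, function(m) {
    dv <- attr(stats::predict(m$fit, x, decision.values = TRUE),
               "decision.values")
    m$sign * as.numeric(dv)
  }, numeric(nrow(x)))
  f <- matrix(f, nrow = nrow(x), dimnames = list(NULL, model$classes))
  f
}

#' @param object An `ovr_svm`.
#' @param newdata Feature matrix or vector.
#' @param ... Unused.
#' @return Character vector of predicted classes (argmax of the decision
#'   values; ties resolve to the lowest class index).
#' @rdname decision_values
#' @export
predict.ovr_svm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  object$classes[apply(f, 1, which.max)]
}

#' Train the one-class SVM on pooled target features
#'
#' All target classes are pooled; the RBF width follows the scale heuristic
#' `gamma = 1 / (d * Var(z))` computed on the flattened training matrix
#' (population variance).
#'
#' @param train Training feature data frame (target trials, pooled).
#' @param cfg An [ocsvm_config()].
#' @return Object of class `ocsvm` with elements `fit`, `gamma`, `nu`,
#'   `train_ids`.
#' @export
train_ocsvm <- function(train, cfg = ocsvm_config()) {
  x <- feature_matrix(train)
  if (nrow(x) == 0) stop("empty training set")
  v <- mean((x - mean(x))^2)
  gamma <- 1 / (ncol(x) * v)
  fit <- e1071::svm(x, y = NULL, type = "one-classification",
                    kernel = "radial", nu = cfg$nu, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, gamma = gamma, nu = cfg$nu,
                 train_ids = train$trial_id),
            class = "ocsvm")
}

#' Signed one-class score
#'
#' @param model An `ocsvm`.
#' @param x Feature matrix or vector.
#' @return Numeric vector of signed scores `Delta(z)`; positive inside the
#'   learned region.
#' @export
ocsvm_score <- function(model, x) {
  stopifnot(inherits(model, "ocsvm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.numeric(attr(stats::predict(model$fit, x, decision.values = TRUE),
                  "decision.values"))
}

#' Train the softmax multilayer perceptron
#'
#' A 40-25-6 network (input - tanh hidden - softmax output) trained
#' full-batch for a fixed number of epochs to minimize multiclass
#' cross-entropy with the Adam optimizer. Initial Adam moments are zero and
#' initial weights are drawn from U\[0, 1) under the configured seed, so
#' training is deterministic given data and seed.
#'
#' @param train Training feature data frame (target trials).
#' @param cfg A [bpnn_config()].
#' @param classes Class label order (default: sorted unique motions).
#' @return Object of class `bpnn` with the weight matrices, class order and
#'   final training loss.
#' @export
train_bpnn <- function(train, cfg = bpnn_config(), classes = NULL) {
  x <- feature_matrix(train)
  y <- as.character(train$motion)
  if (is.null(classes)) classes <- sort(unique(y))
  stopifnot(all(y %in% classes))
  yi <- match(y, classes)
  K <- length(classes)
  n <- nrow(x); d <- ncol(x); h <- cfg$hidden

  par <- withr::with_seed(cfg$seed, {
    r <- function(m) if (cfg$init == "uniform01") stats::runif(m)
                     else stats::runif(m) - 0.5
    list(W1 = matrix(r(d * h), d, h), b1 = r(h),
         W2 = matrix(r(h * K), h, K), b2 = r(K))
  })
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), yi)] <- 1
  ones <- rep(1, n)
  loss <- NA_real_

  for (epoch in seq_len(cfg$epochs)) {
    H <- tanh(x %*% par$W1 + tcrossprod(ones, par$b1))
    S <- H %*% par$W2 + tcrossprod(ones, par$b2)
    P <- softmax_rows(S)
    loss <- -mean(log(pmax(P[cbind(seq_len(n), yi)], 1e-300)))
    if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
    G <- (P - Y) / n
    dH <- (G %*% t(par$W2)) * (1 - H^2)
    grad <- list(W1 = crossprod(x, dH), b1 = colSums(dH),
                 W2 = crossprod(H, G), b2 = colSums(G))
    for (nm in names(par)) {
      mom[[nm]] <- cfg$beta1 * mom[[nm]] + (1 - cfg$beta1) * grad[[nm]]
      vel[[nm]] <- cfg$beta2 * vel[[nm]] + (1 - cfg$beta2) * grad[[nm]]^2
      mhat <- mom[[nm]] / (1 - cfg$beta1^epoch)
      vhat <- vel[[nm]] / (1 - cfg$beta2^epoch)
      par[[nm]] <- par[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
    }
  }
  structure(list(W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
                 classes = classes, cfg = cfg, final_loss = loss,
                 train_ids = train$trial_id),
            class = "bpnn")
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Class-probability outputs of the MLP
#'
#' @param model A `bpnn`.
#' @param x Feature matrix or vector.
#' @return Matrix (n x K) of softmax probabilities, rows summing to 1.
#' @export
bpnn_probs <- function(model, x) {
  stopifnot(inherits(model, "bpnn"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  ones <- rep(1, nrow(x))
  H <- tanh(x %*% model$W1 + tcrossprod(ones, model$b1))
  P <- softmax_rows(H %*% model$W2 + tcrossprod(ones, model$b2))
  colnames(P) <- model$classes
  P
}

#' @param object A `bpnn`.
#' @param newdata Feature matrix or vector.
#' @param ... Unused.
#' @return Character vector of predicted classes (argmax probability, ties
#'   to the lowest class index).
#' @rdname bpnn_probs
#' @export
predict.bpnn <- function(object, newdata, ...) {
  P <- bpnn_probs(object, newdata)
  object$classes[apply(P, 1, which.max)]
}

#' Train all three classifier backbones on one shared partition
#'
#' @param features Feature data frame for one session.
#' @param fraction,seed Partition parameters for [split_trials()].
#' @param svm_cfg,ocsvm_cfg,bpnn_cfg Hyperparameter configurations.
#' @param classes Class order; default: the session's sorted target motions.
#' @return Object of class `model_bundle`: `ovr_svm`, `ocsvm`, `bpnn`,
#'   the shared `split` and the class order.
#' @export
train_model_bundle <- function(features, fraction = 0.5, seed = 1,
                               svm_cfg = svm_config(),
                               ocsvm_cfg = ocsvm_config(),
                               bpnn_cfg = bpnn_config(),
                               classes = NULL) {
  split <- split_trials(features, fraction, seed)
  if (is.null(classes))
    classes <- sort(unique(as.character(split$train$motion)))
  structure(
    list(ovr_svm = train_ovr_svm(split$train, svm_cfg, classes),
         ocsvm = train_ocsvm(split$train, ocsvm_cfg),
         bpnn = train_bpnn(split$train, bpnn_cfg, classes),
         split = split, classes = classes),
    class = "model_bundle"
  )
}
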