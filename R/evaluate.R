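#' Retrospective ambiguity labeling
#'
#' Ambiguous motions are not a separately recorded category: they are
#' defined retrospectively as target-motion trials that the corresponding
#' base classifier misclassifies on a pass with no rejection. SVM-based
#' mechanisms share the baseline OvR-SVM labeling; the entropy mechanism
#' uses the MLP's own predictions.
#'
#' @param decisions No-rejection decision data frame for target trials
#'   (columns `trial_id`, `output`); must contain no `"REJECT"` outputs.
#' @param truth Data frame with `trial_id`, `motion` and `category` for the
#'   same trials (target category only).
#' @return Character vector of ambiguous (misclassified) trial ids.
#' @export
label_ambiguous <- function(decisions, truth) {
  if (any(decisions$output == "REJECT"))
    stop("ambiguity labeling needs a no-rejection pass; got REJECT outputs")
  if (any(truth$category != "target"))
    stop("ambiguity is defined only over target-category trials")
  m <- merge(decisions[, c("trial_id", "output")],
             truth[, c("trial_id", "motion")], by = "trial_id")
  if (nrow(m) != nrow(decisions))
    stop("decisions and truth do not cover the same trials")
  m$trial_id[m$output != m$motion]
}

#' Classification accuracy on accepted target trials
#'
#' Correctly classified accepted target trials over all accepted target
#' trials. Undefined (`NA`) when every target trial was rejected.
#'
#' @param decisions Decision data frame (`trial_id`, `output`, `rejected`).
#' @param truth Data frame with `trial_id`, `motion`, `category`.
#' @return Accuracy in `[0, 1]`, or `NA_real_` if no trials were accepted.
#' @export
accuracy <- function(decisions, truth) {
  m <- merge(decisions, truth[, c("trial_id", "motion", "category")],
             by = "trial_id")
  m <- m[m$category == "target", , drop = FALSE]
  acc <- m[!m$rejected, , drop = FALSE]
  if (nrow(acc) == 0) return(NA_real_)
  mean(acc$output == acc$motion)
}

#' Category-wise rejection rate
#'
#' Rejected trials over all trials of the category. For the pseudo-category
#' `"ambiguous"`, supply the retrospective ambiguous trial ids.
#'
#' @param decisions Decision data frame.
#' @param truth Truth data frame (`trial_id`, `category`).
#' @param category One of `"target"`, `"unknown"`, `"nontarget"`,
#'   `"ambiguous"`.
#' @param ambiguous_ids Trial ids from [label_ambiguous()] (required for
#'   `category = "ambiguous"`).
#' @return Rate in `[0, 1]`, or `NA_real_` if the category is empty.
#' @export
rejection_rate <- function(decisions, truth, category,
                           ambiguous_ids = NULL) {
  m <- merge(decisions, truth[, c("trial_id", "category")], by = "trial_id")
  sel <- if (category == "ambiguous") {
    if (is.null(ambiguous_ids)) stop("ambiguous_ids required")
    m$trial_id %in% ambiguous_ids
  } else m$category == category
  if (!any(sel)) return(NA_real_)
  mean(m$rejected[sel])
}

#' Rejection precision
#'
#' Fraction of rejected trials that belong to the unintended set (for the
#' ambiguous-motion analysis: the retrospectively labeled misclassified
#' target trials, evaluated over target trials). Undefined (`NA`) when
#' nothing was rejected.
#'
#' @param decisions Decision data frame.
#' @param unintended_ids Trial ids counted as unintended.
#' @param restrict_to Optional trial ids to evaluate over (e.g. target
#'   trials only); default all decisions.
#' @return Precision in `[0, 1]`, or `NA_real_` with zero rejections.
#' @export
rejection_precision <- function(decisions, unintended_ids,
                                restrict_to = NULL) {
  d <- decisions
  if (!is.null(restrict_to))
    d <- d[d$trial_id %in% restrict_to, , drop = FALSE]
  rej <- d[d$rejected, , drop = FALSE]
  if (nrow(rej) == 0) return(NA_real_)
  mean(rej$trial_id %in% unintended_ids)
}

#' ROC-style operating-point selection
#'
#' Given a grid of candidate parameter values with their pooled target and
#' unintended rejection rates, selects the candidate minimizing the
#' Euclidean distance to the ideal point `(RR_target, RR_unintended) =
#' (0, 1)`. Ties resolve to the smaller parameter value.
#'
#' @param params Numeric vector of candidate parameter values.
#' @param rr_target,rr_unintended Rejection rates per candidate.
#' @return List with `param`, `distance`, and the index `which`.
#' @export
select_operating_point <- function(params, rr_target, rr_unintended) {
  stopifnot(length(params) >= 1,
            length(rr_target) == length(params),
            length(rr_unintended) == length(params))
  d <- sqrt(rr_target^2 + (1 - rr_unintended)^2)
  best <- which(d == min(d))
  best <- best[which.min(params[best])]
  list(param = params[best], distance = d[best], which = best)
}

#' Session-wise paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-tests over session-wise metric values for every
#' requested system pair; the significance level is `0.05 / N_comp` with
#' `N_comp` the number of pairs tested (6 when comparing the four systems on
#' accuracy, 3 when comparing the three rejection mechanisms). Sessions with
#' an undefined value in either member of a pair are dropped pairwise.
#'
#' @param metric_table Data frame or matrix, sessions as rows, systems as
#'   columns (`NA` = undefined for that session).
#' @param pairs Optional 2-column character matrix of system pairs; default
#'   all unordered pairs of columns.
#' @return Object of class `study_stats`: data frame with `system_a`,
#'   `system_b`, `n`, `mean_diff` (percentage points, a - b), `t`, `p`,
#'   `alpha_adj`, `significant`.
#' @export
paired_tests <- function(metric_table, pairs = NULL) {
  metric_table <- as.data.frame(metric_table)
  sys <- names(metric_table)
  if (is.null(pairs)) {
    if (length(sys) < 2) stop("need >= 2 systems to compare")
    pairs <- t(utils::combn(sys, 2))
  }
  n_comp <- nrow(pairs)
  alpha_adj <- 0.05 / n_comp
  rows <- lapply(seq_len(n_comp), function(i) {
    a <- metric_table[[pairs[i, 1]]]
    b <- metric_table[[pairs[i, 2]]]
    ok <- !is.na(a) & !is.na(b)
    diff <- (a - b)[ok]
    if (length(diff) < 2) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
      md <- if (length(diff)) mean(diff) else NA_real_
    } else {
      md <- mean(diff)
      # constant differences make the t statistic undefined in
      # stats::t.test ("data are essentially constant"); resolve
      # analytically: no difference -> t = 0, p = 1
      degenerate <- function()
        if (isTRUE(all.equal(md, 0))) list(statistic = 0, p.value = 1)
        else list(statistic = sign(md) * Inf, p.value = 0)
      tt <- tryCatch({
        ht <- stats::t.test(a[ok], b[ok], paired = TRUE)
        if (is.nan(ht$statistic)) degenerate()
        else list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }, error = function(e) degenerate())
    }
    data.frame(system_a = pairs[i, 1], system_b = pairs[i, 2],
               n = sum(ok), mean_diff = 100 * md,
               t = tt$statistic, p = tt$p.value,
               alpha_adj = alpha_adj,
               significant = !is.na(tt$p.value) & tt$p.value < alpha_adj,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("study_stats", "data.frame"),
            n_comp = n_comp)
}

#' Evaluate one session across all mechanisms
#'
#' Extracts features, trains the three backbones on one shared stratified
#' partition, applies every requested mechanism to the test trials, labels
#' ambiguous trials retrospectively per base classifier, and computes the
#' session report.
#'
#' @param rec A `pvdf_recording` (or a precomputed feature data frame).
#' @param mechanisms Mechanisms to evaluate (default all four).
#' @param fraction,split_seed Partition parameters.
#' @param filter_cfg,svm_cfg,ocsvm_cfg,bpnn_cfg,reject_cfg Configurations.
#' @return Object of class `session_eval`: list with `report` (one row per
#'   mechanism: accuracy and category rejection metrics), `decisions` (long
#'   data frame over mechanisms), `ambiguous` (per-base-classifier id
#'   lists), `bundle`, `features`.
#' @export
evaluate_session <- function(rec,
                             mechanisms = c("baseline", "ocsvm",
                                            "bpnn_entropy", "ovr_ro"),
                             fraction = 0.5, split_seed = 1,
                             filter_cfg = filter_config(),
                             svm_cfg = svm_config(),
                             ocsvm_cfg = ocsvm_config(),
                             bpnn_cfg = bpnn_config(),
                             reject_cfg = reject_config()) {
  features <- if (inherits(rec, "pvdf_recording"))
    extract_trial_features(rec, filter_cfg) else rec
  session_id <- features$session_id[1]
  bundle <- train_model_bundle(features, fraction, split_seed,
                               svm_cfg, ocsvm_cfg, bpnn_cfg)
  test <- bundle$split$test
  truth <- test[, c("trial_id", "motion", "category", "ambiguous")]
  test_target <- test[test$category == "target", , drop = FALSE]

  # no-rejection passes over target test trials for retrospective labeling
  xt <- feature_matrix(test_target)
  amb <- list(
    svm = test_target$trial_id[predict(bundle$ovr_svm, xt) !=
                                 test_target$motion],
    bpnn = test_target$trial_id[predict(bundle$bpnn, xt) !=
                                  test_target$motion])

  decisions <- list(); report <- list()
  for (mech in mechanisms) {
    d <- decide_trials(bundle, test, mech, reject_cfg)
    amb_ids <- if (mech == "bpnn_entropy") amb$bpnn else amb$svm
    report[[mech]] <- data.frame(
      session_id = session_id, mechanism = mech,
      accuracy = accuracy(d, truth),
      rr_target = rejection_rate(d, truth, "target"),
      rr_ambiguous = rejection_rate(d, truth, "ambiguous",
                                    ambiguous_ids = amb_ids),
      rr_unknown = rejection_rate(d, truth, "unknown"),
      rr_nontarget = rejection_rate(d, truth, "nontarget"),
      rp_ambiguous = rejection_precision(d, amb_ids,
                                         restrict_to = test_target$trial_id),
      n_test = nrow(test),
      n_ambiguous = length(amb_ids),
      stringsAsFactors = FALSE)
    decisions[[mech]] <- d
  }
  structure(list(report = do.call(rbind, c(report, make.row.names = FALSE)),
                 decisions = do.call(rbind, c(decisions,
                                              make.row.names = FALSE)),
                 ambiguous = amb, bundle = bundle, features = features),
            class = "session_eval")
}

#' Aggregate session reports and run the study-level statistics
#'
#' Stacks per-session reports, computes per-mechanism means, and runs the
#' paired-comparison suite: accuracy over all systems present
#' (`N_comp = choose(4, 2) = 6` with four systems) and each rejection metric
#' over the rejecting mechanisms only (`N_comp = 3` with three), since the
#' baseline has no reject option.
#'
#' @param session_reports List of `session_eval` objects or a stacked report
#'   data frame.
#' @return Object of class `study_report`: list with `sessions` (stacked
#'   reports), `means` (per-mechanism metric means), and `stats` (named list
#'   of `study_stats`).
#' @export
study_report <- function(session_reports) {
  df <- if (is.data.frame(session_reports)) session_reports
        else do.call(rbind, c(lapply(session_reports, `[[`, "report"),
                              make.row.names = FALSE))
  mechs <- unique(df$mechanism)
  rej_mechs <- setdiff(mechs, "baseline")
  metrics <- c("accuracy", "rr_target", "rr_ambiguous", "rr_unknown",
               "rr_nontarget", "rp_ambiguous")
  means <- stats::aggregate(df[metrics], by = list(mechanism = df$mechanism),
                            FUN = function(v) mean(v, na.rm = TRUE))
  wide <- function(metric, systems) {
    tab <- stats::reshape(
      df[df$mechanism %in% systems, c("session_id", "mechanism", metric)],
      direction = "wide", idvar = "session_id", timevar = "mechanism")
    names(tab) <- sub(paste0("^", metric, "\\."), "", names(tab))
    tab[, systems, drop = FALSE]
  }
  stats_list <- list()
  if (length(mechs) >= 2)
    stats_list$accuracy <- paired_tests(wide("accuracy", mechs))
  if (length(rej_mechs) >= 2) {
    for (metric in c("rr_target", "rr_unknown", "rr_nontarget",
                     "rp_ambiguous")) {
      tab <- wide(metric, rej_mechs)
      if (any(colSums(!is.na(tab)) >= 2))
        stats_list[[metric]] <- paired_tests(tab)
    }
  }
  structure(list(sessions = df, means = means, stats = stats_list),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", length(unique(x$sessions$session_id)),
      " sessions, mechanisms: ",
      paste(unique(x$sessions$mechanism), collapse = ", "), "\n\n", sep = "")
  m <- x$means
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], function(v) round(100 * v, 1))
  cat("Mean metrics (%):\n")
  print(m, row.names = FALSE)
  invisible(x)
}
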