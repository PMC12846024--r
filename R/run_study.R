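#' End-to-end study configuration
#'
#' Bundles every stage's configuration and seed so that a whole simulated
#' study — simulate, preprocess, train, decide, evaluate — is reproducible
#' from one object.
#'
#' @param n_sessions Number of simulated sessions (default 12).
#' @param session_spec_args Named list of [session_spec()] overrides shared
#'   by all sessions.
#' @param overrides Per-session override list (default:
#'   [study_overrides()] for `n_sessions = 12`, else none).
#' @param mechanisms Mechanisms to evaluate.
#' @param fraction Training fraction of the stratified split.
#' @param seed Master seed; session sub-seeds and the split seed derive
#'   from it.
#' @param filter_cfg,svm_cfg,ocsvm_cfg,bpnn_cfg,reject_cfg Stage
#'   configurations.
#' @return Object of class `run_config`.
#' @export
run_config <- function(n_sessions = 12, session_spec_args = list(),
                       overrides = NULL,
                       mechanisms = c("baseline", "ocsvm", "bpnn_entropy",
                                      "ovr_ro"),
                       fraction = 0.5, seed = 1,
                       filter_cfg = filter_config(),
                       svm_cfg = svm_config(),
                       ocsvm_cfg = ocsvm_config(),
                       bpnn_cfg = bpnn_config(),
                       reject_cfg = reject_config()) {
  if (is.null(overrides) && n_sessions == 12) overrides <- study_overrides()
  structure(list(n_sessions = n_sessions,
                 session_spec_args = session_spec_args,
                 overrides = overrides, mechanisms = mechanisms,
                 fraction = fraction, seed = as.integer(seed),
                 filter_cfg = filter_cfg, svm_cfg = svm_cfg,
                 ocsvm_cfg = ocsvm_cfg, bpnn_cfg = bpnn_cfg,
                 reject_cfg = reject_cfg),
            class = "run_config")
}

#' Stable hash of a configuration
#'
#' MD5 of the deparsed configuration; embedded in every output file header
#' so results are traceable to their exact settings.
#'
#' @param config Any R object.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config, control = c("all", "digits17")), f)
  unname(tools::md5sum(f))
}

write_csv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [run_study()] / the CLI
#'
#' Validates the schema (identification columns plus `z1..zD`) and errors
#' with the offending file name on mismatch.
#'
#' @param path CSV path.
#' @return Feature data frame.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  id_cols <- c("trial_id", "session_id", "motion", "category", "ambiguous",
               "t_detect_s")
  zcols <- grep("^z[0-9]+$", names(df), value = TRUE)
  if (!all(id_cols %in% names(df)) || length(zcols) == 0 ||
      !setequal(names(df), c(id_cols, zcols)))
    stop("feature file '", path, "' does not match the expected schema (",
         paste(id_cols, collapse = ", "), ", z1..zD)")
  df
}

#' Run a complete simulated study
#'
#' Simulates `n_sessions` recordings, preprocesses each, trains the three
#' backbones per session on a shared partition, applies the configured
#' rejection mechanisms, and aggregates session reports into study-level
#' statistics. With `out_dir` set, writes features, decisions, the
#' session-report table and the study statistics as columnar text files,
#' each headed by the configuration hash.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param verbose Emit per-stage progress via [message()].
#' @return A [study_report()] object (invisibly if `out_dir` is set), with
#'   the per-session evaluations in attribute `"sessions"`.
#' @export
run_study <- function(config = run_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  hash <- config_hash(config)

  base_spec <- do.call(session_spec,
                       c(config$session_spec_args, list(seed = config$seed)))
  say("simulate: ", config$n_sessions, " sessions (seed ", config$seed, ")")
  recs <- generate_study(config$n_sessions, base_spec, config$overrides)

  evals <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    ev <- evaluate_session(
      recs[[i]], mechanisms = config$mechanisms,
      fraction = config$fraction, split_seed = config$seed,
      filter_cfg = config$filter_cfg, svm_cfg = config$svm_cfg,
      ocsvm_cfg = config$ocsvm_cfg, bpnn_cfg = config$bpnn_cfg,
      reject_cfg = config$reject_cfg)
    say(sprintf(
      "%s: %d trials simulated, %d features, %d test, %d accepted, %d rejected",
      recs[[i]]$session_id, nrow(recs[[i]]$annotations), nrow(ev$features),
      nrow(ev$bundle$split$test), sum(!ev$decisions$rejected),
      sum(ev$decisions$rejected)))
    evals[[i]] <- ev
  }
  rep <- study_report(evals)
  attr(rep, "sessions") <- evals
  attr(rep, "config_hash") <- hash

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0("# config_hash: ", hash)
    feats <- do.call(rbind, c(lapply(evals, `[[`, "features"),
                              make.row.names = FALSE))
    write_csv_with_header(feats, file.path(out_dir, "features.csv"), hdr)
    decs <- do.call(rbind, c(lapply(seq_along(evals), function(i)
      cbind(session_id = recs[[i]]$session_id, evals[[i]]$decisions)),
      make.row.names = FALSE))
    write_csv_with_header(decs, file.path(out_dir, "decisions.csv"), hdr)
    keep <- report_columns(config$mechanisms)
    write_csv_with_header(rep$sessions[, keep],
                          file.path(out_dir, "session_reports.csv"), hdr)
    if (length(rep$stats)) {
      stats_df <- do.call(rbind, c(lapply(names(rep$stats), function(nm)
        cbind(metric = nm, rep$stats[[nm]])), make.row.names = FALSE))
      write_csv_with_header(stats_df, file.path(out_dir, "study_stats.csv"),
                            hdr)
    }
    return(invisible(rep))
  }
  rep
}

# rejection columns only appear when a rejecting mechanism is configured
report_columns <- function(mechanisms) {
  base <- c("session_id", "mechanism", "accuracy", "n_test")
  if (identical(mechanisms, "baseline")) base
  else c(base, "rr_target", "rr_ambiguous", "rr_unknown", "rr_nontarget",
         "rp_ambiguous", "n_ambiguous")
}
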