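# End-to-end orchestration: preprocessing -> connectivity -> graph
# metrics -> variability -> group statistics, patient by patient, with
# QC exclusion bookkeeping and a reproducibility manifest.

#' Pipeline configuration
#'
#' Validated bundle of every tunable of the analysis chain with the
#' protocol defaults.
#'
#' @param target_fs Analysis sampling rate (Hz).
#' @param band Band-pass edges in Hz.
#' @param epoch_length_s Epoch length (s).
#' @param z_channel Bad-channel robust-z threshold.
#' @param z_epoch Bad-epoch robust-z threshold.
#' @param max_bad_epoch_fraction Recording-level rejection threshold
#'   (strictly-greater rule).
#' @param wpli_window_s,wpli_overlap_s wPLI window parameters (s).
#' @param partition_seed Seed for the module partitioner.
#' @param population_cv Use population SDs in CVs.
#' @param fdr_q FDR level of per-electrode contrasts.
#' @param disconnected Handling of unreachable node pairs in the
#'   characteristic path length.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_fs = 500, band = c(1, 45),
                            epoch_length_s = 10, z_channel = 3,
                            z_epoch = 5, max_bad_epoch_fraction = 0.30,
                            wpli_window_s = 2, wpli_overlap_s = 1,
                            partition_seed = 1, population_cv = FALSE,
                            fdr_q = 0.05, disconnected = "exclude") {
  cfg <- list(target_fs = target_fs, band = band,
              epoch_length_s = epoch_length_s, z_channel = z_channel,
              z_epoch = z_epoch,
              max_bad_epoch_fraction = max_bad_epoch_fraction,
              wpli_window_s = wpli_window_s,
              wpli_overlap_s = wpli_overlap_s,
              partition_seed = partition_seed,
              population_cv = population_cv, fdr_q = fdr_q,
              disconnected = disconnected)
  if (band[1] <= 0 || band[1] >= band[2] || band[2] >= target_fs / 2)
    stopf("invalid band for target_fs %g", target_fs)
  if (epoch_length_s < wpli_window_s)
    stopf("epoch shorter than the wPLI window")
  if (max_bad_epoch_fraction < 0 || max_bad_epoch_fraction > 1)
    stopf("max_bad_epoch_fraction must be in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Analyse the five sessions of one patient
#'
#' Preprocesses each session, computes the session wPLI patterns and
#' network metrics, and assembles the patient's variability summary. A
#' session failing the 30% epoch rule makes the patient unusable (the
#' QC reason is returned instead of results).
#'
#' @param sessions List of 5 [raw_recording()]s in temporal order.
#' @param config A [pipeline_config()].
#' @return List with `status` (`"ok"` or `"excluded"`), and on success
#'   `patterns` (5 session connectivity matrices), `metrics`
#'   (5 `network_metrics`), `variability` (a `patient_variability`) and
#'   the per-session `qc` records.
#' @export
analyze_patient_sessions <- function(sessions, config = pipeline_config()) {
  if (length(sessions) != 5) stopf("expected 5 sessions, got %d",
                                   length(sessions))
  patterns <- vector("list", 5)
  metrics <- vector("list", 5)
  qc <- vector("list", 5)
  for (s in seq_len(5)) {
    ep <- preprocess_recording(sessions[[s]], config)
    qc[[s]] <- list(session = sessions[[s]]$session_label,
                    bad_channels = ep$qc$bad_channels,
                    rejected_epochs = sum(!ep$qc$keep),
                    n_epochs = length(ep$qc$keep),
                    usable = ep$qc$usable,
                    reason = ep$qc$reason)
    if (!isTRUE(ep$qc$usable))
      return(list(status = "excluded", qc = qc,
                  reason = sprintf("session %s unusable: %s",
                                   sessions[[s]]$session_label,
                                   ep$qc$reason %||% "")))
    patterns[[s]] <- session_connectivity(ep, config$wpli_window_s,
                                          config$wpli_overlap_s,
                                          config$band)
    metrics[[s]] <- network_metrics(patterns[[s]], config$disconnected)
  }
  var <- patient_variability(metrics, patterns,
                             seed = config$partition_seed,
                             population = config$population_cv)
  list(status = "ok", patterns = patterns, metrics = metrics,
       variability = var, qc = qc)
}

patient_row <- function(patient_id, group, crsr, res) {
  v <- res$variability
  row <- data.frame(patient_id = patient_id, group = group, crsr = crsr,
                    avg_degree = mean(v$mean_metrics$degree),
                    cpl = v$mean_metrics$cpl, cc = v$mean_metrics$cc,
                    bc_mean = v$mean_metrics$bc_mean,
                    nmi_mean = v$nmi_mean, gev = v$gev,
                    cv_cpl = v$cv_cpl, cv_cc = v$cv_cc,
                    cv_bc_mean = v$cv_bc_mean,
                    stringsAsFactors = FALSE)
  for (ch in names(v$cv_degree))
    row[[paste0("cv_degree_", ch)]] <- v$cv_degree[[ch]]
  for (ch in names(v$cv_bc))
    row[[paste0("cv_bc_", ch)]] <- v$cv_bc[[ch]]
  row
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes preprocessing, connectivity, graph metrics and variability
#' for every patient (sessions are realised lazily and discarded one
#' patient at a time), assembles the cohort table, and runs the group
#' statistics. Patients excluded by QC are reported but absent from the
#' statistics.
#'
#' @param cohort A `synthetic_cohort`, or a list of patients each with
#'   fields `patient_id`, `group`, `crsr` and `sessions` (5
#'   [raw_recording()]s).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, the cohort table,
#'   statistics tables, QC report and run manifest are written there.
#' @return An object of class `cohort_analysis`: `table` (one row per
#'   analysed patient), `stats` (a `group_statistics`), `patients`
#'   (per-patient variability summaries), `excluded`, `qc`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         output_dir = NULL) {
  patients <- if (inherits(cohort, "synthetic_cohort")) cohort$patients
              else cohort
  rows <- list(); pat_out <- list(); excluded <- list(); qc_all <- list()
  for (p in patients) {
    if (is.null(p$sessions) && inherits(cohort, "synthetic_cohort"))
      p <- realize_sessions(p, cohort)
    res <- analyze_patient_sessions(p$sessions, config)
    qc_all[[p$patient_id]] <- res$qc
    if (res$status != "ok") {
      excluded[[p$patient_id]] <- res$reason
      next
    }
    rows[[p$patient_id]] <- patient_row(p$patient_id, p$group, p$crsr, res)
    pat_out[[p$patient_id]] <- res$variability
  }
  if (!length(rows)) stopf("no usable patients after QC")
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  # group statistics need >= 2 patients per group; a QC-depleted cohort
  # still yields the table, with the statistics stage skipped and noted
  stats <- tryCatch(group_statistics(table, q = config$fdr_q),
                    error = function(e) {
                      warnf("group statistics skipped: %s",
                            conditionMessage(e))
                      NULL
                    })
  out <- structure(list(table = table, stats = stats,
                        patients = pat_out,
                        excluded = excluded, qc = qc_all,
                        config = config),
                   class = "cohort_analysis")
  if (!is.null(output_dir)) write_results(out, output_dir)
  out
}

#' Cohort table of a pipeline run
#'
#' @param analysis A `cohort_analysis`.
#' @return The per-patient data frame of scalar and per-electrode
#'   metrics.
#' @export
cohort_table <- function(analysis) analysis$table

# Tiny stable content hash (djb2 over the serialized JSON) for the
# manifest; avoids a cryptographic dependency.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

write_results <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(analysis$table, file.path(dir, "cohort_table.csv"),
                   row.names = FALSE)
  if (!is.null(analysis$stats)) {
    utils::write.csv(analysis$stats$omnibus,
                     file.path(dir, "stats_omnibus.csv"), row.names = FALSE)
    utils::write.csv(analysis$stats$pairwise,
                     file.path(dir, "stats_pairwise.csv"), row.names = FALSE)
    if (!is.null(analysis$stats$per_electrode))
      utils::write.csv(analysis$stats$per_electrode,
                       file.path(dir, "stats_per_electrode.csv"),
                       row.names = FALSE)
    utils::write.csv(analysis$stats$correlations,
                     file.path(dir, "stats_correlations.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(qc = analysis$qc, excluded = analysis$excluded),
    file.path(dir, "qc_report.json"), auto_unbox = TRUE, null = "null")
  manifest <- list(
    config = unclass(analysis$config),
    config_hash = config_hash(analysis$config),
    n_patients = nrow(analysis$table),
    n_excluded = length(analysis$excluded),
    software = sprintf("eegnetvar %s",
                       as.character(utils::packageVersion("eegnetvar"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d patients analysed, %d excluded by QC\n",
              nrow(x$table), length(x$excluded)))
  med <- stats::aggregate(
    x$table[, c("avg_degree", "cpl", "cc", "bc_mean", "nmi_mean",
                "cv_cpl", "cv_cc", "cv_bc_mean")],
    by = list(group = x$table$group), FUN = stats::median)
  print(med, digits = 3)
  invisible(x)
}

#' @export
summary.cohort_analysis <- function(object, ...) {
  print(object)
  if (is.null(object$stats)) {
    cat("\n(group statistics unavailable for this run)\n")
    return(invisible(object))
  }
  cat("\nKendall correlations with CRS-R:\n")
  print(object$stats$correlations[, c("contrast", "tau", "p")], digits = 3)
  cat("\nOmnibus group contrasts:\n")
  print(object$stats$omnibus[, c("metric", "statistic", "p")], digits = 3)
  invisible(object)
}
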