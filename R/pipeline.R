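# Study-level orchestration: simulate -> preprocess -> MMN/theta ->
# connectivity -> agreement, with manifest-based checkpointing.

#' Build a pipeline run configuration
#'
#' Defaults reproduce the study conditions (612/102+102 oddball block, SOA
#' 1.555 s, 10 habituation standards, 5 min rest, 0.1-25 Hz band, 512 Hz,
#' 15 ICA components at r = 0.2, 150 µV peak-to-peak preset, >70% trials and
#' SNR > 1 inclusion). Reduce `n_standards`/`rest_duration`/`n_subjects` for
#' desk-scale runs.
#'
#' @param n_subjects simulated subjects.
#' @param seed master seed; every stage derives its own stream from it.
#' @param systems systems to simulate and compare.
#' @param truth a [ground_truth()] shared by all subjects.
#' @param task oddball design parameters (see [oddball_sequence()]).
#' @param rest_duration rest length, seconds.
#' @param preprocess thresholds (see [preproc_defaults()]).
#' @param with_tfr compute the theta time-frequency stage (requires epochs of
#'   +/- 1.2 s; disable for amplitude-only runs).
#' @param bands connectivity bands (names from [band_definitions()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(n_subjects = 23, seed = 1L,
                       systems = c("wet", "dry"),
                       truth = ground_truth(seed = seed),
                       task = list(n_standards = 612, n_deviants_per_type = 102,
                                   min_gap = 2, max_gap = 4, soa = 1.555,
                                   n_habituation = 10),
                       rest_duration = 300,
                       preprocess = preproc_defaults(),
                       with_tfr = TRUE,
                       bands = names(band_definitions())) {
  cfg <- list(n_subjects = n_subjects, seed = as.integer(seed),
              systems = systems, truth = truth, task = task,
              rest_duration = rest_duration, preprocess = preprocess,
              with_tfr = with_tfr, bands = bands)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  digest_string(paste(deparse(unclass(config)), collapse = ""))
}

# read a stage CSV that may legitimately be empty (e.g. too few included
# subjects for any group-level comparison)
read_csv_safe <- function(path) {
  tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
           error = function(e) data.frame())
}

#' Serialize / restore a run configuration as YAML
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  x <- rapply(unclass(config), unclass, how = "replace")
  x$truth$noise_scale <- as.list(x$truth$noise_scale)  # YAML drops vector names
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  truth <- raw$truth
  truth$noise_scale <- unlist(truth$noise_scale)
  truth$resting_phase_lags <- lapply(truth$resting_phase_lags, as.data.frame)
  do.call(run_config, c(
    raw[c("n_subjects", "seed", "systems", "rest_duration", "with_tfr", "bands")],
    list(truth = do.call(ground_truth, truth[setdiff(names(truth), "seed")]),
         task = raw$task, preprocess = raw$preprocess)
  ))
}

# number of trials available per condition after the averaging exclusions
count_available <- function(epochs) {
  ev <- epochs$events
  cond <- epochs$condition
  cond[cond != "standard"] <- "deviant"
  eligible <- epochs$kept & !ev$is_habituation &
    !(cond == "standard" & ev$follows_deviant)
  c(standard = sum(eligible & cond == "standard"),
    deviant = sum(eligible & cond == "deviant"))
}

#' Task-stage metrics for one preprocessed system
#'
#' Runs trial selection/equalization, condition averaging, MMN metrics,
#' plus-minus SNR and (optionally) the theta time-frequency extraction at the
#' analysis channel.
#'
#' @param epochs cleaned task `eeg_epochs`.
#' @param seed seed for trial subsampling.
#' @param n_per_condition cross-system equalization cap.
#' @param with_tfr compute dB theta power (epochs must span +/- 1.2 s).
#' @return named list of scalar metrics.
#' @export
analyze_task <- function(epochs, seed = 1L, n_per_condition = NULL,
                         with_tfr = FALSE) {
  sel <- select_trials(epochs, seed = seed, n_per_condition = n_per_condition)
  ch <- attr(epochs$layout, "mmn_channel")
  ev_dev <- condition_average(sel, "deviant")
  ev_std <- condition_average(sel, "standard")
  m <- mmn_metrics(ev_dev, ev_std, channel = ch)
  m$snr <- plus_minus_snr(sel, channel = ch)
  times <- epoch_times(ev_dev$tmin, ncol(ev_dev$data), ev_dev$fs)
  win <- time_window_idx(times, m$window[1], m$window[2])
  ci <- match(ch, ev_dev$channel_labels)
  out <- list(
    mean_amplitude = m$mean_amplitude,
    peak_amplitude = m$peak_amplitude,
    peak_latency = m$peak_latency,
    snr = m$snr,
    n_trials_used = m$n_trials_used,
    amp_dev = mean(ev_dev$data[ci, win]),
    amp_std = mean(ev_std$data[ci, win])
  )
  if (with_tfr) {
    tfr_dev <- db_baseline(morlet_tfr(sel, "deviant", channels = ch))
    tfr_std <- db_baseline(morlet_tfr(sel, "standard", channels = ch))
    th <- extract_theta(tfr_dev, tfr_std, channel = ch)
    out$theta_dev <- th$theta_dev
    out$theta_std <- th$theta_std
    out$theta_diff <- th$theta_diff
  }
  out
}

#' Resting-state metrics for one preprocessed system
#'
#' Per band: subject mean PLI and the normalized minimum-spanning-tree
#' diameter of the 1 - PLI distance graph.
#'
#' @param epochs rest `eeg_epochs`.
#' @param bands band names.
#' @return named list `pli_<band>`, `mst_d_<band>`, `mst_D_<band>`.
#' @export
analyze_rest <- function(epochs, bands = names(band_definitions())) {
  epochs <- average_reference(epochs)
  out <- list()
  for (b in bands) {
    res <- subject_pli(epochs, band = b, average_ref = FALSE)
    mst <- mst_diameter(pli_to_distance(res))
    out[[paste0("pli_", b)]] <- res$mean_pli
    out[[paste0("mst_d_", b)]] <- mst$d
    out[[paste0("mst_D_", b)]] <- mst$D
  }
  out
}

process_subject <- function(subj, config) {
  seed <- config$seed
  task_par <- config$task
  seq <- do.call(oddball_sequence,
                 c(task_par, list(seed = derive_seed(seed, subj, "seq"))))
  params <- config$preprocess
  if (config$with_tfr) { params$tmin <- -1.2; params$tmax <- 1.2 }
  sys_data <- list()
  for (sys in config$systems) {
    lay <- if (sys == "wet") "wet64" else "dry64"
    task_rec <- simulate_task_recording(seq, config$truth, layout = lay,
                                        system = sys,
                                        seed = derive_seed(seed, subj, sys, "task"))
    rest_rec <- simulate_rest_recording(config$truth, layout = lay, system = sys,
                                        duration = config$rest_duration,
                                        seed = derive_seed(seed, subj, sys, "rest"))
    task <- preprocess_recording(task_rec, "task", params,
                                 seed = derive_seed(seed, subj, sys, "ica"))
    rest <- preprocess_recording(rest_rec, "rest", params,
                                 seed = derive_seed(seed, subj, sys, "ica-rest"))
    sys_data[[sys]] <- list(task = task, rest = rest)
  }
  n_eq <- min(vapply(sys_data, function(s) min(count_available(s$task$epochs)),
                     numeric(1)))
  rows <- list()
  for (sys in config$systems) {
    tm <- analyze_task(sys_data[[sys]]$task$epochs,
                       seed = derive_seed(seed, subj, "select"),
                       n_per_condition = n_eq, with_tfr = config$with_tfr)
    rep_task <- apply_inclusion_rule(sys_data[[sys]]$task$report, tm$snr)
    rm <- analyze_rest(sys_data[[sys]]$rest$epochs, config$bands)
    rows[[sys]] <- c(
      list(subject = subj, system = sys,
           included_task = rep_task$included,
           exclusion_reasons = paste(rep_task$reasons, collapse = "; "),
           fraction_trials_retained = rep_task$fraction_trials_retained,
           n_channels_rejected = rep_task$n_channels_rejected,
           n_components_rejected = rep_task$n_components_rejected),
      tm, rm
    )
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Run the full wet-versus-dry comparison pipeline
#'
#' Stage `subjects`: per subject and system, simulate the paired session,
#' preprocess, and compute task (MMN amplitude/latency, SNR, theta) and rest
#' (PLI, MST diameter per band) metrics; written to `subject_metrics.csv`.
#' Stage `agreement`: subjects included in the task analysis (both systems:
#' >70% trials retained and SNR > 1) enter the Bland-Altman and paired-test
#' comparison for every task measure; all subjects with complete rest data
#' enter the connectivity comparisons; written to `agreement.csv`, the
#' system-by-tone ANOVAs to `anova.csv`, exclusion bookkeeping to
#' `report.json`. A `manifest.json` with a configuration hash makes reruns
#' incremental: stages whose outputs exist under the same hash are skipped,
#' and a changed configuration forces a full rerun.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param resume honour an existing manifest (default) or force a full rerun.
#' @return invisible list with `subjects` (data.frame), `agreement`
#'   (data.frame), `anova` (data.frame), `report` (list).
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  man_path <- file.path(out_dir, "manifest.json")
  manifest <- list(hash = "", stages = list())
  if (resume && file.exists(man_path)) {
    manifest <- tryCatch(jsonlite::read_json(man_path, simplifyVector = TRUE),
                         error = function(e) {
                           warning("corrupted manifest; full re-run")
                           list(hash = "", stages = list())
                         })
  }
  if (!identical(manifest$hash, hash)) manifest <- list(hash = hash, stages = list())
  write_run_config(config, file.path(out_dir, "config.yaml"))
  write_ground_truth(config$truth, file.path(out_dir, "ground_truth.json"))

  subj_path <- file.path(out_dir, "subject_metrics.csv")
  if (!isTRUE(manifest$stages$subjects == hash) || !file.exists(subj_path)) {
    rows <- lapply(seq_len(config$n_subjects), function(s) {
      tryCatch(process_subject(s, config),
               error = function(e) stop(sprintf("subject %d failed: %s", s,
                                                conditionMessage(e)), call. = FALSE))
    })
    subjects <- do.call(rbind, rows)
    utils::write.csv(subjects, subj_path, row.names = FALSE)
    manifest$stages$subjects <- hash
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE)
  } else {
    subjects <- utils::read.csv(subj_path, stringsAsFactors = FALSE)
  }

  agree_path <- file.path(out_dir, "agreement.csv")
  anova_path <- file.path(out_dir, "anova.csv")
  report_path <- file.path(out_dir, "report.json")
  if (!isTRUE(manifest$stages$agreement == hash) ||
      !all(file.exists(c(agree_path, report_path)))) {
    res <- summarize_agreement(subjects, config)
    utils::write.csv(res$agreement, agree_path, row.names = FALSE)
    utils::write.csv(res$anova, anova_path, row.names = FALSE)
    jsonlite::write_json(res$report, report_path, auto_unbox = TRUE, digits = NA)
    manifest$stages$agreement <- hash
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE)
  } else {
    res <- list(agreement = read_csv_safe(agree_path),
                anova = read_csv_safe(anova_path),
                report = jsonlite::read_json(report_path, simplifyVector = TRUE))
  }
  invisible(list(subjects = subjects, agreement = res$agreement,
                 anova = res$anova, report = res$report))
}

# group-level agreement summaries from the per-subject metrics table
summarize_agreement <- function(subjects, config) {
  two <- all(c("wet", "dry") %in% subjects$system)
  wide <- function(col) {
    w <- subjects[subjects$system == "wet", c("subject", col)]
    d <- subjects[subjects$system == "dry", c("subject", col)]
    m <- merge(w, d, by = "subject", suffixes = c("_wet", "_dry"))
    m[order(m$subject), ]
  }
  task_ok <- stats::aggregate(included_task ~ subject, subjects, all)
  task_subjects <- task_ok$subject[task_ok$included_task]
  task_measures <- intersect(
    c("mean_amplitude", "peak_amplitude", "peak_latency", "snr", "theta_diff"),
    names(subjects)
  )
  rest_measures <- grep("^(pli|mst_D)_", names(subjects), value = TRUE)
  rows <- list(); anova_rows <- list()
  if (two) {
    for (meas in c(task_measures, rest_measures)) {
      m <- wide(meas)
      if (meas %in% task_measures) m <- m[m$subject %in% task_subjects, ]
      if (nrow(m) < 3) next
      pm <- paired_measures(m$subject, m[[paste0(meas, "_wet")]],
                            m[[paste0(meas, "_dry")]], measure_name = meas)
      ba <- bland_altman(pm)
      tt <- paired_t_test(pm)
      rows[[meas]] <- data.frame(
        measure = meas, n = ba$n, bias = ba$bias,
        bias_ci_lo = ba$bias_ci[1], bias_ci_hi = ba$bias_ci[2],
        loa_lo = ba$loa_low, loa_hi = ba$loa_high, sd_diff = ba$sd_diff,
        significant = ba$significant,
        t = tt$statistic, t_p = tt$p, cohen_d = tt$effect_size$value,
        d_label = effect_size_label(tt$effect_size$value),
        sign_convention = ba$sign_convention,
        stringsAsFactors = FALSE
      )
    }
    for (dv in intersect(c("amp", "theta"), c("amp", if (config$with_tfr) "theta"))) {
      cols <- paste0(dv, c("_std", "_dev"))
      if (!all(cols %in% names(subjects))) next
      sub <- subjects[subjects$subject %in% task_subjects, ]
      if (length(unique(sub$subject)) < 3) next
      long <- do.call(rbind, lapply(cols, function(cc) {
        data.frame(subject = sub$subject, system = sub$system,
                   tone = if (grepl("dev", cc)) "deviant" else "standard",
                   value = sub[[cc]], stringsAsFactors = FALSE)
      }))
      an <- rm_anova_2x2(long)
      an$dv <- dv
      anova_rows[[dv]] <- as.data.frame(an)
    }
  }
  excl <- subjects[!subjects$included_task,
                   c("subject", "system", "exclusion_reasons")]
  report <- list(
    n_subjects = config$n_subjects,
    n_included_task = length(task_subjects),
    n_included_rest = length(unique(subjects$subject)),
    mean_snr = stats::aggregate(snr ~ system, subjects, mean),
    exclusions = excl
  )
  list(
    agreement = if (length(rows)) do.call(rbind, rows) else data.frame(),
    anova = if (length(anova_rows)) do.call(rbind, anova_rows) else data.frame(),
    report = report
  )
}
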