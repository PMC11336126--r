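# Configuration and the end-to-end pipeline:
# synth -> preproc -> microstates -> stats -> classify.

#' Default pipeline configuration
#'
#' Nested list of every tunable the pipeline reads.  The single global
#' `seed` expands into stage-specific child seeds by a fixed counter
#' scheme (`seed * 1000 + stage offset`), so individual stages can be
#' rerun in isolation and still reproduce.
#'
#' @return a `pipeline_config` (nested list).
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    synth = list(n_channels = 19L, k = 4L,
                 n_case = 10L, n_control = 10L,
                 duration_s = 60, snr = 0.5, sfreq = 500,
                 mean_dwell = 0.07, dwell_dispersion = 0.5,
                 dwell_shift_class = "C", dwell_shift_s = 0.006,
                 subject_dwell_cv = 0.15),
    preproc = list(band = c(0.1, 40), notch = c(48, 52), target_sfreq = 500,
                   epoch_s = 2, amp_thresh = 100, flat_thresh = 0.1,
                   neighbor_z = 4),
    microstates = list(band = c(2, 20), k_min = 2L, k_max = 8L,
                       gev_gain_threshold = 0.01, force_k = NULL,
                       min_segment_ms = 0, max_peaks = 1000L),
    stats = list(covariates = c("sex", "age", "education"),
                 p_enter = 0.05, p_remove = 0.10),
    classify = list(test_fraction = 0.2, folds = 5L)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; keys absent
#' from the defaults are rejected (typo guard).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge_checked <- function(base, user, prefix = "") {
    for (key in names(user)) {
      if (!key %in% names(base)) {
        stop_invalid("unknown config key: ", prefix, key)
      }
      if (is.list(base[[key]]) && is.list(user[[key]])) {
        base[[key]] <- merge_checked(base[[key]], user[[key]],
                                     paste0(prefix, key, "."))
      } else {
        base[[key]] <- user[[key]]
      }
    }
    base
  }
  out <- merge_checked(unclass(base), user)
  class(out) <- "pipeline_config"
  out
}

# merge runs shorter than min_ms into the preceding run (next run for a
# leading short run); disabled at min_ms = 0, the package default
smooth_labels <- function(ls, min_ms) {
  if (min_ms <= 0) return(ls)
  min_len <- ceiling(min_ms / 1000 * ls$sfreq)
  for (e in unique(ls$epoch_index)) {
    sel <- which(ls$epoch_index == e)
    lab <- ls$labels[sel]
    r <- rle(lab)
    while (any(r$lengths < min_len) && length(r$lengths) > 1L) {
      i <- which.min(r$lengths)
      if (r$lengths[i] >= min_len) break
      r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
      r <- rle(inverse.rle(r))
    }
    ls$labels[sel] <- inverse.rle(r)
  }
  ls
}

# GEV of a backfit labeling over all kept samples of an epoch set
.gev_of_backfit <- function(ep, templates, ls) {
  ep <- kept_epochs(ep)
  dims <- dim(ep$epochs)
  maps <- matrix(aperm(ep$epochs, c(2L, 3L, 1L)), ncol = dims[1L])
  maps <- demean_map(maps)
  gfp <- sqrt(rowMeans(maps^2))
  compute_gev(maps, gfp, templates, ls$labels)
}

#' Run the complete synthetic-cohort pipeline
#'
#' Simulates a cohort, preprocesses every subject, performs per-subject
#' AAHC with model-order selection, averages aligned templates into a
#' single group set (cases and controls jointly), backfits all subjects,
#' computes dynamics metrics, runs the statistical battery (group
#' comparison with family-wise FDR, covariate-adjusted partial rank
#' correlations, stepwise regression of CSF amyloid on microstate
#' predictors) and the decision-tree classification, and writes all tables
#' plus a provenance record to `out_dir`.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed), or NULL to skip
#'   writing files.
#' @return (invisibly) a list with `metrics`, `covariates`,
#'   `group_templates`, `selected_k`, `stat_table`, `chi_square_sex`,
#'   `correlations`, `regression`, `classification`, `provenance`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  sy <- config$synth
  seed <- as.integer(config$seed)
  layout <- make_layout(sy$n_channels)
  templates_true <- make_templates(layout, sy$k, seed = seed * 1000L + 1L)
  dyn <- dynamics_spec(k = sy$k, mean_dwell = sy$mean_dwell,
                       dwell_dispersion = sy$dwell_dispersion)
  dwell_shift <- stats::setNames(sy$dwell_shift_s, sy$dwell_shift_class)
  spec <- cohort_spec(n_per_group = c(AD = sy$n_case, HC = sy$n_control),
                      dwell_shift = dwell_shift,
                      subject_dwell_cv = sy$subject_dwell_cv,
                      duration_s = sy$duration_s, snr = sy$snr,
                      sfreq = sy$sfreq, seed = seed * 1000L + 2L)
  cohort <- simulate_cohort(spec, layout, templates_true, dyn,
                            synthesize = TRUE)
  n_subj <- nrow(cohort$covariates)

  pp <- config$preproc
  ms <- config$microstates
  log_rows <- vector("list", n_subj)
  ep_ms_list <- vector("list", n_subj)
  indiv <- vector("list", n_subj)
  selected_k <- integer(n_subj)
  for (i in seq_len(n_subj)) {
    rec <- cohort$recordings[[i]]
    ep_broad <- preprocess(rec, band = pp$band, notch = pp$notch,
                           target_sfreq = pp$target_sfreq,
                           epoch_s = pp$epoch_s, amp_thresh = pp$amp_thresh,
                           flat_thresh = pp$flat_thresh,
                           neighbor_z = pp$neighbor_z)
    # separate 2-20 Hz copy for microstate analysis, sharing the
    # broad-band epoch rejection decisions
    rec_ms <- apply_filters(rec, band = ms$band, notch = pp$notch)
    if (pp$target_sfreq < rec_ms$sfreq) {
      rec_ms <- resample_recording(rec_ms, pp$target_sfreq)
    }
    ep_ms <- make_epochs(rec_ms, pp$epoch_s)
    ep_ms$kept <- ep_broad$kept
    ep_ms$bad_channels <- ep_broad$bad_channels
    ep_ms <- average_reference(ep_ms)
    ep_ms_list[[i]] <- ep_ms
    res <- run_microstate_analysis(ep_ms, k_min = ms$k_min, k_max = ms$k_max,
                                   gev_gain_threshold = ms$gev_gain_threshold,
                                   force_k = NULL, max_peaks = ms$max_peaks,
                                   seed = seed * 1000L + 100L + i)
    selected_k[i] <- res$k
    indiv[[i]] <- res
    log_rows[[i]] <- data.frame(
      subject = cohort$covariates$subject[i],
      kept_epochs = sum(ep_broad$kept),
      bad_channels = paste(ep_broad$bad_channels, collapse = ";"),
      selected_k = res$k, stringsAsFactors = FALSE)
  }

  # one shared template set (cases + controls jointly), at force_k when
  # pinned, else the majority selected k
  k_group <- ms$force_k %||% as.integer(names(which.max(table(selected_k))))
  indiv_sets <- lapply(indiv, function(r)
    r$clustering$sets[[as.character(k_group)]]$templates)
  group_templates <- align_and_average_templates(indiv_sets, layout = layout)

  metric_rows <- vector("list", n_subj)
  run_rows <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    ls <- backfit(ep_ms_list[[i]], group_templates)
    ls <- smooth_labels(ls, ms$min_segment_ms)
    rl <- segment_runs(ls)
    run_rows[[i]] <- data.frame(
      subject = cohort$covariates$subject[i], epoch = rl$epoch,
      start_sample = rl$start, length = rl$length,
      class = group_templates$class_labels[rl$class],
      stringsAsFactors = FALSE)
    gev <- .gev_of_backfit(ep_ms_list[[i]], group_templates, ls)
    mm <- compute_metrics(rl, ls$sfreq, k_group, gev = gev,
                          class_labels = group_templates$class_labels)
    tp <- transition_probabilities(rl, k_group,
                                   class_labels = group_templates$class_labels)
    metric_rows[[i]] <- data.frame(
      subject = cohort$covariates$subject[i],
      group = cohort$covariates$group[i],
      as.data.frame(as.list(metrics_to_row(mm, tp))),
      stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, metric_rows)

  # --- statistics -----------------------------------------------------
  cl <- group_templates$class_labels
  families <- list(
    global = c("gev", "total_time", "mean_duration", "mean_occurrence"),
    duration = paste0("duration_", cl),
    occurrence = paste0("occurrence_", cl),
    coverage = paste0("coverage_", cl),
    transition = grep("^tp_", names(metrics), value = TRUE))
  stat_table <- compare_groups(metrics, "group", families)

  cov <- cohort$covariates
  sex_tab <- table(cov$group, cov$sex)
  chi_sex <- chi_square_2x2(matrix(as.numeric(sex_tab), 2L, 2L))

  case_lv <- names(spec$n_per_group)[1L]
  sel_case <- cov$group == case_lv
  adj <- cbind(sex = as.numeric(cov$sex == "M"), age = cov$age,
               education = cov$education)[sel_case, , drop = FALSE]
  ms_vars <- intersect(c(paste0("duration_", cl[3]), paste0("duration_", cl[4]),
                         "mean_duration", paste0("occurrence_", cl[2]),
                         "mean_occurrence",
                         paste0("tp_", cl[3], "_", cl[1])),
                       names(metrics))
  outcome_vars <- intersect(c("mmse", "moca", "adl", "scwt_dot", "scwt_word",
                              "vft_s", "abeta42", "abeta40", "ptau181",
                              "ttau", "nfl"), names(cov))
  cor_rows <- list()
  for (mv in ms_vars) {
    for (ov in outcome_vars) {
      pr <- partial_rank_correlation(metrics[[mv]][sel_case],
                                     cov[[ov]][sel_case], adj)
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        metric = mv, outcome = ov, rho = pr$rho, p = pr$p, n = pr$n,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cor_rows)

  reg_X <- data.frame(metrics[sel_case, ms_vars, drop = FALSE],
                      sex = as.numeric(cov$sex[sel_case] == "M"),
                      age = cov$age[sel_case],
                      education = cov$education[sel_case])
  regression <- stepwise_regression(cov$abeta42[sel_case], reg_X,
                                    p_enter = config$stats$p_enter,
                                    p_remove = config$stats$p_remove)

  feat_cols <- c(paste0("duration_", cl), paste0("occurrence_", cl),
                 paste0("coverage_", cl), "mean_duration", "mean_occurrence",
                 "gev", "total_time", grep("^tp_", names(metrics), value = TRUE))
  features <- metrics[, c("group", feat_cols)]
  classification <- classify_cohort(features, "group",
                                    test_fraction = config$classify$test_fraction,
                                    folds = config$classify$folds,
                                    seed = seed * 1000L + 3L,
                                    positive = case_lv)

  provenance <- list(
    package = "microstatr",
    package_version = as.character(utils::packageVersion("microstatr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, config = unclass(config),
    selected_k_per_subject = selected_k, k_group = k_group)

  result <- list(metrics = metrics, covariates = cov,
                 group_templates = group_templates,
                 selected_k = selected_k, k_group = k_group,
                 stat_table = stat_table, chi_square_sex = chi_sex,
                 correlations = correlations, regression = regression,
                 classification = classification,
                 subject_log = do.call(rbind, log_rows),
                 provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(metrics, file.path(out_dir, "metrics.csv"))
    write_table(cov, file.path(out_dir, "covariates.csv"))
    write_table(as.data.frame(stat_table),
                file.path(out_dir, "group_comparison.csv"))
    write_table(correlations, file.path(out_dir, "correlations.csv"))
    if (nrow(regression$coefficients)) {
      write_table(regression$coefficients,
                  file.path(out_dir, "regression_coefficients.csv"))
    }
    write_table(result$subject_log, file.path(out_dir, "subject_log.csv"))
    write_table(do.call(rbind, run_rows),
                file.path(out_dir, "label_runs.csv"))
    tmpl_df <- data.frame(class = group_templates$class_labels,
                          group_templates$maps, check.names = FALSE)
    write_table(tmpl_df, file.path(out_dir, "group_templates.csv"))
    rep <- classification$report
    jsonlite::write_json(
      list(per_class = rep$per_class, accuracy = rep$accuracy,
           macro_avg = as.list(rep$macro_avg),
           weighted_avg = as.list(rep$weighted_avg), auc = rep$auc,
           fold_accuracy = classification$fold_accuracy),
      file.path(out_dir, "classification_report.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(rep$roc)) {
      write_table(rep$roc, file.path(out_dir, "roc_points.csv"))
    }
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  invisible(result)
}
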