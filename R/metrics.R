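# Backfitting, run segmentation, and microstate dynamics metrics.

#' Backfit template maps to every sample
#'
#' Assigns each sample to the template with the highest polarity-invariant
#' spatial correlation (ties broken by lowest class index).  Samples with
#' zero spatial variance inherit the previous sample's label within their
#' epoch; a zero-variance first sample takes the next valid label.
#'
#' @param ep an `epoch_set` (average-referenced, conventionally 2-20 Hz;
#'   only kept epochs are labeled).
#' @param templates a `template_set`.
#' @return a `label_sequence`: integer `labels` (1..k) over all kept
#'   samples, `epoch_index`, `sample_index`, `sfreq`, plus the template
#'   `class_labels` as an attribute.
#' @export
backfit <- function(ep, templates) {
  ep <- kept_epochs(ep)
  tm <- unit_norm(demean_map(templates$maps))
  dims <- dim(ep$epochs)
  n_ep <- dims[3L]; spe <- dims[2L]
  labels <- integer(n_ep * spe)
  for (e in seq_len(n_ep)) {
    V <- ep$epochs[, , e]
    V <- sweep(V, 2L, colMeans(V), "-")
    nrm <- sqrt(colSums(V^2))
    corr <- abs(tm %*% V)                  # k x samples (unnormalized by nrm
    lab <- max.col(t(corr), "first")       #  — argmax unaffected by scale)
    bad <- nrm < 1e-12
    if (any(bad)) {
      if (all(bad)) stop_quality("zero-variance epoch")
      good_idx <- which(!bad)
      # inherit previous valid label; leading gaps take the next valid one
      filled <- lab
      last <- NA_integer_
      for (s in seq_len(spe)) {
        if (!bad[s]) last <- filled[s] else if (!is.na(last)) filled[s] <- last
      }
      first_good <- good_idx[1L]
      if (first_good > 1L) filled[seq_len(first_good - 1L)] <- filled[first_good]
      lab <- filled
    }
    labels[((e - 1L) * spe + 1L):(e * spe)] <- lab
  }
  structure(list(labels = labels,
                 epoch_index = rep(seq_len(n_ep), each = spe),
                 sample_index = rep(seq_len(spe), n_ep),
                 sfreq = ep$sfreq,
                 class_labels = templates$class_labels),
            class = "label_sequence")
}

#' Collapse a label sequence into maximal constant-class runs
#'
#' Runs never span epoch boundaries; the first and last run of each epoch
#' are flagged truncated (their true extent is censored by the epoch cut).
#'
#' @param ls a `label_sequence`.
#' @return a `run_list` data.frame with columns `class`, `start` (global
#'   sample index), `length` (samples), `epoch`, `trunc_start`,
#'   `trunc_end`.
#' @export
segment_runs <- function(ls) {
  out <- vector("list", 0L)
  offset <- 0L
  for (e in unique(ls$epoch_index)) {
    lab <- ls$labels[ls$epoch_index == e]
    r <- rle(lab)
    n_r <- length(r$lengths)
    starts <- offset + c(1L, 1L + cumsum(r$lengths[-n_r]))
    out[[length(out) + 1L]] <- data.frame(
      class = r$values, start = starts, length = r$lengths,
      epoch = e,
      trunc_start = seq_len(n_r) == 1L,
      trunc_end = seq_len(n_r) == n_r)
    offset <- offset + length(lab)
  }
  rl <- do.call(rbind, out)
  class(rl) <- c("run_list", "data.frame")
  rl
}

#' Microstate dynamics metrics from a run list
#'
#' Per class c: `duration_c` = mean run length in seconds (truncated
#' epoch-edge runs included, keeping the coverage identity exact);
#' `occurrence_c` = runs per second; `coverage_c` = fraction of labeled
#' samples.  Globals: `mean_duration` = total labeled time / total runs,
#' `mean_occurrence` = total runs / total time (equal to the sum of class
#' occurrences), `total_time` = labeled samples / sfreq.  A class with no
#' runs gets `NA` duration (missing, not zero).
#'
#' @param rl a `run_list`.
#' @param sfreq sampling rate in Hz.
#' @param k number of classes.
#' @param gev the GEV of the labeling (carried through for reporting).
#' @param class_labels optional class names (default `LETTERS`).
#' @return a `microstate_metrics` list: named vectors `duration`,
#'   `occurrence`, `coverage`, scalars `mean_duration`, `mean_occurrence`,
#'   `gev`, `total_time`.
#' @export
compute_metrics <- function(rl, sfreq, k, gev = NA_real_,
                            class_labels = NULL) {
  if (!nrow(rl)) stop_invalid("empty run list")
  class_labels <- class_labels %||% LETTERS[seq_len(k)]
  total_samples <- sum(rl$length)
  total_time <- total_samples / sfreq
  n_runs <- nrow(rl)
  duration <- occurrence <- coverage <- stats::setNames(numeric(k), class_labels)
  for (c_i in seq_len(k)) {
    sel <- rl$class == c_i
    n_c <- sum(sel)
    occurrence[c_i] <- n_c / total_time
    coverage[c_i] <- sum(rl$length[sel]) / total_samples
    duration[c_i] <- if (n_c) mean(rl$length[sel]) / sfreq else NA_real_
  }
  structure(list(duration = duration, occurrence = occurrence,
                 coverage = coverage,
                 mean_duration = total_time / n_runs,
                 mean_occurrence = n_runs / total_time,
                 gev = gev, total_time = total_time),
            class = "microstate_metrics")
}

#' Transition probabilities between microstate classes
#'
#' Counts transitions between consecutive runs within each epoch (never
#' across epoch boundaries) and normalizes jointly by the total transition
#' count, so the k(k-1) off-diagonal entries sum to 1 (diagonal zero).
#' With zero transitions the matrix is all-`NA` (missing, not zero).
#'
#' @param rl a `run_list`.
#' @param k number of classes.
#' @param class_labels optional class names.
#' @return k x k matrix of transition fractions.
#' @export
transition_probabilities <- function(rl, k, class_labels = NULL) {
  class_labels <- class_labels %||% LETTERS[seq_len(k)]
  counts <- matrix(0, k, k, dimnames = list(class_labels, class_labels))
  for (e in unique(rl$epoch)) {
    cls <- rl$class[rl$epoch == e]
    if (length(cls) < 2L) next
    counts <- counts + unclass(table(factor(cls[-length(cls)], levels = seq_len(k)),
                                     factor(cls[-1L], levels = seq_len(k))))
  }
  tot <- sum(counts)
  if (tot == 0) {
    counts[] <- NA_real_
    return(counts)
  }
  counts / tot
}

#' Flatten metrics and transition matrix into one named row
#'
#' Produces the tidy per-subject row used by the statistics and
#' classification stages: `duration_A..`, `occurrence_A..`,
#' `coverage_A..`, `mean_duration`, `mean_occurrence`, `gev`,
#' `total_time`, and `tp_A_B..` (row-major, off-diagonal).
#'
#' @param mm a `microstate_metrics`.
#' @param tp k x k transition matrix.
#' @return a named numeric vector.
#' @export
metrics_to_row <- function(mm, tp) {
  cl <- names(mm$duration)
  out <- c(stats::setNames(mm$duration, paste0("duration_", cl)),
           stats::setNames(mm$occurrence, paste0("occurrence_", cl)),
           stats::setNames(mm$coverage, paste0("coverage_", cl)),
           mean_duration = unname(mm$mean_duration),
           mean_occurrence = unname(mm$mean_occurrence),
           gev = unname(mm$gev), total_time = unname(mm$total_time))
  k <- length(cl)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) out[paste0("tp_", cl[i], "_", cl[j])] <- tp[i, j]
  }
  out
}
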