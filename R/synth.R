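# Synthetic EEG with known microstate ground truth.
#
# Recordings are built as a semi-Markov sequence of quasi-stable scalp
# topographies modulated by a rectified alpha-band oscillation, plus
# spatially correlated sensor noise.  Every generator is a pure function of
# (spec, seed), so downstream stages can be tested against exact ground
# truth without external data.

#' Deterministic scalp-cap sensor layout
#'
#' Places `n_channels` sensors on the upper hemisphere of the unit sphere
#' (cap region, z >= -0.2) along a Fibonacci spiral, giving roughly uniform
#' coverage for any channel count.
#'
#' @param n_channels number of sensors (4..256).
#' @return an object of class `eeg_layout`: list with `channel_names` and a
#'   `n_channels x 3` matrix `positions` of unit vectors.
#' @export
#' @examples
#' lay <- make_layout(19)
#' range(lay$positions[, "z"])
make_layout <- function(n_channels = 60L) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 4 || n_channels > 256) {
    stop_invalid("n_channels must be a single value in 4..256")
  }
  n <- as.integer(n_channels)
  i <- seq_len(n)
  # z descends from just below the vertex to the cap rim at -0.2
  z <- 1 - (i - 0.5) / n * 1.2
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (i - 1)
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)
  structure(list(channel_names = sprintf("E%03d", i), positions = pos),
            class = "eeg_layout")
}

#' Construct a template set from raw maps
#'
#' Average-references and unit-normalizes each map.
#'
#' @param maps k x n_channels matrix, one topography per row.
#' @param class_labels optional labels (defaults to `"C1"..`).
#' @return a `template_set`.
#' @export
template_set <- function(maps, class_labels = NULL) {
  if (!is.matrix(maps) || nrow(maps) < 2L) stop_invalid("need >= 2 maps")
  maps <- unit_norm(demean_map(maps))
  labels <- class_labels %||% sprintf("C%d", seq_len(nrow(maps)))
  if (length(labels) != nrow(maps)) stop_invalid("label/map count mismatch")
  rownames(maps) <- labels
  structure(list(maps = maps, class_labels = labels), class = "template_set")
}

#' Generate smooth dipolar microstate templates
#'
#' Each template is the difference of two Gaussian blobs centred at
#' antipodal points on the sphere — a smooth dipolar field resembling the
#' canonical microstate maps.  Candidates too collinear with already
#' accepted templates (|spatial correlation| >= 0.8) are redrawn, so the
#' returned set is mutually distinguishable.  Deterministic given `seed`.
#'
#' @param layout an `eeg_layout`.
#' @param k number of template classes (2 .. n_channels - 1).
#' @param seed integer seed.
#' @return a `template_set` with `k` average-referenced unit-norm maps.
#' @export
make_templates <- function(layout, k = 4L, seed = 1L) {
  n <- length(layout$channel_names)
  if (k < 2 || k > n - 1) stop_invalid("k must be in 2..n_channels-1")
  with_seed(seed, {
    maps <- matrix(0, k, n)
    accepted <- 0L
    attempts <- 0L
    pos <- layout$positions
    while (accepted < k) {
      attempts <- attempts + 1L
      if (attempts > 1000L) stop_invalid("could not draw non-collinear templates")
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      sigma <- stats::runif(1, 0.8, 1.4)
      d1 <- sqrt(colSums((t(pos) - d)^2))
      d2 <- sqrt(colSums((t(pos) + d)^2))
      m <- exp(-(d1 / sigma)^2) - exp(-(d2 / sigma)^2)
      m <- m - mean(m)
      nrm <- sqrt(sum(m^2))
      if (nrm < 1e-8) next
      m <- m / nrm
      if (accepted > 0L &&
          any(abs(maps[seq_len(accepted), , drop = FALSE] %*% m) >= 0.8)) next
      accepted <- accepted + 1L
      maps[accepted, ] <- m
    }
    colnames(maps) <- layout$channel_names
    template_set(maps, class_labels = LETTERS[seq_len(k)])
  })
}

#' Microstate dynamics specification
#'
#' Ground-truth dynamics for the semi-Markov label generator: dwell times
#' are gamma-distributed with per-class mean `mean_dwell` (seconds) and a
#' common coefficient of variation `dwell_dispersion`; the class following
#' each dwell is drawn from the corresponding row of `transition_weights`
#' (zero diagonal, rows renormalized internally).
#'
#' @param k number of classes (used when `transition_weights` is NULL).
#' @param transition_weights k x k nonnegative matrix, zero diagonal.
#' @param mean_dwell mean dwell per class in seconds (scalar recycled).
#' @param dwell_dispersion coefficient of variation of dwell times.
#' @return a `dynamics_spec`.
#' @export
dynamics_spec <- function(k = 4L, transition_weights = NULL,
                          mean_dwell = 0.07, dwell_dispersion = 0.5) {
  if (is.null(transition_weights)) {
    transition_weights <- matrix(1, k, k)
    diag(transition_weights) <- 0
  }
  k <- nrow(transition_weights)
  if (ncol(transition_weights) != k || any(transition_weights < 0) ||
      any(diag(transition_weights) != 0)) {
    stop_invalid("transition_weights must be square, nonnegative, zero diagonal")
  }
  if (any(rowSums(transition_weights) <= 0)) {
    stop_invalid("every class needs at least one allowed successor")
  }
  mean_dwell <- rep_len(mean_dwell, k)
  if (any(mean_dwell <= 0) || dwell_dispersion <= 0) {
    stop_invalid("mean_dwell and dwell_dispersion must be positive")
  }
  structure(list(transition_weights = transition_weights,
                 mean_dwell = mean_dwell,
                 dwell_dispersion = dwell_dispersion, k = k),
            class = "dynamics_spec")
}

#' Simulate a ground-truth microstate label sequence
#'
#' Semi-Markov process: gamma dwell times (shape = 1/CV^2) rounded to
#' samples (minimum one sample), successor classes from the normalized
#' transition weights.  Consecutive runs always differ in class.
#'
#' @param dyn a `dynamics_spec`.
#' @param n_samples sequence length in samples.
#' @param sfreq sampling rate in Hz.
#' @param seed integer seed.
#' @return a `label_sequence`: list with integer `labels` (1..k), `sfreq`,
#'   and `epoch_index` (all 1 — a continuous recording is one epoch).
#' @export
simulate_labels <- function(dyn, n_samples, sfreq, seed = 1L) {
  if (n_samples < 1 || sfreq <= 0) stop_invalid("need n_samples >= 1, sfreq > 0")
  with_seed(seed, {
    k <- dyn$k
    shape <- 1 / dyn$dwell_dispersion^2
    labels <- integer(n_samples)
    pos <- 1L
    state <- sample.int(k, 1L)
    while (pos <= n_samples) {
      dwell_s <- stats::rgamma(1, shape = shape,
                               scale = dyn$mean_dwell[state] / shape)
      len <- max(1L, as.integer(round(dwell_s * sfreq)))
      end <- min(n_samples, pos + len - 1L)
      labels[pos:end] <- state
      pos <- end + 1L
      w <- dyn$transition_weights[state, ]
      state <- sample.int(k, 1L, prob = w)
    }
    structure(list(labels = labels, sfreq = sfreq,
                   epoch_index = rep(1L, n_samples)),
              class = "label_sequence")
  })
}

#' Synthesize a continuous EEG recording from labels and templates
#'
#' The instantaneous topography is the active class template carried by an
#' alpha-band oscillation `sin(2 pi f t + pi/4)` (amplitude in microvolts),
#' so the GFP follows the rectified `|sin|`-shaped amplitude envelope with
#' two peaks per carrier cycle, and the field polarity reverses every
#' half-cycle — the physical reason microstate clustering is
#' polarity-invariant.  The pi/4 phase keeps sample grids off the exact
#' carrier zeros.  Sensor noise is spatially smoothed white noise scaled so
#' that RMS(signal)/RMS(noise) equals `snr`.
#'
#' @param templates a `template_set`.
#' @param labels a `label_sequence` (its `sfreq` must equal `sfreq`).
#' @param osc_freq envelope oscillation frequency in Hz.
#' @param snr signal-to-noise ratio (RMS ratio), > 0.
#' @param sfreq sampling rate in Hz.
#' @param seed integer seed (noise only; envelope is deterministic).
#' @param amplitude peak envelope amplitude in microvolts.
#' @param noise_smoothness spatial length scale (chordal distance) of the
#'   sensor-noise correlation kernel.
#' @param layout optional `eeg_layout`; when given, sensor noise is smoothed
#'   across neighboring channels and the layout is attached to the result.
#' @return an `eeg_recording` with `data` (n_channels x n_samples, uV),
#'   `sfreq` and `layout`.
#' @export
synthesize_recording <- function(templates, labels, osc_freq = 10, snr = 2,
                                 sfreq = 500, seed = 1L, amplitude = 15,
                                 noise_smoothness = 0.6, layout = NULL) {
  n <- length(labels$labels)
  if (labels$sfreq != sfreq) stop_invalid("labels/sfreq mismatch")
  if (osc_freq <= 0 || osc_freq >= sfreq / 2) stop_invalid("osc_freq out of band")
  if (snr <= 0) stop_invalid("snr must be > 0")
  tt <- (seq_len(n) - 1) / sfreq
  env <- sin(2 * pi * osc_freq * tt + pi / 4) * amplitude
  maps_t <- t(templates$maps)                       # n_channels x k
  sig <- maps_t[, labels$labels, drop = FALSE] *
    matrix(env, nrow(maps_t), n, byrow = TRUE)
  noise <- with_seed(seed, {
    nc <- nrow(maps_t)
    white <- matrix(stats::rnorm(nc * n), nc, n)
    white
  })
  # spatial smoothing over neighboring sensors makes the noise realistic
  # (and bad-channel detection nontrivial)
  if (!is.null(layout)) {
    dmat <- as.matrix(stats::dist(layout$positions))
    kern <- exp(-(dmat / noise_smoothness)^2)
    noise <- kern %*% noise
  }
  rms_sig <- sqrt(mean(sig^2))
  rms_noise <- sqrt(mean(noise^2))
  noise <- noise * (rms_sig / (snr * rms_noise))
  out <- sig + noise
  dimnames(out) <- NULL
  if (!is.null(layout)) rownames(out) <- layout$channel_names
  structure(list(data = out, sfreq = sfreq, layout = layout,
                 annotations = list()),
            class = "eeg_recording")
}

#' Bundle data and layout into a recording
#'
#' @param data n_channels x n_samples matrix in microvolts.
#' @param sfreq sampling rate (Hz).
#' @param layout an `eeg_layout` with matching channel count.
#' @param annotations optional list of (label, start_s, duration_s).
#' @return an `eeg_recording`.
#' @export
recording <- function(data, sfreq, layout, annotations = list()) {
  if (!is.matrix(data) || !all(is.finite(data))) stop_invalid("data must be a finite matrix")
  if (nrow(data) != length(layout$channel_names)) {
    stop_invalid("data/layout channel count mismatch")
  }
  if (sfreq <= 0) stop_invalid("sfreq must be > 0")
  rownames(data) <- layout$channel_names
  structure(list(data = data, sfreq = sfreq, layout = layout,
                 annotations = annotations),
            class = "eeg_recording")
}

#' Cohort simulation specification
#'
#' Defines group sizes, the group effect on class dwell times, planted
#' metric-covariate correlations, and recording parameters.  Defaults
#' emulate an Alzheimer's disease (AD) vs healthy control (HC) resting-state
#' cohort: 56 AD / 38 HC, class-C dwell lengthened by 6 ms in AD, and
#' moderate planted correlations between class-C duration and CSF
#' amyloid-beta(1-42) / Stroop dot-naming score.
#'
#' @param n_per_group named counts, e.g. `c(AD = 56, HC = 38)`.
#' @param dwell_shift named numeric: additive shift (seconds) applied to the
#'   first-named ("case") group's mean dwell, by class label.
#' @param planted_correlations data.frame with columns `metric`, `covariate`,
#'   `rho` (|rho| < 1); realized within the case group.
#' @param subject_dwell_cv between-subject lognormal CV of class dwell means.
#' @param duration_s recording length per subject in seconds.
#' @param snr recording signal-to-noise ratio.
#' @param sfreq sampling rate (Hz).
#' @param seed integer master seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(AD = 56, HC = 38),
                        dwell_shift = c(C = 0.006),
                        planted_correlations = data.frame(
                          metric = c("duration_C", "duration_C"),
                          covariate = c("abeta42", "scwt_dot"),
                          rho = c(-0.40, 0.45)),
                        subject_dwell_cv = 0.15,
                        duration_s = 60, snr = 0.5, sfreq = 500,
                        seed = 1L) {
  if (any(n_per_group < 2)) stop_invalid("need >= 2 subjects per group")
  if (length(n_per_group) != 2L || is.null(names(n_per_group))) {
    stop_invalid("n_per_group must be two named counts")
  }
  if (nrow(planted_correlations) > 0 &&
      any(abs(planted_correlations$rho) >= 1)) {
    stop_invalid("|target rho| must be < 1")
  }
  structure(list(n_per_group = n_per_group, dwell_shift = dwell_shift,
                 planted_correlations = planted_correlations,
                 subject_dwell_cv = subject_dwell_cv,
                 duration_s = duration_s, snr = snr, sfreq = sfreq,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Demographic / clinical covariate profile per group (means, sds) at the
# scale of a typical AD vs HC cohort.  Case group first.
.covariate_profile <- function() {
  list(
    case = list(age = c(62.2, 8.4), education = c(8.2, 4.4), p_male = 25 / 56,
                mmse = c(18.7, 6.4), moca = c(13.4, 6.4),
                adl = c(28.3, 7.3), scwt_dot = c(40, 12), scwt_word = c(45, 13),
                vft_s = c(10, 4),
                abeta42 = c(729.6, 395.5), abeta40 = c(8885.7, 3651.2),
                ptau181 = c(111.9, 51.6), ttau = c(546.0, 262.7),
                nfl = c(1408.6, 1097.1)),
    control = list(age = c(60.3, 7.1), education = c(12.4, 2.6), p_male = 14 / 38,
                   mmse = c(28.5, 1.4), moca = c(26.4, 1.8),
                   adl = c(20.2, 0.8), scwt_dot = c(28, 8), scwt_word = c(33, 9),
                   vft_s = c(15, 4),
                   abeta42 = c(1100, 300), abeta40 = c(9500, 3000),
                   ptau181 = c(45, 15), ttau = c(250, 100),
                   nfl = c(600, 300))
  )
}

#' Simulate a full cohort: per-subject label sequences, ground-truth
#' metrics, covariates, and (optionally) raw EEG recordings
#'
#' Each subject draws a subject-level dwell vector (lognormal between-subject
#' variability around the group mean, case group shifted per
#' `spec$dwell_shift`), simulates a label sequence, and computes ground-truth
#' microstate metrics from it.  Planted correlations are realized within the
#' case group by the exact linear mixture
#' `covariate = rho * z(metric) + sqrt(1 - rho^2) * z_noise`, rescaled to the
#' covariate's profile mean/sd, so the target rho is analytic.
#'
#' @param spec a `cohort_spec`.
#' @param layout an `eeg_layout`.
#' @param templates a `template_set` (k classes).
#' @param dyn a `dynamics_spec` (control-group dynamics).
#' @param synthesize if TRUE, also synthesize the raw EEG recording per
#'   subject (memory-heavy; metrics and covariates never require it).
#' @return list with `metrics` (ground-truth per-subject metrics
#'   data.frame), `covariates` (data.frame: subject, group, sex, age,
#'   education, cognitive scores, CSF values), `labels` (list of
#'   `label_sequence`), and `recordings` (list or NULL).
#' @export
simulate_cohort <- function(spec, layout, templates, dyn, synthesize = FALSE) {
  k <- dyn$k
  groups <- names(spec$n_per_group)
  n_total <- sum(spec$n_per_group)
  group_col <- rep(groups, spec$n_per_group)
  prof <- .covariate_profile()
  n_samples <- round(spec$duration_s * spec$sfreq)

  labels_list <- vector("list", n_total)
  recordings <- if (synthesize) vector("list", n_total) else NULL
  metrics_rows <- vector("list", n_total)

  class_labels <- templates$class_labels
  shift_vec <- rep(0, k)
  if (length(spec$dwell_shift)) {
    idx <- match(names(spec$dwell_shift), class_labels)
    if (anyNA(idx)) stop_invalid("dwell_shift names must match class labels")
    shift_vec[idx] <- spec$dwell_shift
  }

  for (i in seq_len(n_total)) {
    sseed <- spec$seed * 10000L + i
    base_dwell <- dyn$mean_dwell
    if (group_col[i] == groups[1L]) base_dwell <- base_dwell + shift_vec
    subj_dwell <- with_seed(sseed, {
      base_dwell * exp(stats::rnorm(k, 0, spec$subject_dwell_cv) -
                         spec$subject_dwell_cv^2 / 2)
    })
    dyn_i <- dynamics_spec(transition_weights = dyn$transition_weights,
                           mean_dwell = subj_dwell,
                           dwell_dispersion = dyn$dwell_dispersion)
    ls <- simulate_labels(dyn_i, n_samples, spec$sfreq, seed = sseed + 1L)
    labels_list[[i]] <- ls
    rl <- segment_runs(ls)
    mm <- compute_metrics(rl, spec$sfreq, k, gev = NA_real_,
                          class_labels = class_labels)
    tp <- transition_probabilities(rl, k, class_labels = class_labels)
    metrics_rows[[i]] <- c(as.list(metrics_to_row(mm, tp)),
                           list(subject = sprintf("S%03d", i),
                                group = group_col[i]))
    if (synthesize) {
      recordings[[i]] <- synthesize_recording(
        templates, ls, snr = spec$snr, sfreq = spec$sfreq,
        seed = sseed + 2L, layout = layout)
    }
  }

  metrics <- do.call(rbind, lapply(metrics_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  metrics <- metrics[, c("subject", "group",
                         setdiff(names(metrics), c("subject", "group")))]

  covariates <- with_seed(spec$seed * 10000L + n_total + 99L, {
    df <- data.frame(subject = metrics$subject, group = metrics$group,
                     stringsAsFactors = FALSE)
    vars <- setdiff(names(prof$case), "p_male")
    grp_prof <- list(prof$case, prof$control)
    df$sex <- NA_character_
    for (g in 1:2) {
      sel <- df$group == groups[g]
      df$sex[sel] <- ifelse(stats::runif(sum(sel)) < grp_prof[[g]]$p_male,
                            "M", "F")
      for (v in vars) {
        ms <- grp_prof[[g]][[v]]
        df[[v]][sel] <- stats::rnorm(sum(sel), ms[1], ms[2])
      }
    }
    # realize planted correlations inside the case group
    pc <- spec$planted_correlations
    if (!is.null(pc) && nrow(pc) > 0) {
      sel <- df$group == groups[1L]
      for (j in seq_len(nrow(pc))) {
        met <- metrics[[pc$metric[j]]][sel]
        if (is.null(met)) stop_invalid("unknown planted metric: ", pc$metric[j])
        zmet <- as.numeric(scale(met))
        rho <- pc$rho[j]
        ms <- prof$case[[pc$covariate[j]]]
        if (is.null(ms)) stop_invalid("unknown planted covariate: ", pc$covariate[j])
        znoise <- stats::rnorm(sum(sel))
        df[[pc$covariate[j]]][sel] <-
          ms[1] + ms[2] * (rho * zmet + sqrt(1 - rho^2) * znoise)
      }
    }
    df
  })

  list(metrics = metrics, covariates = covariates,
       labels = labels_list, recordings = recordings)
}
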