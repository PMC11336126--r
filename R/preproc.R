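# Deterministic preprocessing: zero-phase filtering, resampling, epoching,
# bad-channel repair, amplitude-based epoch rejection, average reference.
# Fixed pipeline order: filter -> resample -> epoch -> repair -> reject ->
# re-reference.

.filtfilt_rows <- function(x, filt) {
  t(apply(x, 1L, function(ch) as.numeric(signal::filtfilt(filt, ch))))
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass
#' (second-order high-pass at `band[1]`, fourth-order low-pass at `band[2]`)
#' followed by a second-order band-stop over `notch`.  Zero-phase filtering
#' is used throughout so that microstate boundaries are not phase-shifted.
#'
#' @param rec an `eeg_recording`.
#' @param band c(low, high) pass band in Hz; `band[1] = 0` skips the
#'   high-pass.
#' @param notch c(low, high) stop band in Hz, or NULL to skip.
#' @return the filtered recording (same length).
#' @export
apply_filters <- function(rec, band = c(0.1, 40), notch = c(48, 52)) {
  nyq <- rec$sfreq / 2
  if (length(band) != 2L || band[1] < 0 || band[1] >= band[2] || band[2] >= nyq) {
    stop_invalid("band must satisfy 0 <= low < high < sfreq/2")
  }
  x <- rec$data
  if (band[1] > 0) {
    x <- x - rowMeans(x)    # remove DC first: shrinks high-pass transients
    hp <- signal::butter(2, band[1] / nyq, type = "high")
    x <- .filtfilt_rows(x, hp)
  }
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  x <- .filtfilt_rows(x, lp)
  if (!is.null(notch)) {
    if (length(notch) != 2L || notch[1] <= 0 || notch[1] >= notch[2] ||
        notch[2] >= nyq) {
      stop_invalid("notch interval must lie inside (0, sfreq/2)")
    }
    bs <- signal::butter(2, notch / nyq, type = "stop")
    x <- .filtfilt_rows(x, bs)
  }
  rownames(x) <- rownames(rec$data)
  rec$data <- x
  rec
}

#' Downsample a recording
#'
#' Integer decimation with a zero-phase anti-alias low-pass (cutoff at 80%
#' of the new Nyquist); non-integer ratios go through polyphase resampling.
#' Upsampling is refused (never needed by the pipeline).
#'
#' @param rec an `eeg_recording`.
#' @param target_sfreq new sampling rate in Hz (<= current).
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_sfreq) {
  if (target_sfreq > rec$sfreq) stop_invalid("upsampling not supported")
  if (target_sfreq == rec$sfreq) return(rec)
  ratio <- rec$sfreq / target_sfreq
  x <- rec$data
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- as.integer(round(ratio))
    aa <- signal::butter(6, 0.8 * (target_sfreq / 2) / (rec$sfreq / 2),
                         type = "low")
    x <- .filtfilt_rows(x, aa)
    x <- x[, seq(1L, ncol(x), by = q), drop = FALSE]
  } else {
    p <- target_sfreq
    q <- rec$sfreq
    g <- .gcd_int(round(p), round(q))
    x <- t(apply(x, 1L, function(ch)
      as.numeric(signal::resample(ch, round(p) / g, round(q) / g))))
  }
  rownames(x) <- rownames(rec$data)
  rec$data <- x
  rec$sfreq <- target_sfreq
  rec
}

.gcd_int <- function(a, b) if (b == 0) a else .gcd_int(b, a %% b)

#' Cut a recording into non-overlapping fixed-length epochs
#'
#' @param rec an `eeg_recording`.
#' @param length_s epoch length in seconds (default 2).
#' @return an `epoch_set`: list with `epochs` (n_channels x samples x
#'   n_epochs array, uV), `sfreq`, `layout`, logical `kept` per epoch, and
#'   `bad_channels` (character).  A recording shorter than one epoch yields
#'   zero epochs with a warning.
#' @export
make_epochs <- function(rec, length_s = 2) {
  if (length_s <= 0) stop_invalid("length_s must be > 0")
  spe <- round(length_s * rec$sfreq)
  n_ep <- floor(ncol(rec$data) / spe)
  if (n_ep == 0L) warning("recording shorter than one epoch; empty epoch set")
  ep <- array(NA_real_, dim = c(nrow(rec$data), spe, n_ep))
  for (e in seq_len(n_ep)) {
    ep[, , e] <- rec$data[, ((e - 1L) * spe + 1L):(e * spe)]
  }
  dimnames(ep) <- list(rownames(rec$data), NULL, NULL)
  structure(list(epochs = ep, sfreq = rec$sfreq, layout = rec$layout,
                 kept = rep(TRUE, n_ep), bad_channels = character(0)),
            class = "epoch_set")
}

#' Detect and interpolate bad channels
#'
#' A channel is flagged bad if (a) its absolute amplitude exceeds
#' `amp_thresh` in more than 20% of epochs, (b) its per-epoch peak-to-peak
#' amplitude falls below `flat_thresh` (flat line) in more than 20% of
#' epochs, or (c) the robust z-score of its median deviation from the mean
#' of its 4 nearest neighbors exceeds `neighbor_z`.  Flagged channels are
#' replaced by the inverse-distance-weighted mean of their 4 nearest good
#' neighbors.  These thresholds are automated surrogates for visual
#' inspection criteria and are recorded with the output.
#'
#' @param ep an `epoch_set`.
#' @param amp_thresh amplitude criterion in microvolts (default 100).
#' @param flat_thresh flat-line peak-to-peak criterion in microvolts
#'   (default 0.1).
#' @param neighbor_z robust z threshold for neighbor deviation (default 4).
#' @return the repaired `epoch_set` with `bad_channels` filled in.
#' @export
repair_bad_channels <- function(ep, amp_thresh = 100, flat_thresh = 0.1,
                                neighbor_z = 4) {
  if (amp_thresh <= 0 || flat_thresh <= 0 || neighbor_z <= 0) {
    stop_invalid("thresholds must be positive")
  }
  dims <- dim(ep$epochs)
  nc <- dims[1L]; n_ep <- dims[3L]
  if (n_ep == 0L) return(ep)
  frac_amp <- frac_flat <- numeric(nc)
  for (c_i in seq_len(nc)) {
    chan <- ep$epochs[c_i, , , drop = FALSE]
    per_ep_max <- apply(abs(chan), 3L, max)
    per_ep_ptp <- apply(chan, 3L, function(m) diff(range(m)))
    frac_amp[c_i] <- mean(per_ep_max > amp_thresh)
    frac_flat[c_i] <- mean(per_ep_ptp < flat_thresh)
  }
  bad_ab <- frac_amp > 0.2 | frac_flat > 0.2
  # neighbor-deviation rule, with neighbors drawn from channels that passed
  # the amplitude/flat rules so one loud channel cannot implicate its
  # whole neighborhood
  dmat <- as.matrix(stats::dist(ep$layout$positions))
  diag(dmat) <- Inf
  dmat[, bad_ab] <- Inf
  dev <- numeric(nc)
  for (c_i in seq_len(nc)) {
    nb <- order(dmat[c_i, ])[1:4]
    nb_mean <- apply(ep$epochs[nb, , , drop = FALSE], c(2L, 3L), mean)
    dev[c_i] <- stats::median(sqrt(apply(
      (ep$epochs[c_i, , ] - nb_mean)^2, 2L, mean)))
  }
  dev_ok <- dev[!bad_ab]
  mad_dev <- stats::mad(dev_ok)
  z_dev <- if (mad_dev > 0) {
    (dev - stats::median(dev_ok)) / mad_dev
  } else {
    rep(0, nc)
  }
  bad <- bad_ab | z_dev > neighbor_z
  if (mean(bad) > 0.25) stop_quality("more than 25% of channels flagged bad")
  if (any(bad)) {
    d <- as.matrix(stats::dist(ep$layout$positions))
    good <- which(!bad)
    for (c_i in which(bad)) {
      ord <- good[order(d[c_i, good])][1:4]
      w <- 1 / d[c_i, ord]
      w <- w / sum(w)
      interp <- apply(ep$epochs[ord, , , drop = FALSE], c(2L, 3L),
                      function(v) sum(v * w))
      ep$epochs[c_i, , ] <- interp
    }
  }
  ep$bad_channels <- ep$layout$channel_names[bad]
  ep
}

#' Reject epochs with residual amplitude artifacts
#'
#' Marks `kept = FALSE` for every epoch containing any sample with
#' `|v| > amp_thresh` (applied after channel repair).  Kept epochs are
#' unchanged.
#'
#' @param ep an `epoch_set`.
#' @param amp_thresh rejection threshold in microvolts (default 100).
#' @return the `epoch_set` with an updated `kept` mask.
#' @export
reject_epochs <- function(ep, amp_thresh = 100) {
  if (amp_thresh <= 0) stop_invalid("amp_thresh must be > 0")
  n_ep <- dim(ep$epochs)[3L]
  if (n_ep == 0L) return(ep)
  over <- apply(abs(ep$epochs), 3L, max) > amp_thresh
  ep$kept <- ep$kept & !over
  if (!any(ep$kept)) stop_quality("all epochs rejected")
  ep
}

#' Re-reference every epoch to the whole-head average
#'
#' After re-referencing, the channel mean at every sample is zero (a
#' prerequisite for topographic analysis).  Idempotent.
#'
#' @param ep an `epoch_set` (>= 2 channels).
#' @return the re-referenced `epoch_set`.
#' @export
average_reference <- function(ep) {
  if (dim(ep$epochs)[1L] < 2L) stop_invalid("need >= 2 channels")
  mu <- apply(ep$epochs, c(2L, 3L), mean)
  ep$epochs <- sweep(ep$epochs, c(2L, 3L), mu, "-")
  ep
}

#' Standard preprocessing chain
#'
#' filter -> resample -> epoch -> repair -> reject -> average reference,
#' with the module defaults.
#'
#' @param rec an `eeg_recording`.
#' @param band pass band in Hz.
#' @param notch stop band in Hz or NULL.
#' @param target_sfreq output sampling rate.
#' @param epoch_s epoch length in seconds.
#' @param amp_thresh amplitude criterion (uV).
#' @param flat_thresh flat-line criterion (uV peak-to-peak).
#' @param neighbor_z neighbor-deviation robust z threshold.
#' @return a clean, average-referenced `epoch_set`.
#' @export
preprocess <- function(rec, band = c(0.1, 40), notch = c(48, 52),
                       target_sfreq = 500, epoch_s = 2, amp_thresh = 100,
                       flat_thresh = 0.1, neighbor_z = 4) {
  rec <- apply_filters(rec, band = band, notch = notch)
  if (target_sfreq < rec$sfreq) rec <- resample_recording(rec, target_sfreq)
  ep <- make_epochs(rec, epoch_s)
  ep <- repair_bad_channels(ep, amp_thresh, flat_thresh, neighbor_z)
  ep <- reject_epochs(ep, amp_thresh)
  average_reference(ep)
}

#' Remove externally computed ICA components
#'
#' The package never computes an ICA itself; this hook accepts a
#' precomputed unmixing matrix and a component-exclusion list (at most
#' five components by the usual curation convention) and reconstructs the
#' recording without the excluded components.
#'
#' @param rec an `eeg_recording`.
#' @param unmixing n_components x n_channels unmixing matrix `W` (sources
#'   = `W %*% data`).
#' @param exclude integer indices of components to remove.
#' @return the reconstructed `eeg_recording`.
#' @export
remove_components <- function(rec, unmixing, exclude) {
  if (!is.matrix(unmixing) || ncol(unmixing) != nrow(rec$data)) {
    stop_invalid("unmixing matrix does not match channel count")
  }
  if (!length(exclude)) return(rec)
  if (any(exclude < 1 | exclude > nrow(unmixing))) {
    stop_invalid("component index out of range")
  }
  sources <- unmixing %*% rec$data
  mixing <- if (nrow(unmixing) == ncol(unmixing)) {
    solve(unmixing)
  } else {
    .pinv(unmixing)
  }
  keep <- setdiff(seq_len(nrow(unmixing)), exclude)
  cleaned <- mixing[, keep, drop = FALSE] %*% sources[keep, , drop = FALSE]
  rownames(cleaned) <- rownames(rec$data)
  rec$data <- cleaned
  rec
}

# Moore-Penrose pseudoinverse via SVD (rectangular unmixing matrices)
.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1L]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Keep only retained epochs
#'
#' @param ep an `epoch_set`.
#' @return the `epoch_set` restricted to `kept` epochs (mask reset to TRUE).
#' @export
kept_epochs <- function(ep) {
  ep$epochs <- ep$epochs[, , ep$kept, drop = FALSE]
  ep$kept <- rep(TRUE, dim(ep$epochs)[3L])
  ep
}
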