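# Shared fixtures, built in code.

# small standard scene: layout + templates + dynamics
tiny_scene <- function(n_channels = 19, k = 4, seed = 1) {
  lay <- make_layout(n_channels)
  list(layout = lay,
       templates = make_templates(lay, k, seed = seed),
       dyn = dynamics_spec(k))
}

# synthesize, band-pass to the microstate band and epoch a recording
ms_epochs <- function(rec, epoch_s = 2) {
  rec <- apply_filters(rec, band = c(2, 20), notch = NULL)
  average_reference(make_epochs(rec, epoch_s))
}

# an epoch_set wrapping a given channel x sample matrix as one epoch
epochs_from_matrix <- function(x, sfreq = 100, layout = NULL) {
  if (is.null(layout)) layout <- make_layout(max(4, nrow(x)))
  layout$channel_names <- layout$channel_names[seq_len(nrow(x))]
  layout$positions <- layout$positions[seq_len(nrow(x)), , drop = FALSE]
  ep <- array(x, dim = c(nrow(x), ncol(x), 1L))
  structure(list(epochs = ep, sfreq = sfreq, layout = layout,
                 kept = TRUE, bad_channels = character(0)),
            class = "epoch_set")
}

# a label_sequence built directly from integer labels (single epoch unless
# epoch_index given)
labels_from_vector <- function(labels, sfreq = 100, epoch_index = NULL) {
  structure(list(labels = as.integer(labels),
                 epoch_index = epoch_index %||% rep(1L, length(labels)),
                 sample_index = seq_along(labels), sfreq = sfreq),
            class = "label_sequence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive-best 2-partition GEV of a set of maps: for every nonempty
# proper subset, the optimal cluster template is the first principal axis,
# whose explained sum of squares is the top eigenvalue of the cluster
# scatter matrix
brute_force_gev_k2 <- function(maps) {
  maps <- maps - rowMeans(maps)
  n <- nrow(maps)
  total <- sum(maps^2)
  top_eig <- function(idx) {
    s <- crossprod(maps[idx, , drop = FALSE])
    max(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  }
  best <- -Inf
  for (mask in 1:(2^n - 2)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    gev <- (top_eig(idx) + top_eig(setdiff(seq_len(n), idx))) / total
    if (gev > best) best <- gev
  }
  best
}
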