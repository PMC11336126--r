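# Template alignment, group averaging, and canonical A-D labeling.

# all permutations of 1..k (k <= 8)
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  r <- 0L
  for (pos in seq_len(k)) {
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- integer(k)
      row[pos] <- k
      row[-pos] <- sub[i, ]
      out[r, ] <- row
    }
  }
  out
}

# permutation of rows of `maps` maximizing total |corr| with `ref` rows;
# exhaustive for k <= 8
.best_permutation <- function(maps, ref) {
  k <- nrow(ref)
  corr <- abs(unit_norm(demean_map(maps)) %*% t(unit_norm(demean_map(ref))))
  if (k <= 8L) {
    perms <- .permutations(k)
    scores <- apply(perms, 1L, function(p) sum(corr[cbind(p, seq_len(k))]))
    perms[which.max(scores), ]
  } else {
    # greedy fallback for unusually large k
    p <- integer(k)
    avail <- seq_len(k)
    for (j in order(apply(corr, 2L, max), decreasing = TRUE)) {
      best <- avail[which.max(corr[avail, j])]
      p[j] <- best
      avail <- setdiff(avail, best)
    }
    p
  }
}

#' Built-in canonical microstate maps A-D for a layout
#'
#' Idealized gradients used only to assign canonical class labels: A and B
#' are the two diagonal left/right-frontal-to-posterior gradients, C the
#' anterior-posterior gradient, D the central-peaked radial map.  For
#' k > 4, additional classes keep generic labels.
#'
#' @param layout an `eeg_layout`.
#' @param k number of canonical maps (<= 4 meaningful).
#' @return a `template_set`.
#' @export
canonical_templates <- function(layout, k = 4L) {
  p <- layout$positions
  base <- rbind(A = p[, 1] + p[, 2],
                B = -p[, 1] + p[, 2],
                C = p[, 2],
                D = p[, 3])
  k_use <- min(k, 4L)
  template_set(base[seq_len(k_use), , drop = FALSE],
               class_labels = LETTERS[seq_len(k_use)])
}

#' Align individual template sets and average them into group templates
#'
#' Each subject's set is matched to the reference (or, when `reference` is
#' NULL, to the running average) by the one-to-one assignment maximizing
#' total polarity-invariant spatial correlation (exhaustive over
#' permutations for k <= 8); signs are aligned to the reference before
#' averaging; the result is re-normalized.  When `layout` is supplied the
#' averaged maps are reordered and labeled A-D by matching against
#' [canonical_templates()].
#'
#' @param individual list of `template_set`s sharing k and channel count.
#' @param reference optional `template_set` to align to.
#' @param layout optional `eeg_layout` for canonical A-D ordering.
#' @return the averaged `template_set`.
#' @export
align_and_average_templates <- function(individual, reference = NULL,
                                        layout = NULL) {
  if (!length(individual)) stop_invalid("empty template list")
  k <- nrow(individual[[1L]]$maps)
  C <- ncol(individual[[1L]]$maps)
  for (ts in individual) {
    if (nrow(ts$maps) != k || ncol(ts$maps) != C) stop_invalid("k mismatch")
  }
  ref <- if (!is.null(reference)) {
    unit_norm(demean_map(reference$maps))
  } else {
    unit_norm(demean_map(individual[[1L]]$maps))
  }
  acc <- matrix(0, k, C)
  n_acc <- 0L
  for (ts in individual) {
    m <- unit_norm(demean_map(ts$maps))
    perm <- .best_permutation(m, ref)
    m <- m[perm, , drop = FALSE]
    sgn <- sign(rowSums(m * ref))
    sgn[sgn == 0] <- 1
    acc <- acc + m * sgn
    n_acc <- n_acc + 1L
    if (is.null(reference)) ref <- unit_norm(demean_map(acc / n_acc))
  }
  avg <- unit_norm(demean_map(acc / n_acc))
  labels <- sprintf("C%d", seq_len(k))
  if (!is.null(layout)) {
    can <- canonical_templates(layout, k)
    kc <- nrow(can$maps)
    if (kc == k) {
      perm <- .best_permutation(avg, can$maps)
      avg <- avg[perm, , drop = FALSE]
      labels <- can$class_labels
    } else {
      # label the best-matching kc maps canonically, keep the rest generic
      labels <- sprintf("X%d", seq_len(k))
    }
  }
  colnames(avg) <- colnames(individual[[1L]]$maps)
  template_set(avg, class_labels = labels)
}
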