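# The analytic core: global field power, GFP-peak topographies,
# polarity-invariant atomize-agglomerate hierarchical clustering (AAHC),
# global explained variance (GEV) and model-order selection.
#
# Conventions: topographic "maps" are average-referenced channel vectors;
# peak-map matrices hold one map per row.  For an average-referenced map m
# over C channels, GFP = ||m|| / sqrt(C), and the Pearson spatial
# correlation between unit-normalized zero-mean maps is their dot product.
# Hence the GEV contribution of a cluster with scatter matrix
# S = sum_i m_i m_i^T is lambda_1(S) / C, maximized exactly by the first
# principal axis — the polarity-proof centroid used throughout.

#' Global field power of an epoch set
#'
#' GFP(t) is the spatial standard deviation of the scalp potential at one
#' time point: `sqrt(mean((v - mean(v))^2))` across channels.  For
#' average-referenced data the channel mean is zero.
#'
#' @param ep an `epoch_set` (average-referenced; only kept epochs are used).
#' @return a `gfp_series`: list with `values` (uV, one per sample of every
#'   kept epoch, concatenated), `epoch_index`, `sample_index` (within
#'   epoch), and `sfreq`.
#' @export
compute_gfp <- function(ep) {
  ep <- kept_epochs(ep)
  dims <- dim(ep$epochs)
  n_ep <- dims[3L]
  vals <- vector("list", n_ep)
  for (e in seq_len(n_ep)) {
    x <- ep$epochs[, , e]
    x <- sweep(x, 2L, colMeans(x), "-")
    vals[[e]] <- sqrt(colMeans(x^2))
  }
  structure(list(values = unlist(vals),
                 epoch_index = rep(seq_len(n_ep), each = dims[2L]),
                 sample_index = rep(seq_len(dims[2L]), n_ep),
                 sfreq = ep$sfreq),
            class = "gfp_series")
}

#' Extract topographies at GFP peaks
#'
#' Peaks are strict local maxima of the GFP within each epoch (epoch-edge
#' samples are never peaks).  When two peaks fall closer than
#' `min_separation` samples, the one with larger GFP is kept.
#'
#' @param ep an `epoch_set` (average-referenced, band-passed upstream —
#'   conventionally 2-20 Hz for microstate analysis).
#' @param min_separation minimum peak spacing in samples (0 disables).
#' @param gfp optionally a precomputed `gfp_series` for `ep`.
#' @return a `peak_maps` object: `maps` (n_peaks x n_channels,
#'   average-referenced uV), `peak_gfp`, `epoch`, `sample`.
#' @export
find_gfp_peaks <- function(ep, min_separation = 0L, gfp = NULL) {
  ep <- kept_epochs(ep)
  if (is.null(gfp)) gfp <- compute_gfp(ep)
  dims <- dim(ep$epochs)
  keep_e <- integer(0); keep_s <- integer(0); keep_g <- numeric(0)
  for (e in seq_len(dims[3L])) {
    v <- gfp$values[gfp$epoch_index == e]
    n <- length(v)
    if (n < 3L) next
    i <- 2:(n - 1L)
    pk <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
    if (min_separation > 0L && length(pk) > 1L) {
      ord <- pk[order(v[pk], decreasing = TRUE)]
      chosen <- integer(0)
      for (p in ord) {
        if (!length(chosen) || all(abs(chosen - p) >= min_separation)) {
          chosen <- c(chosen, p)
        }
      }
      pk <- sort(chosen)
    }
    keep_e <- c(keep_e, rep(e, length(pk)))
    keep_s <- c(keep_s, pk)
    keep_g <- c(keep_g, v[pk])
  }
  if (!length(keep_s)) stop_quality("no GFP peaks found")
  maps <- matrix(NA_real_, length(keep_s), dims[1L])
  for (j in seq_along(keep_s)) {
    m <- ep$epochs[, keep_s[j], keep_e[j]]
    maps[j, ] <- m - mean(m)
  }
  colnames(maps) <- dimnames(ep$epochs)[[1L]]
  structure(list(maps = maps, peak_gfp = keep_g,
                 epoch = keep_e, sample = keep_s),
            class = "peak_maps")
}

#' Spatial correlation between two topographic maps
#'
#' Pearson correlation across channels; with `polarity_invariant = TRUE`
#' (the microstate convention) the absolute value is returned, treating a
#' map and its sign-reversed counterpart as the same state.
#'
#' @param a,b channel vectors of equal length.
#' @param polarity_invariant take the absolute value (default TRUE).
#' @return correlation in \[-1, 1\] (or \[0, 1\] when invariant).
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  if (length(a) != length(b)) stop_invalid("maps differ in length")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) {
    stop("undefined-correlation: zero-variance map", call. = FALSE)
  }
  r <- sum(a * b) / (na * nb)
  if (polarity_invariant) abs(r) else r
}

# --- AAHC -------------------------------------------------------------

#' Atomize-agglomerate hierarchical clustering of peak topographies
#'
#' Bottom-up polarity-invariant clustering: every peak map starts as a
#' singleton cluster; at each step the cluster with the lowest GEV
#' contribution is atomized and each freed map is reassigned to the
#' surviving cluster whose centroid it correlates with most strongly
#' (absolute spatial correlation; centroids are held fixed during the
#' round, then recomputed for clusters that gained members).  Centroids are
#' the GFP-weighted first principal axis of the member maps — the exact
#' maximizer of the cluster's GEV contribution, immune to polarity flips.
#' A template set and the total GEV are recorded at every k from `k_max`
#' down to `k_min`.
#'
#' Tie rules (making the result deterministic given input order): equal
#' GEV contribution — atomize the cluster with fewer members, then the
#' lowest index; equal correlation on reassignment — the lowest cluster
#' index.
#'
#' @param p a `peak_maps` object or a plain n x C matrix of
#'   average-referenced maps.
#' @param k_min,k_max range of cluster counts to record (2 <= k_min <=
#'   k_max <= n_peaks).
#' @return a `clustering_result`: list with `k_range` and, per recorded k,
#'   `sets[[as.character(k)]]` holding `templates` (a `template_set`),
#'   `assignment` (cluster id 1..k per input map) and `gev`.
#' @export
aahc_cluster <- function(p, k_min = 2L, k_max = 8L) {
  maps <- if (inherits(p, "peak_maps")) p$maps else p
  n <- nrow(maps); C <- ncol(maps)
  if (k_min < 2L || k_max < k_min) stop_invalid("need 2 <= k_min <= k_max")
  if (n < k_max) stop_invalid("need at least k_max peak maps")
  maps <- demean_map(maps)
  norms <- sqrt(rowSums(maps^2))
  if (any(norms < 1e-12)) stop_invalid("zero-variance peak map")
  total_ss <- sum(norms^2)

  unit_maps <- maps / norms
  first <- unit_maps[1L, ]
  if (all(abs(unit_maps %*% first) > 1 - 1e-9)) {
    warning("all peak maps identical up to sign; returning k = 1 result")
    return(structure(list(k_range = 1L,
                          sets = list(`1` = list(
                            templates = structure(
                              list(maps = matrix(first, 1L, C),
                                   class_labels = "C1"),
                              class = "template_set"),
                            assignment = rep(1L, n), gev = 1))),
                     class = "clustering_result"))
  }

  members <- as.list(seq_len(n))
  scatter <- vector("list", n)
  centroid <- matrix(NA_real_, n, C)
  contrib <- numeric(n)
  for (i in seq_len(n)) {
    scatter[[i]] <- tcrossprod(maps[i, ])
    centroid[i, ] <- unit_maps[i, ]
    contrib[i] <- norms[i]^2
  }
  alive <- rep(TRUE, n)
  n_alive <- n
  sets <- list()

  snapshot <- function() {
    idx <- which(alive)
    k <- length(idx)
    tm <- centroid[idx, , drop = FALSE]
    colnames(tm) <- colnames(maps)
    assignment <- integer(n)
    for (j in seq_along(idx)) assignment[members[[idx[j]]]] <- j
    list(templates = structure(list(maps = tm,
                                    class_labels = sprintf("C%d", seq_len(k))),
                               class = "template_set"),
         assignment = assignment,
         gev = sum(contrib[idx]) / total_ss)
  }

  while (n_alive > k_min) {
    if (n_alive <= k_max) sets[[as.character(n_alive)]] <- snapshot()
    idx <- which(alive)
    # victim: lowest contribution; ties -> fewer members -> lowest index
    sizes <- lengths(members[idx])
    ord <- order(contrib[idx], sizes, idx)
    victim <- idx[ord[1L]]
    freed <- sort(members[[victim]])
    alive[victim] <- FALSE
    n_alive <- n_alive - 1L
    surv <- which(alive)
    # assign freed maps against centroids frozen for the round
    cm <- centroid[surv, , drop = FALSE]
    corr <- abs(cm %*% t(unit_maps[freed, , drop = FALSE]))  # n_surv x n_freed
    dest <- surv[apply(corr, 2L, which.max)]
    changed <- unique(dest)
    for (j in seq_along(freed)) {
      members[[dest[j]]] <- c(members[[dest[j]]], freed[j])
      scatter[[dest[j]]] <- scatter[[dest[j]]] + tcrossprod(maps[freed[j], ])
    }
    for (cl in changed) {
      eg <- eigen(scatter[[cl]], symmetric = TRUE)
      v <- eg$vectors[, 1L]
      v <- v - mean(v)
      centroid[cl, ] <- v / sqrt(sum(v^2))
      contrib[cl] <- eg$values[1L]
    }
  }
  sets[[as.character(k_min)]] <- snapshot()
  structure(list(k_range = sort(as.integer(names(sets))), sets = sets),
            class = "clustering_result")
}

#' Global explained variance of a labeling
#'
#' `GEV = sum_t (GFP_t * corr(v_t, T_label(t)))^2 / sum_t GFP_t^2`, the
#' fraction of GFP-weighted topographic variance explained by assigning
#' each map (or sample) to its labeled template.
#'
#' @param maps n x C matrix of average-referenced maps.
#' @param gfp GFP value per map (uV).
#' @param templates a `template_set`.
#' @param labels integer template index per map.
#' @return a fraction in \[0, 1\].
#' @export
compute_gev <- function(maps, gfp, templates, labels) {
  maps <- demean_map(maps)
  norms <- sqrt(rowSums(maps^2))
  denom <- sum(gfp^2)
  if (denom <= 0) stop("undefined: all-zero GFP", call. = FALSE)
  ok <- norms > 1e-12
  tm <- unit_norm(demean_map(templates$maps))
  corr <- rowSums(maps[ok, , drop = FALSE] * tm[labels[ok], , drop = FALSE]) /
    norms[ok]
  sum((gfp[ok] * corr)^2) / denom
}

#' Select the number of microstate classes
#'
#' Incremental-gain stopping rule: the smallest recorded k whose GEV gain
#' to k + 1 falls below `gev_gain_threshold`; if the gain never drops below
#' the threshold, `k_max` is returned.  `force_k` pins the answer (the
#' conventional choice in the literature is 4).
#'
#' @param cr a `clustering_result`.
#' @param gev_gain_threshold minimal incremental GEV gain (default 0.01).
#' @param force_k optional override.
#' @return the selected k.
#' @export
select_k <- function(cr, gev_gain_threshold = 0.01, force_k = NULL) {
  ks <- cr$k_range
  if (!is.null(force_k)) {
    if (!force_k %in% ks) stop_invalid("force_k outside clustered range")
    return(as.integer(force_k))
  }
  if (length(ks) == 1L) return(ks)
  gev <- vapply(as.character(ks), function(k) cr$sets[[k]]$gev, numeric(1))
  for (i in seq_len(length(ks) - 1L)) {
    if (gev[i + 1L] - gev[i] < gev_gain_threshold) return(ks[i])
  }
  ks[length(ks)]
}

#' GFP-peak extraction, AAHC and model-order selection in one call
#'
#' Convenience wrapper used per subject: band-passed, average-referenced
#' epochs in, selected template set out.  When a subject yields more than
#' `max_peaks` GFP peaks, a random subsample (deterministic given `seed`)
#' is clustered — standard practice keeping AAHC cost bounded.
#'
#' @param ep an `epoch_set` (2-20 Hz band, average-referenced).
#' @param k_min,k_max candidate range of cluster counts.
#' @param gev_gain_threshold stopping threshold for [select_k()].
#' @param force_k optional fixed k.
#' @param max_peaks cap on peak maps entering AAHC (default 1000).
#' @param min_separation peak spacing in samples.
#' @param seed seed for the peak subsample.
#' @return list with `peaks`, `clustering`, `k`, and `templates` (the
#'   `template_set` at the selected k).
#' @export
run_microstate_analysis <- function(ep, k_min = 2L, k_max = 8L,
                                    gev_gain_threshold = 0.01,
                                    force_k = NULL, max_peaks = 1000L,
                                    min_separation = 0L, seed = 1L) {
  pk <- find_gfp_peaks(ep, min_separation = min_separation)
  if (nrow(pk$maps) > max_peaks) {
    sel <- sort(with_seed(seed, sample.int(nrow(pk$maps), max_peaks)))
    pk <- structure(list(maps = pk$maps[sel, , drop = FALSE],
                         peak_gfp = pk$peak_gfp[sel],
                         epoch = pk$epoch[sel], sample = pk$sample[sel]),
                    class = "peak_maps")
  }
  cr <- aahc_cluster(pk, k_min = k_min, k_max = min(k_max, nrow(pk$maps)))
  k <- select_k(cr, gev_gain_threshold, force_k)
  list(peaks = pk, clustering = cr, k = k,
       templates = cr$sets[[as.character(k)]]$templates)
}
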