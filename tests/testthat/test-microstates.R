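test_that("GFP matches its defining formula", {
  ep <- epochs_from_matrix(rbind(c(1, 0, 2), c(-1, 0, -2)))
  g <- compute_gfp(ep)
  expect_equal(g$values, c(1, 0, 2))          # 2 channels at +-v -> GFP |v|

  set.seed(4)
  x <- matrix(rnorm(6 * 20), 6)
  x <- sweep(x, 2, colMeans(x), "-")
  g2 <- compute_gfp(epochs_from_matrix(x))
  oracle <- apply(x, 2, function(v) sqrt(sum((v - mean(v))^2) / length(v)))
  expect_equal(g2$values, oracle, tolerance = 1e-12)
})

test_that("GFP peaks are strict interior local maxima with separation rule", {
  v <- c(1, 3, 2, 5, 4)
  ep <- epochs_from_matrix(rbind(v, -v))
  pk <- find_gfp_peaks(ep)
  expect_equal(pk$sample, c(2L, 4L))
  expect_equal(pk$peak_gfp, c(3, 5))

  mono <- epochs_from_matrix(rbind(1:6, -(1:6)))
  expect_error(find_gfp_peaks(mono), "data-quality")   # no interior maxima

  # separation: two close peaks -> keep the larger
  v2 <- c(1, 5, 1, 4, 1, 1, 1, 6, 1)
  pk2 <- find_gfp_peaks(epochs_from_matrix(rbind(v2, -v2)), min_separation = 3)
  expect_equal(pk2$sample, c(2L, 8L))
})

test_that("a 10 Hz carrier yields about 20 GFP envelope peaks per second", {
  sc <- tiny_scene(19, 4, seed = 6)
  ls <- simulate_labels(sc$dyn, 2 * 500, 500, seed = 6)
  rec <- synthesize_recording(sc$templates, ls, snr = 1e6, sfreq = 500,
                              seed = 6, layout = sc$layout)
  ep <- average_reference(make_epochs(rec, 2))
  pk <- find_gfp_peaks(ep)
  expect_gt(nrow(pk$maps), 34)
  expect_lt(nrow(pk$maps), 46)
})

test_that("spatial correlation is polarity-invariant on request", {
  a <- c(1, -1, 2, -2); b <- -a
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, b, polarity_invariant = TRUE), 1)
  expect_equal(spatial_correlation(a, b, polarity_invariant = FALSE), -1)
  orth <- c(1, 1, -1, -1)
  expect_lt(abs(spatial_correlation(a, orth)), 1e-9)
  expect_error(spatial_correlation(a, rep(0, 4)), "undefined-correlation")
})

test_that("AAHC reproduces exact mixtures and matches the brute-force partition oracle", {
  lay <- make_layout(12)
  tm <- make_templates(lay, 2, seed = 3)
  scales <- c(3, 5, 2, 7, 4, 6)
  maps <- do.call(rbind, lapply(scales, function(s)
    tm$maps[1 + (s %% 2), ] * s))
  cr <- aahc_cluster(maps, k_min = 2, k_max = 2)
  res <- cr$sets[["2"]]
  expect_equal(res$gev, 1, tolerance = 1e-9)
  match_corr <- abs(res$templates$maps %*% t(tm$maps))
  expect_equal(sort(apply(match_corr, 1, max)), c(1, 1), tolerance = 1e-9)

  # 8 noisy maps from the 2 templates: AAHC equals exhaustive best 2-partition
  set.seed(11)
  noisy <- do.call(rbind, lapply(1:8, function(i) {
    base <- tm$maps[1 + i %% 2, ] * runif(1, 2, 6)
    base + rnorm(12, sd = 0.2)
  }))
  cr2 <- aahc_cluster(noisy, k_min = 2, k_max = 2)
  expect_equal(cr2$sets[["2"]]$gev, brute_force_gev_k2(noisy),
               tolerance = 1e-6)
})

test_that("sign-flipping any subset of maps leaves AAHC results unchanged", {
  lay <- make_layout(10)
  tm <- make_templates(lay, 3, seed = 8)
  set.seed(12)
  maps <- do.call(rbind, lapply(1:30, function(i)
    tm$maps[1 + i %% 3, ] * runif(1, 1, 5) + rnorm(10, sd = 0.1)))
  flipped <- maps
  flip <- c(2, 5, 7, 11, 20, 28)
  flipped[flip, ] <- -flipped[flip, ]
  cr_a <- aahc_cluster(maps, 2, 4)
  cr_b <- aahc_cluster(flipped, 2, 4)
  for (k in as.character(2:4)) {
    expect_equal(cr_a$sets[[k]]$gev, cr_b$sets[[k]]$gev, tolerance = 1e-9)
    expect_equal(abs(cr_a$sets[[k]]$templates$maps %*%
                       t(cr_b$sets[[k]]$templates$maps)) |> diag(),
                 rep(1, as.integer(k)), tolerance = 1e-9)
    expect_identical(cr_a$sets[[k]]$assignment, cr_b$sets[[k]]$assignment)
  }
})

test_that("GEV is 1 for exact template data, near 0 for orthogonal templates, and non-decreasing in k", {
  lay <- make_layout(16)
  tm <- make_templates(lay, 3, seed = 2)
  maps <- tm$maps[c(1, 2, 3, 1, 2), ] * c(2, 3, 4, 5, 6)
  gfp <- sqrt(rowSums(maps^2) / 16)
  expect_equal(compute_gev(maps, gfp, tm, c(1, 2, 3, 1, 2)), 1,
               tolerance = 1e-9)

  # orthogonalize templates against the data rows -> explained variance ~ 0
  q <- qr.Q(qr(t(rbind(maps, rep(1, 16)))))
  null_dirs <- diag(16) - q %*% t(q)
  tm_orth <- template_set(null_dirs[1:3, ])
  expect_lt(compute_gev(maps, gfp, tm_orth, c(1, 2, 3, 1, 2)), 1e-9)

  sc <- tiny_scene(19, 4, seed = 13)
  ls <- simulate_labels(sc$dyn, 20 * 500, 500, seed = 13)
  rec <- synthesize_recording(sc$templates, ls, snr = 5, sfreq = 500,
                              seed = 13, layout = sc$layout)
  ep <- ms_epochs(rec)
  cr <- aahc_cluster(find_gfp_peaks(ep), 2, 6)
  gev <- vapply(as.character(2:6), function(k) cr$sets[[k]]$gev, numeric(1))
  expect_true(all(diff(gev) > -1e-6))
})

test_that("k selection applies the incremental-gain stopping rule", {
  fake <- structure(list(
    k_range = 2:5,
    sets = list(`2` = list(gev = 0.50), `3` = list(gev = 0.70),
                `4` = list(gev = 0.71), `5` = list(gev = 0.72))),
    class = "clustering_result")
  expect_equal(select_k(fake, 0.02), 3)

  linear <- structure(list(
    k_range = 2:5,
    sets = list(`2` = list(gev = 0.5), `3` = list(gev = 0.55),
                `4` = list(gev = 0.6), `5` = list(gev = 0.65))),
    class = "clustering_result")
  expect_equal(select_k(linear, 0.01), 5)
  expect_equal(select_k(linear, 0.01, force_k = 4), 4)
  single <- structure(list(k_range = 3L, sets = list(`3` = list(gev = 0.8))),
                      class = "clustering_result")
  expect_equal(select_k(single), 3L)
})

test_that("template alignment matches permutations, ignores sign flips, and averages exactly", {
  lay <- make_layout(24)
  ref <- make_templates(lay, 3, seed = 21)
  perms <- list(c(2, 3, 1), c(3, 1, 2), c(1, 3, 2))
  subs <- lapply(perms, function(p) template_set(ref$maps[p, ]))
  avg <- align_and_average_templates(subs, reference = ref)
  expect_equal(abs(diag(avg$maps %*% t(ref$maps))), rep(1, 3),
               tolerance = 1e-9)

  subs_flip <- subs
  subs_flip[[2]]$maps <- -subs_flip[[2]]$maps
  avg_flip <- align_and_average_templates(subs_flip, reference = ref)
  expect_equal(abs(diag(avg_flip$maps %*% t(ref$maps))), rep(1, 3),
               tolerance = 1e-9)

  # noisy sets: recovered average stays close to the generating set
  set.seed(30)
  noisy <- lapply(1:3, function(i) {
    p <- sample(3)
    template_set((ref$maps + matrix(rnorm(3 * 24, sd = 0.05), 3))[p, ])
  })
  avg_n <- align_and_average_templates(noisy, reference = ref)
  expect_true(all(abs(diag(avg_n$maps %*% t(ref$maps))) > 0.98))

  expect_error(align_and_average_templates(list(ref, template_set(ref$maps[1:2, ]))),
               "invalid-argument")
})

test_that("canonical labeling orders averaged templates A-D", {
  lay <- make_layout(32)
  can <- canonical_templates(lay, 4)
  shuffled <- template_set(can$maps[c(3, 1, 4, 2), ])
  avg <- align_and_average_templates(list(shuffled, shuffled), layout = lay)
  expect_identical(avg$class_labels, c("A", "B", "C", "D"))
  expect_equal(unname(abs(diag(avg$maps %*% t(can$maps)))), rep(1, 4),
               tolerance = 1e-9)
})

test_that("backfitting is scale- and polarity-invariant with zero-variance carry-forward", {
  lay <- make_layout(12)
  tm <- make_templates(lay, 4, seed = 5)
  x <- cbind(3.7 * tm$maps[2, ], -tm$maps[3, ], 0 * tm$maps[1, ],
             2 * tm$maps[1, ])
  ep <- epochs_from_matrix(x, layout = lay)
  fit <- backfit(ep, tm)
  expect_equal(fit$labels, c(2L, 3L, 3L, 1L))   # zero sample inherits previous

  ep0 <- epochs_from_matrix(cbind(0 * tm$maps[1, ], 5 * tm$maps[4, ]),
                            layout = lay)
  expect_equal(backfit(ep0, tm)$labels, c(4L, 4L))  # leading gap takes next
})

test_that("run segmentation respects epoch boundaries and truncation flags", {
  ls <- labels_from_vector(c(1, 1, 2, 2, 2, 1))
  rl <- segment_runs(ls)
  expect_equal(rl$class, c(1, 2, 1))
  expect_equal(rl$length, c(2, 3, 1))
  expect_equal(rl$trunc_start, c(TRUE, FALSE, FALSE))
  expect_equal(rl$trunc_end, c(FALSE, FALSE, TRUE))

  const <- segment_runs(labels_from_vector(rep(2, 10)))
  expect_equal(nrow(const), 1)
  expect_true(const$trunc_start && const$trunc_end)

  two_ep <- labels_from_vector(rep(1, 8), epoch_index = rep(1:2, each = 4))
  expect_equal(nrow(segment_runs(two_ep)), 2)   # A|A never merges
})

test_that("dynamics metrics match hand computation and the coverage identity", {
  ls <- labels_from_vector(c(1, 1, 1, 2, 2, 3, 3, 3, 3, 3), sfreq = 100)
  mm <- compute_metrics(segment_runs(ls), 100, 3)
  expect_equal(unname(mm$duration["A"]), 0.03)
  expect_equal(unname(mm$occurrence["A"]), 10)
  expect_equal(unname(mm$coverage["A"]), 0.3)
  expect_equal(mm$mean_duration, 0.1 / 3, tolerance = 1e-9)
  expect_equal(mm$mean_occurrence, 30)
  expect_equal(mm$total_time, 0.1)

  # class with zero runs: missing duration, zero occurrence
  mm4 <- compute_metrics(segment_runs(ls), 100, 4)
  expect_true(is.na(mm4$duration[4]))
  expect_equal(unname(mm4$occurrence[4]), 0)

  # identity & summation properties on simulated sequences
  for (s in 1:5) {
    sim <- simulate_labels(dynamics_spec(4), 5000, 500, seed = s)
    m <- compute_metrics(segment_runs(sim), 500, 4)
    expect_lt(max(abs(m$coverage - m$duration * m$occurrence)), 1e-9)
    expect_lt(abs(sum(m$coverage) - 1), 1e-9)
    expect_lt(abs(sum(m$occurrence) - m$mean_occurrence), 1e-9)
  }
})

test_that("transition probabilities are jointly normalized within epochs", {
  ls <- labels_from_vector(c(1, 1, 2, 3, 3, 1))
  tp <- transition_probabilities(segment_runs(ls), 3)
  expect_equal(tp["A", "B"], 1 / 3)
  expect_equal(tp["B", "C"], 1 / 3)
  expect_equal(tp["C", "A"], 1 / 3)
  expect_equal(sum(tp), 1)
  expect_true(all(diag(tp) == 0))

  sim <- simulate_labels(dynamics_spec(4), 800 * 500, 500, seed = 17)
  tp_u <- transition_probabilities(segment_runs(sim), 4)
  expect_lt(max(abs(tp_u[row(tp_u) != col(tp_u)] - 1 / 12)), 0.01)

  single <- segment_runs(labels_from_vector(rep(1, 5)))
  expect_true(all(is.na(transition_probabilities(single, 3))))
})
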