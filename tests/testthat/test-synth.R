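test_that("layout covers the scalp cap with unit-norm, distinct sensors", {
  lay <- make_layout(60)
  expect_length(lay$channel_names, 60)
  expect_false(anyDuplicated(lay$channel_names) > 0)
  expect_true(all(abs(sqrt(rowSums(lay$positions^2)) - 1) < 1e-9))
  expect_true(all(lay$positions[, "z"] >= -0.2))
  lay4 <- make_layout(4)
  expect_equal(nrow(unique(lay4$positions)), 4)
  expect_error(make_layout(2), "invalid-argument")
  expect_error(make_layout(500), "invalid-argument")
})

test_that("templates are average-referenced, unit-norm, distinguishable and seeded", {
  lay <- make_layout(32)
  t1 <- make_templates(lay, 4, seed = 1)
  t2 <- make_templates(lay, 4, seed = 1)
  expect_identical(t1$maps, t2$maps)
  expect_true(all(abs(rowSums(t1$maps)) < 1e-9))
  expect_true(all(abs(sqrt(rowSums(t1$maps^2)) - 1) < 1e-9))
  cors <- abs(t1$maps %*% t(t1$maps))
  expect_true(all(cors[upper.tri(cors)] < 0.8))
  t3 <- make_templates(lay, 4, seed = 2)
  cross <- abs(t1$maps %*% t(t3$maps))
  expect_true(any(cross < 0.99))
  expect_error(make_templates(lay, 32, seed = 1), "invalid-argument")
})

test_that("semi-Markov label sequences honor dwell law, support and seed", {
  dyn <- dynamics_spec(4, mean_dwell = 0.07)
  ls <- simulate_labels(dyn, 120 * 500, 500, seed = 7)
  runs <- rle(ls$labels)
  mean_ms <- mean(runs$lengths) / 500 * 1000
  expect_lt(abs(mean_ms - 70) / 70, 0.10)
  expect_true(all(diff(runs$values) != 0))

  w <- matrix(0, 4, 4)
  w[cbind(1:4, c(2, 3, 4, 1))] <- 1        # forced A->B->C->D->A cycle
  cyc <- simulate_labels(dynamics_spec(4, transition_weights = w),
                         20000, 500, seed = 3)
  rl <- segment_runs(cyc)
  tp <- transition_probabilities(rl, 4)
  observed <- which(tp > 0, arr.ind = TRUE)
  expect_true(all(observed[, 2] == (observed[, 1] %% 4) + 1))

  expect_identical(simulate_labels(dyn, 5000, 500, seed = 11)$labels,
                   simulate_labels(dyn, 5000, 500, seed = 11)$labels)
})

test_that("synthesized recordings reduce to the active template in the noise-free limit", {
  sc <- tiny_scene(19, 4, seed = 2)
  ls <- simulate_labels(sc$dyn, 10 * 500, 500, seed = 2)
  rec <- synthesize_recording(sc$templates, ls, snr = 1e6, sfreq = 500,
                              seed = 2, layout = sc$layout)
  ep <- average_reference(make_epochs(rec, 2))
  fit <- backfit(ep, sc$templates)
  expect_gte(mean(fit$labels == ls$labels), 0.99)

  maps <- t(rec$data)
  gfp <- sqrt(rowMeans((maps - rowMeans(maps))^2))
  gev <- compute_gev(maps, gfp, sc$templates, ls$labels)
  expect_gte(gev, 0.99)

  rec_b <- synthesize_recording(sc$templates, ls, snr = 1e6, sfreq = 500,
                                seed = 3, layout = sc$layout)
  expect_false(identical(rec$data, rec_b$data))   # fresh noise
  # identical envelope: the signal parts coincide, so the difference is
  # pure (tiny) noise
  expect_lt(max(abs(rec$data - rec_b$data)), 1e-3)
  rec_c <- synthesize_recording(sc$templates, ls, snr = 1e6, sfreq = 500,
                                seed = 2, layout = sc$layout)
  expect_identical(rec$data, rec_c$data)
})

test_that("cohorts have the configured size and realize planted correlations", {
  sc <- tiny_scene(19, 4, seed = 5)
  spec <- cohort_spec(n_per_group = c(AD = 56, HC = 38), duration_s = 20,
                      seed = 5)
  ch <- simulate_cohort(spec, sc$layout, sc$templates, sc$dyn)
  expect_equal(nrow(ch$covariates), 94)
  expect_equal(nrow(ch$metrics), 94)
  expect_true(all(c("subject", "group", "sex", "age", "education",
                    "mmse", "abeta42", "nfl") %in% names(ch$covariates)))

  spec60 <- cohort_spec(n_per_group = c(AD = 60, HC = 10),
                        planted_correlations = data.frame(
                          metric = "duration_C", covariate = "abeta42",
                          rho = -0.40),
                        duration_s = 30, seed = 8)
  ch60 <- simulate_cohort(spec60, sc$layout, sc$templates, sc$dyn)
  ad <- ch60$covariates$group == "AD"
  r <- cor(ch60$metrics$duration_C[ad], ch60$covariates$abeta42[ad])
  expect_lt(abs(r - (-0.40)), 0.2)
})

test_that("templates and dwell durations are recovered end-to-end at moderate noise", {
  lay <- make_layout(19)
  tm <- make_templates(lay, 4, seed = 4)
  ls <- simulate_labels(dynamics_spec(4), 60 * 500, 500, seed = 4)
  rec <- synthesize_recording(tm, ls, snr = 5, sfreq = 500, seed = 4,
                              layout = lay)
  ep_ms <- ms_epochs(rec)
  res <- run_microstate_analysis(ep_ms, seed = 4)
  expect_equal(res$k, 4L)
  # optimal matching: recovered templates vs ground truth
  match_corr <- apply(abs(res$templates$maps %*% t(tm$maps)), 2, max)
  expect_gte(mean(match_corr), 0.95)
  # duration recovery needs the minimum-segment option: isolated label
  # flips at GFP troughs otherwise shatter runs (see methods vignette)
  fit <- backfit(ep_ms, tm)
  fit <- microstatr:::smooth_labels(fit, 20)
  mm <- compute_metrics(segment_runs(fit), 500, 4)
  expect_lt(abs(mm$mean_duration - 0.07) / 0.07, 0.15)
})

test_that("cohort generation is a pure function of the spec seed", {
  sc <- tiny_scene(19, 4, seed = 1)
  spec <- cohort_spec(n_per_group = c(AD = 3, HC = 3), duration_s = 5,
                      seed = 4)
  a <- simulate_cohort(spec, sc$layout, sc$templates, sc$dyn)
  b <- simulate_cohort(spec, sc$layout, sc$templates, sc$dyn)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$covariates, b$covariates)
})
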