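test_that("Pearson chi-square on 2x2 tables matches theory and the stats oracle", {
  prop <- matrix(c(10, 20, 10, 20), 2)
  expect_equal(chi_square_2x2(prop)$chi2, 0)

  perfect <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(chi_square_2x2(perfect)$chi2, 10)

  set.seed(2)
  for (i in 1:5) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ours <- chi_square_2x2(tab)
    oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(ours$chi2, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(ours$p, oracle$p.value, tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "invalid-argument")
})

test_that("Benjamini-Hochberg adjustment matches the hand rule and p.adjust", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.37), 0.37)

  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    adj <- fdr_bh(p)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    perm <- sample(length(p))
    expect_equal(fdr_bh(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("group comparison gates on Shapiro normality and adjusts within families", {
  set.seed(9)
  n <- 40
  df <- data.frame(
    group = rep(c("AD", "HC"), each = n),
    normal_shift = c(rnorm(n, 1), rnorm(n, 0)),
    skewed_shift = c(rexp(n, 1 / 2), rexp(n, 1)),
    null_var = rnorm(2 * n))
  tab <- compare_groups(df, "group",
                        families = list(f1 = c("normal_shift", "skewed_shift"),
                                        f2 = "null_var"))
  expect_equal(tab$test[tab$variable == "normal_shift"], "t")
  expect_equal(tab$test[tab$variable == "skewed_shift"], "mann-whitney")
  # decisions reproducible from stored Shapiro p-values
  expect_true(all((tab$shapiro_p_1 > 0.05 & tab$shapiro_p_2 > 0.05) ==
                    (tab$test == "t")))
  # single-variable family: adjusted equals raw
  expect_equal(tab$p_fdr[tab$variable == "null_var"],
               tab$p_raw[tab$variable == "null_var"])
  expect_true(all(tab$p_fdr >= tab$p_raw - 1e-12))
  expect_lt(tab$p_fdr[tab$variable == "normal_shift"], 0.05)

  dfc <- df; dfc$constant <- 1
  expect_warning(compare_groups(dfc, "group",
                                families = list(a = c("normal_shift", "constant"))),
                 "constant")
})

test_that("a planted class-C dwell prolongation is detected in most cohorts", {
  lay <- make_layout(19)
  tm <- make_templates(lay, 4, seed = 1)
  dyn <- dynamics_spec(4)
  fams <- list(duration = paste0("duration_", c("A", "B", "C", "D")))
  res <- vapply(1:9, function(s) {
    ch <- simulate_cohort(cohort_spec(seed = s), lay, tm, dyn)
    tab <- compare_groups(ch$metrics, "group", fams)
    row <- tab[tab$variable == "duration_C", ]
    c(sig = row$p_raw < 0.05, dir = row$mean_1 > row$mean_2)
  }, numeric(2))
  expect_gte(mean(res["dir", ]), 0.5)   # AD duration_C longer
  expect_gte(mean(res["sig", ]), 0.5)   # and detected at raw alpha = 0.05
})

test_that("Mann-Whitney z reproduces the U statistic of the stats oracle", {
  set.seed(14)
  x <- rexp(25); y <- rexp(30, 0.7)
  ours <- microstatr:::.mann_whitney_z(x, y)
  oracle <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  expect_equal(ours$U, unname(oracle$statistic))
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-9)
})

test_that("partial rank correlation reduces to Spearman and detects exact relations", {
  set.seed(3)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  pr <- partial_rank_correlation(x, y)
  expect_equal(pr$rho, cor(x, y, method = "spearman"), tolerance = 1e-9)

  z <- matrix(rnorm(100), 50)
  expect_equal(partial_rank_correlation(x, x, z)$rho, 1, tolerance = 1e-9)

  set.seed(4)
  xx <- rnorm(1000); yy <- rnorm(1000); cc <- matrix(rnorm(3000), 1000)
  expect_lt(abs(partial_rank_correlation(xx, yy, cc)$rho), 0.08)

  expect_error(partial_rank_correlation(rnorm(4), rnorm(4), matrix(rnorm(12), 4)),
               "invalid-argument")
})

test_that("stepwise regression selects the true support and refuses collinear twins", {
  set.seed(1)
  n <- 80
  X <- as.data.frame(matrix(rnorm(n * 5), n))
  names(X) <- paste0("x", 1:5)
  y <- 2 * X$x1 + rnorm(n, sd = 0.1)
  fit <- stepwise_regression(y, X)
  expect_identical(fit$terms, "x1")
  expect_equal(fit$coefficients$estimate, 2, tolerance = 0.1)
  expect_true(fit$coefficients$ci_low < fit$coefficients$estimate &&
                fit$coefficients$estimate < fit$coefficients$ci_high)

  X2 <- X; X2$x1_copy <- X$x1
  fit2 <- stepwise_regression(y, X2)
  expect_false(all(c("x1", "x1_copy") %in% fit2$terms))

  # empty model when nothing passes entry
  fit3 <- stepwise_regression(rnorm(n), X["x1"], p_enter = 1e-6)
  expect_length(fit3$terms, 0)

  # the trace replays to the final model
  net <- character(0)
  for (i in seq_len(nrow(fit$trace))) {
    if (fit$trace$action[i] == "enter") net <- c(net, fit$trace$term[i])
    else net <- setdiff(net, fit$trace$term[i])
  }
  expect_identical(sort(net), sort(fit$terms))
})

test_that("stepwise backward removal drops terms that lose significance", {
  set.seed(33)
  n <- 120
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, sd = 0.4)   # proxy for x1, enters first alone
  y <- x1 + rnorm(n, sd = 0.3)
  fit <- stepwise_regression(y, data.frame(x1 = x1, x2 = x2))
  expect_true("x1" %in% fit$terms)
  # whatever the path, every retained term is significant at p_remove
  expect_true(all(fit$coefficients$p <= 0.10))
})
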