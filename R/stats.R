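# Group comparison, FDR control, covariate-adjusted partial rank
# correlation, and stepwise linear regression.

#' Pearson chi-square test on a 2x2 count table
#'
#' Pearson chi-square without continuity correction, df = 1, upper-tail p.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return list with `chi2`, `p`, `df`.
#' @export
chi_square_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L) || any(table < 0)) {
    stop_invalid("need a 2x2 nonnegative count table")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_invalid("zero margin")
  }
  n <- sum(table)
  chi2 <- n * (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])^2 /
    prod(rowSums(table), colSums(table))
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH: `p_(i) * m / i`, then a cumulative minimum from the largest
#' rank down, capped at 1.  Order-preserving and idempotent.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
fdr_bh <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop_invalid("p outside [0,1]")
  m <- length(pvals)
  if (m <= 1L) return(pvals)
  ord <- order(pvals)
  adj <- pvals[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# tie-corrected normal-approximation z for the Mann-Whitney U test
.mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(z = 0, p = 1, U = U))
  z <- (U - mu) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), U = U)
}

#' Two-group comparison battery with normality gating and FDR families
#'
#' For each variable: Shapiro-Wilk in both groups at alpha = 0.05; if both
#' normal, an equal-variance two-sample t-test, otherwise a Mann-Whitney U
#' test reported as a tie-corrected normal-approximation z.  Raw p-values
#' are two-sided; Benjamini-Hochberg adjustment is applied within each
#' declared family (e.g. durations, occurrences, coverages, transition
#' probabilities, global rows) — the family partition changes adjusted p
#' and is therefore recorded in the output.
#'
#' @param metrics data.frame with one row per subject.
#' @param grouping name of the two-level grouping column.
#' @param families named list mapping family label -> variable names;
#'   defaults to one family holding every numeric column.
#' @return a `stat_table` data.frame: variable, per-group mean and sd, test
#'   name, statistic, shapiro p per group, raw p, FDR-adjusted p, family.
#' @export
compare_groups <- function(metrics, grouping = "group", families = NULL) {
  g <- factor(metrics[[grouping]])
  if (nlevels(g) != 2L) stop_invalid("grouping must have exactly two levels")
  if (any(table(g) < 2L)) stop_invalid("need >= 2 subjects per group")
  if (is.null(families)) {
    numvars <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
    families <- list(all = numvars)
  }
  rows <- list()
  for (fam in names(families)) {
    for (v in families[[fam]]) {
      x <- metrics[[v]][g == levels(g)[1L]]
      y <- metrics[[v]][g == levels(g)[2L]]
      cc <- stats::complete.cases(x); x <- x[cc]
      cc <- stats::complete.cases(y); y <- y[cc]
      if (length(unique(c(x, y))) < 2L) {
        warning("constant variable skipped: ", v)
        next
      }
      sw_x <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
      sw_y <- tryCatch(stats::shapiro.test(y)$p.value, error = function(e) 0)
      if (sw_x > 0.05 && sw_y > 0.05) {
        tt <- stats::t.test(x, y, var.equal = TRUE)
        test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
      } else {
        mw <- .mann_whitney_z(x, y)
        test <- "mann-whitney"; statistic <- mw$z; p <- mw$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, family = fam,
        mean_1 = mean(x), sd_1 = stats::sd(x),
        mean_2 = mean(y), sd_2 = stats::sd(y),
        test = test, statistic = statistic,
        shapiro_p_1 = sw_x, shapiro_p_2 = sw_y,
        p_raw = p, p_fdr = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  for (fam in unique(tab$family)) {
    sel <- tab$family == fam
    tab$p_fdr[sel] <- fdr_bh(tab$p_raw[sel])
  }
  attr(tab, "group_levels") <- levels(g)
  class(tab) <- c("stat_table", "data.frame")
  tab
}

#' Covariate-adjusted partial rank correlation
#'
#' Rank-transforms x and y (average ranks for ties), residualizes both on
#' an intercept plus the covariates by least squares, and returns the
#' Pearson correlation of the residuals — the common SPSS-style
#' "partial Spearman" estimator.  p is two-sided from a t distribution
#' with n - n_covariates - 2 degrees of freedom.  With no covariates this
#' equals the Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of covariates, or NULL.
#' @return list with `rho`, `p`, `n`, `df`, `covariates` (count).
#' @export
partial_rank_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), length(x), 0L)
  }
  covariates <- as.matrix(covariates)
  cc <- stats::complete.cases(x, y, covariates)
  x <- x[cc]; y <- y[cc]
  covariates <- covariates[cc, , drop = FALSE]
  n <- length(x)
  q <- ncol(covariates)
  if (n <= q + 2L) stop_invalid("insufficient complete cases")
  rx <- rank(x); ry <- rank(y)
  X <- cbind(1, covariates)
  res_x <- stats::lm.fit(X, rx)$residuals
  res_y <- stats::lm.fit(X, ry)$residuals
  rho <- stats::cor(res_x, res_y)
  df <- n - q - 2L
  t_stat <- rho * sqrt(df / max(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(rho = rho, p = p, n = n, df = df, covariates = q)
}

#' Stepwise multiple linear regression (p-value entry/removal)
#'
#' Classic forward-entry / backward-removal stepwise selection: at each
#' step the candidate with the smallest partial p-value below `p_enter`
#' is added, then any included term with p above `p_remove` is removed
#' (largest first); the loop stops when no change occurs.  Candidates
#' collinear with the current model (rank check) never enter.  Reports
#' standardized coefficients (Beta), unstandardized coefficients with 95%
#' confidence intervals, t and p per retained term, the model R-squared,
#' and the full selection trace.
#'
#' @param y outcome vector.
#' @param X data.frame/matrix of candidate predictors.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return a `regression_result`: list with `terms`, `coefficients`
#'   (data.frame: term, beta_std, estimate, ci_low, ci_high, t, p),
#'   `r_squared`, `trace` (data.frame: step, action, term, p), and `model`
#'   (the final `lm`, or NULL for the empty model).
#' @export
stepwise_regression <- function(y, X, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(X)
  cc <- stats::complete.cases(y, X)
  y <- y[cc]; X <- X[cc, , drop = FALSE]
  vars <- names(X)
  included <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      term = character(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  step_i <- 0L

  term_p <- function(model_vars, term) {
    dat <- data.frame(.y = y, X[, c(model_vars, term), drop = FALSE])
    Xm <- stats::model.matrix(~ ., dat[, -1, drop = FALSE])
    if (qr(Xm)$rank < ncol(Xm)) return(NA_real_)   # collinear: never enters
    fit <- stats::lm(.y ~ ., data = dat)
    cf <- summary(fit)$coefficients
    if (!term %in% rownames(cf)) return(NA_real_)
    cf[term, 4L]
  }

  repeat {
    changed <- FALSE
    candidates <- setdiff(vars, included)
    if (length(candidates)) {
      pv <- vapply(candidates, function(v) term_p(included, v), numeric(1))
      if (any(!is.na(pv)) && min(pv, na.rm = TRUE) < p_enter) {
        add <- candidates[which.min(pv)]
        included <- c(included, add)
        step_i <- step_i + 1L
        trace <- rbind(trace, data.frame(step = step_i, action = "enter",
                                         term = add, p = min(pv, na.rm = TRUE)))
        changed <- TRUE
      }
    }
    while (length(included)) {
      dat <- data.frame(.y = y, X[, included, drop = FALSE])
      fit <- stats::lm(.y ~ ., data = dat)
      cf <- summary(fit)$coefficients
      pin <- cf[included, 4L]
      if (max(pin) <= p_remove) break
      drop_v <- included[which.max(pin)]
      included <- setdiff(included, drop_v)
      step_i <- step_i + 1L
      trace <- rbind(trace, data.frame(step = step_i, action = "remove",
                                       term = drop_v, p = max(pin)))
      changed <- TRUE
    }
    if (!changed) break
  }

  if (!length(included)) {
    return(structure(list(terms = character(0),
                          coefficients = data.frame(),
                          r_squared = 0, trace = trace, model = NULL),
                     class = "regression_result"))
  }
  dat <- data.frame(.y = y, X[, included, drop = FALSE])
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  sd_y <- stats::sd(y)
  coefs <- do.call(rbind, lapply(included, function(v) {
    est <- sm$coefficients[v, ]
    data.frame(term = v,
               beta_std = unname(est[1L]) * stats::sd(X[[v]]) / sd_y,
               estimate = unname(est[1L]),
               ci_low = ci[v, 1L], ci_high = ci[v, 2L],
               t = unname(est[3L]), p = unname(est[4L]),
               stringsAsFactors = FALSE)
  }))
  structure(list(terms = included, coefficients = coefs,
                 r_squared = sm$r.squared, trace = trace, model = fit),
            class = "regression_result")
}
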