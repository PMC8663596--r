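#' 2x2 contingency table of exposure by outcome
#'
#' @param a Exposed with outcome.
#' @param b Exposed without outcome.
#' @param c Unexposed with outcome.
#' @param d Unexposed without outcome.
#' @return List of class `"contingency_table"`.
#' @export
contingency_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("contingency counts must be nonnegative integers.",
          class = "sbdhrisk_data_error")
  }
  structure(as.list(counts), class = "contingency_table")
}

#' Crude odds ratio with Wald confidence interval
#'
#' Computes the cross-product odds ratio `(a*d)/(b*c)` and its Wald interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells raise an
#' error by default; the optional Haldane 0.5 continuity correction (adds 0.5
#' to every cell) can be enabled explicitly.
#'
#' @param table A [contingency_table()], or the count `a` if `b`, `c`, `d`
#'   are given.
#' @param b,c,d Remaining counts when `table` is given as a scalar.
#' @param z Normal quantile for the interval (default 1.959964, a 95% CI).
#' @param continuity_correction Add 0.5 to every cell (off by default).
#' @param term Optional label for the estimate.
#' @return One-row tibble (`term`, `or`, `ci_low`, `ci_high`, `kind`), class
#'   `"effect_estimate"` preserved in the `kind` column as `"crude"`.
#' @export
crude_or <- function(table, b = NULL, c = NULL, d = NULL, z = 1.959964,
                     continuity_correction = FALSE, term = NA_character_) {
  if (inherits(table, "contingency_table")) {
    counts <- unlist(table[c("a", "b", "c", "d")])
  } else {
    counts <- c(a = table, b = b, c = c, d = d)
    contingency_table(counts[1], counts[2], counts[3], counts[4])
  }
  if (any(counts == 0)) {
    if (!continuity_correction) {
      abort(paste0("contingency table has a zero cell; enable ",
                   "`continuity_correction` or report the level as ",
                   "inestimable."),
            class = "sbdhrisk_zero_cell_error")
    }
    counts <- counts + 0.5
  }
  log_or <- log(counts[["a"]]) + log(counts[["d"]]) -
    log(counts[["b"]]) - log(counts[["c"]])
  se <- sqrt(sum(1 / counts))
  tibble::tibble(term = term, or = exp(log_or),
                 ci_low = exp(log_or - z * se),
                 ci_high = exp(log_or + z * se),
                 kind = "crude")
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Newton-Raphson maximization of the Bernoulli log-likelihood (identical to
#' Fisher scoring under the canonical logit link), with step halving,
#' convergence declared when the relative change in log-likelihood falls
#' below `tol`, and the covariance taken as the inverse observed information
#' at the optimum.
#'
#' @param x Design matrix (numeric). An intercept column is prepended unless
#'   `intercept = FALSE` or a constant column named `"(Intercept)"` is
#'   already present.
#' @param y Binary outcome (0/1 or logical).
#' @param weights Optional nonnegative case weights (e.g. cell counts).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @param separation_bound Coefficient magnitude beyond which quasi-complete
#'   separation is declared.
#' @param intercept Whether to prepend an intercept column.
#' @return List of class `"logistic_fit"`: `coefficients`, `covariance`,
#'   `log_likelihood`, `n_iterations`, `converged`, `fitted`.
#' @export
fit_logistic <- function(x, y, weights = NULL, tol = 1e-8, max_iter = 50L,
                         separation_bound = 15, intercept = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (any(is.na(y)) || !all(y %in% c(0, 1))) {
    abort("`y` must be binary (0/1).", class = "sbdhrisk_data_error")
  }
  if (nrow(x) != length(y)) {
    abort("`x` and `y` sizes differ.", class = "sbdhrisk_data_error")
  }
  w <- weights %||% rep(1, length(y))
  if (intercept && !"(Intercept)" %in% colnames(x)) {
    x <- cbind("(Intercept)" = 1, x)
  }
  ybar <- sum(w * y) / sum(w)
  if (ybar <= 0 || ybar >= 1) {
    abort("outcome is degenerate (all 0 or all 1): model is not identifiable.",
          class = "sbdhrisk_separation_error")
  }
  p <- ncol(x)
  beta <- numeric(p)
  if ("(Intercept)" %in% colnames(x)) {
    beta[match("(Intercept)", colnames(x))] <- qlogis(ybar)
  }
  loglik <- function(b) {
    eta <- drop(x %*% b)
    # numerically stable Bernoulli log-likelihood
    sum(w * (y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  trace <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- plogis(drop(x %*% beta))
    wt <- w * mu * (1 - mu)
    info <- crossprod(x * wt, x)
    score <- drop(crossprod(x, w * (y - mu)))
    step <- tryCatch(solve(info, score), error = function(e) {
      abort(paste0("information matrix is singular; the design is rank ",
                   "deficient or separation occurred."),
            class = "sbdhrisk_separation_error")
    })
    # step halving keeps the likelihood non-decreasing
    factor <- 1
    repeat {
      cand <- beta + factor * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || factor < 1e-8) break
      factor <- factor / 2
    }
    beta <- cand
    trace <- c(trace, ll_new)
    if (max(abs(beta)) > separation_bound) {
      abort(sprintf(paste0("coefficient magnitude exceeded %g: ",
                           "quasi-complete separation suspected."),
                    separation_bound),
            class = "sbdhrisk_separation_error")
    }
    if (abs(ll_new - ll) / (abs(ll) + 1e-10) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) {
    cnd <- rlang::error_cnd(class = "sbdhrisk_nonconvergence_error",
                            message = sprintf(
                              "IRLS did not converge in %d iterations.",
                              max_iter),
                            trace_ll = trace)
    rlang::cnd_signal(cnd)
  }
  mu <- plogis(drop(x %*% beta))
  wt <- w * mu * (1 - mu)
  covariance <- solve(crossprod(x * wt, x))
  dimnames(covariance) <- list(colnames(x), colnames(x))
  structure(list(coefficients = setNames(drop(beta), colnames(x)),
                 covariance = covariance,
                 log_likelihood = ll,
                 n_iterations = iter,
                 converged = converged,
                 fitted = mu,
                 n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d obs, %d coefficients, logLik %.3f (%d iter)\n",
              x$n, length(x$coefficients), x$log_likelihood, x$n_iterations))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Akaike information criterion of a logistic fit
#' @param fit A `"logistic_fit"`.
#' @return `-2 logLik + 2 p`.
#' @export
aic <- function(fit) -2 * fit$log_likelihood + 2 * length(fit$coefficients)

#' Adjusted odds ratios with Wald confidence intervals from a fitted model
#'
#' For every non-intercept coefficient: `aOR = exp(beta)` with interval
#' `exp(beta +/- z * se)`.
#'
#' @param fit A converged `"logistic_fit"`.
#' @param z Normal quantile (default 1.959964).
#' @return Tibble (`term`, `or`, `ci_low`, `ci_high`, `kind = "adjusted"`).
#' @export
adjusted_or <- function(fit, z = 1.959964) {
  if (!isTRUE(fit$converged)) {
    abort("fit did not converge; adjusted ORs are unavailable.",
          class = "sbdhrisk_data_error")
  }
  keep <- setdiff(names(fit$coefficients), "(Intercept)")
  beta <- fit$coefficients[keep]
  se <- sqrt(diag(fit$covariance))[keep]
  tibble::tibble(term = keep, or = unname(exp(beta)),
                 ci_low = unname(exp(beta - z * se)),
                 ci_high = unname(exp(beta + z * se)),
                 kind = "adjusted")
}

#' Build the treatment-coded design matrix of the overdose model
#'
#' Categorical variables are expanded against their reference levels (the
#' first level of each declared set) with column names `"variable:level"`;
#' binary clinical flags keep their own names. Only variables present in
#' `data` are used, so the same helper serves the full model and submodels.
#'
#' @param data Analysis table (or truth tibble) containing the model
#'   variables.
#' @param terms Optional character vector restricting which variables enter.
#' @return Numeric design matrix without intercept.
#' @export
build_design <- function(data, terms = NULL) {
  level_sets <- c(.demographic_levels, .sbdh_levels)
  if (is.null(terms)) {
    vars <- c(names(.demographic_levels), .clinical_vars, .sbdh_vars)
    vars <- vars[vars %in% names(data)]
  } else {
    missing <- setdiff(terms, names(data))
    if (length(missing)) {
      abort(sprintf("model terms not found in the data: %s.",
                    paste(missing, collapse = ", ")),
            class = "sbdhrisk_data_error")
    }
    vars <- terms
  }
  cols <- list()
  for (v in vars) {
    if (v %in% names(level_sets)) {
      lev <- level_sets[[v]]
      val <- as.character(data[[v]])
      for (l in lev[-1]) {
        cols[[paste0(v, ":", l)]] <- as.numeric(val == l)
      }
    } else {
      cols[[v]] <- as.numeric(data[[v]])
    }
  }
  do.call(cbind, cols)
}

#' Fit the multivariable overdose model on an analysis table
#'
#' @param data An `"analysis_table"` (needs an `outcome` column).
#' @param terms Optional restriction of the modeled variables.
#' @param ... Passed to [fit_logistic()].
#' @return A `"logistic_fit"` whose coefficient names follow the
#'   `"variable:level"` convention.
#' @export
fit_overdose_model <- function(data, terms = NULL, ...) {
  fit_logistic(build_design(data, terms), data$outcome, ...)
}

#' Sequential forward selection of model variables
#'
#' Greedy selection: starting from `base_terms`, each step adds the candidate
#' variable whose inclusion most improves the criterion (default AIC; or a
#' likelihood-ratio entry test at level `alpha`), stopping when no candidate
#' improves. Ties are broken deterministically by candidate name order. A
#' candidate whose inner fit fails is skipped with a warning and recorded in
#' the trace.
#'
#' @param data Analysis table with an `outcome` column.
#' @param candidates Character vector of candidate variable names.
#' @param base_terms Variables always kept in the model.
#' @param criterion `"aic"` or `"lrt"`.
#' @param alpha Entry significance level for `criterion = "lrt"`.
#' @param ... Passed to [fit_logistic()].
#' @return List of class `"selection_trace"`: `trace` (tibble of steps),
#'   `selected`, `final_terms`, `failed`.
#' @export
forward_select <- function(data, candidates, base_terms = character(0),
                           criterion = c("aic", "lrt"), alpha = 0.05, ...) {
  criterion <- match.arg(criterion)
  if (length(intersect(candidates, base_terms))) {
    abort("`candidates` must be disjoint from `base_terms`.",
          class = "sbdhrisk_config_error")
  }
  fit_terms <- function(terms) {
    des <- build_design(data, terms)
    if (is.null(des)) des <- matrix(numeric(0), nrow = nrow(data), ncol = 0)
    fit_logistic(des, data$outcome, ...)
  }
  current <- sort(base_terms)
  cur_fit <- fit_terms(current)
  remaining <- sort(candidates)
  selected <- character(0)
  failed <- character(0)
  steps <- list()
  step_no <- 0L
  repeat {
    best <- NULL
    for (cand in remaining) {
      fit <- tryCatch(fit_terms(c(current, cand)), error = function(e) e)
      if (inherits(fit, "error")) {
        warn(sprintf("forward selection: fit with `%s` failed (%s); skipped.",
                     cand, conditionMessage(fit)))
        failed <- unique(c(failed, cand))
        next
      }
      if (criterion == "aic") {
        improves <- aic(fit) < aic(cur_fit) - 1e-9
        score <- aic(fit)
      } else {
        lr <- 2 * (fit$log_likelihood - cur_fit$log_likelihood)
        df <- length(fit$coefficients) - length(cur_fit$coefficients)
        score <- pchisq(lr, df, lower.tail = FALSE)
        improves <- score < alpha
      }
      if (improves && (is.null(best) || score < best$score - 1e-9)) {
        best <- list(cand = cand, fit = fit, score = score)
      }
    }
    if (is.null(best)) break
    step_no <- step_no + 1L
    steps[[step_no]] <- tibble::tibble(
      step = step_no, variable = best$cand,
      criterion_before = aic(cur_fit), criterion_after = aic(best$fit))
    current <- c(current, best$cand)
    selected <- c(selected, best$cand)
    remaining <- setdiff(remaining, best$cand)
    cur_fit <- best$fit
    if (!length(remaining)) break
  }
  trace <- if (length(steps)) dplyr::bind_rows(steps) else
    tibble::tibble(step = integer(0), variable = character(0),
                   criterion_before = numeric(0), criterion_after = numeric(0))
  structure(list(trace = trace, selected = selected,
                 final_terms = c(sort(base_terms), selected),
                 failed = failed, final_fit = cur_fit),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  if (nrow(x$trace)) print(x$trace) else cat("  no variable improved the criterion\n")
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Observations are sorted by fitted probability and split into `groups`
#' near-equal deciles of risk; observations tied with the value at a group
#' boundary stay in the lower group. The statistic sums
#' `(observed - expected)^2 / expected` over groups and both outcome
#' classes; degrees of freedom are `groups - 2` and the p-value comes from
#' the chi-square survival function.
#'
#' @param probs Fitted probabilities in (0, 1).
#' @param outcomes Binary outcomes.
#' @param groups Number of risk groups (default 10).
#' @return List of class `"hl_test"`: `chi2`, `df`, `p_value`,
#'   `group_count`, `table` (per-group observed/expected counts).
#' @export
hosmer_lemeshow <- function(probs, outcomes, groups = 10L) {
  y <- as.numeric(outcomes)
  if (length(probs) != length(y)) {
    abort("`probs` and `outcomes` sizes differ.",
          class = "sbdhrisk_data_error")
  }
  if (any(probs <= 0 | probs >= 1)) {
    abort("`probs` must lie strictly inside (0, 1).",
          class = "sbdhrisk_data_error")
  }
  n <- length(y)
  if (n < groups) {
    abort("need at least as many observations as groups.",
          class = "sbdhrisk_data_error")
  }
  ord <- order(probs)
  p_s <- probs[ord]
  y_s <- y[ord]
  # near-equal group sizes; ties at a quantile boundary stay in the lower group
  bounds <- floor(seq_len(groups - 1L) * n / groups)
  for (k in seq_along(bounds)) {
    while (bounds[k] < n && p_s[bounds[k] + 1L] == p_s[bounds[k]]) {
      bounds[k] <- bounds[k] + 1L
    }
  }
  bounds <- unique(pmin(bounds, n))
  grp <- findInterval(seq_len(n), c(0, bounds) + 1L)
  tab <- tibble::tibble(
    group = seq_len(max(grp)),
    n = as.integer(table(factor(grp, levels = seq_len(max(grp))))),
    observed_events = as.numeric(tapply(y_s, grp, sum)),
    expected_events = as.numeric(tapply(p_s, grp, sum)))
  tab$observed_nonevents <- tab$n - tab$observed_events
  tab$expected_nonevents <- tab$n - tab$expected_events
  if (any(tab$expected_events <= 0) || any(tab$expected_nonevents <= 0)) {
    abort("a risk group has zero expected count; try fewer groups.",
          class = "sbdhrisk_data_error")
  }
  chi2 <- sum((tab$observed_events - tab$expected_events)^2 /
                tab$expected_events +
              (tab$observed_nonevents - tab$expected_nonevents)^2 /
                tab$expected_nonevents)
  g <- nrow(tab)
  structure(list(chi2 = chi2, df = g - 2L,
                 p_value = pchisq(chi2, g - 2L, lower.tail = FALSE),
                 group_count = g, table = tab),
            class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2(%d) = %.3f, p = %.3f (%d groups)\n",
              x$df, x$chi2, x$p_value, x$group_count))
  invisible(x)
}

#' Variance inflation factors
#'
#' For each column of the design, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j`
#' comes from the least-squares regression of column j on the remaining
#' columns (plus an intercept). Perfectly collinear columns are reported as
#' `Inf`.
#'
#' @param design Numeric matrix with at least two columns (no intercept
#'   column).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  if (ncol(design) < 2) {
    abort("`design` needs at least two columns.",
          class = "sbdhrisk_data_error")
  }
  out <- setNames(numeric(ncol(design)), colnames(design))
  for (j in seq_len(ncol(design))) {
    yj <- design[, j]
    xj <- cbind(1, design[, -j, drop = FALSE])
    fit <- stats::lm.fit(xj, yj)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) {
      out[j] <- NA_real_
      next
    }
    r2 <- 1 - sum(fit$residuals^2) / tss
    out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}
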