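test_that("crude odds ratios match hand-checked published tables to 2 dp", {
  est <- crude_or(80, 1413, 91, 47285)
  expect_identical(round(est$or, 2), 29.42)
  est2 <- crude_or(28, 981, 143, 47717)
  expect_identical(round(est2$or, 2), 9.52)
  # Wald CI bounds agree with the closed form
  se <- sqrt(1 / 80 + 1 / 1413 + 1 / 91 + 1 / 47285)
  expect_equal(est$ci_low, exp(log(est$or) - 1.959964 * se))
  expect_equal(est$ci_high, exp(log(est$or) + 1.959964 * se))
})

test_that("a balanced table gives OR 1 with a log-symmetric interval", {
  est <- crude_or(10, 10, 10, 10)
  expect_equal(est$or, 1)
  expect_equal(log(est$ci_low), -log(est$ci_high))
})

test_that("zero cells error unless the continuity correction is requested", {
  expect_error(crude_or(0, 10, 5, 20), class = "sbdhrisk_zero_cell_error")
  est <- crude_or(0, 10, 5, 20, continuity_correction = TRUE)
  expect_equal(est$or, (0.5 * 20.5) / (10.5 * 5.5))
  expect_error(crude_or(-1, 10, 5, 20), class = "sbdhrisk_data_error")
})

test_that("confidence bounds always bracket the estimate", {
  set.seed(99)
  for (i in 1:50) {
    counts <- sample(1:500, 4, replace = TRUE)
    est <- crude_or(counts[1], counts[2], counts[3], counts[4])
    expect_lte(est$ci_low, est$or)
    expect_lte(est$or, est$ci_high)
  }
})

test_that("IRLS reproduces the reference ML fit on random data", {
  set.seed(123)
  for (rep in 1:5) {
    n <- 400
    x <- cbind(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.3),
               x3 = stats::runif(n))
    y <- stats::rbinom(n, 1, plogis(-1 + 0.7 * x[, 1] - 0.5 * x[, 2]))
    fit <- fit_logistic(x, y, tol = 1e-12)
    ref <- stats::glm(y ~ x, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-12))
    expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(sqrt(diag(fit$covariance))),
                 unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-5)
    expect_equal(fit$log_likelihood, as.numeric(stats::logLik(ref)),
                 tolerance = 1e-8)
  }
})

test_that("the intercept-only fit is the closed-form Bernoulli odds", {
  fit <- fit_logistic(matrix(numeric(0), nrow = 2, ncol = 0), c(1, 0),
                      weights = c(171, 48698))
  expect_equal(exp(unname(fit$coefficients)), 171 / 48698, tolerance = 1e-8)
})

test_that("a single binary covariate reproduces the cross-product odds ratio", {
  x <- matrix(c(1, 1, 0, 0), ncol = 1, dimnames = list(NULL, "exposed"))
  y <- c(1, 0, 1, 0)
  w <- c(80, 1413, 91, 47285)
  fit <- fit_logistic(x, y, weights = w, tol = 1e-12)
  or_irls <- exp(fit$coefficients[["exposed"]])
  or_xprod <- (80 * 47285) / (1413 * 91)
  expect_lt(abs(or_irls / or_xprod - 1), 1e-6)
  aor <- adjusted_or(fit)
  expect_identical(aor$term, "exposed")
  expect_equal(aor$or, or_irls)
})

test_that("degenerate and separated inputs raise informative errors", {
  x <- matrix(stats::rnorm(40), ncol = 2)
  expect_error(fit_logistic(x, rep(0, 20)),
               class = "sbdhrisk_separation_error")
  # perfectly separating covariate
  xs <- matrix(c(rep(0, 10), rep(1, 10)), ncol = 1)
  ys <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(xs, ys), class = "sbdhrisk_separation_error")
  # non-convergence carries its likelihood trace
  set.seed(4)
  xn <- matrix(stats::rnorm(600), ncol = 3)
  yn <- stats::rbinom(200, 1, plogis(xn[, 1]))
  err <- tryCatch(fit_logistic(xn, yn, max_iter = 1L, tol = 1e-14),
                  sbdhrisk_nonconvergence_error = function(e) e)
  expect_s3_class(err, "sbdhrisk_nonconvergence_error")
  expect_true(length(err$trace_ll) >= 1)
})

test_that("null coefficients give unit odds ratios with the closed-form CI", {
  fit <- structure(list(
    coefficients = c("(Intercept)" = -2, term_a = 0),
    covariance = diag(c(0.04, 0.01)) |>
      `dimnames<-`(list(c("(Intercept)", "term_a"),
                        c("(Intercept)", "term_a"))),
    converged = TRUE), class = "logistic_fit")
  aor <- adjusted_or(fit)
  expect_equal(aor$or, 1)
  expect_identical(round(aor$ci_low, 2), 0.82)
  expect_identical(round(aor$ci_high, 2), 1.22)
})

test_that("forward selection prefers the generating variable and breaks ties by name", {
  set.seed(7)
  n <- 3000
  data <- tibble::tibble(
    outcome = NA,
    signal = stats::rbinom(n, 1, 0.3) == 1,
    noise = stats::rbinom(n, 1, 0.3) == 1)
  data$outcome <- stats::rbinom(n, 1, plogis(-2 + 1.5 * data$signal)) == 1
  sel <- forward_select(data, candidates = c("noise", "signal"))
  expect_identical(sel$trace$variable[1], "signal")
  expect_true(all(diff(c(sel$trace$criterion_before[1],
                         sel$trace$criterion_after)) < 0))

  # duplicated candidate columns: exactly one enters, first name wins
  data$aa <- data$signal
  data$ab <- data$signal
  # the twin of the selected column makes later fits singular: it is skipped
  # with a warning and recorded as failed
  expect_warning(sel2 <- forward_select(data, candidates = c("ab", "aa")),
                 "skipped")
  expect_identical(sel2$selected[1], "aa")
  expect_false("ab" %in% sel2$selected)

  # empty candidate list
  sel3 <- forward_select(data, candidates = character(0))
  expect_identical(nrow(sel3$trace), 0L)
  expect_identical(sel3$final_terms, character(0))

  expect_error(forward_select(data, candidates = "signal",
                              base_terms = "signal"),
               class = "sbdhrisk_config_error")
})

test_that("perfectly calibrated probabilities give a zero HL statistic", {
  probs <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  outcomes <- unlist(lapply(seq(0.05, 0.95, by = 0.1), function(p) {
    c(rep(1, round(20 * p)), rep(0, 20 - round(20 * p)))
  }))
  hl <- hosmer_lemeshow(probs, outcomes, groups = 10)
  expect_equal(hl$chi2, 0, tolerance = 1e-12)
  expect_identical(hl$df, 8L)
  expect_equal(hl$p_value, 1)
})

test_that("HL groups are near-equal and boundary ties stay in the lower group", {
  set.seed(8)
  probs <- stats::runif(1000, 0.05, 0.95)
  y <- stats::rbinom(1000, 1, probs)
  hl <- hosmer_lemeshow(probs, y, groups = 10)
  expect_identical(hl$group_count, 10L)
  expect_identical(hl$df, 8L)
  expect_true(all(abs(hl$table$n - 100) <= 1))
  expect_identical(sum(hl$table$n), 1000L)
  expect_error(hosmer_lemeshow(c(0, 0.5), c(0, 1)),
               class = "sbdhrisk_data_error")
})

test_that("VIFs match closed forms for orthogonal, correlated and collinear designs", {
  ortho <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(ortho)), c(1, 1))
  a <- c(1, -1, 1, -1)
  cvec <- c(1, 1, -1, -1)
  corr <- cbind(a = a, b = 0.6 * a + 0.8 * cvec)  # sample correlation 0.6
  expect_equal(unname(vif(corr)), c(1.5625, 1.5625), tolerance = 1e-10)
  dup <- cbind(a = a, b = a)
  expect_true(all(is.infinite(vif(dup))))
  expect_error(vif(matrix(1:4, ncol = 1)), class = "sbdhrisk_data_error")
})

test_that("the odds-ratio report surfaces inestimable levels as zero cells", {
  set.seed(21)
  n <- 600
  tab <- tibble::tibble(
    outcome = stats::rbinom(n, 1, 0.3) == 1,
    drug_use_disorder = stats::rbinom(n, 1, 0.4) == 1,
    housing_insecurity = factor(sample(c("no", "unknown"), n, replace = TRUE),
                                levels = c("no", "yes", "unknown")))
  rep <- or_report(tab)
  expect_true("housing_insecurity:yes" %in% rep$zero_cells)
  est <- rep$estimates
  expect_true(is.na(est$aor[est$term == "housing_insecurity:yes"]))
  expect_false(is.na(est$aor[est$term == "drug_use_disorder"]))
})
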