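test_that("the 31-term basis expands coded points in fixed order", {
  labs <- term_basis(study_space$name)
  expect_length(labs, 31)
  expect_equal(labs[1], "b0")

  center <- expand_terms(rep(0, 5), study_space$name)
  expect_equal(unname(drop(center)), c(1, rep(0, 30)))

  ones <- expand_terms(rep(1, 5), study_space$name)
  expect_equal(unname(drop(ones)), rep(1, 31))

  x <- expand_terms(c(SW = 1, AM = -1, EV = 0, WC = 0, ET = 0))
  expect_equal(x[, "SW:AM"][[1]], -1)
  expect_equal(x[, "SW^2"][[1]], 1)
  expect_equal(x[, "AM^2"][[1]], 1)
  touches_others <- grepl("EV|WC|ET", colnames(x))
  expect_true(all(x[, touches_others] == 0))
})

test_that("basis size follows 1 + k + C(k,2) + C(k,3) + k for general k", {
  for (k in c(1, 2, 3, 4, 5)) {
    expect_length(term_basis(paste0("F", 1:k)),
                  1 + k + choose(k, 2) + choose(k, 3) + k)
  }
})

test_that("noiseless synthetic tables are refit to the generating coefficients", {
  for (system in c("citrate", "acetate")) {
    truth <- quechers_coefficients(system)
    tab <- simulate_recoveries(study_design, truth, noise_sd = 0)
    for (cp in names(truth)) {
      fit <- fit_full_model(tab, cp)
      expect_equal(unname(fit$coefficients),
                   unname(truth[[cp]]$coefficients), tolerance = 1e-10)
    }
  }
})

test_that("a constant response fits as pure intercept with zero SSE", {
  tab <- recovery_table(study_design,
                        matrix(100, 45, 1, dimnames = list(NULL, "flat")))
  fit <- fit_full_model(tab, "flat")
  expect_equal(unname(fit$coefficients[1]), 100)
  expect_equal(unname(fit$coefficients[-1]), rep(0, 30), tolerance = 1e-10)
  expect_lt(fit$sse, 1e-18)
})

test_that("QR fit agrees with an independent normal-equations solve", {
  set.seed(21)
  X <- expand_terms(coded_matrix(study_design), study_space$name)
  for (i in 1:5) {
    y <- 100 + rnorm(45, sd = 5)
    tab <- recovery_table(study_design,
                          matrix(y, ncol = 1, dimnames = list(NULL, "y")))
    fit <- fit_full_model(tab, "y")
    oracle <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(fit$coefficients), unname(drop(oracle)),
                 tolerance = 1e-8)
  }
})

test_that("prediction at the design center equals the intercept", {
  set.seed(22)
  y <- 100 + rnorm(45, sd = 3)
  fit <- fit_full_model(recovery_table(study_design,
                                       matrix(y, ncol = 1,
                                              dimnames = list(NULL, "y"))))
  expect_identical(unname(predict(fit, rep(0, 5))),
                   unname(fit$coefficients[1]))
})

test_that("R is invariant to shifting all observations by a constant", {
  set.seed(23)
  y <- 100 + rnorm(45, sd = 4)
  fit1 <- fit_full_model(recovery_table(study_design,
                                        matrix(y, ncol = 1,
                                               dimnames = list(NULL, "y"))))
  fit2 <- fit_full_model(recovery_table(study_design,
                                        matrix(y + 37, ncol = 1,
                                               dimnames = list(NULL, "y"))))
  expect_equal(fit1$R, fit2$R, tolerance = 1e-10)
})

test_that("significance letters follow the 95/90/80/70% confidence thresholds", {
  expect_equal(significance_letter(c(0.01, 0.07, 0.15, 0.25, 0.35)),
               c("a", "b", "c", "d", ""))
  # boundaries are exclusive upward: p = 0.05 is the 90% band
  expect_equal(significance_letter(c(0.05, 0.10, 0.20, 0.30)),
               c("b", "c", "d", ""))
  expect_error(significance_letter(1.2), "\\[0, 1\\]")
  expect_error(significance_letter(-0.1), "\\[0, 1\\]")
})

test_that("a single-factor quadratic fit matches the closed-form parabola", {
  sp1 <- factor_space("X", "u", -1, 1)
  des1 <- ccf_design(sp1, 1)  # runs at -1, +1 (factorial), -1, +1 (axial), 0
  y_at <- function(x) 50 + 3 * x - 7 * x^2
  y <- y_at(coded_matrix(des1)[, 1])
  fit <- fit_full_model(recovery_table(des1, matrix(y, ncol = 1,
                                                    dimnames = list(NULL, "y"))))
  # parabola through (-1, y-), (0, y0), (+1, y+):
  # b0 = y0, b1 = (y+ - y-)/2, b11 = (y+ + y-)/2 - y0
  expect_equal(unname(fit$coefficients),
               c(y_at(0), (y_at(1) - y_at(-1)) / 2,
                 (y_at(1) + y_at(-1)) / 2 - y_at(0)), tolerance = 1e-10)
})

test_that("fitting fails informatively on rank deficiency and short tables", {
  subset_design <- function(design, rows) {
    d <- as.data.frame(design)[rows, ]
    class(d) <- class(design)
    attr(d, "space") <- attr(design, "space")
    d
  }
  # fewer runs than the 31 terms
  d20 <- subset_design(study_design, 1:20)
  expect_error(fit_full_model(recovery_table(d20, matrix(100, 20, 1))),
               "more runs")
  # dropping the ET axial pair aliases ET^2 with the other quadratics
  d40 <- subset_design(study_design, 1:40)
  expect_error(fit_full_model(recovery_table(d40, matrix(rnorm(40, 100), 40, 1))),
               "rank-deficient")
})

test_that("coefficient sampling noise matches the analytic OLS standard errors", {
  truth <- quechers_coefficients("citrate")$alloxydim
  sd_true <- 2
  X <- expand_terms(coded_matrix(study_design), study_space$name)
  se_analytic <- sd_true * sqrt(diag(solve(crossprod(X))))

  n_rep <- 300
  fits <- matrix(NA_real_, n_rep, 31)
  set.seed(31)
  for (r in seq_len(n_rep)) {
    tab <- simulate_recoveries(study_design, list(alloxydim = truth),
                               noise_sd = sd_true)
    fits[r, ] <- fit_full_model(tab, "alloxydim")$coefficients
  }
  # unbiasedness of the headline effect (acetonitrile proportion)
  i_am <- match("AM", truth$terms)
  mc_err <- se_analytic[i_am] / sqrt(n_rep)
  expect_lt(abs(mean(fits[, i_am]) - truth$coefficients[["AM"]]), 4 * mc_err)
  # empirical spread tracks the analytic standard errors (15% band)
  emp_se <- apply(fits, 2, sd)
  expect_true(all(abs(emp_se / se_analytic - 1) < 0.15))
})
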