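test_that("level-0 pruning is the identity on the full equation", {
  model <- quechers_coefficients("citrate")$alloxydim
  pr <- prune_model(model, 0)
  expect_length(pr$retained, 31)
  expect_equal(pr$coefficients, model$coefficients)
  x <- c(SW = 0.3, AM = -0.5, EV = 1, WC = -1, ET = 0.1)
  expect_equal(predict(pr, x), predict(model, x))
})

test_that("the published significance letters give the expected 95% term sets", {
  cit <- quechers_coefficients("citrate")$alloxydim
  expect_equal(prune_model(cit, 95)$retained, c("b0", "AM"))
  ace <- quechers_coefficients("acetate")$alloxydim
  expect_equal(prune_model(ace, 95)$retained,
               c("b0", "SW", "AM", "SW:WC", "AM:ET", "AM^2"))
})

test_that("retained term sets are nested across confidence levels", {
  for (system in c("citrate", "acetate")) {
    for (model in quechers_coefficients(system)) {
      sets <- lapply(c(95, 90, 80, 70, 0),
                     function(lv) prune_model(model, lv)$retained)
      for (i in 1:4) {
        expect_true(all(sets[[i]] %in% sets[[i + 1]]))
      }
    }
  }
})

test_that("the intercept survives pruning whatever its letter", {
  # a model whose intercept is tiny and non-significant
  set.seed(41)
  y <- rnorm(45, mean = 0, sd = 1) + 50  # recoveries must be >= 0
  fit <- fit_full_model(recovery_table(study_design,
                                       matrix(y, ncol = 1,
                                              dimnames = list(NULL, "y"))))
  expect_true("b0" %in% prune_model(fit, 95)$retained)
})

test_that("pruning never reduces the SSE below the full fit, in either mode", {
  set.seed(42)
  for (rep in 1:3) {
    tab <- simulate_recoveries(study_design, quechers_coefficients("acetate"),
                               noise_sd = 3)
    for (cp in tab$compounds[c(1, 4)]) {
      fit <- fit_full_model(tab, cp)
      obs <- tab$observations[, cp]
      cm <- coded_matrix(study_design)
      for (lv in c(95, 90, 80, 70, 0)) {
        for (mode in c("truncate", "refit")) {
          pr <- prune_model(fit, lv, mode = mode, table = tab)
          sse <- sum((predict(pr, cm) - obs)^2)
          expect_gte(sse, fit$sse - 1e-8)
        }
      }
    }
  }
})

test_that("refit-mode R never exceeds the full-model R", {
  set.seed(43)
  tab <- simulate_recoveries(study_design, quechers_coefficients("citrate"),
                             noise_sd = 3)
  fit <- fit_full_model(tab, "profoxydim")
  obs <- tab$observations[, "profoxydim"]
  cm <- coded_matrix(study_design)
  for (lv in c(95, 90, 80, 70)) {
    pr <- prune_model(fit, lv, mode = "refit", table = tab)
    r <- cor(predict(pr, cm), obs)
    expect_lte(r, fit$R + 1e-12)
  }
})

test_that("deviation ranges are the min/max absolute per-run residuals", {
  set.seed(44)
  tab <- simulate_recoveries(study_design, quechers_coefficients("acetate"),
                             noise_sd = 2)
  fit <- fit_full_model(tab, "sethoxydim")
  # level 0: equals the full-model residual range
  dev0 <- deviation_range(prune_model(fit, 0), tab)
  cm <- coded_matrix(study_design)
  resid <- abs(predict(fit, cm) - tab$observations[, "sethoxydim"])
  expect_equal(unname(dev0), c(min(resid), max(resid)))
  # brute-force recomputation at a pruned level
  pr <- prune_model(fit, 95)
  dev95 <- deviation_range(pr, tab)
  manual <- abs(drop(expand_terms(cm, study_space$name)[, pr$retained] %*%
                       pr$coefficients) - tab$observations[, "sethoxydim"])
  expect_equal(unname(dev95), c(min(manual), max(manual)))
  expect_gte(dev95[["min"]], 0)
  expect_lte(dev95[["min"]], dev95[["max"]])
})

test_that("perfect-fit data prune to zero deviations when truth survives", {
  truth <- coef_vector(c(b0 = 100, AM = -20))
  tab <- simulate_recoveries(study_design, matrix(truth, ncol = 1,
                                                  dimnames = list(NULL, "y")),
                             noise_sd = 0)
  fit <- fit_full_model(tab, "y")
  for (lv in c(95, 0)) {
    dev <- deviation_range(prune_model(fit, lv), tab)
    expect_equal(unname(dev), c(0, 0), tolerance = 1e-9)
  }
})

test_that("the report pairs deviation ranges with R across levels and compounds", {
  set.seed(45)
  tab <- simulate_recoveries(study_design,
                             quechers_coefficients("acetate")[c(1, 2)],
                             noise_sd = 2)
  models <- fit_all_models(tab)
  rep_tab <- selection_report(models, tab)
  expect_equal(nrow(rep_tab), 2 * 5)
  expect_setequal(names(rep_tab), c("compound", "level", "n_terms",
                                    "deviation_min", "deviation_max", "R"))
  # level-0 rows reproduce the full fit
  for (cp in names(models)) {
    row0 <- rep_tab[rep_tab$compound == cp & rep_tab$level == 0, ]
    expect_equal(row0$R, models[[cp]]$R, tolerance = 1e-10)
    expect_equal(row0$deviation_max,
                 deviation_range(prune_model(models[[cp]], 0), tab)[["max"]])
  }
  # independent recomputation of one pruned cell
  cp <- names(models)[1]
  pr <- prune_model(models[[cp]], 90)
  dev <- deviation_range(pr, tab)
  row <- rep_tab[rep_tab$compound == cp & rep_tab$level == 90, ]
  expect_equal(c(row$deviation_min, row$deviation_max), unname(dev))
})

test_that("all-constant observations give zero deviations at every level", {
  tab <- recovery_table(study_design,
                        matrix(100, 45, 1, dimnames = list(NULL, "flat")))
  rep_tab <- selection_report(fit_all_models(tab), tab)
  expect_true(all(rep_tab$deviation_max < 1e-9))
})

test_that("a high R can coexist with large deviations, and the report shows both", {
  # wide response range driven by AM, plus one far-off run: R stays high
  # while the maximum deviation is large -- R alone cannot certify accuracy
  truth <- coef_vector(c(b0 = 100, AM = 40))
  set.seed(46)
  obs <- simulate_recoveries(study_design, matrix(truth, ncol = 1,
                                                  dimnames = list(NULL, "y")),
                             noise_sd = 1)$observations
  obs[10, 1] <- obs[10, 1] + 25  # single outlying recovery
  tab <- recovery_table(study_design, obs)
  rep_tab <- selection_report(fit_all_models(tab), tab, levels = c(95, 0))
  expect_true(all(rep_tab$R > 0.9))
  row95 <- rep_tab[rep_tab$level == 95, ]
  expect_gt(row95$deviation_max, 15)
})
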