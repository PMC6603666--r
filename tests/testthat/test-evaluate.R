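test_that("state bands follow the half-open-downward convention", {
  expect_identical(as.character(classify_state(85)), "awake")
  expect_identical(as.character(classify_state(50)), "general")
  expect_identical(as.character(classify_state(c(80, 60, 40, 39.999))),
                   c("awake", "light", "general", "deep"))
  expect_identical(as.character(classify_state(0)), "deep")
  expect_identical(as.character(classify_state(100)), "awake")
  expect_error(classify_state(105), "\\[0, 100\\]")
})

make_table <- function(diag_counts, totals) {
  counts <- matrix(0L, 4, 4, dimnames = list(reference = state_levels_(),
                                             predicted = state_levels_()))
  for (i in 1:4) {
    counts[i, i] <- diag_counts[i]
    spill <- totals[i] - diag_counts[i]
    counts[i, (i %% 4) + 1] <- counts[i, (i %% 4) + 1] + spill
  }
  structure(counts, class = c("doa_confusion", "matrix"))
}

state_levels_ <- function() c("awake", "light", "general", "deep")

test_that("sensitivity and accuracy follow their defining ratios exactly", {
  tab <- make_table(c(8, 6, 9, 1), c(10, 10, 10, 10))
  s <- sensitivity(tab)
  expect_equal(s$sensitivity, c(0.8, 0.6, 0.9, 0.1))
  expect_equal(accuracy(tab), 0.6)

  perfect <- make_table(c(10, 10, 10, 10), c(10, 10, 10, 10))
  expect_equal(sensitivity(perfect)$sensitivity, rep(1, 4))
  expect_equal(accuracy(perfect), 1)

  none <- make_table(c(0, 0, 0, 0), c(10, 10, 10, 10))
  expect_equal(sensitivity(none)$sensitivity, rep(0, 4))

  # absent state: sensitivity undefined, reported missing (not 0)
  absent <- make_table(c(5, 3, 2, 0), c(10, 10, 10, 0))
  expect_true(is.na(sensitivity(absent)$sensitivity[4]))
})

test_that("accuracy equals the totals-weighted mean of sensitivities on random tables", {
  withr::with_seed(15, {
    for (rep in 1:25) {
      counts <- matrix(rpois(16, 8), 4, 4,
                       dimnames = list(reference = state_levels_(),
                                       predicted = state_levels_()))
      tab <- structure(counts, class = c("doa_confusion", "matrix"))
      s <- sensitivity(tab)
      keep <- !is.na(s$sensitivity)
      expect_equal(accuracy(tab),
                   sum(s$sensitivity[keep] * s$n_total[keep]) / sum(s$n_total[keep]),
                   tolerance = 1e-12)
    }
  })
})

test_that("Pearson correlation matches the direct formula", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, direct, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "3")
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("Bland-Altman bias and limits are exact on constructed cases", {
  x <- c(10, 40, 70, 90)
  ident <- bland_altman(x, x)
  expect_equal(c(ident$bias, ident$lower, ident$upper), c(0, 0, 0))

  offset <- bland_altman(x, x + 5)
  expect_equal(offset$bias, 5)
  expect_equal(offset$upper - offset$lower, 0)

  two <- bland_altman(c(0, 0), c(1, -1))
  expect_equal(two$bias, 0)
  expect_equal(two$upper, 1.96 * sqrt(2), tolerance = 1e-3)
})

test_that("Bland-Altman limits cover ~95% of Gaussian differences", {
  withr::with_seed(16, {
    ref <- runif(4000, 20, 80)
    pred <- ref + rnorm(4000, 1, 6)
    ba <- bland_altman(ref, pred)
    d <- pred - ref
    cover <- mean(d >= ba$lower & d <= ba$upper)
    expect_equal(cover, 0.95, tolerance = 0.02)
  })
})

test_that("LOOCV pools minutes across folds (micro-averaging)", {
  # unbalanced synthetic cohort where pooled and fold-averaged accuracy differ:
  # verify the reported accuracy is the pooled one
  f <- toy_regression(n = 90, seed = 17, noise_sd = 2)
  f$subject <- rep(c("a", "b", "c"), times = c(60, 20, 10))
  f$ref_index <- f$target
  ev <- loocv(f, "ann", hyper = ann_control(max_epochs = 600), seed = 3)
  expect_equal(nrow(ev$per_fold), 3)
  pooled_acc <- accuracy(confusion_table(ev$pooled$ref_index, ev$pooled$pred_index))
  expect_identical(ev$accuracy, pooled_acc)
  weights <- ev$per_fold$n_minutes / sum(ev$per_fold$n_minutes)
  micro_from_folds <- sum(ev$per_fold$fold_accuracy * weights)
  expect_equal(ev$accuracy, micro_from_folds, tolerance = 1e-12)
  # fold count equals subject count
  expect_identical(sort(ev$per_fold$subject), c("a", "b", "c"))
})

test_that("LOOCV learns a perfectly learnable cohort", {
  base <- toy_regression(n = 50, seed = 18, noise_sd = 0)
  cohort <- dplyr::bind_rows(
    lapply(c("s1", "s2", "s3"), function(s) dplyr::mutate(base, subject = s))
  )
  cohort$ref_index <- cohort$target
  ev <- loocv(cohort, "ann", seed = 4)
  expect_gte(ev$accuracy, 0.95)
  expect_gte(ev$pearson$r, 0.99)
})

test_that("ablation enumerates all 15 feature subsets", {
  f <- toy_regression(n = 45, seed = 19, noise_sd = 2)
  f$subject <- rep(c("a", "b", "c"), each = 15)
  f$ref_index <- f$target
  ab <- ablation_study(f, hyper = ann_control(max_epochs = 30), seed = 5)
  expect_equal(nrow(ab), 15)
  expect_setequal(ab$n_features, rep(1:4, times = c(4, 6, 4, 1)))
})

test_that("model comparison uses paired per-subject accuracies", {
  f <- toy_regression(n = 120, seed = 20, noise_sd = 2)
  f$subject <- rep(c("a", "b", "c", "d"), each = 30)
  f$ref_index <- f$target
  ann <- loocv(f, "ann", hyper = ann_control(max_epochs = 800), seed = 6)
  svr <- loocv(f, "svr", seed = 6)
  cmp <- compare_models(ann, svr)
  expect_true(is.finite(cmp$p_value))
  expect_gte(cmp$p_value, 0)
  expect_lte(cmp$p_value, 1)
})
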