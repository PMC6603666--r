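#' Classify a 0-100 index into an anesthesia state
#'
#' Bands are half-open downward: awake \[80,100\], light \[60,80),
#' general \[40,60), deep \[0,40). So an index of exactly 80 is awake and
#' exactly 40 is general.
#'
#' @param index Numeric vector of index values in \[0,100\].
#' @return Factor with levels `awake`, `light`, `general`, `deep`.
#' @examples
#' classify_state(c(85, 50, 40, 80, 12))
#' @export
classify_state <- function(index) {
  if (any(!is.na(index) & (index < 0 | index > 100))) {
    abort("index values must lie in [0, 100].")
  }
  out <- dplyr::case_when(
    index >= 80 ~ "awake",
    index >= 60 ~ "light",
    index >= 40 ~ "general",
    !is.na(index) ~ "deep",
    TRUE ~ NA_character_
  )
  factor(out, levels = state_levels())
}

#' Build a 4x4 confusion table of anesthesia states
#'
#' @param reference Factor (or index vector) of reference states per minute.
#' @param predicted Factor (or index vector) of predicted states.
#' @return A `doa_confusion`: 4x4 integer matrix, reference states in rows.
#' @export
confusion_table <- function(reference, predicted) {
  if (is.numeric(reference)) reference <- classify_state(reference)
  if (is.numeric(predicted)) predicted <- classify_state(predicted)
  reference <- factor(reference, levels = state_levels())
  predicted <- factor(predicted, levels = state_levels())
  keep <- !is.na(reference) & !is.na(predicted)
  tab <- table(reference = reference[keep], predicted = predicted[keep])
  structure(unclass(tab), class = c("doa_confusion", "matrix"))
}

#' Per-state sensitivity
#'
#' `S_i = N_i,detected / N_i,total`: the diagonal count over the row total.
#' States absent from the reference are reported as `NA` (the ratio is
#' undefined), not as 0.
#'
#' @param table A [confusion_table()].
#' @return Tibble with columns `state`, `n_total`, `n_detected`,
#'   `sensitivity`.
#' @export
sensitivity <- function(table) {
  stopifnot(inherits(table, "doa_confusion"))
  totals <- rowSums(table)
  detected <- diag(table)
  tibble::tibble(
    state = factor(rownames(table), levels = state_levels()),
    n_total = as.integer(totals),
    n_detected = as.integer(detected),
    sensitivity = unname(ifelse(totals > 0, detected / totals, NA_real_))
  )
}

#' Overall classification accuracy
#'
#' `ACC = N_detected / N_total`: the confusion-table trace over the grand
#' total — equal, by construction, to the totals-weighted mean of the
#' per-state sensitivities.
#'
#' @param table A [confusion_table()].
#' @return Accuracy in \[0,1\].
#' @export
accuracy <- function(table) {
  stopifnot(inherits(table, "doa_confusion"))
  total <- sum(table)
  if (total == 0) abort("empty confusion table.")
  sum(diag(table)) / total
}

#' Pearson correlation with p-value
#'
#' @param x,y Equal-length numeric series (n >= 3, nonzero variance).
#' @return Tibble with columns `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs.")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) abort("zero variance in input series.")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bland-Altman agreement
#'
#' Bias is the mean of (predicted - reference); the limits of agreement are
#' bias +/- 1.96 times the sample SD (n-1) of the differences.
#'
#' @param reference,predicted Equal-length numeric series.
#' @return Tibble with columns `bias`, `lower`, `upper`, `sd_diff`, `n`.
#' @export
bland_altman <- function(reference, predicted) {
  ok <- is.finite(reference) & is.finite(predicted)
  d <- predicted[ok] - reference[ok]
  if (length(d) < 2) abort("need at least 2 complete pairs.")
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(
    bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
    sd_diff = s, n = length(d)
  )
}

#' Leave-one-subject-out cross-validation of the fusion model
#'
#' For each subject in turn, trains on all other subjects' minutes, predicts
#' the held-out subject, and pools minutes across folds. Metrics
#' (sensitivities, accuracy, Pearson r, Bland-Altman) are computed on the
#' pooled minutes — micro-averaging, matching cohort-level reporting.
#'
#' @param cohort Tibble with columns `subject`, the feature columns, and
#'   `ref_index` (see [cohort_features()]).
#' @param model_kind `"ann"` or `"svr"`.
#' @param hyper [ann_control()] for the ANN.
#' @param seed Integer seed (per-fold training seeds are derived).
#' @param feature_names Feature subset to use (default all four).
#' @param C,epsilon SVR hyperparameters.
#' @return A `doa_evaluation`: list with `pooled` (per-minute tibble),
#'   `confusion`, `sensitivities`, `accuracy`, `pearson`, `bland_altman`,
#'   `per_fold`.
#' @export
loocv <- function(cohort, model_kind = c("ann", "svr"),
                  hyper = ann_control(), seed = 1,
                  feature_names = NULL, C = 10, epsilon = 2) {
  model_kind <- match.arg(model_kind)
  stopifnot(all(c("subject", "ref_index") %in% names(cohort)))
  feature_names <- feature_names %||% intersect(doa_features(), names(cohort))
  subjects <- unique(cohort$subject)
  if (length(subjects) < 3) abort("LOOCV needs at least 3 subjects.")
  seeds <- derive_seeds(seed, length(subjects))
  pooled <- list(); per_fold <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    train <- cohort[cohort$subject != s, , drop = FALSE]
    test <- cohort[cohort$subject == s, , drop = FALSE]
    if (nrow(test) == 0) {
      message(sprintf("fold for subject %s skipped: no valid minutes.", s))
      next
    }
    model <- if (model_kind == "ann") {
      train_doa_ann(train, train$ref_index, hyper = hyper, seed = seeds[i],
                    feature_names = feature_names)
    } else {
      train_doa_svr(train, train$ref_index, C = C, epsilon = epsilon,
                    feature_names = feature_names)
    }
    pred <- predict_index(model, test)
    fold <- tibble::tibble(
      subject = s,
      minute = test$minute %||% (seq_len(nrow(test)) - 1L),
      ref_index = test$ref_index,
      pred_index = pred$index
    )
    pooled[[length(pooled) + 1]] <- fold
    per_fold[[length(per_fold) + 1]] <- tibble::tibble(
      subject = s, n_minutes = nrow(fold),
      fold_accuracy = accuracy(confusion_table(fold$ref_index, fold$pred_index)),
      fold_rmse = sqrt(mean((fold$pred_index - fold$ref_index)^2))
    )
  }
  pooled <- dplyr::bind_rows(pooled)
  pooled$ref_state <- classify_state(pooled$ref_index)
  pooled$pred_state <- classify_state(pooled$pred_index)
  tab <- confusion_table(pooled$ref_state, pooled$pred_state)
  structure(
    list(
      model_kind = model_kind,
      feature_names = feature_names,
      pooled = pooled,
      confusion = tab,
      sensitivities = sensitivity(tab),
      accuracy = accuracy(tab),
      pearson = pearson_r(pooled$ref_index, pooled$pred_index),
      bland_altman = bland_altman(pooled$ref_index, pooled$pred_index),
      per_fold = dplyr::bind_rows(per_fold),
      seed = as.integer(seed)
    ),
    class = "doa_evaluation"
  )
}

#' @export
print.doa_evaluation <- function(x, ...) {
  cat(sprintf(
    "<doa_evaluation: %s on %s> %d folds, %d pooled minutes\n",
    x$model_kind, paste(x$feature_names, collapse = "+"),
    nrow(x$per_fold), nrow(x$pooled)
  ))
  cat(sprintf("  accuracy %.3f | r %.3f | bias %.2f [%.2f, %.2f]\n",
              x$accuracy, x$pearson$r, x$bland_altman$bias,
              x$bland_altman$lower, x$bland_altman$upper))
  print(x$sensitivities)
  invisible(x)
}

#' @export
tidy.doa_evaluation <- function(x, ...) x$sensitivities

#' @export
glance.doa_evaluation <- function(x, ...) {
  tibble::tibble(
    model_kind = x$model_kind,
    n_subjects = nrow(x$per_fold),
    n_minutes = nrow(x$pooled),
    accuracy = x$accuracy,
    pearson_r = x$pearson$r,
    pearson_p = x$pearson$p_value,
    ba_bias = x$bland_altman$bias,
    ba_lower = x$bland_altman$lower,
    ba_upper = x$bland_altman$upper,
    rmse = sqrt(mean((x$pooled$pred_index - x$pooled$ref_index)^2))
  )
}

#' Feature-ablation study
#'
#' Runs [loocv()] for every nonempty subset of the four features (15 runs)
#' and tabulates the pooled accuracies.
#'
#' @inheritParams loocv
#' @param feature_subsets List of character vectors; defaults to all 15
#'   nonempty subsets of `pe`, `br`, `sef95`, `sfs`.
#' @return Tibble with columns `features`, `n_features`, `accuracy`,
#'   `pearson_r`, `rmse`, sorted by descending accuracy.
#' @export
ablation_study <- function(cohort, model_kind = "ann", hyper = ann_control(),
                           seed = 1, feature_subsets = NULL) {
  feats <- doa_features()
  if (is.null(feature_subsets)) {
    feature_subsets <- unlist(
      lapply(seq_along(feats), function(k) {
        asplit(utils::combn(feats, k), 2)
      }),
      recursive = FALSE
    )
    feature_subsets <- lapply(feature_subsets, as.character)
  }
  rows <- purrr::imap(feature_subsets, function(fset, i) {
    ev <- loocv(cohort, model_kind = model_kind, hyper = hyper,
                seed = seed, feature_names = fset)
    g <- glance(ev)
    tibble::tibble(
      features = paste(fset, collapse = "-"),
      n_features = length(fset),
      accuracy = g$accuracy, pearson_r = g$pearson_r, rmse = g$rmse
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$accuracy))
}

#' Permutation-null LOOCV accuracies
#'
#' Shuffles the reference index within each subject and reruns LOOCV,
#' returning the accuracy per shuffle together with the chance agreement
#' rate `p_e = sum_i p_ref(i) * p_pred(i)` computed from the pooled shuffled
#' results (the accuracy expected when predictions are independent of the
#' reference).
#'
#' @inheritParams loocv
#' @param n_shuffles Number of shuffles (default 20).
#' @return Tibble of per-shuffle accuracies with attribute `chance_rate`.
#' @export
permutation_null <- function(cohort, n_shuffles = 20, model_kind = "ann",
                             hyper = ann_control(), seed = 1) {
  seeds <- derive_seeds(seed, n_shuffles)
  ref_tab <- numeric(4); pred_tab <- numeric(4)
  accs <- numeric(n_shuffles)
  for (k in seq_len(n_shuffles)) {
    shuffled <- with_seed(seeds[k], {
      dplyr::group_by(cohort, .data$subject) |>
        dplyr::mutate(ref_index = sample(.data$ref_index)) |>
        dplyr::ungroup()
    })
    ev <- loocv(shuffled, model_kind = model_kind, hyper = hyper,
                seed = seeds[k])
    accs[k] <- ev$accuracy
    ref_tab <- ref_tab + as.numeric(table(ev$pooled$ref_state))
    pred_tab <- pred_tab + as.numeric(table(ev$pooled$pred_state))
  }
  p_e <- sum((ref_tab / sum(ref_tab)) * (pred_tab / sum(pred_tab)))
  structure(
    tibble::tibble(shuffle = seq_len(n_shuffles), accuracy = accs),
    chance_rate = p_e
  )
}

#' Paired comparison of ANN and SVR accuracies
#'
#' Wilcoxon signed-rank test on per-subject fold accuracies from two LOOCV
#' evaluations of the same cohort.
#'
#' @param eval_ann,eval_svr `doa_evaluation` objects over the same subjects.
#' @return Tibble with `mean_acc_ann`, `mean_acc_svr`, `p_value`, `statistic`.
#' @export
compare_models <- function(eval_ann, eval_svr) {
  stopifnot(inherits(eval_ann, "doa_evaluation"),
            inherits(eval_svr, "doa_evaluation"))
  a <- eval_ann$per_fold$fold_accuracy
  b <- eval_svr$per_fold$fold_accuracy
  if (length(a) != length(b)) abort("evaluations cover different subjects.")
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
  tibble::tibble(
    mean_acc_ann = mean(a), mean_acc_svr = mean(b),
    p_value = wt$p.value, statistic = unname(wt$statistic)
  )
}
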