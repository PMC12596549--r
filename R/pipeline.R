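# Evaluation and cross-validation harness -----------------------------------

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with half credit for ties (computed via
#' midranks).
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (both classes must be present).
#' @return AUC in \\[0, 1\\].
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_counts <- function(y, yhat, threshold = 0.5) {
  pred <- as.integer(yhat >= threshold)
  c(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
    TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1))
}

# rates from confusion counts; undefined ratios yield NA, F1 uses the
# 2TP/(2TP+FP+FN) form (defined unless the fold is all correctly-negative)
derive_rates <- function(cm, auc = NA_real_) {
  n <- sum(cm)
  prec <- if (cm["TP"] + cm["FP"] > 0) cm["TP"] / (cm["TP"] + cm["FP"]) else NA_real_
  rec <- if (cm["TP"] + cm["FN"] > 0) cm["TP"] / (cm["TP"] + cm["FN"]) else NA_real_
  spec <- if (cm["TN"] + cm["FP"] > 0) cm["TN"] / (cm["TN"] + cm["FP"]) else NA_real_
  f1 <- if (2 * cm["TP"] + cm["FP"] + cm["FN"] > 0)
    2 * cm["TP"] / (2 * cm["TP"] + cm["FP"] + cm["FN"]) else NA_real_
  c(accuracy = unname((cm["TP"] + cm["TN"]) / n), precision = unname(prec),
    recall = unname(rec), specificity = unname(spec), f1 = unname(f1),
    auc = auc)
}

#' Evaluate a model on a test partition
#'
#' Confusion counts at the 0.5 decision threshold plus accuracy, precision,
#' recall, specificity, F1 and AUC (positive class = disease present).
#'
#' @param model A `model_state`.
#' @param test An `encoded_matrix` carrying labels `y`.
#' @return A `metrics_report`: `confusion`, `rates`, `n`, `scores`.
#' @export
evaluate_model <- function(model, test) {
  if (nrow(test$values) == 0) stop("empty test set")
  yhat <- predict_risk(model, test)
  y <- test$y
  cm <- confusion_counts(y, yhat)
  auc <- if (length(unique(y)) == 2) auc_score(yhat, y) else NA_real_
  rep <- list(confusion = cm, rates = derive_rates(cm, auc),
              n = length(y), scores = yhat, y = y)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report on %d records: TP=%d FP=%d TN=%d FN=%d\n",
              x$n, x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  r <- x$rates
  cat(sprintf("  acc %.3f | prec %.3f | rec %.3f | spec %.3f | F1 %.3f | AUC %.3f\n",
              r["accuracy"], r["precision"], r["recall"], r["specificity"],
              r["f1"], r["auc"]))
  invisible(x)
}

# subgroup F1 / error rate (percent) along the two fairness axes
subgroup_metrics <- function(y, yhat, cohort_rows) {
  axes <- list(
    gender = ifelse(cohort_rows$sex == 1, "male", "female"),
    age = ifelse(cohort_rows$age >= 50, "ge50", "lt50")
  )
  out <- list()
  for (ax in names(axes)) {
    key <- axes[[ax]]
    f1s <- c(); errs <- c()
    for (lev in sort(unique(key))) {
      sel <- key == lev
      if (!any(sel)) next
      cm <- confusion_counts(y[sel], yhat[sel])
      r <- derive_rates(cm)
      f1s[lev] <- 100 * r[["f1"]]
      errs[lev] <- 100 * (cm[["FP"]] + cm[["FN"]]) / sum(sel)
    }
    out$f1[[ax]] <- f1s
    out$error[[ax]] <- errs
  }
  out
}

# fit preprocessing on the training rows only, apply to both partitions
prepare_fold <- function(cohort, train_idx, test_idx, seed) {
  icfg <- imputation_config(seed = seed)
  train_raw <- cohort[train_idx, , drop = FALSE]
  test_raw <- cohort[test_idx, , drop = FALSE]
  train <- fuzzy_impute(train_raw, icfg)
  test <- fuzzy_impute(test_raw, icfg, donors = train)
  num <- uci_numeric_fields()
  scaling <- fit_minmax(as.matrix(as.data.frame(train)[, num]))
  list(train = one_hot_encode(train, scaling = scaling),
       test = one_hot_encode(test, scaling = scaling),
       train_cohort = train, test_cohort = test, scaling = scaling)
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold cross-validation of the full pipeline. In each fold,
#' imputation donors, min-max ranges and demographic weights are fitted on
#' the training folds only and applied unchanged to the held-out fold;
#' every record is tested exactly once. Reports fold-wise metrics with
#' mean and sd, pooled-over-folds confusion counts, and the fairness gaps
#' (mean over folds of subgroup F1 / error-rate differences, in percentage
#' points).
#'
#' @param cohort An `ihd_cohort` (missing values allowed; imputed per fold).
#' @param config A [run_config()].
#' @param checkpoint Optional pretraining checkpoint (a path, a
#'   `model_state`, or `NULL`); used when `config$transfer_checkpoint` is
#'   unset.
#' @param strict Passed to [transfer_init()] when a checkpoint is used.
#' @return A `cv_result`: `fold_metrics` (data frame), `mean`, `sd`,
#'   `pooled` (confusion + rates over pooled counts and pooled scores),
#'   `fairness` (`f1` and `error` gaps), `subgroup_f1` (mean subgroup F1
#'   over folds, percent), `plan`, `config`, `diagnostics`.
#' @export
cross_validate <- function(cohort, config = run_config(), checkpoint = NULL,
                           strict = TRUE) {
  n <- nrow(cohort)
  if (n < config$k) stop("fewer records than folds")
  if (is.null(checkpoint) && !is.null(config$transfer_checkpoint))
    checkpoint <- config$transfer_checkpoint
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)

  plan <- make_folds(cohort, config$k, config$seed)
  fold_rows <- list(); fairness_f1 <- list(); fairness_err <- list()
  diagnostics <- list()
  pooled_cm <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  pooled_scores <- numeric(n); pooled_y <- integer(n)

  for (fold in seq_len(config$k)) {
    test_idx <- which(plan$assignments == fold)
    train_idx <- which(plan$assignments != fold)
    prep <- tryCatch(
      prepare_fold(cohort, train_idx, test_idx, config$seed + fold),
      error = function(e) stop(sprintf("fold %d: %s", fold,
                                       conditionMessage(e)))
    )
    groups <- group_keys(prep$train_cohort)
    weights <- NULL; wtab <- NULL
    if (config$fairness_reweighting) {
      wtab <- inverse_frequency_weights(group_proportions(groups))
      weights <- sample_weights(wtab, groups)
    }
    init <- NULL
    if (!is.null(checkpoint)) {
      fresh <- new_model(d = ncol(prep$train$values),
                         lstm_units = config$lstm_units,
                         lambda = config$lambda,
                         residual_attention = config$residual_attention,
                         pool = config$pool,
                         seed = (config$seed + 1000L * fold) %% .Machine$integer.max,
                         feature_names = colnames(prep$train$values))
      init <- transfer_init(fresh, checkpoint, strict = strict)
    }
    fold_cfg <- config
    fold_cfg$seed <- (config$seed + 1000L * fold) %% .Machine$integer.max
    fit <- train_model(prep$train, fold_cfg, weights = weights, init = init)
    rep <- evaluate_model(fit$model, prep$test)

    pooled_cm <- pooled_cm + rep$confusion
    pooled_scores[test_idx] <- rep$scores
    pooled_y[test_idx] <- rep$y
    fold_rows[[fold]] <- c(fold = fold, rep$confusion, rep$rates)
    sg <- subgroup_metrics(rep$y, rep$scores, prep$test_cohort)
    fairness_f1[[fold]] <- sg$f1
    fairness_err[[fold]] <- sg$error
    diagnostics[[fold]] <- list(test_idx = test_idx,
                                scaling = prep$scaling,
                                weight_table = wtab,
                                loss_trace = fit$loss_trace)
  }

  fm <- as.data.frame(do.call(rbind, fold_rows))
  rate_cols <- c("accuracy", "precision", "recall", "specificity", "f1", "auc")
  pooled <- list(confusion = pooled_cm,
                 rates = derive_rates(pooled_cm,
                                      auc_score(pooled_scores, pooled_y)))

  # per-axis mean subgroup F1 over folds (percent), for table rendering
  sgf <- list()
  for (ax in c("gender", "age")) {
    vals <- lapply(fairness_f1, `[[`, ax)
    levs <- unique(unlist(lapply(vals, names)))
    sgf[[ax]] <- vapply(levs, function(l) {
      v <- vapply(vals, function(x) if (l %in% names(x)) x[[l]] else NA_real_,
                  numeric(1))
      mean(v, na.rm = TRUE)
    }, numeric(1))
  }

  out <- list(fold_metrics = fm,
              mean = colMeans(fm[rate_cols], na.rm = TRUE),
              sd = apply(fm[rate_cols], 2, stats::sd, na.rm = TRUE),
              pooled = pooled,
              fairness = list(f1 = fairness_report(fairness_f1),
                              error = fairness_report(fairness_err)),
              subgroup_f1 = sgf,
              plan = plan, config = config, diagnostics = diagnostics)
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold on %d records\n", x$config$k,
              length(x$plan$assignments)))
  m <- x$mean; s <- x$sd
  for (r in names(m))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", r, m[[r]], s[[r]]))
  cm <- x$pooled$confusion
  cat(sprintf("  pooled confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cm["TP"], cm["FP"], cm["TN"], cm["FN"]))
  cat(sprintf("  dF1(gender)=%.2f pp, dF1(age)=%.2f pp\n",
              x$fairness$f1$gap[["gender"]], x$fairness$f1$gap[["age"]]))
  invisible(x)
}

#' Ablation over the transfer-learning and residual-attention components
#'
#' Runs [cross_validate()] for the four variants {TL, no TL} x {RA, no RA}
#' on identical folds and seeds. The no-RA arms disable the attention mask
#' and feature track (plain BiLSTM + head); the no-TL arms use fresh
#' seeded initialization instead of the checkpoint. The TL/no-RA arm
#' transfers non-strictly, since only the recurrent cells are shared with
#' the full-architecture checkpoint.
#'
#' @param cohort An `ihd_cohort`.
#' @param config A [run_config()].
#' @param checkpoint Pretraining checkpoint (path or `model_state`)
#'   required by the TL arms.
#' @return An `ablation_result`: list of four `cv_result`s keyed by
#'   variant, plus a `summary` data frame of variant flags and headline
#'   rates.
#' @export
ablate <- function(cohort, config = run_config(), checkpoint = NULL) {
  if (is.null(checkpoint)) checkpoint <- config$transfer_checkpoint
  if (is.null(checkpoint))
    stop("ablation needs a pretraining checkpoint for the TL arms")
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  grid <- expand.grid(tl = c(TRUE, FALSE), ra = c(TRUE, FALSE))
  runs <- list(); rows <- list()
  for (i in seq_len(nrow(grid))) {
    tl <- grid$tl[i]; ra <- grid$ra[i]
    cfg <- config
    cfg$residual_attention <- ra
    cfg$transfer_checkpoint <- NULL
    res <- cross_validate(cohort, cfg,
                          checkpoint = if (tl) checkpoint else NULL,
                          strict = ra)
    key <- paste0(if (tl) "TL" else "noTL", "_", if (ra) "RA" else "noRA")
    runs[[key]] <- res
    rows[[key]] <- data.frame(variant = key, transfer_learning = tl,
                              residual_attention = ra,
                              accuracy = res$mean[["accuracy"]],
                              f1 = res$mean[["f1"]],
                              auc = res$mean[["auc"]])
  }
  out <- list(runs = runs,
              summary = do.call(rbind, c(rows, make.row.names = FALSE)))
  class(out) <- "ablation_result"
  out
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("ablation_result:\n")
  print(transform(x$summary, accuracy = round(accuracy, 3),
                  f1 = round(f1, 3), auc = round(auc, 3)))
  invisible(x)
}

#' Write a cross-validation report as JSON
#' @param result A `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(result, path) {
  payload <- list(mean = as.list(result$mean), sd = as.list(result$sd),
                  pooled_confusion = as.list(result$pooled$confusion),
                  pooled_rates = as.list(result$pooled$rates),
                  fairness_gap_f1 = as.list(result$fairness$f1$gap),
                  fairness_gap_error = as.list(result$fairness$error$gap),
                  k = result$config$k)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export ROC coordinates
#'
#' Threshold sweep over the unique scores, yielding (FPR, TPR) pairs.
#' @param scores Prediction scores.
#' @param labels Binary labels.
#' @param path Optional CSV path; when given, coordinates are written there.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_coordinates <- function(scores, labels, path = NULL) {
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  df <- do.call(rbind, lapply(ths, function(th) {
    pred <- scores >= th
    data.frame(threshold = th, fpr = sum(pred & labels == 0) / n0,
               tpr = sum(pred & labels == 1) / n1)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
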