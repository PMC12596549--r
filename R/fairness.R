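# Demographic reweighting and fairness reporting ----------------------------

#' Demographic group proportions
#' @param groups Vector/factor of per-record group keys.
#' @return Named proportions summing to 1.
#' @export
group_proportions <- function(groups) {
  if (length(groups) == 0) stop("no records to compute proportions from")
  groups <- as.character(groups)
  tab <- table(groups)
  p <- as.numeric(tab) / length(groups)
  stats::setNames(p, names(tab))
}

#' Inverse-frequency group weights
#'
#' Raw weights are `w(g) = 1 / p(g)`; they are then rescaled so the mean
#' per-sample weight over the supplied proportions equals 1 (equivalently,
#' total weight N), which keeps the effective learning rate independent of
#' group imbalance while preserving the minority-upweighting ratios.
#'
#' @param p Named group proportions (all > 0, summing to 1).
#' @return A `group_weight_table`: list with `p`, `w` (normalized weights),
#'   `raw_w`, `normalization` (the divisor applied to the raw weights).
#' @export
inverse_frequency_weights <- function(p) {
  if (any(p <= 0)) stop("every group must be present in the training fold (p(g) > 0)")
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  raw <- 1 / p
  # mean per-sample raw weight = sum_g p(g) * (1/p(g)) = number of groups
  z <- sum(p * raw)
  tab <- list(p = p, w = raw / z, raw_w = raw, normalization = z)
  class(tab) <- "group_weight_table"
  tab
}

#' @export
print.group_weight_table <- function(x, ...) {
  df <- data.frame(p = x$p, w = x$w, row.names = names(x$p))
  cat("group_weight_table (mean per-sample weight = 1):\n")
  print(round(df, 4))
  invisible(x)
}

#' Per-sample weights from a group weight table
#' @param table A `group_weight_table`.
#' @param groups Per-record group keys.
#' @return Numeric weight per record.
#' @export
sample_weights <- function(table, groups) {
  groups <- as.character(groups)
  unknown <- setdiff(unique(groups), names(table$w))
  if (length(unknown))
    stop("group(s) absent from the weight table: ",
         paste(unknown, collapse = ", "))
  unname(table$w[groups])
}

#' Fairness-aware reweighted binary cross-entropy
#'
#' `L = -sum_i w_i * (y_i log yhat_i + (1 - y_i) log(1 - yhat_i))`, with
#' probabilities clamped to `[eps, 1 - eps]`. With all weights 1 this is
#' the ordinary summed BCE.
#'
#' @param y Binary labels.
#' @param yhat Predicted probabilities.
#' @param w Per-sample weights (default 1).
#' @param eps Clamping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
reweighted_bce <- function(y, yhat, w = rep(1, length(y)), eps = 1e-7) {
  if (length(y) != length(yhat) || length(y) != length(w))
    stop("y, yhat and w must have equal length")
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  -sum(w * (y * log(yhat) + (1 - y) * log(1 - yhat)))
}

#' Fairness gaps from per-fold subgroup metrics
#'
#' For each axis (e.g. gender, age bin), the per-fold gap is the maximum
#' pairwise absolute difference of the subgroup metric in that fold; the
#' reported gap is the mean over folds. Folds in which a subgroup has no
#' test records are excluded for that axis and listed in `excluded_folds`.
#'
#' @param per_fold A list (one element per fold) of lists keyed by axis,
#'   each a named numeric vector of subgroup metric values (e.g.
#'   `list(gender = c(male = 98.5, female = 97.9))`). A single such list is
#'   also accepted and treated as one fold.
#' @return A `fairness_gap` object: per-axis `gap` (mean over usable
#'   folds), `fold_gaps`, `excluded_folds`.
#' @export
fairness_report <- function(per_fold) {
  if (!is.list(per_fold)) stop("per_fold must be a list")
  if (length(per_fold) && !is.list(per_fold[[1]])) per_fold <- list(per_fold)
  axes <- unique(unlist(lapply(per_fold, names)))
  gaps <- list(); fold_gaps <- list(); excluded <- list()
  for (ax in axes) {
    gs <- numeric(0); excl <- integer(0)
    for (i in seq_along(per_fold)) {
      v <- per_fold[[i]][[ax]]
      if (is.null(v) || anyNA(v) || length(v) < 2) {
        excl <- c(excl, i)
        next
      }
      gs <- c(gs, max(stats::dist(matrix(v, ncol = 1))))
    }
    fold_gaps[[ax]] <- gs
    excluded[[ax]] <- excl
    gaps[[ax]] <- if (length(gs)) mean(gs) else NA_real_
  }
  out <- list(gap = unlist(gaps), fold_gaps = fold_gaps,
              excluded_folds = excluded)
  class(out) <- "fairness_gap"
  out
}

#' @export
print.fairness_gap <- function(x, ...) {
  cat("fairness gaps (mean over folds of max pairwise |difference|):\n")
  for (ax in names(x$gap)) {
    nexcl <- length(x$excluded_folds[[ax]])
    cat(sprintf("  %-8s %6.3f  (%d fold(s)%s)\n", ax, x$gap[[ax]],
                length(x$fold_gaps[[ax]]),
                if (nexcl) sprintf(", %d excluded", nexcl) else ""))
  }
  invisible(x)
}

#' Render a subgroup fairness table
#'
#' Text table of subgroup F1 (percent) and the per-axis gaps, in the layout
#' of a clinical fairness evaluation.
#' @param subgroup_f1 Named numeric vector of subgroup F1 values (percent).
#' @param gaps A `fairness_gap` (or named numeric of per-axis gaps).
#' @return Character vector of table lines, invisibly printed.
#' @export
format_fairness_table <- function(subgroup_f1, gaps) {
  if (inherits(gaps, "fairness_gap")) gaps <- gaps$gap
  lines <- c(sprintf("%-12s %10s", "Subgroup", "F1 (%)"),
             sprintf("%-12s %10.1f", names(subgroup_f1), subgroup_f1),
             sprintf("%-12s %10.1f", paste0("dF1 (", names(gaps), ")"), gaps))
  cat(lines, sep = "\n")
  invisible(lines)
}
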