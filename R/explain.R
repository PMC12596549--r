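# Shapley-value attribution --------------------------------------------------
#
# Interventional Shapley values over ORIGINAL features: the one-hot columns
# of a categorical move in and out of coalitions together.  The value of a
# coalition S is the model output averaged over the background set with the
# columns of S pinned to the explained record.  Exact mode enumerates all
# 2^p coalitions (the oracle); sampled mode averages marginal contributions
# over random feature permutations, which telescopes to exact additivity
# per permutation.

feature_groups <- function(feature_of_column) {
  feats <- unique(feature_of_column)
  stats::setNames(lapply(feats, function(f) which(feature_of_column == f)),
                  feats)
}

coalition_value <- function(f, background, x, cols) {
  Z <- background
  if (length(cols)) Z[, cols] <- matrix(x[cols], nrow(Z), length(cols),
                                        byrow = TRUE)
  mean(f(Z))
}

#' Shapley attribution of one prediction
#'
#' Explains `f(x)` as `base_value + sum_j phi_j`, where `phi_j` is the
#' Shapley value of original feature j under background-marginal
#' replacement of absent features. One-hot blocks of a categorical are
#' treated as a single player.
#'
#' @param model A `model_state` or any function mapping an n x d matrix to
#'   n predictions.
#' @param background Background sample: an `encoded_matrix` or plain
#'   matrix. For a trained model use (up to) 100 seeded training-fold
#'   records.
#' @param x The encoded record to explain (length-d numeric).
#' @param mode `"exact"` (full 2^p enumeration; requires p <= 12 features)
#'   or `"sampled"` (permutation sampling).
#' @param feature_of_column Character vector mapping encoded columns to
#'   original features; taken from `background` when it is an
#'   `encoded_matrix`, else every column is its own feature.
#' @param n_perm Number of permutations in sampled mode.
#' @param seed Seed for sampled mode.
#' @return A `shap_attribution`: `base_value`, `phi` (named per original
#'   feature), `prediction`, `mode`.
#' @export
shap_attribute <- function(model, background, x,
                           mode = c("exact", "sampled"),
                           feature_of_column = NULL, n_perm = 200L,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(background, "encoded_matrix")) {
    if (is.null(feature_of_column)) feature_of_column <- background$feature_of_column
    background <- background$values
  }
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("background set must be nonempty")
  x <- as.numeric(x)
  if (length(x) != ncol(background)) stop("x and background widths differ")
  if (is.null(feature_of_column))
    feature_of_column <- colnames(background) %||% paste0("f", seq_along(x))
  f <- if (inherits(model, "model_state")) {
    function(m) predict_risk(model, m)
  } else model
  groups <- feature_groups(feature_of_column)
  p <- length(groups)

  if (mode == "exact") {
    if (p > 12)
      stop("exact mode enumerates 2^p coalitions and is limited to 12 ",
           "features; use mode = 'sampled'")
    nsub <- bitwShiftL(1L, p)
    vals <- numeric(nsub)
    for (s in 0:(nsub - 1L)) {
      members <- which(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      cols <- unlist(groups[members], use.names = FALSE)
      vals[s + 1L] <- coalition_value(f, background, x, cols)
    }
    phi <- numeric(p)
    lf <- lgamma(seq_len(p + 1))  # lgamma(k+1) = log(k!)
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      for (s in 0:(nsub - 1L)) {
        if (bitwAnd(s, bit) != 0L) next
        k <- sum(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
        w <- exp(lf[k + 1] + lf[p - k] - lf[p + 1])
        phi[j] <- phi[j] + w * (vals[bitwOr(s, bit) + 1L] - vals[s + 1L])
      }
    }
    base <- vals[1L]
  } else {
    base <- coalition_value(f, background, x, integer(0))
    phi <- numeric(p)
    perms <- with_seed(seed, replicate(n_perm, sample(p), simplify = FALSE))
    for (perm in perms) {
      cols <- integer(0)
      v_prev <- base
      for (j in perm) {
        cols <- c(cols, groups[[j]])
        v_new <- coalition_value(f, background, x, cols)
        phi[j] <- phi[j] + (v_new - v_prev)
        v_prev <- v_new
      }
    }
    phi <- phi / n_perm
  }
  out <- list(base_value = base,
              phi = stats::setNames(phi, names(groups)),
              prediction = as.numeric(f(matrix(x, 1))),
              mode = mode)
  class(out) <- "shap_attribution"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("shap_attribution (%s): base %.4f, prediction %.4f\n",
              x$mode, x$base_value, x$prediction))
  ord <- order(abs(x$phi), decreasing = TRUE)
  for (j in utils::head(ord, 8))
    cat(sprintf("  %-10s %+.4f\n", names(x$phi)[j], x$phi[j]))
  invisible(x)
}

#' Global feature importance from a set of attributions
#'
#' Mean absolute Shapley value per feature, sorted descending; ties keep
#' the original (schema) feature order.
#'
#' @param attributions List of `shap_attribution` objects over the same
#'   feature set.
#' @return Data frame with `feature` and `mean_abs_phi`, ranked.
#' @export
global_importance <- function(attributions) {
  if (length(attributions) == 0) stop("need at least one attribution")
  feats <- names(attributions[[1]]$phi)
  for (a in attributions)
    if (!identical(names(a$phi), feats))
      stop("attributions have inconsistent feature sets")
  mat <- vapply(attributions, function(a) abs(a$phi), numeric(length(feats)))
  mean_abs <- if (is.matrix(mat)) rowMeans(mat) else mat
  ord <- order(-mean_abs, seq_along(feats))
  data.frame(feature = feats[ord], mean_abs_phi = unname(mean_abs[ord]),
             row.names = NULL)
}

#' Serialize attributions
#' @param attribution A `shap_attribution`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_attribution <- function(attribution, path) {
  jsonlite::write_json(list(base_value = attribution$base_value,
                            phi = as.list(attribution$phi),
                            prediction = attribution$prediction,
                            mode = attribution$mode),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_attribution
#' @param importance A data frame from [global_importance()].
#' @export
write_global_importance <- function(importance, path) {
  utils::write.csv(importance, path, row.names = FALSE)
  invisible(path)
}
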