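# UCI CSV dialect I/O ------------------------------------------------------

#' Read a UCI processed heart-disease CSV
#'
#' Supports the classic headerless 14-field dialect (fields in schema order,
#' `?` marking missing) and a headered variant. Original disease severities
#' 1-4 in the target column are binarized to 1.
#'
#' @param path Path to the file.
#' @param dialect `"headerless"` (classic processed file) or `"headered"`.
#' @return A validated `ihd_cohort`; `?` fields become explicit `NA`.
#' @export
read_uci_csv <- function(path, dialect = c("headerless", "headered")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = dialect == "headered",
                        na.strings = "?", strip.white = TRUE,
                        colClasses = "character")
  if (ncol(df) != 14)
    stop(sprintf("expected 14 fields per row, found %d", ncol(df)))
  names(df) <- uci_field_names()
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad))
      stop(sprintf("row %d: non-numeric value '%s' in field '%s'",
                   bad[1], df[[j]][bad[1]], names(df)[j]))
    df[[j]] <- v
  }
  # some processed files carry float-coded categoricals ("3.0"); target 1-4 -> 1
  df$target <- as.integer(df$target > 0)
  cohort <- as_ihd_cohort(df)
  validate_cohort(cohort)
  cohort
}

#' Write a cohort in the UCI CSV dialect
#'
#' @param cohort An `ihd_cohort`.
#' @param path Output path.
#' @param dialect `"headerless"` (no header, `?` for missing) or `"headered"`.
#' @return `path`, invisibly.
#' @export
write_uci_csv <- function(cohort, path, dialect = c("headerless", "headered")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(cohort)
  for (j in seq_along(df)) {
    v <- ifelse(is.na(df[[j]]), "?", format(df[[j]], trim = TRUE,
                                            scientific = FALSE))
    df[[j]] <- v
  }
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = dialect == "headered")
  invisible(path)
}

#' Count explicitly missing entries in one field
#' @param cohort An `ihd_cohort`.
#' @param field Field name from the schema.
#' @return Integer count of records with that field missing.
#' @export
count_missing <- function(cohort, field) {
  if (!field %in% uci_field_names()) stop("unknown field: ", field)
  sum(is.na(cohort[[field]]))
}

# Min-max scaling -----------------------------------------------------------

#' Fit and apply min-max scaling
#'
#' `fit_minmax` learns per-column minima and maxima on the training
#' partition only; `transform_minmax` maps to `(x - Xmin) / (Xmax - Xmin)`
#' and clips to `[0, 1]`, so train columns land exactly in `[0, 1]` and
#' out-of-range test values stay inside the model-input contract. A
#' constant training column maps to 0.
#'
#' @param x Numeric matrix (records x numeric features), column names kept.
#' @return `fit_minmax`: a `minmax_scaling` list with `min` and `max`;
#'   `transform_minmax`: the scaled matrix.
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("scaling input must be complete (impute first)")
  sc <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  class(sc) <- "minmax_scaling"
  sc
}

#' @rdname fit_minmax
#' @param scaling A fitted `minmax_scaling`.
#' @export
transform_minmax <- function(x, scaling) {
  x <- as.matrix(x)
  stopifnot(inherits(scaling, "minmax_scaling"),
            identical(colnames(x), names(scaling$min)))
  rng <- scaling$max - scaling$min
  out <- sweep(x, 2, scaling$min)
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  pmin(pmax(out, 0), 1)
}

# One-hot encoding ----------------------------------------------------------

#' One-hot encode a complete cohort into a design matrix
#'
#' Numeric fields pass through (optionally min-max scaled via `scaling`);
#' two-level categoricals (`sex`, `fbs`, `exang`) pass through as single
#' 0/1 columns; multi-level categoricals expand to one indicator column per
#' domain level. Column order is schema order, then domain order, so the
#' encoded layout is identical across cohorts.
#'
#' @param cohort A complete `ihd_cohort` (no missing predictors).
#' @param scaling Optional `minmax_scaling` fitted on a training partition;
#'   if `NULL` numeric columns pass through unscaled.
#' @return An `encoded_matrix`: list with `values` (n x d matrix), `feature_names`,
#'   `feature_of_column` (source field per column), `encoding_map`
#'   (field -> domain), `scaling`, and `y` (target vector).
#' @export
one_hot_encode <- function(cohort, scaling = NULL) {
  validate_cohort(cohort, allow_missing = FALSE)
  doms <- uci_categorical_domains()
  passthrough <- c("sex", "fbs", "exang")
  n <- nrow(cohort)
  cols <- list(); of <- character(0)
  for (f in uci_predictors()) {
    if (f %in% uci_numeric_fields() || f %in% passthrough) {
      cols[[f]] <- matrix(cohort[[f]], ncol = 1,
                          dimnames = list(NULL, f))
      of <- c(of, f)
    } else {
      dom <- doms[[f]]
      bad <- setdiff(unique(cohort[[f]]), dom)
      if (length(bad))
        stop(sprintf("unseen category %s in field '%s'", bad[1], f))
      m <- outer(cohort[[f]], dom, `==`) * 1
      colnames(m) <- paste0(f, "_", dom)
      cols[[f]] <- m
      of <- c(of, rep(f, length(dom)))
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- NULL
  if (!is.null(scaling)) {
    num <- uci_numeric_fields()
    values[, num] <- transform_minmax(values[, num, drop = FALSE], scaling)
  }
  out <- list(values = values,
              feature_names = colnames(values),
              feature_of_column = of,
              encoding_map = doms[setdiff(names(doms), passthrough)],
              scaling = scaling,
              y = cohort$target)
  class(out) <- "encoded_matrix"
  out
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("encoded_matrix: %d records x %d columns (%s scaled)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$scaling)) "not" else "min-max"))
  invisible(x)
}

#' Recover original categories from an encoded matrix
#'
#' Inverse of the one-hot expansion for a single categorical field.
#' @param encoded An `encoded_matrix`.
#' @param field A multi-level categorical field name.
#' @return Vector of category values.
#' @export
decode_categorical <- function(encoded, field) {
  dom <- encoded$encoding_map[[field]]
  if (is.null(dom)) stop("not an expanded categorical field: ", field)
  block <- encoded$values[, paste0(field, "_", dom), drop = FALSE]
  dom[max.col(block)]
}

# Fold construction ---------------------------------------------------------

#' Build a stratified k-fold plan
#'
#' Records are shuffled within each target class and dealt cyclically to
#' folds with a fold pointer that continues across classes, so fold sizes
#' differ by at most one record overall and per class.
#'
#' @param cohort An `ihd_cohort` (only `target` is used).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `fold_plan`: list with `k`, `assignments` (fold index per
#'   record), `seed`, `stratified = TRUE`.
#' @export
make_folds <- function(cohort, k, seed = 1L) {
  n <- nrow(cohort)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k must not exceed the number of records")
  assignments <- integer(n)
  with_seed(seed, {
    ptr <- 0L
    for (cls in sort(unique(cohort$target))) {
      idx <- sample(which(cohort$target == cls))
      assignments[idx] <- ((ptr + seq_along(idx) - 1L) %% k) + 1L
      ptr <- (ptr + length(idx)) %% k
    }
  })
  plan <- list(k = as.integer(k), assignments = assignments,
               seed = as.integer(seed), stratified = TRUE)
  class(plan) <- "fold_plan"
  plan
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: k=%d, n=%d, sizes %s\n", x$k, length(x$assignments),
              paste(tabulate(x$assignments, x$k), collapse = "/")))
  invisible(x)
}

#' Serialize / read a fold plan as JSON
#' @param plan A `fold_plan`.
#' @param path File path.
#' @return `write_fold_plan` returns `path` invisibly; `read_fold_plan` a
#'   `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  plan <- jsonlite::read_json(path, simplifyVector = TRUE)
  plan$k <- as.integer(plan$k)
  plan$assignments <- as.integer(plan$assignments)
  class(plan) <- "fold_plan"
  plan
}
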