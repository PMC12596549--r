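# Fuzzy-membership multiple imputation --------------------------------------
#
# Each missing cell is filled from donor records that are complete on the
# target field.  Donor relevance is a fuzzy membership: a Gaussian kernel of
# the normalized Euclidean distance over the features that query and donor
# both observe (min-max-normalized numerics, simple-matching categoricals).
# Numeric cells are the membership-weighted donor mean, averaged over m
# seeded draws of the donor pool; categorical cells take the category with
# the largest total membership, so imputed values always stay inside the
# observed category set.

#' Configuration for fuzzy multiple imputation
#'
#' @param m Number of imputation draws pooled per cell (>= 1).
#' @param kernel_bandwidth Bandwidth of the Gaussian membership kernel on
#'   normalized distances (> 0). Large bandwidths flatten the weights
#'   toward the plain donor mean.
#' @param k_donors Donor pool size per draw; `Inf` (default) uses every
#'   complete donor, making the m draws identical and the imputation
#'   deterministic apart from the seed-stable donor ordering.
#' @param seed Integer seed for donor subsampling.
#' @return An `imputation_config`.
#' @export
imputation_config <- function(m = 5L, kernel_bandwidth = 1, k_donors = Inf,
                              seed = 1L) {
  if (m < 1) stop("m must be >= 1")
  if (kernel_bandwidth <= 0) stop("kernel_bandwidth must be positive")
  if (k_donors < 1) stop("k_donors must be >= 1")
  cfg <- list(m = as.integer(m), kernel_bandwidth = kernel_bandwidth,
              k_donors = k_donors, seed = as.integer(seed))
  class(cfg) <- "imputation_config"
  cfg
}

# normalized distance matrix between one query row and donor rows over
# co-observed predictors; numerics min-max normalized on the pooled values
record_distances <- function(query, donors) {
  num <- uci_numeric_fields()
  cats <- setdiff(uci_predictors(), num)
  d2 <- numeric(nrow(donors))
  used <- 0L
  for (f in uci_predictors()) {
    q <- query[[f]]
    if (is.na(q)) next
    v <- donors[[f]]
    ok <- !is.na(v)
    if (!any(ok)) next
    if (f %in% num) {
      pool <- c(q, v[ok])
      rng <- diff(range(pool))
      contrib <- if (rng > 0) ((v - q) / rng)^2 else numeric(length(v))
    } else {
      contrib <- as.numeric(v != q)
    }
    contrib[!ok] <- 0   # unobserved donor fields contribute no distance
    d2 <- d2 + contrib
    used <- used + 1L
  }
  if (used == 0L) return(rep(0, nrow(donors)))
  sqrt(d2 / used)
}

#' Fuzzy membership weights of donors for one query record
#'
#' Gaussian kernel `exp(-dist^2 / (2 bw^2))` of the normalized Euclidean
#' distance over co-observed features, renormalized to sum to 1.
#'
#' @param query A single-row data.frame / list with the schema predictors.
#' @param donors An `ihd_cohort` (or data.frame) of candidate donors.
#' @param config An [imputation_config()] (only the bandwidth is used).
#' @return Numeric weight per donor, summing to 1; weights decrease with
#'   distance from the query.
#' @export
membership_weights <- function(query, donors, config = imputation_config()) {
  if (nrow(donors) == 0) stop("empty donor pool")
  d <- record_distances(query, donors)
  w <- exp(-d^2 / (2 * config$kernel_bandwidth^2))
  if (sum(w) == 0) w <- rep(1, length(w))
  w / sum(w)
}

#' Impute all missing predictor values in a cohort
#'
#' Applies the fuzzy-membership multiple-imputation rule cell by cell.
#' Observed values are never touched; an already-complete cohort is
#' returned unchanged.
#'
#' @param cohort An `ihd_cohort`, possibly with missing predictors.
#' @param config An [imputation_config()].
#' @param donors Optional donor cohort (defaults to `cohort` itself). In
#'   cross-validation the training partition is passed here when completing
#'   test records, so no test statistic leaks into the fill values.
#' @return The completed `ihd_cohort`.
#' @export
fuzzy_impute <- function(cohort, config = imputation_config(), donors = NULL) {
  if (is.null(donors)) donors <- cohort
  miss <- which(is.na(as.data.frame(cohort)[, uci_predictors()]), arr.ind = TRUE)
  if (nrow(miss) == 0) return(cohort)
  draw_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max, config$m))
  fields <- uci_predictors()[miss[, 2]]
  for (j in seq_len(nrow(miss))) {
    i <- miss[j, 1]; f <- fields[j]
    cohort[[f]][i] <- impute_one_cell_from(cohort, donors, i, f, config,
                                           draw_seeds)
  }
  validate_cohort(cohort, allow_missing = FALSE)
  cohort
}

impute_one_cell_from <- function(cohort, donors, i, field, config, draw_seeds) {
  pool_all <- donors[!is.na(donors[[field]]), , drop = FALSE]
  if (nrow(pool_all) == 0)
    stop(sprintf("record %d: field '%s' has no complete donors", i, field))
  query <- cohort[i, , drop = FALSE]
  is_num <- field %in% uci_numeric_fields()
  vals <- numeric(config$m)
  cat_tally <- NULL
  for (r in seq_len(config$m)) {
    pool <- pool_all
    if (is.finite(config$k_donors) && config$k_donors < nrow(pool_all)) {
      keep <- with_seed((draw_seeds[r] + i) %% .Machine$integer.max,
                        sample(nrow(pool_all), config$k_donors))
      pool <- pool_all[keep, , drop = FALSE]
    }
    w <- membership_weights(query, pool, config)
    if (is_num) {
      vals[r] <- sum(w * pool[[field]])
    } else {
      tl <- tapply(w, factor(pool[[field]]), sum)
      if (is.null(cat_tally)) cat_tally <- tl
      else {
        lv <- union(names(cat_tally), names(tl))
        out <- stats::setNames(rep(0, length(lv)), lv)
        out[names(cat_tally)] <- cat_tally
        out[names(tl)] <- out[names(tl)] + tl
        cat_tally <- out
      }
    }
  }
  if (is_num) {
    v <- mean(vals)
    min(max(v, min(pool_all[[field]])), max(pool_all[[field]]))
  } else {
    best <- names(cat_tally)[cat_tally >= max(cat_tally) - 1e-12]
    as.numeric(min(as.numeric(best)))
  }
}

# Post-imputation validation -------------------------------------------------

#' Compare distributional statistics before and after imputation
#'
#' Per-predictor change in mean and variance (observed cases before vs the
#' completed column after) and the largest absolute change in pairwise
#' feature correlations (pairwise-complete before vs complete after), with
#' every predictor coerced to its numeric code.
#'
#' @param before Cohort prior to imputation (may contain missing values).
#' @param after The completed cohort (same records, same schema).
#' @return An `imputation_report`: `delta_mean`, `delta_variance`,
#'   `max_abs_delta_r`, `imputed_counts`.
#' @export
imputation_report <- function(before, after) {
  if (nrow(before) != nrow(after)) stop("record count mismatch")
  if (!identical(names(before), names(after))) stop("schema mismatch")
  preds <- uci_predictors()
  b <- as.matrix(as.data.frame(before)[, preds])
  a <- as.matrix(as.data.frame(after)[, preds])
  dmean <- colMeans(a) - colMeans(b, na.rm = TRUE)
  dvar <- apply(a, 2, stats::var) - apply(b, 2, stats::var, na.rm = TRUE)
  suppressWarnings({
    rb <- stats::cor(b, use = "pairwise.complete.obs")
    ra <- stats::cor(a)
  })
  dr <- abs(ra - rb)
  dr[!is.finite(dr)] <- 0   # constant columns / empty pairs carry no signal
  counts <- colSums(is.na(b)) - colSums(is.na(a))
  rep <- list(delta_mean = dmean, delta_variance = dvar,
              max_abs_delta_r = max(dr), imputed_counts = counts)
  class(rep) <- "imputation_report"
  rep
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("imputation_report: %d cell(s) imputed, max |delta r| = %.4f\n",
              sum(x$imputed_counts), x$max_abs_delta_r))
  changed <- names(x$imputed_counts)[x$imputed_counts > 0]
  for (f in changed)
    cat(sprintf("  %s: n=%d  delta mean %+0.4f  delta var %+0.4f\n", f,
                x$imputed_counts[[f]], x$delta_mean[[f]], x$delta_variance[[f]]))
  invisible(x)
}

#' Serialize an imputation report as JSON
#' @param report An `imputation_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_imputation_report <- function(report, path) {
  jsonlite::write_json(lapply(unclass(report), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
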