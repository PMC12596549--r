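# Synthetic cohort generation ---------------------------------------------
#
# Cohorts are drawn from fixed marginals per predictor (means/spreads chosen
# to resemble published summaries of the Cleveland heart-disease cohort) and
# a linear logistic risk model on centred per-feature scores.  Demographic
# disparity is injected only through `bias_shift`, a per-group additive
# log-odds offset, so that with bias_shift = 0 all demographic subgroups
# share the same outcome rate by construction.

#' Specification of a synthetic cohort
#'
#' @param n Number of records (>= 0).
#' @param seed Integer seed; identical specs (including seed) generate
#'   byte-identical cohorts.
#' @param prevalence Target base rate of the binary outcome, in (0, 1). The
#'   intercept of the generative logistic model is calibrated so the
#'   expected outcome rate equals this value.
#' @param group_mix Named proportions over the four demographic groups
#'   (`F.lt50`, `F.ge50`, `M.lt50`, `M.ge50`), summing to 1.
#' @param risk_coefficients Named per-feature log-odds effects applied to
#'   centred feature scores. Defaults emphasize cp, oldpeak, thal and
#'   thalach; sex and age default to 0 so demographics carry no direct
#'   effect.
#' @param bias_shift Named per-group additive log-odds offset (unfairness
#'   injection); default all 0.
#' @param missing_rates Named per-field missingness probabilities (MCAR).
#'   Default: small rates on `thal` and `ca` only, matching the fields that
#'   carry missingness in the public Cleveland file.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 303L,
                        seed = 1L,
                        prevalence = 0.46,
                        group_mix = c(F.lt50 = 0.09, F.ge50 = 0.23,
                                      M.lt50 = 0.22, M.ge50 = 0.46),
                        risk_coefficients = default_risk_coefficients(),
                        bias_shift = c(F.lt50 = 0, F.ge50 = 0,
                                       M.lt50 = 0, M.ge50 = 0),
                        missing_rates = c(thal = 2 / 303, ca = 4 / 303)) {
  spec <- list(n = as.integer(n), seed = as.integer(seed),
               prevalence = prevalence,
               group_mix = group_mix,
               risk_coefficients = risk_coefficients,
               bias_shift = bias_shift,
               missing_rates = missing_rates)
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: n=%d seed=%d prevalence=%.2f\n",
              x$n, x$seed, x$prevalence))
  cat("  group_mix:", paste(sprintf("%s=%.2f", names(x$group_mix), x$group_mix),
                            collapse = " "), "\n")
  if (any(x$bias_shift != 0))
    cat("  bias_shift:", paste(sprintf("%s=%+.2f", names(x$bias_shift),
                                       x$bias_shift), collapse = " "), "\n")
  invisible(x)
}

#' Default generative risk coefficients
#'
#' Log-odds effects on centred feature scores. Chest-pain type, ST
#' depression, thalassemia status and maximum heart rate dominate; sex and
#' age are 0 so that subgroup outcome rates coincide unless `bias_shift`
#' says otherwise.
#' @return Named numeric vector over the 13 predictors.
#' @export
default_risk_coefficients <- function() {
  c(age = 0, sex = 0, cp = 1.6, trestbps = 0.3, chol = 0.3, fbs = 0,
    restecg = 0.1, thalach = -1.2, exang = 0.7, oldpeak = 1.5,
    slope = 0.4, ca = 0.9, thal = 1.3)
}

validate_cohort_spec <- function(spec) {
  if (is.na(spec$n) || spec$n < 0) stop("n must be a non-negative integer")
  if (!(spec$prevalence > 0 && spec$prevalence < 1))
    stop("prevalence must lie in (0, 1)")
  gm <- spec$group_mix
  if (is.null(names(gm)) || !setequal(names(gm), levels(group_keys(data.frame(sex = 1, age = 60)))))
    stop("group_mix must be named over F.lt50, F.ge50, M.lt50, M.ge50")
  if (any(gm < 0) || abs(sum(gm) - 1) > 1e-9)
    stop("group_mix proportions must be non-negative and sum to 1")
  mr <- spec$missing_rates
  if (length(mr)) {
    if (is.null(names(mr)) || !all(names(mr) %in% uci_predictors()))
      stop("missing_rates must be named over schema predictors")
    if (any(mr < 0 | mr > 1)) stop("missing_rates must lie in [0, 1]")
  }
  rc <- spec$risk_coefficients
  if (is.null(names(rc)) || !all(names(rc) %in% uci_predictors()))
    stop("risk_coefficients must be named over schema predictors")
  invisible(spec)
}

# run expr under a private RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# fixed reference centring used by the generative model (NOT data-fitted);
# (centre, half-spread) per numeric field
risk_reference <- function() {
  list(age = c(54, 9), trestbps = c(131, 17), chol = c(246, 52),
       thalach = c(150, 23), oldpeak = c(1.0, 1.1))
}

# centred per-feature scores in roughly [-1, 1]
feature_scores <- function(df) {
  ref <- risk_reference()
  s <- data.frame(row.names = seq_len(nrow(df)))
  for (f in names(ref)) s[[f]] <- (df[[f]] - ref[[f]][1]) / ref[[f]][2]
  s$sex <- df$sex - 0.5
  s$fbs <- df$fbs - 0.5
  s$exang <- df$exang - 0.5
  s$cp <- (df$cp - 2.5) / 1.5
  s$restecg <- df$restecg - 1
  s$slope <- df$slope - 2
  s$ca <- (df$ca - 1.5) / 1.5
  s$thal <- c(`3` = -0.5, `6` = 0, `7` = 0.5)[as.character(df$thal)]
  s[, uci_predictors()]
}

# marginal sampler; `mean_shift` moves numeric means (pretraining corpus)
sample_predictors <- function(n, group_mix, mean_shift = NULL) {
  groups <- sample(names(group_mix), n, replace = TRUE, prob = group_mix)
  sexbit <- as.integer(startsWith(groups, "M"))
  ge50 <- endsWith(groups, "ge50")
  ms <- function(f) if (!is.null(mean_shift) && f %in% names(mean_shift))
    mean_shift[[f]] else 0

  clipr <- function(x, f) {
    r <- uci_numeric_ranges()[[f]]
    pmin(pmax(x, r[1]), r[2])
  }
  age <- ifelse(ge50,
                round(clipr(stats::rnorm(n, 58 + ms("age"), 6), "age")),
                round(clipr(stats::rnorm(n, 44 + ms("age"), 4), "age")))
  age <- ifelse(ge50, pmax(age, 50), pmin(age, 49))
  df <- data.frame(
    age = age,
    sex = sexbit,
    cp = sample(1:4, n, TRUE, prob = c(0.08, 0.17, 0.28, 0.47)),
    trestbps = round(clipr(stats::rnorm(n, 131 + ms("trestbps"), 17), "trestbps")),
    chol = round(clipr(stats::rnorm(n, 246 + ms("chol"), 52), "chol")),
    fbs = stats::rbinom(n, 1, 0.15),
    restecg = sample(0:2, n, TRUE, prob = c(0.50, 0.02, 0.48)),
    thalach = round(clipr(stats::rnorm(n, 150 + ms("thalach"), 23), "thalach")),
    exang = stats::rbinom(n, 1, 0.33),
    oldpeak = round(clipr(pmax(stats::rnorm(n, 0.9 + ms("oldpeak"), 1.1), 0), "oldpeak"), 1),
    slope = sample(1:3, n, TRUE, prob = c(0.46, 0.46, 0.08)),
    ca = sample(0:3, n, TRUE, prob = c(0.59, 0.21, 0.13, 0.07)),
    thal = sample(c(3, 6, 7), n, TRUE, prob = c(0.55, 0.06, 0.39))
  )
  list(df = df, groups = groups)
}

# calibrate the intercept so mean(plogis(b0 + lp)) == prevalence
calibrate_intercept <- function(lp, prevalence) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

generate_cohort_impl <- function(spec, mean_shift = NULL, coef_shift = NULL) {
  validate_cohort_spec(spec)
  n <- spec$n
  if (n == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), 14),
                                        uci_field_names()))
    return(as_ihd_cohort(df))
  }
  rc <- spec$risk_coefficients
  if (!is.null(coef_shift)) {
    idx <- intersect(names(coef_shift), names(rc))
    rc[idx] <- rc[idx] + unlist(coef_shift[idx])
  }
  with_seed(spec$seed, {
    sp <- sample_predictors(n, spec$group_mix, mean_shift)
    df <- sp$df
    sc <- feature_scores(df)
    beta <- stats::setNames(rep(0, length(uci_predictors())), uci_predictors())
    beta[names(rc)] <- rc
    lp <- as.numeric(as.matrix(sc) %*% beta)
    lp <- lp + unname(spec$bias_shift[sp$groups])
    b0 <- calibrate_intercept(lp, spec$prevalence)
    df$target <- stats::rbinom(n, 1, stats::plogis(b0 + lp))
    # MCAR masking, restricted to fields named in missing_rates
    for (f in names(spec$missing_rates)) {
      r <- spec$missing_rates[[f]]
      if (r > 0) df[[f]][stats::runif(n) < r] <- NA
    }
    cohort <- as_ihd_cohort(df)
    attr(cohort, "spec") <- spec
    validate_cohort(cohort)
    cohort
  })
}

#' Generate a synthetic UCI-schema cohort
#'
#' Draws `spec$n` records from fixed predictor marginals; the binary target
#' follows a logistic model on centred feature scores with an intercept
#' calibrated to `spec$prevalence`, plus each record's group `bias_shift`.
#' Missing entries (explicit `NA`) are masked completely at random per
#' `spec$missing_rates`.
#'
#' @param spec A [cohort_spec()].
#' @return An `ihd_cohort` data.frame (14 schema columns), with the spec
#'   attached as attribute `"spec"`.
#' @examples
#' co <- generate_cohort(cohort_spec(n = 50, seed = 7))
#' table(co$target)
#' @export
generate_cohort <- function(spec) generate_cohort_impl(spec)

#' Generate a source-domain corpus for transfer learning
#'
#' Same schema and generative family as [generate_cohort()], but with
#' shifted numeric means and/or perturbed risk coefficients, giving a
#' related-but-not-identical source domain to pretrain on. With a null
#' shift the output is identical to `generate_cohort(spec)`.
#'
#' @param spec A [cohort_spec()]; typically `n` is several times the target
#'   cohort size (default pretraining size used in this package: 3030).
#' @param shift List with optional elements `mean` (named additive shifts to
#'   numeric feature means) and `coef` (named additive shifts to risk
#'   coefficients). `NULL` elements mean no shift.
#' @return An `ihd_cohort`.
#' @export
generate_pretrain_corpus <- function(spec, shift = pretrain_shift()) {
  stopifnot(is.list(shift))
  generate_cohort_impl(spec, mean_shift = shift$mean, coef_shift = shift$coef)
}

#' Default source-domain shift for the pretraining corpus
#' @param chol,trestbps,thalach Additive shifts of the numeric means.
#' @param cp,oldpeak Additive shifts of the corresponding risk coefficients.
#' @return List with elements `mean` and `coef`.
#' @export
pretrain_shift <- function(chol = 15, trestbps = 5, thalach = -5,
                           cp = -0.3, oldpeak = 0.3) {
  list(mean = c(chol = chol, trestbps = trestbps, thalach = thalach),
       coef = c(cp = cp, oldpeak = oldpeak))
}

#' Mask an exact number of values in one field
#'
#' Utility for building fixtures whose missingness counts are fixed rather
#' than binomial (e.g. a cohort with exactly 2 missing `thal`).
#'
#' @param cohort An `ihd_cohort`.
#' @param field Predictor name.
#' @param k Number of records to mask.
#' @param seed Integer seed choosing which records.
#' @return The cohort with `k` additional `NA`s in `field`.
#' @export
mask_missing <- function(cohort, field, k, seed = 1L) {
  stopifnot(field %in% uci_predictors(), k >= 0)
  avail <- which(!is.na(cohort[[field]]))
  if (k > length(avail)) stop("not enough observed values to mask")
  with_seed(seed, {
    cohort[[field]][sample(avail, k)] <- NA
  })
  cohort
}

# Spec (de)serialization ---------------------------------------------------

#' Read/write a cohort spec as YAML
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `write_cohort_spec` returns `path` invisibly; `read_cohort_spec`
#'   returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  yaml::write_yaml(lapply(unclass(spec), function(x)
    if (is.null(names(x))) x else as.list(x)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  unl <- function(x) if (is.list(x)) unlist(x) else x
  cohort_spec(n = raw$n, seed = raw$seed, prevalence = raw$prevalence,
              group_mix = unl(raw$group_mix),
              risk_coefficients = unl(raw$risk_coefficients),
              bias_shift = unl(raw$bias_shift),
              missing_rates = unl(raw$missing_rates))
}
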