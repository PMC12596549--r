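#' @keywords internal
"_PACKAGE"

# UCI Heart Disease "processed" schema: 13 predictors + binary target.
# Field order is fixed and is the column order of every cohort data.frame,
# every encoded matrix block, and the 14-field CSV dialect.

#' Schema constants of the 14-field heart-disease record format
#'
#' Field names in schema order, the 13 predictors, the continuous
#' predictors, and the categorical domains (binary fields pass through the
#' encoder as single columns).
#' @return Character vectors, or a named list of domains.
#' @export
uci_field_names <- function() {
  c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg", "thalach",
    "exang", "oldpeak", "slope", "ca", "thal", "target")
}

#' @rdname uci_field_names
#' @export
uci_predictors <- function() setdiff(uci_field_names(), "target")

#' @rdname uci_field_names
#' @export
uci_numeric_fields <- function() c("age", "trestbps", "chol", "thalach", "oldpeak")

#' @rdname uci_field_names
#' @export
uci_categorical_domains <- function() {
  list(
    sex     = c(0, 1),
    cp      = c(1, 2, 3, 4),
    fbs     = c(0, 1),
    restecg = c(0, 1, 2),
    exang   = c(0, 1),
    slope   = c(1, 2, 3),
    ca      = c(0, 1, 2, 3),
    thal    = c(3, 6, 7)
  )
}

# plausible numeric ranges used for validation and for the generator clips
uci_numeric_ranges <- function() {
  list(
    age      = c(18, 100),
    trestbps = c(80, 220),
    chol     = c(85, 603),
    thalach  = c(60, 220),
    oldpeak  = c(0, 7)
  )
}

#' Demographic group key for each record
#'
#' Groups are the cross of sex (male/female) and an age bin split at 50
#' years, the two fairness axes carried by the UCI schema.
#'
#' @param cohort An `ihd_cohort` or a data.frame with `sex` and `age` columns.
#' @return Factor of length `nrow(cohort)` with levels
#'   `F.lt50`, `F.ge50`, `M.lt50`, `M.ge50`.
#' @export
group_keys <- function(cohort) {
  stopifnot(all(c("sex", "age") %in% names(cohort)))
  sex <- ifelse(cohort$sex == 1, "M", "F")
  ageb <- ifelse(cohort$age >= 50, "ge50", "lt50")
  factor(paste(sex, ageb, sep = "."),
         levels = c("F.lt50", "F.ge50", "M.lt50", "M.ge50"))
}

validate_cohort <- function(df, allow_missing = TRUE) {
  fields <- uci_field_names()
  if (!all(fields %in% names(df)))
    stop("cohort is missing fields: ",
         paste(setdiff(fields, names(df)), collapse = ", "))
  doms <- uci_categorical_domains()
  for (f in names(doms)) {
    v <- df[[f]]
    bad <- !is.na(v) & !(v %in% doms[[f]])
    if (any(bad))
      stop(sprintf("field '%s' has out-of-domain value(s): %s", f,
                   paste(unique(v[bad]), collapse = ", ")))
    if (!allow_missing && anyNA(v))
      stop(sprintf("field '%s' has missing values where none are allowed", f))
  }
  for (f in uci_numeric_fields()) {
    v <- df[[f]]
    if (any(!is.na(v) & !is.finite(v)))
      stop(sprintf("field '%s' has non-finite values", f))
  }
  if (any(!df$target %in% c(0, 1)))
    stop("target must be binary 0/1")
  invisible(df)
}

as_ihd_cohort <- function(df) {
  df <- as.data.frame(df)[, uci_field_names()]
  rownames(df) <- NULL
  class(df) <- c("ihd_cohort", "data.frame")
  df
}

#' @export
as.data.frame.ihd_cohort <- function(x, ...) {
  attr(x, "spec") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.ihd_cohort <- function(x, ...) {
  nmiss <- sum(is.na(x[, uci_predictors()]))
  cat(sprintf("ihd_cohort: %d records, prevalence %.3f, %d missing cell(s)\n",
              nrow(x), if (nrow(x)) mean(x$target) else NA_real_, nmiss))
  if (nrow(x)) print(utils::head(as.data.frame(x), 4L))
  invisible(x)
}
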