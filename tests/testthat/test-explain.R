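# exact Shapley enumeration written directly from the definition; used as
# the oracle for the package's attribution code
brute_shapley <- function(f, background, x, groups) {
  p <- length(groups)
  v <- function(members) {
    Z <- background
    cols <- unlist(groups[members], use.names = FALSE)
    if (length(cols)) Z[, cols] <- matrix(x[cols], nrow(Z), length(cols),
                                          byrow = TRUE)
    mean(f(Z))
  }
  phi <- numeric(p)
  subsets <- unlist(lapply(0:p, function(k)
    combn(p, k, simplify = FALSE)), recursive = FALSE)
  for (j in seq_len(p)) {
    for (S in subsets) {
      if (j %in% S) next
      k <- length(S)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      phi[j] <- phi[j] + w * (v(c(S, j)) - v(S))
    }
  }
  list(base = v(integer(0)), phi = phi)
}

test_that("exact attribution satisfies the Shapley axioms on toy models", {
  set.seed(3)
  bg <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- c(a = 0.9, b = 0.4, c = 0.1)

  # dummy axiom: a constant model attributes nothing
  f_const <- function(m) rep(0.7, nrow(m))
  at <- shap_attribute(f_const, bg, x, mode = "exact")
  expect_equal(at$base_value, 0.7)
  expect_true(all(abs(at$phi) < 1e-9))

  # single-feature model: all mass on that feature
  f_one <- function(m) plogis(3 * m[, 2])
  at1 <- shap_attribute(f_one, bg, x, mode = "exact")
  expect_lt(abs(at1$phi[["a"]]), 1e-9)
  expect_lt(abs(at1$phi[["c"]]), 1e-9)
  expect_gt(abs(at1$phi[["b"]]), 0.01)

  # symmetry axiom: exchangeable features with equal values get equal phi
  bg_sym <- bg; bg_sym[, 2] <- bg_sym[, 1]
  x_sym <- c(a = 0.8, b = 0.8, c = 0.3)
  f_sym <- function(m) m[, 1] + m[, 2] + 0.5 * m[, 3]
  at2 <- shap_attribute(f_sym, bg_sym, x_sym, mode = "exact")
  expect_equal(at2$phi[["a"]], at2$phi[["b"]], tolerance = 1e-9)

  # additivity in exact mode
  expect_equal(at2$base_value + sum(at2$phi), at2$prediction,
               tolerance = 1e-9)
})

test_that("exact attribution equals brute-force enumeration with grouped one-hots", {
  set.seed(8)
  bg <- matrix(runif(40), 8, 5,
               dimnames = list(NULL, c("n1", "c_1", "c_2", "c_3", "n2")))
  foc <- c("n1", "c", "c", "c", "n2")
  x <- c(0.3, 0, 1, 0, 0.8)
  f <- function(m) plogis(m[, 1] - 2 * m[, 3] + 0.5 * m[, 5] + m[, 1] * m[, 5])
  at <- shap_attribute(f, bg, x, mode = "exact", feature_of_column = foc)
  oracle <- brute_shapley(f, bg, x,
                          groups = list(n1 = 1L, c = 2:4, n2 = 5L))
  expect_equal(at$base_value, oracle$base, tolerance = 1e-12)
  expect_equal(unname(at$phi), oracle$phi, tolerance = 1e-12)
  expect_equal(at$base_value + sum(at$phi), at$prediction, tolerance = 1e-9)
})

test_that("sampled attribution stays additive and close to exact values", {
  set.seed(5)
  d <- 6
  bg <- matrix(runif(60), 10, d,
               dimnames = list(NULL, paste0("f", 1:d)))
  x <- runif(d)
  beta <- c(2, -1.5, 1, 0, 0.5, -0.7)
  f <- function(m) plogis(m %*% beta)
  exact <- shap_attribute(f, bg, x, mode = "exact")
  sampled <- shap_attribute(f, bg, x, mode = "sampled", n_perm = 300, seed = 2)
  expect_equal(sampled$base_value + sum(sampled$phi), sampled$prediction,
               tolerance = 1e-3)
  expect_lt(max(abs(sampled$phi - exact$phi)), 0.05)
  # determinism under fixed seed
  again <- shap_attribute(f, bg, x, mode = "sampled", n_perm = 300, seed = 2)
  expect_identical(sampled$phi, again$phi)
})

test_that("exact mode refuses too many features and empty backgrounds", {
  bg <- matrix(runif(26), 2, 13)
  expect_error(shap_attribute(function(m) m[, 1], bg, runif(13),
                              mode = "exact"), "sampled")
  expect_error(shap_attribute(function(m) m[, 1], bg[0, , drop = FALSE],
                              runif(13)), "nonempty")
})

test_that("global importance ranks by mean |phi| with stable ties", {
  a1 <- structure(list(phi = c(f1 = 0.3, f2 = -0.1, f3 = 0)),
                  class = "shap_attribution")
  expect_equal(global_importance(list(a1))$feature, c("f1", "f2", "f3"))
  a2 <- structure(list(phi = c(f1 = -0.1, f2 = 0.5, f3 = 0)),
                  class = "shap_attribution")
  g <- global_importance(list(a1, a2))
  expect_equal(g$feature[1], "f2")
  expect_equal(g$mean_abs_phi, sort(g$mean_abs_phi, decreasing = TRUE))
  # permutation invariance of the input collection
  expect_identical(global_importance(list(a2, a1)), g)
  # ties keep schema order
  t1 <- structure(list(phi = c(a = 0.2, b = 0.2, c = 0.1)),
                  class = "shap_attribution")
  expect_equal(global_importance(list(t1))$feature, c("a", "b", "c"))
  bad <- structure(list(phi = c(zz = 1)), class = "shap_attribution")
  expect_error(global_importance(list(a1, bad)), "inconsistent")
})

test_that("global importance recovers the generator's dominant risk factors", {
  # cohorts whose log-odds are dominated by cp and oldpeak; a model trained
  # on each should rank those two among its top-3 global features when
  # attributions are pooled over five seeds
  dom <- c(age = 0, sex = 0, cp = 2.5, trestbps = 0.3, chol = 0.3, fbs = 0,
           restecg = 0.1, thalach = -0.5, exang = 0.3, oldpeak = 3.5,
           slope = 0.2, ca = 0.3, thal = 0.4)
  rank_probe <- function(seed) {
    co <- generate_cohort(cohort_spec(n = 300, seed = seed,
                                      missing_rates = c(thal = 0, ca = 0),
                                      risk_coefficients = dom))
    enc <- encode_complete(co)
    fit <- train_model(enc, run_config(lstm_units = 8, epochs = 40,
                                       learning_rate = 0.01, batch_size = 16,
                                       seed = seed, pool = "mean"))
    bg <- enc$values[1:40, ]
    lapply(41:52, function(i)
      shap_attribute(fit$model, bg, enc$values[i, ], mode = "sampled",
                     n_perm = 20, seed = seed + i,
                     feature_of_column = enc$feature_of_column))
  }
  ats <- unlist(lapply(1:5, rank_probe), recursive = FALSE)
  top3 <- global_importance(ats)$feature[1:3]
  expect_true(all(c("cp", "oldpeak") %in% top3))
})
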