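test_that("UCI dialect parsing handles constructed rows, '?' and binarization", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "57,1,2,130,236,0,2,174,0,0.0,2,1,3,0",
    "63,1,4,145,233,1,2,150,0,2.3,3,0,?,2",
    "67,0,3,115,564,0,0,160,0,1.6,2,?,7,1"
  ), path)
  co <- read_uci_csv(path)
  expect_equal(nrow(co), 3)
  expect_equal(co$cp[1], 2)
  expect_equal(co$target, c(0, 1, 1))  # severities 2 and 1 binarized
  expect_true(is.na(co$thal[2]))
  expect_true(is.na(co$ca[3]))
  expect_equal(count_missing(co, "thal"), 1)
  expect_error(count_missing(co, "bogus"), "unknown field")
})

test_that("malformed files are rejected with informative errors", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines("57,1,2,130,236,0,2,174,0,0.0,2,1,3", p1)  # 13 fields
  expect_error(read_uci_csv(p1), "14 fields")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("57,1,9,130,236,0,2,174,0,0.0,2,1,3,0", p2)  # cp out of domain
  expect_error(read_uci_csv(p2), "cp")
})

test_that("read-write-read round trip is lossless including missing flags", {
  co <- generate_cohort(cohort_spec(n = 60, seed = 21,
                                    missing_rates = c(thal = 0.1, ca = 0.1)))
  for (dialect in c("headerless", "headered")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_uci_csv(co, path, dialect = dialect)
    back <- read_uci_csv(path, dialect = dialect)
    expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)
  }
})

test_that("min-max scaling follows the (x - min)/(max - min) contract", {
  x <- matrix(c(0, 5, 10, 2, 2, 2), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  sc <- fit_minmax(x)
  out <- transform_minmax(x, sc)
  expect_equal(out[, "a"], c(0, 0.5, 1))     # endpoints and midpoint
  expect_equal(out[, "b"], c(0, 0, 0))       # constant column rule
  # test-time clipping
  xt <- matrix(c(-5, 20, 2, 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(transform_minmax(xt, sc)[, "a"], c(0, 1))
  # monotone non-decreasing in x
  xs <- matrix(sort(runif(50, -2, 12)), ncol = 1, dimnames = list(NULL, "a"))
  sc1 <- fit_minmax(matrix(c(0, 10), ncol = 1, dimnames = list(NULL, "a")))
  expect_true(all(diff(transform_minmax(xs, sc1)) >= 0))
})

test_that("one-hot encoding expands to the documented 25 columns", {
  co <- complete_cohort(n = 80, seed = 3)
  enc <- one_hot_encode(co)
  # 5 numeric + 3 binary pass-through + 4+3+3+4+3 indicator columns
  expect_equal(ncol(enc$values), 25)
  expect_equal(enc$values[co$cp == 2, "cp_2"],
               rep(1, sum(co$cp == 2)))
  # one-hot blocks row-sum to exactly 1
  for (f in names(enc$encoding_map)) {
    block <- enc$values[, paste0(f, "_", enc$encoding_map[[f]]), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, nrow(block)), label = f)
  }
  # binary fields pass through
  expect_equal(unname(enc$values[, "sex"]), co$sex)
  # decode recovers the category exactly
  for (f in names(enc$encoding_map))
    expect_equal(decode_categorical(enc, f), co[[f]], label = f)
})

test_that("scaled training matrices keep numeric columns in [0,1]", {
  co <- complete_cohort(n = 100, seed = 5)
  enc <- encode_complete(co)
  num <- enc$values[, uci_numeric_fields()]
  expect_true(all(num >= 0 & num <= 1))
  expect_equal(unname(apply(num, 2, min)), rep(0, 5))
  expect_equal(unname(apply(num, 2, max)), rep(1, 5))
})

test_that("stratified folds partition the cohort with balanced classes", {
  co <- complete_cohort(n = 100, seed = 8)
  co$target <- rep(c(0, 1), 50)
  plan <- make_folds(co, k = 10, seed = 4)
  sizes <- tabulate(plan$assignments, 10)
  expect_equal(sizes, rep(10, 10))
  for (f in 1:10)
    expect_equal(sum(co$target[plan$assignments == f]), 5)
  expect_identical(make_folds(co, 10, seed = 4)$assignments, plan$assignments)

  co303 <- complete_cohort(n = 303, seed = 9)
  p <- make_folds(co303, k = 10, seed = 2)
  sz <- tabulate(p$assignments, 10)
  expect_true(all(sz %in% c(30, 31)))
  expect_equal(sort(unlist(lapply(1:10, function(f) which(p$assignments == f)))),
               1:303)  # union is everything, pairwise disjoint
  # per-fold class counts within 1 of an even split
  for (cls in 0:1) {
    cnt <- vapply(1:10, function(f)
      sum(co303$target[p$assignments == f] == cls), numeric(1))
    expect_lte(max(cnt) - min(cnt), 1)
  }
  expect_error(make_folds(co303, k = 400, seed = 1), "exceed")
  expect_error(make_folds(co303, k = 1, seed = 1), "at least 2")
})

test_that("fold plans round-trip through JSON", {
  co <- complete_cohort(n = 40, seed = 2)
  plan <- make_folds(co, 4, seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  expect_identical(read_fold_plan(path)$assignments, plan$assignments)
})
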