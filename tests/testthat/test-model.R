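test_that("sequence view maps encoded columns to scalar tokens bijectively", {
  enc <- encode_complete(complete_cohort(n = 12, seed = 1))
  sv <- tabular_to_sequence(enc)
  expect_equal(ncol(sv$tokens), 25)          # T = d, token dimension 1
  expect_equal(sv$mapping, 1:25)
  expect_identical(sv$tokens[3, ], enc$values[3, ])
  # identical rows give identical sequences
  two <- tabular_to_sequence(enc$values[c(1, 1), ])
  expect_identical(two$tokens[1, ], two$tokens[2, ])
  bad <- enc$values; bad[1, 1] <- NaN
  expect_error(tabular_to_sequence(bad), "finite")
})

test_that("BiLSTM output width is twice the hidden size and zero is a fixed point", {
  m <- new_model(d = 6, lstm_units = 4, seed = 2)
  X <- matrix(runif(18), 3, 6)
  hs <- bilstm_forward(X, m$par)
  expect_length(hs, 6)
  expect_equal(dim(hs[[1]]), c(3, 8))
  # all-zero weights and biases annihilate the hidden state
  zpar <- lapply(m$par, function(p) p * 0)
  hz <- bilstm_forward(X, zpar)
  expect_true(all(vapply(hz, function(h) all(h == 0), logical(1))))
})

test_that("forward and backward passes mirror each other on reversed input", {
  # with the backward cell sharing the forward cell's weights, reading a
  # reversed sequence backward equals reading the original forward
  m <- new_model(d = 5, lstm_units = 3, seed = 4)
  par <- m$par
  par$Wxb <- par$Wxf; par$Whb <- par$Whf; par$bb <- par$bf
  X <- matrix(runif(10), 2, 5)
  Xrev <- X[, 5:1]
  h1 <- bilstm_forward(X, par)
  h2 <- bilstm_forward(Xrev, par)
  H <- 3
  for (t in 1:5) {
    expect_equal(h1[[t]][, 1:H], h2[[5 + 1 - t]][, H + 1:H], tolerance = 1e-12)
  }
})

test_that("residual update obeys its limiting cases and the algebraic rewrite", {
  D <- 4
  Wi <- matrix(runif(D), 1); Wr <- matrix(runif(D * D), D)
  x <- c(0.3, -0.2); XF <- matrix(runif(2 * D), 2)
  # lambda = 1: identity; lambda = 0: plain activation
  expect_equal(residual_update(x, XF, Wi, Wr, lambda = 1), XF)
  a <- 1 / (1 + exp(-(outer(x, Wi[1, ]) + XF %*% Wr)))
  expect_equal(residual_update(x, XF, Wi, Wr, lambda = 0), a)
  # scalar oracle: Wi=1, Wr=0, X=0, XF=0, lambda=0.5 -> 0.5 * sigmoid(0) = 0.25
  expect_equal(residual_update(0, matrix(0, 1, 1), matrix(1, 1, 1),
                               matrix(0, 1, 1), lambda = 0.5),
               matrix(0.25, 1, 1))
  # interpolated form equals activation + lambda * (XF - activation)
  for (rep in 1:20) {
    lam <- runif(1)
    XF2 <- matrix(rnorm(2 * D), 2)
    upd <- residual_update(x, XF2, Wi, Wr, lambda = lam)
    act <- 1 / (1 + exp(-(outer(x, Wi[1, ]) + XF2 %*% Wr)))
    expect_equal(upd, act + lam * (XF2 - act), tolerance = 1e-12)
  }
})

test_that("attention mask and update match their closed forms", {
  D <- 3
  H_t <- matrix(rnorm(2 * D), 2)
  # zero parameters: sigmoid(0) = 0.5 everywhere
  expect_equal(attention_mask(H_t, matrix(0, D, D), numeric(D)),
               matrix(0.5, 2, D))
  # saturation
  expect_true(all(attention_mask(H_t, matrix(0, D, D), rep(30, D)) > 0.999))
  # hand-set 2-d case
  Wm <- matrix(c(1, 0, 0, -1), 2); bm <- c(0.5, -0.5)
  h <- matrix(c(0.2, -0.3), 1)
  expect_equal(attention_mask(h, Wm, bm),
               matrix(plogis(c(0.2 + 0.5, 0.3 - 0.5)), 1), tolerance = 1e-12)
  # update: zero mask is a pure skip connection
  XF <- matrix(c(1, 2), 1)
  expect_equal(attention_update(XF, 0 * XF, 0 * XF), XF)
  res <- matrix(c(0.1, 0.2), 1)
  expect_equal(attention_update(XF, 0 * XF, res), XF + res)
  expect_equal(attention_update(matrix(c(1, 2), 1), matrix(0.5, 1, 2),
                                matrix(0, 1, 2)),
               matrix(c(1.5, 3), 1))
})

test_that("the sigmoid head honours its closed form and monotonicity", {
  expect_equal(predict_head(c(1, 2), matrix(0, 2, 1), 0), 0.5)
  expect_gt(predict_head(c(1, 2), matrix(0, 2, 1), 20), 0.999)
  logits <- seq(-3, 3, length.out = 11)
  probs <- vapply(logits, function(b) predict_head(0, matrix(0, 1, 1), b),
                  numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("the full forward pass is deterministic and bounded", {
  enc <- encode_complete(complete_cohort(n = 25, seed = 7))
  m <- new_model(d = 25, lstm_units = 6, seed = 3,
                 feature_names = colnames(enc$values))
  p1 <- predict_risk(m, enc)
  p2 <- predict_risk(m, enc)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # extreme but finite inputs stay bounded
  extreme <- matrix(c(rep(0, 25), rep(1, 25), runif(25, 0, 1)), 3,
                    byrow = TRUE)
  pe <- predict_risk(m, extreme)
  expect_true(all(is.finite(pe) & pe >= 0 & pe <= 1))
})

test_that("disabling residual attention reduces to a plain BiLSTM head", {
  X <- matrix(runif(40), 4, 10)
  m_off <- new_model(d = 10, lstm_units = 5, seed = 9,
                     residual_attention = FALSE)
  # the model centers its [0,1] tokens to [-1,1] before the recurrent cells
  hs <- bilstm_forward(2 * X - 1, m_off$par)
  manual <- predict_head(hs[[10]], m_off$par$Wo, m_off$par$bo)
  expect_equal(predict_risk(m_off, X), manual, tolerance = 1e-12)
})

test_that("backpropagation matches central finite differences", {
  set.seed(10)
  n <- 3; Tn <- 4
  X <- matrix(runif(n * Tn), n, Tn)
  y <- c(1, 0, 1); w <- c(1.3, 0.7, 1.0)
  for (ra in c(TRUE, FALSE)) for (pool in c("last", "mean")) {
    m <- new_model(d = Tn, lstm_units = 3, lambda = 0.35,
                   residual_attention = ra, pool = pool, seed = 21)
    fwd <- ihdri:::model_forward_impl(m, X, keep = TRUE)
    gr <- ihdri:::model_backward(m, fwd$cache, w * (fwd$yhat - y))
    lossfn <- function(par) {
      m2 <- m; m2$par <- par
      reweighted_bce(y, ihdri:::model_forward_impl(m2, X)$yhat, w)
    }
    eps <- 1e-5
    for (nm in names(m$par)) {
      p <- m$par[[nm]]
      for (i in unique(round(seq(1, length(p), length.out = 4)))) {
        pp <- m$par; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- m$par; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-5,
                     label = sprintf("grad %s[%d] ra=%s pool=%s", nm, i, ra, pool))
      }
    }
  }
})

test_that("checkpoints round-trip bit-identically and guard their schema", {
  enc <- encode_complete(complete_cohort(n = 10, seed = 15))
  m <- new_model(d = 25, lstm_units = 4, seed = 5,
                 feature_names = colnames(enc$values))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, path, provenance = "unit test")
  back <- load_checkpoint(path)
  expect_identical(predict_risk(back, enc), predict_risk(m, enc))

  # strict transfer requires a matching fingerprint
  target <- new_model(d = 25, lstm_units = 4, seed = 99,
                      feature_names = colnames(enc$values))
  init <- transfer_init(target, back, strict = TRUE)
  for (nm in setdiff(names(init$par), c("Wo", "bo")))
    expect_identical(init$par[[nm]], back$par[[nm]])
  # the head stays fresh
  expect_identical(init$par$Wo, target$par$Wo)

  wrong <- new_model(d = 25, lstm_units = 8, seed = 1)
  expect_error(transfer_init(wrong, back, strict = TRUE), "H_dim")
  # non-strict with an incompatible checkpoint keeps the fresh init
  relaxed <- transfer_init(wrong, back, strict = FALSE)
  expect_identical(relaxed$par, wrong$par)
  # non-strict with no checkpoint at all: fully fresh (the no-TL arm)
  expect_identical(transfer_init(wrong, NULL, strict = FALSE)$par, wrong$par)
})
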