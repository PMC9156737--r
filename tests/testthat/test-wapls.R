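test_that("one-component WA-PLS equals brute-force WA with inverse deshrinking", {
  # small fixed fixture
  Y <- random_sqrt_matrix(5, 3, seed = 7)
  x <- c(210, 480, 350, 790, 520)
  fit <- wapls(Y, x, ncomp = 1)
  expect_equal(unname(fitted(fit, 1)), wa_inverse_deshrink(Y, x),
               tolerance = 1e-10)
  # random small matrices, several seeds
  for (s in 1:10) {
    set.seed(s + 100)
    n <- sample(5:12, 1); m <- sample(3:8, 1)
    Y <- random_sqrt_matrix(n, m, seed = s)
    x <- runif(n, 100, 900)
    fit <- wapls(Y, x, ncomp = 1)
    expect_lt(max(abs(unname(fitted(fit, 1)) - wa_inverse_deshrink(Y, x))),
              1e-8)
  }
})

test_that("degenerate inputs are rejected", {
  Y <- random_sqrt_matrix(5, 3, seed = 1)
  expect_error(wapls(Y, rep(400, 5)), "constant")
  expect_error(wapls(Y, c(1, 2, 3, 4, 5), ncomp = 6), "between 1 and 5")
  expect_error(wapls(Y[1:2, ], c(1, 2)), "at least 3")
  expect_warning(wapls(cbind(Y, zero = 0), c(1, 5, 2, 8, 3), ncomp = 1),
                 "all-zero")
})

test_that("training fit is near-perfect on a noiseless unimodal set", {
  resp <- make_taxon_responses(25, c(200, 800), seed = 1)
  x <- seq(200, 800, length.out = 200)
  sim <- simulate_modern_trainingset(resp, x, depth = Inf, seed = 1)
  ys <- sqrt_transform(sim$assemblage)
  fit <- wapls(ys, x, ncomp = 2)
  expect_gte(fit$apparent["comp2", "r2"], 0.95)
})

test_that("apparent weighted RMSE is non-increasing in component count", {
  for (s in 1:5) {
    Y <- random_sqrt_matrix(30, 10, seed = s)
    set.seed(s)
    x <- runif(30, 0, 100)
    fit <- wapls(Y, x, ncomp = 5)
    r <- rowSums(Y)
    wrmse <- apply(fit$fitted, 2L, function(f)
      sqrt(sum(r * (f - x)^2) / sum(r)))
    expect_true(all(diff(wrmse) <= 1e-10))
  }
})

test_that("prediction is consistent, scale-invariant and guards taxa", {
  resp <- make_taxon_responses(10, c(0, 100), seed = 3)
  sim <- simulate_modern_trainingset(resp, seq(5, 95, length.out = 40),
                                     depth = 500, seed = 4)
  ys <- sqrt_transform(to_proportions(sim$assemblage))
  fit <- wapls(ys, sim$climate$x, ncomp = 3)

  # training row fed back as "fossil" returns the fitted value
  pred <- predict(fit, ys$values[4, , drop = FALSE], ncomp = 2)
  expect_equal(unname(pred), unname(fitted(fit, 2)[4]), tolerance = 1e-12)

  # multiplying fossil counts by 7 before the transform chain changes nothing
  counts <- sim$assemblage$values[10:12, ]
  a1 <- sqrt_transform(to_proportions(assemblage(counts)))
  a7 <- sqrt_transform(to_proportions(assemblage(counts * 7)))
  expect_equal(predict(fit, a1, ncomp = 2), predict(fit, a7, ncomp = 2),
               tolerance = 1e-12)

  # unknown-only fossil rejected; partial overlap drops with a message
  alien <- matrix(c(0.6, 0.4), 1, dimnames = list("f", c("X1", "X2")))
  expect_error(predict(fit, alien), "no taxa shared")
  mixed <- cbind(ys$values[1, , drop = FALSE], X1 = 0.1)
  expect_message(predict(fit, mixed, ncomp = 2), "dropping 1 taxa")
})

test_that("leave-one-out matches manual refits and is deterministic", {
  Y <- random_sqrt_matrix(4, 3, seed = 9)
  x <- c(10, 40, 25, 60)
  cv <- wapls_loo(Y, x, ncomp = 2)
  for (i in 1:4) {
    fit <- wapls(Y[-i, ], x[-i], ncomp = 2)
    for (c in 1:2)
      expect_equal(unname(cv$predictions[i, c]),
                   as.numeric(suppressWarnings(
                     predict(fit, Y[i, , drop = FALSE], ncomp = c))),
                   tolerance = 1e-12)
  }
  expect_error(wapls_loo(Y[1:3, ], x[1:3]), "at least 4")

  Y2 <- random_sqrt_matrix(20, 6, seed = 11)
  set.seed(11); x2 <- runif(20, 0, 50)
  cv1 <- wapls_loo(Y2, x2, ncomp = 5)
  cv2 <- wapls_loo(Y2, x2, ncomp = 5)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1$stats), 5L)   # one row per component count
})

test_that("performance statistics follow their definitions", {
  obs <- c(3, 9, 5, 14, 7, 11, 2, 8)
  ps <- performance_stats(obs, obs)
  expect_equal(unlist(ps), c(r2 = 1, rmsep = 0, max_bias = 0))

  ps2 <- performance_stats(obs + 10, obs)
  expect_equal(ps2$r2, 1)
  expect_equal(ps2$rmsep, 10)
  expect_equal(ps2$max_bias, 10)

  set.seed(77)
  ps3 <- performance_stats(rnorm(1000), rnorm(1000))
  expect_lt(ps3$r2, 0.02)

  expect_error(performance_stats(1:3, 1:4), "lengths differ")
})

test_that("max bias picks the worst of ten gradient segments", {
  obs <- seq(0, 10, length.out = 50)
  pred <- obs
  pred[obs > 9] <- pred[obs > 9] + 5   # bias confined to the top segment
  expect_equal(performance_stats(pred, obs)$max_bias, 5)
})

test_that("VIF matches its closed form and flags exact collinearity", {
  z1 <- c(1, 1, -1, -1); z2 <- c(1, -1, 1, -1)
  # exactly orthogonal, equal norms: correlation of v1, v2 is exactly 0.9
  v1 <- z1
  v2 <- 0.9 * z1 + sqrt(1 - 0.81) * z2
  out <- vif(cbind(a = v1, b = v2))
  expect_equal(as.numeric(out), rep(1 / (1 - 0.81), 2), tolerance = 1e-10)
  expect_false(any(attr(out, "flagged")))

  orth <- vif(cbind(a = z1, b = z2))
  expect_equal(as.numeric(orth), c(1, 1), tolerance = 1e-12)

  coll <- vif(cbind(a = v1, b = v2, c = v1 + v2))
  expect_true(is.infinite(coll["c"]))
  expect_true(attr(coll, "flagged")["c"])
  expect_error(vif(cbind(a = v1)), "at least 2")
})

test_that("model serialization writes coefficients with metadata", {
  Y <- random_sqrt_matrix(8, 4, seed = 2)
  set.seed(2); x <- runif(8, 0, 10)
  fit <- wapls(Y, x, ncomp = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_wapls(fit, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# wapls x_bar=.* ncomp=2 transform=sqrt_proportions")
  tab <- read.csv(f, comment.char = "#")
  expect_equal(tab$taxon, fit$taxa)
  expect_equal(tab$comp2, unname(signif(fit$beta[, 2], 12)))
})
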