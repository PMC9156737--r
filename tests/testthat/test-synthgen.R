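test_that("taxon responses are reproducible and respect the gradient", {
  r1 <- make_taxon_responses(15, c(200, 800), seed = 5)
  r2 <- make_taxon_responses(15, c(200, 800), seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$optimum >= 200 & r1$optimum <= 800))
  expect_true(all(r1$tolerance > 0))
  expect_true(all(r1$height > 0))
  expect_error(make_taxon_responses(1, c(0, 1), seed = 1), "at least 2")
  expect_error(make_taxon_responses(5, c(800, 200), seed = 1), "lo < hi")
  # seeded draws do not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_taxon_responses(5, c(0, 1), seed = 9))
  expect_identical(runif(1), before)
})

test_that("modern sets are multinomial with exact depth and right mode", {
  resp <- make_taxon_responses(8, c(0, 100), seed = 2)
  x <- seq(10, 90, length.out = 25)
  sim <- simulate_modern_trainingset(resp, x, depth = 300, seed = 3)
  expect_equal(unname(rowSums(sim$assemblage$values)), rep(300, 25))
  expect_identical(sim$assemblage,
                   simulate_modern_trainingset(resp, x, depth = 300,
                                               seed = 3)$assemblage)
  expect_equal(rownames(sim$climate), rownames(sim$assemblage$values))

  # at huge depth the most abundant taxon at a well-separated optimum is
  # that taxon itself
  resp2 <- structure(data.frame(taxon = c("A", "B", "C"),
                                optimum = c(20, 50, 80),
                                tolerance = c(8, 8, 8),
                                height = c(1, 1, 1)),
                     gradient = c(0, 100),
                     class = c("taxon_responses", "data.frame"))
  sim2 <- simulate_modern_trainingset(resp2, c(20, 50, 80), depth = 1e5,
                                      seed = 4)
  expect_equal(unname(apply(sim2$assemblage$values, 1, which.max)), 1:3)

  # noise-free variant returns the expected proportions directly
  simInf <- simulate_modern_trainingset(resp2, c(20, 50), depth = Inf,
                                        seed = 1)
  expect_equal(simInf$assemblage$kind, "proportions")
  expect_error(simulate_modern_trainingset(resp, x, depth = 10, seed = 1),
               ">= 50")
})

test_that("climate histories honour events, spacing regimes and seeds", {
  ev <- data.frame(start = c(150000, 60000), end = c(130000, 40000),
                   amplitude = c(300, 300), ramp = c(4000, 4000))
  sched <- history_schedule(events = ev, noise_sd = 0)
  h <- simulate_climate_history(sched, seed = 6)
  expect_true(all(diff(h$t) > 0))
  expect_identical(h$y, h$truth)   # noise_sd = 0
  inside <- h$t < 146000 & h$t > 134000
  outside <- h$t > 160000 | (h$t > 70000 & h$t < 120000)
  expect_equal(mean(h$truth[inside]) - mean(h$truth[outside]), 300)

  expect_identical(simulate_climate_history(sched, seed = 6)$y, h$y)

  bad <- data.frame(start = c(100000, 80000), end = c(70000, 50000),
                    amplitude = c(1, 1), ramp = c(10, 10))
  expect_error(history_schedule(events = bad), "overlap")
  expect_error(history_schedule(events = data.frame(start = 1000, end = 5000,
                                                    amplitude = 1, ramp = 1)),
               "younger")
})

test_that("realized spacing matches the two-regime design", {
  gaps_old <- gaps_young <- numeric(0)
  for (s in 1:30) {
    h <- simulate_climate_history(history_schedule(noise_sd = 0), seed = s)
    old <- h$t > 30000
    gaps_old <- c(gaps_old, diff(h$t[old]))
    gaps_young <- c(gaps_young, diff(h$t[h$t < 30000]))
  }
  expect_lt(abs(mean(gaps_old) / 447 - 1), 0.1)
  expect_lt(abs(mean(gaps_young) / 96 - 1), 0.1)

  # a target sample count rescales both regimes proportionally
  h438 <- simulate_climate_history(history_schedule(n_samples = 438),
                                   seed = 1)
  expect_lt(abs(length(h438$t) / 438 - 1), 0.15)
})

test_that("fossil records close the generative loop", {
  resp <- make_taxon_responses(20, c(200, 800), seed = 7)
  ev <- data.frame(start = 100000, end = 60000, amplitude = 250, ramp = 5000)
  sched <- history_schedule(range_kyr = c(0, 150000), baseline = 350,
                            events = ev, noise_sd = 0, n_samples = 200)
  hist <- simulate_climate_history(sched, seed = 8)
  fos <- simulate_fossil_record(resp, hist, depth = 400, seed = 9)
  expect_s3_class(fos, "assemblage")
  expect_equal(fos$ages, hist$t)
  expect_true(all(abs(rowSums(to_proportions(fos)$values) - 1) <= 1e-9))
  expect_identical(fos, simulate_fossil_record(resp, hist, depth = 400,
                                               seed = 9))

  # reconstruction through a matching modern set tracks the truth
  x <- seq(200, 800, length.out = 150)
  mod <- simulate_modern_trainingset(resp, x, depth = 400, seed = 10)
  fit <- wapls(sqrt_transform(to_proportions(mod$assemblage)), x, ncomp = 2)
  pred <- predict(fit, sqrt_transform(to_proportions(fos)), ncomp = 2)
  expect_gt(cor(pred, hist$truth), 0.9)
})
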