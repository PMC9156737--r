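test_that("a constant noise-free series yields no significant pixels", {
  t <- seq(0, 1000, length.out = 40)
  sz <- snsizer(t, rep(5, 40), n_scales = 8, grid_n = 41)
  expect_false(any(sz$state %in% c("increase", "decrease")))
})

test_that("insufficient sampling is masked exactly where ESS is low", {
  # a large gap in the middle of the record starves small-scale pixels
  set.seed(9)
  t <- sort(c(runif(30, 0, 2000), runif(30, 8000, 10000)))
  y <- rnorm(60)
  sz <- snsizer(t, y, n_scales = 10, grid_n = 81)
  expect_identical(unname(sz$state == "insufficient"),
                   unname(sz$ess < sz$ess_min | !is.finite(sz$deriv)))
  expect_true(any(sz$state[1, ] == "insufficient"))   # smallest scale
  expect_true(all(is.finite(sz$scaled[sz$state != "insufficient"])))
})

test_that("a strong monotone rise toward the present is detected as increase", {
  set.seed(10)
  t <- seq(0, 10000, length.out = 150)
  y <- 600 - 0.03 * t + rnorm(150, 0, 10)   # higher values at younger ages
  sz <- snsizer(t, y, n_scales = 10, grid_n = 81)
  mid <- round(nrow(sz$state) / 2)
  expect_gt(mean(sz$state[mid, ] == "increase"), 0.5)
  expect_false(any(sz$state == "decrease"))
})

test_that("states are invariant to time translation and input order", {
  set.seed(12)
  t <- sort(runif(80, 0, 5000))
  y <- 100 + 0.01 * t + rnorm(80, 0, 3)
  sz1 <- snsizer(t, y, n_scales = 8, grid_n = 61)
  sz2 <- snsizer(t + 77777, y, n_scales = 8, grid_n = 61)
  expect_identical(sz1$state, sz2$state)
  idx <- rev(seq_along(t))
  sz3 <- snsizer(t[idx], y[idx], n_scales = 8, grid_n = 61)
  expect_identical(sz1$state, sz3$state)
  expect_equal(sz1$scaled, sz3$scaled)
})

test_that("the map is deterministic and validates its configuration", {
  set.seed(13)
  t <- sort(runif(40, 0, 100)); y <- rnorm(40)
  expect_identical(snsizer(t, y, n_scales = 6, grid_n = 31),
                   snsizer(t, y, n_scales = 6, grid_n = 31))
  expect_error(snsizer(t[1:5], y[1:5]), "at least 10")
  expect_error(snsizer(t, y, scales = 3), "at least 2 scales")
  expect_error(snsizer(t, y, alpha = 1.2), "alpha")
  expect_error(snsizer(t, y, grid = c(5000, 6000)), "outside the data range")
})

test_that("interval extraction cuts maximal runs at exact scale rows", {
  grid <- seq(22000, 2000, length.out = 11)  # will be sorted ascending
  grid <- sort(grid)
  states <- matrix("none", 2, 11)
  # ages 10k-20k significantly increasing at the second scale
  states[2, grid >= 10000 & grid <= 20000] <- "increase"
  sz <- stub_snsizer(states, scales = c(100, 1000), grid = grid)
  iv <- extract_intervals(sz, 1000)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$direction, "increase")
  expect_gt(iv$start, iv$end)            # start is the older edge
  expect_equal(iv$start, 21000)          # outer pixel edges
  expect_equal(iv$end, 9000)

  # all-none row is empty; split runs give two intervals
  expect_equal(nrow(extract_intervals(sz, 100)), 0L)
  states2 <- states
  states2[2, 6] <- "none"
  states2[2, 9:10] <- "decrease"
  sz2 <- stub_snsizer(states2, scales = c(100, 1000), grid = grid)
  iv2 <- extract_intervals(sz2, 1000)
  expect_equal(nrow(iv2), 3L)
  expect_true(all(iv2$start > iv2$end))
  # ordered past -> present
  expect_true(all(diff(iv2$start) < 0))

  expect_error(extract_intervals(sz, 555), "not a scale row")
})

test_that("map export writes parallel state and magnitude matrices", {
  set.seed(15)
  t <- seq(0, 10000, length.out = 60)
  y <- 500 - 0.02 * t + rnorm(60, 0, 5)
  sz <- snsizer(t, y, n_scales = 6, grid_n = 41)
  d <- withr::local_tempdir()
  write_snsizer(sz, d)
  states <- read.csv(file.path(d, "snsizer_states.csv"), comment.char = "#")
  mags <- read.csv(file.path(d, "snsizer_scaled_derivative.csv"),
                   comment.char = "#")
  expect_equal(dim(states), c(6L, 42L))
  expect_equal(dim(mags), c(6L, 42L))
  codes <- as.matrix(states[, -1])
  expect_true(all(codes %in% c(-1, 0, 1, NA)))
  expect_equal(unname(!is.na(codes) & codes == 1),
               unname(sz$state == "increase"))
})

test_that("plotting renders without error", {
  set.seed(16)
  t <- seq(0, 1000, length.out = 50)
  y <- 10 - 0.005 * t + rnorm(50)
  sz <- snsizer(t, y, n_scales = 6, grid_n = 31)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(sz))
  grDevices::dev.off()
  expect_true(file.exists(f))
})
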