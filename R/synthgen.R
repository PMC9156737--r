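#' Unimodal taxon-climate response parameters
#'
#' Draws one Gaussian response curve per taxon along a climate gradient:
#' expected relative abundance proportional to
#' \eqn{c_k \exp(-(x - u_k)^2 / (2 t_k^2))} with optimum \eqn{u_k},
#' tolerance \eqn{t_k} and peak height \eqn{c_k}. Optima are uniform on the
#' gradient, tolerances uniform on a stated fraction of the gradient width
#' (default 8-25%), heights log-uniform over a decade. Gaussian curves are
#' the minimal model satisfying the unimodality assumption behind WA-PLS.
#'
#' @param m number of taxa (>= 2).
#' @param gradient numeric `c(lo, hi)` climate range (e.g. mm/yr).
#' @param seed integer seed; the result is a pure function of the
#'   arguments.
#' @param tol_frac range of tolerances as a fraction of the gradient width.
#' @return Object of class `taxon_responses`: data frame with `taxon`,
#'   `optimum`, `tolerance`, `height`, plus the gradient as an attribute.
#' @export
make_taxon_responses <- function(m, gradient, seed,
                                 tol_frac = c(0.08, 0.25)) {
  m <- as.integer(m)
  if (m < 2L) stop("need at least 2 taxa")
  if (length(gradient) != 2L || gradient[1L] >= gradient[2L])
    stop("gradient must be c(lo, hi) with lo < hi")
  width <- diff(gradient)
  out <- with_seed(seed, data.frame(
    taxon = sprintf("taxon%02d", seq_len(m)),
    optimum = stats::runif(m, gradient[1L], gradient[2L]),
    tolerance = stats::runif(m, tol_frac[1L] * width, tol_frac[2L] * width),
    height = 10^stats::runif(m, -0.5, 0.5),
    stringsAsFactors = FALSE))
  structure(out, gradient = gradient, class = c("taxon_responses",
                                                "data.frame"))
}

# expected composition (rows sum to 1) at climate values x
expected_composition <- function(responses, x) {
  E <- vapply(seq_len(nrow(responses)), function(k)
    responses$height[k] *
      exp(-(x - responses$optimum[k])^2 / (2 * responses$tolerance[k]^2)),
    numeric(length(x)))
  if (length(x) == 1L) E <- matrix(E, nrow = 1L)
  rs <- rowSums(E)
  if (any(rs < 1e-300))
    stop(sprintf("all taxon responses underflow at x = %.6g",
                 x[which(rs < 1e-300)[1L]]))
  colnames(E) <- responses$taxon
  E / rs
}

#' Simulate a modern calibration set
#'
#' Draws one multinomial pollen count per sample from the expected
#' composition at its climate value; the counting depth plays the role of
#' the pollen sum. `depth = Inf` returns the noise-free expected
#' proportions instead (useful for checking estimator consistency).
#'
#' @param responses a [make_taxon_responses()] object.
#' @param x climate value per sample.
#' @param depth multinomial total count per sample (>= 50), or `Inf`.
#' @param seed integer seed.
#' @return List with `assemblage` (counts, or proportions when
#'   `depth = Inf`) and `climate` (data frame with column `x`).
#' @export
simulate_modern_trainingset <- function(responses, x, depth, seed) {
  stopifnot(inherits(responses, "taxon_responses"))
  x <- as.numeric(x)
  P <- expected_composition(responses, x)
  ids <- sprintf("mod%04d", seq_along(x))
  rownames(P) <- ids
  if (is.infinite(depth)) {
    tab <- assemblage(P, sample_id = ids, kind = "proportions")
  } else {
    depth <- as.integer(depth)
    if (depth < 50L) stop("depth must be >= 50 (or Inf for noise-free)")
    counts <- with_seed(seed, t(vapply(seq_along(x), function(i)
      as.numeric(stats::rmultinom(1L, depth, P[i, ])),
      numeric(ncol(P)))))
    dimnames(counts) <- dimnames(P)
    tab <- assemblage(counts, sample_id = ids, kind = "counts")
  }
  climate <- data.frame(x = x, row.names = ids)
  list(assemblage = tab, climate = climate)
}

#' Schedule for a synthetic climate history
#'
#' Describes a precipitation history over an age range as a baseline plus
#' trapezoidal (ramped boxcar) humid events, Gaussian observation noise,
#' and a two-regime irregular sampling scheme patterned on long lacustrine
#' pollen records: denser sampling in the recent window. Defaults mirror a
#' ~200-kyr record with mean spacing 447 yr before 30 kyr BP and 96 yr
#' after, and a 200-800 mm/yr value range.
#'
#' @param range_kyr age range in years BP, `c(young, old)`.
#' @param baseline baseline climate value (mm/yr).
#' @param events data frame with columns `start` (older edge, yr BP), `end`
#'   (younger edge), `amplitude` (mm/yr) and `ramp` (yr): the value ramps
#'   up over \[start, start - ramp\], holds, and ramps back down over
#'   \[end + ramp, end\]. Events must not overlap.
#' @param noise_sd observation noise SD (mm/yr).
#' @param spacing data frame with columns `max_age` and `mean_gap` defining
#'   mean exponential gaps per age window (defaults: 96 yr up to 30 kyr BP,
#'   447 yr beyond).
#' @param n_samples optional target sample count; when set, both window
#'   gaps are scaled by a common factor so the expected count matches while
#'   preserving the resolution contrast.
#' @return Object of class `history_schedule`.
#' @export
history_schedule <- function(range_kyr = c(0, 197000), baseline = 400,
                             events = NULL, noise_sd = 30,
                             spacing = data.frame(
                               max_age = c(30000, Inf),
                               mean_gap = c(96, 447)),
                             n_samples = NULL) {
  if (length(range_kyr) != 2L || range_kyr[1L] >= range_kyr[2L])
    stop("range must be c(young, old) with young < old")
  if (is.null(events))
    events <- data.frame(start = numeric(), end = numeric(),
                         amplitude = numeric(), ramp = numeric())
  stopifnot(all(c("start", "end", "amplitude", "ramp") %in% names(events)))
  if (nrow(events) > 0L) {
    if (any(events$end >= events$start))
      stop("each event needs end (younger) < start (older)")
    if (any(events$start > range_kyr[2L] | events$end < range_kyr[1L]))
      stop("event outside the age range")
    ev <- events[order(events$start), ]
    if (nrow(ev) > 1L && any(ev$start[-nrow(ev)] > ev$end[-1L]))
      stop("events overlap")
  }
  if (any(spacing$mean_gap <= 0)) stop("spacing must be positive")
  structure(list(range = range_kyr, baseline = baseline, events = events,
                 noise_sd = noise_sd, spacing = spacing,
                 n_samples = n_samples),
            class = "history_schedule")
}

# deterministic trajectory (no noise) at ages
history_trajectory <- function(schedule, ages) {
  v <- rep(schedule$baseline, length(ages))
  ev <- schedule$events
  for (i in seq_len(nrow(ev))) {
    s <- ev$start[i]; e <- ev$end[i]; A <- ev$amplitude[i]; rl <- ev$ramp[i]
    up <- ages <= s & ages > s - rl
    v[up] <- v[up] + A * (s - ages[up]) / rl
    hold <- ages <= s - rl & ages >= e + rl
    v[hold] <- v[hold] + A
    dn <- ages < e + rl & ages >= e
    v[dn] <- v[dn] + A * (ages[dn] - e) / rl
  }
  v
}

#' Simulate an irregularly sampled climate history
#'
#' Ages are drawn with exponential gaps whose mean depends on the age
#' window; values are the schedule trajectory plus Gaussian noise.
#'
#' @param schedule a [history_schedule()].
#' @param seed integer seed.
#' @return List of class `signal_series` with `t` (ages, strictly
#'   increasing), `y` (values), `truth` (noise-free trajectory) and
#'   `schedule`.
#' @export
simulate_climate_history <- function(schedule, seed) {
  stopifnot(inherits(schedule, "history_schedule"))
  sp <- schedule$spacing[order(schedule$spacing$max_age), , drop = FALSE]
  rng <- schedule$range
  gap_scale <- 1
  if (!is.null(schedule$n_samples)) {
    lo <- rng[1L]
    expected <- 0
    for (i in seq_len(nrow(sp))) {
      hi <- min(sp$max_age[i], rng[2L])
      if (hi > lo) expected <- expected + (hi - lo) / sp$mean_gap[i]
      lo <- hi
    }
    gap_scale <- expected / schedule$n_samples
  }
  ages <- with_seed(seed, {
    a <- rng[1L]
    out <- numeric(0)
    repeat {
      gap <- sp$mean_gap[match(TRUE, a < sp$max_age)] * gap_scale
      a <- a + stats::rexp(1L, 1 / gap)
      if (a > rng[2L]) break
      out <- c(out, a)
    }
    out
  })
  ages <- sort(unique(ages))
  truth <- history_trajectory(schedule, ages)
  y <- with_seed(derive_seed(seed, "history-noise"),
                 truth + stats::rnorm(length(ages), 0, schedule$noise_sd))
  structure(list(t = ages, y = y, truth = truth, schedule = schedule),
            class = "signal_series")
}

#' @export
print.signal_series <- function(x, ...) {
  cat(sprintf("Signal series: %d samples, %.5g-%.5g yr BP, mean spacing %.4g yr\n",
              length(x$t), min(x$t), max(x$t), mean(diff(x$t))))
  invisible(x)
}

#' Simulate a fossil pollen record from a climate history
#'
#' One multinomial assemblage per sampled age, driven by the noise-free
#' climate value at that age through the same response curves as the
#' modern set, closing the generative loop modern set -> transfer
#' function -> reconstruction.
#'
#' @param responses a [make_taxon_responses()] object.
#' @param history a `signal_series` from [simulate_climate_history()]; the
#'   `truth` trajectory drives the assemblages.
#' @param depth multinomial count per sample.
#' @param seed integer seed.
#' @return An [assemblage] of counts carrying the history's ages.
#' @export
simulate_fossil_record <- function(responses, history, depth, seed) {
  stopifnot(inherits(responses, "taxon_responses"),
            inherits(history, "signal_series"))
  depth <- as.integer(depth)
  if (depth < 50L) stop("depth must be >= 50")
  P <- expected_composition(responses, history$truth)
  counts <- with_seed(seed, t(vapply(seq_len(nrow(P)), function(i)
    as.numeric(stats::rmultinom(1L, depth, P[i, ])), numeric(ncol(P)))))
  colnames(counts) <- colnames(P)
  assemblage(counts, sample_id = sprintf("fos%04d", seq_len(nrow(P))),
             ages = history$t, kind = "counts")
}
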