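#' SnSiZer: scale-normalized significant zero-crossing map
#'
#' Scans an irregular time series across a log-spaced grid of smoothing
#' bandwidths and, for every (time, scale) pixel, tests whether the
#' derivative of the Nadaraya-Watson smooth differs significantly from
#' zero. On top of the classic SiZer states the map records the
#' scale-normalized derivative \eqn{h \, \partial L/\partial t}
#' (\eqn{\gamma}-normalized with \eqn{\gamma = 1}, first derivative), whose
#' magnitude is comparable across smoothing levels and is used to shade the
#' strength of each significant change.
#'
#' Ages are calendar years BP (larger = older) and features are read from
#' past to present: a pixel is an `increase` when the smooth rises toward
#' the present, i.e. the derivative with respect to age is significantly
#' negative. Inference is row-wise simultaneous at level `alpha`, in the
#' spirit of the original SiZer: the derivative is a linear smoother
#' \eqn{\sum_i w_i(t, h) y_i} with variance
#' \eqn{\hat\sigma^2(h) \sum_i w_i^2}, where \eqn{\hat\sigma^2(h)} comes
#' from the NW residuals at that scale with divisor
#' \eqn{n - \mathrm{tr}(S_h)} (clamped at 1). The simultaneous quantile
#' per row comes from the expected-crossings (Rice / Euler-characteristic)
#' bound for the discrete t-field of standardized derivatives: with
#' \eqn{\kappa(h) = \sum_j \sqrt{2(1 - \rho_j)}} summed over adjacent
#' unmasked pixel pairs (\eqn{\rho_j} the correlation of their weight
#' vectors) and \eqn{\nu(h) = n - \mathrm{tr}(S_h)} degrees of freedom,
#' \eqn{q} solves
#' \deqn{2 P(T_\nu > q) + \frac{\kappa}{\pi}
#'   \left(1 + q^2/\nu\right)^{-(\nu - 1)/2} = \alpha.}
#' For a dense design \eqn{\kappa \to T \sqrt{3/2}\,/\,h}, the continuous
#' Rice bound for Gaussian-derivative smoothing of white noise; because the
#' crossing bound dominates the true excursion probability, the realised
#' row-wise false-positive rate stays at or below `alpha`. Pixels with
#' effective sample size below `ess_min` are masked as `insufficient`
#' regardless of the test.
#'
#' @param t ages in calendar years BP (any strictly ordered numeric works;
#'   "increase" then means increase toward smaller `t`).
#' @param y signal values (e.g. reconstructed precipitation, mm/yr).
#' @param scales bandwidth grid; defaults to `n_scales` values equally
#'   spaced in log10(h) from twice the median sampling interval to half the
#'   time range.
#' @param grid time grid; defaults to `grid_n` regular points spanning `t`.
#' @param n_scales,grid_n sizes of the default grids.
#' @param alpha simultaneous significance level per scale row.
#' @param ess_min effective-sample-size mask threshold (default 5, the
#'   classic SiZer convention).
#' @param highlight bandwidths highlighted for interval extraction;
#'   defaults to the scale rows nearest the 25/50/75% quantiles of the
#'   log-scale range.
#' @return An object of class `snsizer`: list with `state` (scales x grid
#'   matrix with entries "increase", "decrease", "none", "insufficient"),
#'   `deriv` (toward-present derivative of the smooth), `scaled`
#'   (h * deriv), `se`, `ess`, `smooth` (L(t, h^2) per row), `grid`,
#'   `scales`, `highlight`, `alpha`, `ess_min`, `n`, plus the input series.
#' @seealso [extract_intervals()], [plot.snsizer()], [nw_smooth()]
#' @examples
#' set.seed(42)
#' t <- sort(runif(120, 0, 10000))
#' y <- 400 - 0.02 * t + rnorm(120, 0, 15)   # rises toward the present
#' sz <- snsizer(t, y, n_scales = 12, grid_n = 81)
#' summary(sz)
#' @export
snsizer <- function(t, y, scales = NULL, grid = NULL, n_scales = 50,
                    grid_n = 401, alpha = 0.05, ess_min = 5,
                    highlight = NULL) {
  stopifnot(length(t) == length(y))
  if (anyNA(t) || anyNA(y) || any(!is.finite(t)) || any(!is.finite(y)))
    stop("t and y must be finite")
  n <- length(t)
  if (n < 10L) stop("need at least 10 observations for a significance map")
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  if (any(diff(t) <= 0)) stop("duplicated time points")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (ess_min < 1) stop("ess_min must be >= 1")

  if (is.null(scales)) {
    h_lo <- 2 * stats::median(diff(t))
    h_hi <- diff(range(t)) / 2
    if (h_lo >= h_hi) stop("degenerate default scale grid; supply scales")
    scales <- 10^seq(log10(h_lo), log10(h_hi), length.out = n_scales)
  }
  scales <- sort(as.numeric(scales))
  if (length(scales) < 2L) stop("need at least 2 scales")
  if (any(scales <= 0)) stop("scales must be positive")
  if (is.null(grid)) grid <- seq(min(t), max(t), length.out = grid_n)
  grid <- sort(as.numeric(grid))
  if (min(grid) < min(t) - diff(range(t)) || max(grid) > max(t) + diff(range(t)))
    stop("time grid far outside the data range")

  S <- length(scales); G <- length(grid)
  dn <- list(sprintf("h=%.6g", scales), NULL)
  state <- matrix("insufficient", S, G, dimnames = dn)
  deriv <- scaled <- se <- ess <- smooth <- matrix(NA_real_, S, G,
                                                   dimnames = dn)
  sigma2 <- edf <- numeric(S)

  dd <- outer(t, t, "-")                # reused across scales
  for (s in seq_len(S)) {
    h <- scales[s]
    ess[s, ] <- effective_sample_size(t, h, grid)
    # noise level at this scale from NW residuals at the data points
    Kd <- gauss_k(dd, h)
    rsK <- rowSums(Kd)
    yhat <- drop(Kd %*% y) / rsK
    trS <- sum(1 / rsK)                 # diagonal of the smoother matrix
    nu <- max(n - trS, 1)
    sigma2[s] <- sum((y - yhat)^2) / nu
    edf[s] <- nu

    W <- nw_deriv_weights(t, h, grid)
    d_age <- drop(W %*% y)
    deriv[s, ] <- -d_age                # toward-present convention
    scaled[s, ] <- -h * d_age
    se[s, ] <- sqrt(sigma2[s] * rowSums(W^2))
    smooth[s, ] <- nw_smooth(t, y, h, grid)

    ok <- is.finite(deriv[s, ]) & ess[s, ] >= ess_min
    if (any(ok)) {
      st <- rep("none", G)
      if (stats::sd(y) > 0) {           # a constant series has no features
        q <- sizer_quantile(W, ok, nu, alpha)
        st[deriv[s, ] - q * se[s, ] > 0] <- "increase"
        st[deriv[s, ] + q * se[s, ] < 0] <- "decrease"
      }
      st[!ok] <- "insufficient"
      state[s, ] <- st
    }
  }

  if (is.null(highlight)) {
    lh <- log10(scales)
    targets <- min(lh) + c(0.25, 0.5, 0.75) * diff(range(lh))
    highlight <- scales[vapply(targets, function(x) which.min(abs(lh - x)),
                               integer(1))]
  } else {
    highlight <- vapply(highlight, function(h) match_scale(h, scales),
                        numeric(1))
  }

  structure(list(state = state, deriv = deriv, scaled = scaled, se = se,
                 ess = ess, smooth = smooth, grid = grid, scales = scales,
                 highlight = highlight, alpha = alpha, ess_min = ess_min,
                 sigma2 = sigma2, edf = edf, n = n, t = t, y = y),
            class = "snsizer")
}

# Row-wise simultaneous quantile from the expected-crossings bound for the
# discrete t-field Z_j = w_j' y / (sigma ||w_j||): kappa counts the
# standardized sign-change opportunities along the row.
sizer_quantile <- function(W, ok, nu, alpha) {
  Wok <- W[ok, , drop = FALSE]
  norms <- sqrt(rowSums(Wok^2))
  G <- nrow(Wok)
  kappa <- if (G > 1L) {
    rho <- rowSums(Wok[-G, , drop = FALSE] * Wok[-1L, , drop = FALSE]) /
      (norms[-G] * norms[-1L])
    sum(sqrt(pmax(2 * (1 - rho), 0)))
  } else 0
  f <- function(q)
    2 * stats::pt(q, nu, lower.tail = FALSE) +
    (kappa / pi) * (1 + q^2 / nu)^(-(nu - 1) / 2) - alpha
  lo <- stats::qt(1 - alpha / 2, nu)
  if (f(lo) <= 0) return(lo)
  stats::uniroot(f, c(lo, 50), tol = 1e-8)$root
}

# exact scale-row lookup; no silent nearest-row snapping
match_scale <- function(h, scales) {
  i <- which(abs(log10(scales) - log10(h)) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("bandwidth %.6g is not a scale row of this map", h))
  scales[i]
}

#' @export
print.snsizer <- function(x, ...) {
  cat(sprintf("SnSiZer map: %d scales x %d time points (n = %d, alpha = %g)\n",
              length(x$scales), length(x$grid), x$n, x$alpha))
  tab <- table(factor(x$state,
                      c("increase", "decrease", "none", "insufficient")))
  cat("  pixel states: ",
      paste(sprintf("%s %.1f%%", names(tab), 100 * tab / sum(tab)),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  scales: %.4g-%.4g (log10 %.3g-%.3g); highlighted: %s\n",
              min(x$scales), max(x$scales), log10(min(x$scales)),
              log10(max(x$scales)),
              paste(sprintf("%.4g", x$highlight), collapse = ", ")))
  invisible(x)
}

#' @export
summary.snsizer <- function(object, ...) {
  print(object)
  for (h in object$highlight) {
    iv <- extract_intervals(object, h)
    cat(sprintf("  h = %.4g: %d significant interval(s)\n", h, nrow(iv)))
    if (nrow(iv) > 0L)
      for (i in seq_len(nrow(iv)))
        cat(sprintf("    %s %.5g -> %.5g (peak |h dL/dt| = %.4g)\n",
                    iv$direction[i], iv$start[i], iv$end[i], iv$peak[i]))
  }
  invisible(object)
}

#' Extract significant intervals at one smoothing level
#'
#' Maximal runs of consecutive `increase` (or `decrease`) pixels along the
#' requested scale row become intervals. Endpoints are the outer pixel
#' edges (pixel centres +/- half a grid step); `start` is the older edge.
#' The bandwidth must be exactly one of the map's scale rows.
#'
#' @param object an [snsizer] map.
#' @param h bandwidth of the scale row to cut.
#' @return Data frame with columns `h`, `start`, `end` (age units, start
#'   older), `direction` ("increase"/"decrease") and `peak` (largest
#'   |scale-normalized derivative| in the run).
#' @export
extract_intervals <- function(object, h) {
  stopifnot(inherits(object, "snsizer"))
  h <- match_scale(h, object$scales)
  s <- which(object$scales == h)
  st <- object$state[s, ]
  grid <- object$grid
  half <- if (length(grid) > 1L) diff(grid) / 2 else 0
  lo_edge <- grid - c(half[1L], half)
  hi_edge <- grid + c(half, half[length(half)])
  out <- data.frame(h = numeric(), start = numeric(), end = numeric(),
                    direction = character(), peak = numeric(),
                    stringsAsFactors = FALSE)
  for (dir in c("increase", "decrease")) {
    r <- rle(st == dir)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- starts[k]; i2 <- ends[k]
      out <- rbind(out, data.frame(
        h = h,
        start = max(hi_edge[i2], hi_edge[i1]),   # older edge (larger BP)
        end = min(lo_edge[i1], lo_edge[i2]),
        direction = dir,
        peak = max(abs(object$scaled[s, i1:i2])),
        stringsAsFactors = FALSE))
    }
  }
  out[order(-out$start), , drop = FALSE]
}

#' Plot an SnSiZer map
#'
#' Renders the (time, log10 bandwidth) lattice with the conventional
#' palette: red for significant increases toward the present, blue for
#' significant decreases, dark grey for no significant change and light
#' grey where the sampling resolution is too low. Colour intensity encodes
#' the relative magnitude of the scale-normalized derivative, normalised by
#' the largest value over all significant pixels of the map. The time axis
#' is reversed (past on the right) and horizontal lines mark the
#' highlighted smoothing levels.
#'
#' @param x an [snsizer] map.
#' @param shade use magnitude shading (default `TRUE`).
#' @param xlab,ylab,main usual graphics labels.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.snsizer <- function(x, shade = TRUE, xlab = "Age (yr BP)",
                         ylab = expression(log[10](h)),
                         main = "SnSiZer significance map", ...) {
  nlev <- 8L
  peak <- suppressWarnings(max(abs(x$scaled[x$state %in%
                                              c("increase", "decrease")])))
  if (!is.finite(peak) || peak == 0) peak <- 1
  rel <- pmin(abs(x$scaled) / peak, 1)
  lev <- if (shade) pmax(ceiling(rel * nlev), 1L) else nlev
  code <- matrix(0L, nrow(x$state), ncol(x$state))
  code[x$state == "none"] <- 1L
  code[x$state == "increase"] <- 1L + lev[x$state == "increase"]
  code[x$state == "decrease"] <- 1L + nlev + lev[x$state == "decrease"]
  reds <- grDevices::colorRampPalette(c("mistyrose", "red3"))(nlev)
  blues <- grDevices::colorRampPalette(c("lightsteelblue1", "blue3"))(nlev)
  pal <- c("grey85", "grey40", reds, blues)
  graphics::image(x$grid, log10(x$scales), t(code), col = pal,
                  breaks = seq(-0.5, 1.5 + 2 * nlev, by = 1),
                  xlim = rev(range(x$grid)), xlab = xlab, ylab = ylab,
                  main = main, ...)
  graphics::abline(h = log10(x$highlight), col = c("red", "blue", "gold2"),
                   lwd = 2)
  invisible(x)
}

#' Export an SnSiZer map to CSV
#'
#' Writes two parallel matrices over the (scale, time) lattice: state codes
#' (+1 increase, -1 decrease, 0 none, NA insufficient) and scale-normalized
#' derivatives, plus the interval list for every highlighted level.
#'
#' @param x an [snsizer] map.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_snsizer <- function(x, dir) {
  stopifnot(inherits(x, "snsizer"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  code <- matrix(NA_integer_, nrow(x$state), ncol(x$state))
  code[x$state == "increase"] <- 1L
  code[x$state == "decrease"] <- -1L
  code[x$state == "none"] <- 0L
  hdr <- c(sprintf("# snsizer alpha=%g ess_min=%g n=%d", x$alpha, x$ess_min,
                   x$n),
           sprintf("# scales=%s", paste(sprintf("%.8g", x$scales),
                                        collapse = ";")),
           sprintf("# highlight=%s", paste(sprintf("%.8g", x$highlight),
                                           collapse = ";")))
  wr <- function(m, file) {
    con <- file(file.path(dir, file), "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(data.frame(h = x$scales, m, check.names = FALSE),
                     con, row.names = FALSE)
  }
  colnames(code) <- sprintf("t%.8g", x$grid)
  wr(code, "snsizer_states.csv")
  sc <- signif(x$scaled, 8)
  colnames(sc) <- sprintf("t%.8g", x$grid)
  wr(sc, "snsizer_scaled_derivative.csv")
  iv <- do.call(rbind, lapply(x$highlight, function(h)
    extract_intervals(x, h)))
  utils::write.csv(iv, file.path(dir, "snsizer_intervals.csv"),
                   row.names = FALSE)
  invisible(dir)
}
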