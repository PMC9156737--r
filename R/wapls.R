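#' Weighted Averaging-Partial Least Squares transfer function
#'
#' Fits a WA-PLS calibration model relating a samples x taxa abundance table
#' to a single climate variable. WA-PLS assumes each taxon has a unimodal
#' response along the climate gradient; successive components are weighted
#' averages of residual climate that progressively correct the basic
#' weighted-average predictor.
#'
#' The algorithm works on the square-root transformed proportion matrix
#' \eqn{Y} with row sums \eqn{y_{i+}} and column sums \eqn{y_{+k}}:
#' starting from residuals \eqn{r_i = x_i - \bar x} (with \eqn{\bar x} the
#' \eqn{y_{i+}}-weighted mean of the climate variable), each component takes
#' taxon scores \eqn{u_k = \sum_i y_{ik} r_i / y_{+k}}, sample scores
#' \eqn{z_i = \sum_k y_{ik} u_k / y_{i+}}, orthogonalises \eqn{z} against
#' earlier components under weights \eqn{y_{i+}}, standardises it to
#' weighted mean 0 / variance 1, and regresses \eqn{x} on all components so
#' far by weighted least squares; the regression residuals feed the next
#' component. Every affine step has an exact taxon-space representation, so
#' the fitted model collapses to one coefficient vector \eqn{\beta^{(c)}}
#' per component count with
#' \deqn{\hat x_i = \sum_k y_{ik} \beta^{(c)}_k / y_{i+},}
#' i.e. prediction is an abundance-weighted average of taxon coefficients
#' (intercepts are absorbed because the weights are the row sums of the same
#' matrix). With one component this reduces exactly to classical Weighted
#' Averaging with (weighted) inverse deshrinking.
#'
#' @param y an [assemblage] with `kind = "sqrt_proportions"`, or a plain
#'   numeric matrix on that scale.
#' @param x numeric vector of the climate variable, one value per sample.
#' @param ncomp maximum number of components to fit (1 to 5).
#' @return An object of class `wapls`: list with `beta` (taxa x ncomp
#'   coefficient matrix), `fitted` (n x ncomp apparent predictions),
#'   `apparent` (per-component R2, RMSE, max bias on the training set),
#'   `x`, `x_bar`, `taxa`, `ncomp`, `transform`.
#' @seealso [predict.wapls()], [wapls_loo()], [performance_stats()]
#' @examples
#' set.seed(1)
#' resp <- make_taxon_responses(12, gradient = c(200, 800), seed = 1)
#' sim <- simulate_modern_trainingset(resp, x = seq(200, 800, length = 60),
#'                                    depth = 300, seed = 2)
#' ytr <- sqrt_transform(to_proportions(sim$assemblage))
#' fit <- wapls(ytr, sim$climate$x, ncomp = 3)
#' fit
#' @export
wapls <- function(y, x, ncomp = 5) {
  Y <- if (inherits(y, "assemblage")) {
    if (y$kind != "sqrt_proportions")
      stop("wapls expects a sqrt_proportions assemblage; apply ",
           "to_proportions() and sqrt_transform() first")
    y$values
  } else as.matrix(y)
  x <- as.numeric(x)
  n <- nrow(Y)
  if (length(x) != n) stop("length(x) must equal nrow(y)")
  if (n < 3L) stop("need at least 3 samples")
  if (!all(is.finite(x))) stop("climate values must be finite")
  if (stats::sd(x) == 0) stop("climate variable is constant")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > 5L) stop("ncomp must be between 1 and 5")

  zero <- colSums(Y) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero taxon column(s): %s", sum(zero),
                    paste(colnames(Y)[zero], collapse = ", ")))
    Y <- Y[, !zero, drop = FALSE]
  }
  if (ncol(Y) < 2L) stop("need at least 2 taxa with nonzero totals")

  r <- rowSums(Y)                       # y_i+
  if (any(r == 0)) stop("sample(s) with all-zero abundances")
  s <- colSums(Y)                       # y_+k
  x_bar <- sum(r * x) / sum(r)

  m <- ncol(Y)
  beta <- matrix(NA_real_, m, ncomp,
                 dimnames = list(colnames(Y), paste0("comp", seq_len(ncomp))))
  fitted <- matrix(NA_real_, n, ncomp,
                   dimnames = list(rownames(Y), paste0("comp", seq_len(ncomp))))
  Z <- matrix(0, n, ncomp)              # standardized sample scores
  A <- matrix(0, m, ncomp)              # taxon-space representation of Z
  e <- x - x_bar
  for (c in seq_len(ncomp)) {
    u <- drop(crossprod(Y, e)) / s      # taxon scores of residuals
    z <- drop(Y %*% u) / r              # sample scores
    a <- u
    if (c > 1L) {
      for (j in seq_len(c - 1L)) {      # weighted Gram-Schmidt (components
        phi <- sum(r * z * Z[, j]) / sum(r)   # are orthonormal under r)
        z <- z - phi * Z[, j]
        a <- a - phi * A[, j]
      }
    }
    mu <- sum(r * z) / sum(r)
    sdev <- sqrt(sum(r * (z - mu)^2) / sum(r))
    if (sdev < 1e-12) {
      if (c == 1L) stop("degenerate component: taxon scores carry no signal")
      warning(sprintf("component %d is degenerate; stopping at %d", c, c - 1L))
      beta <- beta[, seq_len(c - 1L), drop = FALSE]
      fitted <- fitted[, seq_len(c - 1L), drop = FALSE]
      ncomp <- c - 1L
      break
    }
    z <- (z - mu) / sdev
    a <- (a - mu) / sdev                # constant shifts commute with the
    Z[, c] <- z                         # weighted-average operator
    A[, c] <- a
    fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, Z[, seq_len(c), drop = FALSE]),
                          x, w = r)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    beta[, c] <- cf[1L] + drop(A[, seq_len(c), drop = FALSE] %*% cf[-1L])
    fitted[, c] <- drop(Y %*% beta[, c]) / r
    e <- x - fitted[, c]
  }

  apparent <- t(vapply(seq_len(ncomp), function(c)
    unlist(performance_stats(fitted[, c], x)), numeric(3)))
  rownames(apparent) <- colnames(beta)

  structure(list(beta = beta, fitted = fitted, apparent = apparent,
                 x = x, x_bar = x_bar, taxa = rownames(beta),
                 ncomp = ncomp, transform = "sqrt_proportions"),
            class = "wapls")
}

#' @export
print.wapls <- function(x, ...) {
  cat(sprintf("WA-PLS transfer function: %d taxa, %d samples, %d component(s)\n",
              length(x$taxa), length(x$x), x$ncomp))
  cat("Apparent performance (training set):\n")
  print(round(x$apparent, 4))
  invisible(x)
}

#' @export
summary.wapls <- function(object, ...) {
  print(object)
  cat(sprintf("\nWeighted climate mean: %.6g\n", object$x_bar))
  rng <- range(object$beta, na.rm = TRUE)
  cat(sprintf("Taxon coefficient range: [%.6g, %.6g]\n", rng[1], rng[2]))
  invisible(object)
}

#' @export
coef.wapls <- function(object, ...) object$beta

#' @export
fitted.wapls <- function(object, ncomp = object$ncomp, ...)
  object$fitted[, ncomp]

#' @export
residuals.wapls <- function(object, ncomp = object$ncomp, ...)
  object$x - object$fitted[, ncomp]

#' Predict climate for new (fossil) assemblages
#'
#' Prediction is the abundance-weighted average of taxon coefficients over
#' the taxa shared with the training set, computed on the square-root
#' transformed proportions of the new samples. It is therefore invariant to
#' rescaling any sample's counts by a positive constant. Taxa unknown to the
#' model are dropped with a message; predictions outside the training
#' gradient may occur and negative values are returned as-is but flagged in
#' the `"flagged_negative"` attribute.
#'
#' @param object a fitted [wapls] model.
#' @param newdata an [assemblage] with `kind = "sqrt_proportions"` (or a
#'   matrix on that scale) whose columns are taxon names.
#' @param ncomp component count to use (default 2, the usual choice for
#'   noisy calibration sets).
#' @param ... unused.
#' @return Numeric vector of predictions, named by sample id, with
#'   attribute `flagged_negative` (integer indices) when applicable.
#' @export
predict.wapls <- function(object, newdata, ncomp = min(2L, object$ncomp), ...) {
  F <- if (inherits(newdata, "assemblage")) {
    if (newdata$kind != "sqrt_proportions")
      stop("newdata must be on the sqrt_proportions scale")
    newdata$values
  } else as.matrix(newdata)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > object$ncomp)
    stop("ncomp must be between 1 and ", object$ncomp)
  shared <- intersect(colnames(F), object$taxa)
  if (length(shared) == 0L) stop("no taxa shared with the training set")
  unknown <- setdiff(colnames(F), object$taxa)
  if (length(unknown) > 0L)
    message(sprintf("predict.wapls: dropping %d taxa unseen in training",
                    length(unknown)))
  Fs <- F[, shared, drop = FALSE]
  denom <- rowSums(Fs)
  pred <- drop(Fs %*% object$beta[shared, ncomp]) / denom
  if (any(denom == 0)) {
    warning("sample(s) with zero abundance across shared taxa; returning NA")
    pred[denom == 0] <- NA_real_
  }
  names(pred) <- rownames(F)
  neg <- which(!is.na(pred) & pred < 0)
  if (length(neg) > 0L) {
    attr(pred, "flagged_negative") <- neg
    warning(sprintf("%d negative prediction(s) flagged (kept as-is)",
                    length(neg)))
  }
  pred
}

#' Transfer-function performance statistics
#'
#' @param pred,obs numeric vectors of predicted and observed climate values.
#' @return List with `r2` (squared Pearson correlation of predicted vs
#'   observed), `rmsep` (root mean square error of prediction) and
#'   `max_bias` (the observed range is cut into 10 equal-width segments; the
#'   per-segment mean residual pred - obs is computed and the largest
#'   absolute value among non-empty segments returned).
#' @export
performance_stats <- function(pred, obs) {
  pred <- as.numeric(pred); obs <- as.numeric(obs)
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(obs) < 3L) stop("need at least 3 pairs")
  if (stats::sd(obs) == 0) stop("observed values are constant")
  resid <- pred - obs
  breaks <- seq(min(obs), max(obs), length.out = 11L)
  seg <- findInterval(obs, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bias <- tapply(resid, seg, mean)
  list(r2 = stats::cor(pred, obs)^2,
       rmsep = sqrt(mean(resid^2)),
       max_bias = max(abs(bias)))
}

#' Leave-one-out cross-validation of WA-PLS
#'
#' Each training sample is predicted from a model refitted on the remaining
#' n - 1 samples, for every component count up to `ncomp`; R2, RMSEP and
#' maximum bias are computed from those held-out predictions. The default
#' selected component count is 2: with noisy compositional data additional
#' components chase noise even when they reduce the apparent error.
#'
#' @inheritParams wapls
#' @param ncomp number of components (default 5).
#' @param select component count reported as selected (default 2).
#' @return An object of class `wapls_cv`: list with `predictions` (n x
#'   ncomp matrix of LOO predictions), `stats` (per-component r2, rmsep,
#'   max_bias), `selected`.
#' @export
wapls_loo <- function(y, x, ncomp = 5, select = 2) {
  Y <- if (inherits(y, "assemblage")) y$values else as.matrix(y)
  x <- as.numeric(x)
  n <- nrow(Y)
  if (n < 4L) stop("leave-one-out needs at least 4 samples")
  ncomp <- as.integer(ncomp)
  pred <- matrix(NA_real_, n, ncomp,
                 dimnames = list(rownames(Y), paste0("comp", seq_len(ncomp))))
  for (i in seq_len(n)) {
    fit <- suppressWarnings(wapls(Y[-i, , drop = FALSE], x[-i], ncomp = ncomp))
    row <- Y[i, , drop = FALSE]
    for (c in seq_len(fit$ncomp))
      pred[i, c] <- suppressWarnings(suppressMessages(
        predict(fit, row, ncomp = c)))
  }
  stats <- t(vapply(seq_len(ncomp), function(c)
    unlist(performance_stats(pred[, c], x)), numeric(3)))
  rownames(stats) <- colnames(pred)
  select <- min(as.integer(select), ncomp)
  structure(list(predictions = pred, stats = stats, x = x,
                 selected = select),
            class = "wapls_cv")
}

#' @export
print.wapls_cv <- function(x, ...) {
  cat(sprintf("WA-PLS leave-one-out cross-validation (n = %d)\n",
              length(x$x)))
  print(round(x$stats, 4))
  best <- which.min(x$stats[, "rmsep"])
  cat(sprintf("Selected: %d component(s)", x$selected))
  if (best != x$selected)
    cat(sprintf("  [note: CV-optimal RMSEP at %d component(s)]", best))
  cat("\n")
  invisible(x)
}

#' Variance inflation factors
#'
#' Each variable is regressed by ordinary least squares on all the others;
#' `VIF = 1 / (1 - R2)`. Values above `threshold` (default 20, the usual
#' cutoff in pollen-climate calibration work) are flagged as collinear.
#' Exactly collinear variables yield `Inf` rather than an error.
#'
#' @param x numeric matrix or data frame of climate variables (>= 2
#'   columns, each non-constant).
#' @param threshold flag level for high collinearity.
#' @return Named numeric vector of VIFs with logical attribute `flagged`.
#' @export
vif <- function(x, threshold = 20) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 variables")
  if (any(apply(x, 2L, stats::sd) == 0)) stop("constant variable")
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x) %||% paste0("v", seq_len(ncol(x)))
  attr(out, "flagged") <- out > threshold
  out
}

#' Serialize a WA-PLS model to CSV
#'
#' Writes the taxon coefficient matrix with a commented metadata header
#' (weighted climate mean, component count, transform tag).
#'
#' @param object a [wapls] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wapls <- function(object, path) {
  stopifnot(inherits(object, "wapls"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# wapls x_bar=%.12g ncomp=%d transform=%s",
                       object$x_bar, object$ncomp, object$transform)), con)
  df <- data.frame(taxon = object$taxa,
                   signif(object$beta, 12), check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
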