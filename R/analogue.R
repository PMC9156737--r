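#' Squared-chord distance between two composition vectors
#'
#' \eqn{d(p, q) = \sum_k (\sqrt{p_k} - \sqrt{q_k})^2}, the standard
#' assemblage dissimilarity; ranges from 0 (identical compositions) to 2
#' (no shared taxa). Both vectors must be proportions over the same taxon
#' universe (absences coded as 0).
#'
#' @param p,q non-negative numeric vectors of equal length, each summing to
#'   1 within 1e-9.
#' @return The squared-chord distance, a scalar in \[0, 2\].
#' @export
squared_chord <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("each vector must sum to 1")
  sum((sqrt(p) - sqrt(q))^2)
}

#' Analogue quality control by minimum squared-chord distance
#'
#' For each fossil sample the minimum squared-chord distance to the modern
#' calibration set is computed and classified against percentiles of a
#' reference distribution, here all modern-modern pairwise distances
#' (n(n-1)/2 values): `good` below the 5th percentile, `fair` between the
#' 5th and 10th, `none` at or above the 10th. Percentiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#' Distances are computed on untransformed proportions; the square root is
#' already inside the chord formula.
#'
#' @param fossil,modern [assemblage] objects with `kind = "proportions"`.
#'   Taxon universes are merged (absences = 0).
#' @return An object of class `analogue_report`: data frame `samples` with
#'   per-fossil-sample `sample_id`, `age`, `min_distance`,
#'   `nearest_modern_id`, `class`; plus `t5`, `t10`, `proportions` (percent
#'   in each class) and `reference` ("modern-modern pairs").
#' @export
classify_analogues <- function(fossil, modern) {
  stopifnot(inherits(fossil, "assemblage"), inherits(modern, "assemblage"))
  if (fossil$kind != "proportions" || modern$kind != "proportions")
    stop("both tables must be proportions")
  if (nrow(modern$values) < 2L) stop("need at least 2 modern samples")

  univ <- union(colnames(fossil$values), colnames(modern$values))
  pad <- function(v) {
    out <- matrix(0, nrow(v), length(univ),
                  dimnames = list(rownames(v), univ))
    out[, colnames(v)] <- v
    out
  }
  Fs <- sqrt(pad(fossil$values))
  Ms <- sqrt(pad(modern$values))

  # squared chord = squared Euclidean distance between sqrt compositions
  ref <- as.numeric(stats::dist(Ms))^2
  t5 <- unname(stats::quantile(ref, 0.05, type = 7))
  t10 <- unname(stats::quantile(ref, 0.10, type = 7))

  # cross distances via ||f||^2 + ||m||^2 - 2 f.m ; norms are 1 exactly
  cross <- 2 - 2 * tcrossprod(Fs, Ms)
  cross[cross < 0] <- 0                 # numerical floor
  nearest <- apply(cross, 1L, which.min)
  dmin <- cross[cbind(seq_len(nrow(cross)), nearest)]
  cls <- ifelse(dmin < t5, "good", ifelse(dmin < t10, "fair", "none"))

  samples <- data.frame(
    sample_id = rownames(fossil$values),
    age = if (is.null(fossil$ages)) NA_real_ else fossil$ages,
    min_distance = dmin,
    nearest_modern_id = rownames(modern$values)[nearest],
    class = factor(cls, levels = c("good", "fair", "none")),
    stringsAsFactors = FALSE, row.names = NULL)
  prop <- 100 * table(samples$class) / nrow(samples)
  structure(list(samples = samples, t5 = t5, t10 = t10,
                 proportions = c(prop),
                 reference = "modern-modern pairs"),
            class = "analogue_report")
}

#' @export
print.analogue_report <- function(x, ...) {
  cat(sprintf("Analogue QC: %d fossil samples vs reference of %s\n",
              nrow(x$samples), x$reference))
  cat(sprintf("  thresholds: t5 = %.5g, t10 = %.5g\n", x$t5, x$t10))
  cat(sprintf("  good %.2f%%, fair %.2f%%, non-analogue %.2f%%\n",
              x$proportions["good"], x$proportions["fair"],
              x$proportions["none"]))
  invisible(x)
}

#' Write an analogue report to CSV
#'
#' Header comment lines carry the percentile thresholds and the reference
#' population used.
#'
#' @param x an `analogue_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_analogue_report <- function(x, path) {
  stopifnot(inherits(x, "analogue_report"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# analogue thresholds t5=%.12g t10=%.12g", x$t5, x$t10),
               sprintf("# reference=%s", x$reference)), con)
  utils::write.csv(x$samples, con, row.names = FALSE)
  invisible(path)
}
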