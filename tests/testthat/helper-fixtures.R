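# Shared fixtures and independent oracles, built in code at test time.

# small counts table with named taxa
toy_counts <- function() {
  m <- matrix(c(2, 3, 5,
                1, 1, 8,
                4, 4, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("Pinus", "Quercus", "Artemisia")))
  assemblage(m)
}

# random compositional training data on the sqrt-proportion scale
random_sqrt_matrix <- function(n, m, seed) {
  set.seed(seed)
  Y <- matrix(stats::rexp(n * m), n, m)
  Y <- sqrt(Y / rowSums(Y))
  colnames(Y) <- paste0("t", seq_len(m))
  rownames(Y) <- paste0("s", seq_len(n))
  Y
}

# Independent oracle: classical Weighted Averaging with inverse
# deshrinking (weighted regression of x on the initial WA estimates),
# written directly from the definition, no component machinery.
wa_inverse_deshrink <- function(Y, x) {
  u <- colSums(Y * x) / colSums(Y)           # taxon optima
  init <- drop(Y %*% u) / rowSums(Y)         # initial WA estimates
  fit <- stats::lm(x ~ init, weights = rowSums(Y))
  unname(stats::fitted(fit))
}

# Brute-force analogue classifier built from scalar squared_chord calls.
brute_force_analogues <- function(fossil, modern) {
  univ <- union(taxa(fossil), taxa(modern))
  pad <- function(a) {
    out <- matrix(0, nrow(a$values), length(univ),
                  dimnames = list(rownames(a$values), univ))
    out[, taxa(a)] <- a$values
    out
  }
  Fm <- pad(fossil); Mm <- pad(modern)
  nm <- nrow(Mm)
  ref <- numeric(0)
  for (i in seq_len(nm - 1L))
    for (j in (i + 1L):nm)
      ref <- c(ref, squared_chord(Mm[i, ], Mm[j, ]))
  t5 <- unname(stats::quantile(ref, 0.05, type = 7))
  t10 <- unname(stats::quantile(ref, 0.10, type = 7))
  dmin <- apply(Fm, 1L, function(f)
    min(apply(Mm, 1L, function(mo) squared_chord(f, mo))))
  cls <- ifelse(dmin < t5, "good", ifelse(dmin < t10, "fair", "none"))
  list(t5 = t5, t10 = t10, dmin = unname(dmin), class = unname(cls))
}

# significance map stub for exercising interval extraction in isolation
stub_snsizer <- function(states, scales, grid) {
  structure(list(state = states, scaled = abs(states == "increase") * 1 +
                   (states == "decrease") * 1,
                 grid = grid, scales = scales,
                 highlight = scales, alpha = 0.05, ess_min = 5,
                 n = 50L),
            class = "snsizer")
}
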