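# Independent oracles used to cross-check the implementation.  These are
# deliberately written as slow, literal transcriptions (scalar loops,
# brute-force search) and share no code with the package internals.

# Five-layer Sugeno forward pass, one input row at a time:
# layer 1 memberships -> layer 2 products -> layer 3 normalization ->
# layer 4 weighted consequents -> layer 5 sum.
oracle_anfis_predict <- function(model, x) {
  span <- model$ranges$max - model$ranges$min
  xs <- numeric(length(x))
  for (j in seq_along(x)) {
    xs[j] <- if (span[j] > 0) (x[j] - model$ranges$min[j]) / span[j] else 0
  }
  R <- nrow(model$centers)
  w <- numeric(R)
  for (i in seq_len(R)) {
    prod_ij <- 1
    for (j in seq_along(xs)) {
      prod_ij <- prod_ij *
        exp(-(xs[j] - model$centers[i, j])^2 / (2 * model$sigmas[i, j]^2))
    }
    w[i] <- prod_ij
  }
  if (sum(w) < 1e-12) {
    wbar <- rep(1 / R, R)
  } else {
    wbar <- w / sum(w)
  }
  out <- 0
  for (i in seq_len(R)) {
    z_i <- sum(model$coef[i, seq_along(xs)] * xs) + model$coef[i, length(xs) + 1]
    out <- out + wbar[i] * z_i
  }
  out
}

# Non-dominated sorting by repeated peeling with pairwise dominance checks.
oracle_nds <- function(obj) {
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining) > 0) {
    nd <- remaining[vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        i != j && all(obj[j, ] >= obj[i, ]) && any(obj[j, ] > obj[i, ])
      }, logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    remaining <- setdiff(remaining, nd)
  }
  fronts
}

# Consequent design matrix built independently (per-row, per-rule loops).
oracle_consequent_design <- function(model, X) {
  Xs <- X
  span <- model$ranges$max - model$ranges$min
  for (j in seq_len(ncol(X))) {
    Xs[, j] <- if (span[j] > 0) (X[, j] - model$ranges$min[j]) / span[j] else 0
  }
  R <- nrow(model$centers)
  d <- ncol(X)
  A <- matrix(0, nrow(X), R * (d + 1))
  for (n in seq_len(nrow(X))) {
    w <- numeric(R)
    for (i in seq_len(R)) {
      w[i] <- prod(exp(-(Xs[n, ] - model$centers[i, ])^2 /
                         (2 * model$sigmas[i, ]^2)))
    }
    wbar <- if (sum(w) < 1e-12) rep(1 / R, R) else w / sum(w)
    for (i in seq_len(R)) {
      A[n, ((i - 1) * (d + 1) + 1):(i * (d + 1))] <- wbar[i] * c(Xs[n, ], 1)
    }
  }
  A
}

# Random small ANFIS model over [0,1]^d inputs.
random_anfis <- function(d = 3, R = 4, seed = 1) {
  set.seed(seed)
  ranges <- data.frame(min = rep(0, d), max = rep(1, d))
  m <- init_rules_subtractive(matrix(runif(20 * d), ncol = d,
                                     dimnames = list(NULL, paste0("x", 1:d))))
  m$centers <- matrix(runif(R * d), R, d)
  m$sigmas <- matrix(runif(R * d, 0.1, 0.6), R, d)
  m$coef <- matrix(rnorm(R * (d + 1), sd = 2), R, d + 1)
  m$ranges <- ranges
  m
}

# Small synthetic dataset with all feature columns, where the responses
# depend only on the columns listed in `active`.
toy_dataset <- function(n = 120, active = "d24", seed = 7, noise_sd = 0.5) {
  set.seed(seed)
  X <- data.frame(d24 = runif(n, 0, 2.5), bap = runif(n, 0, 2.5),
                  suc = runif(n, 0, 60), glu = runif(n, 0, 90),
                  fru = runif(n, 0, 90), r = runif(n, 0, 255),
                  g = runif(n, 0, 255), b = runif(n, 0, 255))
  y <- 0
  for (v in active) y <- y + 10 * X[[v]] / max(X[[v]])
  X$y <- y + rnorm(n, 0, noise_sd)
  X
}
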