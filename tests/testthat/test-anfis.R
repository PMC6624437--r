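# ANFIS: membership functions, forward pass, rule seeding, hybrid training.

test_that("Gaussian membership has the closed-form profile", {
  mf <- gaussmf(center = 2, sigma = 0.5)
  expect_equal(membership(mf, 2), 1.0)
  expect_equal(membership(mf, 2.5), exp(-0.5))
  expect_equal(membership(mf, 2 - 1.3), membership(mf, 2 + 1.3))
  expect_error(gaussmf(0, 0), "sigma")
})

test_that("firing strengths are per-rule membership products", {
  m <- random_anfis(d = 3, R = 5, seed = 2)
  set.seed(3)
  for (k in 1:20) {
    x <- runif(3)
    w <- firing_strengths(m, x)
    manual <- vapply(1:5, function(i) {
      prod(exp(-(x - m$centers[i, ])^2 / (2 * m$sigmas[i, ]^2)))
    }, numeric(1))
    expect_equal(w, manual, tolerance = 1e-14)
  }
  # two memberships 0.5 and 0.4 -> strength 0.2
  m1 <- random_anfis(d = 2, R = 1, seed = 1)
  m1$centers[1, ] <- c(0.5, 0.5)
  x <- c(0.5 + m1$sigmas[1, 1] * sqrt(2 * log(2)),      # grade 0.5
         0.5 + m1$sigmas[1, 2] * sqrt(2 * log(1 / 0.4)))  # grade 0.4
  expect_equal(firing_strengths(m1, x), 0.2, tolerance = 1e-12)
})

test_that("normalization sums to 1 and floors degenerate totals", {
  w <- normalize_strengths(c(0.2, 0.2))
  expect_equal(as.numeric(w), c(0.5, 0.5))
  expect_false(attr(w, "floored"))
  expect_equal(as.numeric(normalize_strengths(1)), 1.0)
  tiny <- normalize_strengths(c(1e-20, 1e-18, 1e-19))
  expect_true(attr(tiny, "floored"))
  expect_equal(as.numeric(tiny), rep(1 / 3, 3))
  set.seed(9)
  for (k in 1:25) {
    expect_equal(sum(normalize_strengths(runif(sample(1:8, 1)))), 1)
  }
})

test_that("prediction is the convex combination of rule consequents", {
  # one rule -> exactly its linear consequent
  m <- random_anfis(d = 1, R = 1, seed = 4)
  m$coef <- matrix(c(2, 1), 1)   # z = 2x + 1 on scaled input
  for (x in c(0, 0.3, 1)) expect_equal(predict(m, x), 2 * x + 1)
  # identical consequents -> premises irrelevant
  m2 <- random_anfis(d = 2, R = 4, seed = 5)
  m2$coef <- matrix(rep(c(1.5, -2, 0.25), each = 4), 4)
  set.seed(6)
  X <- matrix(runif(20), ncol = 2, dimnames = list(NULL, m2$input_names))
  expect_equal(predict(m2, X),
               as.numeric(X %*% c(1.5, -2) + 0.25), tolerance = 1e-12)
  # bounded by min/max of rule consequent values at every point
  m3 <- random_anfis(d = 2, R = 4, seed = 7)
  Z <- cbind(X, 1) %*% t(m3$coef)
  p <- predict(m3, X)
  expect_true(all(p >= apply(Z, 1, min) - 1e-9))
  expect_true(all(p <= apply(Z, 1, max) + 1e-9))
})

test_that("forward pass equals the independent five-layer oracle", {
  set.seed(8)
  n_cases <- 0
  for (ms in 1:20) {
    d <- sample(1:4, 1)
    m <- random_anfis(d = d, R = sample(2:6, 1), seed = 100 + ms)
    X <- matrix(runif(50 * d), ncol = d,
                dimnames = list(NULL, m$input_names))
    p <- predict(m, X)
    for (i in seq_len(nrow(X))) {
      expect_equal(p[i], oracle_anfis_predict(m, X[i, ]), tolerance = 1e-12)
      n_cases <- n_cases + 1
    }
  }
  expect_equal(n_cases, 1000)
})

test_that("grid partition enumerates rules and guards high dimension", {
  x2 <- matrix(runif(40), ncol = 2)
  m <- init_rules_grid(x2, 3)
  expect_equal(nrow(m$centers), 9)
  x1 <- matrix(seq(2, 10, length.out = 20), ncol = 1)
  m1 <- init_rules_grid(x1, 5)
  expect_equal(nrow(m1$centers), 5)
  # scaled centers span [0,1] evenly = natural min..max
  expect_equal(sort(m1$centers[, 1]), seq(0, 1, 0.25))
  x8 <- matrix(runif(80), ncol = 8)
  expect_error(init_rules_grid(x8, 3), "subtractive")
})

test_that("subtractive clustering finds separated clouds and clamps counts", {
  set.seed(10)
  cloud <- rbind(matrix(rnorm(50, 0.2, 0.02), ncol = 2),
                 matrix(rnorm(50, 0.8, 0.02), ncol = 2))
  m <- init_rules_subtractive(cloud, 0.5)
  expect_equal(nrow(m$centers), 2)
  # centers near the cloud centroids (scaled space ~ [0,1]^2)
  got <- m$centers[order(m$centers[, 1]), ]
  expect_true(all(abs(got[1, ] - c(0.05, 0.05)) < 0.2))
  expect_true(all(abs(got[2, ] - c(0.95, 0.95)) < 0.2))
  # one duplicated row -> a single rule
  dup <- matrix(rep(c(1, 2, 3), each = 10), nrow = 10)
  expect_equal(nrow(init_rules_subtractive(dup)$centers), 1)
  # never more than 30 rules
  big <- matrix(runif(2000), ncol = 4)
  expect_lte(nrow(init_rules_subtractive(big, 0.2)$centers), 30)
})

test_that("consequent least squares matches the normal-equations oracle", {
  set.seed(11)
  m <- random_anfis(d = 2, R = 3, seed = 12)
  X <- matrix(runif(60), ncol = 2, dimnames = list(NULL, m$input_names))
  y <- rnorm(30)
  lam <- 1e-6
  fitted <- solve_consequents(m, X, y, lam)
  A <- oracle_consequent_design(m, X)
  theta <- solve(t(A) %*% A + lam * diag(ncol(A)), t(A) %*% y)
  expect_equal(as.numeric(t(fitted$coef)), as.numeric(theta),
               tolerance = 1e-8)
  # single rule + exactly linear targets -> recovers the coefficients
  m1 <- random_anfis(d = 1, R = 1, seed = 13)
  X1 <- matrix(runif(30), ncol = 1, dimnames = list(NULL, m1$input_names))
  y1 <- as.numeric(3.5 * X1 - 0.7)
  f1 <- solve_consequents(m1, X1, y1, 1e-12)
  expect_equal(as.numeric(f1$coef), c(3.5, -0.7), tolerance = 1e-6)
  # heavy ridge shrinks the solution toward zero
  fbig <- solve_consequents(m1, X1, y1, 1e8)
  expect_lt(sum(fbig$coef^2), 1e-6)
  expect_error(solve_consequents(m1, X1, c(y1[-1], NA)), "non-finite")
})

test_that("premise gradients match central finite differences", {
  for (case in 1:3) {
    m <- random_anfis(d = 2, R = 3, seed = 20 + case)
    set.seed(30 + case)
    X <- matrix(runif(40), ncol = 2, dimnames = list(NULL, m$input_names))
    y <- rnorm(20)
    grads <- anfisopt:::.premise_gradients(m$centers, m$sigmas, m$coef, X, y)
    mse_at <- function(centers, sigmas) {
      mm <- m; mm$centers <- centers; mm$sigmas <- sigmas
      mean((predict(mm, X) - y)^2)
    }
    h <- 1e-6
    for (i in 1:3) for (j in 1:2) {
      cp <- m$centers; cm <- m$centers
      cp[i, j] <- cp[i, j] + h; cm[i, j] <- cm[i, j] - h
      fd_c <- (mse_at(cp, m$sigmas) - mse_at(cm, m$sigmas)) / (2 * h)
      expect_equal(grads$centers[i, j], fd_c,
                   tolerance = 1e-5 * max(1, abs(fd_c)))
      sp <- m$sigmas; sm <- m$sigmas
      sp[i, j] <- sp[i, j] + h; sm[i, j] <- sm[i, j] - h
      fd_s <- (mse_at(m$centers, sp) - mse_at(m$centers, sm)) / (2 * h)
      expect_equal(grads$sigmas[i, j], fd_s,
                   tolerance = 1e-5 * max(1, abs(fd_s)))
    }
  }
})

test_that("gradient step is the identity at zero error or zero rate", {
  m <- random_anfis(d = 1, R = 1, seed = 40)
  m$coef <- matrix(c(2, 1), 1)
  set.seed(41)
  X <- matrix(runif(25), ncol = 1, dimnames = list(NULL, m$input_names))
  y <- predict(m, X)   # zero training error
  stepped <- premise_gradient_step(m, X, y, 0.1)
  expect_equal(stepped$centers, m$centers)
  expect_equal(stepped$sigmas, m$sigmas)
  m2 <- random_anfis(d = 2, R = 3, seed = 42)
  y2 <- rnorm(20)
  X2 <- matrix(runif(40), ncol = 2, dimnames = list(NULL, m2$input_names))
  frozen <- premise_gradient_step(m2, X2, y2, 0)
  expect_equal(frozen$centers, m2$centers)
  expect_equal(frozen$sigmas, m2$sigmas)
})

test_that("hybrid fit drives a realizable target to machine error", {
  set.seed(50)
  X <- matrix(runif(60, 0, 10), ncol = 1, dimnames = list(NULL, "x1"))
  y <- as.numeric(2 * X + 3)
  m <- fit_anfis(X, y, train_config(rule_init = "grid", mfs_per_input = 3))
  expect_lt(rmse(y, predict(m, X)), 1e-6)
  trace <- attr(m, "loss_trace")
  expect_equal(length(trace), 10)
  expect_equal(min(trace), rmse(y, predict(m, X)), tolerance = 1e-9)
  # best-so-far retention makes the retained loss non-increasing
  expect_true(all(diff(cummin(trace)) <= 0))
})

test_that("fit recovers the function of a known small ANFIS", {
  gen <- random_anfis(d = 2, R = 4, seed = 60)
  set.seed(61)
  X <- matrix(runif(400), ncol = 2, dimnames = list(NULL, gen$input_names))
  y <- predict(gen, X)
  m <- fit_anfis(X, y, train_config(rule_init = "grid", mfs_per_input = 3))
  expect_lt(rmse(y, predict(m, X)), 0.05 * sd(y))
})

test_that("JSON serialization round-trips to full precision", {
  d <- toy_dataset(n = 60, active = c("d24", "glu"), seed = 70)
  m <- fit_anfis(d[, FEATURE_NAMES], d$y, output_name = "y")
  path <- withr::local_tempfile(fileext = ".json")
  anfis_to_json(m, path)
  m2 <- anfis_from_json(path)
  expect_identical(unname(m2$centers), unname(m$centers))
  expect_identical(m2$sigmas, m$sigmas)
  expect_identical(m2$coef, m$coef)
  expect_equal(m2$ranges$min, unname(m$ranges$min))
  X <- d[1:10, FEATURE_NAMES]
  expect_identical(predict(m2, X), predict(m, X))
})
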