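# First-order Sugeno adaptive neuro-fuzzy inference system (ANFIS):
# Gaussian premises, linear consequents, hybrid least-squares /
# gradient-descent training.
#
# Internal convention: inputs are min-max scaled to [0,1] per feature using
# ranges recorded on the model; all public I/O is in natural units.
# A model is a list with
#   centers, sigmas : R x d matrices (scaled space)
#   coef            : R x (d+1) matrix, consequent (p_1..p_d, intercept)
#   ranges          : data.frame(min, max) per feature
#   input_names, output_name, config

W_FLOOR <- 1e-12   # total firing strength below this -> uniform weights
SIGMA_FLOOR <- 1e-3  # minimum premise width, in scaled units (range = 1)

#' Gaussian membership function
#'
#' @param center Center `c` (membership equals 1 there).
#' @param sigma Width, strictly positive.
#' @return Object of class `gaussmf`.
#' @export
gaussmf <- function(center, sigma) {
  stopifnot(is.finite(center), is.finite(sigma), sigma > 0)
  structure(list(center = center, sigma = sigma), class = "gaussmf")
}

#' Evaluate a Gaussian membership grade
#'
#' `exp(-(x - c)^2 / (2 sigma^2))`, in (0, 1], equal to 1 at the center.
#'
#' @param mf A [gaussmf()].
#' @param x Numeric vector of evaluation points.
#' @return Membership grades in (0, 1].
#' @export
membership <- function(mf, x) {
  stopifnot(inherits(mf, "gaussmf"))
  exp(-(x - mf$center)^2 / (2 * mf$sigma^2))
}

#' Training configuration for an ANFIS model
#'
#' @param n_epochs Hybrid training epochs (default 10).
#' @param rule_init Rule seeding: `"subtractive"` clustering (default,
#'   feasible for 8 inputs) or `"grid"` partition (low dimension only).
#' @param mfs_per_input Membership functions per input in grid mode (3--5).
#' @param cluster_radius Subtractive-clustering radius in scaled units.
#' @param learning_rate Step size of the premise gradient stage.
#' @param ridge_lambda Ridge penalty of the consequent least-squares stage.
#' @param seed Integer seed (training itself is deterministic; recorded for
#'   provenance).
#' @return Object of class `train_config`.
#' @export
train_config <- function(n_epochs = 10, rule_init = c("subtractive", "grid"),
                         mfs_per_input = 3, cluster_radius = 0.5,
                         learning_rate = 0.01, ridge_lambda = 1e-8,
                         seed = 42) {
  rule_init <- match.arg(rule_init)
  stopifnot(n_epochs >= 1, mfs_per_input %in% 3:5,
            cluster_radius > 0, cluster_radius <= 1,
            learning_rate >= 0, ridge_lambda >= 0)
  structure(list(n_epochs = as.integer(n_epochs), rule_init = rule_init,
                 mfs_per_input = as.integer(mfs_per_input),
                 cluster_radius = cluster_radius,
                 learning_rate = learning_rate, ridge_lambda = ridge_lambda,
                 seed = as.integer(seed)),
            class = "train_config")
}

.new_anfis <- function(centers, sigmas, coef, ranges, input_names,
                       output_name = "y", config = NULL) {
  stopifnot(identical(dim(centers), dim(sigmas)),
            nrow(coef) == nrow(centers),
            ncol(coef) == ncol(centers) + 1L)
  structure(list(centers = centers, sigmas = pmax(sigmas, SIGMA_FLOOR),
                 coef = coef, ranges = ranges, input_names = input_names,
                 output_name = output_name, config = config),
            class = "anfis")
}

#' @export
print.anfis <- function(x, ...) {
  cat(sprintf("ANFIS model for '%s': %d rules, %d inputs (%s)\n",
              x$output_name, nrow(x$centers), ncol(x$centers),
              paste(x$input_names, collapse = ", ")))
  invisible(x)
}

.scale_inputs <- function(x, ranges) {
  span <- ranges$max - ranges$min
  out <- sweep(x, 2, ranges$min, "-")
  for (j in seq_along(span)) {
    out[, j] <- if (span[j] > 0) out[, j] / span[j] else 0
  }
  out
}

.coerce_inputs <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != length(model$input_names)) {
      stop("input dimension mismatch: expected ",
           length(model$input_names), " features")
    }
    x <- matrix(as.numeric(x), nrow = 1,
                dimnames = list(NULL, model$input_names))
  } else {
    x <- as.data.frame(x)
    if (!all(model$input_names %in% names(x))) {
      stop("input is missing features: ",
           paste(setdiff(model$input_names, names(x)), collapse = ", "))
    }
    x <- as.matrix(x[, model$input_names, drop = FALSE])
  }
  storage.mode(x) <- "double"
  x
}

# Firing-strength matrix (n x R) on scaled inputs.
.firing_matrix <- function(centers, sigmas, xs) {
  n <- nrow(xs)
  R <- nrow(centers)
  W <- matrix(0, n, R)
  for (i in seq_len(R)) {
    q <- sweep(xs, 2, centers[i, ], "-")
    q <- sweep(q^2, 2, 2 * sigmas[i, ]^2, "/")
    W[, i] <- exp(-rowSums(q))
  }
  W
}

#' Rule firing strengths at a point
#'
#' Product of the rule's per-input Gaussian membership grades (AND as
#' product).
#'
#' @param model An `anfis` model.
#' @param x Input vector (natural units) or matrix/data frame of inputs.
#' @return Numeric vector of per-rule strengths (or matrix, one row per
#'   input row).
#' @export
firing_strengths <- function(model, x) {
  stopifnot(inherits(model, "anfis"))
  xs <- .scale_inputs(.coerce_inputs(model, x), model$ranges)
  W <- .firing_matrix(model$centers, model$sigmas, xs)
  if (nrow(W) == 1L) drop(W) else W
}

#' Normalize firing strengths
#'
#' Divides each strength by the total; if the total underflows below the
#' floor (1e-12) the weights are returned uniform and flagged via the
#' `"floored"` attribute.
#'
#' @param w Non-negative numeric vector of rule strengths.
#' @return Weights summing to 1, with logical attribute `floored`.
#' @export
normalize_strengths <- function(w) {
  stopifnot(all(w >= 0))
  s <- sum(w)
  if (s < W_FLOOR) {
    out <- rep(1 / length(w), length(w))
    attr(out, "floored") <- TRUE
  } else {
    out <- w / s
    attr(out, "floored") <- FALSE
  }
  out
}

.normalize_matrix <- function(W) {
  s <- rowSums(W)
  floored <- s < W_FLOOR
  s[floored] <- 1
  Wb <- W / s
  Wb[floored, ] <- 1 / ncol(W)
  attr(Wb, "floored") <- floored
  Wb
}

# Raw forward pass on scaled inputs: returns n-vector of outputs.
.forward <- function(centers, sigmas, coef, xs) {
  Wb <- .normalize_matrix(.firing_matrix(centers, sigmas, xs))
  Z <- cbind(xs, 1) %*% t(coef)   # n x R rule consequent values
  rowSums(Wb * Z)
}

#' Predict from an ANFIS model
#'
#' Weighted sum of the rules' linear consequents with normalized firing
#' strengths as weights.  The raw (unclipped) value is returned; response
#' clipping to physical ranges happens at the pipeline layer.
#'
#' @param object An `anfis` model.
#' @param newdata Input vector, matrix or data frame in natural units.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.anfis <- function(object, newdata, ...) {
  xs <- .scale_inputs(.coerce_inputs(object, newdata), object$ranges)
  .forward(object$centers, object$sigmas, object$coef, xs)
}

.input_ranges <- function(x) {
  data.frame(min = apply(x, 2, min), max = apply(x, 2, max),
             row.names = colnames(x))
}

#' Grid-partition rule initialization
#'
#' Places `mfs_per_input` equally spaced Gaussian centers over each input's
#' observed range (width = spacing / sqrt(8 ln 2), the half-overlap
#' convention) and creates one rule per cell of the Cartesian product.
#' Guarded to at most 4 inputs: the rule count grows as `mfs^d`.
#'
#' @param train_inputs Matrix/data frame of training inputs (natural units).
#' @param mfs_per_input Membership functions per input (3--5).
#' @param output_name Response label stored on the model.
#' @return An `anfis` model with zero-initialized consequents.
#' @export
init_rules_grid <- function(train_inputs, mfs_per_input = 3,
                            output_name = "y") {
  x <- as.matrix(train_inputs)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  d <- ncol(x)
  if (d > 4) {
    stop("grid partition rejected for ", d, " inputs (", mfs_per_input, "^",
         d, " rules); use subtractive clustering instead")
  }
  stopifnot(mfs_per_input %in% 3:5)
  ranges <- .input_ranges(x)
  # scaled space: centers equally spaced on [0,1]
  cgrid <- seq(0, 1, length.out = mfs_per_input)
  spacing <- cgrid[2] - cgrid[1]
  sigma <- spacing / sqrt(8 * log(2))
  cells <- as.matrix(expand.grid(rep(list(cgrid), d)))
  colnames(cells) <- colnames(x)
  .new_anfis(centers = cells,
             sigmas = matrix(sigma, nrow(cells), d),
             coef = matrix(0, nrow(cells), d + 1),
             ranges = ranges, input_names = colnames(x),
             output_name = output_name)
}

#' Subtractive-clustering rule initialization
#'
#' Chiu-style subtractive clustering on the min-max scaled inputs
#' (potential kernel radius `cluster_radius`, squash factor 1.25, accept /
#' reject thresholds 0.5 / 0.15).  Each accepted cluster center becomes a
#' rule with per-input Gaussian width `cluster_radius / sqrt(8)` in scaled
#' units; the rule count is capped at 30.  Degenerate data (all rows
#' identical) yields a single default rule.
#'
#' @inheritParams init_rules_grid
#' @param cluster_radius Neighborhood radius in scaled units, in (0, 1].
#' @return An `anfis` model with zero-initialized consequents.
#' @export
init_rules_subtractive <- function(train_inputs, cluster_radius = 0.5,
                                   output_name = "y") {
  x <- as.matrix(train_inputs)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(cluster_radius > 0, cluster_radius <= 1)
  ranges <- .input_ranges(x)
  xs <- .scale_inputs(x, ranges)
  centers <- .subtractive_centers(xs, cluster_radius)
  d <- ncol(x)
  .new_anfis(centers = centers,
             sigmas = matrix(cluster_radius / sqrt(8), nrow(centers), d),
             coef = matrix(0, nrow(centers), d + 1),
             ranges = ranges, input_names = colnames(x),
             output_name = output_name)
}

.subtractive_centers <- function(xs, r_a, squash = 1.25,
                                 accept = 0.5, reject = 0.15,
                                 max_rules = 30L) {
  # operate on distinct rows, weighting potentials by multiplicity
  key <- apply(xs, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  u <- xs[first, , drop = FALSE]
  cnt <- as.numeric(table(factor(key, levels = key[first])))
  m <- nrow(u)
  if (m == 1L) {
    return(u)
  }
  alpha <- 4 / r_a^2
  beta <- 4 / (squash * r_a)^2
  d2 <- as.matrix(stats::dist(u))^2
  pot <- as.vector(exp(-alpha * d2) %*% cnt)
  p_first <- max(pot)
  centers <- integer(0)
  repeat {
    k <- which.max(pot)
    p_k <- pot[k]
    if (p_k <= 0 || length(centers) >= max_rules) break
    if (p_k > accept * p_first) {
      ok <- TRUE
    } else if (p_k < reject * p_first) {
      break
    } else {
      d_min <- sqrt(min(d2[k, centers]))
      if (d_min / r_a + p_k / p_first >= 1) {
        ok <- TRUE
      } else {
        pot[k] <- 0
        next
      }
    }
    if (ok) {
      centers <- c(centers, k)
      pot <- pot - p_k * exp(-beta * d2[, k])
      pot[k] <- 0
    }
  }
  if (length(centers) == 0L) centers <- which.max(cnt)
  u[centers, , drop = FALSE]
}

# Design matrix of the consequent least-squares problem: row blocks
# w_bar_i * (x, 1) for each rule i, on scaled inputs.
.consequent_design <- function(centers, sigmas, xs) {
  Wb <- .normalize_matrix(.firing_matrix(centers, sigmas, xs))
  R <- nrow(centers)
  X1 <- cbind(xs, 1)
  cols <- lapply(seq_len(R), function(i) Wb[, i] * X1)
  do.call(cbind, cols)
}

#' Least-squares stage: solve all consequent parameters jointly
#'
#' With premises fixed, the model output is linear in the consequents; the
#' ridge-regularized normal equations give the global minimizer of the
#' penalized squared error.
#'
#' @param model An `anfis` model.
#' @param train_inputs,train_targets Training data in natural units.
#' @param ridge_lambda Ridge penalty (guards singular systems).
#' @return The model with updated consequent coefficients.
#' @export
solve_consequents <- function(model, train_inputs, train_targets,
                              ridge_lambda = 1e-8) {
  stopifnot(inherits(model, "anfis"))
  x <- .coerce_inputs(model, train_inputs)
  y <- as.numeric(train_targets)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in training data")
  }
  stopifnot(nrow(x) == length(y))
  xs <- .scale_inputs(x, model$ranges)
  A <- .consequent_design(model$centers, model$sigmas, xs)
  p <- ncol(A)
  theta <- solve(crossprod(A) + diag(ridge_lambda, p), crossprod(A, y))
  model$coef <- matrix(theta, nrow = nrow(model$centers),
                       ncol = ncol(model$centers) + 1, byrow = TRUE)
  model
}

# Mean-squared-error and analytic premise gradients on scaled data.
.premise_gradients <- function(centers, sigmas, coef, xs, y) {
  n <- nrow(xs)
  R <- nrow(centers)
  W <- .firing_matrix(centers, sigmas, xs)
  S <- rowSums(W)
  valid <- S >= W_FLOOR
  Wb <- .normalize_matrix(W)
  Z <- cbind(xs, 1) %*% t(coef)
  pred <- rowSums(Wb * Z)
  resid <- pred - y
  gc_ <- centers * 0
  gs_ <- sigmas * 0
  Sv <- ifelse(valid, S, 1)
  for (i in seq_len(R)) {
    # d pred / d w_i = (z_i - pred) / S  (zero where strengths are floored)
    gw <- ifelse(valid, resid * (Z[, i] - pred) / Sv, 0) * W[, i]
    dx <- sweep(xs, 2, centers[i, ], "-")
    gc_[i, ] <- (2 / n) * colSums(gw * sweep(dx, 2, sigmas[i, ]^2, "/"))
    gs_[i, ] <- (2 / n) * colSums(gw * sweep(dx^2, 2, sigmas[i, ]^3, "/"))
  }
  list(centers = gc_, sigmas = gs_, mse = mean(resid^2))
}

#' Gradient stage: one batch descent step on the premise parameters
#'
#' Takes one full-batch gradient-descent step on the training MSE with
#' respect to every Gaussian center and width (analytic gradients,
#' consequents held fixed).  Widths are floored at 1e-3 in scaled units.
#'
#' @inheritParams solve_consequents
#' @param learning_rate Step size (0 leaves the model unchanged).
#' @return The model with updated premise parameters.
#' @export
premise_gradient_step <- function(model, train_inputs, train_targets,
                                  learning_rate = 0.01) {
  stopifnot(inherits(model, "anfis"))
  x <- .coerce_inputs(model, train_inputs)
  y <- as.numeric(train_targets)
  xs <- .scale_inputs(x, model$ranges)
  g <- .premise_gradients(model$centers, model$sigmas, model$coef, xs, y)
  model$centers <- model$centers - learning_rate * g$centers
  model$sigmas <- pmax(model$sigmas - learning_rate * g$sigmas, SIGMA_FLOOR)
  model
}

#' Fit an ANFIS model by hybrid training
#'
#' Seeds the rule base (subtractive clustering by default), then for each
#' epoch solves the consequents by ridge least squares and takes one
#' gradient step on the premises.  The parameter set with the lowest
#' training RMSE across epochs is retained.  Deterministic for a fixed
#' configuration.
#'
#' @param train_inputs Matrix/data frame of inputs (natural units).
#' @param train_targets Numeric response vector.
#' @param config A [train_config()].
#' @param output_name Response label stored on the model.
#' @return An `anfis` model with attributes `loss_trace` (per-epoch
#'   training RMSE after the least-squares stage) and `best_epoch`.
#' @export
fit_anfis <- function(train_inputs, train_targets, config = train_config(),
                      output_name = "y") {
  x <- as.matrix(train_inputs)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(train_targets)
  stopifnot(nrow(x) >= 10, nrow(x) == length(y))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values in training data")
  }
  model <- switch(config$rule_init,
    grid = init_rules_grid(x, config$mfs_per_input, output_name),
    subtractive = init_rules_subtractive(x, config$cluster_radius,
                                         output_name)
  )
  model$config <- config
  best <- NULL
  best_rmse <- Inf
  best_epoch <- NA_integer_
  trace <- numeric(config$n_epochs)
  for (epoch in seq_len(config$n_epochs)) {
    model <- solve_consequents(model, x, y, config$ridge_lambda)
    e <- rmse(y, predict(model, x))
    if (!is.finite(e)) stop("training diverged: non-finite loss at epoch ",
                            epoch)
    trace[epoch] <- e
    if (e < best_rmse) {
      best_rmse <- e
      best <- model[c("centers", "sigmas", "coef")]
      best_epoch <- epoch
    }
    if (epoch < config$n_epochs) {
      model <- premise_gradient_step(model, x, y, config$learning_rate)
    }
  }
  model[c("centers", "sigmas", "coef")] <- best
  attr(model, "loss_trace") <- trace
  attr(model, "best_epoch") <- best_epoch
  model
}

#' Serialize / deserialize an ANFIS model as JSON
#'
#' The round trip is lossless to full double precision (17 significant
#' digits).
#'
#' @param model An `anfis` model.
#' @param path File path.
#' @return `anfis_from_json` returns the model; `anfis_to_json` returns
#'   `path` invisibly.
#' @export
anfis_to_json <- function(model, path) {
  stopifnot(inherits(model, "anfis"))
  payload <- list(
    class = "anfis",
    output_name = model$output_name,
    input_names = model$input_names,
    ranges = list(min = unname(model$ranges$min),
                  max = unname(model$ranges$max)),
    centers = model$centers, sigmas = model$sigmas, coef = model$coef,
    config = if (!is.null(model$config)) unclass(model$config)
  )
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              matrix = "rowmajor"), path)
  invisible(path)
}

#' @rdname anfis_to_json
#' @export
anfis_from_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  stopifnot(identical(p$class, "anfis"))
  ranges <- data.frame(min = p$ranges$min, max = p$ranges$max,
                       row.names = p$input_names)
  config <- if (!is.null(p$config)) {
    structure(p$config, class = "train_config")
  }
  .new_anfis(centers = matrix(p$centers, ncol = length(p$input_names),
                              dimnames = list(NULL, p$input_names)),
             sigmas = matrix(p$sigmas, ncol = length(p$input_names)),
             coef = matrix(p$coef, ncol = length(p$input_names) + 1),
             ranges = ranges, input_names = p$input_names,
             output_name = p$output_name, config = config)
}
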