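# Goodness-of-fit criteria used to evaluate every trained model.

.check_pair <- function(observed, predicted, min_n = 1L) {
  stopifnot(is.numeric(observed), is.numeric(predicted))
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (length(observed) < min_n) {
    stop("need at least ", min_n, " observations")
  }
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    stop("non-finite values in observed/predicted")
  }
  invisible(TRUE)
}

#' Coefficient of determination
#'
#' `1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)`.  The observed
#' values supply the denominator deviance; a constant observed vector is
#' rejected as the statistic is undefined there.
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @return Scalar, at most 1.
#' @export
r_squared <- function(observed, predicted) {
  .check_pair(observed, predicted, min_n = 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined for a constant observed vector")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return Non-negative scalar in response units.
#' @export
rmse <- function(observed, predicted) {
  .check_pair(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' Mean bias error
#'
#' Signed average error, with the convention `mean(predicted - observed)`:
#' positive values mean the model over-predicts on average.
#'
#' @inheritParams r_squared
#' @return Signed scalar in response units.
#' @export
mbe <- function(observed, predicted) {
  .check_pair(observed, predicted)
  mean(predicted - observed)
}

#' Bundle the three fit criteria for one partition
#'
#' @inheritParams r_squared
#' @param partition `"train"` or `"test"` label.
#' @return One-row data frame with `partition`, `n`, `r2`, `rmse`, `mbe`.
#' @export
fit_report <- function(observed, predicted, partition = c("train", "test")) {
  partition <- match.arg(partition)
  data.frame(partition = partition, n = length(observed),
             r2 = r_squared(observed, predicted),
             rmse = rmse(observed, predicted),
             mbe = mbe(observed, predicted))
}
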