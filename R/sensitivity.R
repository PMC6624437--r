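# Leave-one-feature-out variable importance: variable sensitivity error
# (VSE) and variable sensitivity ratio (VSR).

# Tie-break order for equal VSR values, following the conventional listing
# of the growth factors.
VSR_TIE_ORDER <- c("d24", "bap", "glu", "fru", "suc", "r", "g", "b")

#' Variable sensitivity error
#'
#' Retrains the model from scratch on the same training split with one
#' input column removed (identical hyperparameters) and returns the RMSE
#' of the reduced model over the full dataset (training and testing rows).
#' A large VSE means the model degrades badly without that input.
#'
#' @param data Full dataset (features + responses).
#' @param variable Feature column to drop (one of [FEATURE_NAMES]).
#' @param output Response column to model (`"cf"`, `"ef"` or `"nse"`).
#' @param config A [train_config()].
#' @param train_idx Integer indices of the training rows; defaults to all
#'   rows.
#' @return Non-negative scalar RMSE.
#' @export
vse <- function(data, variable, output, config = train_config(),
                train_idx = seq_len(nrow(data))) {
  stopifnot(variable %in% FEATURE_NAMES, output %in% names(data))
  feats <- setdiff(FEATURE_NAMES, variable)
  if (length(unique(data[[variable]])) < 2) {
    warning("variable '", variable, "' is constant; VSE equals the ",
            "full-model error by construction")
  }
  model <- fit_anfis(data[train_idx, feats], data[train_idx, output],
                     config, output_name = output)
  rmse(data[[output]], predict(model, data[, feats]))
}

#' Variable sensitivity ratio
#'
#' Ratio of the leave-one-out error to the full-model error; values near 1
#' mark inputs the model barely needs, larger values mark important inputs.
#'
#' @param vse_i VSE of the variable.
#' @param rmse_full RMSE of the full model over the same rows (> 0).
#' @return Non-negative scalar.
#' @export
vsr <- function(vse_i, rmse_full) {
  stopifnot(vse_i >= 0)
  if (rmse_full <= 0) {
    stop("full-model RMSE is 0: VSR undefined for a perfect model")
  }
  vse_i / rmse_full
}

#' Rank variables by VSR
#'
#' Sorts descending by VSR (rank 1 = most important); ties follow the
#' conventional factor order 2,4-D, BAP, glucose, fructose, sucrose, R, G,
#' B.
#'
#' @param vsr_values Named numeric vector of VSR values (names from
#'   [FEATURE_NAMES]).
#' @return Data frame with `variable`, `vsr`, `rank`.
#' @export
rank_variables <- function(vsr_values) {
  stopifnot(all(is.finite(vsr_values)),
            !is.null(names(vsr_values)),
            all(names(vsr_values) %in% VSR_TIE_ORDER))
  tie <- match(names(vsr_values), VSR_TIE_ORDER)
  ord <- order(-vsr_values, tie)
  rank <- integer(length(vsr_values))
  rank[ord] <- seq_along(ord)
  data.frame(variable = names(vsr_values), vsr = unname(vsr_values),
             rank = rank, row.names = NULL)
}

#' Full sensitivity analysis for one output
#'
#' Fits the full 8-input model, then one reduced model per input
#' ([vse()]), forms VSR values and ranks.
#'
#' @inheritParams vse
#' @return Data frame with `variable`, `vse`, `vsr`, `rank` and attributes
#'   `output` and `rmse_full`.
#' @export
sensitivity_analysis <- function(data, output, config = train_config(),
                                 train_idx = seq_len(nrow(data))) {
  full <- fit_anfis(data[train_idx, FEATURE_NAMES], data[train_idx, output],
                    config, output_name = output)
  rmse_full <- rmse(data[[output]], predict(full, data[, FEATURE_NAMES]))
  vse_values <- vapply(FEATURE_NAMES, function(v) {
    vse(data, v, output, config, train_idx)
  }, numeric(1))
  vsr_values <- vapply(vse_values, vsr, numeric(1), rmse_full = rmse_full)
  report <- rank_variables(vsr_values)
  report$vse <- unname(vse_values)
  report <- report[, c("variable", "vse", "vsr", "rank")]
  attr(report, "output") <- output
  attr(report, "rmse_full") <- rmse_full
  report
}
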