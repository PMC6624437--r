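# End-to-end orchestration: simulate -> split -> fit three models ->
# evaluate -> sensitivity -> NSGA-II optimization -> ideal point ->
# in-silico validation -> report.

#' Pipeline configuration
#'
#' @param generator A [generator_config()].
#' @param train A [train_config()].
#' @param nsga A [nsga_config()].
#' @param split_fraction Fraction of rows used for training (default 0.75).
#' @param split_seed Seed of the train/test shuffle.
#' @param output_dir Directory for artifacts, or `NULL` to skip writing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            train = train_config(),
                            nsga = nsga_config(),
                            split_fraction = 0.75, split_seed = 42,
                            output_dir = NULL) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  structure(list(generator = generator, train = train, nsga = nsga,
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Split a dataset into train and test with range coverage
#'
#' Uniform shuffle with `floor(fraction * N)` training rows.  The split is
#' accepted only if, for every feature, the training range covers the test
#' range (train min <= test min and train max >= test max), so the test
#' set never requires extrapolation; on violation the shuffle is redrawn
#' with an incremented seed, up to 100 attempts.
#'
#' @param data Dataset with the feature columns.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed of the shuffle.
#' @return List with integer vectors `train_idx`, `test_idx` and the
#'   `seed_used` that satisfied the coverage check.
#' @export
split_dataset <- function(data, fraction = 0.75, seed = 42) {
  n <- nrow(data)
  stopifnot(fraction > 0, fraction < 1, n >= 8)
  n_train <- floor(fraction * n)
  feats <- intersect(FEATURE_NAMES, names(data))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  for (attempt in 0:99) {
    set.seed(seed + attempt)
    perm <- sample.int(n)
    train_idx <- sort(perm[seq_len(n_train)])
    test_idx <- sort(perm[-seq_len(n_train)])
    ok <- all(vapply(feats, function(f) {
      tr <- data[train_idx, f]
      te <- data[test_idx, f]
      min(tr) <= min(te) && max(tr) >= max(te)
    }, logical(1)))
    if (ok) {
      return(list(train_idx = train_idx, test_idx = test_idx,
                  seed_used = seed + attempt))
    }
  }
  stop("no train/test split with full range coverage found in 100 attempts")
}

#' Noise-free truth at a culture condition
#'
#' Evaluates the generator's noise-free response surface at a single input
#' vector: the in-silico analogue of a wet-lab validation experiment.
#'
#' @param x Numeric feature vector (length 8, order [FEATURE_NAMES]).
#' @return List with `cf`, `ef`, `nse`.
#' @export
validate_in_silico <- function(x) {
  r <- true_response(x)
  list(cf = r$cf, ef = r$ef, nse = r$nse)
}

.clip_response <- function(values, output) {
  if (output %in% c("cf", "ef")) pmin(100, pmax(0, values)) else pmax(0, values)
}

#' Build the bi-objective surrogate function for the optimizer
#'
#' Wraps the fitted EF and NSE models into the `(EF, NSE)` objective used
#' by [nsga2()].  Predicted EF is clipped to [0,100] and NSE to >= 0 so
#' the optimizer cannot exploit extrapolation artifacts, and decision
#' vectors outside the rule base's support -- total firing strength below
#' `support_floor` in either model -- score (0, 0): the surrogate is only
#' trusted where at least one rule meaningfully fires (training rows sit
#' around total strength 0.15--1.2; the default floor is two orders of
#' magnitude below that).
#'
#' @param ef_model,nse_model Fitted `anfis` models for EF and NSE.
#' @param support_floor Minimum total firing strength for a point to be
#'   scored by the surrogates (default 0.02, roughly an order of magnitude
#'   below the least-supported training row of the default dataset).
#' @return Function mapping an `n x 8` matrix to an `n x 2` objective
#'   matrix.
#' @export
surrogate_objective <- function(ef_model, nse_model, support_floor = 0.02) {
  function(X) {
    X <- as.data.frame(X)
    names(X) <- FEATURE_NAMES
    w_ef <- firing_strengths(ef_model, X)
    w_nse <- firing_strengths(nse_model, X)
    if (is.null(dim(w_ef))) {
      w_ef <- matrix(w_ef, nrow = 1)
      w_nse <- matrix(w_nse, nrow = 1)
    }
    supported <- rowSums(w_ef) >= support_floor &
      rowSums(w_nse) >= support_floor
    out <- cbind(.clip_response(predict(ef_model, X), "ef"),
                 .clip_response(predict(nse_model, X), "nse"))
    out[!supported, ] <- 0
    out
  }
}

#' Run the full pipeline
#'
#' Generates (or takes) a dataset, splits it 75/25 with range coverage,
#' fits one ANFIS model per response (CF, EF, NSE), evaluates train/test
#' fit, optionally runs the VSE/VSR sensitivity analysis per output, then
#' maximizes the EF and NSE surrogates with NSGA-II over the training-data
#' bounds, selects the ideal-point solution and evaluates the noise-free
#' generator truth there.  Deterministic for fixed seeds.
#'
#' @param config A [pipeline_config()].
#' @param data Optional pre-made dataset; defaults to
#'   `generate_dataset(config$generator)`.
#' @param run_sensitivity Logical; the sensitivity stage retrains 8 reduced
#'   models per output and dominates the runtime.
#' @return A run report: list with the dataset, split indices, `models`,
#'   `fit_reports`, `sensitivity`, `front`, `ideal`, `validation` and the
#'   config echo.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         run_sensitivity = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(data)) data <- generate_dataset(config$generator)
  split <- split_dataset(data, config$split_fraction, config$split_seed)
  tr <- split$train_idx
  te <- split$test_idx

  models <- list()
  fit_reports <- list()
  for (out in RESPONSE_NAMES) {
    m <- fit_anfis(data[tr, FEATURE_NAMES], data[tr, out], config$train,
                   output_name = out)
    models[[out]] <- m
    rep_tr <- fit_report(data[tr, out],
                         .clip_response(predict(m, data[tr, FEATURE_NAMES]), out),
                         "train")
    rep_te <- fit_report(data[te, out],
                         .clip_response(predict(m, data[te, FEATURE_NAMES]), out),
                         "test")
    fit_reports[[out]] <- rbind(rep_tr, rep_te)
  }

  sens <- NULL
  if (run_sensitivity) {
    sens <- lapply(stats::setNames(RESPONSE_NAMES, RESPONSE_NAMES),
                   function(out) {
                     sensitivity_analysis(data, out, config$train, tr)
                   })
  }

  lower <- apply(data[tr, FEATURE_NAMES], 2, min)
  upper <- apply(data[tr, FEATURE_NAMES], 2, max)
  objective_fn <- surrogate_objective(models$ef, models$nse)
  seeds <- unique(as.matrix(data[tr, FEATURE_NAMES]))
  front <- nsga2(objective_fn, lower, upper, config$nsga, init = seeds)
  m_obs <- max(data$ef)
  n_ref <- max(data$nse)
  ideal <- select_ideal_point(front, m_obs, n_ref)
  names(ideal$x) <- FEATURE_NAMES
  validation <- validate_in_silico(ideal$x)

  report <- list(data = data, split = split, models = models,
                 fit_reports = fit_reports, sensitivity = sens,
                 front = front, ideal = ideal, validation = validation,
                 config = config)
  class(report) <- "anfisopt_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.anfisopt_report <- function(x, ...) {
  cat("ANFIS-NSGA-II pipeline report\n")
  cat(sprintf("  dataset: %d rows (%d train / %d test)\n", nrow(x$data),
              length(x$split$train_idx), length(x$split$test_idx)))
  for (out in names(x$fit_reports)) {
    fr <- x$fit_reports[[out]]
    cat(sprintf("  %-3s R2 train %.3f / test %.3f, RMSE train %.3f / test %.3f\n",
                toupper(out), fr$r2[1], fr$r2[2], fr$rmse[1], fr$rmse[2]))
  }
  cat(sprintf("  ideal point: EF %.2f%%, NSE %.2f (distance %.3f)\n",
              x$ideal$objectives[1], x$ideal$objectives[2], x$ideal$distance))
  cat("  at: ", paste(sprintf("%s=%.2f", names(x$ideal$x), x$ideal$x),
                      collapse = ", "), "\n", sep = "")
  cat(sprintf("  in-silico truth there: EF %.2f%%, NSE %.2f\n",
              x$validation$ef, x$validation$nse))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits `dataset.csv`, `model_{cf,ef,nse}.json`, `fit_report.json`,
#' `sensitivity.csv` (if computed), `pareto_front.csv` and `report.json`.
#'
#' @param report A pipeline run report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dataset(report$data, file.path(dir, "dataset.csv"))
  for (out in names(report$models)) {
    anfis_to_json(report$models[[out]],
                  file.path(dir, paste0("model_", out, ".json")))
  }
  fits <- do.call(rbind, lapply(names(report$fit_reports), function(out) {
    cbind(output = out, report$fit_reports[[out]])
  }))
  jsonlite::write_json(fits, file.path(dir, "fit_report.json"),
                       dataframe = "rows", digits = NA)
  if (!is.null(report$sensitivity)) {
    sens <- do.call(rbind, lapply(names(report$sensitivity), function(out) {
      cbind(output = out, report$sensitivity[[out]])
    }))
    utils::write.csv(sens, file.path(dir, "sensitivity.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  front_df <- as.data.frame(report$front$x)
  names(front_df) <- FEATURE_NAMES
  front_df$ef_pred <- report$front$objectives[, 1]
  front_df$nse_pred <- report$front$objectives[, 2]
  front_df$crowding <- report$front$crowding
  utils::write.csv(front_df, file.path(dir, "pareto_front.csv"),
                   row.names = FALSE, quote = FALSE)
  summary <- list(
    n_rows = nrow(report$data),
    n_train = length(report$split$train_idx),
    n_test = length(report$split$test_idx),
    split_seed_used = report$split$seed_used,
    fit = fits,
    ideal = list(x = as.list(report$ideal$x),
                 ef_pred = report$ideal$objectives[1],
                 nse_pred = report$ideal$objectives[2],
                 distance = report$ideal$distance,
                 m = report$ideal$m, n_ref = report$ideal$n_ref),
    validation = report$validation,
    config = .config_echo(report$config)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

.config_echo <- function(config) {
  list(generator = unclass(config$generator),
       train = unclass(config$train),
       nsga = unclass(config$nsga),
       split_fraction = config$split_fraction,
       split_seed = config$split_seed)
}
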