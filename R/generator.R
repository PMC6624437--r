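# Synthetic factorial tissue-culture dataset: a stated response surface for
# chrysanthemum somatic embryogenesis under PGRs, carbohydrates and LED light.

#' Feature column names used throughout the package
#'
#' The eight culture-condition inputs, in their canonical order: 2,4-D and
#' BAP (mg/L), sucrose, glucose and fructose (g/L), and the red, green and
#' blue light channels (0--255).
#'
#' @format Character vector of length 8.
#' @export
FEATURE_NAMES <- c("d24", "bap", "suc", "glu", "fru", "r", "g", "b")

#' Response column names
#'
#' Callogenesis frequency (`cf`, %), embryogenesis frequency (`ef`, %) and
#' number of somatic embryos per explant (`nse`).
#'
#' @format Character vector of length 3.
#' @export
RESPONSE_NAMES <- c("cf", "ef", "nse")

# Fixed surface parameters.  Functional forms and widths are generator
# choices; the only external anchors are the optimum validation point
# (EF = 100, NSE = 12.83) and the zero response at 0.5/0.5 mg/L PGRs.
.gen <- local({
  p <- list(
    pgr_center  = 1.6,    # mg/L, shared peak of the 2,4-D and BAP bumps
    pgr_sd      = 0.7,    # mg/L
    pgr_gate    = 0.75,   # mg/L: both PGRs below this -> no response
    sugar_center = c(suc = 30, glu = 60, fru = 60),  # g/L
    sugar_sd     = c(suc = 12, glu = 30, fru = 30),  # g/L
    sugar_weight = c(suc = 0.80, glu = 1.00, fru = 0.55),
    light_corner = c(darkness = 0.85, white = 0.72, blue = 0.58, red = 1.00),
    nse_max     = 12.83,  # embryos/explant at the calibration anchor
    nse_exp     = 1.3,
    cf_scale    = 1 / 0.9,
    cf_bonus    = 10,     # % points of callus whenever either PGR is active
    anchor      = c(d24 = 1.53, bap = 1.67, suc = 13.74, glu = 57.20,
                    fru = 0.39, r = 254.48, g = 0.57, b = 18.25)
  )
  p
})

.pgr_bump <- function(x) exp(-(x - .gen$pgr_center)^2 / (2 * .gen$pgr_sd^2))

.sugar_mix <- function(suc, glu, fru) {
  w <- .gen$sugar_weight
  b <- function(x, s) exp(-(x - .gen$sugar_center[s])^2 / (2 * .gen$sugar_sd[s]^2))
  (w["suc"] * b(suc, "suc") + w["glu"] * b(glu, "glu") + w["fru"] * b(fru, "fru")) / sum(w)
}

# Bilinear interpolation over the four LED treatment corners in the
# (r/255, b/255) plane.  The green channel is redundant in the four-corner
# design (white is the only treatment with g = 255) and is ignored here.
.light_factor <- function(r, g, b) {
  u <- r / 255
  v <- b / 255
  cr <- .gen$light_corner
  cr["darkness"] * (1 - u) * (1 - v) + cr["red"] * u * (1 - v) +
    cr["blue"] * (1 - u) * v + cr["white"] * u * v
}

# Anchor normalizers, evaluated once: the product of the three factors is
# rescaled so that the validation-experiment optimum maps to EF = 100.
.gen_anchor <- local({
  a <- .gen$anchor
  list(
    pgr   = .pgr_bump(a["d24"]) * .pgr_bump(a["bap"]),
    sugar = .sugar_mix(a["suc"], a["glu"], a["fru"]),
    light = .light_factor(a["r"], a["g"], a["b"])
  )
})

#' Encode an LED light treatment as an RGB triple
#'
#' Maps the four light treatments of the factorial design to their RGB
#' coding: darkness (0,0,0), white (255,255,255), blue (0,0,255) and
#' red (255,0,0).
#'
#' @param light_name One of `"darkness"`, `"white"`, `"blue"`, `"red"`.
#' @return Named numeric vector `c(r=, g=, b=)`.
#' @examples
#' light_to_rgb("red")
#' @export
light_to_rgb <- function(light_name) {
  codes <- list(
    darkness = c(r = 0, g = 0, b = 0),
    white    = c(r = 255, g = 255, b = 255),
    blue     = c(r = 0, g = 0, b = 255),
    red      = c(r = 255, g = 0, b = 0)
  )
  if (length(light_name) != 1L || !is.character(light_name) ||
      !light_name %in% names(codes)) {
    stop("unknown light treatment; valid names are: ",
         paste(names(codes), collapse = ", "))
  }
  codes[[light_name]]
}

#' Noise-free response surface of the synthetic experiment
#'
#' Deterministic treatment means for callogenesis frequency (CF, %),
#' embryogenesis frequency (EF, %) and number of somatic embryos (NSE).
#' EF is a product of a plant-growth-regulator factor (Gaussian bumps in
#' 2,4-D and BAP, gated to zero when both are below 0.75 mg/L), a
#' carbohydrate factor (weighted Gaussian bumps per sugar) and a light
#' factor (bilinear over the four LED corners, red highest, blue lowest),
#' calibrated so the validated optimum yields EF = 100 and NSE = 12.83.
#'
#' @param features Numeric vector of length 8 (order [FEATURE_NAMES]), or a
#'   matrix/data frame with those columns; rows are evaluated independently.
#' @return Data frame with columns `cf`, `ef`, `nse` (one row per input row).
#' @examples
#' true_response(c(1.53, 1.67, 13.74, 57.20, 0.39, 254.48, 0.57, 18.25))
#' @export
true_response <- function(features) {
  x <- .as_feature_matrix(features)
  stopifnot(all(is.finite(x)))
  if (any(x < 0) || any(x[, c("r", "g", "b")] > 255)) {
    stop("features must be non-negative and r,g,b within [0,255]")
  }
  pgr <- .pgr_bump(x[, "d24"]) * .pgr_bump(x[, "bap"]) / .gen_anchor$pgr
  gate <- !(x[, "d24"] < .gen$pgr_gate & x[, "bap"] < .gen$pgr_gate)
  sug <- .sugar_mix(x[, "suc"], x[, "glu"], x[, "fru"]) / .gen_anchor$sugar
  lig <- .light_factor(x[, "r"], x[, "g"], x[, "b"]) / .gen_anchor$light
  ef <- pmin(100, 100 * pgr * sug * lig) * gate
  active <- as.numeric(x[, "d24"] >= .gen$pgr_gate | x[, "bap"] >= .gen$pgr_gate)
  cf <- pmin(100, ef * .gen$cf_scale + .gen$cf_bonus * active)
  nse <- .gen$nse_max * (ef / 100)^.gen$nse_exp
  data.frame(cf = unname(cf), ef = unname(ef), nse = unname(nse))
}

.as_feature_matrix <- function(features) {
  if (is.null(dim(features))) {
    stopifnot(length(features) == length(FEATURE_NAMES))
    features <- matrix(as.numeric(features), nrow = 1,
                       dimnames = list(NULL, FEATURE_NAMES))
  } else {
    features <- as.data.frame(features)
    if (all(FEATURE_NAMES %in% names(features))) {
      features <- as.matrix(features[, FEATURE_NAMES, drop = FALSE])
    } else if (ncol(features) == length(FEATURE_NAMES)) {
      features <- as.matrix(features)
      colnames(features) <- FEATURE_NAMES
    } else {
      stop("features must have 8 columns (",
           paste(FEATURE_NAMES, collapse = ", "), ")")
    }
  }
  storage.mode(features) <- "double"
  features
}

#' Generator configuration
#'
#' @param n_treatments Number of treatments; only the default 24-treatment
#'   factorial reconstruction is built in, other values require `design`.
#' @param n_replicates Replicates per treatment (default 45 = 15 explants
#'   x 3 sets).
#' @param noise_sd_freq Gaussian noise SD, percentage points, added to CF/EF.
#' @param noise_sd_nse Gaussian noise SD added to NSE counts.
#' @param seed Integer RNG seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_treatments = 24, n_replicates = 45,
                             noise_sd_freq = 3.0, noise_sd_nse = 0.4,
                             seed = 42) {
  stopifnot(n_treatments >= 1, n_replicates >= 1,
            noise_sd_freq >= 0, noise_sd_nse >= 0)
  structure(list(n_treatments = as.integer(n_treatments),
                 n_replicates = as.integer(n_replicates),
                 noise_sd_freq = noise_sd_freq, noise_sd_nse = noise_sd_nse,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Enumerate the factorial design
#'
#' Builds the 24-treatment reconstruction of the experiment: 9 PGR
#' combinations (2,4-D x BAP over 0.5/1.5/2.5 mg/L at 30 g/L sucrose,
#' white light), 10 carbohydrate treatments (sucrose 20/30/60, glucose
#' 30/60/90, fructose 30/60/90 g/L alone, plus the 20+20+20 g/L mix, at
#' 1.5/1.5 mg/L PGRs under white light), 4 light treatments
#' (darkness/white/blue/red at 1.5/1.5 mg/L PGRs with 60 g/L glucose) and
#' one zero-PGR control.
#'
#' @param config A [generator_config()].
#' @param design Optional user-supplied design: data frame with
#'   `treatment_id` plus the 8 feature columns, required when
#'   `n_treatments != 24`.
#' @return Data frame with `treatment_id` and the feature columns, one row
#'   per treatment, replicated `n_replicates` times.
#' @export
build_design <- function(config = generator_config(), design = NULL) {
  if (is.null(design)) {
    if (config$n_treatments != 24L) {
      stop("only the built-in 24-treatment design is available; ",
           "supply `design` for other treatment counts")
    }
    design <- .default_design()
  } else {
    design <- as.data.frame(design)
    stopifnot(all(c("treatment_id", FEATURE_NAMES) %in% names(design)),
              nrow(design) == config$n_treatments)
  }
  idx <- rep(seq_len(nrow(design)), each = config$n_replicates)
  out <- design[idx, , drop = FALSE]
  out$replicate <- rep(seq_len(config$n_replicates), times = nrow(design))
  rownames(out) <- NULL
  out
}

.default_design <- function() {
  white <- unname(light_to_rgb("white"))
  pgr <- expand.grid(d24 = c(0.5, 1.5, 2.5), bap = c(0.5, 1.5, 2.5))
  blocks <- list(
    # PGR factorial at standard medium (3% sucrose), white light
    data.frame(d24 = pgr$d24, bap = pgr$bap, suc = 30, glu = 0, fru = 0,
               r = white[1], g = white[2], b = white[3]),
    # carbohydrate sources alone and in a 2+2+2 % mix
    data.frame(d24 = 1.5, bap = 1.5,
               suc = c(20, 30, 60, 0, 0, 0, 0, 0, 0, 20),
               glu = c(0, 0, 0, 30, 60, 90, 0, 0, 0, 20),
               fru = c(0, 0, 0, 0, 0, 0, 30, 60, 90, 20),
               r = white[1], g = white[2], b = white[3]),
    # light quality block at the best PGR/sugar combination
    do.call(rbind, lapply(c("darkness", "white", "blue", "red"), function(l) {
      rgb <- unname(light_to_rgb(l))
      data.frame(d24 = 1.5, bap = 1.5, suc = 0, glu = 60, fru = 0,
                 r = rgb[1], g = rgb[2], b = rgb[3])
    })),
    # zero-PGR control
    data.frame(d24 = 0, bap = 0, suc = 30, glu = 0, fru = 0,
               r = white[1], g = white[2], b = white[3])
  )
  d <- do.call(rbind, blocks)
  rownames(d) <- NULL
  cbind(treatment_id = seq_len(nrow(d)), d)
}

#' Generate a synthetic dataset
#'
#' Evaluates the noise-free surface on the replicated design and adds
#' independent Gaussian noise (`noise_sd_freq` percentage points to CF and
#' EF, `noise_sd_nse` to NSE).  CF/EF are clipped to [0,100], NSE to >= 0;
#' NSE is forced to 0 wherever EF is 0, and CF is raised to EF wherever
#' embryos would otherwise appear without callus.  Reproducible for a
#' fixed seed.
#'
#' @inheritParams build_design
#' @return Data frame of treatment records: `treatment_id`, `replicate`,
#'   the 8 features and the 3 responses.
#' @examples
#' d <- generate_dataset(generator_config(n_replicates = 2))
#' nrow(d)  # 48
#' @export
generate_dataset <- function(config = generator_config(), design = NULL) {
  rows <- build_design(config, design)
  mu <- true_response(rows[, FEATURE_NAMES])
  n <- nrow(rows)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  cf <- pmin(100, pmax(0, mu$cf + stats::rnorm(n, 0, config$noise_sd_freq)))
  ef <- pmin(100, pmax(0, mu$ef + stats::rnorm(n, 0, config$noise_sd_freq)))
  nse <- pmax(0, mu$nse + stats::rnorm(n, 0, config$noise_sd_nse))
  nse[ef == 0] <- 0
  viol <- ef > 0 & cf <= 0
  cf[viol] <- ef[viol]
  out <- cbind(rows[, c(FEATURE_NAMES)], cf = cf, ef = ef, nse = nse,
               treatment_id = rows$treatment_id, replicate = rows$replicate)
  rownames(out) <- NULL
  out
}

#' Read/write a treatment-record dataset as CSV
#'
#' Plain CSV with header `d24,bap,suc,glu,fru,r,g,b,cf,ef,nse,
#' treatment_id,replicate`; concentrations in mg/L (PGRs) and g/L (sugars).
#'
#' @param data Dataset as returned by [generate_dataset()].
#' @param path File path.
#' @return `read_dataset` returns the data frame; `write_dataset` returns
#'   `path` invisibly.
#' @export
write_dataset <- function(data, path) {
  cols <- c(FEATURE_NAMES, RESPONSE_NAMES, "treatment_id", "replicate")
  stopifnot(all(cols %in% names(data)))
  utils::write.csv(data[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c(FEATURE_NAMES, RESPONSE_NAMES) %in% names(d)))
  d
}

# Save/restore the global RNG state so seeded generation does not disturb
# the caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
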