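# Elitist multi-objective genetic algorithm (NSGA-II) over a box of
# culture-condition inputs, both objectives maximized, plus ideal-point
# selection on the final Pareto front.

#' NSGA-II configuration
#'
#' Simulated binary crossover (SBX) and polynomial mutation with the
#' conventional distribution indices.
#'
#' @param pop_size Population size (even, >= 4).
#' @param n_generations Number of generations.
#' @param eta_c,p_c SBX distribution index and crossover probability.
#' @param eta_m,p_m Polynomial-mutation index and per-variable probability;
#'   `p_m = NULL` means 1/d, resolved against the bounds at run time.
#' @param seed Integer RNG seed.
#' @return Object of class `nsga_config`.
#' @export
nsga_config <- function(pop_size = 100, n_generations = 200,
                        eta_c = 15, p_c = 0.9, eta_m = 20, p_m = NULL,
                        seed = 42) {
  stopifnot(pop_size >= 4, pop_size %% 2 == 0, n_generations >= 1,
            p_c >= 0, p_c <= 1, is.null(p_m) || (p_m >= 0 && p_m <= 1))
  structure(list(pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 eta_c = eta_c, p_c = p_c, eta_m = eta_m, p_m = p_m,
                 seed = as.integer(seed)),
            class = "nsga_config")
}

#' Pareto dominance (maximization)
#'
#' `a` dominates `b` iff `a` is at least as good in every objective and
#' strictly better in at least one.
#'
#' @param a,b Numeric objective vectors of equal length (finite).
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  all(a >= b) && any(a > b)
}

# n x n logical matrix: D[i, j] <=> row i dominates row j (maximization).
.dominance_matrix <- function(obj) {
  n <- nrow(obj)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (m in seq_len(ncol(obj))) {
    o <- obj[, m]
    ge_m <- outer(o, o, ">=")
    ge <- ge & ge_m
    gt <- gt | outer(o, o, ">")
  }
  ge & gt
}

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts: front 1 holds the
#' non-dominated points; every member of front k is dominated by some
#' member of front k-1.
#'
#' @param objectives Numeric matrix, one row per individual, objectives
#'   maximized.
#' @return List of integer vectors of row indices, best front first.
#' @export
fast_nondominated_sort <- function(objectives) {
  obj <- as.matrix(objectives)
  stopifnot(nrow(obj) >= 1, all(is.finite(obj)))
  D <- .dominance_matrix(obj)
  n_dom <- colSums(D)        # how many dominate each individual
  fronts <- list()
  assigned <- rep(FALSE, nrow(obj))
  while (!all(assigned)) {
    cur <- which(!assigned & n_dom == 0)
    fronts[[length(fronts) + 1L]] <- cur
    assigned[cur] <- TRUE
    for (i in cur) n_dom <- n_dom - D[i, ]
    n_dom[assigned] <- Inf   # never re-selected
  }
  fronts
}

#' Crowding distance within one front
#'
#' Per objective the front is sorted; boundary individuals receive `Inf`
#' and interior individuals the normalized gap between their neighbors,
#' summed over objectives.  Objectives constant across the front
#' contribute 0.
#'
#' @param objectives Numeric matrix of the front's objective rows.
#' @return Numeric vector of distances (order matches input rows).
#' @export
crowding_distance <- function(objectives) {
  obj <- as.matrix(objectives)
  n <- nrow(obj)
  stopifnot(n >= 1)
  if (n <= 2) return(rep(Inf, n))
  dist <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    ord <- order(obj[, m])
    span <- obj[ord[n], m] - obj[ord[1], m]
    dist[ord[c(1, n)]] <- Inf
    if (span > 0) {
      gaps <- (obj[ord[3:n], m] - obj[ord[1:(n - 2)], m]) / span
      dist[ord[2:(n - 1)]] <- dist[ord[2:(n - 1)]] + gaps
    }
  }
  dist
}

#' Binary tournament selection
#'
#' Draws two individuals uniformly; the lower rank wins, ties on rank go to
#' the larger crowding distance, remaining ties are decided uniformly.
#'
#' @param rank Integer vector of front indices (1 = best).
#' @param crowding Numeric vector of crowding distances.
#' @param candidates Optional pair of candidate indices (drawn uniformly
#'   with replacement when omitted).
#' @return Index of the selected individual.
#' @export
tournament_select <- function(rank, crowding, candidates = NULL) {
  n <- length(rank)
  cand <- if (is.null(candidates)) sample.int(n, 2, replace = TRUE)
          else candidates
  i <- cand[1]; j <- cand[2]
  if (rank[i] < rank[j]) return(i)
  if (rank[j] < rank[i]) return(j)
  if (crowding[i] > crowding[j]) return(i)
  if (crowding[j] > crowding[i]) return(j)
  cand[sample.int(2, 1)]
}

#' Simulated binary crossover (SBX)
#'
#' @param p1,p2 Parent vectors within bounds.
#' @param lower,upper Per-variable bounds.
#' @param eta_c Distribution index.
#' @param p_c Probability that the pair is crossed at all.
#' @return List of two children, clipped to bounds.
#' @export
sbx_crossover <- function(p1, p2, lower, upper, eta_c = 15, p_c = 0.9) {
  d <- length(p1)
  c1 <- p1; c2 <- p2
  if (stats::runif(1) <= p_c) {
    u <- stats::runif(d)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta_c + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta_c + 1)))
    same <- abs(p1 - p2) < 1e-14
    beta[same] <- 1
    c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
    c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

#' Polynomial mutation
#'
#' Bounds-aware polynomial mutation; each variable mutates independently
#' with probability `p_m`.
#'
#' @param x Vector within bounds.
#' @inheritParams sbx_crossover
#' @param eta_m Distribution index.
#' @param p_m Per-variable mutation probability.
#' @return Mutated vector, clipped to bounds.
#' @export
polynomial_mutation <- function(x, lower, upper, eta_m = 20, p_m = 1 / 8) {
  d <- length(x)
  span <- upper - lower
  do_mut <- stats::runif(d) < p_m & span > 0
  if (!any(do_mut)) return(x)
  u <- stats::runif(d)
  mpow <- 1 / (eta_m + 1)
  for (k in which(do_mut)) {
    d1 <- (x[k] - lower[k]) / span[k]
    d2 <- (upper[k] - x[k]) / span[k]
    if (u[k] < 0.5) {
      val <- 2 * u[k] + (1 - 2 * u[k]) * (1 - d1)^(eta_m + 1)
      dq <- val^mpow - 1
    } else {
      val <- 2 * (1 - u[k]) + (2 * u[k] - 1) * (1 - d2)^(eta_m + 1)
      dq <- 1 - val^mpow
    }
    x[k] <- x[k] + dq * span[k]
  }
  pmin(pmax(x, lower), upper)
}

.eval_objectives <- function(objective_fn, X) {
  obj <- objective_fn(X)
  obj <- matrix(as.numeric(obj), nrow = nrow(X))
  if (!all(is.finite(obj))) {
    bad <- which(!stats::complete.cases(ifelse(is.finite(obj), obj, NA)))[1]
    stop("non-finite objective at x = (",
         paste(signif(X[bad, ], 6), collapse = ", "), ")")
  }
  obj
}

.rank_crowd <- function(obj) {
  fronts <- fast_nondominated_sort(obj)
  rank <- integer(nrow(obj))
  crowd <- numeric(nrow(obj))
  for (k in seq_along(fronts)) {
    rank[fronts[[k]]] <- k
    crowd[fronts[[k]]] <- crowding_distance(obj[fronts[[k]], , drop = FALSE])
  }
  list(rank = rank, crowding = crowd, fronts = fronts)
}

#' Run the NSGA-II main loop
#'
#' Initializes the population uniformly in the bounds box, then per
#' generation creates offspring by binary tournament + SBX + polynomial
#' mutation, merges parents and children, sorts the union into
#' non-dominated fronts and fills the next population by rank, breaking
#' the last front by descending crowding distance (elitism).  Fully
#' reproducible for a fixed seed.
#'
#' @param objective_fn Function mapping an `n x d` matrix of decision
#'   vectors to an `n x 2` matrix of finite objectives (maximized).
#' @param lower,upper Per-variable bounds of the decision box.
#' @param config A [nsga_config()].
#' @param init Optional matrix of decision vectors used to warm-start the
#'   population (clipped to bounds; truncated or topped up with uniform
#'   random individuals to `pop_size`).  Seeding with observed conditions
#'   keeps the search on the region where a data-driven objective is
#'   informative.
#' @return List with `x` (decision matrix of the final first front),
#'   `objectives`, `crowding`, plus the final `population` (all ranks) and
#'   the configuration.
#' @export
nsga2 <- function(objective_fn, lower, upper, config = nsga_config(),
                  init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper >= lower))
  p_m <- if (is.null(config$p_m)) 1 / d else config$p_m
  N <- config$pop_size
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  X <- matrix(stats::runif(N * d), N, d)
  X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  if (!is.null(init)) {
    init <- as.matrix(init)
    stopifnot(ncol(init) == d)
    k <- min(nrow(init), N)
    X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                 rep(lower, each = k)),
                            rep(upper, each = k))
  }
  obj <- .eval_objectives(objective_fn, X)
  rc <- .rank_crowd(obj)
  for (gen in seq_len(config$n_generations)) {
    C <- matrix(0, N, d)
    for (i in seq(1, N, by = 2)) {
      a <- tournament_select(rc$rank, rc$crowding)
      b <- tournament_select(rc$rank, rc$crowding)
      kids <- sbx_crossover(X[a, ], X[b, ], lower, upper,
                            config$eta_c, config$p_c)
      C[i, ] <- polynomial_mutation(kids[[1]], lower, upper,
                                    config$eta_m, p_m)
      C[i + 1, ] <- polynomial_mutation(kids[[2]], lower, upper,
                                        config$eta_m, p_m)
    }
    c_obj <- .eval_objectives(objective_fn, C)
    Xall <- rbind(X, C)
    objall <- rbind(obj, c_obj)
    sel <- .environmental_selection(objall, N)
    X <- Xall[sel, , drop = FALSE]
    obj <- objall[sel, , drop = FALSE]
    rc <- .rank_crowd(obj)
  }
  first <- rc$fronts[[1]]
  list(x = X[first, , drop = FALSE],
       objectives = obj[first, , drop = FALSE],
       crowding = rc$crowding[first],
       population = list(x = X, objectives = obj, rank = rc$rank,
                         crowding = rc$crowding),
       config = config)
}

.environmental_selection <- function(obj, N) {
  fronts <- fast_nondominated_sort(obj)
  sel <- integer(0)
  for (f in fronts) {
    if (length(sel) + length(f) <= N) {
      sel <- c(sel, f)
    } else {
      cd <- crowding_distance(obj[f, , drop = FALSE])
      keep <- f[order(cd, decreasing = TRUE)][seq_len(N - length(sel))]
      sel <- c(sel, keep)
      break
    }
  }
  sel
}

#' Ideal-point selection on a Pareto front
#'
#' Picks the front member minimizing the Euclidean distance
#' `sqrt((EF - m)^2 + (NSE - n_ref)^2)` to the ideal point formed by the
#' maximum observed EF and NSE.  Ties are broken by higher EF, then by
#' lexicographic decision vector.
#'
#' @param front Result of [nsga2()] (or any list with `x` and `objectives`).
#' @param m Maximum embryogenesis frequency observed in the data (%).
#' @param n_ref Maximum number of somatic embryos observed in the data.
#' @return List with `x`, `objectives`, `distance`, `m`, `n_ref`, `index`.
#' @export
select_ideal_point <- function(front, m, n_ref) {
  obj <- as.matrix(front$objectives)
  stopifnot(nrow(obj) >= 1, ncol(obj) == 2)
  dist <- sqrt((obj[, 1] - m)^2 + (obj[, 2] - n_ref)^2)
  xo <- as.data.frame(front$x)
  ord <- do.call(order, c(list(dist, -obj[, 1]), xo))
  best <- ord[1]
  list(x = front$x[best, ], objectives = obj[best, ],
       distance = dist[best], m = m, n_ref = n_ref, index = best)
}

#' Dominated hypervolume of a 2-objective front (maximization)
#'
#' Area of objective space dominated by the front relative to a reference
#' point (both objectives maximized).  Used to monitor front quality.
#'
#' @param objectives Numeric matrix with 2 columns.
#' @param ref Reference point (length 2), dominated by all counted points.
#' @return Non-negative scalar.
#' @export
hypervolume_2d <- function(objectives, ref = c(0, 0)) {
  obj <- as.matrix(objectives)
  stopifnot(ncol(obj) == 2)
  keep <- obj[, 1] > ref[1] & obj[, 2] > ref[2]
  obj <- obj[keep, , drop = FALSE]
  if (nrow(obj) == 0) return(0)
  nd <- fast_nondominated_sort(obj)[[1]]
  obj <- obj[nd, , drop = FALSE]
  obj <- obj[order(obj[, 1]), , drop = FALSE]
  o1 <- c(ref[1], obj[, 1])
  sum(diff(o1) * (obj[, 2] - ref[2]))
}
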