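#' Maximise an acquisition function by focus search
#'
#' Per restart: draw `points_per_round` uniform points in the current box,
#' evaluate the acquisition in one vectorised call, recentre the box on
#' the incumbent and halve every dimension's range; repeat
#' `shrink_rounds` times.  Integer dimensions shrink too but never below
#' one unit.  Returns the best point seen over all restarts.
#'
#' @param acq `function(X)` returning the acquisition value for each row
#'   of a point matrix.
#' @param space a [default_space()].
#' @param restarts,shrink_rounds,points_per_round search effort (defaults
#'   5 x 3 x 1000).
#' @return named numeric vector: the located argmax.
#' @export
focus_search <- function(acq, space, restarts = 5L, shrink_rounds = 3L,
                         points_per_round = 1000L) {
  d <- nrow(space)
  best_x <- NULL; best_v <- -Inf
  for (r in seq_len(restarts)) {
    lo <- space$lower; hi <- space$upper
    for (s in seq_len(shrink_rounds)) {
      X <- sapply(seq_len(d), function(j) runif(points_per_round, lo[j], hi[j]))
      X <- matrix(X, nrow = points_per_round, dimnames = list(NULL, space$name))
      X <- round_integer_dims(X, space)
      v <- acq(X)
      k <- which.max(v)
      if (v[k] > best_v) { best_v <- v[k]; best_x <- X[k, ] }
      centre <- X[k, ]
      half <- (hi - lo) / 4
      half[space$integer] <- pmax(half[space$integer], 0.5)
      lo <- pmax(space$lower, centre - half)
      hi <- pmin(space$upper, centre + half)
    }
  }
  best_x
}

#' Propose a batch of q points by EI with the constant-liar strategy
#'
#' Iteratively maximises expected improvement; after each proposal the GP
#' is updated (hyperparameters held fixed) with the lie `L = g_min`, the
#' minimum observed objective value, before the next EI maximisation.
#' Finally, any proposal closer than `filter_tol` (Euclidean distance in
#' unit-scaled coordinates) to an existing training point is replaced by a
#' uniformly random point.
#'
#' @param model a [fit_gp()] model on the real observations.
#' @param q batch size.
#' @param space a [default_space()].
#' @param filter_tol duplicate-proposal threshold (default 1e-3).
#' @param focus_control optional list overriding [focus_search()] effort.
#' @return list with `X` (q x d matrix) and `type` (character vector:
#'   `infill_ei` or `rand_opt` for filtered replacements).
#' @export
propose_batch <- function(model, q, space, filter_tol = 1e-3,
                          focus_control = list()) {
  fc <- utils::modifyList(list(restarts = 5L, shrink_rounds = 3L,
                               points_per_round = 1000L), focus_control)
  lie <- min(model$y)
  work <- model
  X <- matrix(NA_real_, q, nrow(space), dimnames = list(NULL, space$name))
  for (j in seq_len(q)) {
    gmax <- incumbent_mean(work)
    x <- focus_search(function(P) expected_improvement(work, P, gmax),
                      space, fc$restarts, fc$shrink_rounds,
                      fc$points_per_round)
    X[j, ] <- x
    if (j < q) work <- gp_update_data(work, matrix(x, 1), lie)
  }
  type <- rep("infill_ei", q)
  Xs <- scale_to_unit(X, space)
  D <- sqrt(sqdist(Xs, model$Xs))
  collide <- apply(D, 1, min) < filter_tol
  if (any(collide)) {
    X[collide, ] <- random_points(sum(collide), space)
    type[collide] <- "rand_opt"
  }
  list(X = X, type = type)
}

new_run <- function(method, space, seed) {
  structure(list(method = method, space = space, seed = seed,
                 X = NULL, y = numeric(0), iteration = integer(0),
                 type = character(0), failures = 0L,
                 recommendation = NULL, cum_max = numeric(0)),
            class = "bo_run")
}

append_obs <- function(run, X, y, iteration, type) {
  run$X <- rbind(run$X, X)
  run$y <- c(run$y, y)
  run$iteration <- c(run$iteration, rep(iteration, length(y)))
  run$type <- c(run$type, type)
  run
}

# Evaluate the objective at each row of X with its own seed; a failing
# evaluation is recorded and the point replaced by a random one (one
# retry, then NA).
evaluate_rows <- function(objective, X, seeds, space, run) {
  y <- numeric(nrow(X))
  for (k in seq_len(nrow(X))) {
    val <- tryCatch(objective(X[k, ], seeds[k]), error = function(e) NA_real_)
    if (is.na(val)) {
      run$failures <- run$failures + 1L
      X[k, ] <- random_points(1L, space)
      val <- tryCatch(objective(X[k, ], seeds[k] + 1L),
                      error = function(e) NA_real_)
    }
    y[k] <- val
  }
  list(X = X, y = y, run = run)
}

#' Bayesian optimisation of a breeding-scheme objective
#'
#' Evaluates an initial Latin-hypercube design of `init_n` points, then
#' runs `n_iter` iterations of: fit the GP to all real observations,
#' propose `q` points by EI with the constant liar, evaluate them (each
#' with its own derived seed, so evaluation order is immaterial).  The
#' recommendation is the visited point with the highest posterior mean
#' under the final model.
#'
#' @param objective `function(z, seed)` returning the objective value, as
#'   produced by [make_objective()] (or any test function).
#' @param space a [default_space()].
#' @param n_iter number of iterations.
#' @param q batch size per iteration.
#' @param init_n initial design size (default 5).
#' @param filter_tol duplicate threshold in scaled units (default 1e-3).
#' @param seed run seed.
#' @param focus_control optional list overriding [focus_search()] effort.
#' @return object of class `bo_run`: observations (`X`, `y`, `iteration`,
#'   `type`), per-iteration `cum_max`, `recommendation` (list `z`,
#'   `pred`), failure count and seed.
#' @export
run_bayes_opt <- function(objective, space, n_iter, q, init_n = 5L,
                          filter_tol = 1e-3, seed = 1L,
                          focus_control = list()) {
  set.seed(seed)
  seeds <- draw_seeds(init_n + n_iter * q + 64L)
  used <- 0L
  run <- new_run("bayes", space, seed)
  X0 <- latin_hypercube(init_n, space)
  ev <- evaluate_rows(objective, X0, seeds[used + seq_len(init_n)], space, run)
  used <- used + init_n
  run <- append_obs(ev$run, ev$X, ev$y, 0L, rep("initdesign", init_n))
  run$cum_max <- max(run$y)
  for (it in seq_len(n_iter)) {
    model <- fit_gp(run$X, run$y, space)
    prop <- propose_batch(model, q, space, filter_tol, focus_control)
    ev <- evaluate_rows(objective, prop$X, seeds[used + seq_len(q)], space, run)
    used <- used + q
    run <- append_obs(ev$run, ev$X, ev$y, it, prop$type)
    run$cum_max <- c(run$cum_max, max(run$y))
  }
  final <- fit_gp(run$X, run$y, space)
  post <- gp_posterior(final, run$X)
  best <- which.max(post$mean)
  run$recommendation <- list(z = run$X[best, ], pred = post$mean[best],
                             observed = run$y[best])
  run
}

#' Random-search baseline at the Bayesian budget
#'
#' Samples points uniformly in the space: the first iteration includes the
#' `init_n` extra points so the total evaluation count matches the paired
#' Bayesian run (`init_n + n_iter * q`).  The recommendation is the point
#' with the highest observed value.
#'
#' @inheritParams run_bayes_opt
#' @return a `bo_run` with method tag `random`.
#' @export
run_random_opt <- function(objective, space, n_iter, q, init_n = 5L,
                           seed = 1L) {
  set.seed(seed)
  seeds <- draw_seeds(init_n + n_iter * q + 64L)
  used <- 0L
  run <- new_run("random", space, seed)
  for (it in seq_len(n_iter)) {
    n_pts <- if (it == 1L) init_n + q else q
    X <- random_points(n_pts, space)
    ev <- evaluate_rows(objective, X, seeds[used + seq_len(n_pts)], space, run)
    used <- used + n_pts
    run <- append_obs(ev$run, ev$X, ev$y, it, rep("rand_opt", n_pts))
    run$cum_max <- c(run$cum_max, max(run$y))
  }
  best <- which.max(run$y)
  run$recommendation <- list(z = run$X[best, ], pred = run$y[best],
                             observed = run$y[best])
  run
}

#' @export
print.bo_run <- function(x, ...) {
  cat("<bo_run> method=", x$method, ", ", length(x$y), " evaluations, best y = ",
      format(max(x$y), digits = 4), "\n", sep = "")
  if (!is.null(x$recommendation)) {
    cat("  recommendation: ",
        paste(sprintf("%s=%.4g", names(x$recommendation$z),
                      x$recommendation$z), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
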