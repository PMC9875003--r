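#' Define the scheme-parameter search space
#'
#' Four dimensions: `i_init`, `i` (continuous selection intensities),
#' `B_rep` (continuous budget fraction) and `pheno_p` (integer phenotyping
#' period).  Defaults span all qualitatively distinct schemes while
#' avoiding the degenerate zero-selection corners.
#'
#' @param n_gen number of cycles; bounds the phenotyping period.
#' @param lower,upper optional named numeric vectors overriding the
#'   default bounds.
#' @return object of class `bo_space`: data.frame with columns `name`,
#'   `lower`, `upper`, `integer`.
#' @export
default_space <- function(n_gen, lower = NULL, upper = NULL) {
  sp <- data.frame(
    name = c("i_init", "i", "B_rep", "pheno_p"),
    lower = c(0.01, 0.01, 0.05, 1),
    upper = c(0.9, 0.9, 0.95, n_gen),
    integer = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  if (!is.null(lower)) sp$lower[match(names(lower), sp$name)] <- lower
  if (!is.null(upper)) sp$upper[match(names(upper), sp$name)] <- upper
  if (any(sp$lower >= sp$upper)) stop("lower bound must be below upper bound")
  structure(sp, class = c("bo_space", "data.frame"))
}

# Min-max scale points (matrix, columns = dimensions) to the unit cube.
scale_to_unit <- function(X, space) {
  sweep(sweep(X, 2, space$lower), 2, space$upper - space$lower, `/`)
}

# Round integer dimensions of a point matrix to in-bounds integers.
round_integer_dims <- function(X, space) {
  for (j in which(space$integer)) {
    X[, j] <- pmin(pmax(round_half_up(X[, j]), ceiling(space$lower[j])),
                   floor(space$upper[j]))
  }
  X
}

# One uniform random point per row, optionally many.
random_points <- function(n, space) {
  X <- sapply(seq_len(nrow(space)), function(j) {
    runif(n, space$lower[j], space$upper[j])
  })
  X <- matrix(X, nrow = n, dimnames = list(NULL, space$name))
  round_integer_dims(X, space)
}

#' Latin hypercube design
#'
#' One point per axis stratum in every dimension, with uniform jitter
#' within strata; integer dimensions are rounded after sampling.
#'
#' @param n number of points (>= 1).
#' @param space a [default_space()].
#' @return n x d matrix with columns named after the dimensions.
#' @export
latin_hypercube <- function(n, space) {
  stopifnot(n >= 1)
  d <- nrow(space)
  U <- sapply(seq_len(d), function(j) {
    (sample.int(n) - runif(n)) / n
  })
  U <- matrix(U, nrow = n)
  X <- sweep(sweep(U, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
  colnames(X) <- space$name
  round_integer_dims(X, space)
}

# Squared-distance matrix between the rows of A and B.
sqdist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

# Negative concentrated log-likelihood of the kriging model with constant
# mean: correlation R = exp(-D2 / (2 theta^2)) + g I; mean and process
# variance are profiled out analytically.
gp_nll <- function(log_par, D2, y) {
  theta <- exp(log_par[1]); g <- exp(log_par[2])
  n <- length(y)
  R <- exp(-D2 / (2 * theta^2))
  diag(R) <- diag(R) + g + 1e-10
  L <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  one <- rep(1, n)
  Ri_y <- backsolve(L, forwardsolve(t(L), y))
  Ri_1 <- backsolve(L, forwardsolve(t(L), one))
  mu <- sum(Ri_y) / sum(Ri_1)
  r <- y - mu
  Ri_r <- backsolve(L, forwardsolve(t(L), r))
  s2 <- max(sum(r * Ri_r) / n, 1e-300)
  n / 2 * log(s2) + sum(log(diag(L)))
}

#' Fit a Gaussian-process surrogate
#'
#' Kriging with constant mean and Gaussian kernel
#' `k(z, z') = sigma2 * exp(-d^2 / (2 theta^2))` on inputs min-max scaled
#' to the unit hypercube, plus a relative nugget `g` (observation noise
#' `sigma2 * g`) because the breeding objective is stochastic.  The
#' length-scale and nugget are estimated by maximum marginal likelihood
#' (coarse grid then L-BFGS-B); the constant mean and process variance are
#' profiled out analytically.
#'
#' @param X matrix of evaluated points (rows), original units.
#' @param y observed objective values.
#' @param space a [default_space()].
#' @return object of class `bo_gp` with the fitted hyperparameters and the
#'   Cholesky factor needed by [gp_posterior()].
#' @export
fit_gp <- function(X, y, space) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || length(unique(y)) < 2) {
    stop("need >= 2 observations with non-identical values")
  }
  Xs <- scale_to_unit(X, space)
  D2 <- sqdist(Xs, Xs)
  grid <- expand.grid(lt = log(c(0.05, 0.1, 0.2, 0.5, 1, 2)),
                      lg = log(c(1e-6, 1e-4, 1e-2, 1e-1, 1)))
  vals <- apply(grid, 1, function(p) gp_nll(as.numeric(p), D2, y))
  start <- as.numeric(grid[which.min(vals), ])
  opt <- optim(start, gp_nll, D2 = D2, y = y, method = "L-BFGS-B",
               lower = c(log(1e-3), log(1e-8)), upper = c(log(10), log(10)))
  theta <- exp(opt$par[1]); g <- exp(opt$par[2])
  n <- length(y)
  R <- exp(-D2 / (2 * theta^2))
  diag(R) <- diag(R) + g + 1e-10
  L <- chol(R)
  one <- rep(1, n)
  Ri_y <- backsolve(L, forwardsolve(t(L), y))
  Ri_1 <- backsolve(L, forwardsolve(t(L), one))
  mu <- sum(Ri_y) / sum(Ri_1)
  r <- y - mu
  Ri_r <- backsolve(L, forwardsolve(t(L), r))
  sigma2 <- max(sum(r * Ri_r) / n, 1e-300)
  structure(list(Xs = Xs, y = y, theta = theta, nugget = g, mu = mu,
                 sigma2 = sigma2, L = L, alpha = Ri_r, space = space),
            class = "bo_gp")
}

# Rebuild the data-dependent parts of a fitted GP on augmented data,
# keeping the hyperparameters (used by the constant-liar batch loop).
gp_update_data <- function(model, X_new, y_new) {
  Xs <- rbind(model$Xs, scale_to_unit(as.matrix(X_new), model$space))
  y <- c(model$y, y_new)
  D2 <- sqdist(Xs, Xs)
  R <- exp(-D2 / (2 * model$theta^2))
  diag(R) <- diag(R) + model$nugget + 1e-10
  L <- chol(R)
  r <- y - model$mu
  alpha <- backsolve(L, forwardsolve(t(L), r))
  model$Xs <- Xs; model$y <- y; model$L <- L; model$alpha <- alpha
  model
}

#' Gaussian-process posterior mean and standard deviation
#'
#' Standard kriging conditional: far from all data the mean reverts to the
#' fitted constant and the variance to the process variance; at a training
#' point with zero nugget the mean interpolates the observation.
#'
#' @param model a [fit_gp()] model.
#' @param X query points (matrix or single vector, original units).
#' @return list with numeric vectors `mean` and `sd`.
#' @export
gp_posterior <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  Qs <- scale_to_unit(as.matrix(X), model$space)
  K <- exp(-sqdist(Qs, model$Xs) / (2 * model$theta^2))
  mean <- model$mu + drop(K %*% model$alpha)
  v <- backsolve(model$L, forwardsolve(t(model$L), t(K)))
  var_rel <- pmax(1 - colSums(t(K) * v), 0)
  list(mean = mean, sd = sqrt(model$sigma2 * var_rel))
}

#' Expected improvement
#'
#' `EI(z) = E[max(0, g(z) - g_hat_max)]` under the GP posterior, in closed
#' form `(mu - g*) Phi(u) + sigma phi(u)` with `u = (mu - g*) / sigma`;
#' degenerates to `max(0, mu - g*)` when the posterior SD vanishes.
#'
#' @param model a [fit_gp()] model.
#' @param X query points (matrix or vector).
#' @param g_hat_max incumbent: the maximum posterior mean over the
#'   training inputs (not the maximum observed value).
#' @return non-negative numeric vector.
#' @export
expected_improvement <- function(model, X, g_hat_max) {
  post <- gp_posterior(model, X)
  ei_value(post$mean, post$sd, g_hat_max)
}

# Closed-form EI for given posterior moments; shared by the acquisition
# and unit-testable against a Monte-Carlo oracle.
ei_value <- function(mu, sd, g_hat_max) {
  d <- mu - g_hat_max
  out <- pmax(d, 0)
  ok <- sd > 1e-12
  u <- d[ok] / sd[ok]
  out[ok] <- d[ok] * pnorm(u) + sd[ok] * dnorm(u)
  pmax(out, 0)
}

# Incumbent used by EI: max posterior mean at the model's training inputs.
incumbent_mean <- function(model) {
  K <- exp(-sqdist(model$Xs, model$Xs) / (2 * model$theta^2))
  max(model$mu + drop(K %*% model$alpha))
}
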