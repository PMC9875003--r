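# Cheap deterministic 4-D objective with its maximum at z0 (sphere).
sphere_objective <- function(z0) {
  function(z, seed) {
    z <- as.numeric(z)
    -sum((z - z0)^2)
  }
}

test_that("Latin hypercube designs stratify every dimension", {
  sp1 <- structure(data.frame(name = "x", lower = 0, upper = 1,
                              integer = FALSE),
                   class = c("bo_space", "data.frame"))
  set.seed(1)
  x <- latin_hypercube(5, sp1)
  expect_identical(sort(findInterval(x[, 1], seq(0, 1, 0.2),
                                     rightmost.closed = TRUE)), 1:5)
  # 4-D: every continuous dimension has all strata occupied
  sp <- default_space(n_gen = 5)
  set.seed(2)
  X <- latin_hypercube(5, sp)
  for (j in which(!sp$integer)) {
    strata <- seq(sp$lower[j], sp$upper[j], length.out = 6)
    expect_identical(sort(findInterval(X[, j], strata,
                                       rightmost.closed = TRUE)), 1:5)
  }
  expect_true(all(X[, "pheno_p"] == round(X[, "pheno_p"])))
  # determinism
  set.seed(3); A <- latin_hypercube(7, sp)
  set.seed(3); B <- latin_hypercube(7, sp)
  expect_identical(A, B)
})

test_that("focus search finds a known concave maximum", {
  sp <- default_space(n_gen = 10)
  z0 <- c(0.4, 0.25, 0.6, 4)
  acq <- function(X) -rowSums(sweep(breedopt:::scale_to_unit(X, sp), 2,
                                    breedopt:::scale_to_unit(matrix(z0, 1), sp))^2)
  set.seed(4)
  got <- focus_search(acq, sp)
  gs <- breedopt:::scale_to_unit(matrix(got, 1), sp)
  zs <- breedopt:::scale_to_unit(matrix(z0, 1), sp)
  expect_lt(sqrt(sum((gs[, -4] - zs[, -4])^2)), 0.02)
  expect_identical(unname(got[4]), 4)
  # constant acquisition: any in-bounds point, no error
  set.seed(5)
  flat <- focus_search(function(X) rep(1, nrow(X)), sp,
                       restarts = 1, points_per_round = 50)
  expect_true(all(flat >= sp$lower & flat <= sp$upper))
  # bounds respected across seeds
  for (s in 1:20) {
    set.seed(s)
    p <- focus_search(acq, sp, restarts = 1, shrink_rounds = 2,
                      points_per_round = 100)
    expect_true(all(p >= sp$lower & p <= sp$upper))
  }
})

test_that("constant-liar batches are diverse and filtered", {
  sp <- default_space(n_gen = 5)
  set.seed(6)
  X <- latin_hypercube(12, sp)
  y <- apply(X, 1, function(z) -sum(breedopt:::scale_to_unit(matrix(z, 1), sp)^2))
  model <- fit_gp(X, y, sp)
  fc <- list(restarts = 2, points_per_round = 200)
  # q = 2 proposals separated by at least filter_tol in scaled units
  for (s in 1:10) {
    set.seed(s)
    prop <- propose_batch(model, 2, sp, filter_tol = 1e-3,
                          focus_control = fc)
    Ps <- breedopt:::scale_to_unit(prop$X, sp)
    expect_gte(sqrt(sum((Ps[1, ] - Ps[2, ])^2)), 1e-3)
    expect_true(all(prop$X >= matrix(sp$lower, 2, 4, byrow = TRUE) &
                      prop$X <= matrix(sp$upper, 2, 4, byrow = TRUE)))
  }
  # an absurdly large filter_tol forces random replacement of every point
  set.seed(7)
  prop_all <- propose_batch(model, 3, sp, filter_tol = 10,
                            focus_control = fc)
  expect_identical(prop_all$type, rep("rand_opt", 3))
  # q = 1 is plain EI maximisation
  set.seed(8)
  prop1 <- propose_batch(model, 1, sp, focus_control = fc)
  expect_identical(nrow(prop1$X), 1L)
  expect_identical(prop1$type, "infill_ei")
})

test_that("Bayesian runs have the stated budget and bookkeeping", {
  sp <- default_space(n_gen = 5)
  obj <- sphere_objective(c(0.3, 0.3, 0.5, 2))
  fc <- list(restarts = 2, points_per_round = 150)
  run <- run_bayes_opt(obj, sp, n_iter = 3, q = 2, seed = 10,
                       focus_control = fc)
  expect_identical(length(run$y), 5L + 3L * 2L)      # 5 + n_iter * q
  expect_true(all(diff(run$cum_max) >= 0))
  expect_true(any(apply(run$X, 1, function(r)
    identical(unname(r), unname(run$recommendation$z)))))
  expect_identical(run$type[1:5], rep("initdesign", 5))
  # bit-reproducible
  run2 <- run_bayes_opt(obj, sp, n_iter = 3, q = 2, seed = 10,
                        focus_control = fc)
  expect_identical(run$X, run2$X)
  expect_identical(run$y, run2$y)
  expect_identical(run$recommendation$z, run2$recommendation$z)
})

test_that("failing objective evaluations are replaced, not fatal", {
  sp <- default_space(n_gen = 5)
  flaky <- local({
    calls <- 0
    function(z, seed) {
      calls <<- calls + 1
      if (calls == 2) stop("simulated failure")
      -sum(as.numeric(z)^2)
    }
  })
  run <- run_random_opt(flaky, sp, n_iter = 2, q = 2, seed = 11)
  expect_identical(run$failures, 1L)
  expect_identical(length(run$y), 9L)
  expect_true(all(is.finite(run$y)))
})

test_that("random search covers the space uniformly", {
  sp <- default_space(n_gen = 5)
  obj <- function(z, seed) 0
  run <- suppressWarnings(run_random_opt(obj, sp, n_iter = 199, q = 5,
                                         seed = 12))
  expect_identical(length(run$y), 1000L)
  # per continuous dimension: KS test vs uniform not rejected at alpha=.01
  for (j in which(!sp$integer)) {
    u <- (run$X[, j] - sp$lower[j]) / (sp$upper[j] - sp$lower[j])
    expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
  }
  # recommendation is the best observed point
  obj2 <- sphere_objective(c(0.5, 0.5, 0.5, 3))
  run2 <- run_random_opt(obj2, sp, n_iter = 4, q = 3, seed = 13)
  expect_identical(run2$recommendation$observed, max(run2$y))
  expect_identical(length(run2$y), 5L + 4L * 3L)
})

test_that("Bayesian optimisation beats random search on the sphere", {
  # paired seeded runs on a deterministic objective; >= 80% wins
  sp <- default_space(n_gen = 5)
  obj <- sphere_objective(c(0.35, 0.2, 0.55, 2))
  fc <- list(restarts = 2, shrink_rounds = 3, points_per_round = 150)
  n_pairs <- 30   # scaled down from 100 paired runs for runtime
  wins <- 0L
  for (s in seq_len(n_pairs)) {
    rb <- run_bayes_opt(obj, sp, n_iter = 15, q = 2, seed = 1000 + s,
                        focus_control = fc)
    rr <- run_random_opt(obj, sp, n_iter = 15, q = 2, seed = 2000 + s)
    ub <- obj(rb$recommendation$z, 0)
    ur <- obj(rr$recommendation$z, 0)
    if (ub >= ur) wins <- wins + 1L
  }
  expect_gte(wins / n_pairs, 0.8)
})
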