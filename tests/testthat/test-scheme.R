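test_that("n_selected rounds halves up and clamps to [1, n_I]", {
  expect_identical(n_selected(100, 0.05), 5L)
  expect_identical(n_selected(10, 0.01), 1L)   # 0.1 -> 0 -> clamped to 1
  expect_identical(n_selected(7, 0.5), 4L)     # 3.5 rounds half-up
  expect_identical(n_selected(10, 1), 10L)
  expect_identical(n_selected(1, 0.99), 1L)
})

test_that("resource derivation follows the budget arithmetic", {
  cons <- bo_constraints(B = 1000, C_p = 1, C_n = 1, n_gen = 5)
  p <- bo_params(0.1, 0.1, 0.5, 1)
  plan <- derive_resources(cons, p)
  expect_identical(plan$n_new_tot, 500L)
  expect_identical(plan$n_P_tot, 500L)
  expect_equal(plan$B_eff, 1000)

  # phenotyping generations: every pheno_p starting at 1
  cons10 <- bo_constraints(B = 100, n_gen = 10)
  plan3 <- derive_resources(cons10, bo_params(0.1, 0.1, 0.5, 3))
  expect_identical(plan3$pheno_gens, c(1L, 4L, 7L, 10L))
  plan2 <- derive_resources(cons10, bo_params(0.1, 0.1, 0.5, 2))
  expect_identical(plan2$pheno_gens, c(1L, 3L, 5L, 7L, 9L))
  expect_identical(length(plan3$pheno_gens), as.integer(ceiling(10 / 3)))

  # 10 plots over 4 phenotyping generations: permutation of (3,3,2,2)
  set.seed(1)
  cons_s <- bo_constraints(B = 510, C_p = 50, C_n = 1, n_gen = 10)
  plan_s <- derive_resources(cons_s, bo_params(0.1, 0.1, 0.0196, 3))
  expect_identical(plan_s$n_P_tot, 10L)
  expect_identical(sort(plan_s$n_P_t[plan_s$pheno_gens]), c(2L, 2L, 3L, 3L))
  expect_true(all(plan_s$n_P_t[-plan_s$pheno_gens] == 0L))

  # n_P_1 floor of 3
  cons_t <- bo_constraints(B = 100, C_p = 10, C_n = 1, n_gen = 5)
  plan_t <- derive_resources(cons_t, bo_params(0.1, 0.1, 0.9, 1))
  expect_identical(plan_t$n_P_tot, 1L)
  expect_gte(plan_t$n_P_t[1], 3L)
})

test_that("deferred progeny allocation sums to the campaign total", {
  cons <- bo_constraints(B = 200, n_gen = 5)
  plan <- derive_resources(cons, bo_params(0.2, 0.2, 0.5, 2))
  expect_true(all(is.na(plan$n_new_t)))
  set.seed(2)
  plan <- breedopt:::finalize_progeny_plan(plan, n_C1 = 4L, n_gen = 5L)
  expect_identical(plan$n_new_t[1], 4L)
  expect_identical(sum(plan$n_new_t), plan$n_new_tot)
  expect_lte(max(plan$n_new_t[-1]) - min(plan$n_new_t[-1]), 1L)
})

test_that("ridge genomic prediction ranks noiseless phenotypes", {
  # Overdetermined noiseless geometry (n_train > n_snp): ridge with a
  # GCV-chosen penalty recovers the effects, so held-out ranking is
  # near-perfect.  (With LD-free markers and n < p the attainable
  # held-out accuracy is information-limited to rho ~ 0.4, as confirmed
  # by independent dense and glmnet oracles; that regime is covered by
  # the oracle-agreement test below.)
  out <- simulate_founders(350, n_chr = 10, n_snp = 100, seed = 20)
  arch <- sample_qtn_effects(out$genome, 50, seed = 21)
  gv <- genotypic_values(out$pop, arch)
  dos <- dosage_matrix(out$pop)
  train <- 1:300; test <- 301:350
  model <- fit_genomic_prediction(
    dos[train, ],
    data.frame(id = out$pop$ids[train], value = gv[train])
  )
  pred <- predict(model, dos[test, ])
  expect_gte(cor(pred, gv[test], method = "spearman"), 0.95)
})

test_that("ridge predictions agree with a dense oracle when n < p", {
  out <- simulate_founders(120, n_chr = 5, n_snp = 200, seed = 29)
  arch <- sample_qtn_effects(out$genome, 50, seed = 28)
  gv <- genotypic_values(out$pop, arch)
  dos <- dosage_matrix(out$pop)
  train <- 1:100; test <- 101:120
  model <- fit_genomic_prediction(
    dos[train, ],
    data.frame(id = out$pop$ids[train], value = gv[train])
  )
  Xc <- sweep(dos[train, ], 2, colMeans(dos[train, ]))
  b <- solve(crossprod(Xc) + diag(model$lambda, 200),
             crossprod(Xc, gv[train] - mean(gv[train])))
  oracle <- drop(sweep(dos[test, ], 2, colMeans(dos[train, ])) %*% b) +
    mean(gv[train])
  expect_equal(unname(predict(model, dos[test, ])), unname(oracle),
               tolerance = 1e-6)
})

test_that("monomorphic markers get zero effect after centring", {
  out <- simulate_founders(50, 2, 40, seed = 22)
  dos <- dosage_matrix(out$pop)
  dos[, 5] <- 2L  # force a constant column
  arch <- sample_qtn_effects(out$genome, 10, seed = 23)
  y <- drop(dos %*% arch$beta) + rnorm(50, 0, 0.1)
  model <- fit_genomic_prediction(dos, data.frame(id = out$pop$ids, value = y))
  expect_lt(abs(model$beta_hat[5]), 1e-8)
})

test_that("replicated records match the duplicated-row normal equations", {
  set.seed(24)
  X <- matrix(sample(0:2, 6 * 4, replace = TRUE), 6, 4)
  rownames(X) <- paste0("i", 1:6)
  phen <- data.frame(id = rep(rownames(X), times = c(3, 1, 2, 1, 1, 2)),
                     value = rnorm(10))
  model <- fit_genomic_prediction(X, phen)
  # dense oracle: duplicated rows, centred, same lambda
  Xd <- X[phen$id, , drop = FALSE]
  ctr <- colMeans(Xd)
  Xc <- sweep(Xd, 2, ctr)
  lam <- model$lambda
  beta <- solve(crossprod(Xc) + diag(lam, 4), crossprod(Xc, phen$value - mean(phen$value)))
  expect_equal(unname(model$beta_hat), drop(beta), tolerance = 1e-8)
  expect_equal(model$intercept, mean(phen$value))
  expect_equal(unname(model$centers), unname(ctr))
})

test_that("degenerate training data yield an intercept-only model", {
  X <- matrix(0:1, 4, 3); rownames(X) <- paste0("i", 1:4)
  model <- fit_genomic_prediction(X, data.frame(id = rownames(X), value = rep(2, 4)))
  expect_true(all(model$beta_hat == 0))
  expect_equal(model$intercept, 2)
  expect_error(fit_genomic_prediction(X, data.frame(id = "i1", value = 1)),
               "at least 3")
  expect_error(fit_genomic_prediction(X, data.frame(id = c("i1", "i2", "zz"),
                                                    value = 1:3)),
               "without a dosage row")
})

test_that("weighted distance is a seminorm of effect-scaled differences", {
  expect_equal(weighted_distance(c(0, 2), c(2, 2), c(1, 2)), 2)
  expect_equal(weighted_distance(c(1, 1), c(1, 1), c(3, 3)), 0)
  set.seed(25)
  for (k in 1:10) {
    a <- sample(0:2, 5, TRUE); b <- sample(0:2, 5, TRUE); w <- rnorm(5)
    expect_equal(weighted_distance(a, b, w), weighted_distance(b, a, w))
  }
})

test_that("mating tables cover the stated designs", {
  # selfing
  m1 <- order_matings("p", matrix(0, 1, 3), rep(1, 3))
  expect_identical(m1, data.frame(mother = "p", father = "p",
                                  stringsAsFactors = FALSE))
  # n_S = 2: one cross; n_S = 3: all three pairs
  X <- matrix(sample(0:2, 9, TRUE), 3, 3)
  m2 <- order_matings(c("a", "b"), X[1:2, ], rep(1, 3))
  expect_identical(nrow(m2), 1L)
  m3 <- order_matings(c("a", "b", "c"), X, rep(1, 3))
  expect_identical(nrow(m3), 3L)
  expect_setequal(paste(m3$mother, m3$father),
                  c("a b", "a c", "b c"))
})

test_that("TSP mating order is near the exhaustive optimum", {
  # compiled search vs pure-R enumeration oracle, n_S in 5..7
  set.seed(26)
  for (n_S in 5:7) {
    dosages <- matrix(sample(0:2, n_S * 30, TRUE), n_S, 30)
    beta <- rnorm(30)
    ids <- paste0("s", seq_len(n_S))
    mt <- order_matings(ids, dosages, beta)
    expect_identical(nrow(mt), n_S)
    # every parent appears exactly twice in the cycle
    expect_true(all(table(c(mt$mother, mt$father)) == 2))
    D <- breedopt:::weighted_distance_matrix(dosages, beta)
    ord <- match(mt$mother, ids)
    got <- breedopt:::tour_cost(ord, D)
    best <- breedopt:::tour_cost(breedopt:::tsp_exact(D), D)
    expect_lte(got, best * 1.05)
  }
  # heuristic regime (n_S > 8): tour no worse than the identity order
  set.seed(27)
  n_S <- 15
  dosages <- matrix(sample(0:2, n_S * 40, TRUE), n_S, 40)
  beta <- rnorm(40)
  mt <- order_matings(paste0("s", 1:n_S), dosages, beta)
  D <- breedopt:::weighted_distance_matrix(dosages, beta)
  got <- breedopt:::tour_cost(match(mt$mother, paste0("s", 1:n_S)), D)
  expect_lte(got, breedopt:::tour_cost(1:n_S, D))
})

test_that("progeny allocation is uniform with random remainder", {
  set.seed(28)
  expect_identical(sort(allocate_progeny(3, 10)), c(3L, 3L, 4L))
  expect_identical(allocate_progeny(5, 5), rep(1L, 5))
  expect_identical(sort(allocate_progeny(4, 2)), c(0L, 0L, 1L, 1L))
  expect_identical(sum(allocate_progeny(7, 23)), 23L)
})

test_that("breeding campaigns are reproducible and budget-conserving", {
  out <- simulate_founders(60, 5, 120, seed = 30)
  arch <- sample_qtn_effects(out$genome, 30, seed = 31)
  sig2 <- residual_variance(genotypic_values(out$pop, arch), 0.5)
  cons <- bo_constraints(B = 400, n_gen = 4)
  p <- bo_params(0.15, 0.2, 0.4, 2)
  r1 <- run_breeding_scheme(cons, p, out$pop, arch, sig2, seed = 99)
  r2 <- run_breeding_scheme(cons, p, out$pop, arch, sig2, seed = 99)
  expect_identical(r1$u, r2$u)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(length(r1$trajectory), 5L)  # founders + 4 cycles
  # objective equals the final population's mean genotypic value
  expect_equal(r1$u, mean(genotypic_values(r1$final_pop, arch)))
  # generation-1 progeny rule: n_new_1 equals the number of generation-1
  # crosses; with 60 founders and i_init = 0.15 that is n_S_1 = n_C_1 = 9
  expect_identical(r1$plan$n_new_t[1], 9L)
  expect_identical(sum(r1$plan$n_new_t), r1$plan$n_new_tot)
})

test_that("selection raises the genotypic mean when noiseless", {
  # sigma_e = 0, strong selection, ample budget: final mean beats the
  # founder mean in >= 95 of 100 seeded campaigns
  out <- simulate_founders(50, 3, 90, seed = 32)
  arch <- sample_qtn_effects(out$genome, 30, seed = 33)
  founder_mean <- mean(genotypic_values(out$pop, arch))
  cons <- bo_constraints(B = 500, n_gen = 5)
  p <- bo_params(0.1, 0.1, 0.6, 1)
  wins <- 0L
  for (s in 1:100) {
    r <- run_breeding_scheme(cons, p, out$pop, arch, 0, seed = s)
    if (r$u > founder_mean) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("the objective factory validates and reproduces the simulator", {
  out <- simulate_founders(40, 3, 60, seed = 34)
  arch <- sample_qtn_effects(out$genome, 20, seed = 35)
  sig2 <- residual_variance(genotypic_values(out$pop, arch), 0.7)
  cons <- bo_constraints(B = 300, n_gen = 3)
  obj <- make_objective(cons, out$pop, arch, sig2)
  z <- c(i_init = 0.2, i = 0.3, B_rep = 0.5, pheno_p = 1)
  u1 <- obj(z, 7)
  u2 <- run_breeding_scheme(cons, bo_params(0.2, 0.3, 0.5, 1), out$pop,
                            arch, sig2, seed = 7)$u
  expect_identical(u1, u2)
})
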