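#' Breeding-campaign constraints
#'
#' The five quantities the breeder cannot control: total budget `B`, cost
#' per phenotyping plot `C_p`, cost per new genotyped individual `C_n`,
#' number of selection cycles `n_gen`, and the founder population.
#'
#' @param B total budget (> 0, cost units).
#' @param C_p cost of one phenotyping plot (> 0).
#' @param C_n cost of creating and genotyping one new individual (> 0).
#' @param n_gen number of selection cycles (>= 1).
#' @return list of class `bo_constraints`.
#' @export
bo_constraints <- function(B, C_p = 1, C_n = 1, n_gen) {
  stopifnot(B > 0, C_p > 0, C_n > 0, n_gen >= 1)
  structure(list(B = B, C_p = C_p, C_n = C_n, n_gen = as.integer(n_gen)),
            class = "bo_constraints")
}

#' Scheme decision variables
#'
#' The four optimisable parameters: `i_init` (selection intensity applied
#' to the founder generation), `i` (intensity for all later generations),
#' `B_rep` (fraction of the budget spent on creating new individuals; the
#' rest buys phenotyping plots) and `pheno_p` (phenotyping period in
#' generations).
#'
#' @param i_init,i selection intensities in (0, 1].
#' @param B_rep budget fraction in (0, 1).
#' @param pheno_p integer phenotyping period (>= 1).
#' @return list of class `bo_params`.
#' @export
bo_params <- function(i_init, i, B_rep, pheno_p) {
  stopifnot(i_init > 0, i_init <= 1, i > 0, i <= 1,
            B_rep > 0, B_rep < 1, pheno_p >= 1)
  structure(list(i_init = i_init, i = i, B_rep = B_rep,
                 pheno_p = as.integer(round(pheno_p))),
            class = "bo_params")
}

#' Number of parents selected from a generation
#'
#' `n_I * intensity` rounded to the nearest integer (halves up) and
#' clamped to the strictly positive range `[1, n_I]`.
#'
#' @param n_I generation size (>= 1).
#' @param intensity selection intensity in (0, 1].
#' @return integer in `[1, n_I]`.
#' @export
n_selected <- function(n_I, intensity) {
  stopifnot(n_I >= 1, intensity > 0, intensity <= 1)
  as.integer(min(max(round_half_up(n_I * intensity), 1L), n_I))
}

#' Derive per-generation resources from constraints and decision variables
#'
#' Campaign totals: `n_new_tot = round(B * B_rep / C_n)` (nearest, halves
#' up; clamped down if rounding overshoots the budget) and
#' `n_P_tot = floor((B - n_new_tot * C_n) / C_p)`.  Phenotyping happens at
#' generation 1 and then every `pheno_p` generations; `n_P_tot` is split
#' as evenly as possible over those generations (random remainder), after
#' which `n_P_1` is raised to 3 if smaller so the first prediction model
#' can always be fitted.  The per-generation split of new individuals is
#' deferred: generation 1 creates exactly one offspring per cross (parents
#' are homozygous, so same-cross siblings would be genetically identical),
#' and the remainder is split over generations 2..n_gen once the number of
#' generation-1 crosses is known (see `finalize_progeny_plan`).
#'
#' @param constraints a [bo_constraints()].
#' @param params a [bo_params()].
#' @return list of class `bo_plan`: `n_new_tot`, `n_P_tot`, `B_eff`,
#'   `n_P_t` (length n_gen), `pheno_gens`, and `n_new_t` (all `NA` until
#'   finalized).
#' @export
derive_resources <- function(constraints, params) {
  B <- constraints$B; C_p <- constraints$C_p; C_n <- constraints$C_n
  n_gen <- constraints$n_gen
  n_new_tot <- as.integer(round_half_up(B * params$B_rep / C_n))
  note <- character(0)
  if (n_new_tot * C_n > B) {
    n_new_tot <- as.integer(B %/% C_n)
    note <- c(note, "n_new_tot clamped: rounded cost exceeded the budget")
  }
  n_P_tot <- as.integer((B - n_new_tot * C_n) %/% C_p)
  B_eff <- n_new_tot * C_n + n_P_tot * C_p
  pheno_gens <- seq.int(1L, n_gen, by = params$pheno_p)
  n_P_t <- integer(n_gen)
  n_P_t[pheno_gens] <- split_evenly(n_P_tot, length(pheno_gens))
  if (n_P_t[1L] < 3L) {
    note <- c(note, sprintf("n_P_1 raised from %d to 3", n_P_t[1L]))
    n_P_t[1L] <- 3L
  }
  structure(list(n_new_tot = n_new_tot, n_P_tot = n_P_tot, B_eff = B_eff,
                 n_P_t = n_P_t, pheno_gens = pheno_gens,
                 n_new_t = rep(NA_integer_, n_gen), notes = note),
            class = "bo_plan")
}

# Fill in the per-generation counts of new individuals once the number of
# generation-1 crosses is known: n_new_1 = n_C_1, remainder split evenly
# (random remainder) over generations 2..n_gen.
finalize_progeny_plan <- function(plan, n_C1, n_gen) {
  n_new_t <- integer(n_gen)
  n_new_t[1L] <- n_C1
  remaining <- plan$n_new_tot - n_C1
  if (remaining < 0) {
    plan$notes <- c(plan$notes, "n_new_tot smaller than generation-1 crosses")
    remaining <- 0L
  }
  if (n_gen > 1L) {
    n_new_t[2:n_gen] <- split_evenly(remaining, n_gen - 1L)
  } else if (remaining > 0) {
    plan$notes <- c(plan$notes, "single-cycle campaign: surplus new-individual budget unused")
  }
  plan$n_new_t <- n_new_t
  plan
}

#' Fit a ridge (RR-BLUP style) genomic prediction model
#'
#' Ridge regression of plot phenotypes on centred marker dosages with an
#' unpenalised intercept.  Replicated records enter as duplicated rows,
#' handled through weighted normal equations; the penalty is chosen by
#' generalized cross-validation over a log-spaced grid.
#'
#' @param train_dosages dosage matrix with one row per phenotyped
#'   individual, rownames = individual ids.
#' @param train_phenos data.frame with columns `id` and `value`, one row
#'   per plot record (ids may repeat).
#' @return object of class `bo_gpred`: `beta_hat` (length n_snp),
#'   `intercept`, `centers`, `lambda`.  Degenerate training data (constant
#'   phenotypes) yield a zero-effect model with intercept only.
#' @export
fit_genomic_prediction <- function(train_dosages, train_phenos) {
  stopifnot(is.matrix(train_dosages), !is.null(rownames(train_dosages)))
  stopifnot(all(c("id", "value") %in% names(train_phenos)))
  if (nrow(train_phenos) < 3) stop("need at least 3 phenotype records")
  if (!all(train_phenos$id %in% rownames(train_dosages))) {
    stop("phenotyped individual without a dosage row")
  }
  n_rec <- nrow(train_phenos)
  p <- ncol(train_dosages)
  agg_w <- tapply(train_phenos$value, train_phenos$id, length)
  agg_m <- tapply(train_phenos$value, train_phenos$id, mean)
  agg_ss <- tapply(train_phenos$value, train_phenos$id,
                   function(v) sum((v - mean(v))^2))
  ids <- names(agg_w)
  X <- train_dosages[ids, , drop = FALSE]
  w <- as.numeric(agg_w)
  ybar <- as.numeric(agg_m)
  mu <- sum(w * ybar) / sum(w)            # grand mean over records
  if (var(train_phenos$value) == 0) {
    return(structure(list(beta_hat = numeric(p), intercept = mu,
                          centers = colMeans(X), lambda = Inf),
                     class = "bo_gpred"))
  }
  centers <- colSums(w * X) / sum(w)      # record-weighted column means
  Xc <- sweep(X, 2, centers)
  A <- crossprod(Xc * sqrt(w))            # X' W X, p x p
  b <- crossprod(Xc, w * ybar)            # X' W y
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  Vtb <- crossprod(eg$vectors, b)
  yc <- ybar - mu
  within_ss <- sum(agg_ss)
  lambdas <- 10^seq(-4, 8, length.out = 60)
  best <- NULL
  for (lam in lambdas) {
    beta <- eg$vectors %*% (Vtb / (d + lam))
    fit <- drop(Xc %*% beta)
    rss <- sum(w * (yc - fit)^2) + within_ss
    df <- sum(d / (d + lam)) + 1          # +1 for the intercept
    gcv <- n_rec * rss / (n_rec - min(df, n_rec - 1))^2
    if (is.null(best) || gcv < best$gcv) {
      best <- list(gcv = gcv, lambda = lam, beta = drop(beta))
    }
  }
  structure(list(beta_hat = best$beta, intercept = mu, centers = centers,
                 lambda = best$lambda),
            class = "bo_gpred")
}

#' Predict genetic values from a fitted marker model
#'
#' @param object a [fit_genomic_prediction()] model.
#' @param newdata dosage matrix (individuals x markers).
#' @param ... unused.
#' @return numeric vector of predicted values.
#' @export
predict.bo_gpred <- function(object, newdata, ...) {
  drop(sweep(newdata, 2, object$centers) %*% object$beta_hat) + object$intercept
}

#' Effect-weighted genetic distance between two individuals
#'
#' Euclidean norm of the elementwise product of the estimated marker
#' effects with the dosage difference.
#'
#' @param dosage_A,dosage_B dosage vectors of equal length.
#' @param beta_hat estimated marker effects.
#' @return non-negative scalar; 0 iff the weighted profiles coincide.
#' @export
weighted_distance <- function(dosage_A, dosage_B, beta_hat) {
  stopifnot(length(dosage_A) == length(dosage_B),
            length(dosage_A) == length(beta_hat))
  sqrt(sum((beta_hat * (dosage_A - dosage_B))^2))
}

# Pairwise weighted-distance matrix for a dosage matrix.
weighted_distance_matrix <- function(dosages, beta_hat) {
  W <- sweep(dosages, 2, beta_hat, `*`)
  as.matrix(dist(W))
}

# Cost of a cyclic mating order: sum of inverse distances over the cycle's
# edges; zero distances (clones) are clamped at 1e-12 so the tour avoids
# adjacent clones.
tour_cost <- function(order, D) {
  d <- D[cbind(order, c(order[-1], order[1]))]
  sum(1 / pmax(d, 1e-12))
}

# Pure-R exact TSP by enumeration (first city fixed); n <= 8.  Retained
# as the independent oracle against which the compiled tour search is
# tested.
tsp_exact <- function(D) {
  n <- nrow(D)
  perms <- permutations_of(seq_len(n)[-1])
  best <- NULL
  for (p in perms) {
    ord <- c(1L, p)
    cst <- tour_cost(ord, D)
    if (is.null(best) || cst < best$cost) best <- list(order = ord, cost = cst)
  }
  best$order
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Compiled tour search: exact enumeration up to 8 parents, greedy
# construction plus 2-opt above.
tsp_tour <- function(D) {
  inv <- 1 / pmax(D, 1e-12)
  diag(inv) <- 0
  tsp_tour_cpp(inv)
}

#' Build a mating table from the selected parents
#'
#' With 4 or more parents, a travelling-salesperson tour is sought that
#' makes the cycle's summed inverse effect-weighted distances small; each
#' consecutive couple (including the wrap-around) becomes one cross, so
#' `n_C = n_S`.  With 2 or 3 parents every unordered pair is crossed; a
#' single parent is self-fertilized.  The tour is exact (enumeration) for
#' up to 8 parents and nearest-neighbour + 2-opt above.
#'
#' @param selected_ids ids of the selected parents.
#' @param selected_dosages their dosage matrix (rows aligned to
#'   `selected_ids`).
#' @param beta_hat marker effects of the latest prediction model.
#' @return data.frame with columns `mother`, `father` (one row per cross).
#' @export
order_matings <- function(selected_ids, selected_dosages, beta_hat) {
  n_S <- length(selected_ids)
  stopifnot(n_S >= 1)
  if (n_S == 1L) {
    return(data.frame(mother = selected_ids, father = selected_ids,
                      stringsAsFactors = FALSE))
  }
  if (n_S <= 3L) {
    prs <- combn(selected_ids, 2)
    return(data.frame(mother = prs[1, ], father = prs[2, ],
                      stringsAsFactors = FALSE))
  }
  D <- weighted_distance_matrix(selected_dosages, beta_hat)
  ord <- tsp_tour(D)
  ids <- selected_ids[ord]
  data.frame(mother = ids, father = c(ids[-1], ids[1]),
             stringsAsFactors = FALSE)
}

#' Allocate progeny over crosses
#'
#' Every cross gets `floor(n_new / n_C)` offspring; the remainder is
#' assigned one each to crosses chosen uniformly at random.
#'
#' @param n_C number of crosses (>= 1).
#' @param n_new total number of offspring (>= 0).
#' @return integer vector of length `n_C` summing to `n_new`.
#' @export
allocate_progeny <- function(n_C, n_new) {
  stopifnot(n_C >= 1, n_new >= 0)
  split_evenly(n_new, n_C)
}

#' Run one budget-constrained breeding campaign
#'
#' Executes the full loop for `n_gen` cycles: phenotype the current
#' generation on its allotted plots (at phenotyping generations), refit
#' the ridge prediction model on all records accumulated since generation
#' 1, select the top individuals by predicted value (ties broken by id),
#' build the mating table, allocate progeny and cross.  Each new cycle's
#' population consists only of the offspring of the previous cycle.  The
#' objective `u` is the mean true genotypic value of the final offspring
#' generation.
#'
#' @param constraints a [bo_constraints()].
#' @param params a [bo_params()].
#' @param founders founder [bo_pop()] (fully homozygous).
#' @param arch trait architecture ([sample_qtn_effects()]).
#' @param sigma_e2 residual variance (calibrated once on the founders, e.g.
#'   via [residual_variance()]).
#' @param seed integer seed; the whole campaign is reproducible from it.
#' @return object of class `bo_result`: `u`, `trajectory` (mean genotypic
#'   value of founders and of each offspring generation, length
#'   `n_gen + 1` unless the campaign terminated early), `plan`
#'   (realised [derive_resources()] plan), `seed`, `completed_cycles`.
#' @export
run_breeding_scheme <- function(constraints, params, founders, arch,
                                sigma_e2, seed = 1L) {
  set.seed(seed)
  n_gen <- constraints$n_gen
  plan <- derive_resources(constraints, params)
  pop <- founders
  records <- NULL
  train_dos <- NULL
  model <- NULL
  traj <- mean(genotypic_values(pop, arch))
  completed <- 0L
  for (t in seq_len(n_gen)) {
    nI <- n_ind(pop)
    nP <- plan$n_P_t[t]
    if (nP > 0) {
      counts <- allocate_plots(nI, nP)
      recs <- simulate_phenotypes(pop, counts, arch, sigma_e2)
      records <- rbind(records, recs)
      newly <- counts > 0
      if (any(newly)) {
        add <- dosage_matrix(pop)[newly, , drop = FALSE]
        train_dos <- rbind(train_dos, add[!(rownames(add) %in% rownames(train_dos)), , drop = FALSE])
      }
      model <- fit_genomic_prediction(train_dos, records)
    }
    pred <- if (is.null(model)) {
      stats::setNames(numeric(nI), pop$ids)   # cannot happen: n_P_1 >= 3
    } else {
      predict(model, dosage_matrix(pop))
    }
    nS <- n_selected(nI, if (t == 1L) params$i_init else params$i)
    sel <- order(-pred, pop$ids)[seq_len(nS)]
    beta_hat <- if (is.null(model)) numeric(pop$genome$n_snp) else model$beta_hat
    mating <- order_matings(pop$ids[sel],
                            dosage_matrix(pop)[sel, , drop = FALSE],
                            beta_hat)
    n_C <- nrow(mating)
    if (t == 1L) plan <- finalize_progeny_plan(plan, n_C, n_gen)
    n_new <- if (t == 1L) n_C else plan$n_new_t[t]
    if (n_new == 0L) {
      plan$notes <- c(plan$notes,
                      sprintf("no new individuals at cycle %d: campaign ended early", t))
      break
    }
    progeny <- allocate_progeny(n_C, n_new)
    offspring <- cross_table(pop, mating, progeny)
    if (is.null(offspring)) {
      plan$notes <- c(plan$notes,
                      sprintf("no progeny realised at cycle %d: campaign ended early", t))
      break
    }
    pop <- offspring
    traj <- c(traj, mean(genotypic_values(pop, arch)))
    completed <- t
  }
  structure(list(u = traj[length(traj)], trajectory = traj, plan = plan,
                 seed = seed, completed_cycles = completed,
                 final_pop = pop),
            class = "bo_result")
}

#' @export
print.bo_result <- function(x, ...) {
  cat("<bo_result> u = ", format(x$u, digits = 4), " after ",
      x$completed_cycles, " cycle(s); trajectory: ",
      paste(format(x$trajectory, digits = 3), collapse = " -> "), "\n",
      sep = "")
  invisible(x)
}

#' Objective-function factory for the optimiser
#'
#' Binds a founder population, trait architecture and constraints into the
#' scalar objective `g(z)` maximised by [run_bayes_opt()]: given decision
#' variables and a seed, run one campaign and return `u`.
#'
#' @param constraints a [bo_constraints()].
#' @param founders founder [bo_pop()].
#' @param arch trait architecture.
#' @param sigma_e2 residual variance.
#' @return `function(z, seed)` with `z` a named vector/list holding
#'   `i_init`, `i`, `B_rep`, `pheno_p`.
#' @export
make_objective <- function(constraints, founders, arch, sigma_e2) {
  force(constraints); force(founders); force(arch); force(sigma_e2)
  function(z, seed) {
    p <- bo_params(z[["i_init"]], z[["i"]], z[["B_rep"]], z[["pheno_p"]])
    run_breeding_scheme(constraints, p, founders, arch, sigma_e2,
                        seed = seed)$u
  }
}
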