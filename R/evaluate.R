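#' The eight benchmark scenarios
#'
#' All combinations of heritability (0.3, 0.7), campaign length (5, 10
#' cycles) and budget (200 or 600 plot-equivalents per cycle), with unit
#' phenotyping and genotyping costs.
#'
#' @return data.frame with columns `label` (a-h), `H2`, `n_gen`, `B`,
#'   `C_p`, `C_n`.
#' @export
scenario_table <- function() {
  grid <- expand.grid(B_per_gen = c(200, 600), n_gen = c(5L, 10L),
                      H2 = c(0.3, 0.7))
  grid <- grid[order(grid$H2, grid$n_gen, grid$B_per_gen), ]
  data.frame(label = letters[1:8], H2 = grid$H2, n_gen = grid$n_gen,
             B = grid$n_gen * grid$B_per_gen, C_p = 1, C_n = 1,
             stringsAsFactors = FALSE)
}

#' Evaluate fixed scheme parameters by repeated campaigns
#'
#' Runs `n_evaluation` independent seeded campaigns with identical
#' parameters and returns the objective values; per-campaign failures are
#' recorded as `NA`, never fatal.
#'
#' @param objective a [make_objective()] closure.
#' @param z named vector of decision variables.
#' @param n_evaluation number of repeated campaigns.
#' @param seed seed for the campaign-seed pool.
#' @return numeric vector of `n_evaluation` objective values.
#' @export
evaluate_params <- function(objective, z, n_evaluation, seed = 1L) {
  set.seed(seed)
  seeds <- draw_seeds(n_evaluation)
  vapply(seeds, function(s) {
    tryCatch(objective(z, s), error = function(e) NA_real_)
  }, numeric(1))
}

#' Pairwise win proportion of one sample over another
#'
#' Fraction of ordered pairs `(a, b)` with `a > b` strictly; ties count as
#' non-wins, so the proportions of A over B and B over A sum to at most 1.
#'
#' @param samples_A,samples_B non-empty numeric vectors.
#' @return proportion in `[0, 1]`.
#' @export
pairwise_win_proportion <- function(samples_A, samples_B) {
  stopifnot(length(samples_A) > 0, length(samples_B) > 0)
  mean(outer(samples_A, samples_B, `>`))
}

#' Cumulative maxima of a run's observations over iterations
#'
#' @param run a `bo_run`, or a numeric vector of per-iteration values.
#' @return non-decreasing numeric vector, one entry per iteration (the
#'   running maximum over all observations up to that iteration).
#' @export
cumulative_maxima <- function(run) {
  if (is.numeric(run)) return(cummax(run))
  its <- sort(unique(run$iteration))
  cummax(vapply(its, function(i) max(run$y[run$iteration == i]), numeric(1)))
}

#' Pick the representative run of a set
#'
#' The run whose cumulative-maxima curve is closest (mean squared error)
#' to the across-run average curve; ties broken by the lowest index.
#'
#' @param runs list of `bo_run` objects (or numeric curves) of equal
#'   iteration length.
#' @return integer index of the representative run.
#' @export
representative_run <- function(runs) {
  stopifnot(length(runs) >= 2)
  curves <- lapply(runs, cumulative_maxima)
  len <- lengths(curves)
  if (length(unique(len)) != 1L) stop("runs have unequal iteration counts")
  M <- do.call(rbind, curves)
  avg <- colMeans(M)
  mse <- rowMeans(sweep(M, 2, avg)^2)
  which.min(mse)  # which.min is the lowest index on ties
}

#' ECDF table of a sample
#'
#' @param samples non-empty numeric vector.
#' @return data.frame `value`, `quantile` (right-continuous ECDF evaluated
#'   at the sorted unique values; the maximum maps to 1).
#' @export
ecdf_table <- function(samples) {
  stopifnot(length(samples) > 0)
  v <- sort(unique(samples))
  data.frame(value = v, quantile = stats::ecdf(samples)(v))
}

#' Run a full method-comparison experiment
#'
#' For each scenario and each of `n_runs` paired repetitions: generate the
#' founder panel and trait architecture from a shared (paired) seed, run
#' Bayesian and random optimisation with method-specific seeds, then
#' evaluate each recommendation with `n_evaluation` independent
#' campaigns.  With `n_evaluation > 1` the comparison follows the
#' representative-run design (one representative run per method, all
#' evaluation pairs compared); with `n_evaluation = 1` every run
#' contributes one value and all cross-method pairs are compared.
#'
#' @param scenarios subset of [scenario_table()] (rows), or labels.
#' @param n_runs optimisation repetitions per scenario and method.
#' @param n_iter,q optimiser budget per run.
#' @param n_evaluation campaigns per recommendation.
#' @param founder_spec list `n_ind`, `n_chr`, `n_snp`, `n_qtn` for the
#'   synthetic founder panel (default 100 founders, 20 chromosomes,
#'   500 SNPs, 100 QTN).
#' @param seed master seed.
#' @param init_n initial design size (default 5).
#' @param focus_control optional focus-search effort override.
#' @return list of class `bo_report`: per-scenario win proportions,
#'   evaluation samples, failure counts and run summaries.
#' @export
run_experiment <- function(scenarios = scenario_table(), n_runs = 16L,
                           n_iter = 50L, q = 8L, n_evaluation = 32L,
                           founder_spec = list(n_ind = 100L, n_chr = 20L,
                                               n_snp = 500L, n_qtn = 100L),
                           seed = 1L, init_n = 5L, focus_control = list()) {
  if (is.character(scenarios)) {
    tab <- scenario_table()
    scenarios <- tab[tab$label %in% scenarios, , drop = FALSE]
  }
  set.seed(seed)
  pair_seeds <- draw_seeds(n_runs)
  opt_seeds <- matrix(draw_seeds(2L * n_runs), ncol = 2L)
  eval_seeds <- matrix(draw_seeds(2L * n_runs), ncol = 2L)
  out <- list()
  for (sc in seq_len(nrow(scenarios))) {
    s <- scenarios[sc, ]
    cons <- bo_constraints(B = s$B, C_p = s$C_p, C_n = s$C_n, n_gen = s$n_gen)
    space <- default_space(s$n_gen)
    res <- list(bayes = list(runs = list(), samples = list()),
                random = list(runs = list(), samples = list()))
    for (k in seq_len(n_runs)) {
      fnd <- simulate_founders(founder_spec$n_ind, founder_spec$n_chr,
                               founder_spec$n_snp, seed = pair_seeds[k])
      arch <- sample_qtn_effects(fnd$genome, founder_spec$n_qtn,
                                 seed = pair_seeds[k] + 1L)
      g0 <- genotypic_values(fnd$pop, arch)
      sig2 <- residual_variance(g0, s$H2)
      obj <- make_objective(cons, fnd$pop, arch, sig2)
      for (m in c("bayes", "random")) {
        col <- if (m == "bayes") 1L else 2L
        run <- if (m == "bayes") {
          run_bayes_opt(obj, space, n_iter, q, init_n,
                        seed = opt_seeds[k, col],
                        focus_control = focus_control)
        } else {
          run_random_opt(obj, space, n_iter, q, init_n,
                         seed = opt_seeds[k, col])
        }
        smp <- evaluate_params(obj, run$recommendation$z, n_evaluation,
                               seed = eval_seeds[k, col])
        res[[m]]$runs[[k]] <- run
        res[[m]]$samples[[k]] <- smp
      }
    }
    # comparison
    if (n_evaluation > 1L && n_runs >= 2L) {
      rep_b <- representative_run(res$bayes$runs)
      rep_r <- representative_run(res$random$runs)
      a <- res$bayes$samples[[rep_b]]
      b <- res$random$samples[[rep_r]]
      mode <- "representative"
      rep_ids <- c(bayes = rep_b, random = rep_r)
    } else {
      a <- vapply(res$bayes$samples, `[`, numeric(1), 1L)
      b <- vapply(res$random$samples, `[`, numeric(1), 1L)
      mode <- "all_runs"
      rep_ids <- NULL
    }
    ok_a <- !is.na(a); ok_b <- !is.na(b)
    out[[s$label]] <- list(
      scenario = as.list(s),
      mode = mode,
      representative = rep_ids,
      n_comparisons = sum(ok_a) * sum(ok_b),
      win_proportion_bayes = pairwise_win_proportion(a[ok_a], b[ok_b]),
      samples_bayes = a, samples_random = b,
      failures = c(bayes = sum(vapply(res$bayes$runs, `[[`, integer(1), "failures")),
                   random = sum(vapply(res$random$runs, `[[`, integer(1), "failures"))),
      cum_max_bayes = lapply(res$bayes$runs, cumulative_maxima),
      cum_max_random = lapply(res$random$runs, cumulative_maxima)
    )
  }
  structure(list(scenarios = out, seed = seed,
                 config = list(n_runs = n_runs, n_iter = n_iter, q = q,
                               n_evaluation = n_evaluation,
                               founder_spec = founder_spec)),
            class = "bo_report")
}

#' @export
print.bo_report <- function(x, ...) {
  cat("<bo_report> ", length(x$scenarios), " scenario(s)\n", sep = "")
  for (nm in names(x$scenarios)) {
    s <- x$scenarios[[nm]]
    cat(sprintf("  %s: BO win proportion %.2f%% over %d comparisons (%s)\n",
                nm, 100 * s$win_proportion_bayes, s$n_comparisons, s$mode))
  }
  invisible(x)
}
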