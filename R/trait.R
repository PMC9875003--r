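#' Sample the true genetic architecture of the trait
#'
#' Draws `n_qtn` quantitative trait nucleotides uniformly without
#' replacement among the genome's markers.  Each QTN effect is
#' `beta_m = a_m * I_m` with `a_m ~ Exp(rate = 1)` and `I_m = +1/-1`
#' equiprobably; all other marker effects are exactly 0.
#'
#' @param genome a [bo_genome()].
#' @param n_qtn number of causal markers (1 <= n_qtn <= n_snp).
#' @param seed integer seed; identical seeds give bit-identical effects.
#' @return object of class `bo_arch`: list with `beta` (length n_snp),
#'   `qtn_ids` (integer indices of non-zero effects) and `seed`.
#' @export
sample_qtn_effects <- function(genome, n_qtn, seed = 1L) {
  if (n_qtn < 1 || n_qtn > genome$n_snp) stop("n_qtn out of range")
  set.seed(seed)
  qtn <- sort(sample.int(genome$n_snp, n_qtn))
  a <- rexp(n_qtn, rate = 1)
  sgn <- ifelse(runif(n_qtn) < 0.5, 1, -1)
  beta <- numeric(genome$n_snp)
  beta[qtn] <- a * sgn
  structure(list(beta = beta, qtn_ids = qtn, seed = seed), class = "bo_arch")
}

#' True genotypic values of a population
#'
#' @param pop a [bo_pop()].
#' @param arch a [sample_qtn_effects()] architecture (marker order must
#'   match the population's genome).
#' @return numeric vector `G %*% beta`, named by individual id.
#' @export
genotypic_values <- function(pop, arch) {
  if (length(arch$beta) != pop$genome$n_snp) stop("marker/effect dimension mismatch")
  drop(dosage_matrix(pop) %*% arch$beta)
}

#' Residual variance for a target initial-population heritability
#'
#' `sigma_e2 = Var(G0 beta) * (1 / H0^2 - 1)` with `Var` the n-1 sample
#' variance over the founder genotypic values.  The result is computed once
#' on the initial population and then held fixed for the whole campaign, so
#' later-generation heritability floats with the genetic variance.
#'
#' @param founder_values numeric vector of founder genotypic values (>= 2).
#' @param target_H2 heritability in (0, 1).
#' @return residual variance (scalar).
#' @export
residual_variance <- function(founder_values, target_H2) {
  if (length(founder_values) < 2) stop("need at least two founder values")
  if (target_H2 <= 0 || target_H2 >= 1) stop("target_H2 must be in (0, 1)")
  v <- var(founder_values)
  if (v == 0) stop("zero genetic variance in the founders: degenerate architecture")
  v * (1 / target_H2 - 1)
}

#' Allocate phenotyping plots uniformly over individuals
#'
#' Every individual gets `floor(n_P / n_I)` plots; the `n_P %% n_I`
#' remaining plots go to individuals chosen uniformly at random without
#' replacement.
#'
#' @param n_I number of individuals (>= 1).
#' @param n_P number of plots (>= 0); `n_P = 0` yields all-zero counts.
#' @return integer vector of plot counts summing to `n_P`.
#' @export
allocate_plots <- function(n_I, n_P) {
  stopifnot(n_I >= 1, n_P >= 0)
  split_evenly(n_P, n_I)
}

#' Simulate replicated plot phenotypes
#'
#' `y_sr = G_s beta + e_sr`, with `e_sr` i.i.d. normal(0, sigma_e2).
#' No year/location or GxE effects are modelled.
#'
#' @param pop a [bo_pop()].
#' @param plot_counts integer vector aligned to the population (plots per
#'   individual); individuals with 0 plots produce no record.
#' @param arch trait architecture ([sample_qtn_effects()]).
#' @param sigma_e2 residual variance (>= 0).
#' @return data.frame with columns `id`, `generation`, `replicate`,
#'   `value`, one row per (individual, replicate).
#' @export
simulate_phenotypes <- function(pop, plot_counts, arch, sigma_e2) {
  stopifnot(length(plot_counts) == n_ind(pop))
  if (sigma_e2 < 0) stop("sigma_e2 must be non-negative")
  g <- genotypic_values(pop, arch)
  idx <- rep(seq_along(plot_counts), plot_counts)
  n <- length(idx)
  rep_idx <- unlist(lapply(plot_counts, seq_len))
  e <- if (n > 0) rnorm(n, 0, sqrt(sigma_e2)) else numeric(0)
  data.frame(
    id = pop$ids[idx],
    generation = pop$generation[idx],
    replicate = if (n > 0) rep_idx else integer(0),
    value = g[idx] + e,
    stringsAsFactors = FALSE
  )
}
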