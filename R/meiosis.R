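#' Sample a crossover plan for one chromosome
#'
#' The crossover count is Poisson with rate equal to the chromosome length
#' in Morgans; positions are i.i.d. uniform along the chromosome, sorted,
#' and returned with the sentinels 0 and `lambda_chr` attached.  No
#' interference is modelled, so recombination fractions follow the Haldane
#' map function.
#'
#' @param lambda_chr chromosome length in Morgans (> 0).
#' @return list with `n_co` (count) and `copos` (numeric vector
#'   `c(0, sorted positions, lambda_chr)`).
#' @export
sample_crossovers <- function(lambda_chr) {
  if (lambda_chr <= 0) stop("lambda_chr must be > 0")
  n_co <- rpois(1L, lambda_chr)
  pos <- if (n_co > 0) sort(runif(n_co, 0, lambda_chr)) else numeric(0)
  list(n_co = n_co, copos = c(0, pos, lambda_chr))
}

#' Apply a crossover plan to one chromosome's haplotype pair
#'
#' Marker `h` is copied from the starting strand while an even number of
#' crossovers lie at or before its position, and from the other strand
#' otherwise; a marker exactly on a crossover position belongs to the
#' segment that starts there (deterministic tie rule for the measure-zero
#' event).
#'
#' @param hap_pair 2 x m binary matrix (the parent's two homologues).
#' @param positions marker positions in Morgans (sorted, within
#'   `[0, lambda_chr]`).
#' @param plan a [sample_crossovers()] plan.
#' @param start_strand 1 or 2: which homologue the gamete starts on.
#' @return binary vector of length m.
#' @export
apply_crossover_plan <- function(hap_pair, positions, plan, start_strand) {
  stopifnot(nrow(hap_pair) == 2, start_strand %in% c(1L, 2L))
  lam <- plan$copos[length(plan$copos)]
  if (length(positions) &&
      (min(positions) < 0 || max(positions) > lam)) {
    stop("marker position outside [0, lambda_chr]")
  }
  interior <- plan$copos[-c(1L, length(plan$copos))]
  k <- findInterval(positions, interior)  # crossovers at or before marker
  strand <- (start_strand - 1L + k) %% 2L + 1L
  hap_pair[cbind(strand, seq_along(positions))]
}

#' Simulate one gamete of a parent
#'
#' Pure-R reference path: per chromosome, draws a crossover plan, picks the
#' starting strand equiprobably and applies the recombination rule.
#' Consumes the RNG stream in the same order as the compiled batch path
#' used by [cross()], so both give bit-identical gametes from the same
#' seed.
#'
#' @param pop a [bo_pop()].
#' @param ind individual id or row index.
#' @return binary integer vector of length `n_snp` (genome marker order).
#' @export
make_gamete <- function(pop, ind) {
  g <- pop$genome
  i <- if (is.character(ind)) match(ind, pop$ids) else as.integer(ind)
  if (is.na(i)) stop("unknown individual")
  out <- integer(g$n_snp)
  for (l in seq_len(nrow(g$chrom))) {
    lam <- g$chrom$length_m[l]
    plan <- sample_crossovers(lam)
    start <- if (runif(1) < 0.5) 1L else 2L
    if (g$chr_end[l] < g$chr_start[l]) next
    idx <- g$chr_start[l]:g$chr_end[l]
    hp <- rbind(pop$H1[i, idx], pop$H2[i, idx])
    out[idx] <- apply_crossover_plan(hp, g$markers$pos_m[idx], plan, start)
  }
  out
}

# Batch of gametes through the compiled path; parents is a vector of row
# indices, one gamete per entry.
sim_gametes <- function(pop, parents) {
  g <- pop$genome
  sim_gametes_cpp(pop$H1, pop$H2, as.integer(parents), g$markers$pos_m,
                  g$chr_start, g$chr_end, g$chrom$length_m)
}

#' Cross two parents
#'
#' Each offspring receives one independently simulated gamete from each
#' parent as its two haplotypes.  Selfing (`parent1 == parent2`) is
#' permitted.  All `parent1` gametes are drawn first, then all `parent2`
#' gametes (fixed RNG consumption order).
#'
#' @param pop a [bo_pop()] containing both parents.
#' @param parent1,parent2 individual ids (or row indices).
#' @param n_offspring number of offspring (>= 1).
#' @param ids optional offspring ids; default `<p1>x<p2>_k`.
#' @return a [bo_pop()] of the offspring, generation
#'   `max(parent generations) + 1`.
#' @export
cross <- function(pop, parent1, parent2, n_offspring, ids = NULL) {
  stopifnot(n_offspring >= 1)
  i1 <- if (is.character(parent1)) match(parent1, pop$ids) else as.integer(parent1)
  i2 <- if (is.character(parent2)) match(parent2, pop$ids) else as.integer(parent2)
  if (is.na(i1) || is.na(i2)) stop("unknown parent")
  G1 <- sim_gametes(pop, rep.int(i1, n_offspring))
  G2 <- sim_gametes(pop, rep.int(i2, n_offspring))
  if (is.null(ids)) {
    ids <- sprintf("%sx%s_%d", pop$ids[i1], pop$ids[i2], seq_len(n_offspring))
  }
  gen <- max(pop$generation[c(i1, i2)]) + 1L
  bo_pop(pop$genome, G1, G2, ids = ids, generation = gen,
         mother = pop$ids[i1], father = pop$ids[i2])
}

# Generate a whole offspring generation from a mating table and per-cross
# progeny counts.  Crosses with 0 progeny are skipped.
cross_table <- function(pop, mating, progeny) {
  stopifnot(nrow(mating) == length(progeny))
  keep <- progeny > 0
  if (!any(keep)) return(NULL)
  mating <- mating[keep, , drop = FALSE]
  progeny <- progeny[keep]
  mi <- match(mating$mother, pop$ids)
  fi <- match(mating$father, pop$ids)
  mothers <- rep(mi, progeny)
  fathers <- rep(fi, progeny)
  H1 <- sim_gametes(pop, mothers)
  H2 <- sim_gametes(pop, fathers)
  gen <- max(pop$generation[c(mi, fi)]) + 1L
  ids <- sprintf("G%d_%04d", gen, seq_along(mothers))
  bo_pop(pop$genome, H1, H2, ids = ids, generation = gen,
         mother = pop$ids[mothers], father = pop$ids[fathers])
}
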