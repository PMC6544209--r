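#' Draw a randomized founder population
#'
#' Every allele indicator is an independent Bernoulli(`f0`) draw: the founder
#' is maximally diverse standing variation, as in a randomized passage
#' experiment, with expected deleterious-allele frequency `f0` at every site.
#'
#' @param cfg A [sim_config()].
#' @return An `N x L` integer matrix of 0/1 allele indicators (1 = the
#'   deleterious allele) with attribute `generation = 0`.
#' @export
init_population <- function(cfg) {
  pop <- matrix(stats::rbinom(cfg$N * cfg$L, 1L, cfg$f0),
                nrow = cfg$N, ncol = cfg$L)
  attr(pop, "generation") <- 0L
  pop
}

#' Generation stamp of a population
#' @param pop A population matrix.
#' @return Integer generation, or `NA` if unstamped.
#' @export
population_generation <- function(pop) {
  g <- attr(pop, "generation", exact = TRUE)
  if (is.null(g)) NA_integer_ else g
}

#' Log fitness of genomes under additive selection plus pairwise epistasis
#'
#' Log fitness of a binary genome K is
#' \deqn{W = \sum_i s_i K_i + \sum_{i<j} S_{ij} K_i K_j,\qquad
#'       S_{ij} = E_{ij}(|s_i| + |s_j|) T_{ij},}
#' with the sign convention \eqn{s_i = -|s_i|}: every deleterious allele
#' (K = 1) costs its magnitude, and an interacting pair that is doubly
#' mutant gets back the fraction `E` of the summed costs (antagonistic,
#' i.e. partially compensatory, epistasis).  Fitness — the expected progeny
#' number — is `exp(W)`, so `E = 1` restores the doubly-mutant pair to
#' wild-type fitness.
#'
#' @param pop An `N x L` 0/1 matrix, or a single genome vector of length L.
#' @param selection Per-site magnitudes `|s_i|`
#'   (from [draw_selection_coefficients()]).
#' @param topology An [epistatic_topology()].
#' @return Numeric vector of log fitnesses (one per genome).
#' @export
log_fitness <- function(pop, selection, topology) {
  if (is.vector(pop)) pop <- matrix(pop, nrow = 1L)
  if (ncol(pop) != length(selection)) {
    stop("genome length and selection vector length differ")
  }
  W <- -as.vector(pop %*% selection)
  if (nrow(topology) > 0L) {
    i <- topology$site_i
    j <- topology$site_j
    S <- topology$E * (selection[i] + selection[j])
    W <- W + as.vector((pop[, i, drop = FALSE] * pop[, j, drop = FALSE]) %*% S)
  }
  W
}

#' Wright-Fisher reproduction with selection
#'
#' The next generation is N multinomial draws from the current individuals
#' with probabilities proportional to their fitness `exp(W)`.  This exact
#' multinomial resampling keeps the population size constant at N by
#' construction (the "broken-stick" normalization of offspring numbers).
#'
#' @inheritParams log_fitness
#' @return The offspring population, same shape, generation stamp unchanged.
#' @export
reproduce <- function(pop, selection, topology) {
  W <- log_fitness(pop, selection, topology)
  if (any(!is.finite(W))) stop("non-finite log fitness")
  w <- exp(W - max(W))           # rescaling cancels in the multinomial
  idx <- sample.int(nrow(pop), nrow(pop), replace = TRUE, prob = w)
  out <- pop[idx, , drop = FALSE]
  attr(out, "generation") <- attr(pop, "generation", exact = TRUE)
  out
}

#' Symmetric per-site mutation
#'
#' Each allele indicator flips (0 <-> 1) independently with probability `mu`.
#' Implemented by drawing the Binomial(N*L, mu) number of flips and placing
#' them uniformly without replacement — exactly equivalent to N*L independent
#' Bernoulli trials, but O(flips) instead of O(N*L) for small `mu`.
#'
#' @param pop Population matrix.
#' @param mu Per-site flip probability in `[0, 1]`.
#' @return Mutated population, same shape and generation stamp.
#' @export
mutate_alleles <- function(pop, mu) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (mu == 0) return(pop)
  n_cells <- length(pop)
  n_flip <- stats::rbinom(1L, n_cells, mu)
  if (n_flip > 0L) {
    pos <- sample.int(n_cells, n_flip)
    pop[pos] <- 1L - pop[pos]
  }
  pop
}

#' Outcrossing with Poisson-distributed crossovers
#'
#' Each individual independently outcrosses with probability `outcross_prob`
#' (= r): a partner is drawn uniformly from the (pre-recombination)
#' population, `Poisson(crossover_mean)` crossover points (capped at L - 1)
#' are placed uniformly without replacement among the L - 1 junctions, and
#' the focal individual is replaced by the alternating-segment recombinant
#' that starts with its own leftmost segment.  Only the focal row changes,
#' so the population size is untouched and the expected per-site allele
#' frequency is conserved.
#'
#' @param pop Population matrix.
#' @param outcross_prob Outcrossing probability r per genome per generation.
#' @param crossover_mean Mean number of crossovers M per outcrossing event.
#' @return Recombined population, same shape and generation stamp.
#' @export
recombine <- function(pop, outcross_prob, crossover_mean) {
  if (outcross_prob < 0 || outcross_prob > 1) stop("outcross_prob must lie in [0, 1]")
  if (crossover_mean < 0) stop("crossover_mean must be >= 0")
  if (outcross_prob == 0) return(pop)
  N <- nrow(pop)
  L <- ncol(pop)
  focal <- which(stats::runif(N) < outcross_prob)
  if (length(focal) == 0L) return(pop)
  partners <- sample.int(N, length(focal), replace = TRUE)
  n_cross <- pmin(stats::rpois(length(focal), crossover_mean), L - 1L)
  out <- pop
  for (k in seq_along(focal)) {
    if (n_cross[k] == 0L) next
    cuts <- sort(sample.int(L - 1L, n_cross[k]))
    # segment parity: 0 = focal, 1 = partner, alternating at each cut
    seg <- cumsum(c(0L, tabulate(cuts, L - 1L))) %% 2L
    take <- seg == 1L
    out[focal[k], take] <- pop[partners[k], take]
  }
  out
}

#' One Wright-Fisher generation
#'
#' Applies, in order, selection-weighted reproduction, mutation, and
#' recombination, then increments the generation stamp.  The within-
#' generation order is a model convention (the events commute up to O(mu, r)
#' per generation); it is fixed here and documented rather than configurable.
#'
#' @param pop Population matrix.
#' @param cfg A [sim_config()] (mutation and recombination parameters).
#' @param selection Per-site magnitudes `|s_i|`.
#' @param topology An [epistatic_topology()].
#' @return The next generation's population.
#' @export
wf_step <- function(pop, cfg, selection, topology) {
  g <- attr(pop, "generation", exact = TRUE)
  pop <- reproduce(pop, selection, topology)
  pop <- mutate_alleles(pop, cfg$mu)
  pop <- recombine(pop, cfg$outcross_prob, cfg$crossover_mean)
  attr(pop, "generation") <- (if (is.null(g)) 0L else g) + 1L
  pop
}

#' Run a full simulation
#'
#' Evolves a population for `cfg$n_generations` generations, snapshotting
#' per-pair haplotype counts (for all `choose(L, 2)` pairs) at each recorded
#' time.  Deterministic given `cfg$seed`: the master seed fixes the founder,
#' the selection coefficients, any per-pair epistatic strengths, and the
#' evolutionary randomness.
#'
#' @param cfg A [sim_config()].
#' @param founder Optional founder population (an `N x L` 0/1 matrix); when
#'   given it is used instead of drawing one, so several runs can share
#'   standing variation while evolving independently.
#' @param selection Optional pre-drawn selection magnitudes (shared across
#'   replicate runs).
#' @param keep_populations If TRUE, full population snapshots are stored at
#'   each recorded time (memory: `N * L` integers per snapshot).
#' @return A list of class `"simulation_record"` with elements `config`,
#'   `selection`, `topology`, `times`, `counts` (per time, a
#'   `choose(L, 2) x 4` haplotype count matrix, see [all_pair_counts()]),
#'   and optionally `populations`.
#' @export
run_simulation <- function(cfg, founder = NULL, selection = NULL,
                           keep_populations = FALSE) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  topology <- resolve_topology(cfg)
  if (is.null(selection)) selection <- draw_selection_coefficients(cfg)
  pop <- if (is.null(founder)) init_population(cfg) else {
    stopifnot(nrow(founder) == cfg$N, ncol(founder) == cfg$L)
    founder
  }
  attr(pop, "generation") <- 0L

  times <- cfg$record_times
  counts <- vector("list", length(times))
  names(counts) <- as.character(times)
  pops <- if (keep_populations) counts else NULL

  snap <- function(t, pop) {
    k <- match(t, times)
    if (!is.na(k)) {
      counts[[k]] <<- all_pair_counts(pop)
      if (keep_populations) pops[[k]] <<- pop
    }
  }
  snap(0L, pop)
  if (cfg$n_generations > 0L) {
    for (t in seq_len(cfg$n_generations)) {
      pop <- wf_step(pop, cfg, selection, topology)
      snap(t, pop)
    }
  }
  structure(list(config = cfg, selection = selection, topology = topology,
                 times = times, counts = counts, populations = pops,
                 final_population = pop),
            class = "simulation_record")
}

#' Deterministic two-locus selection trajectory
#'
#' Infinite-population, mutation-free dynamics of one isolated epistatic
#' pair: the four haplotype frequencies grow or shrink exponentially with
#' their log fitnesses and are renormalized each instant,
#' \deqn{f_{ab}(t) \propto f_{ab}(0)\, e^{W_{ab} t}}
#' with `W00 = 0`, `W10 = -|s_i|`, `W01 = -|s_j|`, and
#' `W11 = -(1 - E)(|s_i| + |s_j|)`.  This is the analytic oracle behind the
#' interpretation of the UFE statistic: on these (ensemble-mean) frequencies
#' the initial-condition terms cancel whenever the start is symmetric, and
#' UFE equals the epistatic strength `E` at every positive time.
#'
#' @param s_i,s_j Selection magnitudes `|s|` of the two loci.
#' @param E Epistatic strength in `[0, 1]`.
#' @param t Time in generations (may be a vector).
#' @param init Initial haplotype frequencies `c(f00, f01, f10, f11)`,
#'   summing to 1.  Default: the symmetric start `rep(1/4, 4)`.
#' @return For scalar `t`, a [haplotype_freqs()] object; for vector `t`, a
#'   data frame with columns `t`, `f00`, `f01`, `f10`, `f11`.
#' @export
deterministic_two_locus <- function(s_i, s_j, E, t,
                                    init = c(0.25, 0.25, 0.25, 0.25)) {
  if (length(init) != 4L || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    stop("init must be 4 non-negative frequencies summing to 1")
  }
  W <- c(0, -s_j, -s_i, -(1 - E) * (s_i + s_j))   # order f00, f01, f10, f11
  one <- function(tt) {
    f <- init * exp(W * tt)
    f / sum(f)
  }
  if (length(t) == 1L) {
    f <- one(t)
    haplotype_freqs(f[1], f[2], f[3], f[4])
  } else {
    out <- t(vapply(t, one, numeric(4)))
    data.frame(t = t, f00 = out[, 1], f01 = out[, 2],
               f10 = out[, 3], f11 = out[, 4])
  }
}
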