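#' Epistatic interaction topology
#'
#' An interaction topology is a set of unordered, *disjoint* site pairs, each
#' carrying an epistatic strength `E` in `[0, 1]`.  Disjointness ("isolated
#' pairs": no site interacts with more than one partner) is enforced because
#' all downstream interpretation of the UFE statistic as the compensation
#' strength of a pair relies on it.
#'
#' @param site_i,site_j Integer vectors of 1-based site indices; each
#'   `(site_i[k], site_j[k])` is one interacting pair.
#' @param E Epistatic strength per pair, recycled to the number of pairs.
#'   `E = 0` is no compensation, `E = 1` full mutual compensation of the two
#'   deleterious alleles.
#' @return A data frame of class `"epistatic_topology"` with columns
#'   `site_i`, `site_j`, `E` (pairs stored with `site_i < site_j`).
#' @seealso [neighbor_topology()] for the default nearest-neighbour pairing.
#' @export
epistatic_topology <- function(site_i, site_j, E) {
  if (length(site_i) != length(site_j)) {
    stop("site_i and site_j must have the same length")
  }
  site_i <- as.integer(site_i)
  site_j <- as.integer(site_j)
  if (any(site_i == site_j)) stop("a site cannot interact with itself")
  lo <- pmin(site_i, site_j)
  hi <- pmax(site_i, site_j)
  E <- rep_len(as.numeric(E), length(lo))
  if (any(E < 0 | E > 1)) stop("epistatic strength E must lie in [0, 1]")
  sites <- c(lo, hi)
  if (anyDuplicated(sites)) {
    stop("epistatic pairs must be disjoint: no site may appear in more than one pair")
  }
  out <- data.frame(site_i = lo, site_j = hi, E = E)
  class(out) <- c("epistatic_topology", "data.frame")
  out
}

#' Nearest-neighbour pairing of an even-length genome
#'
#' The default topology: each odd site interacts with its right neighbour,
#' i.e. pairs (1,2), (3,4), ..., (L-1, L).
#'
#' @param L Genome length (sites).  Only `floor(L / 2)` pairs are formed, so
#'   an odd trailing site is left non-interacting.
#' @param E Epistatic strength, a scalar applied to every pair or a vector of
#'   length `floor(L / 2)`.
#' @inherit epistatic_topology return
#' @export
neighbor_topology <- function(L, E = 0.75) {
  L <- as.integer(L)
  if (L < 2L) stop("need L >= 2 to form at least one pair")
  i <- seq.int(1L, 2L * (L %/% 2L), by = 2L)
  epistatic_topology(i, i + 1L, E)
}

#' Simulation configuration
#'
#' Collects every parameter of the Wright-Fisher model in one validated
#' object.  Defaults reproduce the reference condition used throughout the
#' package: `N = 2e4` genomes of `L = 50` sites, genome-wide mutation rate
#' `muL = 0.07` (per-site `mu = muL / L = 1.4e-3`), constant selection
#' magnitude `s0 = 0.1`, nearest-neighbour epistatic pairs of strength
#' `E = 0.75`, initial deleterious-allele frequency `f0 = 0.4`, no
#' recombination, and snapshots at generations 1, 5, 10, 25 and 50.
#'
#' @param N Population size (number of haploid genomes), `>= 2`.
#' @param L Genome length in sites, `>= 2`.
#' @param mu Per-site, per-generation mutation (flip) probability.  Exactly
#'   one of `mu` and `muL` may be given; the default is via `muL`.
#' @param muL Genome-wide mutation rate; translated to `mu = muL / L`.
#' @param s0 Mean selection magnitude per deleterious allele (positive as
#'   quoted; the deleterious allele contributes `-|s|` to log fitness).
#' @param s_mode `"constant"` (every site has magnitude `s0`) or
#'   `"half_gaussian"` (magnitudes drawn from a half-normal with mean `s0`).
#' @param E Epistatic strength in `[0, 1]` used when `topology` is NULL;
#'   ignored otherwise.
#' @param E_mode `"constant"` or `"uniform"`; with `"uniform"` each pair's
#'   strength is drawn uniformly on `[0, 1]` when the simulation starts.
#' @param topology An [epistatic_topology()], or NULL for the default
#'   nearest-neighbour pairing of strength `E`.
#' @param f0 Initial deleterious-allele frequency in `[0, 1]`.
#' @param outcross_prob Per-genome, per-generation probability of outcrossing
#'   with a random partner (recombination rate `r`).
#' @param crossover_mean Mean number of crossovers per outcrossing event
#'   (Poisson parameter `M`).
#' @param n_generations Number of generations to evolve.
#' @param record_times Generations at which to snapshot (subset of
#'   `0:n_generations`; 0 is the founder).
#' @param seed Master random seed; every stochastic stage derives its stream
#'   from it, so equal seeds give bit-identical runs.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(N = 20000, L = 50, mu = NULL, muL = 0.07,
                       s0 = 0.1, s_mode = c("constant", "half_gaussian"),
                       E = 0.75, E_mode = c("constant", "uniform"),
                       topology = NULL, f0 = 0.4,
                       outcross_prob = 0, crossover_mean = 0,
                       n_generations = 50,
                       record_times = c(1, 5, 10, 25, 50),
                       seed = 1L) {
  s_mode <- match.arg(s_mode)
  E_mode <- match.arg(E_mode)
  if (is.null(mu)) {
    mu <- muL / L
  } else if (!missing(muL) && !is.null(muL)) {
    stop("give either mu or muL, not both")
  }
  cfg <- list(N = as.integer(N), L = as.integer(L), mu = as.numeric(mu),
              s0 = as.numeric(s0), s_mode = s_mode,
              E = as.numeric(E), E_mode = E_mode, topology = topology,
              f0 = as.numeric(f0),
              outcross_prob = as.numeric(outcross_prob),
              crossover_mean = as.numeric(crossover_mean),
              n_generations = as.integer(n_generations),
              record_times = as.integer(sort(unique(record_times))),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every invariant of [sim_config()] and returns the config invisibly;
#' stops with a field-precise message on the first violation.
#'
#' @param cfg A `"sim_config"` object (or bare list with the same fields).
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(cfg$N >= 2L, "N: population size must be >= 2")
  chk(cfg$L >= 2L, "L: genome length must be >= 2")
  chk(is.finite(cfg$mu) && cfg$mu >= 0 && cfg$mu <= 1,
      "mu: per-site mutation probability must lie in [0, 1]")
  chk(is.finite(cfg$s0) && cfg$s0 >= 0, "s0: selection magnitude must be >= 0")
  chk(cfg$E >= 0 && cfg$E <= 1, "E: epistatic strength must lie in [0, 1]")
  chk(cfg$f0 >= 0 && cfg$f0 <= 1, "f0: initial allele frequency must lie in [0, 1]")
  chk(cfg$outcross_prob >= 0 && cfg$outcross_prob <= 1,
      "outcross_prob: probability must lie in [0, 1]")
  chk(cfg$crossover_mean >= 0, "crossover_mean: must be >= 0")
  chk(cfg$n_generations >= 0L, "n_generations: must be >= 0")
  chk(all(cfg$record_times >= 0L & cfg$record_times <= cfg$n_generations),
      "record_times: must lie in [0, n_generations]")
  if (!is.null(cfg$topology)) {
    chk(inherits(cfg$topology, "epistatic_topology"),
        "topology: must be an epistatic_topology")
    chk(all(cfg$topology$site_j <= cfg$L),
        "topology: pair indices must not exceed L")
  }
  invisible(cfg)
}

# Resolve the topology actually used by a run: explicit topology wins;
# otherwise nearest-neighbour pairs with strength E (possibly drawn
# uniformly per pair when E_mode == "uniform"; the draw consumes the
# caller's RNG stream).
resolve_topology <- function(cfg) {
  if (!is.null(cfg$topology)) return(cfg$topology)
  n_pairs <- cfg$L %/% 2L
  E <- if (identical(cfg$E_mode, "uniform")) stats::runif(n_pairs) else cfg$E
  neighbor_topology(cfg$L, E)
}

#' Draw per-site selection magnitudes
#'
#' In `"constant"` mode every site gets magnitude `s0`.  In
#' `"half_gaussian"` mode magnitudes are `|Normal(0, sigma)|` with
#' `sigma = s0 * sqrt(pi / 2)`, so that the half-normal mean equals `s0`
#' (the quoted `s0` is always the *average* magnitude).
#'
#' @param cfg A [sim_config()] (fields `L`, `s0`, `s_mode` are used).
#' @return Numeric vector of length `L` of non-negative magnitudes `|s_i|`.
#'   The deleterious allele at site i contributes `-|s_i|` to log fitness.
#' @export
draw_selection_coefficients <- function(cfg) {
  if (cfg$s0 < 0) stop("s0 must be >= 0")
  switch(cfg$s_mode,
    constant = rep(cfg$s0, cfg$L),
    half_gaussian = abs(stats::rnorm(cfg$L, 0, cfg$s0 * sqrt(pi / 2)))
  )
}

#' Derive child seeds from a master seed
#'
#' Deterministically expands one master seed into `n` independent child
#' seeds (for replicate runs or pipeline stages) without touching the
#' caller's RNG state.
#'
#' @param master Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_child_seeds <- function(master, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}
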