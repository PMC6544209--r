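test_that("selection coefficients follow the requested mode", {
  cfg <- sim_config(L = 50, s0 = 0.1, s_mode = "constant")
  expect_equal(draw_selection_coefficients(cfg), rep(0.1, 50))

  cfg0 <- sim_config(L = 20, s0 = 0)
  expect_equal(draw_selection_coefficients(cfg0), rep(0, 20))

  # half-Gaussian scaled so the mean magnitude equals s0
  set.seed(11)
  cfg_h <- sim_config(L = 1e5, s0 = 0.1, s_mode = "half_gaussian")
  draws <- draw_selection_coefficients(cfg_h)
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), 0.1, tolerance = 0.01)

  expect_error(sim_config(s0 = -0.1), "s0")
})

test_that("founder population is Bernoulli(f0) standing variation", {
  set.seed(1)
  expect_true(all(init_population(sim_config(N = 50, L = 8, f0 = 0)) == 0L))
  expect_true(all(init_population(sim_config(N = 50, L = 8, f0 = 1)) == 1L))

  cfg <- sim_config(N = 20000, L = 50, f0 = 0.4)
  pop <- init_population(cfg)
  se <- sqrt(0.4 * 0.6 / (cfg$N * cfg$L))
  expect_lt(abs(mean(pop) - 0.4), 3 * se)
  expect_identical(population_generation(pop), 0L)
})

test_that("log fitness implements additive costs with pairwise compensation", {
  top <- neighbor_topology(4, E = 0.75)
  smag <- rep(0.1, 4)
  expect_equal(log_fitness(c(0, 0, 0, 0), smag, top), 0)
  expect_equal(log_fitness(c(1, 0, 0, 0), smag, top), -0.1)
  # both partners mutant: costs partially refunded by E * (|si| + |sj|)
  expect_equal(log_fitness(c(1, 1, 0, 0), smag, top), -0.2 + 0.75 * 0.2)
  top_full <- neighbor_topology(4, E = 1)
  expect_equal(log_fitness(c(1, 1, 0, 0), smag, top_full), 0)
  expect_error(log_fitness(c(1, 0), smag, top), "length")
})

test_that("reproduction is selection-weighted multinomial resampling at constant N", {
  top <- epistatic_topology(integer(), integer(), numeric())
  pop <- matrix(rep(c(0L, 1L), each = 50 * 4), nrow = 100, ncol = 4,
                byrow = TRUE)
  # identical genomes: offspring identical
  mono <- matrix(1L, 30, 4)
  out <- reproduce(mono, rep(0.1, 4), top)
  expect_identical(dim(out), dim(mono))
  expect_true(all(out == 1L))

  # 50 genomes at W = 0 (all-zero) vs 50 at W = -0.1; expected count of the
  # fitter (all-zero) type is 100 * 50 / (50 + 50 * exp(-0.1)) ~ 52.50
  set.seed(5)
  smag <- c(0.1, 0, 0, 0)
  pop2 <- rbind(matrix(0L, 50, 4),
                cbind(rep(1L, 50), matrix(0L, 50, 3)))
  n_rep <- 1e4
  counts <- replicate(n_rep, sum(rowSums(reproduce(pop2, smag, top)) == 0))
  expected <- 100 * 50 / (50 + 50 * exp(-0.1))
  se <- stats::sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("mutation flips each allele independently with probability mu", {
  pop <- matrix(rbinom(200, 1L, 0.5), 20, 10)
  expect_identical(mutate_alleles(pop, 0), pop)
  expect_identical(mutate_alleles(pop, 1), 1L - pop)

  set.seed(3)
  cfg <- sim_config(N = 20000, L = 50)   # mu = muL / L = 1.4e-3
  expect_equal(cfg$mu, 1.4e-3)
  big <- matrix(0L, cfg$N, cfg$L)
  flips <- replicate(20, sum(mutate_alleles(big, cfg$mu)))
  expected <- cfg$N * cfg$L * cfg$mu     # 1400 per generation
  se <- stats::sd(flips) / sqrt(length(flips))
  expect_lt(abs(mean(flips) - expected), 3 * se)
})

test_that("recombination preserves size and allele frequencies", {
  set.seed(9)
  pop <- matrix(rbinom(2000 * 20, 1L, 0.5), 2000, 20)
  expect_identical(recombine(pop, 0, 5), pop)

  # identical parents: recombinants are identical to the parents
  clone <- matrix(rep(c(0L, 1L), 10), 50, 20, byrow = TRUE)
  expect_identical(recombine(clone, 1, 5), clone)

  # frequency conservation: outcrossing only reshuffles segments
  deltas <- replicate(20, {
    out <- recombine(pop, 0.2, 5)
    colMeans(out) - colMeans(pop)
  })
  expect_lt(abs(mean(deltas)), 3 * stats::sd(deltas) / sqrt(length(deltas)))
  expect_lt(max(abs(deltas)), 0.06)
})

test_that("a Wright-Fisher step conserves N and is neutral-unbiased", {
  cfg <- fast_cfg(s0 = 0, E = 0)
  top <- resolve_topology(cfg)
  smag <- draw_selection_coefficients(cfg)
  set.seed(2)
  pop <- init_population(cfg)
  one_genotype <- matrix(rep(pop[1, ], each = cfg$N), cfg$N, cfg$L)
  cfg_frozen <- fast_cfg(s0 = 0, E = 0, muL = 0)
  stepped <- wf_step(one_genotype, cfg_frozen, smag, top)
  expect_true(all(stepped == one_genotype))
  expect_identical(nrow(stepped), cfg$N)

  # drift is unbiased: mean frequency change over replicate steps is 0
  set.seed(4)
  d <- replicate(1000, {
    p <- matrix(rbinom(cfg$N * cfg$L, 1L, 0.4), cfg$N, cfg$L)
    mean(wf_step(p, cfg, smag, top)) - mean(p)
  })
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("run_simulation snapshots, conserves N, and is seed-reproducible", {
  cfg <- fast_cfg()
  cfg0 <- fast_cfg()
  cfg0$n_generations <- 0L
  cfg0$record_times <- 0L
  rec0 <- run_simulation(cfg0)
  expect_identical(names(rec0$counts), "0")

  rec_a <- run_simulation(cfg, keep_populations = TRUE)
  rec_b <- run_simulation(cfg, keep_populations = TRUE)
  expect_identical(rec_a$counts, rec_b$counts)
  expect_identical(rec_a$populations, rec_b$populations)
  for (cnt in rec_a$counts) expect_true(all(rowSums(cnt) == cfg$N))

  # negative selection: mean deleterious frequency decreases over the run
  cfg_sel <- sim_config(N = 2000, L = 20, n_generations = 50,
                        record_times = c(0, 50), seed = 8)
  rec <- run_simulation(cfg_sel, keep_populations = TRUE)
  expect_lt(mean(rec$populations[["50"]]), mean(rec$populations[["0"]]))
})

test_that("selection-only site trajectories follow the logistic decay oracle", {
  # mu = 0, E = 0, r = 0: the ensemble-mean frequency of each site follows
  # f(t) = f0 e^{-s t} / (f0 e^{-s t} + 1 - f0); at s = 0.1, f0 = 0.4,
  # t = 10 the oracle gives ~0.1970.
  expect_equal(logistic_decay(0.4, 0.1, 10), 0.19696, tolerance = 1e-4)
  cfg <- sim_config(N = 20000, L = 50, muL = 0, s0 = 0.1, E = 0, f0 = 0.4,
                    n_generations = 10, record_times = 10, seed = 1)
  runs <- vapply(1:8, function(k) {
    cfg$seed <- k
    rec <- run_simulation(cfg, keep_populations = TRUE)
    mean(rec$populations[["10"]])
  }, numeric(1))
  se <- stats::sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - logistic_decay(0.4, 0.1, 10)), 3 * se + 1e-4)
})

test_that("deterministic two-locus trajectory reproduces the UFE identity", {
  init <- c(0.1, 0.2, 0.3, 0.4)
  f0 <- deterministic_two_locus(0.1, 0.1, 0.75, t = 0, init = init)
  expect_equal(as_cells <- unlist(f0[c("f00", "f01", "f10", "f11")]),
               c(f00 = 0.1, f01 = 0.2, f10 = 0.3, f11 = 0.4))

  # full compensation: W11 = W00, so f11/f00 stays constant
  tr <- deterministic_two_locus(0.1, 0.2, 1, t = c(0, 5, 20))
  expect_equal(tr$f11 / tr$f00, rep(1, 3))

  # symmetric start, E = 0.75: UFE equals E exactly at every t > 0
  for (t in c(1, 10, 100)) {
    f <- deterministic_two_locus(0.1, 0.1, 0.75, t = t)
    expect_equal(ufe_statistic(f), 0.75, tolerance = 1e-12)
  }
  expect_error(deterministic_two_locus(0.1, 0.1, 0.5, t = 1,
                                       init = c(0.5, 0.5, 0.5, 0.5)), "sum")
})

test_that("epistatic-pair ensemble means recover E through UFE", {
  # mu = 0, r = 0, f0 = 0.5: ensemble-averaged haplotype frequencies of an
  # isolated pair approach the deterministic trajectory, where UFE = E.
  cfg <- sim_config(N = 20000, L = 10, muL = 0, s0 = 0.1, E = 0.75,
                    f0 = 0.5, n_generations = 5, record_times = 5, seed = 1)
  cells <- Reduce(`+`, lapply(1:10, function(k) {
    cfg$seed <- k
    rec <- run_simulation(cfg)
    cnt <- rec$counts[["5"]]
    pair1 <- which(attr(cnt, "site_i") == 1 & attr(cnt, "site_j") == 2)
    cnt[pair1, ] / sum(cnt[pair1, ])
  })) / 10
  ufe <- ufe_statistic(haplotype_freqs(cells[1], cells[2], cells[3],
                                       cells[4]))
  expect_equal(ufe, 0.75, tolerance = 0.1)
})
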