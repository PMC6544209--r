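#' Evolve independent replicate populations
#'
#' Runs `R` simulations that share every parameter and the per-site
#' selection magnitudes but evolve with independent randomness (child seeds
#' derived deterministically from the master seed).  The founder policy
#' controls the standing variation: `"shared_founder"` (default) evolves all
#' replicates from one common randomized founder, `"independent_founders"`
#' redraws the founder per replicate.
#'
#' @param cfg A [sim_config()]; `cfg$seed` is the master seed.
#' @param R Number of replicate populations, `>= 1`.
#' @param founder_policy `"shared_founder"` or `"independent_founders"`.
#' @param keep_populations Keep full population snapshots per replicate.
#' @return A list of class `"replicate_set"`: `config`, `R`,
#'   `founder_policy`, `child_seeds`, and `records` (list of
#'   `"simulation_record"`s).
#' @export
run_replicates <- function(cfg, R, founder_policy = c("shared_founder",
                                                      "independent_founders"),
                           keep_populations = FALSE) {
  founder_policy <- match.arg(founder_policy)
  if (R < 1L) stop("R must be >= 1")
  validate_sim_config(cfg)
  seeds <- derive_child_seeds(cfg$seed, R + 1L)
  set.seed(seeds[1L])                  # founder / selection stream
  topology <- resolve_topology(cfg)
  selection <- draw_selection_coefficients(cfg)
  founder <- if (founder_policy == "shared_founder") init_population(cfg)
             else NULL
  records <- vector("list", R)
  for (k in seq_len(R)) {
    cfg_k <- cfg
    cfg_k$seed <- seeds[k + 1L]
    cfg_k$topology <- topology         # freeze any uniform-E draw
    records[[k]] <- run_simulation(cfg_k, founder = founder,
                                   selection = selection,
                                   keep_populations = keep_populations)
  }
  structure(list(config = cfg, R = as.integer(R),
                 founder_policy = founder_policy,
                 child_seeds = seeds[-1L], topology = topology,
                 selection = selection, records = records),
            class = "replicate_set")
}

# Replicate-averaged cell frequencies for all pairs at one recorded time.
# Per-replicate counts get the pseudocount, are normalized, then averaged
# arithmetically cell by cell (populations have equal size, so the average
# is unweighted); the result sums to 1 per pair by construction.
averaged_cells <- function(rs, time, pseudocount = 0.5, use = NULL) {
  use <- if (is.null(use)) seq_len(rs$R) else use
  k <- match(time, rs$records[[1L]]$times)
  if (is.na(k)) stop("time ", time, " is not a recorded time")
  mats <- lapply(rs$records[use], function(rec) {
    cells <- rec$counts[[k]] + pseudocount
    cells / rowSums(cells)
  })
  avg <- Reduce(`+`, mats) / length(mats)
  attr(avg, "site_i") <- attr(rs$records[[use[1L]]]$counts[[k]], "site_i")
  attr(avg, "site_j") <- attr(rs$records[[use[1L]]]$counts[[k]], "site_j")
  avg
}

#' Cross-population average of one pair's haplotype frequencies
#'
#' Arithmetic mean of the four haplotype cell frequencies across replicate
#' populations for a single locus pair, the operation that filters out
#' stochastic linkage: founder-divergence LD has random sign across
#' independent populations and cancels in the mean, while the epistatic
#' contribution has fixed sign and survives.
#'
#' @param rs A [run_replicates()] result.
#' @param pair Integer pair `c(i, j)` of 1-based sites, `i < j`.
#' @param time A recorded generation.
#' @param pseudocount Applied per replicate before normalization (default 0:
#'   raw frequencies).
#' @return A [haplotype_freqs()] object.
#' @export
average_freqs <- function(rs, pair, time, pseudocount = 0) {
  avg <- averaged_cells(rs, time, pseudocount = pseudocount)
  hit <- which(attr(avg, "site_i") == pair[1L] &
               attr(avg, "site_j") == pair[2L])
  if (length(hit) != 1L) stop("pair not found; need i < j within 1..L")
  haplotype_freqs(avg[hit, 1L], avg[hit, 2L], avg[hit, 3L], avg[hit, 4L])
}

#' LD panel on replicate-averaged frequencies
#'
#' Computes the six-statistic panel after averaging haplotype frequencies
#' across replicates (see [average_freqs()]) for every locus pair.
#'
#' @inheritParams average_freqs
#' @param use Optional subset of replicate indices to average over (e.g. the
#'   first R of a larger set).
#' @param epsilon Singularity guard for UFE.
#' @return A panel data frame as from [compute_panel()].
#' @export
averaged_panel <- function(rs, time, pseudocount = 0.5, epsilon = 1e-6,
                           use = NULL) {
  avg <- averaged_cells(rs, time, pseudocount = pseudocount, use = use)
  site_i <- attr(avg, "site_i")
  site_j <- attr(avg, "site_j")
  stats <- ld_stats_from_cells(avg[, 1L], avg[, 2L], avg[, 3L], avg[, 4L],
                               epsilon)
  key <- paste(site_i, site_j)
  epi_key <- paste(rs$topology$site_i, rs$topology$site_j)
  out <- cbind(data.frame(time = time, site_i = site_i, site_j = site_j),
               stats, data.frame(is_epistatic = key %in% epi_key))
  rownames(out) <- NULL
  out
}

#' Detection timecourse on replicate-averaged frequencies
#'
#' At each recorded time, haplotype frequencies are averaged across the
#' replicate populations, the panel is computed once on the averaged
#' frequencies, and the detector is applied once — the multi-population
#' protocol.  `mode = "detect_then_average"` gives the contrasting
#' single-population protocol (per-run detection, reports averaged), which
#' coincides with this one at `R = 1`.
#'
#' @param rs A [run_replicates()] result.
#' @param measure Panel statistic to threshold.
#' @param config A [detection_config()].
#' @param mode `"average_then_detect"` (default) or `"detect_then_average"`.
#' @param pseudocount,epsilon Passed to the panel computation.
#' @param use Optional subset of replicate indices.
#' @return Data frame: `time`, `threshold`, `detection_pct`, `fpos_pct`,
#'   `fdr_pct`, `objective`, `n_runs`.
#' @export
averaged_detection_timecourse <- function(rs, measure = "UFE",
                                          config = detection_config(),
                                          mode = c("average_then_detect",
                                                   "detect_then_average"),
                                          pseudocount = 0.5, epsilon = 1e-6,
                                          use = NULL) {
  mode <- match.arg(mode)
  if (mode == "detect_then_average") {
    recs <- if (is.null(use)) rs$records else rs$records[use]
    return(detection_timecourse(recs, measure = measure, config = config,
                                pseudocount = pseudocount,
                                epsilon = epsilon))
  }
  times <- rs$records[[1L]]$times
  out <- do.call(rbind, lapply(times, function(t) {
    panel <- averaged_panel(rs, t, pseudocount = pseudocount,
                            epsilon = epsilon, use = use)
    rep <- optimize_threshold(panel[[measure]], panel$is_epistatic, config,
                              time = t)
    rep[, c("time", "threshold", "detection_pct", "fpos_pct", "fdr_pct",
            "objective")]
  }))
  out$n_runs <- if (is.null(use)) rs$R else length(use)
  rownames(out) <- NULL
  out
}

#' Detection map over replicate number and time
#'
#' For each combination of replicate count R (subset of one simulated
#' replicate set) and recorded time, averages haplotype frequencies over the
#' first R replicates and reports the detection percentage of the
#' capped-FDR detector — the map showing how many independent populations
#' rescue detection at late times.
#'
#' @param cfg A [sim_config()].
#' @param R_values Increasing replicate counts to evaluate; `max(R_values)`
#'   replicates are simulated once and reused.
#' @param times Recorded generations to evaluate (default: all of
#'   `cfg$record_times`).
#' @param fdr_cap FDR cap for the detector (default 0.2).
#' @param measure Panel statistic.
#' @param founder_policy Passed to [run_replicates()].
#' @return Long-format data frame: `R`, `time`, `threshold`,
#'   `detection_pct`, `fpos_pct`, `fdr_pct`.
#' @export
replicate_map <- function(cfg, R_values, times = NULL, fdr_cap = 0.2,
                          measure = "UFE",
                          founder_policy = "shared_founder") {
  R_values <- sort(unique(as.integer(R_values)))
  if (is.null(times)) times <- cfg$record_times
  rs <- run_replicates(cfg, max(R_values), founder_policy = founder_policy)
  dc <- detection_config(mode = "max_det_at_fdr_cap", fdr_cap = fdr_cap)
  rows <- list()
  for (R in R_values) {
    for (t in times) {
      panel <- averaged_panel(rs, t, use = seq_len(R))
      rep <- optimize_threshold(panel[[measure]], panel$is_epistatic, dc,
                                time = t)
      rows[[length(rows) + 1L]] <-
        data.frame(R = R, time = t, threshold = rep$threshold,
                   detection_pct = rep$detection_pct,
                   fpos_pct = rep$fpos_pct, fdr_pct = rep$fdr_pct)
    }
  }
  do.call(rbind, rows)
}

#' Detection-window sweep over one model parameter
#'
#' For each parameter value, evolves `R` replicate populations, computes the
#' per-run detection timecourse (single-population protocol: per-run
#' thresholds, reports averaged over runs), and summarizes the detection
#' window.  Raw timecourses are attached so window criteria can be
#' re-evaluated without re-simulation.
#'
#' @param base_cfg The configuration to perturb.
#' @param parameter One of `"s0"`, `"L"`, `"N"`, `"f0"`, `"outcross_prob"`,
#'   `"crossover_mean"`, `"E"`, `"s_mode"`.
#' @param values Parameter values to sweep.
#' @param R Replicate runs per value.
#' @param measure Panel statistic.
#' @param config A [detection_config()].
#' @param open_criterion,close_criterion Window criteria, see
#'   [window_metrics()].
#' @param founder_policy Passed to [run_replicates()]; sweeps default to
#'   independent founders since each value is its own experiment.
#' @return Data frame with one row per value: the parameter value, window
#'   metrics, and the peak `DET - FPOS` separation; attribute
#'   `"timecourses"` holds the per-value timecourse tables.
#' @export
parameter_sweep <- function(base_cfg, parameter, values, R = 25,
                            measure = "UFE", config = detection_config(),
                            open_criterion = 50, close_criterion = 10,
                            founder_policy = "independent_founders") {
  allowed <- c("s0", "L", "N", "f0", "outcross_prob", "crossover_mean",
               "E", "s_mode")
  if (!parameter %in% allowed) {
    stop("parameter must be one of: ", paste(allowed, collapse = ", "))
  }
  tcs <- list()
  rows <- list()
  for (v in values) {
    cfg <- base_cfg
    cfg[[parameter]] <- if (parameter %in% c("N", "L")) as.integer(v) else v
    if (parameter == "L") cfg$topology <- NULL   # re-pair for the new length
    validate_sim_config(cfg)
    rs <- run_replicates(cfg, R, founder_policy = founder_policy)
    tc <- detection_timecourse(rs$records, measure = measure, config = config)
    wm <- window_metrics(tc, open_criterion, close_criterion)
    tcs[[as.character(v)]] <- tc
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(parameter = parameter, value = v, R = R), wm,
            data.frame(peak_separation = max(tc$detection_pct - tc$fpos_pct)))
  }
  out <- do.call(rbind, rows)
  attr(out, "timecourses") <- tcs
  out
}
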