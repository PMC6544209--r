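#' Detector configuration
#'
#' The detector knows the true epistatic pairs (labels are available by
#' construction in simulated data) and tunes a threshold — one per statistic
#' — to separate the labeled clouds as well as theoretically possible.  Two
#' objectives are supported: maximize `DET - a * FPOS` (detection percentage
#' minus `a` times the false-positive percentage; `a` is a weighting
#' parameter, default 1), or maximize `DET` subject to a false-discovery-rate
#' cap.
#'
#' @param a Non-negative weight on the false-positive percentage.
#' @param sided `"upper"`: detect when value >= threshold (antagonistic
#'   epistasis drives the statistics positive); `"two_sided"`: detect when
#'   |value| >= threshold.
#' @param mode `"max_det_minus_fpos"` or `"max_det_at_fdr_cap"`.
#' @param fdr_cap FDR cap in `[0, 1]`, required in capped mode (0 means no
#'   false positive tolerated at all).
#' @param measures Character vector of 1-3 panel statistics (columns of a
#'   [compute_panel()] table) used by multi-measure detection.
#' @param n_quantiles Per-axis quantile grid size for the box search.
#' @return A list of class `"detection_config"`.
#' @export
detection_config <- function(a = 1, sided = c("upper", "two_sided"),
                             mode = c("max_det_minus_fpos", "max_det_at_fdr_cap"),
                             fdr_cap = NULL, measures = "UFE",
                             n_quantiles = 50L) {
  sided <- match.arg(sided)
  mode <- match.arg(mode)
  if (a < 0) stop("objective weight a must be >= 0")
  if (mode == "max_det_at_fdr_cap") {
    if (is.null(fdr_cap)) stop("capped mode requires fdr_cap")
    if (fdr_cap < 0 || fdr_cap > 1) stop("fdr_cap must lie in [0, 1]")
  }
  if (length(measures) < 1L || length(measures) > 3L) {
    stop("measures must name 1 to 3 statistics")
  }
  structure(list(a = a, sided = sided, mode = mode, fdr_cap = fdr_cap,
                 measures = measures, n_quantiles = as.integer(n_quantiles)),
            class = "detection_config")
}

# Detection / false-positive / FDR percentages at one threshold rule.
# detected: logical vector; labels: logical (TRUE = epistatic).
detection_metrics <- function(detected, labels) {
  n_true <- sum(labels)
  n_false <- sum(!labels)
  tp <- sum(detected & labels)
  fp <- sum(detected & !labels)
  det <- 100 * tp / n_true
  fpos <- 100 * fp / n_false
  fdr <- if (tp + fp == 0L) 0 else 100 * fp / (tp + fp)
  c(detection_pct = det, fpos_pct = fpos, fdr_pct = fdr)
}

#' Optimal single-statistic threshold given true labels
#'
#' Exhaustive search over the observed values (plus the "detect nothing"
#' threshold) for the detection rule `value >= threshold` (or
#' `|value| >= threshold` when two-sided).  Default objective:
#' `DET - a * FPOS`; capped mode: maximize `DET` subject to `FDR <= cap`.
#' Ties are broken toward the higher threshold, i.e. fewer false positives.
#' Invalid (NA) values are excluded before optimization; percentages are
#' relative to the valid pairs of each label.
#'
#' @param values Numeric statistic values, one per pair (NA = invalid).
#' @param labels Logical truth labels (TRUE = epistatic pair).
#' @param config A [detection_config()].
#' @param time Optional time stamp carried into the report.
#' @return A one-row data frame (`"detection_report"`): `time`, `threshold`,
#'   `detection_pct`, `fpos_pct`, `fdr_pct`, `objective`, `n_true`,
#'   `n_false`.
#' @export
optimize_threshold <- function(values, labels, config = detection_config(),
                               time = NA_integer_) {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- as.logical(labels[keep])
  if (length(values) == 0L) stop("no valid values to optimize over")
  if (all(labels) || !any(labels)) {
    stop("need at least one true and one false label among valid pairs")
  }
  v <- if (config$sided == "two_sided") abs(values) else values
  cand <- c(sort(unique(v)), Inf)

  # value >= threshold, evaluated for all candidates at once:
  # sort descending, count detections by label cumulatively.
  ord <- order(v, decreasing = TRUE)
  vs <- v[ord]
  ls <- labels[ord]
  n_true <- sum(labels)
  n_false <- sum(!labels)
  cum_tp <- cumsum(ls)
  cum_fp <- cumsum(!ls)
  # number of values >= each candidate threshold (candidates are sorted)
  va <- rev(vs)                       # ascending
  idx <- length(va) - findInterval(cand, va, left.open = TRUE)
  tp <- ifelse(idx == 0L, 0, cum_tp[pmax(idx, 1L)] * (idx > 0L))
  fp <- ifelse(idx == 0L, 0, cum_fp[pmax(idx, 1L)] * (idx > 0L))
  det <- 100 * tp / n_true
  fpos <- 100 * fp / n_false
  fdr <- ifelse(tp + fp == 0L, 0, 100 * fp / (tp + fp))

  if (config$mode == "max_det_minus_fpos") {
    obj <- det - config$a * fpos
    best <- which(obj == max(obj))
  } else {
    feasible <- fdr <= 100 * config$fdr_cap + 1e-9
    obj <- det
    if (!any(feasible)) stop("no feasible threshold under the FDR cap")
    obj[!feasible] <- -Inf
    best <- which(obj == max(obj))
  }
  k <- best[which.max(cand[best])]    # tie -> higher threshold
  out <- data.frame(time = time, threshold = cand[k],
                    detection_pct = det[k], fpos_pct = fpos[k],
                    fdr_pct = fdr[k], objective = det[k] - config$a * fpos[k],
                    n_true = n_true, n_false = n_false)
  class(out) <- c("detection_report", "data.frame")
  out
}

#' Optimal axis-aligned box over 2-3 statistics
#'
#' A pair is detected iff it exceeds every per-measure threshold (an
#' axis-aligned conjunction).  Thresholds are optimized by exhaustive search
#' on a per-measure quantile grid (default 50 quantiles per axis; set
#' `exhaustive = TRUE` to search all observed values, feasible for small
#' panels), under the same objective as [optimize_threshold()].
#'
#' @param panel A [compute_panel()] data frame, or a numeric matrix with one
#'   column per measure.
#' @param labels Truth labels; taken from `panel$is_epistatic` when omitted.
#' @param config A [detection_config()] whose `measures` name 2-3 columns.
#' @param exhaustive Use every observed value as a candidate threshold
#'   instead of the quantile grid.
#' @param time Optional time stamp.
#' @return A one-row data frame like [optimize_threshold()]'s, with a
#'   `thresholds` list-column (named per-measure vector).
#' @export
optimize_box <- function(panel, labels = NULL, config = detection_config(),
                         exhaustive = FALSE, time = NA_integer_) {
  m <- config$measures
  if (length(m) < 2L) stop("box optimization needs 2 or 3 measures")
  if (is.data.frame(panel)) {
    if (is.null(labels)) labels <- panel$is_epistatic
    X <- as.matrix(panel[, m, drop = FALSE])
  } else {
    X <- as.matrix(panel)
    colnames(X) <- m
  }
  labels <- as.logical(labels)
  if (config$sided == "two_sided") X <- abs(X)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  if (all(labels) || !any(labels)) {
    stop("need at least one true and one false label among valid pairs")
  }
  grids <- lapply(seq_along(m), function(k) {
    g <- if (exhaustive) sort(unique(X[, k])) else
      sort(unique(stats::quantile(X[, k], probs = seq(0, 1, length.out =
        config$n_quantiles), names = FALSE, type = 1)))
    c(g, Inf)
  })
  combos <- expand.grid(lapply(grids, seq_along))
  best <- NULL
  best_obj <- -Inf
  best_thr <- NULL
  for (row in seq_len(nrow(combos))) {
    thr <- vapply(seq_along(m), function(k) grids[[k]][combos[row, k]],
                  numeric(1))
    detected <- rep(TRUE, nrow(X))
    for (k in seq_along(m)) detected <- detected & (X[, k] >= thr[k])
    met <- detection_metrics(detected, labels)
    if (config$mode == "max_det_at_fdr_cap" &&
        met["fdr_pct"] > 100 * config$fdr_cap + 1e-9) next
    obj <- if (config$mode == "max_det_minus_fpos") {
      met["detection_pct"] - config$a * met["fpos_pct"]
    } else {
      met["detection_pct"]
    }
    # ties -> larger thresholds (compare lexicographically on sum)
    if (obj > best_obj + 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 && !is.null(best_thr) &&
         sum(pmin(thr, 1e300)) > sum(pmin(best_thr, 1e300)))) {
      best_obj <- obj
      best_thr <- thr
      best <- met
    }
  }
  if (is.null(best)) stop("no feasible box under the FDR cap")
  out <- data.frame(time = time, threshold = NA_real_,
                    detection_pct = best[["detection_pct"]],
                    fpos_pct = best[["fpos_pct"]],
                    fdr_pct = best[["fdr_pct"]],
                    objective = best[["detection_pct"]] -
                      config$a * best[["fpos_pct"]],
                    n_true = sum(labels), n_false = sum(!labels))
  out$thresholds <- list(stats::setNames(best_thr, m))
  class(out) <- c("detection_report", "data.frame")
  out
}

#' Detection performance over time
#'
#' Runs the threshold detector on the panel at every recorded time of one or
#' several simulation records.  With several records (replicate runs), the
#' detector is applied per run and the reports are averaged pointwise over
#' runs — the single-population protocol, in which each run gets its own
#' optimal threshold.  (Contrast [averaged_detection_timecourse()], which
#' first averages haplotype frequencies across populations.)
#'
#' @param x A `"simulation_record"` or a list of them (same record times).
#' @param measure Panel statistic to threshold (default `"UFE"`).
#' @param config A [detection_config()].
#' @param pseudocount,epsilon Passed to [compute_panel()].
#' @return Data frame: `time`, `threshold` (run mean), `detection_pct`,
#'   `fpos_pct`, `fdr_pct`, `objective` (all run means), `n_runs`.
#' @export
detection_timecourse <- function(x, measure = "UFE",
                                 config = detection_config(),
                                 pseudocount = 0.5, epsilon = 1e-6) {
  records <- if (inherits(x, "simulation_record")) list(x) else x
  stopifnot(length(records) >= 1L)
  times <- records[[1L]]$times
  per_run <- lapply(records, function(rec) {
    do.call(rbind, lapply(seq_along(rec$times), function(k) {
      panel <- compute_panel(rec$counts[[k]], rec$topology,
                             pseudocount = pseudocount, epsilon = epsilon,
                             time = rec$times[k])
      optimize_threshold(panel[[measure]], panel$is_epistatic, config,
                         time = rec$times[k])
    }))
  })
  cols <- c("threshold", "detection_pct", "fpos_pct", "fdr_pct", "objective")
  avg <- Reduce(`+`, lapply(per_run, function(d) as.matrix(d[, cols]))) /
    length(per_run)
  out <- data.frame(time = times, avg, n_runs = length(per_run))
  attr(out, "per_run") <- per_run
  out
}

#' Detection-window summary of a timecourse
#'
#' Operationalizes the qualitative "detection window" on the separation
#' between the detection percentage and the false-discovery percentage of
#' the optimized detector: the window *opens* at the earliest time with
#' separation `>= open_criterion` (default 50 percentage points) and
#' *closes* at the earliest later time with separation `<= close_criterion`
#' (default 10 points).  False discovery — the fraction of detected pairs
#' that are not epistatic — is the quantity that races ahead of detection
#' when stochastic linkage takes over (the non-epistatic pairs outnumber the
#' epistatic ones by a factor of about L), so it, rather than the
#' false-positive *rate*, is what closes the window; `separation = "fpos"`
#' gives the rate-based alternative.  Absence of a window and
#' right-censoring (never closes within the horizon) are explicit statuses,
#' not errors.
#'
#' @param tc A timecourse data frame with columns `time`, `detection_pct`,
#'   `fdr_pct` and/or `fpos_pct` (e.g. from [detection_timecourse()]).
#' @param open_criterion,close_criterion Percentage-point criteria.
#' @param separation `"fdr"` (default): separation is
#'   `detection_pct - fdr_pct`; `"fpos"`: `detection_pct - fpos_pct`.
#' @return A one-row data frame: `open_time`, `close_time`, `width`
#'   (generations; NA where undefined), `status` one of `"no_window"`,
#'   `"closed"`, `"right_censored"`.
#' @export
window_metrics <- function(tc, open_criterion = 50, close_criterion = 10,
                           separation = c("fdr", "fpos")) {
  separation <- match.arg(separation)
  stopifnot(nrow(tc) >= 1L)
  sep <- tc$detection_pct -
    (if (separation == "fdr") tc$fdr_pct else tc$fpos_pct)
  open_idx <- which(sep >= open_criterion)
  if (length(open_idx) == 0L) {
    return(data.frame(open_time = NA_real_, close_time = NA_real_,
                      width = NA_real_, status = "no_window"))
  }
  o <- open_idx[1L]
  close_idx <- which(seq_along(sep) > o & sep <= close_criterion)
  if (length(close_idx) == 0L) {
    return(data.frame(open_time = tc$time[o], close_time = NA_real_,
                      width = NA_real_, status = "right_censored"))
  }
  cl <- close_idx[1L]
  data.frame(open_time = tc$time[o], close_time = tc$time[cl],
             width = tc$time[cl] - tc$time[o], status = "closed")
}

#' Onset time of false-positive contamination
#'
#' The earliest recorded time at which the (run-averaged) false-positive
#' percentage of the optimized detector reaches `criterion` — the
#' operational marker for the beginning of the transition that degrades
#' single-population detection.
#'
#' @param tc A timecourse data frame with `time` and `fpos_pct`.
#' @param criterion Percentage threshold (default 20).
#' @return The onset time, or NA if never reached.
#' @export
fpos_onset_time <- function(tc, criterion = 20) {
  idx <- which(tc$fpos_pct >= criterion)
  if (length(idx) == 0L) NA_real_ else tc$time[idx[1L]]
}
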