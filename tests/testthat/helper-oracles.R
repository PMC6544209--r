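# Independent first-principles oracles used to cross-check the package's
# vectorized implementations.  Deliberately written along different routes
# than the implementation (e.g. D via the determinant identity
# f11*f00 - f01*f10 instead of f11 - p*q).

oracle_ld <- function(f00, f01, f10, f11, epsilon = 1e-6) {
  # D via the determinant of the 2x2 haplotype table
  D <- f11 * f00 - f01 * f10
  pa <- f10 + f11     # allele 1 at locus i
  pb <- f01 + f11     # allele 1 at locus j
  poly <- pa > 0 && pa < 1 && pb > 0 && pb < 1

  dprime_ab <- function(D_ab, fa, fb) {
    if (!poly) return(NA_real_)
    if (D_ab == 0) return(0)
    dmax <- if (D_ab > 0) min(fa * (1 - fb), (1 - fa) * fb)
            else max(-fa * fb, -(1 - fa) * (1 - fb))
    D_ab / dmax
  }
  Dp11 <- dprime_ab(D, pa, pb)
  Dp01 <- dprime_ab(-D, 1 - pa, pb)
  r11 <- if (poly) D / sqrt(pa * (1 - pa) * pb * (1 - pb)) else NA_real_
  pos <- all(c(f00, f01, f10, f11) > 0)
  WU <- if (pos) log((f11 * f00) / (f01 * f10)) else NA_real_
  den <- if (pos) log((f01 * f10) / f00^2) else NA_real_
  UFE <- if (pos && abs(den) >= epsilon) 1 - log(f11 / f00) / den else NA_real_
  list(Dp11 = Dp11, Dp01 = Dp01, r11 = r11, r01 = if (poly) -r11 else NA_real_,
       WU = WU, UFE = UFE)
}

# Brute-force threshold optimizer: literal double loop over candidates.
oracle_threshold <- function(values, labels, a = 1, sided = "upper") {
  keep <- !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  v <- if (sided == "two_sided") abs(values) else values
  cand <- c(sort(unique(v)), Inf)
  best <- NULL
  for (th in cand) {
    det <- 100 * sum(v >= th & labels) / sum(labels)
    fpos <- 100 * sum(v >= th & !labels) / sum(!labels)
    obj <- det - a * fpos
    if (is.null(best) || obj > best$objective ||
        (obj == best$objective && th > best$threshold)) {
      best <- list(threshold = th, detection_pct = det, fpos_pct = fpos,
                   objective = obj)
    }
  }
  best
}

# Closed-form single-site haploid selection trajectory (no mutation/drift).
logistic_decay <- function(f0, s, t) {
  f0 * exp(-s * t) / (f0 * exp(-s * t) + 1 - f0)
}

# Small random frequency 4-vector (strictly positive unless allow_zero).
random_cells <- function(allow_zero = FALSE) {
  x <- stats::runif(4)
  if (allow_zero && stats::runif(1) < 0.2) x[sample.int(4, 1)] <- 0
  x / sum(x)
}

fast_cfg <- function(...) {
  sim_config(N = 200, L = 10, n_generations = 10,
             record_times = c(0, 5, 10), seed = 42, ...)
}
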