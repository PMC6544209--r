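#' Two-locus haplotype frequencies
#'
#' Container for the four haplotype cell frequencies of a bi-allelic locus
#' pair, with derived marginals `p1 = f10 + f11` (frequency of allele 1 at
#' the first locus) and `q1 = f01 + f11` (at the second).
#'
#' @param f00,f01,f10,f11 Cell frequencies (first subscript: allele at locus
#'   i; second: at locus j); must be non-negative and sum to 1 within 1e-9.
#' @return A list of class `"haplotype_freqs"`.
#' @export
haplotype_freqs <- function(f00, f01, f10, f11) {
  f00 <- unname(f00); f01 <- unname(f01)
  f10 <- unname(f10); f11 <- unname(f11)
  f <- c(f00, f01, f10, f11)
  if (any(f < 0)) stop("haplotype frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  structure(list(f00 = f00, f01 = f01, f10 = f10, f11 = f11,
                 p1 = f10 + f11, q1 = f01 + f11),
            class = "haplotype_freqs")
}

#' Haplotype frequencies of one locus pair in a population
#'
#' Counts the four two-locus haplotypes over all N genomes, optionally adds a
#' pseudocount to every cell (Haldane-style continuity correction so that the
#' log-based statistics stay finite), and normalizes.
#'
#' @param pop Population matrix (`N x L`, 0/1).
#' @param i,j 1-based site indices with `i < j <= L`.
#' @param pseudocount Non-negative value added to each of the four counts
#'   before normalization (default 0: raw frequencies).
#' @return A [haplotype_freqs()] object; the raw counts are attached as
#'   attribute `"counts"` (named `n00, n01, n10, n11`).
#' @export
pair_haplotype_freqs <- function(pop, i, j, pseudocount = 0) {
  L <- ncol(pop)
  if (!(i >= 1 && j <= L && i < j)) stop("need 1 <= i < j <= L")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  a <- pop[, i]
  b <- pop[, j]
  n11 <- sum(a & b)
  n10 <- sum(a) - n11
  n01 <- sum(b) - n11
  n00 <- nrow(pop) - n11 - n10 - n01
  n <- c(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
  f <- unname((n + pseudocount) / sum(n + pseudocount))
  out <- haplotype_freqs(f[1], f[2], f[3], f[4])
  attr(out, "counts") <- n
  out
}

#' Haplotype counts for every locus pair
#'
#' Computes the `choose(L, 2) x 4` table of two-locus haplotype counts for
#' all site pairs in one pass (a single cross-product of the allele matrix),
#' the workhorse behind whole-genome panels.
#'
#' @param pop Population matrix (`N x L`, 0/1).
#' @return Integer matrix with one row per pair (ordered (1,2), (1,3), ...,
#'   column-major upper triangle) and columns `n00, n01, n10, n11`;
#'   attributes `site_i`, `site_j` (1-based index vectors) and `N`.
#' @export
all_pair_counts <- function(pop) {
  N <- nrow(pop)
  L <- ncol(pop)
  cs <- colSums(pop)
  M11 <- crossprod(pop)               # L x L matrix of n11 counts
  iu <- which(upper.tri(M11))
  site_j <- ((iu - 1L) %/% L) + 1L
  site_i <- ((iu - 1L) %% L) + 1L
  n11 <- M11[iu]
  n10 <- cs[site_i] - n11
  n01 <- cs[site_j] - n11
  n00 <- N - n11 - n10 - n01
  out <- cbind(n00 = n00, n01 = n01, n10 = n10, n11 = n11)
  storage.mode(out) <- "integer"
  attr(out, "site_i") <- site_i
  attr(out, "site_j") <- site_j
  attr(out, "N") <- N
  out
}

# Vectorized panel statistics from cell-frequency vectors.  Returns a data
# frame of the six statistics plus per-statistic validity flags.  Conventions:
#   D_11 = f11 - p1*q1  (focal alleles 1,1);  D_01 = -D_11 (identity).
#   D'   = D / Dmax with Dmax evaluated on the focal-allele marginals
#          (two sign branches); D = 0 maps to D' = 0.
#   r_ab = D_ab / sqrt(p(1-p) q(1-q));  r_01 = -r_11.
#   WU   = ln(f11 f00 / (f01 f10));  natural logs throughout.
#   UFE  = 1 - ln(f11/f00) / ln(f01 f10 / f00^2), guarded against the
#          singularity where the denominator log vanishes.
ld_stats_from_cells <- function(f00, f01, f10, f11, epsilon = 1e-6) {
  p1 <- f10 + f11
  q1 <- f01 + f11
  poly <- p1 > 0 & p1 < 1 & q1 > 0 & q1 < 1
  D11 <- f11 - p1 * q1

  dprime <- function(D, fa, fb) {
    dmax <- ifelse(D > 0,
                   pmin(fa * (1 - fb), (1 - fa) * fb),
                   pmax(-fa * fb, -(1 - fa) * (1 - fb)))
    ifelse(D == 0, 0, D / dmax)
  }
  Dp11 <- ifelse(poly, dprime(D11, p1, q1), NA_real_)
  Dp01 <- ifelse(poly, dprime(-D11, 1 - p1, q1), NA_real_)

  denom_r <- sqrt(p1 * (1 - p1) * q1 * (1 - q1))
  r11 <- ifelse(poly, D11 / denom_r, NA_real_)
  r01 <- -r11

  pos <- f00 > 0 & f01 > 0 & f10 > 0 & f11 > 0
  WU <- ifelse(pos, log(f11) + log(f00) - log(f01) - log(f10), NA_real_)

  den <- log(f01) + log(f10) - 2 * log(f00)
  ufe_ok <- pos & abs(den) >= epsilon
  UFE <- ifelse(ufe_ok, 1 - (log(f11) - log(f00)) / den, NA_real_)

  data.frame(Dp11 = Dp11, Dp01 = Dp01, r11 = r11, r01 = r01,
             WU = WU, UFE = UFE,
             valid_Dp11 = poly, valid_Dp01 = poly,
             valid_r11 = poly, valid_r01 = poly,
             valid_WU = as.vector(pos), valid_UFE = as.vector(ufe_ok))
}

as_freq_cells <- function(freqs) {
  if (inherits(freqs, "haplotype_freqs")) {
    unname(unlist(freqs[c("f00", "f01", "f10", "f11")]))
  } else if (is.numeric(freqs) && length(freqs) == 4L) {
    unname(freqs)
  } else {
    stop("expected a haplotype_freqs object or 4 frequencies")
  }
}

stat_one <- function(freqs, column, epsilon = 1e-6) {
  f <- as_freq_cells(freqs)
  s <- ld_stats_from_cells(f[1], f[2], f[3], f[4], epsilon)
  s[[column]]
}

#' Lewontin's D' for a chosen pair of focal alleles
#'
#' `D_ab = f_ab - f_a f_b` normalized by its frequency-constrained extreme
#' `Dmax` (the sign-dependent bound on D given the marginals), so that
#' `D' \in [0, 1]` wherever both loci are polymorphic.  `D = 0` maps to
#' `D' = 0` by convention.  The two panel members are the conventions
#' `(a, b) = (1, 1)` and `(0, 1)`.
#'
#' @param freqs A [haplotype_freqs()] object or 4 cell frequencies
#'   `(f00, f01, f10, f11)`.
#' @param a,b Focal alleles (0 or 1) at the first and second locus.
#' @return D' value, or `NA` when a locus is fixed (statistic invalid).
#' @export
lewontin_Dprime <- function(freqs, a = 1, b = 1) {
  f <- as_freq_cells(freqs)
  p1 <- f[3] + f[4]
  q1 <- f[2] + f[4]
  if (!(p1 > 0 && p1 < 1 && q1 > 0 && q1 < 1)) return(NA_real_)
  fa <- if (a == 1) p1 else 1 - p1
  fb <- if (b == 1) q1 else 1 - q1
  fab <- f[1L + a * 2L + b]           # cells ordered 00, 01, 10, 11
  D <- fab - fa * fb
  if (D == 0) return(0)
  dmax <- if (D > 0) min(fa * (1 - fb), (1 - fa) * fb) else
    max(-fa * fb, -(1 - fa) * (1 - fb))
  D / dmax
}

#' Pearson correlation between alleles at two loci
#'
#' `r_ab = D_ab / sqrt(f_a (1 - f_a) f_b (1 - f_b))`; the denominator is
#' allele-choice invariant, so `r_01 = -r_11` identically.
#'
#' @inheritParams lewontin_Dprime
#' @return r in `[-1, 1]`, or `NA` when a locus is fixed.
#' @export
pearson_r <- function(freqs, a = 1, b = 1) {
  f <- as_freq_cells(freqs)
  r11 <- stat_one(f, "r11")
  if (is.na(r11)) return(NA_real_)
  sign <- if (xor(a == 1, b == 1)) -1 else 1
  sign * r11
}

#' WU log odds-ratio statistic
#'
#' `WU = ln(f11 f00 / (f01 f10))`, the natural-log odds ratio of the four
#' haplotype cells: symmetric under exchange of the two loci, antisymmetric
#' under relabelling the alleles at exactly one locus, zero under
#' independence, and scale-invariant (counts and frequencies agree).
#'
#' @inheritParams lewontin_Dprime
#' @return WU value, or `NA` if any cell is zero (invalid without a
#'   pseudocount).
#' @export
wu_statistic <- function(freqs) stat_one(freqs, "WU")

#' UFE haplotype statistic
#'
#' `UFE = 1 - ln(f11 / f00) / ln(f01 f10 / f00^2)`.  Unlike the classical LD
#' measures this one has a direct fitness meaning: for an isolated
#' antagonistically interacting pair, evaluated on ensemble-averaged
#' haplotype frequencies, it recovers the epistatic strength, `UFE = E`
#' (see [deterministic_two_locus()]).  It is zero under independence and
#' invariant under exchanging `f01` and `f10`.
#'
#' @inheritParams lewontin_Dprime
#' @param epsilon Guard band: the statistic is flagged invalid (NA) when the
#'   denominator log is within `epsilon` of its singular point
#'   `f01 f10 = f00^2`.
#' @return UFE value, or `NA` (zero cell or singular denominator).
#' @export
ufe_statistic <- function(freqs, epsilon = 1e-6) {
  f <- as_freq_cells(freqs)
  stat_one(f, "UFE", epsilon)
}

#' Six-statistic LD panel over locus pairs
#'
#' Evaluates all six panel statistics (`Dp11`, `Dp01`, `r11`, `r01`, `WU`,
#' `UFE`) for every locus pair of a population (or for a precomputed
#' haplotype count table), labels each pair as epistatic or not from the
#' interaction topology, and flags invalid statistics per pair instead of
#' dropping them.
#'
#' @param x Either a population matrix (`N x L`, 0/1), a count matrix from
#'   [all_pair_counts()], or a data frame with columns `site_i`, `site_j`,
#'   `n00`, `n01`, `n10`, `n11` (e.g. read back from a TSV).
#' @param topology An [epistatic_topology()] supplying the truth labels.
#' @param pseudocount Added to each haplotype count before normalization
#'   (default 0.5; use 0 to get raw frequencies plus invalidity flags).
#' @param epsilon Singularity guard for UFE, see [ufe_statistic()].
#' @param time Optional generation stamp copied into the output.
#' @param pairs Optional restriction: a data frame (or 2-column matrix) of
#'   `site_i`, `site_j` pairs to evaluate; all `choose(L, 2)` pairs
#'   otherwise.
#' @return Data frame with one row per pair: `time`, `site_i`, `site_j`, the
#'   six statistics, six `valid_*` flags, and the logical `is_epistatic`.
#' @export
compute_panel <- function(x, topology, pseudocount = 0.5, epsilon = 1e-6,
                          time = NA_integer_, pairs = NULL) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  is_counts <- is.matrix(x) && !is.null(attr(x, "site_i")) &&
    identical(colnames(x), c("n00", "n01", "n10", "n11"))
  if (is.matrix(x) && !is_counts) x <- all_pair_counts(x)
  if (is.matrix(x)) {
    site_i <- attr(x, "site_i")
    site_j <- attr(x, "site_j")
    counts <- x[, c("n00", "n01", "n10", "n11"), drop = FALSE]
  } else if (is.data.frame(x)) {
    site_i <- x$site_i
    site_j <- x$site_j
    counts <- as.matrix(x[, c("n00", "n01", "n10", "n11")])
    if (is.na(time) && !is.null(x$time)) time <- x$time
  } else {
    stop("x must be a population matrix, a pair-count matrix, or a data frame")
  }
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    want <- paste(pmin(pairs[[1L]], pairs[[2L]]),
                  pmax(pairs[[1L]], pairs[[2L]]))
    keep <- paste(site_i, site_j) %in% want
    site_i <- site_i[keep]
    site_j <- site_j[keep]
    counts <- counts[keep, , drop = FALSE]
  }
  cells <- counts + pseudocount
  tot <- rowSums(cells)
  f <- cells / tot
  stats <- ld_stats_from_cells(f[, 1], f[, 2], f[, 3], f[, 4], epsilon)
  key <- paste(site_i, site_j)
  epi_key <- paste(topology$site_i, topology$site_j)
  out <- cbind(data.frame(time = time, site_i = site_i, site_j = site_j),
               stats,
               data.frame(is_epistatic = key %in% epi_key))
  rownames(out) <- NULL
  out
}
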