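#' Clone decomposition by fitness class
#'
#' Collapses a population to its unique sequences (clones), counting copies
#' and annotating each clone with its fitness class `k` (number of
#' deleterious alleles) and log fitness `W`.  Adapting asexual populations
#' develop a characteristic structure of large clonal lineages stacked
#' within discrete fitness classes; this table makes it visible.
#'
#' @param pop Population matrix (`N x L`, 0/1).
#' @param selection Per-site magnitudes `|s_i|`.
#' @param topology An [epistatic_topology()].
#' @return Data frame sorted by copy count (descending): `rank`, `count`,
#'   `k`, `W`, `sequence` (the genome as a 0/1 string).  Counts sum to N.
#' @export
clone_decomposition <- function(pop, selection, topology) {
  key <- apply(pop, 1L, paste, collapse = "")
  tab <- table(key)
  seqs <- names(tab)
  counts <- as.integer(tab)
  ord <- order(counts, seqs, decreasing = c(TRUE, FALSE), method = "radix")
  seqs <- seqs[ord]
  counts <- counts[ord]
  geno <- t(vapply(strsplit(seqs, ""),
                   function(x) as.integer(x), integer(ncol(pop))))
  data.frame(rank = seq_along(counts), count = counts,
             k = rowSums(geno),
             W = log_fitness(geno, selection, topology),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Exclude the largest clones from a population sample
#'
#' Removes the `n_excluded` largest clones — a denoising attempt: the
#' biggest clonal lineages carry the strongest shared-ancestry signal, so
#' dropping them might reduce stochastic LD.  Ties in clone size are broken
#' by lexicographic sequence order, making the exclusion deterministic.
#'
#' @param pop Population matrix.
#' @param n_excluded Number of largest clones to remove (`>= 0`).
#' @param mode `"drop"` removes every copy of an excluded clone;
#'   `"cap"` keeps exactly one copy of each.
#' @return A list: `sample` (the retained genomes), `excluded_pct`
#'   (percentage of sequences removed), `n_clones_excluded`.
#' @export
exclude_top_clones <- function(pop, n_excluded, mode = c("drop", "cap")) {
  mode <- match.arg(mode)
  if (n_excluded < 0) stop("n_excluded must be >= 0")
  if (n_excluded == 0L) {
    return(list(sample = pop, excluded_pct = 0, n_clones_excluded = 0L))
  }
  key <- apply(pop, 1L, paste, collapse = "")
  tab <- table(key)
  ord <- order(as.integer(tab), names(tab),
               decreasing = c(TRUE, FALSE), method = "radix")
  if (n_excluded > length(tab)) {
    stop("n_excluded exceeds the number of distinct clones (",
         length(tab), ")")
  }
  top <- names(tab)[ord][seq_len(n_excluded)]
  hit <- key %in% top
  kept <- pop[!hit, , drop = FALSE]
  removed <- if (mode == "cap") {
    first <- match(top, key)
    kept <- rbind(kept, pop[first, , drop = FALSE])
    sum(hit) - length(top)
  } else {
    sum(hit)
  }
  if (nrow(kept) == 0L) stop("exclusion removed every sequence")
  list(sample = kept, excluded_pct = 100 * removed / nrow(pop),
       n_clones_excluded = as.integer(n_excluded))
}

#' Variance-to-mean ratio of a haplotype-frequency observable
#'
#' The VMR (index of dispersion, population-variance form) measures the
#' amplitude of stochastic fluctuations of haplotype frequencies across
#' locus pairs.  Given a panel (or frequency table) plus labels, the default
#' observable is the doubly-mutant cell frequency `f11` across
#' *non-epistatic* pairs, i.e. pure linkage noise.
#'
#' @param x A numeric vector of observable values, or a data frame holding
#'   the observable column (e.g. a [compute_panel()] table augmented with
#'   frequencies, or any per-pair table).
#' @param labels Optional logical epistatic labels; when given, only pairs
#'   with `labels == FALSE` enter the ratio.
#' @param observable Column name used when `x` is a data frame.
#' @return The ratio `var(x) / mean(x)` with the population (1/n) variance.
#' @export
vmr_fluctuation <- function(x, labels = NULL, observable = "f11") {
  v <- if (is.data.frame(x)) x[[observable]] else x
  if (!is.null(labels)) v <- v[!as.logical(labels)]
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 valid values")
  m <- mean(v)
  if (m == 0) stop("degenerate observable: mean is 0")
  pvar <- mean((v - m)^2)
  pvar / m
}

#' Sample genomes and build a hierarchical-clustering tree
#'
#' Uniformly samples `sample_size` genomes without replacement, computes all
#' pairwise Hamming distances, and builds an average-linkage (UPGMA-style)
#' hierarchical clustering tree — the genealogy proxy used to watch a
#' population collapse from a star-like founder burst toward a monophyletic
#' coalescent shape.
#'
#' @param pop Population matrix.
#' @param sample_size Number of genomes to sample (`<= N`).  `NULL` or `N`
#'   uses every genome.
#' @param method Linkage method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A list: `dist` (the `stats::dist` Hamming matrix), `hclust`,
#'   `phylo` (an [ape::as.phylo()] tree ready for Newick export), and
#'   `mean_distance` (mean pairwise Hamming distance in the sample).
#' @export
sample_and_tree <- function(pop, sample_size = 500, method = "average") {
  N <- nrow(pop)
  if (is.null(sample_size)) sample_size <- N
  if (sample_size > N) stop("sample_size exceeds the population size")
  idx <- if (sample_size == N) seq_len(N) else sample.int(N, sample_size)
  s <- pop[idx, , drop = FALSE]
  d <- stats::dist(s, method = "manhattan")   # Hamming for 0/1 genomes
  hc <- stats::hclust(d, method = method)
  list(dist = d, hclust = hc, phylo = ape::as.phylo(hc),
       mean_distance = mean(d))
}

#' Mean pairwise Hamming distance of a genome sample
#'
#' @param pop Population matrix (or a sample of one).
#' @param sample_size Optional subsample size (uniform, without
#'   replacement); `NULL` uses all rows.
#' @return Mean Hamming distance over all pairs in the (sub)sample.
#' @export
mean_pairwise_distance <- function(pop, sample_size = NULL) {
  if (!is.null(sample_size) && sample_size < nrow(pop)) {
    pop <- pop[sample.int(nrow(pop), sample_size), , drop = FALSE]
  }
  mean(stats::dist(pop, method = "manhattan"))
}
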