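# epiwindow

When can pairwise epistasis be read out of sequence data, and when is it
drowned by shared ancestry?  `epiwindow` is an R package plus a small
analysis workflow that answers this question in silico for an adapting
asexual (or weakly recombining) population.

## The problem

Epistasis — a non-multiplicative contribution of alleles at different loci
to fitness — generates linkage disequilibrium (LD) between interacting
sites.  But so does linkage itself: in a population without abundant
recombination, whole genomes are inherited as blocks, and the random
haplotype of whoever becomes a recent common ancestor imprints strong LD of
*random sign* on every pair of loci, interacting or not.  Anyone hunting
interaction partners in viral, bacterial or cancer sequence panels faces
this confound.  The package quantifies the best theoretically possible
separation of the two signals, by simulating populations in which the true
interacting pairs are known and letting a detector tune its thresholds with
that knowledge: if the oracle-assisted detector fails, every label-free
method fails too.

## The model and statistics

A haploid population of `N` binary genomes of length `L` evolves by
Wright-Fisher resampling.  Log fitness of a genome `K` is

    W = sum_i s_i K_i + sum_{i<j} S_ij K_i K_j,   S_ij = E_ij (|s_i| + |s_j|) T_ij

with `s_i = -|s_i|` for the deleterious allele and `T` a disjoint pairing of
sites (by default 1-2, 3-4, ...).  `E` in [0, 1] is the epistatic strength:
the fraction of the combined cost refunded when both partners are mutant
(`E = 1` — full mutual compensation).  Each generation applies
selection-weighted multinomial reproduction (constant `N`), symmetric
per-site mutation (`mu = muL / L`), and optional outcrossing with
Poisson-distributed crossovers.

For every locus pair the package computes six haplotype-based LD
statistics — Lewontin's `D'` and Pearson `r` in the (1,1) and (0,1)
focal-allele conventions, the log odds ratio `WU = ln(f11 f00 / f01 f10)`,
and

    UFE = 1 - ln(f11 / f00) / ln(f01 f10 / f00^2),

which, on ensemble-averaged frequencies of an isolated pair, equals `E`
itself.  A threshold detector (single statistic or 2-3 statistic boxes)
reports detection, false-positive and false-discovery percentages over
time, window summaries, multi-population frequency averaging, parameter
sweeps, and clonal/genealogical structure (clone tables, Hamming-distance
trees with Newick export).

## A worked example

A small population evolved under the reference parameters, with the
label-optimized UFE detector applied at each snapshot:

```r
library(epiwindow)

cfg <- sim_config(N = 2000, L = 20, s0 = 0.1, E = 0.75, muL = 0.07,
                  f0 = 0.4, n_generations = 50,
                  record_times = c(1, 5, 10, 25, 50), seed = 42)
rec <- run_simulation(cfg)
detection_timecourse(rec, measure = "UFE")
```

```
  time threshold detection_pct  fpos_pct  fdr_pct objective n_runs
1    1 0.1245435            70 17.777778 82.05128  52.22222      1
2    5 0.3383649            90  1.666667 25.00000  88.33333      1
3   10 0.3429759           100  5.000000 47.36842  95.00000      1
4   25 0.3762658           100  6.666667 54.54545  93.33333      1
5   50 0.2649619            30  1.111111 40.00000  28.88889      1
```

Read it row by row: by `t = 5` the ten truly epistatic pairs separate well
from the 180 other pairs (90% detection, 1.7% false positives).  At
`t = 10`-`25` detection is total, but the false-positive rate creeps up —
and because non-epistatic pairs outnumber epistatic ones 18:1, even a 5-7%
rate means roughly half of all detections are wrong (`fdr_pct`).  By
`t = 50` the separation itself has collapsed (30% detection).  At this
small `N` the window degrades earlier and more raggedly than at the
reference `N = 2e4`; the mechanism is the same.  Averaging haplotype
frequencies over independently founded replicate populations cancels the
stochastic part and reopens the window:

```r
rs <- run_replicates(cfg, 10, founder_policy = "independent_founders")
panel <- averaged_panel(rs, 25)
optimize_threshold(panel$UFE, panel$is_epistatic, time = 25)
```

```
  time threshold detection_pct fpos_pct fdr_pct objective n_true n_false
1   25 0.5213965           100        0       0       100     10     180
```

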