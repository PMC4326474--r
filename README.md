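# xgram

Transcriptogram profiling of genome-wide expression data on a
seriation-ordered gene list.

Single-gene differential-expression tests often miss coordinated shifts
spread across a functional module, because each gene's change is small
relative to its noise. `xgram` implements the transcriptogram approach for
people analyzing replicated, pre-normalized (log2) expression data who have
a protein–protein association network for their organism: order the genes
so that associated genes become list neighbors, average expression over
sliding windows of the ordered list, and do the statistics on the windowed
profiles, where uncorrelated noise has been averaged down but module-level
signal survives.

## The method in brief

**Seriation.** With the association matrix written in list coordinates
($A_{ij} = 1$ when the genes at positions $i,j$ are associated), the
ordering minimizes

$$F = \sum_{i<j} A_{ij}\,|i-j|^{\alpha} + \beta \sum_{i,j}\big(|A_{i,j}-A_{i+1,j}| + |A_{i,j}-A_{i,j+1}|\big)$$

by simulated annealing (Metropolis swaps; initial temperature $10^{-4}$ of
the starting cost, halved every 100 Monte Carlo steps; incremental
$\Delta F$ evaluation). Ordering quality is diagnosed with the occupation
fraction $\gamma(d)$ (fraction of association partners at list distance
$d$) and the window modularity $M_i(r)$ (fraction of window-touching
associations that stay inside the window).

**Profiling.** The transcriptogram of a sample assigns to each position the
coverage-masked average of expression over the window of radius $r$
($w = 2r+1$ positions, truncated at the ends). On top of that sit class
averages, relative profiles against a reference class, gene-set projection
profiles, a variance decomposition into technical and biological
components, per-position Welch tests with Bonferroni and BH/Storey FDR
control, contrast-to-noise summaries, and Lin's concordance correlation for
between-laboratory reproducibility.

A planted-module network generator and a three-component expression
simulator (signal + biological deviation + technical noise, with a
within-cluster correlation knob) make every stage testable offline.

## Worked example

```r
library(xgram)

pl  <- make_planted_network(n_clusters = 6, cluster_size = 25,
                            p_in = 0.5, p_out = 0.01, seed = 42)
sim <- make_expression(pl$labels, conditions = c("control", "treated"),
                       n_b = 4, n_a = 3, sigma_b = 0.3, sigma_xi = 0.5,
                       delta = 0.4, seed = 43)

fit <- anneal_ordering(pl$network, alpha = 1, seed = 44)
glance(fit)
#> # A tibble: 1 × 8
#>       n alpha  beta f_init f_best n_mcs final_temperature  seed
#>   <int> <dbl> <dbl>  <dbl>  <dbl> <int>             <dbl> <int>
#> 1   150     1     1  57075  16049  1110           0.00279    44
```

The annealer cut the cost from 57,075 to 16,049 in 1,110 Monte Carlo
steps. After ordering, 90.7% of association mass sits within list distance
25 (`sum(gamma_profile(pl$network, fit$ordering)$gamma[1:25])`), i.e. the
planted modules are contiguous on the list. Comparing the two conditions
on windowed profiles:

```r
tg   <- transcriptogram(sim$expression, fit$ordering, r = 20)
des  <- sim$design
wide <- tidyr::pivot_wider(tg[c("position", "sample", "value")],
                           names_from = "sample", values_from = "value")
cmp  <- welch_compare(as.matrix(wide[des$sample[des$condition == "control"]]),
                      as.matrix(wide[des$sample[des$condition == "treated"]]),
                      family_alpha = 0.01)
glance(cmp)
#> # A tibble: 1 × 6
#>   n_positions family_size bonferroni_threshold n_bonferroni n_q05   pi0
#>         <int>       <int>                <dbl>        <int> <int> <dbl>
#> 1         150         150            0.0000667           41   100 0.451
```

41 positions pass the Bonferroni threshold $0.01/150 = 6.7\times10^{-5}$.
They fall on the two truly shifted clusters (4 and 6 in this simulation)
plus their immediate list neighbors — windows of radius 20 bleed across
the boundaries of 25-gene clusters, which is the expected cost of window
smoothing. The per-gene shift here (0.4 log2 units against total SD
$\sqrt{0.3^2+0.5^2} \approx 0.58$) is hard to see gene by gene; the
windowed test recovers it as two contiguous significant stretches.

`autoplot(fit)`, `autoplot(cmp)`, `plot_class_profiles()` and
`plot_term_profiles()` give the standard figures; `tidy()`/`glance()` work
on all fitted objects. A command-line front end over the same functions is
in `inst/exec/xgram.R` (`order`, `diagnose`, `profile`, `project`,
`compare`, `simulate`).

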