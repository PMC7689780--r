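# psfsignal

Phylogenetic signal in plant–soil feedbacks: hierarchical Bayesian
measurement-error models of how feedback dissimilarity changes with
divergence time, ranked by PSIS-LOO.

## The problem

Plants cultivate soil microbiota that feed back on plant performance. A
pairwise feedback experiment grows two species, A and B, in soil cultivated
by each, giving four biomass means. The **dissimilarity response**

```
r = ln(A_a / B_a) − ln(A_b / B_b)
```

is 0 when the two species respond identically (proportionally) to the two
soil communities, and grows in magnitude as their responses diverge; with
conspecific performance in the left numerator, positive r is positive
feedback. Its sampling variance is the delta-method log-response-ratio
variance `Σ (SE/mean)²`.

The package is for ecologists and evolutionary biologists who want to ask,
across a compilation of such experiments: is there a phylogenetic signal in
feedback outcomes, and is it a **directional trend** (mean r drifts with
phylogenetic distance t), **gradual Brownian divergence** (normal responses,
variance `σ² + k·t`), **heavy-tailed divergence** (Student-t responses with
distance-varying degrees of freedom `ν + k·t`, i.e. occasional major
co-evolutionary shifts), and/or **family-level shifts** (`α_f` terms for
plant family pairs)? Seven nested models (`model_spec(1:7)`) encode those
hypotheses on top of a common measurement hierarchy

```
r_ij ~ Normal(r*_ij, σ²_rij),   r*_ij ~ Normal(r*_j, σ²_w),
```

are fitted by MCMC (JAGS) with weakly-informative priors, and compared by
Pareto-smoothed importance-sampling leave-one-out cross-validation on the
deviance scale (ΔLOO > 10 read as decisive).

## Worked example

Everything runs on synthetic compilations with known truth, so the example
is self-contained:

```r
library(psfsignal)

# a study-scale synthetic compilation: 470 species pairs, 165 species,
# 39 families, heavy-tailed divergence with a slight negative trend
sim   <- simulate_pairs(simulation_config(seed = 1))
tab   <- filter_whole_soil(sim$table)
pairs <- assemble_pairs(tab)
pairs
#> psf_pairs: 987 feedbacks, 470 unique species pairs, 165 species, 39 families
#> phylogenetic distance: 10-799 Myr; replicates per pair: 1-11

fits <- lapply(c(1, 3, 5), function(m)
  fit_model(m, pairs, chains = 2, iter = 2000, burn_in = 500, seed = 1))
compare_models(fits)
#>   model   summary                                          loo    delta_loo
#> 1 model 5 Co-evolutionary shifts without directional trend 1512.0 0.0
#> 2 model 3 Gradual divergence without directional trend     1517.6 5.6
#> 3 model 1 Constant variance without directional trend      1518.4 6.4
```

The heavy-tailed divergence model (5) comes out on top, ahead of the
Brownian (3) and no-signal (1) models. The margins are single-digit LOO
units: the default generating conditions deliberately encode a *subtle*
signal — a slight trend and slowly growing kurtosis, the regime the method
is meant for — and at this scale that is what honest model comparison
looks like. Crank up the generator's `k` (or drop `nu`) and the gaps grow
decisive (`delta_loo > 10`). `posterior_summary(fit)` gives
means and 95% credible intervals (β and k are rates per 100 Myr);
`plot_dissimilarity()`, `plot_model_fit_density()` and
`plot_family_effects()` draw the standard figures;
`run_analysis(config)` does the whole read → filter → assemble → fit →
compare → report pipeline from one (YAML-able) config, deterministically in
its seed.

Real compilations are read with `read_compilation(path, mapping)`, where
the column mapping adapts any CSV dialect to the canonical fields.

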