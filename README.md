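# coralnet

Resistance and robustness analysis of coral–symbiont association networks.

Coral bleaching — the breakdown of the association between a coral host and
its Symbiodiniaceae endosymbionts — can be modelled as a perturbation on a
bipartite ecological network: host nodes are geographically distinct coral
species, symbiont nodes are ITS2 types, and every curated association is a
link. `coralnet` builds these networks from association tables, assigns
thermal tolerances τ ∈ [0, 1] to both partners (hosts from Bleaching
Resistance Index values, τ_host = 1 − BRI/100; symbionts from
thermal-tolerance rank scores, τ_symbiont = √rank/10), and gives every link
an absolute temperature threshold

    W_{h,s} = T_MMM + T_Δ · (τ_symbiont + τ_host) / 2

where T_MMM is the mean monthly maximum sea surface temperature of the
host's subregion and T_Δ (3.0 °C) is the upper thermal limit of the
association. Ramping temperature breaks links as their thresholds are
exceeded; a host is *bleached* once isolated. From the resulting response
curves the package computes:

* **Resistance** `R = (T_90% − T_10%) / T_Δ` — the normalized temperature
  rise taking the network from 10% to 90% of hosts bleached;
* **Ecological robustness** `R50` — the fraction of links or nodes that
  must be removed (under five attack models: random links, bleaching order,
  susceptible links by holobiont/host/symbiont tolerance, random nodes,
  susceptible nodes) for the surviving nodes to fall to half the original
  count, with secondary isolations counted as losses;
* four **null networks** (shuffled tolerances, uniform-random tolerances,
  degree-conserved rewiring, non-degree-conserved random bipartite) that
  separate the roles of physiology and structure; and
* **randomization tests** with significance-letter groupings for comparing
  simulation ensembles.

A synthetic-data generator (`synth_bundle()`) produces association records,
climatology, and tolerance tables with the statistical structure the
analysis assumes — a heavy-tailed symbiont degree distribution with planted
generalist hubs, subregional T_MMM values, BRI-like host tolerances, a
three-class symbiont tolerance mixture, and a configurable fraction of taxa
left out of the tables to exercise imputation — so the entire pipeline is
testable without external data.

The package is tidyverse-native: functions take and return tibbles, results
have `tidy()`/`glance()` methods and `autoplot()` displays, and everything
chains with the pipe.

## Worked example

```r
library(coralnet)

bundle <- synth_bundle("global-like", seed = 42)  # 685 hosts, 250 symbionts
net <- bundle_network(bundle)                     # build + tolerance plan
network_summary(net)
#> # A tibble: 1 × 8
#>   n_nodes n_hosts n_symbionts n_species n_links mean_degree ...
#> 1     935     685         250       362    1697        3.63

r_nat <- resistance_ensemble(net, replicates = 100, seed = 1)
r_nat
#> <resistance_result> natural network, 100 replicates
#>   R = 0.818 ± 0.019
r_uni <- resistance_ensemble(net, replicates = 100, seed = 2,
                             null = "random_tolerance")
r_uni
#> <resistance_result> random_tolerance network, 100 replicates
#>   R = 0.913 ± 0.033

tidy(compare_ensembles(list(natural = r_nat, random_tolerance = r_uni),
                       n_perm = 999, seed = 3))
#> # A tibble: 2 × 5
#>   group                n  mean     sd letters
#> 1 natural            100 0.818 0.0189 a
#> 2 random_tolerance   100 0.913 0.0332 b

robustness_ensemble(net, "random_links", replicates = 100, seed = 4)
#> <r50_result> random_links, 100 replicates
#>   R50 = 0.675 ± 0.012
robustness_ensemble(net, "bleaching", replicates = 100, seed = 5)
#> <r50_result> bleaching, 100 replicates
#>   R50 = 0.552 ± 0.005
```

Reading the numbers: flattening the natural tolerance distribution to a
uniform one makes the network significantly *more* resistant (0.913 vs
0.818; distinct letters at α = 0.05) — the natural tolerance assignment is
a weakness, not a strength. And the network weathers random link loss
(R50 = 0.675) much better than the environmentally ordered bleaching attack
(R50 = 0.552): removing the associations in threshold order is a targeted
attack on the system's weak flank.

`run_coral_pipeline()` orchestrates the full analysis — build, tolerances,
nulls, bleaching, robustness, comparisons — across the global network and
its regional and subregional subsets (locations with fewer than 40 links
are excluded from simulation), with one master seed driving documented
substreams so reruns are bit-identical.

## Documentation

The methods vignette (`vignettes/coral-symbiont-networks.Rmd`) describes
the model and its assumptions, the imputation and null-model conventions,
the synthetic generator's design and its limits, and the package's
numerical choices.
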