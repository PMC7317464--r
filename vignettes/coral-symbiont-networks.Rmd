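---
title: "Resistance and robustness of coral-symbiont association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistance and robustness of coral-symbiont association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralnet)
library(dplyr)
```

## The model

Coral bleaching is the breakdown of the association between a coral host and
its endosymbiotic dinoflagellates (family Symbiodiniaceae). `coralnet`
represents the set of known associations as a bipartite network: host nodes
are geographically distinct coral species (the same species sampled in two
subregions is two nodes, each carrying its local environment) and symbiont
nodes are Symbiodiniaceae ITS2 types, one node per type worldwide. Every
curated association record becomes one undirected link.

Each node carries a dimensionless thermal tolerance $\tau \in [0, 1]$:

* **Hosts.** The Bleaching Resistance Index (BRI) of a species is the
  percentage of bleached tissue expected under heat stress; tolerance is its
  complement, $\tau_\mathrm{host} = 1 - \mathrm{BRI}/100$.
* **Symbionts.** Rank-aggregated thermal-tolerance scores order ITS2 types
  from 0 to 100 but are not magnitude-calibrated, so the scale is compressed
  before rescaling: $\tau_\mathrm{symbiont} = \sqrt{\mathrm{rank}}/10$.

Each link is assigned an absolute temperature threshold

$$W_{h,s} = T_\mathrm{MMM} + T_\Delta \,\frac{\tau_\mathrm{symbiont} +
\tau_\mathrm{host}}{2},$$

where $T_\mathrm{MMM}$ is the mean monthly maximum sea surface temperature of
the *host's* subregion (the packaged climatology in
`subregion_environment()`) — corals are expected to begin bleaching once
temperatures exceed this baseline — and $T_\Delta$ (default 3.0 °C) is the
upper thermal limit of the association above it. The two tolerances are
averaged because the evidence does not settle which partner fails first; the
holobiont is treated as the unit of tolerance.

The **bleaching model** ramps temperature upward. A link breaks when the
ramp reaches its threshold ($T \ge W$, a closed threshold; ties break
simultaneously), and a host is *bleached* once it is isolated — it has no
remaining symbiont alternatives. Because the bleached fraction can only
change when some host loses its last link, the sweep is event-driven: the
exact curve is a step function with breakpoints at the per-host maxima of
$W$, and `simulate_bleaching()` computes it directly rather than walking a
temperature grid. A property test checks this event form against a naive
fine-grid ramp.

## The two metrics

**Resistance** summarizes a bleaching curve: the temperature rise taking the
network from 10% to 90% of hosts bleached, normalized by the maximum
possible excursion for that range,

$$R = \frac{T_{90\%} - T_{10\%}}{T_\Delta}.$$

Crossings use the first-passage convention on the event step function
(first breakpoint at which the fraction meets or exceeds the threshold),
not interpolation: bleaching is a discrete per-host isolation event. For a
network confined to one subregion every $W$ lies in
$[T_\mathrm{MMM}, T_\mathrm{MMM} + T_\Delta]$, so $R \le 1$; multi-region
networks can exceed 1 because their subregional baselines separate the
curves along the temperature axis. $R$ is computed per simulation replicate
and then averaged (each replicate has its own imputation draws), rather
than once on the ensemble-mean curve; the mean curve smooths the steps and
would bias the crossing temperatures.

**Ecological robustness** treats an attack as a stepped perturbation.
`removal_order()` implements five attack models — random links, bleaching
order (links ascending by $W$), susceptible links (ascending by the
averaged, host-only, or symbiont-only tolerance), random nodes, and
susceptible nodes (hosts and symbionts pooled, ascending by tolerance) —
and `removal_trajectory()` tracks the nodes remaining after every removal.
A node "remains" while it keeps at least one link, for *both* attack
classes: secondary isolations count as losses, which puts link and node
attacks on one comparable axis (the food-web robustness convention). The
fraction-removed axis counts primary removals over the original entity
count. $R_{50}$ is the smallest fraction removed at which the surviving
nodes fall to half the original count. Ties in any ordering are broken by
an independent uniform shuffle, fresh per replicate, so a zero ensemble
spread occurs only when the order is genuinely forced.

## Tolerance sources, imputation, and replicates

Measured tolerances come from the host BRI table and the symbiont rank
table. Taxa absent from the tables are imputed:

* **Hosts** draw a BRI from a normal distribution parameterized by the
  closest listed relative group — congeners first (matched on the genus part
  of the binomial), then confamilials, then all listed species — clamped to
  $[0, 100]$ rather than redrawn, which preserves the stated normal draw
  while guaranteeing the unit-interval invariant. For a group the donor
  mean is the mean of the members' BRI means and the donor sd pools the
  within-species variances with the between-species variance. If the host
  table is entirely empty an uninformative mid-scale donor (mean 50,
  sd 25) is used so that fully synthetic runs still work.
* **Symbionts** draw a tolerance class (high / medium / low) with
  genus-specific mixing proportions, then a rank score from that class's
  distribution. The packaged default (`default_class_model()`) uses normals
  truncated to $[0, 100]$ with means 75 / 45 / 15 and sd 10, and genus
  proportions that weight *Durusdinium* toward the high class and
  *Cladocopium* toward low/medium. The empirical class frequency
  distributions behind the published analysis are not reproducible from the
  available text, so these defaults are explicit, plain-data stand-ins meant
  to be overridden when empirical shapes are available.

`tolerance_plan()` resolves every node once; `realize_tolerances()` draws
one replicate's values. Measured tolerances are replicate-invariant; imputed
symbiont tolerances are redrawn every replicate. The redraw convention for
imputed *host* tolerances is not settled by the source material, which
states per-replicate variation only for symbionts; the package redraws
hosts per replicate as well, for symmetry, and `host_impute_once = TRUE`
freezes them so both readings are testable.

## Null networks

Four controls separate physiology from structure, each answering one
question:

* `null_shuffled_tolerance()` — permute tolerances within each node class
  (multisets preserved exactly; a with-replacement option exists because
  "drawn from the original distribution" admits both readings).
* `null_random_tolerance()` — iid Uniform(0, 1) tolerances.
* `null_rbdc()` — degree-conserved rewiring by bipartite double-edge swaps
  (default $10L$ attempted swaps), then shuffled tolerances. Swaps are used
  instead of stub matching to guarantee a simple graph at every step.
* `null_rbndc()` — a uniformly random simple bipartite graph with the same
  host count, symbiont count, and link count, then shuffled tolerances.
  A fixed-link-count generator was chosen over a fixed-probability one so
  the null conserves $L$ exactly. Host nodes keep their subregion and
  thus their $T_\mathrm{MMM}$ — the bleaching model needs an environment
  for every host.

Inside the ensembles a null is applied to each realized replicate, so the
ensemble spread reflects both the tolerance draws and the randomization of
the null itself, rather than freezing one arbitrary null instance.

## Randomization tests

Ensembles are compared with a two-sided randomization test: pool the two
replicate vectors, relabel `n_perm` times (default 9,999), and compare
$|\bar a - \bar b|$ against the permuted differences with the add-one
correction. Pairwise outcomes at $\alpha = 0.05$ are summarized as
significance letters via a greedy clique cover (groups sharing a letter are
pairwise non-significant). No multiple-testing correction is applied by
default, matching the letters-per-pair display convention; a Holm option is
available. The test statistic and permutation unit are a re-specification —
the original procedure's details are not in the available text — so the
simplest defensible randomization test is used and documented as such.

## The synthetic-data generator

`synth_bundle()` generates mutually consistent association records,
environment, tolerance tables, and taxonomy, plus the complete ground truth
of every drawn parameter. It emulates the features the analysis assumes:

* a sparse bipartite network with few generalist symbiont hubs and many
  specialists — symbiont degrees follow a discrete truncated power law
  ($p(k) \propto k^{-1.4} e^{-k/35}$, chosen so the non-hub mean degree
  matches the global network's marginals) with three planted *Cladocopium*
  hubs of degree ≥ 140, while host degrees are low and light-tailed;
* hosts partitioned into the 14 packaged subregions with the published
  host and link counts per subregion, 685 host nodes drawn from a pool of
  362 species, 250 symbiont types, and 1,697 links in the global-like
  preset — so the construction pipeline can be checked against the
  published marginals end to end;
* host BRI means from a normal centred at 40 (sd 20, truncated to
  $[0,100]$) and symbiont ranks from the three-class mixture;
* a configurable unlisted fraction (default 25% of species and of ITS2
  types) withheld from the tolerance tables to exercise both imputation
  paths.

Degree sequences are drawn independently for the two sides and are then
wired by a Havel–Hakimi-style construction (each host, largest first,
connects to the symbionts with the most remaining stubs), which realizes
any jointly graphical pair of sequences as a simple graph; the
deterministic wiring is randomized by degree-preserving double-edge swaps,
and non-graphical draws are rejected and redrawn. The per-subregion link
totals are hit exactly by random unit adjustments of the drawn degrees.

What the generator does **not** emulate: real species and ITS2 labels,
nestedness and modularity of the real wiring beyond what the degree
sequences induce, correlations between a taxon's tolerance and its degree
or geography, and the real (unpublished) class frequency shapes. Tests that
pass on synthetic bundles therefore validate the machinery and the
qualitative orderings (e.g. link attacks are better tolerated than node
attacks; the uniform-tolerance null is the most resistant), not the
published point values, which require the curated data deposit and the
tolerance meta-analysis tables as inputs.

## Numerical and design choices

* **Connectance** is reported in both circulating conventions —
  $L/(\mathrm{hosts}\times\mathrm{symbionts})$ and $L/N^2$, which do not
  agree with each other — labelled, and used for nothing downstream.
* **Degree-distribution fits** (`fit_degree_distribution()`) are discrete
  maximum-likelihood fits of power-law, truncated power-law, and
  exponential models ranked by AIC, with normalizing constants computed by
  direct summation over a large finite support. Purely descriptive.
* **Seeds.** One master seed spawns per-stage, per-replicate substreams via
  integer hashing (`substream_seed()`), so adding a stage or replicate never
  perturbs the draws of another, and every ensemble is bit-reproducible.
* **Degenerate inputs.** Empty networks summarize to zeros with undefined
  connectance; a curve that never reaches 90% bleached makes resistance an
  explicit error (and such replicates are excluded from ensembles, counted
  and warned about); a wiring too constrained to swap returns the input
  with a warning.
* **Scope filtering.** Locations with fewer than 40 links are excluded from
  resistance/robustness simulation by default (`min_links`), following the
  published analysis convention.
* **Problem sizes.** The examples and the test suite run ensembles of 5–100
  replicates on networks of tens to ~935 nodes; the full pipeline at 100
  replicates on the global-like preset completes in about a minute on one
  core because both the bleaching sweep and the removal trajectories are
  computed in closed form per replicate ($O(L \log L)$), not by stepwise
  graph mutation.

## Worked example

```{r example, eval = FALSE}
bundle <- synth_bundle("global-like", seed = 42)
net <- bundle_network(bundle)
network_summary(net)

r_nat <- resistance_ensemble(net, replicates = 100, seed = 1)
r_uni <- resistance_ensemble(net, replicates = 100, seed = 2,
                             null = "random_tolerance")
compare_ensembles(list(natural = r_nat, random_tolerance = r_uni),
                  n_perm = 999, seed = 3)

r50_links <- robustness_ensemble(net, "random_links", replicates = 100, seed = 4)
r50_bleach <- robustness_ensemble(net, "bleaching", replicates = 100, seed = 5)
```

## Known limitations

* ITS2 types mask within-type diversity and host specificity; one node per
  type is a modelling convention inherited from the data, not a biological
  claim.
* Temperature is the only stressor; irradiance, flow, and degree-heating
  accumulation are out of scope, as are adaptive rewiring and recovery
  (resilience).
* The published point values of resistance and $R_{50}$ for the real
  network can only be reproduced with the curated association deposit and
  the host/symbiont tolerance tables supplied as inputs; the package ships
  neither, and its synthetic preset matches the real network's marginals
  but not its full wiring or tolerance-to-node assignment.
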