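# trophicmotifs

Tools for analysing the structure of directed **food webs** — networks in
which nodes are species and links point from prey to predator — and for
explaining their local wiring patterns through a single global property:
**trophic coherence**.

The package is aimed at ecologists and network scientists who work with
empirical food-web edge lists and want to (i) quantify how layered a web is,
(ii) score which three-species interaction patterns (motifs) are over- or
under-represented relative to a degree-preserving null model, (iii) compare
and cluster webs by those motif profiles, and (iv) generate synthetic webs
with a tunable degree of coherence for model-based inference.

## The quantities it computes

**Trophic levels and incoherence.** Each species' trophic level is one plus
the mean level of its prey,

    s_j = 1 + (1/k_in_j) * sum_i a_ij s_i,

with `s = 1` on basal species (zero in-degree). Every link has a trophic
distance `x_ij = s_j − s_i`; its distribution has mean 1 identically, and
its standard deviation

    q = sqrt(<x^2> − 1)

is the *trophic incoherence parameter*: `q = 0` is a perfectly layered web,
large `q` means widespread cross-level feeding (omnivory).

**Triad significance profiles (TSP).** The 13 connected three-node triads
(`S1`–`S5` with single links — food chain, omnivory/feed-forward, cycle,
apparent and direct competition — and `D1`–`D8` containing mutual
predation) are counted as induced subgraphs and scored against an ensemble
of degree-preserving edge-swap randomizations:

    z_k = (N_k − <N_k>_rand) / sigma_rand,

normalized to unit length for cross-web comparison. Webs are compared by the
Pearson correlation `r` of their normalized profiles, converted to the
metric distance `d = sqrt(2(1 − r))`, and clustered into **motif families**
by UPGMA with a threshold cut.

**A generative model with tunable coherence.** Webs are assembled by
preferential preying: `B` basal nodes, then `N − B` nodes that each pick one
prey at random, then extra links laid down with probability

    P_ij ∝ exp(−(x̂_ij − 1)^2 / (2 T^2)),

normalized so the expected link count is `L`. The temperature `T` tunes the
incoherence of the generated webs from `q = 0` (at `T = 0`) upward, and can
be calibrated to an empirical `q` by stochastic root finding
(`gppm_fit()`). The model reproduces the empirically observed split of food
webs into an omnivory-poor and an omnivory-rich family, with a critical
temperature separating the two regimes (`gppm_s2_transition()`).

## Worked example

```r
library(trophicmotifs)

# a tiny omnivory motif: basal -> mid -> top plus basal -> top
tri <- make_toy("omnivory-triangle")
trophic_incoherence(tri)
#> Trophic profile: 3 species, 3 links
#>   levels in [1.000, 2.500]; mean trophic distance 1.000000
#>   incoherence q = 0.4082
```

The levels are 1, 2 and 2.5 (the top predator eats prey at levels 1 and 2),
the three link distances are 1, 1.5 and 0.5 — mean exactly 1 — and their
spread gives `q = sqrt(1/6) ≈ 0.41`: mild omnivory.

```r
d <- gppm_generate(B = 5, N = 40, L = 160, T_ = 0.4, seed = 3)
d
#> Preferential-preying draw: B=5 N=40 target L=160 T=0.4 -> 155 links
round(trophic_incoherence(d$web)$q, 4)
#> [1] 0.2964

triad_significance(d$web, ensemble_size = 50, seed = 2)
#> Triad significance profile (plain null, 50 randomizations)
#>    count null_mean null_sd     z  z_hat
#> S1   442    308.28   25.87  5.17  0.455
#> S2    24     55.74    8.20 -3.87 -0.341
#> ...
```

A moderately coherent model web (`q ≈ 0.3`) shows the signature of the
coherent food-web family: chains (S1) and competition triads (S4, S5)
over-represented, the omnivory triad (S2) under-represented.

```r
regress_q_on_basal_ratio(food_web_summaries())
#> q = -1.053 (B/N) + 0.765   [n = 46, R^2 = 0.532, p = 8.9e-09]
```

Across 46 published webs, incoherence is strongly anti-correlated with the
fraction of basal species.

A command-line front end wrapping these functions is shipped at
`inst/cli/trophic-motifs.R` (subcommands `coherence`, `tsp`, `compare`,
`gppm simulate|fit|transition`, `fixtures`, `pipeline`).

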