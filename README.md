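# regnet

Tools for analysing literature-curated transcriptional regulatory maps —
directed networks of transcription factor (TF) → target regulations with
activation/repression modes and publication evidence, of the kind built for
*Arabidopsis* from decades of small-scale experiments.

Curated maps raise a recurring set of questions that this package answers
with one consistent, tested toolchain:

* **Is the map any good?** The fraction of regulator–target pairs that share
  a biological-process annotation, compared against a baseline network with
  a one-tailed exact binomial test, plus recall of an independently
  summarized reference pathway.
* **How do functional subnetworks differ?** Global topology of induced
  subnetworks — targets per TF, regulators per target, characteristic
  directed path length, global clustering coefficient — with an
  edge-subsampling procedure (50–90 % of regulations, many replicates) to
  show the contrasts are robust.
* **Which wiring patterns are over-represented?** A full three-node triad
  census over the 13 weakly connected classes, compared against
  degree-preserving edge-switch null ensembles. A class is a *network
  motif* when `z = (N_obs − ⟨N_rand⟩)/σ_rand ≥ 2`, its empirical
  `p = (1 + #{N_rand ≥ N_obs})/(1 + n_rand) ≤ 0.01`, and it occurs at least
  4 times.
* **How is the map organised?** Markov clustering (expansion–inflation
  iteration on the symmetrized stochastic matrix) into communities, labeled
  by their dominant process term.
* **What distinguishes evolutionarily novel TFs?** Families dated
  ancient/novel from a presence–absence profile across green algae and land
  plants; binding specificity scored as position-weight-matrix information
  content, `IC = Σ_j (2 + Σ_b p_bj log₂ p_bj)` bits; and a battery of
  one-tailed Fisher/Wilcoxon tests for whether novel-family TFs prefer
  developmental processes, TF targets, and particular motifs — including
  the Spearman correlation between IC and the per-TF fraction of targets
  that are TFs.
* **What can those motifs do?** Hill-kinetics ODE models
  (`dx_i/dt = b + β·Π act·Π rep − α·x_i`, AND input integration) of ≤3-node
  circuits: stable-state enumeration from a grid of initial conditions and
  pulse-driven transitions between states (the classic bistable toggle
  switch is the benchmark).

Synthetic generators (`gen_network()`, `gen_annotations()`, `gen_pwms()`,
`gen_presence()`, `gen_ic_wired_network()`, `plant_motifs()`) produce inputs
with planted, known structure at the scale of the curated *Arabidopsis* map
(388 TFs, 47 families, ~1,400 regulations), so every stage is testable
without downloads.

## Worked example

```r
library(regnet)

net <- gen_atrm_like(seed = 1)   # synthetic map at curated-map scale
glance(net)
#> # A tibble: 1 × 9
#>   genes   tfs families regulations evidence_ids activation repression  dual
#> 1   788   388       47        1330         1330        813        517     0

ann <- gen_annotations(net, q = 0.6, n_terms = 10, seed = 2)
coannotation_quality(net, ann, baseline = c(300, 1000))
#> <reg_quality> 807/1330 co-annotated pairs (60.7%)
#>   vs baseline 30%: p = 4.11e-118

enr <- motif_enrichment(net, n_random = 200, seed = 3)
dplyr::filter(enr, observed > 0)
#> # A tibble: 5 × 6
#>   class_id name              observed null_mean z_score empirical_p
#> 1        1 fan-out              34123  33980.     1.18       0.0995
#> 2        2 cascade               2067   1919.     1.17       0.119
#> 3        4 fan-in                 918    912.     0.326      0.393
#> 4        5 feed-forward loop      132    129.     0.152      0.463
#> 5        9 three-node cycle         2      1.25   0.689      0.343
```

60.7 % of regulations are co-annotated versus the 30 % baseline — the
planted rate, recovered, with an overwhelming binomial p-value. No triad
class is flagged as a motif here because the preset generator wires edges
without planted patterns; `plant_motifs()` adds instances that
`motif_enrichment()` then detects (see the vignette). Results are tibbles
throughout, so they pipe straight into dplyr/ggplot2; fitted objects have
`tidy()`/`glance()`/`autoplot()` methods.

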