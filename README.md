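# retinacomm

Intercellular-communication analysis for retinal ganglion cell (RGC)
survival. After optic nerve injury, some transcriptomic RGC subclasses
(ipRGCs, αRGCs, Gpr88⁺ RGCs) survive far better than others, and part of
that resilience appears to come from the signals other retinal cells send
them. `retinacomm` implements the computational side of that question as a
tested, reusable R pipeline: given a multi-cell-type expression atlas
sampled over an injury time course, it scores ligand–receptor
communication toward each RGC subclass, detects sender↔receiver feedback
loops through signalling/regulatory networks, and asks which interactions
are systematically stronger toward the subclasses that live.

It is written for computational biologists analysing single-cell or
single-nucleus RNA-seq of injured neural tissue, and for anyone who wants
a fully synthetic, ground-truthed test bed for differential cell–cell
communication methods.

## The model

For a ligand–receptor pair (L, R), a sender cell type and a receiver
group at time point *t*, the interaction score is

    S_LR(sender, receiver, t) = sqrt( ℓ · r ),

where ℓ and r are the mean normalized (counts-per-10k, log1p) expressions
of L in the sender and R in the receiver, each min–max scaled to [0, 1]
per gene across all (cell group, time point) means of the dataset.
Feedback support multiplies the score: if receptor signalling in the
receiver can reach a back ligand L₂ (a directed path R → … → L₂ of at
most 4 edges in the receiver's active subgraph) whose receptor R₂ sits on
the original sender, then

    S_LR ← min(1, S_LR · (1 + β · max over loops of back-pair score)),

with β = 0.5 by default. Pairs are kept when both genes are detected in
≥ 10 % of their cell type and the score reaches ≥ 0.5 at some time point.

The differential statistic contrasts high- versus low-survival receiver
subclasses:

    D_SLR = mean over high subclasses of max_t S_LR
          − mean over low  subclasses of max_t S_LR,

with D_SLR > 0.25 called **protective** and D_SLR < −0.25 **depleted**.
Protective interactions are further classified as **preset** (already
stronger toward high-survival subclasses before injury) or **induced**
(advantage appears only after injury), and score trajectories can be
screened for variability (fold change > 1.2 between any two time points)
and clustered into temporal groups.

Also included: the standard scRNA-seq QC filters (nUMI, nGene,
mitochondrial rate, log10GenesPerUMI, gene detection breadth) with the
published threshold presets, marker-based cell type assignment,
cross-dataset compatibility checks, survival-normalized subclass
composition (adjusting within-sample percentages by externally measured
total survival rates), and the RNAscope dot-quantification formulas
(background-corrected average intensity per dot and total dot number)
on intensity images.

## Worked example

The package ships a synthetic-atlas generator whose defaults define a
complete study: 6 sender cell types, 6 RGC subclasses (3 high-, 3
low-survival), 4 time points (sham, 12 h, 24 h, 48 h), and 6 planted
protective interactions (3 preset, 3 induced, 4× expression boost toward
the high-survival subclasses) hidden among 50 decoy pairs.

```r
library(retinacomm)
res <- run_pipeline(list(seed = 1), out_dir = "demo_out")
head(res$differential[res$differential$call == "protective", ], 6)
```

```
      sender ligand receptor mean_high mean_low  dslr       call
1   Amacrine  g0525    g0519     0.976    0.411 0.565 protective
2   Amacrine  g0526    g0520     0.532    0.234 0.298 protective
15 Astrocyte  g0527    g0521     0.967    0.516 0.451 protective
16 Astrocyte  g0526    g0520     0.569    0.207 0.363 protective
17 Astrocyte  g0525    g0519     0.502    0.221 0.280 protective
36   Bipolar  g0524    g0518     0.960    0.496 0.464 protective
```

`mean_high`/`mean_low` are the subclass-averaged max-over-time scores;
every planted pair surfaces with D_SLR well above the 0.25 cutoff. The
non-redundant aggregate collapses these across senders:

```r
head(res$aggregate, 4)
```

```
  ligand receptor best_dslr n_senders                              senders
1  g0525    g0519     0.565         4 Amacrine,Astrocyte,Bipolar,Microglia
2  g0526    g0520     0.540         4 Amacrine,Astrocyte,Bipolar,Microglia
3  g0523    g0517     0.503         3      Bipolar,Microglia,Photoreceptor
4  g0528    g0522     0.490         3     Bipolar,MullerGlia,Photoreceptor
```

and `res$preset_induced` recovers each planted pair's dynamics, e.g.
`Microglia g0526–g0520: pre_diff 0.62 → preset`, `Amacrine g0525–g0519:
pre_diff −0.01, post_diff 0.57 → induced`.

FISH quantification works the same way from planted images:

```r
q <- quantify_dot_field(generate_dot_image(20, seed = 1)$field)
c(q$n_dots_detected, q$total_dot_estimate, q$avg_per_dot)
#> 20 20 450
```

and survival-normalized composition:

```r
normalize_by_survival(c(ipRGC = 120, alphaRGC = 80, other = 300), 0.638)
#>   subclass count raw_pct adjusted_pct
#> 1    ipRGC   120      24         15.3
#> 2 alphaRGC    80      16         10.2
#> 3    other   300      60         38.3
```

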