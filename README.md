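# mitonet

Network analysis of quantitative mitochondrial proteomics under
mitochondrial DNA depletion.

When a cell line is depleted of its mitochondrial DNA (a ρ0 line, obtained by
long-term ethidium bromide exposure) and compared with its parental ρ+ line,
quantitative proteomics of isolated mitochondria yields one abundance ratio
ρ0/ρ+ per identified protein. The biological questions are systemic: which
proteins reliably belong to the mitochondrial proteome, how do up- and
down-regulated proteins organise within the protein functional-association
network, which functional modules change coherently, and how do protein
changes relate to the transcriptome? `mitonet` implements that analysis as a
tested, reusable R pipeline, together with a synthetic-world generator that
plants known module, regulation, and concordance structure so every stage can
be validated end to end.

## The analysis

1. **Regulation classification.** Each protein with linear-scale ratio r is
   called *up* if r ≥ 1.5, *down* if r ≤ 0.67 (the conventional printed value
   for a 1.5-fold decrease), *unchanged* otherwise; both boundaries
   inclusive, both thresholds configurable.
2. **Reliability tiering.** A protein is *reference-supported* when it
   carries the mitochondrial cellular-component annotation **and** occurs in
   at least one reference catalog. Remaining proteins are rescued by a single
   hop: a physical (protein–protein interaction) link to a reference protein
   puts them in the *physical* tier, otherwise a functional association puts
   them in the *functional* tier; physical evidence takes precedence so the
   tiers are disjoint. The reliable set is the union of the three tiers.
3. **Functional network.** The simple weighted graph induced on reliable
   proteins by the link table (confidence scores in [0,1], STRING-style);
   analysis proceeds on the largest connected component. Edges are
   *intraregulatory* (up–up or down–down), *interregulatory* (up–down), or
   *other*. Per-protein intra/inter link fractions and unweighted (BFS)
   shortest-path lengths for same-class versus opposite-class pairs are
   compared with a Mann–Whitney U test (mid-rank ties, tie-corrected normal
   approximation with continuity correction, exact permutation for small
   samples).
4. **Module detection.** Average-linkage (UPGMA) agglomeration on the
   confidence-score similarity matrix (absent edge = similarity 0), stopping
   when the best average inter-cluster similarity falls below a cut τ.
   Clusters become functional modules when they pass two one-sided
   hypergeometric tests at α = 0.01: enrichment of some annotation term, and
   enrichment of one regulation class, which also labels the module up or
   down.
5. **Proteome–transcriptome concordance.** The replicated expression matrix
   is detection-filtered (a gene must be detected, p ≤ 0.05, in at least one
   sample of each condition), log2-transformed and quantile-normalized;
   per-gene mRNA log2 ratios are joined with protein log2 ratios and
   partitioned by k-means (k = 5) into up-up, down-down, up-down, down-up and
   unchanged groups, labelled from the centroid geometry. Module-level means
   ± sd of both ratios and cross-platform pattern agreement complete the
   picture.

## Worked example

```r
library(mitonet)

cfg    <- world_config(seed = 42L)          # planted synthetic study
world  <- generate_world(cfg)
report <- run_pipeline(world, pipeline_config(tau = suggest_tau(cfg)))
report
#> Pipeline report
#>   classes: 108 up / 159 down / 395 unchanged of 662
#>   reliable: 662 ( 100 % )
#>   network: 662 nodes / 2651 edges ( 0 excluded )
#>   links: 515 intra / 208 inter ( 71.23 % intra of regulatory )
#>   modules: 13
#> # A tibble: 1 x 9
#>       n n_up_up n_down_down n_up_down n_down_up n_unchanged n_positive ...
#> 1   662      93         107        51       137         274        200
```

Reading this: of 662 simulated proteins, 108/159/395 are classified
up/down/unchanged; every protein ends up reliable in this dense synthetic
world; 71.23% of the regulatory links are intraregulatory (same-class), the
planted tendency of regulated proteins to cluster among themselves; 13
functional modules are detected (the 13 planted ones), and 200 proteins show
positively correlated protein/mRNA changes. Individual stages are ordinary
functions returning tibbles, e.g.

```r
report$modules$modules[1:3, ]
#>   module_id n_members regulation_label regulation_p representative_term   term_p
#> 1 M1               18 up                  0.000126  TERM_MOD02          9.87e-26
#> 2 M2               18 down                0.000121  TERM_MOD07          1.53e-18
#> 3 M3               18 down                0.0000160 TERM_MOD12          1.39e-21

report$path_length_test
#>           U  p_value alternative method                 n_x   n_y
#> 1 148093708 7.34e-27 less        normal_approximation 18339 17172
```

so same-class protein pairs sit significantly closer in the network than
opposite-class pairs. `tidy()`, `glance()` and `autoplot()` methods are
available for the network, cluster, module and concordance objects.

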