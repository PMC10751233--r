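# rarity — rare cell population discovery via binary latent expression signatures

Unsupervised phenotyping of highly multiplexed single-cell protein data
(imaging mass cytometry and similar 10–40-marker panels) has a blind
spot: populations of a few dozen cells that differ from a population a
hundred times larger in only one or two markers get absorbed into their
big neighbours. `rarity` is built for exactly those populations. It is
aimed at analysts of segmented single-cell intensity tables who need
clusters that are *sensitive to rarity* and *readable as marker
patterns*.

## The model

Every marker `g` of every cell `i` is assumed to have a hidden binary
on/off state `z_ig`; the continuous intensity is a draw from a
two-component Gaussian mixture selected by that state:

    z_ig ~ Bernoulli(p),    p = 0.5
    x_ig | z_ig ~ (1 - z_ig) N(mu_off, sigma_off^2) + z_ig N(mu_on, sigma_on^2)

Posterior inference of the states is amortized through an encoder
network trained by stochastic gradient ascent on the ELBO, with the
relaxed-Bernoulli (binary Concrete) reparameterization and an annealed
temperature. Thresholding the posterior probabilities gives each cell a
binary *signature*; cells with identical signatures form a cluster. A
rare population differing in even one marker has its own signature and
cannot be merged away — and every cluster is directly interpretable as
an on/off marker pattern that can be queried (Hamming-ball
neighbourhoods) and gated (marker constraints).

The package also implements the *conditional* clustering metrics used to
evaluate rare-type recovery — conditional completeness
`1 − H(K|C=c)/H(K)`, conditional homogeneity `1 − H(C|K=k*)/H(C)` with
`k*` the focal type's modal cluster, and their harmonic mean (the
conditional V-measure) — plus a calibrated synthetic-data generator and
a downsampling self-consistency benchmark harness with pluggable
clustering backends.

## Worked example

Simulate the reference five-population design (three common types A–C,
two rare types D and E at 0.74% and 0.49% prevalence), fit the model,
and inspect the clusters:

```r
library(rarity)

d <- simulate_reference(seed = 1)
d
#> <cell_dataset> 8100 cells x 7 markers (seed 1)
#>   types: A=4000, B=3000, C=1000, D=60, E=40

fit <- rarity(d, seed = 1)
fit
#> Binary latent signature model (amortized variational mixture)
#>   8100 cells, 7 markers; 200 epochs, final ELBO/cell 2.851
#>   mixture (shared across markers): off ~ N(0.049, 0.032^2), on ~ N(0.502, 0.177^2)
```

The fitted mixture has recovered the generative components (off:
N(0.05, 0.03²), on: N(0.5, 0.18²)). Clustering by signature:

```r
cl <- predict(fit, d, type = "cluster")
cl
#> <signature_clusters> 8100 cells in 24 clusters (P = 7)
#>   cluster size signature
#> 1       1 3690   1111000
#> 2       2 2761   1110100
#> 3       3  899   1111010
#> 4       4  209   1110000
#> 5       5   95   0111000
```

The three largest clusters carry exactly the signatures of A, B and C.
Rare type E appears as its own cluster with its generator signature
`1100000`; how well is it recovered?

```r
conditional_scores(contingency(d$labels, cl$cluster[rownames(d$X)]), "E")
#> Conditional scores for type 'E' (modal cluster '11'):
#>   completeness 0.9167  homogeneity 0.7081  V-measure 0.7990
```

Completeness 0.92: 11/12ths of E's entropy-normalized mass sits in one
cluster. Homogeneity 0.71: the modal cluster is mostly, not purely, E —
a few cells of the big types land on the same signature via single-marker
flips, which is the intrinsic overlap of the generative components, not
an inference failure. Exploring the neighbourhood of cluster 4 (type D's
signature) shows the interpretability layer:

```r
hamming_ball_query(cl, cl$signatures[4, ], radius = 1)
#>   cluster distance size signature
#> 1       4        0  209   1110000
#> 2       1        1 3690   1111000
#> 3       2        1 2761   1110100
#> 4      11        1   42   1100000
#> 5      14        1   20   1110010
#> ...
```

D's signature differs by exactly one marker from A (`1111000`), B
(`1110100`) and E (`1100000`) — the designed hard case for rare-type
detection. Cells can be gated on signatures by marker name:

```r
epi <- select_cells(cl, marker_constraint(colnames(d$X),
                                          on = c("M1", "M2", "M3", "M4"),
                                          off = "M5"))
```

A thin command-line interface wraps the same functions
(`inst/cli/rarity`): `simulate`, `fit`, `assign`, `query`, `select`,
`metrics`, `benchmark`, each accepting `--seed`.

## Scope

Real-tissue analyses (breast-cancer and colon-mucosa panels) require
external data downloads and third-party clustering tools and are out of
scope here; everything the package claims is reproducible offline from
its own generator. See the vignette
(`vignettes/binary-signature-model.Rmd`) for the model's assumptions,
parameter defaults, metric conventions and known limitations.
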