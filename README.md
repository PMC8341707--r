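# TCRdens

Distance-preserving autoencoder embeddings and local density analysis of
T-cell receptor (TCR) repertoires.

## What it does, and for whom

Rep-seq experiments summarize each T-cell clone by its CDR3 amino-acid
sequence, V-gene usage and clone size — three incompatible
representations (strings, categories, counts). TCRdens is for
immunologists and computational biologists who want those components in
**one real-valued space** where geometric questions become tractable:

* How *locally dense* is the repertoire around a given receptor
  (self-density), and around receptors of another sample
  (cross-density)?
* How similar are two repertoire samples as clouds of receptors, and do
  samples cluster by host?
* Can a single clone be assigned to a specificity group or compartment?

The core is a multilayer-perceptron autoencoder over one-hot encoded
CDR3s (21-letter blocks: 20 amino acids + a stop symbol, right
zero-padded to the corpus maximum length, optionally concatenated with a
V-gene one-hot). The encoder maps the $n$-dimensional input to
$z \in \mathbb{R}^{30}$ through fully connected layers
$n \to 300 \to 100 \to 30$ (Elu, dropout 0.1); the decoder mirrors it
with a per-block softmax. Four flavors: **E** (reconstruction MSE only),
**VE** (+V gene), **EM** and **VEM** (+a distance-maintenance loss)

$$\mathcal{L} \;=\; \underbrace{\tfrac1N\textstyle\sum_i (x_i-\hat
x_i)^2}_{\text{MSE}} \;+\; \lambda\,
\tbinom{b}{2}^{-1}\!\!\sum_{i<j}\big(\lVert z_i - z_j\rVert -
D_{ij}\big)^2,$$

with $D_{ij}$ the Euclidean distance between the batch's one-hot inputs.
Local density of a projection $x$ against a reference sample
$\{y_1,\dots,y_R\}$ is a Gaussian KDE,
$f_h(x) = \frac{1}{Rh}\sum_i w_i K\!\big((x-y_i)/h\big)$ with
$h = 1.06\,\mathrm{STD}(S)\,R^{-1/5}$ and $w_i$ either 1 or the clone
frequency; sample similarity is the mean cross-density over a fixed-size
subsample (100 clones). Edit-distance and V-usage (Kullback–Leibler)
similarities, average-linkage clustering with cluster-entropy
evaluation, one-vs-all clone classification on the frozen encoder, and
a synthetic repertoire generator round out the toolkit. See the methods
vignette (`vignettes/tcr-embedding-density.Rmd`) for the full model
account.

## Worked example

```r
library(TCRdens)

# four synthetic samples, two hosts sharing public clones within host
cfg  <- generatorConfig(clonesPerSample = 400, seed = 7)
reps <- generateRepertoire(cfg)

model <- trainAutoencoder(reps, aeConfig("EM", epochs = 60, seed = 1))
distanceCorrelation(model, clones(reps[[4]])[1:300, ])
#> [1] 0.7718325

M <- similarityMatrix(reps, "kde", model = model, R = 100, seed = 3)
round(similarityValues(M), 1)
#>          host1_s1 host1_s2 host2_s1 host2_s2
#> host1_s1    -66.1    -34.6    -65.7    -52.6
#> host1_s2    -34.6    -51.5    -60.5    -60.1
#> host2_s1    -64.4    -59.5    -63.2    -35.3
#> host2_s2    -52.7    -60.4    -35.2    -64.8
```

The matrix holds **log mean cross-densities** (higher = more similar).
After just 60 epochs the distance-regularized embedding already ranks
pairwise distances at rho ≈ 0.77, and the within-host entries
(`host1_s1` vs `host1_s2`: −34.6) tower over every between-host entry
(−52 to −65) because samples of one host share planted public clones,
which sit at zero embedded distance from each other. (The diagonal is
the *leave-self-out* self-density, which is why it is lower than the
within-host cross terms.) Clustering recovers the hosts exactly:

```r
hosts <- setNames(sapply(reps, category), sapply(reps, sampleId))
cl <- hierarchicalCluster(M, k = 2)
clusterIndices(cl)
#> host1_s1 host1_s2 host2_s1 host2_s2
#>        1        1        2        2
clusterEntropy(cl, hosts)$mean    # 0 bits: hosts perfectly separated
#> [1] 0
```

Reconstruction, by contrast, needs a real training budget: this 60-epoch
demonstration model reconstructs only ~12% of held-out clones within 2
mismatches, while the full-scale plain `E` flavor (5,000 clones, 600
epochs, ~7 minutes on one CPU) reaches ~88%, and the distance-preserving
flavors trade reconstruction for geometry by design (see the methods
vignette, including why rank correlations on this synthetic corpus are
bounded near 0.89 by an oracle envelope).

A command-line interface wraps the same functions
(`exec/tcrdens`): `simulate`, `train`, `embed`, `density`, `compare`,
`cluster`, `classify-train`, `classify`, `stats`, `tsne`, and `rerun`
(byte-identical replay of any run from its recorded manifest).

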