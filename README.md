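# sgsdc — structure-guided soft deep clustering of paired single-cell data

`sgsdc` clusters cells measured with **paired scRNA-seq and scATAC-seq**
(both modalities profiled in the same cells) and, unlike standard hard
clustering, returns a **probability vector over clusters for every cell**.
That matters whenever cells are moving between identities — differentiation,
reprogramming, tumor plasticity — because a transitional cell genuinely
belongs to more than one cluster.

## The method in brief

For paired matrices $X^1 \in \mathbb{R}^{n\times d_1}$ (RNA) and
$X^2 \in \mathbb{R}^{n\times d_2}$ (ATAC):

* two autoencoders compress each modality to latents $Z^1, Z^2$
  (reconstruction loss $\mathcal{L}_r$, squared error);
* a global attention block computes a row-stochastic **structural matrix**
  $S = \mathrm{softmax}(Z W_1 (Z W_2)^\top / \sqrt{\bar d})$ over the
  concatenated latent $Z = [Z^1\,Z^2]$ and fuses
  $\hat H = (Z + S\,Z W_R)W_3 + b_3$ — the consensus representation;
* a **structure-guided contrastive loss** $\mathcal{L}_c$ aligns modality
  heads $H^1, H^2$ with $\hat H$, down-weighting negatives that $S$ already
  marks as structurally close;
* a **soft-clustering loss** $\mathcal{L}_s = \sum_i \mathrm{KL}(\gamma_i \Vert q_i)$
  pulls Student-t assignments $q$ toward fuzzy c-means memberships $\gamma$
  (fuzzifier $m = 1.5$), which—unlike the classical self-sharpening
  target—lets ambiguous cells keep mass on several clusters.

Training minimizes $\mathcal{L} = \mathcal{L}_r + \alpha\mathcal{L}_c +
\beta\mathcal{L}_s$ (defaults $\alpha = \beta = 1$, temperature $T = 0.5$)
with Adam, after reconstruction-only pretraining and k-means center
initialization. Outputs: k-means hard labels on $\hat H$, the membership
matrix $\gamma$, and ACC/NMI/ARI when ground truth is supplied.

## Worked example

```r
library(sgsdc)

# paired bimodal counts with 4 planted clusters, 600 cells
gen <- generate_dataset(synthetic_spec(n_cells = 600, n_clusters = 4,
                                       separation = 8, seed = 0))
ds  <- preprocess(gen$dataset)          # top-feature selection + log1p
res <- sg_fit(ds, training_config(pretrain_epochs = 50, train_epochs = 20,
                                  seed = 0))
res
#> clustering_result: 600 cells, 4 clusters
#>   ACC 1.0000  NMI 1.0000  ARI 1.0000
#>   epochs: 50 pretrain + 20 joint

head(res$soft_memberships, 3)  # per-cell cluster probabilities (rows sum to 1)
evaluate_clustering(ds$labels, res$hard_labels)
```

The printed metrics are clustering accuracy under optimal label matching
(Hungarian), normalized mutual information and adjusted Rand index against
the planted labels; 1.0 means the planted partition was recovered exactly.
On data with transitional cells (`frac_transitional = 0.3`),
`membership_entropy(res$soft_memberships)` is systematically higher for the
mixed cells than for pure ones (about 0.86 vs 0.34 nats in the example
above), which is the point of soft assignments.

There is also a command-line interface:

```sh
exec/sgsdc simulate --n 600 --k 4 --seed 0 --out data/
exec/sgsdc fit --config cfg.yaml
exec/sgsdc evaluate --true data/labels.txt --pred run/labels.txt
```

plus `ablate` and `sweep` subcommands for the ablation battery and
hyperparameter grids. See `vignettes/structure-guided-soft-clustering.Rmd`
for the full model description and design rationale.

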