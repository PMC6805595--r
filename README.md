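# netmeth

Gene selection for case-control association studies with high-dimensional
DNA methylation array data, **using prior genetic-network knowledge**.

## Who this is for

Epigenome-wide studies measure methylation at many CpG sites per gene, and
genes that are linked in curated networks (KEGG, Reactome, protein-protein
interaction databases, ...) tend to have correlated methylation. Standard
selection tools — per-gene tests, group lasso over CpG blocks — ignore that
structure. `netmeth` is for analysts who have (i) a samples × CpG matrix,
(ii) a CpG→gene annotation, (iii) a binary phenotype and (iv) an undirected
gene network, and who want a ranked list of outcome-associated genes that
exploits the network.

## Method in brief

1. **Dimension reduction** — each gene's mean-centered CpG block
   `X_m` (n × k_m) is collapsed to one feature: first principal component
   (PC), normalized PC (`z/√e`, unit ℓ2-norm; the recommended choice),
   supervised PC (t-statistic screening + PC), or a PLS-style component
   from per-site logistic slopes.
2. **Network-penalized logistic regression** — minimize

   ```
   -(1/n) Σ_i [ y_i log p(z_i) + (1-y_i) log(1-p(z_i)) ]
        + λ α ‖β‖₁ + λ (1-α) βᵀ Sᵀ L S β
   ```

   where `L` is the normalized graph Laplacian (`l_uu = 1` for connected
   genes, `l_uv = -(d_u d_v)^(-1/2)` on edges) and `S = diag(±1)` holds
   preliminary coefficient signs so linked genes with opposite effects are
   smoothed, not cancelled. Solved by IRLS + cyclic coordinate descent
   with warm starts over a log-spaced λ path (compiled code).
3. **Stability ranking** — over S balanced half-sample resamples and the
   whole (α, λ) grid, each gene's selection probability is
   `SP_j = max_{α,λ} (1/S) Σ_s I(β̂_j(I_s; α, λ) ≠ 0)`;
   genes are reported by descending SP. No tuning-parameter selection is
   needed.

The package also ships the full simulation framework used to benchmark the
method (Gaussian-graphical-model covariance from the network, latent gene
values with degree-scaled case shifts `±(δ/3)√d_j`, CpG-level emission),
the comparators (logistic group lasso; PC t-test, global test, SAM-GS,
Hotelling T²), and a canonical-correlation permutation test for checking
that linked genes really are more co-methylated than random pairs.

## Worked example

A small paired benchmark: two 100-gene network modules (one carrying 12
outcome genes), n = 50 + 50, ω = 4 causal CpG sites per gene, σ = 2.

```r
library(netmeth)
cfg <- experiment_config(
  simulation = sim_config(n_cases = 50, n_controls = 50, n_modules = 2,
                          omega = 4, sigma = 2, seed = 1),
  n_resamples = 20L, replicates = 2L, top_k = c(10, 20, 50))
res <- run_methods_battery(cfg, c("Net+nPC", "group-lasso", "t-test"))
print(res$tpr, row.names = FALSE)
#>   k   Net+nPC group-lasso    t-test
#>  10 0.2222222   0.1777778 0.2111111
#>  20 0.4444444   0.3111111 0.4000000
#>  50 0.9444444   0.5333333 0.7000000
```

Each row is the averaged true positive rate — the fraction of the truly
outcome-related genes recovered among the top-k ranked genes — over
replicates that all methods saw identically (paired design). The
network-aware method recovers 94% of the causal genes in its top 50, while
the group lasso (same selection unit, no network) reaches 53% and a
per-gene PC t-test 70%.

For a single real dataset the flow is:

```r
feats <- reduce_all(x, annotation, y, method = "nPC")   # n x p features
L     <- build_laplacian(graph)                          # from the edge list
prof  <- selection_probability(feats, y, L,
                               scheme = subsample_scheme(500, seed = 1),
                               standardize = FALSE)      # nPC is pre-scaled
head(prof$gene_ids[prof$ranking], 100)                   # top-100 genes
```

A command-line wrapper with `simulate`, `reduce`, `fit`, `stability`,
`tpr`, `battery` and `cca` subcommands is installed at
`system.file("cli", "netmeth.R", package = "netmeth")`; experiment
configurations are JSON (`write_experiment_config()`).

## Documentation

See the methods vignette (`vignettes/network-methylation.Rmd`) for the
model, the simulator's assumptions, all numerical design decisions, and
known limitations.
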