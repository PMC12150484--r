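# tcamap

Maps single cells from scRNA-seq onto the spots of a spatial transcriptomics
reference by aligning the two datasets in a shared latent space with
**transfer component analysis (TCA)**, a domain-adaptation method that
minimises the maximum mean discrepancy (MMD) between the two populations.
From the cell-to-spot assignments the package derives spot deconvolution
(cell-type composition per spot), cell-type localisation maps, spatial
aggregation of per-cell activity scores (e.g. SCENIC regulon AUCs) with
Jensen–Shannon specificity ranking, and serial anchored 2-D embeddings for
time-series data. A seeded synthetic-tissue generator and a grid-based
pseudo-spot benchmark make the whole pipeline testable offline.

## The method

Stack the harmonized reference spots and query cells as rows of $X$
($n = n_1 + n_2$ observations). The empirical MMD between the projected
domains is $\mathrm{tr}(A^{\mathsf T} K L K A)$, where $K$ is the kernel matrix
(primal, linear, or RBF), and $L = uu^{\mathsf T}$ with $u_i = 1/n_1$ on reference
rows and $-1/n_2$ on query rows. TCA solves

$$\min_A \; \mathrm{tr}(A^{\mathsf T} K L K A) + \lambda\,\mathrm{tr}(A^{\mathsf T} A)
\quad \text{s.t.}\quad A^{\mathsf T} K H K A = I,
\qquad H = I - \tfrac1n \mathbf{1}\mathbf{1}^{\mathsf T},$$

via the generalized eigenproblem $(KHK)a = \eta\,(KLK + \lambda I)a$,
keeping the $d$ largest-$\eta$ eigenvectors; latent coordinates are
$Z = KA$ (primal: $Z = XA$). Each cell is then assigned the spot whose
latent profile it Pearson-correlates with best; pairs below a threshold
(default 0.7) are flagged unassigned. See the methods vignette
(`vignettes/tcamap-methods.Rmd`) for the full account, including how $d$
should be matched to the data's latent complexity.

## Worked example

A closed-loop benchmark on synthetic tissue: grid single cells into
pseudo-bulk spots with known dominant types, realign the cells, and score
the recovered composition.

```r
library(tcamap)

tis  <- generate_tissue(tissue_config(n_cells = 1500, n_genes = 200, seed = 1))
pair <- make_benchmark_pair(tis, grid_size = 115, seed = 1)
pair$reference
#> Pseudo-spot set: 81 spots (grid 115 units), 200 genes, 1500 member cells
#>   truth labels: type1, type2, type3, type4

fit <- tca(pair$reference$pseudo_bulk, pair$query, d = 10)
fit
#> Transfer component analysis alignment
#>   kernel: primal   d: 10   lambda: 1
#>   reference spots: 81   query cells: 1500   genes: 200
#>   latent-space MMD: 6.57194e-09

mp <- map_cells(fit)                      # best spot + PCC per cell
head(mp, 3)
#>    cell_id best_spot_id       pcc assigned
#> 1 cell0001          2_5 0.6787845    FALSE
#> 2 cell0002          1_3 0.5778762    FALSE
#> 3 cell0003          5_5 0.4653929    FALSE

comp  <- spot_composition(mp, pair$query_types, spots = rownames(fit$TC_R))
dom   <- dominant_type(comp)
truth <- setNames(pair$reference$spots$truth_label, pair$reference$spots$spot_id)
m     <- classification_metrics(dom, truth)
#> ACC 0.914  macro-F1 0.916  ARI 0.800

ep <- expression_pcc(fit$ref, fit$query, mp)
pcc_summary(ep)
#> evaluation PCC 0.227 [0.222, 0.232] over 831 assigned cells
```

The fitted alignment drives the latent-space MMD to ~1e-8 — the two
populations are statistically indistinguishable in the shared space — and
the dominant cell type of 91% of pseudo-spots is recovered (chance-corrected
agreement ARI 0.80). The evaluation PCC is the expression-space correlation
of each assigned cell with its matched spot, deliberately distinct from the
latent-space mapping PCC used for assignment.

A thin command-line wrapper over the same functions lives at
`inst/scripts/tcamap-run.R` (subcommands `simulate`, `pseudobulk`, `fit`,
`map`, `run`).

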