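---
title: "Clade-wise phylogenetic profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-wise phylogenetic profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantpp)
```

## The problem

Phylogenetic profiling predicts gene function from evolution: genes whose
products work together tend to be retained or lost together across genomes,
so correlated conservation profiles across many species are evidence of a
functional link. `plantpp` implements this idea for plant-scale proteome
collections: starting from all-vs-all best-hit bit-scores between a
reference proteome (for example a halophyte such as *Spartina alterniflora*)
and hundreds of other plant proteomes, it finds genes whose profiles
co-evolve with a curated query set (for example known salt stress-related
genes) and ranks them as functional candidates.

## The profile model

For reference gene $i$ and target proteome $j$, let $BS_{i,j}$ be the best
BLASTP/DIAMOND bit-score of $i$ against proteome $j$, and $BS_{i,ref}$ the
score of $i$ aligned to itself. Two normalizations turn raw scores into
comparable profiles:

1. **Length**: $LPP_{i,j} = BS_{i,j} / BS_{i,ref}$. Bit-scores grow with
   protein length; dividing by the self-score maps each gene onto a
   conservation fraction in $(0, 1]$.
2. **Phylogenetic distance**: $NPP_{i,j} = (LPP_{i,j} - \mu_j)/\sigma_j$,
   where $\mu_j, \sigma_j$ are the mean and standard deviation of column
   $j$. Species close to the reference have uniformly high $LPP$; Z-scoring
   each species column removes that global trend so that rows measure
   conservation *relative to the genome-wide expectation* in each species.

We use the sample standard deviation ($n-1$ denominator) throughout; with
thousands of retained genes per matrix the sample statistics approximate
the population ones. Constant columns ($\sigma_j = 0$) are set to zero and
flagged rather than dropped, so column indices stay aligned with the
species-to-clade map.

Before normalization four cleaning rules apply, in this order: proteins
shorter than 40 residues are removed; proteins whose self-alignment score is
at or below 80 bits are removed (such self-hits are unreliable anchors for
normalization); every score below 24.6 bits — the score equivalent to an
E-value of 0.05 — and every absent hit is floored at 24.6; and genes without
a score above the floor in at least 5 non-reference proteomes are removed
(a profile that is flat at the noise floor nearly everywhere carries no
co-evolution signal). The order matters only for the attribution of genes
to rules in the filter report; final membership is order-independent, and a
test asserts idempotence of the whole filter. An absent hit is floored
rather than treated as missing because a missing best hit is, by
construction, below any reporting threshold.

## Clade-wise co-evolution and the maximal ratio score

Co-evolution can be global or confined to one branch of the species tree
(for example, a signal present only within Poales). The scan therefore
clusters the NPP rows twice over: once on all species (pseudo-clade `ALL`)
and once per clade with at least 10 species. Ward's minimum-variance
criterion on Euclidean distances (`hclust`, method `ward.D2`) is used, as is
standard for this analysis. The 10-species eligibility threshold follows
the clade lists used in published clade-wise profiling work, which include
10-species clades (i.e. the rule is "at least ten", not "more than ten").

Each dendrogram is cut into $k$ flat clusters for every $k$ in a
multi-resolution grid, by default $\{10, 20, 50, 100, 200, 500\}$
intersected with $[2, n_{genes}-1]$. A fixed grid was chosen over dynamic
tree cutting because it is deterministic, cheap, and lets the score inspect
both coarse and fine cluster structure; the grid is configurable.

For gene $g$ in cluster $C$ at clade $c$ and cut $k$, with query set $Q$:

$$\mathrm{ratio}(g, c, k) = \frac{|C \cap Q \setminus \{g\}|}{|C \setminus \{g\}|}
\quad \text{if } |C| \ge 3, \text{ else } 0,$$

and the **maximal ratio score** is
$\mathrm{MRS}(g) = \max_{c,k} \mathrm{ratio}(g,c,k)$. The score is the
query purity of the best cluster the gene ever lands in, excluding the gene
itself, so it lies in $[0, 1]$ and equals 1 only when the gene co-clusters
exclusively with query genes at some resolution. **This formula is a
reconstruction**: the published description of the score fixes its range
and "similarity to the query set" semantics but not its arithmetic. Query
purity maximized over clades and cut levels is the simplest statistic
consistent with both; the minimum cluster size of 3 (configurable) exists
because any gene paired with a single query gene would otherwise score a
meaningless 1. At fine cut levels small clusters still make purity-1 scores
attainable for occasional background genes; the top-fraction rule, not the
raw score, does the calling, and on well-sized matrices (thousands of
genes) planted-module recovery is robust (see the recovery test:
recall $\ge 0.8$ over 20 simulations).

Candidates are the top $\lfloor 0.01 \cdot n_{genes} \rfloor$ (at least 1)
genes by MRS. Ranks are computed over all genes; query genes keep their
rank but are excluded from the returned list, so the list always contains
the stated number of *new* candidates. Boundary ties break by gene id,
keeping every run deterministic.

## Classifier validation

To check that profiles carry enough signal to predict query-set membership
across species, `plantpp` mirrors the standard validation: clean the
matrix, balance the classes, train MLP and random-forest classifiers, and
report accuracy, precision, recall and F1 with confusion counts.

Cleaning (`ml_clean`) applies the 3-sigma rule per feature (values strictly
outside $\mu \pm 3\sigma$ become missing), drops features and then samples
with more than 20% missing (strict: exactly 20% is kept), and fills the
remaining gaps by linear interpolation along each gene row over the fixed
species ordering, with edge gaps taking the nearest observed value. The
interpolation direction (along rows) and the edge rule are this package's
reconstruction of an under-specified step; both are documented here rather
than hidden.

Class imbalance (few query orthologs among thousands of genes) is handled
by Cluster-Centroids undersampling: K-means with $k$ equal to the minority
count (k-means++ seeding, Lloyd iterations) is run on the majority rows,
which are then replaced by the $k$ centroids. Minority rows are never
modified. Undersampling is applied to the training partition only, after an
80/20 stratified split, to avoid leaking test information into the
centroids.

The MLP has three hidden layers of 180, 90 and 40 ReLU units, a sigmoid
output, Adam updates with initial learning rate $10^{-4}$, and L2
coefficient $\alpha = 0.1$; the random forest uses 55 trees with maximum
depth 15 and impurity-based feature importance. These hyperparameters are
the defaults of `classifier_spec()`; `grid_search()` re-derives them by
cross-validated search over a declared grid when a new dataset warrants
it. The MLP is implemented in the package
(plain R matrix algebra) with minibatches of 200, up to 1000 epochs and an
early-stopping rule (patience 10 at tolerance $10^{-5}$); with fixed seeds
training is reproducible to the reported four decimals. Per-species forest
importances averaged within clades (standard error $sd/\sqrt{n}$,
10-species minimum) show which branches of the tree drive the prediction.

## Correlation and enrichment

For a designated anchor gene, `profile_correlation()` ranks all other genes
by Pearson correlation of NPP rows — Pearson because the profiles are
Z-scored and their correlation coefficients are close to normally
distributed — and flags the top 1% (floor rule, minimum 1, id tie-break).
When several anchors are of interest the per-anchor top sets are reported
separately; forming unions is left to the caller, since the right
combination rule depends on the question.

Term enrichment of any gene set uses the hypergeometric upper tail
($p = P(X \ge k)$ for overlap $k$, term size $K$, query size $n$, universe
$N$) over flat gene-to-term annotations, with Benjamini–Hochberg adjustment
across the tested terms. BH is the default of the standard enrichment
tooling this stage stands in for; ontology-graph propagation is out of
scope, so annotations are taken as given. The default universe is the set
of annotated genes retained in the NPP matrix.

## The synthetic generator

`simulate_dataset()` exists so every stage is testable without downloading
proteomes. Its generative model mirrors the structure the method assumes in
real data:

* **Clade blocks.** Each planted module draws one latent conservation mean
  per clade, uniform on $[0,1]$; all species in a clade share it. This
  emulates the clade-blocked conservation visible in real NPP heatmaps.
* **Co-evolution strength.** Module genes perturb the shared profile with
  independent Gaussian noise of sd $(1 - s) \cdot \sigma_{bg}$, where $s$
  is the module's signal strength and $\sigma_{bg}$ (default 0.5 on the
  latent scale) the background noise level. $s = 1$ gives identical latent
  rows; real co-evolution effect sizes are unknown, so $s$ is a calibration
  knob, not an estimate.
* **Background.** Every background gene draws its own clade means and
  full-strength noise: clade-structured but mutually uncorrelated rows.
* **Score scale.** Latent profiles map affinely onto
  $[24.6, BS_{i,ref}]$ with self-scores uniform on $(200, 1000)$ and
  protein lengths uniform on $[100, 800]$ residues, so the noise floor and
  self-normalization behave as with real bit-scores, and the self-score
  and length filters only trigger when a test configures them to.
* **Missingness.** A configurable fraction (default 10%) of entries is
  deleted and omitted from the written hit tables, matching real tabular
  search output where absent hits are absent rows, not zeros.

Default geometry is 2,000 genes in 5 clades of 12 species with one 20-gene
module at signal 0.9. What passing tests on this generator do **not** show:
robustness to phylogenetic autocorrelation *within* clades, to biased
missingness (real absences concentrate in distant species), or to the
heavy-tailed length and score distributions of real proteomes. The
generator is a correctness harness, not a realism benchmark.

## Numerical and engineering choices

* Determinism everywhere: one seed drives simulation, splits, K-means,
  classifiers; candidate and correlation ties break lexicographically by
  gene id in the C locale.
* Degenerate inputs: constant NPP columns are zeroed with a warning;
  single-row matrices, empty queries, constant anchor profiles and
  single-class training labels are errors naming the offender.
* K-means degeneracy: if the majority class has no more distinct rows than
  clusters, the centroids are those rows themselves (the limit of Lloyd
  iterations on duplicated points), avoiding the failure of standard
  K-means on non-distinct centers.
* Problem sizes in the test-suite simulations (hundreds to a few thousand
  genes, 36–60 species, 20 seeds for ensemble checks) were chosen as the
  smallest scales at which the statistical properties under test are
  stable.

## Known limitations

* The MRS arithmetic and the cut-level grid are reconstructions (above);
  rankings are faithful to the stated semantics but not guaranteed
  identical to other implementations.
* Flat annotations only; no GO-graph propagation.
* Headline real-data figures (e.g. >90% classifier accuracy on full
  proteome collections) require the full 365-proteome matrices and are out
  of desk-scale reach; the package's claims are the contractual behaviors
  its tests compute.

## A minimal run

```{r demo, eval = FALSE}
man <- demo_pipeline(seed = 1, out_dir = "demo_out")
str(man$stages)
```

The demo simulates a dataset, writes FASTA/hit-table/clade-map fixtures,
builds the NPP matrix, runs the clade scan, validates with both
classifiers, and enriches the candidate set — the same path a real analysis
takes with downloaded proteomes.
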