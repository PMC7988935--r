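---
title: "Cluster-aware assignment of single cells to tumor clones: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-aware assignment of single cells to tumor clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemap)
```

## The model

`clonemap` assigns clusters of single tumor cells to evolutionary clones.
The observed data are a binary clone-genotype matrix $\Omega_{i,k}$
($N$ mutations $\times$ $K$ clones) produced by an upstream phylogeny
tool, sparse matrices $A_{i,j} \le D_{i,j}$ of alternative-allele and
total UMI counts per mutation and cell, and a partition of the $M$ cells
into $Q$ clusters together with a cell-to-cluster distance matrix
$G_{j,q}$ (in our motivating application, clusters are cells with an
identical B-cell-receptor heavy chain and $G$ counts differing BCR
mutations). Both the genotypes and the clustering are treated as noisy
inputs and corrected during inference.

The hidden variables and their priors:

* $I_q \in \{1..K\}$, the clone of cluster $q$, uniform prior $1/K$;
* $T_j \in \{1..Q\}$, the corrected cluster of cell $j$, categorical with
  $p_{j,q} = e^{-c G_{j,q}} / \sum_{q'} e^{-c G_{j,q'}}$;
* $C_{i,k} \in \{0,1\}$, the corrected genotype, Bernoulli with
  $P(C_{i,k}=1 \mid \Omega_{i,k}, \xi) = \xi^{1-\Omega_{i,k}}
  (1-\xi)^{\Omega_{i,k}} = |\Omega_{i,k} - \xi|$;
* $\xi \sim \mathrm{Beta}(\kappa_0, \kappa_1)$, the genotype error rate;
* $\theta_0 \sim \mathrm{Beta}(\alpha_0, \beta_0)$ and
  $\theta_i \sim \mathrm{Beta}(\alpha_1, \beta_1)$, the background and
  per-position allelic success probabilities.

The likelihood of a covered entry is
$A_{i,j} \sim \mathrm{Binom}(D_{i,j}, \theta_i)$ if the clone assigned to
cell $j$'s corrected cluster carries mutation $i$
($C_{i, I_{T_j}} = 1$), and $\mathrm{Binom}(D_{i,j}, \theta_0)$
otherwise. Entries with $D_{i,j} = 0$ contribute a likelihood factor of
exactly 1 and are skipped.

Every full conditional is available in closed form: $I$, $T$ and $C$ are
discrete (products of binomial likelihoods over the relevant cells and
positions), and $\theta$ and $\xi$ are conjugate beta updates on the
alternative/reference read totals split by carried status, and on the
match/mismatch counts between $C$ and $\Omega$. One sweep updates, in this
fixed order: $I$ (all clusters), $\theta$, $T$ (all cells), $C$ (all
entries — they are conditionally independent given the rest, so the whole
matrix is drawn as one block), and $\xi$. The sweep is a systematic scan,
not a random scan.

Cells inherit the clone of their corrected cluster; the reported cell-level
posterior is the fraction of retained sweeps each cell spent under each
clone, marginalizing over the cluster correction.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $c$ | switch-prior strength (per distance unit) | 2 | makes one BCR mutation of distance cost $e^{-2} \approx 0.14$ in prior odds; $c=0$ is a flat prior, large $c$ pins cells to their nearest cluster |
| $\kappa$ | beta prior on $\xi$ | (1, 9) | weak prior, mean 0.1: genotype calls are mostly right but errors are expected |
| $(\alpha_0,\beta_0)$ | prior on $\theta_0$ | (0.3, 29.7) | mean 0.01, the scale of sequencing error on non-carried positions |
| $(\alpha_1,\beta_1)$ | prior on $\theta_i$ | (2.25, 2.65) | mean $\approx 0.46$: allelic expression with dropout; matches the published defaults of the per-cell predecessor model |
| iterations / chains | sweep budget | 20 000 / 10 | conservative defaults for real data; the examples and tests use shorter chains because the conjugate structure mixes in a few sweeps on simulated data |
| burn-in | discarded fraction | 0.5 | standard conservative choice; not stated by the original description, exposed in the configuration |

## Chain combination and summaries

How the multiple starting points should be merged is not specified by the
model's original description, so the package makes a documented choice:
chains differ only in the random initial $I$ (everything else starts at
the inputs and prior means), and the reporting chain is the one with the
highest mean post-burn-in log joint. Pooling is deliberately avoided
because unmixed chains would blur the posterior; instead the maximum
absolute cross-chain difference in cluster-to-clone probabilities (after
clone-label alignment on the corrected genotypes) is reported as a
convergence diagnostic. MAP ties break toward the lowest clone index and
are counted in the diagnostics. Clone labels of two corrected-genotype
sets are aligned by minimizing the total column-wise $L_1$ distance —
exhaustively for $K \le 8$, by the Hungarian algorithm otherwise.

## Numerical choices

All discrete conditionals are evaluated in log space and normalized after
subtracting the row maximum, so the largest term is $e^0$ and underflow
can only affect terms that are negligible anyway; no clipping is applied,
which preserves exact zeros (e.g. $P(C_{i,k}=1) = 0$ when $\xi = 0$ and
$\Omega_{i,k} = 0$). Categorical draws use the Gumbel-max trick on the
log-weights, which is exact and vectorizes over rows. Beta draws are
clamped to $[10^{-12}, 1-10^{-12}]$ to keep downstream logarithms finite.
The full pipeline output is a pure function of the inputs, the
configuration and the master seed; each chain derives its own seed from
(master seed, chain index).

Degenerate inputs are handled explicitly: a cluster left empty by the
$T$ update receives a uniform clone draw (its likelihood is an empty
product); a cell without covered positions follows its switch prior; a
genotype entry with no currently assigned expressing cells follows its
prior $|\Omega_{i,k} - \xi|$.

## The synthetic-data generator

`sim_config()` encodes the study conditions the model assumes: a random
perfect-phylogeny genotype matrix (clone 1 is the all-zero base clone;
every other clone attaches to a random earlier clone and acquires at
least one private mutation), genotype errors applied entrywise at rate
`xi_true = 0.05`, `M = 400` cells, `coverage_rate = 0.15` with covered
depths $1 + \mathrm{Pois}(1)$ (mean 2), background rate
`theta0_true = 0.01`, per-position rates drawn from
$\mathrm{Beta}(2.25, 2.65)$, and 5% of cells misclustered.

The clonotype-cluster size distribution of real repertoires is
singleton-dominated, so the generator places `multiplet_fraction = 0.5`
of the cells into `Q = 50` multiplet clusters whose sizes follow a
truncated power law (exponent 2, minimum size 2, adjusted to hit the
exact cell total), and gives every remaining cell its own singleton
cluster. `Q` therefore counts *multiplet* clusters; an interpretation in
which `Q` counted all clusters could not put half of 400 cells into
singletons with only 50 clusters. Distances are 0 to the input cluster,
1 to the true cluster of a misclustered cell, and
$2 + \mathrm{Pois}(2)$ to unrelated clusters.

What the generator does *not* emulate: doublets and ambient RNA,
position-dependent coverage (real 5' scRNA-seq concentrates coverage near
transcript ends), copy-number-driven allelic imbalance, or errors in the
distance matrix itself. Passing the recovery tests therefore shows the
sampler inverts its own generative assumptions correctly — not that those
assumptions capture every artifact of real data.

The package also contains an exact-enumeration oracle
(`enumerate_posterior()`) for small instances with $\theta$ and $\xi$
clamped (jointly marginalizing them with $C$ has no closed form). The sum
over $T$ factorizes per cell given $(I, C)$, so only the
$K^Q \times 2^{NK}$ grid is enumerated; the test suite checks it against
a second, naive enumerator that loops over every joint state.

## Relation to the per-cell predecessor model

With every cluster a singleton, the clustering layer carries no
information and the model reduces to the per-cell assignment sampler it
extends. The reduction is exact when the cluster-switch update is inert
(each cell keeps its own cluster, so $I$ plays the role of the per-cell
clone label); the test suite verifies this against an independently coded
per-cell sampler. With the switch update *active* under a flat prior, the
models are close but not identical: cells can transiently share a
cluster, which couples their clone labels — a small effect (mean
per-entry difference about 0.01 in the test configuration) that the
per-cell model cannot express, and the reason the flat-prior comparison
is asserted on the mean rather than the maximum.

## Filtering conventions

`join_axes()` keeps mutations present in both the genotypes and the
counts that show at least one alternative read in at least one cell, then
drops cells without evidence. "A cell contains at least one common
mutation" is read as *at least one alternative read* (variant evidence),
not merely coverage; the `cell_filter = "coverage"` switch provides the
laxer reading. Clusters emptied by the cell filter are removed and the
remainder re-indexed; the filter report records all before/after sizes.

## Problem sizes used in the tests

The test suite favors many short chains on small instances: the
enumeration comparison uses $K=2, Q=3, M=4, N=3$ with 50 000 sweeps; the
per-cell reduction uses $M=30$ cells with 12 000 sweeps; parameter
recovery runs the full default design ($M=400$) with 1 500 sweeps and 2
chains, which the conjugate sampler converges well within; the
confidence-effect comparison uses ten replicate seeds at $M=120$. These
sizes are the package's own choice of a thorough-but-quick regression
suite; real analyses should use the 20 000-sweep, 10-chain defaults.

## Known limitations

* The clone tree itself is taken as input; only its genotypes are
  corrected. A wrong number of clones cannot be repaired, only partially
  absorbed into the genotype correction.
* The distance matrix $G$ is fixed at its input values; cluster
  representatives are not recomputed as cells move between clusters.
* The prior on $I$ is uniform; clone prevalences from the upstream
  phylogeny are deliberately not used.
* With `K = 1` the model degenerates (everything maps to the single
  clone); the code warns and proceeds.
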