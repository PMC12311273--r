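---
title: "Network-propagation pathway enrichment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-propagation pathway enrichment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peanut)
```

## The model

The package scores pathways against a *network-smoothed* version of a
preranked gene list. Three objects enter: a vector of signed per-gene
scores $x$ (typically log2 fold changes), an undirected PPI network with
adjacency matrix $A$ and degree matrix $D$, and a collection of gene sets.
Because a perturbed pathway may contain both up- and down-regulated
members, the signed scores are first replaced by their magnitudes,
$p_0 = |x|$, restricted to the network's node set (nodes without a score
are zero-filled so the diffusion operator keeps its dimension). The
magnitudes are then diffused by random walk with restart,

$$p_k = \alpha\, p_0 + (1 - \alpha)\, W p_{k-1},
  \qquad W = D^{-1/2} A D^{-1/2},$$

whose fixed point $p = \alpha (I - (1-\alpha) W)^{-1} p_0$ redistributes
score mass along edges: a gene surrounded by high-scoring interaction
partners is pulled up even if its own measurement is weak or missing. The
symmetric normalization keeps $W$ symmetric with spectral radius at most 1,
so the iteration contracts in any norm with ratio at most $1-\alpha$ and
the fixed point is unique for $\alpha > 0$. Rows and columns of isolated
nodes are defined as zero ($D^{-1/2}$ entry 0), which leaves their fixed
point at exactly $\alpha p_0$ — isolated nodes are common after
intersecting real score lists with real networks and must not be an error.

The key modeling assumptions are therefore: (i) relevance is carried by
score *magnitude*, not direction; (ii) biologically coherent signal is
*locally concentrated* in the network, so diffusion amplifies it while
diluting isolated noise spikes; (iii) the network's edges are meaningful at
a uniform weight scale (weights are supported but the default input mode is
unweighted).

## The statistical cascade

After propagation every pathway is compared against the background of all
other scored genes in three gated stages, each followed by
Benjamini-Hochberg correction:

1. a two-sample Kolmogorov-Smirnov test on the propagated scores, over all
   testable pathways (effective size at least 2, background at least 2);
2. a Mann-Whitney U test, only for pathways whose K-S FDR passes the
   threshold, with BH within that subset;
3. a permutation test, only for pathways whose MW FDR passes, comparing
   the mean propagated member score to the means of `n_perm` same-size
   gene sets sampled uniformly without replacement from the scored
   universe, with add-one empirical p-values
   $(1 + \#\{null \ge obs\})/(1 + n_{perm})$ and BH within the subset.

A pathway is called significant when its K-S *and* MW FDRs pass; the
permutation stage only refines the ordering of the significant block. The
final ranking key is (permutation FDR if present else $\infty$, MW FDR,
K-S FDR, K-S p, pathway name) for significant pathways and (K-S FDR, K-S p,
name) for the rest; ending on the name makes the output fully
deterministic.

Three choices here were genuinely open and are worth recording:

* **Sidedness.** Propagated magnitudes make enrichment one-directional
  (more perturbed = larger scores), so both the K-S and the MW test default
  to the one-sided "pathway greater" alternative; `alternative =
  "two.sided"` restores symmetric tests. Note the R convention: internally
  the one-sided K-S call uses `alternative = "less"`, which in `ks.test`
  denotes the CDF of the first sample lying *below* the second — i.e. the
  pathway being stochastically greater.
* **Permutation statistic.** The mean effective-member score, the simplest
  location statistic comparable across set sizes; the median is available
  via `stat = "median"`.
* **Correction scope.** BH at stages 2 and 3 is computed within the subset
  actually tested at that stage, a literal reading of correcting "after
  each stage"; `adjust_within_stage = FALSE` corrects over all stage-1
  pathways instead.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.2 | restart probability (unitless, in (0, 1]); 0.2 favors smoothing while preserving the input signal; 1 disables diffusion |
| `tol` | 1e-6 | L1 stopping tolerance of the iteration; with $\alpha = 0.2$ the residual shrinks geometrically by $\le 0.8$ per step, so this is reached in a few dozen iterations |
| `max_iter` | 1000 | iteration cap; non-convergence returns the last iterate with a warning and a `converged = FALSE` flag |
| `n_perm` | 10000 | permutation draws per pathway (stage 3) or per preranked null; the empirical p resolution is $1/(n_{perm}+1)$ |
| `threshold` | 0.05 | adjusted-p gate and significance cutoff |
| `min_size`, `max_size` | 15, 500 | inclusive database-side pathway size filter, applied to full member sets before network intersection (effective sizes are tracked separately) |
| `weight` | 1 | exponent of the preranked running-sum statistic for the comparator methods; 0 gives the rank-only statistic |

Scores are *not* renormalized before propagation: all downstream tests are
rank-based, hence scale-invariant, and keeping raw magnitudes makes the
propagated values interpretable. `normalize_input = TRUE` rescales to unit
L1 mass for cross-dataset comparability.

## Comparator methods

Signed GSEA, ABS GSEA and NGSEA share one hand-implemented preranked core
(descending sort with name tie-break; increments $|s|^{weight}/N_R$ at
member hits, decrements $1/(N-m)$ at misses; ES = signed maximum deviation)
so that the method comparison never confounds transform with
implementation. The running sum is piecewise linear between hits, so the
implementation evaluates only the just-before/just-after hit extremes
($O(m \log m)$ per set) rather than walking all $N$ positions; an
exhaustive walk and `fgsea::calcGseaStat` serve as independent oracles in
the tests. The null is gene-label permutation (random same-size member
sets on the same ranked list), nominal p the add-one same-sign tail, NES
the ES over the mean same-sign null ES, and FDR q the standard pooled
normalized-ES ratio with a monotonicity pass from least to most extreme
NES, so a more extreme pathway never receives a larger q. The NGSEA
transform $NS_i = |x_i| + n_i^{-1}\sum_j |x_j|$ is undefined at $n_i = 0$;
isolated genes keep $NS_i = |x_i|$, the continuous limit of a vanishing
neighbor term. Neighborhoods are edge-based; weights do not enter the
average.

## The synthetic benchmark generator

`synth_generate()` emulates the benchmark situation of a disease dataset
with one known associated pathway: background scores are
$N(0, \sigma^2)$; each planted signal pathway receives scores of magnitude
$|N(0, \sigma^2)| + \delta$ with *random signs*, i.e. strong but
directionally incoherent — exactly the mixed pattern that motivates
magnitude-based scoring; with `signal_connected = TRUE` the members are
grown breadth-first from a random node so that diffusion concentrates on
them; decoy pathways are uniform random gene sets. Defaults (500 genes,
Erdos-Renyi edges at $p = 0.02$, 50 pathways of 15-40 genes, one connected
signal pathway at $\delta = 3\sigma$) are sized so a full four-method
comparison over 20 seeds runs in about a minute; these are also the
problem sizes used by the calibration and benchmark tests
(20 seeds $\times$ 200 decoy pathways for the null calibration).

What the generator does *not* emulate: correlated measurement noise,
scale-free degree structure coupled to expression, pathway overlap and
cross-talk, partial membership annotation, and identifier mismatch. A
passing benchmark therefore shows the machinery is correct and calibrated,
not that the method's advantage on real expression compendia is
reproduced.

One behavior of the strong-signal regime deserves a note: when *every*
signal gene has $|x| \ge 3\sigma$, the members cluster at both extremes of
the signed ranking, and the two-sided running-sum ES of signed GSEA still
deviates strongly — so at $\delta = 3\sigma$ signed GSEA usually also ranks
the planted pathway first, and the methods separate in the mean rank and
the failure tail rather than the median. The relative advantage of
propagation grows as the signal gets weaker, sparser, or less completely
annotated.

## Numerical and reproducibility choices

* Duplicate edges keep the maximum weight; duplicate `.rnk` genes keep the
  largest magnitude — both deterministic and order-independent.
* Gene identifiers are matched case-sensitively after whitespace trimming;
  `uppercase = TRUE` in the readers folds case, a common failure mode with
  symbol identifiers.
* All randomized stages draw from per-pathway child seeds obtained by a
  stable polynomial hash of (master seed, pathway name), so results are
  independent of pathway iteration order and identical runs are
  byte-identical.
* Degenerate inputs are defined, not errors: all-tied score vectors give
  p = 1 in every test; zero total member weight in the running sum falls
  back to the unweighted increment; an all-zero score vector propagates to
  itself.
* Empirical p-values use the add-one estimator and can never be 0; the
  smallest reportable value is $1/(n_{perm}+1)$.

## Known limitations

Directed, signed, or confidence-weighted-by-type networks are out of
scope, as is leading-edge gene extraction and pathway cross-talk
correction. The K-S and MW stages treat genes as exchangeable under the
null, which propagation slightly violates (scores of adjacent genes are
correlated); the pure-null calibration test bounds the practical effect at
the default settings. Very small effective pathways (under the
`min_size = 2` floor) and pathways covering nearly the whole scored
universe are skipped with recorded reasons rather than tested.
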