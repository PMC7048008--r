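---
title: "Methods: graph-regularized tri-factorization for microbe-disease co-modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-regularized tri-factorization for microbe-disease co-modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdnmf)
```

## The model and its assumptions

The input is a binary association matrix $X \in \{0,1\}^{n_m \times n_d}$
(microbes by diseases). The working hypothesis is modular: groups of
microbes act together, groups of diseases share microbial drivers, and
the two group structures are coupled. The package fits

$$\min_{H_1,H_2,S_1,S_2 \ge 0}
\;\|MS - H_1 S_1 H_1^T\|_F^2
+ \lambda_1 \|X - H_1 H_2^T\|_F^2
+ \lambda_2 \|DS - H_2 S_2 H_2^T\|_F^2
+ \mu\left(\mathrm{tr}(H_1^T L_1 H_1) + \mathrm{tr}(H_2^T L_2 H_2)\right)$$

Three assumptions deserve emphasis:

1. **GIP kernels are informative.** $MS$ and $DS$ are Gaussian
   interaction-profile kernels computed *from $X$ itself*
   ($MS(i,j) = e^{-\gamma_m\|X_{i\cdot}-X_{j\cdot}\|^2}$, bandwidth
   normalized by the mean squared profile norm, base
   $\gamma'_m = \gamma'_d = 1$). They add no external information; they
   re-express pairwise profile structure in a form the symmetric
   tri-factor terms can cluster. Entities with empty profiles make the
   kernel degenerate, so an all-zero $X$ is rejected.
2. **The coupling term defines co-modules.** $\|X - H_1H_2^T\|_F^2$ is a
   tri-factorization with the identity in the middle, which binds column
   $c$ of $H_1$ to column $c$ of $H_2$. Co-module $c$ is therefore a
   *positional* pairing, not a post-hoc matching.
3. **The priors only smooth.** $L_1$ is the Laplacian of
   $MS_{phy} = 1 - M_{phy}$ (phylogenetic distances in $[0,1]$, e.g.
   Kimura 2-parameter distances computed elsewhere; a matrix with maximum
   $> 1$ is rescaled by that maximum, with a warning) and $L_2$ of a
   symptom-based cosine similarity. Since
   $\mathrm{tr}(H^T L H) = \tfrac12\sum_{ij} W_{ij}\|h_i - h_j\|^2$, the
   penalty only pulls rows of $H$ together where the prior weight is
   positive. Entities missing from a prior get zero edge weight
   (`alignSimilarity()`): no information, no smoothing — the neutral
   choice in a graph penalty, and the package's own decision since real
   priors rarely cover every entity (the motivating data had phylogeny
   for 91 of 292 microbes).

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 15 | factor rank = number of co-modules; 15 suits the 292×39 scale of curated association databases, while benchmarks here use the planted `kTrue`. Must satisfy `k < min(n_m, n_d)`. |
| `lambda1` | $n_m/n_d$ | weight of the coupling term; derived at fit time from matrix shape so the three reconstruction terms have comparable magnitude. |
| `lambda2` | $(n_m/n_d)^2$ | weight of the disease-similarity term, same shape-balancing convention. Both are overridable. |
| `mu` | 0.001 | Laplacian weight, selected from \{0.001, 0.01, 0.1\}; dropped automatically when no prior is supplied. |
| `gammaM`, `gammaD` | 1 | GIP bandwidth bases (dimensionless). |
| `t` | 1.5 | module threshold multiplier (see below). |
| `restarts` | 50 | random restarts; the minimum-objective restart is kept. Benchmarks in this package use 10 restarts, which already saturates recovery on planted data. |
| `maxIter`, `tol` | 500, 1e-6 | iteration cap and relative-objective-change stopping rule (the optimization literature for these updates states no canonical stopping rule; relative change is the standard choice). |

## The update rules and the two modes

All four factors are updated multiplicatively (order $S_1, S_2, H_1,
H_2$), each entry multiplied by a ratio of the negative to the positive
part of the gradient, denominators floored at $10^{-12}$ — the standard
guard, and the reason zero entries stay zero (a property the tests
assert).

For the graph term there are two placements, exposed as `updateMode`:

- **`"descent"` (default).** The similarity part $\mu W H$ joins the
  numerator and the degree part $\mu D H$ the denominator. This is the
  standard graph-regularized NMF placement: splitting the gradient
  $2\mu(D-W)H$ this way makes each update a non-increasing step on the
  penalized objective. The acceptance suite audits this over 200
  iterations on 60×20 instances at $\mu \in \{0, 0.001, 0.1\}$ and
  observes no relative increase above $10^{-9}$.
- **`"paper"`.** The opposite placement ($\mu D H$ in the numerator),
  matching the update rules as printed in the original description of
  this method verbatim. That placement *ascends* the $+\mu\,
  \mathrm{tr}(H^TLH)$ penalty and is therefore not monotone; it is kept
  so the printed rules remain exactly reproducible, but it is not the
  default.

Both modes coincide at $\mu = 0$, and the model then *is* NetNMF (the
joint tri-factorization without priors) — the suite checks this nesting
seed-for-seed. Freezing $S_1$ at the identity and dropping the two
similarity terms recovers the plain NMF coupling; the plain NMF baseline
(`fitBaseline(..., "nmf")`) uses the classical Lee–Seung updates.

Restart $r$ draws its factors (H's i.i.d. Uniform(0,1), S's symmetrized
uniforms) from a stream seeded deterministically by `(seed, r)`, so the
50-restart protocol is reproducible restart-by-restart. Restarts whose
factors turn non-finite are excluded from selection with a warning; the
fit fails only if every restart does. No column normalization is applied
between iterations (none is part of the method's description; the
module threshold below is scale-equivariant per row, which removes most
of the need).

## Module extraction

Row $f$ of a factor matrix joins module $c$ iff
$H_{fc} > \mathrm{mean}(H_{f\cdot}) + t\cdot \mathrm{sd}(H_{f\cdot})$,
with the *sample* standard deviation over the $k$ row entries (divisor
$k-1$; the method's printed divisor "$n-1$" is undefined for a length-$k$
row and is read as $k-1$). The inequality is strict, so ties — including
constant rows — are excluded. Two structural consequences worth knowing:

- membership is equivariant under positive row scaling;
- for small $k$ the threshold can be unreachable: with $k \le 4$ even a
  one-hot row fails $t = 1.5$ (its largest standardized entry is
  $(k-1)/\sqrt{k\,(k-1)} < 1.5$), so meaningful extraction needs
  $k \ge 5$ at the default $t$.

Links between co-modules are read from the off-diagonals of $S_2$
(disease level, with $S_1$ weights recorded alongside), sorted
descending; the diagonal is reported separately as per-module cohesion.
No link cut-off is imposed — the tables list all positive weights and the
CLI trims with `--top-links`, because the method's description names
associated co-modules without stating a threshold.

## Enrichment and the enrichment index

Microbe modules are tested against a GMT taxon-set collection with the
exact hypergeometric upper tail; every set is intersected with the
universe first, and FDR is controlled per module by Benjamini–Hochberg
(the field-standard reading of an unqualified "FDR"). A set is
significant when $p < 0.005$ *and* $q < 0.05$. The default universe is
the association-matrix microbes that appear in at least one taxon set —
the least arbitrary local analogue of a hosted service's unstated
universe.

The enrichment index of co-module $c$ is the Jaccard overlap between the
*names* of its significantly enriched sets and its disease members.
Because curated set names match disease names only loosely, both sides
are normalized (casefold, parenthetical qualifiers and punctuation
stripped) with an optional user synonym map; the rule is explicit and
overridable rather than implicit. An empty union leaves EI undefined
(`NA`), and the evaluation statistic is the mean EI over co-modules with
defined EI. The summary also reports `tsSig` (distinct significant sets)
and `ots` (significant sets matching no disease of their own co-module —
enrichment signal beyond the diseases already present).

## The planted benchmark

`generatePlanted()` emulates the study conditions end-to-end: blockwise
Bernoulli associations (within-density 0.8, background 0.05, 2% flip
noise at 150×45 with 5 co-modules — the defaults), phylogenetic
distances drawn around 0.1 within / 0.6 between microbe modules, symptom
similarities around 0.7 within / 0.1 between disease modules (sd 0.05,
truncated to $[0,1]$ — genus-level 16S distances and symptom cosine
values in these ranges are what curated data show; values are sampled
rather than constant so kernels and thresholds stay non-degenerate), one
disease-named taxon set per planted module plus twice as many
size-matched decoy sets as a calibrated null. `overlapFraction` defaults
to 0: overlapping planted memberships are structurally dropped by the
$t = 1.5$ rule (a row loading equally on two of five modules falls below
its own threshold), so overlap is an explicit experiment, not a default
condition. Recovery is scored by best-match F1 under optimal one-to-one
matching (exhaustive for $k \le 8$, greedy beyond), which is invariant
to column permutation as factorization output requires.

What passing these benchmarks does **not** show: real association
matrices are sparser and far from blockwise-independent Bernoulli; real
phylogenies have hierarchical, not block, structure; real taxon sets
overlap each other; and real priors are noisy and partial. The planted
tests validate the machinery — monotone optimization, exact threshold
semantics, correct pairing and scoring — not biological performance.

Problem sizes used by the test and acceptance runs (the package's own
choice of benchmark scale): kernel oracles up to 50×20, descent audits
on 60×20 with $k = 5$, recovery on the default 150×45 benchmark with 10
restarts over 10 generator seeds, enumeration oracles for the
hypergeometric tail up to universe 12.

## Numerical choices and degenerate inputs

- Denominator floor $10^{-12}$ in every multiplicative update.
- Square matrices are symmetrized on read as $(A+A^T)/2$; asymmetry
  beyond $10^{-8}$ is a hard error (rounded exports carry tiny
  asymmetry; larger signals corruption).
- All-zero association matrix: degenerate-input error (the kernel
  bandwidth is undefined). A disease with an empty symptom profile gets
  zero off-diagonal cosine similarity, with a warning.
- Convergence by relative objective change with an absolute floor,
  plus the `maxIter` cap; the objective trace is recorded every
  iteration and exposed via `objectiveTrace()`.
- Ties at the module threshold are excluded (strict inequality); no
  minimum module size is imposed and empty module sides are reported as
  such (they occur in practice).
- Factor scale is not identifiable across runs; tests and scores
  compare objectives and membership sets, never raw factor values.

## Known limitations

- Multiplicative updates find local minima; the multi-restart protocol
  mitigates but does not remove this.
- The `"paper"` update mode is intentionally non-monotone (see above).
- Best-match F1 switches from exhaustive to greedy matching above
  $k = 8$; greedy can under-score adversarial overlap patterns.
- EI depends on a name-normalization convention; a synonym map is
  supported but disease nomenclature reconciliation is out of scope.
- The threshold rule's small-$k$ blind spot ($k \le 4$ with $t = 1.5$)
  is inherent to the mean + t·sd form, not an implementation artifact.
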