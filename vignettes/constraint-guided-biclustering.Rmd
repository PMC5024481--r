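---
title: "Constraint-guided pattern-based biclustering: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-guided pattern-based biclustering: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A bicluster is a submatrix $(I, J)$ of a real-valued matrix $A$ (rows =
genes, columns = conditions; or nodes $\times$ nodes for a weighted network)
whose values follow a coherency model

$$a_{ij} = k_j + \gamma_i + \eta_{ij},$$

where $k_j$ is the expected value of column $j$ (the bicluster *pattern*),
$\gamma_i$ a per-row adjustment ($\gamma_i = 0$: constant model; otherwise
additive), and $\eta_{ij}$ bounded noise. Symmetric models additionally allow
per-row sign flips $c_i \in \{+1, -1\}$, and order-preserving models replace
value coherency with a shared linear ordering of the columns. The coherency
*strength* is $\delta = \bar A / |\mathcal L|$, where $\bar A$ is the value
amplitude and $\mathcal L$ the discretization alphabet: finer alphabets mean
stricter coherency.

`bic2pam` finds these biclusters by full-pattern mining. The matrix is
discretized and mapped to a transactional database — items concatenate the
column id with the symbol (`y2.-1`) — and every closed frequent itemset with
its supporting transaction ids is a *full-pattern* $(P, \Phi_P, \Psi_P,
\Upsilon_P)$ that maps directly to a bicluster: $I = \Phi_P$, $J = \Psi_P$,
pattern $= \Upsilon_P$. Order-preserving biclusters come instead from closed
sequential patterns over per-row column orderings, where columns with tied
values share one itemset.

Constraints are predicates over the pattern, its items, rows or columns.
They are parsed from a small grammar (`min(pattern) <= -2`,
`rows superset {x2,x3}`, `regex(y2 < (y1 y3) < *)`), classified by their
pruning properties, and *pushed* into the mining searches:

* **succinct** bounds delete conflicting items and transactions up front
  ($\mu$- and $\alpha$-reductions, re-applied on every $\tau$-th conditional
  projection);
* **anti-monotone** constraints prune whole subtrees the moment a pattern
  fails;
* **monotone** constraints stop being re-checked once a prefix satisfies
  them, and delete transactions whose full item set already fails;
* **convertible** average bounds become prefix-checkable under a cost-sorted
  enumeration;
* sequential constraints use the prefix-monotone property, and regular
  expressions prune via dead states of a token automaton.

Constraint pushing never changes the result relative to post-filtering; the
test suite asserts this on hundreds of random instances per constraint
class, against brute-force enumeration oracles.

### Closure semantics

Closure is computed *within the constraint-satisfying pattern space*: a
satisfying pattern is reported iff no satisfying superset (or
supersequence) has identical coverage, and the minimum-length filter is
applied after closure. This is required for constrained mining to behave
sensibly — under `sum(P) <= 1` on the worked three-transaction example, the
pattern `{a,b}` must be reported even though its unconstrained closure
`{a,b,c}` violates the bound. For sequential patterns, closure maximality is
fixed on (pattern, coverage) pairs; ties that create multiple equivalent
orderings are kept as distinct patterns when their coverages differ.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_items` | `{3, 5, 7}` swept | alphabet sizes; $\delta = \bar A/|\mathcal L|$. Order-preserving runs use $\lceil m/4 \rceil$ symbols only to decide ties (trading precedences against co-occurrences), floored at 2 so tiny matrices keep an ordering. |
| `alpha_multi` | 0.25 | multi-item boundary fraction: cells within $\alpha \cdot$ bin width of a cutpoint carry both adjacent symbols. At 0.25 the dual bands span the whole bin, so a module whose expected value happens to fall near a cutpoint is never split across two symbols — with narrower bands (say 0.1), planted-benchmark measurements show such modules losing half their support and sometimes disappearing entirely. The cost, roughly 50% database inflation, is absorbed by the saturation guard on the coarsest alphabet. |
| `theta_start`, `theta_step` | 0.80, 0.10 | support starts at 80% and decreases by 10% *relatively* per round ($\theta \leftarrow 0.9\,\theta$); a relative decrease never crosses zero. |
| `stop_biclusters`, `stop_coverage` | 50, 0.10 | the descent stops once the postprocessed solution holds 50 dissimilar biclusters or covers 10% of the observed cells. |
| `min_cols` | 5 | minimum pattern length. In matrices with tens to hundreds of columns, 2–4-column patterns are dominated by spurious cross-module conjunctions (columns of two different modules supported by the union of their rows plus background); such conjunctions genuinely exceed a column-independence null, so length is the honest lever. Set 2 for small worked examples. |
| `merge_overlap` | 0.70 | cell-Jaccard above which biclusters merge (union of rows and columns; pattern recomputed as per-column mode, ties toward the symbol nearest zero). |
| `filter_overlap` | 0.60 | similarity above which a bicluster is dropped against a larger retained one (see below). |
| `significance_alpha` | 0.01 | level of the Bonferroni-corrected binomial-tail filter. |
| `noise_tolerance` | 0.1 | extension/reduction tolerance: rows (then columns) matching at least $1-$ tolerance of pattern positions are added; below it, removed. At 0.1, patterns up to 9 columns require exact matches — deliberately conservative, since looser extension floods coarse-alphabet biclusters with background rows. |
| `tau` | 1 | pruning periodicity: conditional data reductions re-applied every $\tau$-th projection. |
| `max_rounds` | 25 | support-descent cap; 25 rounds from 0.8 ends near 6% support, below which module membership is indistinguishable from background co-occurrence. |
| `mine_node_budget` | 1e5 | saturation guard per mining call: a round that visits more pattern nodes has dissolved into background noise at that support level; the round is discarded and that alphabet stops descending. Coarse alphabets saturate before fine ones. |

## Statistical significance

The exact significance statistic used by the original line of work is not
reproduced here; it is replaced — openly — by a column-independence
binomial-tail test. The probability that a random row matches a constant
pattern is $p_\varphi = \prod_{j \in J} f_j(k_j)$ with $f_j$ the empirical
symbol frequency in column $j$ (multi-item assignments included); additive
patterns sum $p_\varphi$ over all feasible shifts, symmetric ones over both
orientations, and an order-preserving pattern has $p_\varphi = 1/|J|!$ (one
ordering, no ties). The p-value is the upper tail $P(\mathrm{Bin}(n,
p_\varphi) \ge |I|)$, Bonferroni-corrected by the number of candidate
patterns. A candidate whose *uncorrected* tail already exceeds the level can
never survive the corrected filter, so the pipeline drops such candidates on
sight; this is lossless and keeps low-support rounds tractable.

The column-independence null is deliberately simple. Its known blind spot is
cross-module structure: a conjunction of columns from two planted modules is
supported by both row sets and exceeds the null by a wide margin. The
`min_cols` default and the row-overlap redundancy rule (next section) are
the structural mitigations.

## Postprocessing and redundancy

Merging unions biclusters above 0.7 cell-Jaccard to a fixpoint. Extension
and reduction then add/remove rows and columns by pattern-match fraction,
per the bicluster's own alphabet (each mined bicluster remembers which swept
discretization produced it). The final filter drops insignificant
biclusters, then walks the remainder in order of corrected p-value and
drops any bicluster too similar to a larger retained one.

When several alphabet sizes are swept, a **consensus row reduction** runs
after merging: a row stays in a bicluster only if it matches the module's
per-alphabet pattern (modal symbol per column over the current rows) in at
least half of the swept coherency strengths. Background rows admitted by
the coarsest alphabet's wide symbol bands fail the finer alphabets and drop
out, while genuine member rows pass nearly all; on planted benchmarks this
single step removes the 10–25% background-row contamination that unions of
pattern variants otherwise accumulate.

Similarity in this filter is the larger of the **cell-set Jaccard** and the
**row-set Jaccard**, and the row-set rule also applies at equal sizes. The
cell-set measure alone can never identify a *column fragment* — a
sub-pattern over fewer columns whose coverage is a module's rows plus
background — because the fragment's extra rows keep the cell overlap low
(a two-column fragment of a six-column module tops out near 0.3). Measured
on planted benchmarks, the cell-only rule retained dozens of fragments and
symbol variants per true module, saturating the stop criteria before the
full modules became frequent. All other similarity computations (merging,
match scores) remain cell-set Jaccard.

## The synthetic benchmark generator

`generate_synthetic()` emulates expression-like matrices with planted
modules: background cells i.i.d. uniform on $[0,1]$ (configurable only in
code — uniform keeps planted patterns detectable without distributional
tuning), $K$ biclusters with sizes uniform over per-setting ranges, constant
modules sharing per-column expected values, order-preserving modules sharing
a column ordering. The four settings ($500 \times 50$ to $4000 \times 400$)
plant $K = \{6, 10, 15, 20\} \cdot 1/\mu$ biclusters with $\mu = 1$
(constant) or $\mu = 2$ (order-preserving, with size ranges doubled).
Defaults: 5 background symbols ($\delta = 20\%$), deviations of $\delta/2$
on 2% of cells, 2% missing values, overlap degree $\theta = 0.2$.

Interpretations where the source material delegates detail: the overlap
machinery forces $\mathrm{round}(\kappa K)$ adjacent pairs ($\kappa = 0.3$,
read as a fraction of $K$) to share a $\theta$ fraction of rows and
$\theta\phi$ of columns; shared cells combine by the plaid function $f$
(sum, product, or $\nu$-weighted mean) plus $\epsilon$-scaled Gaussian
noise. "$\pm 20\%$ of the range" noise is additive uniform on
$[-d, d]$, $d =$ deviation $\times\, \delta$, applied to the noisy fraction
of cells. Annotation generation sizes the background term universe so each
term lands on about `per_term_rows` rows in expectation (the $\pm$sd is not
separately enforced), and gives each planted module a dedicated term shared
by a Normal fraction of its rows.

What the generator does *not* emulate: heavy-tailed expression
distributions, correlated background (batch effects), missingness that
depends on intensity, and annotation hierarchies. Passing recovery tests on
these benchmarks therefore demonstrates correctness of the mining and
postprocessing machinery under the stated planting model, not performance
on real assays.

Benchmark sizes used in the test suite are kept at the $500 \times 50$
setting with three seeds' worth of instances — chosen so the full suite
runs in minutes while still exercising the support descent end to end.

## Numerical choices and degenerate inputs

* Gaussian-quantile cutpoints come from a Normal fit to all observed cells;
  zero-variance matrices fall back to equal-width with a warning, and a
  zero-amplitude matrix lands every cell mid-alphabet.
* Even alphabet sizes skip 0 ($\{-2,-1,1,2\}$), odd ones center on it.
* A value exactly on a cutpoint belongs to the upper bin; with
  `alpha_multi > 0` it also carries the lower symbol.
* Additive anchoring subtracts each row's minimum symbol, so patterns are
  zero-anchored and $\gamma_i$ is the subtracted minimum; re-adding
  $\gamma_i$ reconstructs the symbols exactly.
* Mirrored transactions from symmetric mining fold back keeping the
  first-seen orientation per row.
* Ties in header/enumeration order break by support then lexicographically;
  modal-symbol ties break toward the symbol nearest zero. Both make runs
  bit-reproducible under a fixed seed.
* Multi-item patterns can carry two symbols of one column; the bicluster
  mapping keeps the symbol nearest zero.
* Convertible pruning is direction-aware: enumeration runs in descending
  cost order for `avg >= v` (every extension can only lower the running
  average) and ascending for `avg <= v` — the prefix-growth equivalent of a
  cost-ordered header table. With several convertible constraints, the
  first determines the order; the rest still post-filter exactly.
* Fractional support thresholds convert as $\lceil \theta_1 |D| \rceil$;
  the descent floors at 2 rows.

## Known limitations

* The binomial significance filter is a stated replacement, not the
  original statistic; its column-independence null is optimistic for
  correlated columns.
* Association-rule-based noise handling and plaid-model composition are out
  of scope; overlapping planted modules are generated but mined only under
  the four basic coherencies.
* The sequential engine assumes item-indexability (each column once per
  sequence), which holds for order-preserving biclustering but not for
  general sequence mining; gap/temporal constraints are deliberately
  unsupported.
* Matrices beyond roughly $10^7$ cells need partitioning, which this
  package does not implement.
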