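---
title: "Building and comparing correlation networks with corrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and comparing correlation networks with corrnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrnet)
```

## The model

A correlation network treats each measured variable (here: a metabolite) as
a vertex and draws an undirected edge between two variables whose pairwise
correlation across samples is both strong and statistically significant.
Nothing causal is claimed: an edge records coordinated behaviour across the
sampled conditions, which is why the graph is undirected. The pipeline has
four stages, each with explicit, user-controlled parameters.

### 1. Correlation

`correlate()` computes, for every unordered variable pair,

* the correlation coefficient $r \in [-1, 1]$ — Pearson, Spearman (average
  ranks, so $r_s$ equals the Pearson correlation of the column ranks), or
  Kendall $\tau_b$;
* the raw two-sided p-value — for Pearson/Spearman from the t
  approximation $t = r\sqrt{df/(1-r^2)}$ with $df = n - 2$, where $n$ is
  that pair's number of *complete* observations; Kendall uses the normal
  approximation $z = 3\tau\sqrt{n(n-1)}/\sqrt{2(2n+5)}$ (tie correction of
  the variance is omitted; with heavy ties prefer Spearman);
* the adjusted p-value over the family of $m = v(v-1)/2$ unique pairs —
  Benjamini–Hochberg step-up (the usual reading of "FDR"/q-value) or
  Bonferroni. Each condition's matrix is corrected independently, because
  each condition's network is an independent family of tests.

**Missing data.** Metabolomics matrices routinely miss a sizeable fraction
of entries. Listwise deletion would discard most samples, so correlations
use pairwise-complete observations; the price is that each pair has its own
$n$, which is why the result carries an `n_pairs` matrix and why a
`min_pairs` floor (default 4) marks under-observed pairs as undefined
rather than reporting a correlation estimated from 2–3 points. Undefined
pairs can never become edges.

**Method choice.** Pearson assumes approximately normal marginals.
`normality_screen()` runs a Shapiro–Wilk test per variable (a stock
routine) and recommends Pearson only if *every* variable's p-value exceeds
`alpha`; one non-normal or untestable (fewer than 3 observed values)
variable flips the recommendation to Spearman. With $n \approx 30$ samples
and skewed abundance data, Spearman is the default.

### 2. Edge selection

`select_edges()` applies the two-threshold rule: keep the pair iff
$|r| \ge r_{min}$ and $p < p_{max}$. By default $p$ is the adjusted
p-value, the $r$ comparison is inclusive and the $p$ comparison strict,
matching the reporting style "$r \ge |\pm 0.7|$ and $q_{FDR} < 0.05$";
both directions are configurable (`strict_r`, `strict_p`) because the
convention only matters at exact ties. Negative correlations pass on
magnitude and keep their sign as the edge weight. There is no universal
$r_{min}$: 0.3 has been used for biological data, 0.9 in physics; 0.7 with
$q < 0.05$ is a conservative choice for $n = 30$ metabolomics samples and
is the package default.

### 3. Topology

`analyze_topology()` reports, with the conventions of Cytoscape's
NetworkAnalyzer for undirected graphs:

* **density** $2e/(v(v-1))$;
* **diameter** — the longest shortest path, unweighted hop counts, over
  the largest connected component (the component count is reported
  alongside so a disconnected graph is visible);
* **global transitivity** $3\cdot\text{triangles}/\text{triples}$ with
  triples $\sum_v \binom{deg(v)}{2}$ — "the probability to form cliques".
  The mean *local* clustering coefficient is a different statistic and is
  reported separately; a graph with no connected triple has undefined
  transitivity, reported as 0 with `transitivity_defined = FALSE`;
* **average shortest path** over all mutually reachable ordered pairs;
* per-vertex **degree**, **betweenness centrality** normalized by
  $(v-1)(v-2)/2$ over the whole graph (so values live in $[0,1]$; a star
  centre scores 1, every vertex of a complete graph 0), and **clustering
  coefficient** (degree < 2 gives 0);
* per-edge **betweenness** (unnormalized fractional shortest-path counts);
* a **power-law fit**: least squares on $\log(\text{count})$ vs
  $\log(\text{degree})$ over non-zero histogram bins, requiring at least 3
  distinct degree values; the slope magnitude is the exponent.

Correlation weights are attributes, never path lengths — all distances are
hop counts, which is what makes the reported diameters small integers.

`rank_hubs()` orders vertices by betweenness (descending), then degree,
then label, the order in which hub metabolites are usually tabulated.

### 4. Differential comparison

`network_union()`, `network_intersection()` and `network_difference()`
match edges by unordered label pair, ignoring weights for membership
(weights come from the first argument where both have the edge). All three
return graphs whose vertex set is exactly the vertices incident to a
surviving edge. Dropping isolated vertices is what shrinks a difference
network's vertex count relative to its parent, and for consistency the
same rule applies to union and intersection — a design choice this package
makes explicitly, since merge tools differ on it. Two invariants follow
and are tested: $e(\mathrm{diff}(a,b)) + e(\mathrm{int}(a,b)) = e(a)$, and
$\mathrm{diff}(a,a)$ is empty.

## File formats

* `write_correlation_tables()` emits `r_table.csv` (full symmetric matrix,
  unit diagonal) and `p_table.csv` in the **dual-triangle** convention:
  the strictly-lower triangle holds raw p-values, the strictly-upper
  triangle the adjusted ones, diagonal 0. One file thus carries both
  matrices, and `read_correlation_tables()` reconstructs them, rejecting
  asymmetric r matrices or out-of-range p-values.
* Edge tables are three-column tab-delimited text (source, target, r) with
  no header — importable by Cytoscape as a table. On reading, self-loops
  are skipped with a warning and duplicate unordered pairs collapse to the
  first occurrence. Vertex labels match exactly and case-sensitively;
  silent case folding could merge distinct metabolites.
* `export_graph()` writes SIF (fixed interaction type `corr`) and GraphML.
* Numeric output uses 6 significant digits, comfortably above the 2–3
  decimals usually printed, so write/read round-trips are lossless at the
  1e-6 level.

## The synthetic generator: what a green test establishes

`synthetic_spec()` describes a two-condition experiment: by default 30
samples per condition and 26 variables — two shared correlation blocks (5
and 4 variables), one block specific to each condition (4 and 5), and 8
independent noise variables, all blocks at $\rho = 0.9$, 5% of entries
missing completely at random. Block variables follow the one-factor model
$x_j = \sqrt{\rho} f + \sqrt{1-\rho}\,\epsilon_j$ with standard-normal $f$
and $\epsilon_j$, which makes every within-block pair's true correlation
exactly $\rho$ — the reason this construction was chosen over a Cholesky
factorization of an arbitrary target matrix, whose pairwise correlations
are harder to reason about. Defaults mirror the scale of a typical GC-MS
cell-culture study (tens of samples, tens of uniquely identified
metabolites, strong within-pathway correlation).

The generator emulates correlation *structure*, not GC-MS physics: no
peak-intensity distributions, batch effects, heteroscedasticity, or
informative missingness. A green recovery test therefore establishes that
the statistical machinery (pairwise-complete Spearman, BH over
$v(v-1)/2$ pairs, the threshold rule, the set operations) behaves
correctly at the stated effect size and sample size — not that any
particular real data set would yield a particular network.

With the defaults and thresholds $|r| \ge 0.7$, $q_{BH} < 0.05$, planted
within-block edges are recovered with recall ≥ 0.95 and false-discovery
proportion ≤ 0.05 averaged over 100 seeds, and the difference network
between conditions recovers the condition-specific block; both are
asserted in the test suite, and the missing-data policy is characterized
by a test showing recall degrades by less than 0.1 at a 10% missing rate.

## Numerical and design notes

* **Ties in Spearman** use average ranks with the t-approximation p-value;
  exact permutation p-values are out of scope at $n = 30$.
* **Adjustment family with undefined pairs**: the BH/Bonferroni family
  size stays $m = v(v-1)/2$ even when some pairs are undefined —
  equivalent to giving untested pairs $p = 1$, which is conservative.
* **Rounding for display** follows the spreadsheet convention (half away
  from zero): a density of 0.225 prints as 0.23.
* **Diameter on disconnected graphs** is taken over the largest component
  (by vertex count, first on ties); whether historical NetworkAnalyzer
  runs normalized betweenness per component or per whole graph is not
  documentable, and this package uses the whole graph, stating it here.
* **Determinism**: `analyze_topology()` on the same edge table is
  byte-identical across runs; all simulation is seeded through `withr`.
* **Degenerate inputs**: fewer than 3 samples or 2 variables are rejected
  at load; a constant variable warns and yields undefined correlations; an
  empty edge set is a valid (empty) network; betweenness on $v < 3$
  vertices is all zeros; the power-law fit refuses fewer than 3 distinct
  degrees (a star or regular graph).

## Limitations

Correlation networks capture marginal association only — no partial
correlations, shrinkage, or directionality; hubs are statistical, not
mechanistic, objects. Module/community detection, weighted-path metrics
and closeness/eigenvector centralities are out of scope. P-values rely on
large-sample approximations that get conservative for very small
per-pair $n$; the `min_pairs` floor is a guard, not a cure.

## A complete run

```{r pipeline}
spec <- synthetic_spec(seed = 7)
pair <- simulate_paired_conditions(spec)

net <- lapply(pair, function(dm) {
  correlate(dm, method = "spearman", adjust_method = "BH") |>
    select_edges(r_min = 0.7, p_max = 0.05) |>
    build_network()
})

analyze_topology(net$b)
analyze_topology(network_difference(net$b, net$a))
rank_hubs(analyze_topology(network_difference(net$b, net$a)))
```
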