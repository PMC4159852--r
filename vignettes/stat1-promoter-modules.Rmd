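---
title: "From up-regulated genes to composite STAT1 promoter modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From up-regulated genes to composite STAT1 promoter modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stat1mod)
```

## Scope

Inflammatory gene programs in vascular lesions are driven in part by
interferon-γ signalling through STAT1 and by toll-like-receptor signalling
through NFκB and the IRF family. Cross-talk between these pathways leaves a
genomic footprint: promoters of synergistically induced genes tend to carry a
STAT1 binding element (a GAS or ISRE site) and an NFκB or IRF site *in close
proximity* — a composite cis-regulatory module. `stat1mod` implements the
full in-silico chain needed to look for that footprint in two-condition
expression data:

1. select significantly up-regulated genes with an empirical-Bayes moderated
   t test (`quantile_normalize()`, `adjust_batches()`, `collapse_probes()`,
   `moderated_t()`, `select_upregulated()`);
2. build position frequency matrices from seed occurrence sets and scan
   promoter windows with an information-weighted similarity score
   (`build_matrix_from_seeds()`, `matrix_similarity()`, `scan_promoters()`);
3. call composite STAT1–NFκB and STAT1–IRF modules under a spacing
   constraint (`detect_modules()`, `build_flag_table()`);
4. quantify over-representation of sites and modules in a gene set against
   the promoter background with hypergeometric z-scores, and GO terms with a
   Benjamini–Yekutieli-adjusted hypergeometric test (`feature_zscore()`,
   `go_enrichment()`);
5. intersect up-regulated lists across cohorts into a gene signature with
   localization and prior-knowledge annotation (`intersect_signatures()`,
   `annotate_signature()`, `export_links()`).

Every stage is exercisable end-to-end on synthetic data with planted ground
truth (`simulate_expression()`, `simulate_promoters()`), which is how the
package validates itself without any external download.

## Differential expression model

For gene $g$ with group means $\bar y_{g2}$ (case) and $\bar y_{g1}$
(control) on the log2 scale, the effect is $\mathrm{log2FC}_g = \bar y_{g2} -
\bar y_{g1}$ and the pooled residual variance $s^2_g$ has $d = n_1 + n_2 - 2$
degrees of freedom. Gene-wise variances are shrunk toward a common prior
$s_0^2$ with prior degrees of freedom $d_0$:

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}, \qquad
  t_g = \frac{\mathrm{log2FC}_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

with two-sided p-values from a t distribution on $d_0 + d$ degrees of
freedom and Bonferroni adjustment over the $m$ tested genes. Selection
requires $\mathrm{log2FC} \ge \log_2(\mathrm{fc})$ — the "at least
fc-fold" boundary is deliberately **inclusive** — and adjusted $p < \alpha$
(defaults fc = 2, α = 0.05). Only up-regulation is selected; the two-sided p
is retained.

The prior is estimated by closed-form moment matching on $\log s^2_g$, using
the marginal moments
$\mathrm{E}[\log s^2] = \log s_0^2 + \psi(d/2) - \log(d/2) - \psi(d_0/2) +
\log(d_0/2)$ and
$\mathrm{Var}[\log s^2] = \psi'(d/2) + \psi'(d_0/2)$, solved for $d_0$ by
Newton inversion of the trigamma function. Two degenerate branches are
defined precisely:

* if the observed spread of $\log s^2$ does not exceed its chi-square
  sampling component ($\mathrm{Var}[\log s^2] \le \psi'(d/2)$), the
  inversion diverges: $d_0 = \infty$ and every gene receives the
  bias-corrected common variance $s_0^2$;
* if the gene variances are *exactly* identical (zero observed spread, which
  contradicts the sampling model outright), the common variance is passed
  through unshrunk, so the moderated t collapses to the ordinary two-sample
  t. This keeps the equal-variance limit exact rather than inflated by the
  $\psi(d/2) - \log(d/2)$ bias term.

Genes with zero residual variance are excluded from prior estimation but
still moderated; a matrix in which *every* gene has zero variance is an
explicit error. Moment matching rather than iterative likelihood fitting
keeps the estimator deterministic and dependency-free; on simulated data
with constant true noise, $s_0^2$ recovers the noise variance within a few
percent (tested to 20%).

Upstream conveniences mirror common microarray practice: quantile
normalization forces identical column distributions (ties receive the mean
of the tied reference values); probe-to-gene collapse takes the per-sample
mean over a probe map (median and max are options — the mean is the
default because collapse utilities in mainstream microarray GUIs average);
batch adjustment is a deliberate location–scale simplification of
empirical-Bayes batch correction: each batch's per-gene sub-vector is
recentered to the gene's pooled mean and rescaled to the pooled standard
deviation. This is deterministic, testable, and exactly removes the
additive per-gene batch shifts the generator plants; it does not shrink
batch effects across genes, which matters only for very small batches. A
batch wholly confounded with one condition group triggers a warning rather
than an error, since the adjustment is still well-defined.

## Matrix model and similarity score

A position frequency matrix over width $W$ stores pseudocount-regularized
base frequencies $f_{i,b} = (c_{i,b} + 0.25)/(n + 1)$ — one extra
observation spread uniformly over the four bases, which keeps every log
finite and vanishes with seed depth — and per-position information weights

$$w_i = 2 + \sum_b f_{i,b} \log_2 f_{i,b} \in [0, 2].$$

The similarity of a width-$W$ subsequence $s$ is the information-weighted
frequency ratio normalized by the consensus score:

$$\mathrm{sim}(s) = \frac{\sum_i w_i\, f_{i, s_i}}
                         {\sum_i w_i \max_b f_{i,b}} \in (0, 1],$$

which equals 1 exactly when $s$ is the per-position argmax string.
Commercial matrix scanners use scores of this family; the exact constants
here are documented so that the conventional thresholds (0.8 for scan
occurrences, 0.9 for matrix-building inclusion) are meaningful *within this
package* — no bit-compatibility with any proprietary implementation is
claimed. An `N` base contributes the minimum frequency at its position
(conservative: an ambiguous base can never create a call); a matrix with
all-zero information weights (uniform columns) is rejected rather than
scored. Consensus ties break in A < C < G < T order, making every
downstream result order-independent.

### Building matrices from seed occurrence sets

`build_matrix_from_seeds()` reconstructs a conserved-tuple matrix-definition
procedure: (1) find the 8-mer present in at least 60% of the seed
sequences, breaking ties by total occurrence count and then lexicographic
order; (2) anchor-align all sequences containing it at their first
occurrence and keep the columns covered by every sequence; (3) build a
provisional matrix; (4) rescan *all* input sequences (both strands, best
window) and rebuild the matrix from those scoring at least the inclusion
threshold (default 0.9). The tuple census runs on the forward strand only:
seed occurrence sets produced by a site scanner arrive strand-oriented, and
a strand-blind census would let a near-palindromic variant collapse onto
its own reverse complement and erase real degeneracy from the matrix. The
inclusion rescan, by contrast, is strand-blind, so a mis-oriented seed is
still recovered. If no tuple reaches the required fraction the error
reports the best fraction achieved.

### Scanning

`scan_promoters()` slides every matrix over a TSS-relative window (default
−950 to +50, the region in which the score thresholds are conventionally
applied; the wider 1.5 kb/0.5 kb retrieval context is simply stored with
the sequences) on both strands, reporting all placements with similarity at
or above the threshold. Coordinates are 0-based, half-open and TSS-relative
(negative = upstream); a minus-strand call is reported at the forward
coordinates of the window it occupies, which makes strand closure exact:
scanning a reverse-complemented promoter yields the mirrored calls with
flipped strands. The inner loop is compiled (Rcpp); an R reference scorer
cross-checks it in the test suite, and the optional core-similarity
pre-filter speedup common in commercial scanners is *not* used, so results
are exactly the exhaustive scan.

## Composite modules

A module call is a pair of site calls on one promoter, one from the STAT1
class (GAS or ISRE — STAT1-containing complexes bind both element types;
a GAS-only definition is a configuration away) and one from the partner
class (NFκB or IRF), whose **edge-to-edge** gap

$$\mathrm{gap} = \max(0,\; \mathrm{start}_B - \mathrm{end}_A,\;
                         \mathrm{start}_A - \mathrm{end}_B)$$

does not exceed 50 bp. Overlapping sites have gap 0 and do qualify; element
order and strands are unconstrained, making the rule symmetric in the two
classes. "Not more than 50 nucleotides apart" is read as separation between
the elements' nearest edges — the most natural reading of "apart" — and
both the convention and the GAS/ISRE question are surfaced as configuration
rather than hard-coded, since field usage varies. The per-gene flag table
(`build_flag_table()`) reduces calls to presence flags in the +/− shape of
published module-presence tables.

## Over-representation statistics

For a gene set of size $n$ drawn from a promoter universe of size $N$ in
which $K$ promoters carry a feature, the carrier count $X$ is exactly
hypergeometric under the null of random membership, so

$$E = \frac{nK}{N}, \qquad
  \mathrm{sd} = \sqrt{\frac{nK(N-K)(N-n)}{N^2(N-1)}}, \qquad
  z = \frac{x - E}{\mathrm{sd}},$$

with no continuity correction, and $|z| > 2$ as the conventional
significance boundary (p ≈ 0.05 under the normal approximation). The
background universe is **all promoters in the analyzed input set**, not a
genome-wide collection — the z-score is computed "against promoter
background". Features carried by none or all promoters have sd = 0 and are
reported with an explanatory status instead of a number; an empty or
universe-sized gene set is an error. The moments are verified against
exhaustive enumeration of all $\binom{N}{n}$ draws for every universe up to
$N = 12$, and against $10^5$-draw permutation estimates at realistic sizes.

GO enrichment uses the upper-tail hypergeometric p-value per term over an
ancestor-closed annotation, with Benjamini–Yekutieli adjustment across all
tested terms — BY rather than BH because nested GO terms are arbitrarily
dependent — reporting terms below an adjusted 0.01 (top 20, most
significant first, with $\log_{10} p$). The closure is expected as input; a
minimal OBO `is_a` parser and transitive-closure helper are included for
convenience, but full ontology handling (relationship types other than
`is_a`, cross-products) is out of scope, as is semantic redundancy
reduction of reported terms — the top-k list is the substitute.

## Synthetic data: what is emulated, and what is not

`simulate_expression()` draws per-gene baselines
$\mathcal N(8, 1.5^2)$ log2 units, adds i.i.d. Gaussian noise (default SD
0.5), additive per-gene × batch shifts (default SD 0.3, batches balanced
across groups), and a planted log2 fold change (default 2, i.e. four-fold)
to a random 10% of genes in the case group. `simulate_promoters()` draws
i.i.d. bases at a fixed GC content (default 45%) and plants exact consensus
instances — GAS, ISRE, NFκB, IRF strings shipped as editable fixtures, not
hard-coded — on random strands inside the scanning window, by rejection
sampling so planted features never overlap (keeping the truth manifest
unambiguous). Composite modules (a STAT1-class plus a partner-class
instance, edge gap uniform on 5–50 bp, random order) are planted in 40% of
a designated 100-promoter target set versus 5% of the 5000-promoter
background. Every planted feature is recorded in a manifest from which it
is reconstructible exactly.

Defaults were chosen once to match the validation design: 1000 genes with
10 samples per group (a typical small two-condition cohort), four-fold
planted effects, 2 kb promoters with the TSS at offset 1500 (mirroring a
1.5 kb upstream / 0.5 kb downstream retrieval convention), and the
0.4-versus-0.05 module-rate contrast. The i.i.d. background is the
*simplest model satisfying the enrichment null*; real promoters have CpG
islands, repeats and Markov structure that raise motif false-positive rates
non-uniformly. Passing tests therefore demonstrate correctness of the
statistics and recovery machinery, not that effect sizes on real promoters
will match.

## Numerical choices and degenerate inputs

* Score threshold comparisons are inclusive with a $10^{-12}$ guard, so a
  window scoring exactly at threshold is called on every platform.
* Probabilities for the z permutation and calibration checks use set sizes
  (n = 500 of N = 5000, carrier prevalence ~30–40%) at which the normal
  approximation behind the "$|z|>2 \leftrightarrow p \approx 0.05$"
  interpretation holds; at low-prevalence discrete features the exceedance
  rate of a strict $|z| > 2$ rule is necessarily below 0.0455, which is a
  property of the discreteness, not an implementation artifact.
* Validation problem sizes are the package's own choice: 200 end-to-end
  promoter-universe replicates for planted-module recovery, 1000 replicate
  draws for null calibration, 2000 null genes for type-I error.
* Tuple census ties, consensus ties, and flag-table row order are all
  resolved deterministically, so fixed inputs give bit-identical outputs.
* `collapse_probes()` drops unmapped probes (reported) rather than carrying
  them under probe ids — downstream stages are gene-keyed.
* Gene identity in signatures is the upper-cased HGNC-style symbol; an
  alias map can be applied upstream if cohorts use different symbol
  vintages.

## Known limitations

Raw probe-level preprocessing (background correction, summarization of CEL
files) is out of scope — the pipeline starts from a log2 matrix. The batch
adjustment is not empirical-Bayes; accession-level gene counts obtained
with the full method will differ. The similarity score is a documented
reconstruction, so absolute z-scores from proprietary scanners are not
reproducible, only the statistical behavior. Pathway analysis, literature
mining, and circular-figure rendering are out of scope; the links-file
export is a tabular stand-in consumable by external plotting tools.
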