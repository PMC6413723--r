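---
title: "Methods: the uterine-receptivity analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the uterine-receptivity analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptr)
```

This vignette is the package's account of the science it implements: the
models and rules at each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators emulate (and
deliberately do not), and the numerical and design choices made where the
problem left them open.

## The biological setting

The uterus accepts an implanting blastocyst only during a short receptive
window — day 4 of pregnancy in the mouse, against the non-receptive day 3.
Bulk RNA-seq of whole uterus across these two days, with three biological
replicates each, yields gene-level abundances (FPKM-like, non-negative,
roughly log-normal across genes). The pipeline asks, in order: which genes
change (DE calling), can the changes be confirmed on an independent platform
(qRT-PCR), what processes and upstream regulators they implicate (gene-set
and TFBS enrichment), how the changed genes organize into an interaction
network (hub detection), which compounds might oppose the receptive
expression state (connectivity-map scoring), and how the mouse changes
compare with human endometrial receptivity (ortholog concordance).

## Differential expression

Per gene, the two condition means on the abundance scale give a stabilized
fold change $(m_B + \varepsilon)/(m_A + \varepsilon)$ with
$\varepsilon = 0.5$ pseudo-abundance. The $\varepsilon$ keeps genes silent
in one condition finite and maps genes silent in both to fold change 1 (they
are reported as unchanged with $p = 1$ rather than dropped, so every module
downstream sees the same gene universe). The per-gene test is a two-sided
Welch $t$ on $\log_2(x+1)$ replicate values — a deliberately assumption-light
choice for a 3-vs-3 design on log abundances; the upstream assembler's
internal test is not part of this package's scope, so the test had to be
chosen here, and Welch on the log scale is the conservative field default.
Degenerate inputs are pinned by convention: two constant equal groups give
$p = 1$, constant unequal groups $p = 0$.

A gene is called *up* iff fold change $> 2$ **and** $p < 0.05$, both strict;
*down* symmetrically on the reciprocal. The strictness matters at the
boundary (fold change exactly 2 is unchanged) and is what makes the
partition invariants exact. A `BH` variant (`call_de(adjust = "BH",
p_cutoff = 0.01)`) reproduces the stricter FDR-based criterion sometimes
used for volcano-plot displays; the raw-p criterion is the default because
it is the one stated as the study's gene-selection rule.

Heatmap ordering clusters the DE submatrix with distance $1 - r$ (Pearson)
and average linkage (UPGMA), for genes and samples alike. Zero-variance rows
have no defined correlation and are dropped with a warning. `hclust` is
deterministic given the input order, which fixes tie-breaks; the test suite
checks its merge heights against a direct UPGMA recursion on small matrices.

## qRT-PCR concordance

Relative quantification uses the $2^{-\Delta\Delta C_t}$ method with a
constant reference gene (default *Rpl7*): technical replicates are averaged
on the $C_t$ scale first, $\Delta C_t$ is taken within sample, and
$\Delta\Delta C_t$ is the difference of condition means. Platform
concordance is the Pearson correlation of paired $\log_2$ fold changes; the
log scale is a deliberate choice because the validated genes span roughly
70-fold and a raw-scale correlation would be dominated by the largest fold
changes' leverage. The p-value comes from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df — note this depends on $(r, n)$
only, so it is invariant to the fold-change scale entirely; `pearson_p()`
exposes it directly. For ten validated genes with $r = 0.986$ this gives
$p = 1.65\times 10^{-7}$, computed by `scripts/acceptance.R` at run time.
$|r| = 1$ returns the smallest representable double rather than 0.

## Over-representation testing

`hypergeom_upper(N, K, n, k)` is the exact upper tail $P(X \ge k)$,
delegated to the log-space stable distribution function; the suite verifies
it against exhaustive enumeration of every draw for all $N \le 12$. BH is
the FDR procedure across terms. Terms are tested only when they overlap the
query and their background-intersected size is within $[3, 2000]$ —
standard ORA practice that keeps the number of tests meaningful; both bounds
are arguments. Only over-representation is tested; depletion is out of
scope. GO-style results on real data depend entirely on the annotation
(GMT) supplied by the user; the package computes the statistics, not the
annotation.

## TFBS scanning and enrichment

A PWM (counts or frequencies, rows A,C,G,T) becomes a log-odds matrix by
adding a pseudocount of 0.01 to every cell, column-normalizing, and taking
$\log_2(f/b)$ against a uniform background ($b = 0.25$). Both the
pseudocount and background are arguments; uniform-0.25 is the neutral choice
when the true promoter composition is unknown. Every window on both strands
is scored (promoter binding sites are orientation-tolerant; a
forward-strand-only mode exists), and the min–max relative score
$(S - S_{\min})/(S_{\max} - S_{\min})$ is thresholded at 0.9. The min–max
convention (rather than a likelihood-ratio normalization) is adopted and
documented because it makes the relative score exactly 1 iff the window is
the per-column argmax sequence — a property the tests rely on. Windows
containing `N` are skipped. Minus-strand hits are reported at their forward
1-based start coordinate by scanning the forward sequence with the
reverse-complemented matrix.

For enrichment, a gene counts once per TF regardless of hit multiplicity —
the hypergeometric unit is the gene. With $N$ background genes, $K$ carrying
a site, and $k$ of the $n$ up- (separately, down-) regulated genes carrying
one, the upper-tail hypergeometric p is thresholded at raw $p < 0.01$ per
direction; no multiple-testing correction across TFs by default (matching
the conventional per-TF criterion), with `bh = TRUE` available. A TF with
no site anywhere ($K = 0$) is defined to $p = 1$.

## Interaction network

Edges carry combined confidence scores on $[0,1]$ (a loader flag divides
raw STRING-export scores by 999). The filter keeps scores $\ge 0.4$; the
boundary is read inclusively, a documented choice where usage is genuinely
ambiguous. Hubs are nodes with degree strictly above mean $+ 2\cdot$SD;
the SD is the sample SD ($n-1$), the conservative reading where the
convention is unstated. The scale-free character is summarized by the
least-squares slope of $\log_{10} P(D \ge d)$ vs $\log_{10} d$ over observed
degrees — a survival-function fit, which avoids histogram-binning artifacts
on networks of a few hundred nodes. This slope is descriptive only and never
gates hub detection.

## Connectivity-map scoring

Each drug is a ranking of the gene universe, position 1 the gene most
up-regulated by the drug. For a query set of size $t$ at ascending positions
$V(j)$ in a profile of length $n$:

$$a = \max_j\left(\frac{j}{t} - \frac{V(j)}{n}\right),\qquad
  b = \max_j\left(\frac{V(j)}{n} - \frac{j-1}{t}\right)$$

and the enrichment statistic is $a$ if $a > b$, else $-b$. The connectivity
score is 0 when the up- and down-set statistics share a sign (the drug does
not coherently oppose or mimic the signature) and $ks_{up} - ks_{down}$
otherwise; a statistic of exactly 0 is treated as opposite-direction (the
rule tests the strict product $> 0$) so the score is defined everywhere.
Scaled scores divide negative and positive raw scores by their own absolute
maxima across the queried collection, so the best reverser is $-1$; the raw
score is always reported alongside because the scaling constant is
collection-relative.

Permutation p-values draw `n_perm` random disjoint set pairs of the observed
sizes from the profile's universe and use the add-one estimator
$(1 + \#\{|s_{perm}| \ge |s_{obs}|\})/(n_{perm}+1)$, bounded below by
$1/(n_{perm}+1)$. Random set draws (rather than profile shuffling) are
equivalent under exchangeability and much cheaper. One consequence of the
same-sign rule deserves note: the null score distribution has an atom at
exactly 0, so null p-values have a spike at 1 and are *conservative*, not
uniform; the test suite therefore checks one-sided validity
($P(p \le \alpha) \le \alpha$ plus sampling slack), which is the property
that matters for ranking. Query genes absent from a profile are dropped for
that profile with a message, not imputed.

## Cross-species concordance

Mouse and human DE tables are joined through a strictly one-to-one ortholog
map; many-to-many rows are rejected with the offenders listed, because
paralog expansion silently multiplies counts. Direction comes from the sign
of the log2 fold change of genes already called DE in their own species —
not from re-thresholding — so the classification is independent of either
species' cutoffs. The four sign-pair categories partition the shared set
exactly, and swapping the species transposes the two discordant categories,
both of which are tested properties.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its arguments including the seed;
sub-streams are derived from the seed by fixed per-component offsets so one
component's draw count cannot shift another's stream. Defaults encode the
study design: 1000 genes with 316 up and 225 down planted at mean
$|\log_2 FC| = 2$, three replicates per condition, per-sample noise SD 0.25
on the log2 scale. Expression is log-normal (Normal on $\log_2$, baselines
uniform on $[3, 10]$) rather than negative-binomial counts because the
pipeline ingests FPKM-like abundances, not raw counts; the noise SD of 0.25
is a realistic between-replicate spread for bulk tissue on that scale, and
the effect size of 2 matches the fold-change cutoff's intended signal.

Promoters are i.i.d. uniform background with motif instances sampled from
the PWM's column distributions (consensus-only where a test needs relative
score exactly 1). The network generator grows by preferential attachment
from `m_attach` edgeless seed nodes — the first added node attaches to all
seeds, later nodes proportionally to current degree — giving exactly
$m(n-m)$ edges, a connected graph, and a heavy-tailed degree distribution.
Drug profiles rank genes by uniform scores; the planted reverser shifts the
query's down-set up and up-set down by `effect`, displacing ranks by about
`effect`$\times n$ on average, so `effect = 1` is a perfect reversal. Ct
tables lower the condition-B cycle threshold by $\log_2 FC$ with per-well
Gaussian noise, which the $\Delta\Delta C_t$ arithmetic inverts exactly in
the noiseless limit.

Deliberately **not** modeled: library-size and batch effects, count
overdispersion, dropout, correlated genes, promoter GC structure and repeat
content, network modularity beyond degree structure, and correlated drug
profiles. Passing the planted-recovery tests therefore demonstrates that the
implementations recover the structure they are specified to recover at the
stated noise levels — it does not certify performance on real tissue data,
where these unmodeled features dominate the hard cases.

## Problem sizes and determinism

The test suite and acceptance script run the simulations at the study's own
design sizes (1000 genes, 3 vs 3; 50 drug profiles at 1000 permutations;
1000 promoters of 1 kb; a 289-node network; ten recovery seeds per
criterion), which keeps the whole suite comfortably within a coffee break
while still exercising every stage at realistic scale. All randomness flows
from explicit seeds; reruns are bitwise identical, and `run_pipeline()`
emits a manifest (seed plus every resolved parameter) sufficient to
reproduce a run.

## Known limitations

* The per-gene test is a stand-in chosen by this package (Welch on log2);
  results on real data will differ from assembler-internal tests.
* TFBS results depend on the PWM library supplied; the package ships only a
  small synthetic example matrix.
* Enrichment results are only as good as the supplied GMT; no annotation is
  bundled.
* The CMap scaled score is collection-relative and not comparable across
  different profile collections.
* Cross-species analysis requires a curated one-to-one ortholog map; genes
  with paralogous expansions must be resolved upstream.
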