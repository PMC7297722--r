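---
title: "spliceKey: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spliceKey: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceKey)
```

This vignette is the package's own account of the statistics it
implements: what is modelled, which conventions were chosen where several
were defensible, what the synthetic-data generator does and does not
emulate, and where the method's finite-sample behaviour deviates from its
asymptotic reference. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Splice graph and event taxonomy

Gene models (two or more transcripts per gene, exons in 0-based half-open
coordinates internally; GTF is converted on read) are segmented at every
exon boundary: the nodes of the splice graph are the minimal disjoint
exonic segments of the exon union. Two edge kinds connect nodes —
*adjacency* edges between contiguous segments inside one exon and
*junction* edges across spliced-out introns — and every transcript is a
path. Ordered by coordinate the graph is acyclic.

Alternative-splicing events are *bubbles*: pairs of internally
node-disjoint sub-paths between shared anchor segments, plus alternative
terminal sub-paths at transcript ends. Classification is structural and
strand-aware:

* both ends of the inclusion path junction-bounded → **ES** (skipped
  segments) or **ME** when both alternatives carry disjoint
  junction-bounded segments;
* inclusion path all-adjacency (the region stays exonic) against a direct
  junction → **IR**;
* an adjacency-attached extension at the genomic-left (donor on `+`) or
  genomic-right (acceptor on `+`) anchor → **A5SS**/**A3SS**, with the
  labels exchanged on the `-` strand;
* alternative terminal sub-paths → **AFE**/**ALE**, again by strand.

Two conventions are worth making explicit. First, events are enumerated
from annotation only; junctions observed in reads but absent from the
annotation do not create events. Second, nested or mixed local differences
that are neither clean skips nor clean extensions are classified by a
deterministic tie-break (first/last edge type of the inclusion path, ES as
the fallback); the two-isoform models produced by the generator never hit
the fallback, and the brute-force transcript-pair oracle in the test suite
applies the same rules through independent interval arithmetic, so the
tie-break is exercised consistently on both routes.

Counting categories default to `m = 2`: all inclusion-supporting features
pooled against all exclusion-supporting features. Discriminating features
are the junctions unique to each sub-path; intron retention uses the
retained segment itself on the inclusion side, since no junction supports
retention. Pooling keeps the Dirichlet-multinomial test identifiable at
modest depth, which is why it is the default rather than one category per
junction.

## 2. The Dirichlet-multinomial DAS test

Counts `x_i` over the `m` categories of one event in sample `i` (total
`N_i`) are modelled as Dirichlet-multinomial: `p_i ~ Dirichlet(alpha)`,
`x_i | p_i ~ Multinomial(N_i, p_i)`. The concentration `A = sum(alpha)`
captures replicate-level overdispersion — variance of a category
proportion exceeds the multinomial value by the factor
`(A + N) / (A + 1)`. The log-likelihood omits the multinomial coefficient
(constant in `alpha`); all reported log-likelihoods share the convention.

Estimation is maximum likelihood by BFGS on `log(alpha)` — positivity
without constraints — initialized by method of moments from pooled
proportions at `A0 = 10`, with analytic gradients. `A` is capped at `1e6`:
zero-dispersion data place the optimum on the `A -> Inf` ridge, where the
likelihood is flat in `A` but pinned in the proportions; fits on the ridge
are promoted to the cap and flagged. The test suite certifies the
optimizer against a profile grid oracle over `(proportion, A)`.

The test compares H0 (one shared `alpha`) against H1 (per-condition
`alpha`); `2(l1 - l0)`, floored at zero, is referred to chi-square with
`df = m` (H1 has `2m` parameters, H0 has `m`). Events with fewer than 10
pooled reads in either condition are reported untested rather than fitted.
Per-sample PSI divides pooled category counts by the number of pooled
features before forming the ratio (per-junction averaging), so multi-
junction inclusion paths are not biased upward; condition-level PSI applies
the same correction to the fitted Dirichlet proportions, and the reported
`delta_psi` is the difference of those fitted values (model-consistent;
the per-sample values are descriptive). Calling uses the strict printed
thresholds `|dPsi| > 0.05` and BH `q < 0.05`, with BH computed by the
step-up rule over the tested events only.

**Finite-sample behaviour.** The chi-square reference is asymptotic in the
number of replicates, and estimating a separate concentration from five
samples per condition overfits H1 slightly. At the generator's default
conditions (5+5 samples, depth 200, `A = 100`) the acceptance suite
measures a null type-I error of about 0.07 at nominal 0.05 and a p-value
ECDF sup-distance of about 0.08 — mildly anticonservative. The inflation
grows with overdispersion (stronger at `A = 20`) and disappears with more
replicates or higher concentration (near-nominal at `A = 200`). We keep
the statistic and its `df = m` reference as defined rather than applying
an ad-hoc correction, and flag this as the method's main small-sample
caveat: at five replicates per group, downstream q-values are slightly
optimistic under strong overdispersion. Planted-effect recovery is
unaffected (delta-PSI mean absolute error ≈ 0.028 at `|dPsi| = 0.2`,
with ≥ 90% recall against ≤ 7% false calls in the same suite).

## 3. Signed signatures

A perturbation has `sign = +1` (overexpression, knockin) or `-1`
(knockout, knockdown); perturbations without a defined direction (point
mutations, compound treatments) are rejected unless the caller supplies a
sign, because the regulation rules below are only defined for directional
changes. For a tested event, the splicing state is
`sign(delta_psi) * sign` when `|dPsi| > 0.05` and `q < 0.05`, else `0`:
`+` means the factor positively regulates inclusion. Events untested in a
comparison are *absent from its universe*, not `0` — "unchanged" and
"unmeasured" are deliberately distinct, and comparisons only ever use the
intersection of tested universes. Both the disease and compendium sides
use the same thresholds by default (configurable).

Expression signatures come in two semantics: *factor-directional*
(`up` = `sign * log2FC > 0.5`, `q < 0.05` — positively regulated by the
factor) and *process-directional* for the disease side (raw sign of
`log2FC`; the `|log2FC|` cut has no default because applications
legitimately vary it, e.g. 0.2 for weak transcriptomic phenotypes and 1.0
for strong ones). The background is the set of expressed genes in the
table, i.e. whatever survived upstream low-count filtering.

## 4. Noncentral Fisher comparison

Two splicing signatures are crossed into a 3×3 table over the shared
universe and collapsed into two focal 2×2 tables (`++` and `--`): the
focal cell `a`, its row and column remainders, and everything else. Each
is tested one-sided for enrichment of `a` under
`H0: log-odds-ratio < 0.5`. The p-value is `P(X >= a)` under Fisher's
noncentral hypergeometric distribution with the table's margins and odds
ratio `psi_0 = exp(0.5) ~ 1.649`, computed by direct enumeration over the
support with log-space normalization. The base of the logarithm in the
null is a genuine ambiguity; natural log is the default and the base is
exposed (`log_base`), with `psi_0 = 1` recovering the classical one-sided
Fisher exact test (verified against `stats::fisher.test` and a
`dhyper`-reweighting oracle to ~1e-15 over all tables with margins ≤ 30).
The mechanics of the composite null deserve one sentence: we evaluate the
exact conditional test at the boundary `psi_0`, the supremum of the null,
which is the standard conservative treatment of a one-sided composite
hypothesis. Sample odds ratios are reported as `ad/bc`, with a flagged
+0.5 Haldane correction when a cell is zero; p-values never use the
correction, since the exact enumeration handles zeros natively.

For one disease comparison, all factor comparisons and both directions are
tested and BH-adjusted *jointly*; expression-side screens pool across
factors, disease sides and factor sides the same way. Candidates require
`q < 0.25` strictly. Pairs with no shared tested events propagate as
untested rows excluded from the pool.

## 5. Design-covariate models

`#DAS` is modelled as OLS on `T`, `L`, `S`, `T:L`, `T:S` (and `#DEG` on
`T`, `S`, `T:S`; read length does not bear on gene-level power, so `L` and
`T:L` are omitted). The `L:S` and `T:L:S` interactions are deliberately
absent from the DAS model. Covariates stay on natural scales (spots, bp,
count) and responses are raw counts, matching the models as written.
Effective read length is the read length for single-end libraries and the
sum of mate lengths for paired-end. Comparisons are filtered to
`T >= 1e8` spots and `L >= 150` bp, both inclusive.

Normalization to a canonical design shifts *internally studentized*
residuals: `r_i = e_i / (sigma_hat * sqrt(1 - h_ii))` and
`normalized_i = yhat(canonical) + r_i * sigma_hat`. Studentization was
chosen over plain `e_i / sigma_hat` because leverage varies substantially
across the skewed covariate ranges involved; observations with leverage 1
carry no residual information and are excluded with a warning. The
canonical design defaults to the component-wise median of the filtered
comparisons' covariates — no authoritative canonical point exists, and the
median keeps the point inside the covariate hull (a warning fires
otherwise). Pearson correlation of the normalized counts uses the exact
t reference `t = r * sqrt((n - 2) / (1 - r^2))`.

## 6. The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions used throughout the suite:

| parameter | default | rationale |
|---|---|---|
| samples per condition | 5 | typical perturbation RNA-seq arm size |
| depth per event | 200 reads (Poisson) | moderately deep bulk RNA-seq; Poisson totals avoid fixed-N artefacts in fitting |
| precision `A` | 100 | replicate PSI SD ≈ 0.05 at PSI 0.5 under a beta-binomial implies `A ≈ 100` |
| baseline PSI | 0.5 | maximally informative inclusion level |
| planted `|dPsi|` | 0.2 | well above the 0.05 call threshold, so recovery tests measure the method, not raw power |
| compendium | 10 factors, 2 planted, 30% signed overlap | small screen with unambiguous ground truth |
| planted `|log2FC|` | 1.0 (noise SD 0.1) | clears the 0.5 signature cut decisively |
| event universe (abstract) | 2000, signatures 200 signed | ~10% signature density, matching a strong perturbation |
| metadata | `T ~ U(2e7, 4e8)`, `L ∈ {50..300}`, `S ∈ 4..16` | spans the published covariate filter on both sides |

Per event and sample the generator inverts the DAS model exactly —
`p ~ Dirichlet(A * pi)`, counts `Multinomial(Poisson(depth), p)` — with
expected category mass scaled by the number of pooled features, so the
per-junction-averaged PSI convention recovers the planted value. DEG
q-values are emitted directly rather than recomputed from a DE test,
because that test sits upstream of this package's scope. One global seed
drives everything; module-level streams are derived by fixed offsets so
partial re-runs reproduce the full-run streams.

What the generator does **not** emulate: read-level artefacts (mapping
bias, positional coverage, GC effects), annotation incompleteness, shared
junctions between overlapping events, correlated events within a gene, or
any particular published dataset. Passing tests therefore certify the
statistics and their implementation under the stated model — not
robustness to misspecification of real libraries.

The end-to-end pipeline (`run_pipeline()`) chains every stage on generated
inputs — GTF write/read, graph/enumeration, planted counts, DAS testing,
signature construction, both comparison paths, and the design models —
writing each stage output and a manifest; reruns with the same config are
byte-identical. Its default planted fraction is 0.1 of enumerated events,
the signature density at which the compendium screen is realistically
powered. Pipeline-scale runs in the suite use 300–600 events and the
calibration/recovery simulations use 1000–2000 events, sizes at which the
Monte-Carlo error of the reported rates is a few parts per thousand.

## 7. Numerical choices and degenerate inputs

* BH is the step-up rule `q_(i) = min_{j>=i}(p_(j) n / j)` clipped to 1,
  stable under input order; it matches `stats::p.adjust(..., "BH")` to
  multiplication-order rounding (~1e-16).
* DMN fits: convergence requires a vanishing gradient or the BFGS
  convergence code; the `A` cap is recorded (`capped`). All-zero count
  matrices are an error ("no information"); all-zero samples are dropped
  from fits; an all-zero *condition* makes the event untestable with
  `p = 1` by convention.
* Noncentral-Fisher: an all-zero table returns `p = 1`, flagged
  degenerate; `a` at the support minimum gives `p = 1` exactly.
* Zero-total samples have undefined per-sample PSI (reported `NA`,
  excluded from display, fits unaffected).
* Event ids are `gene:type:start-end` with lexicographic (gene, type,
  start) ordering — deterministic across runs; ties between structurally
  identical bubbles deduplicate on the id.
* Rank-deficient design matrices in the covariate models raise an error
  naming the collinear terms rather than silently dropping them.

## 8. Known limitations

1. The LRT's mild anticonservatism at few replicates under strong
   overdispersion (section 2) — the one acceptance property the method
   does not meet at the default study conditions.
2. Annotation-only events: novel junctions are invisible.
3. Two-condition designs only; no pairing or covariate adjustment in the
   DAS test.
4. Comparison-level candidate calls; no aggregation of multiple
   comparisons of the same factor into a single factor-level score.
5. The composite-null treatment (boundary enumeration) is conservative
   for true odds ratios strictly inside the null.
6. The linear models assume unsaturated designs; saturation at extreme
   read counts is not modelled.
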