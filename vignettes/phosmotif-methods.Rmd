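---
title: "Methods: from TMTpro reporter ions to kinase-motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from TMTpro reporter ions to kinase-motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosmotif)
```

## The problem

A common design in quantitative phosphoproteomics compares genotypes (for
instance, a kinase knockout against wild type) across a 16-channel TMTpro
plex: phosphopeptides are enriched, labelled, and quantified by reporter-ion
signal-to-noise per channel. Attributing the differential phosphosites that
emerge to upstream kinases is the hard part: a single kinase's loss perturbs
many other signalling components. phosmotif implements the inference chain
that addresses this — reporter-level processing, per-site differential
statistics, position-specific scoring matrix (PSSM) substrate prediction,
and per-kinase motif enrichment — together with a synthetic-data generator
that spikes a known kinase effect, so that every stage can be validated
against ground truth.

## Reporter-level processing

**Impurity correction.** Each TMTpro reagent leaks known fractions of its
signal into neighbouring channels. With mixing matrix $M$ (column $j$ = the
observed distribution of reagent $j$'s signal), the observed vector is
$M x$; `correct_impurities()` solves the full linear system for $x$ rather
than subtracting sequentially, because that is the exact inverse of the
stated mixing model. Solutions that come out slightly negative through
floating-point noise are clamped to zero.

**Quality filters.** `filter_records()` rejects PSMs with 12 or more of the
16 channels missing, isolation specificity below 0.8, summed reporter
signal-to-noise below 160, or a localization (AScore) below 13 — the
threshold corresponding to 95% confidence in site localization. All
inequalities are strict exactly as written: a summed S/N of exactly 160 is
kept. The total-proteome policy relaxes isolation specificity to 0.7,
rejects at 8 or more missing channels, and applies no localization filter.
Each rejected record is tagged with the *first* failing reason in a fixed
order (missing channels, isolation specificity, summed S/N, localization,
no quantification), which keeps rejection reports deterministic and
auditable.

**Normalization.** Proteins are quantified by summing reporter S/N over
matching PSMs (`collapse_to_protein()`). `normalize_equal_loading()` scales
each channel so all channel totals equal the mean of the original totals —
a scale-preserving, symmetric choice (scaling to the maximum would inflate
the data). Phosphosite rows are then divided by their protein's *relative*
channel profile (`normalize_phospho_to_protein()`), removing protein-level
abundance changes while leaving sites without a quantified protein
untouched but flagged; whether the original analysis used relative or
absolute protein values is not recoverable, and relative profiles are the
variant that leaves a flat-profile protein as a no-op. Finally the log2
table is median-centered per channel. Dataset-level normalization in
published pipelines is often delegated to an external package whose exact
internal transformations are not documented; median centering is the
simplest defensible surrogate and is isolated in `median_center()` so an
alternative (quantile, batch) can be substituted. Missing values stay
missing throughout — no imputation.

## Differential statistics

`contrast_stats()` computes, per site, the difference of mean log2
abundances between the numerator and denominator channel groups and a
two-sample unequal-variance (Welch) t test on the log2 values. Welch is the
robust default when the original test behind a reported "P value and FDR"
cannot be recovered from a Perseus-style analysis. Zero-variance sites with
unequal means receive the smallest representable positive P and a
`degenerate` flag (this arises only in noise-free simulations); sites with
fewer than two observations per side are skipped with a reason.
P values are adjusted per contrast by Benjamini–Hochberg (`adjust_fdr()`).

`classify_sites()` applies the printed stratum definitions with their exact
boundary conventions: **down/up** = $|\log_2 FC| \ge 1$ and FDR $\le 0.1$;
**unregulated** = $|\log_2 FC| < 1$ and FDR $> 0.1$; everything else is
**intermediate** and belongs to neither enrichment stratum (their count is
recorded). Tier labels mark strongly changed sites at raw $P < 0.01$
(tier 1) and $P < 0.05$ (tier 2) with $|\log_2 FC| \ge 1$; the source
analysis pairs these P cutoffs with FDR percentages whose derivation is not
fully explicit, so the tiers here are anchored to the unambiguous raw-P
cutoffs and all thresholds are exposed as parameters.

## Kinase-substrate prediction

Sites are represented by the 11-residue window centred on the
phosphoacceptor (`extract_flank()`), padded with `_` beyond the protein
termini. Only S/T centres are scoreable — the motif library describes
serine/threonine kinases. Each kinase's PSSM covers positions −5..−1, +1..+5
over the 20 residues; the raw score of a flank is

$$s = \sum_{\text{off-centre } i} \log_2 \frac{p_i(\text{residue}_i)}{1/20},$$

the log-odds against a uniform background, with padding contributing zero
and the central residue not scored (matrices are defined on flanking
positions). The formula sits behind a single function (`score_flank()`) so
alternates can be swapped.

Raw scores are not comparable across kinases, so each score is converted to
a percentile of that kinase's background score distribution
(`percentile_of()`: the empirical CDF in percent). By default the
background is the kinase's scores over all scored sites in the current
dataset — a self-contained choice; a library-supplied reference sample
(e.g. scores over a reference phosphoproteome) overrides it when present,
since published percentiles may have been computed against either.

Per site, kinases are ranked by percentile (raw score as secondary key,
kinase id as deterministic tie-break); the top 15 — mirroring the
top-15-of-303 convention — are that site's *predicted kinases*
(`predict_kinases()`). Independently, a site is a *putative substrate* of a
kinase when its percentile strictly exceeds 95 (`putative_substrates()`).
Scoring operates on non-duplicate, singly phosphorylated sites only
(`dedup_sites()`). Phospho-priming (lowercase pre-phosphorylated residues
in flanks) is not modelled.

## Kinase-motif enrichment

For each kinase, a 2×2 table compares the fraction of sites that carry the
kinase among their predicted kinases between the downregulated (resp.
upregulated) stratum and the unregulated stratum. Significance per side is
a one-sided Fisher exact test — the hypergeometric upper tail
$P(X \ge a)$ — adjusted by Benjamini–Hochberg *within each side across
kinases* (two families of tests, matching per-side adjustment of "the
corresponding P values"). Kinases significant on **both** sides at adjusted
$P \le 0.1$ (read inclusively, consistent with the FDR $\le 0.1$ stratum
definition) are excluded; for the rest the more significant side is
selected, with a tie resolving deterministically to down. The scatter
coordinates are $-\log_{10}$ of the selected side's adjusted P against the
log2 ratio of predicted fractions, with a 0.5 pseudocount applied when a
zero cell would make the ratio undefined — the axis choice is conventional;
any monotone effect size would do.

## pLogo-style motif statistics

`plogo_stats()` quantifies residue preference at each flank position as the
signed log odds of a binomial tail: with foreground count $k$ of $n$ and
background probability $p$ (background residue frequency at that position
with a 0.5-per-residue pseudocount), the height is
$-\log_{10} P(\mathrm{Bin}(n,p) \ge k)$ for over-representation and
$+\log_{10} P(\mathrm{Bin}(n,p) \le k)$ (negative) for depletion. The
default background is the study's unregulated-site flanks — the natural
in-dataset null; the published tool's own background choice is not
documented, so it is configurable. Tails are computed on the log scale
(`pbinom(..., log.p = TRUE)`), which keeps extreme heights (e.g.
$20\log_{10}20 \approx 26$ for 20-of-20 at $p = 0.05$) exact.

## The synthetic-data generator

The generator emulates the study conditions: one 16-channel TMTpro plex
carrying {WT, TBK1-null} × {untreated, inhibitor} in quadruplicate (how six
biological groups were laid out across four real plexes is not stated, so
the group-to-channel map is an explicit argument, defaulting to the four
groups of four), 10³–10⁴ phosphosites with ±5 flanks, lognormal reporter
noise (Gaussian on log2 — homoscedastic, matching the log-scale t
statistics), and a spiked kinase whose motif-derived sites are shifted by
`effect_log2` in the TBK1-null channels (a genotype-driven effect).

PSSMs are drawn per position from a symmetric Dirichlet with concentration
$1/\texttt{sharpness}$, so a single parameter controls motif information
content and larger sharpness means peakier motifs; sampling uses the
$\Gamma(a) = \Gamma(a+1)\,U^{1/a}$ representation on the log scale, which
stays exact where naive gamma draws underflow. Flanks mix motif-derived
sites (each off-centre residue sampled from the generating kinase's PSSM
row) with uniform background sites at `motif_fraction`. PSM-level defects
(low isolation specificity, low summed S/N, ≥12 missing channels, low
localization) are injected independently at configurable rates, and the
injected counts are recorded so filter behaviour is checkable. One root
seed is split into fixed per-operation streams (`derive_seed()`), making
each stage reproducible in isolation.

Default study-scale parameters, chosen once: 2000 sites, 50 kinases,
baseline log2 abundance $\mathcal{N}(10, 1.5)$ (reporter S/N of a few
hundred to a few thousand), noise sd 0.25 (typical inter-replicate spread
for TMT phospho data), effect −2 log2 (the "greater than twofold" regime),
motif fraction 0.5. With 50 kinases the spiked kinase contributes ~20
affected sites (~1% of sites), close to the regulated fraction of the real
dataset. Test fixtures that shrink the library keep this affected fraction
and the predicted-call rate (top-k over library size) near study ratios,
because two artifacts otherwise dominate at toy scale: median centering
transfers a visible offset onto null sites when the affected fraction is
large, and a top-15 rule over 20 kinases predicts 75% of kinases for every
site, destroying contrast.

What the generator does **not** emulate: peptide-spectrum matching,
chromatographic or fractionation structure, inter-plex batch effects,
missing-not-at-random intensity dependence, multi-site peptides, or
correlated site effects within proteins. Passing the synthetic recovery
tests therefore demonstrates correctness of the statistical chain under the
stated model, not robustness to every pathology of real data.

## Numerical choices and degenerate inputs

- Impurity correction: full linear solve; singular matrices are an error,
  tiny negative solutions are clamped at relative 1e-8.
- Fisher with degenerate margins (empty stratum or nothing predicted)
  returns P = 1 by convention.
- Equal-loading normalization errors on a zero-sum channel, naming it;
  median centering errors on an all-missing channel.
- Percentile ties count as "≤" (empirical CDF); predicted-set ties break by
  raw score, then kinase id.
- The smallest positive double stands in for P at zero variance with
  unequal means, flagged rather than silently propagated.

## A worked run

```{r run, eval = FALSE}
cfg <- run_config(
  mode = "simulate",
  sim = sim_config(n_sites = 2000, target_kinase = "KIN007",
                   effect_log2 = -2, noise_sd = 0.25,
                   motif_fraction = 0.5, seed = 11),
  n_kinases = 50)
out <- run_pipeline(cfg)
table(out$differential$regulation)
head(attr(out$enrichment, "scatter"))
```

The run report (`out$report`) carries stage counts — records in, rejections
per reason, sites tested and skipped, stratum sizes, kinases tested and
excluded — whose conservation is itself asserted in the test suite.

## Known limitations

- The Welch test has no variance moderation; very small replicate numbers
  (< 3 per side) give noisy P values, and an empirical-Bayes variant is out
  of scope by design.
- Percentiles computed against the in-dataset background shift with dataset
  composition; cross-study comparisons should supply a fixed reference
  background.
- The tier definitions resolve an ambiguity in the source convention (see
  above) and should be re-parameterized if a different mapping is intended.
- Intermediate sites (strong fold change but high FDR, or the converse)
  belong to neither enrichment stratum; their count is reported so the
  information loss is visible.
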