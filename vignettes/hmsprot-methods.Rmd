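---
title: "Methods: expression misregulation screening and cis-regulatory hotspot testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression misregulation screening and cis-regulatory hotspot testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmsprot)
```

# The problem

Hybrid males between *Drosophila pseudoobscura pseudoobscura* and
*D. p. bogotana* are sterile in one cross direction, and male reproductive
tract (MRT) proteases are heavily over-represented among the genes
misregulated in those sterile F1 males. Misregulation in a sterile hybrid
is, however, not evidence of a causal link to sterility: backcross (BC) and
introgression (IG) males that are fully fertile carry many of the same
genomic mismatches, and any gene that reaches sterile-like expression in
*fertile* progeny cannot have its misregulation directly tied to hybrid
male sterility (HMS).

`hmsprot` implements that screening logic as a reusable pipeline:

1. relative expression from qRT-PCR Cq values (dual reference genes),
   with per-gene ANOVA, Scheffé post-hoc contrasts, Benjamini–Hochberg
   q-values and compact letter displays;
2. a genetic exclusion rule over the fertile BC/IG classes, plus the call
   of genes modulated by the X-linked HMS gene *Ovd* (tracked through the
   linked *sepia* marker);
3. tissue-enrichment statistics (testes vs accessory glands) and
   expression-extremes filters that prioritize sperm-side candidates;
4. mapping of fixed interspecies substitutions in TSS-relative coordinates
   from aligned sequence pairs, with a shared-polymorphism filter;
5. an empirical-CDF clustering ("hotspot") test for those substitutions,
   with Monte Carlo and exact-enumeration null distributions.

A synthetic-data generator reproduces the statistical structure of every
input, so the full pipeline is testable end to end without any external
data.

# Relative expression

Expression is quantified as
$\Delta C_q = C_q^{\mathrm{ref}} - C_q^{\mathrm{target}}$, so one unit is
one PCR cycle ($\approx$ 2-fold on the linear scale) and *higher* ΔCq means
*higher* relative expression. Two reference genes (RpL32, RpS18) are
assayed for every sample. Their effect is additive in practice: a two-way
ANOVA (`two_way_anova()`) of gene and reference shows main effects but no
interaction on well-behaved data, which licenses pooling. The per-gene
one-way ANOVA across sample classes (`anova_per_gene()`) therefore centers
ΔCq within each reference gene before fitting, removing the additive
offset without doubling every test; a `pool_references = FALSE` mode fits
each reference separately for users who prefer two families.

Pairwise class contrasts use Scheffé's method: for classes $i, j$ with
$k$ classes and $N$ observations,

$$S = \frac{(\bar y_i - \bar y_j)^2}{\mathrm{MSE}\,(1/n_i + 1/n_j)(k-1)},
\qquad p = \Pr\{F_{k-1,\,N-k} \ge S\},$$

which protects all pairwise contrasts simultaneously and reduces to the
pooled-variance F test at $k = 2$. q-values are Benjamini–Hochberg
(`bh_fdr()`, via `stats::p.adjust`). The default FDR family is *joint*
across all genes' pairwise contrasts in the experiment — the conservative
reading of a single experiment-wide correction — with a per-gene family
available (`fdr_scope = "per_gene"`). Significance is fixed at $q < 0.05$
(configurable `alpha`).

Group letters (`letter_display()`) use the insert-and-absorb algorithm,
and the package verifies by brute force that two classes share a letter
*iff* they are not significantly different.

Degenerate layouts are handled explicitly: exactly-zero residual variance
yields $F = 0, p = 1$ when the group means are also equal and
$p = 0$ (with a warning in the Scheffé routine) when they differ; rows
with non-finite Cq are dropped with a warning and counted.

# The exclusion rule

Classes are labelled Dpb, Dpp (parents), BC1p, BC1b, BC4 (backcrosses),
F8y, F8y+, F8se, F8se+ (introgressions) and F1sterile. F8se+ males carry
the introgressed *Ovd*-linked sterility allele and are sterile; the
*fertile* classes are exactly {BC1p, BC1b, BC4, F8y, F8y+, F8se}.

A gene × class pair is *misregulated* when the class differs significantly
from **both** parental species. A gene is **excluded** as an HMS candidate
iff it is misregulated in at least one fertile class *and* at least one of
those classes is **not** significantly different from sterile F1 males —
fertile males then reach sterile-like expression, so the misregulation
cannot be causal for sterility. A gene misregulated in fertile progeny
whose misregulated classes all *do* differ from sterile F1 is retained by
the letter of the rule but flagged `review`, because the rule only
licenses exclusion through the matching-F1 condition. On the bundled
reference flags this reproduces the published narrowing: 19 genes → 9
excluded → 10 retained, with GA24206 excluded through its backcross branch
alone (its single misregulated introgression class differs from sterile
F1).

Genes with a significant F8se vs F8se+ contrast are reported as likely
*Ovd* targets (`identify_ovd_targets()`).

# Tissue enrichment and prioritization

For each candidate the testes/accessory-gland statistic is
$\mathrm{ratio} = |\Delta C_q(T)| / |\Delta C_q(AG)|$, rounded to 2
decimals, with the enriched tissue decided by the *signed* comparison
($T$-enriched iff $\Delta C_q(T) > \Delta C_q(AG)$) and
$\mathrm{fold} = 1/\mathrm{ratio}$ (reciprocal of the **rounded** ratio)
for testes-enriched genes. This magnitude-ratio convention is a log-scale
artifact, not a linear expression ratio — it is kept because it is the
convention of the reference tables this package reproduces (e.g.
$1/0.04 = 25.00$, where the unrounded reciprocal would be 27.9); both
unrounded values and a clearly-labelled linear-scale
$2^{\Delta\Delta C_q}$ fold are also emitted. One known divergence is
documented: the GA19543 row of the bundled table reports ratio 0.65 where
its printed means give $7.44/11.31 = 0.658 \to 0.66$, presumably computed
from unrounded means; the value is flagged, not corrected.

Prioritization drops accessory-gland-enriched genes (HMS is a
sperm-motility phenotype), genes with $\Delta C_q < -10$ in *all* assayed
MRT tissues (too lowly expressed) and genes with $\Delta C_q > -5$
everywhere (housekeeping-like). On the bundled data: 10 candidates → 7
prioritized.

# TSS coordinates and substitution mapping

Sequenced fragments are addressed TSS-relatively with **no position 0**
(−1 abuts +1); a fragment −1123..+518 therefore spans exactly
$1123 + 518 = 1641$ positions. `tss_to_index()` / `index_to_tss()` form a
bijection with the internal 1-based ungapped index.

`call_differences()` walks an alignment on the species-a (reference)
frame: mismatched columns yield SNVs, runs of gap columns in one species
collapse to a *single* indel event at the leftmost affected base
(insertions anchor to the preceding species-a base), and ambiguity-code
columns are skipped with a warning. Counting an indel as one event is what
makes the reported substitution proportions (events / fragment length)
come out right.

Domains follow the window rules P = −200..+200, PP = −500..−201,
PD strictly upstream of −500 (−500 itself is PP), with feature annotations
taking precedence: CDS (reported `CDS/P` inside the promoter window),
5′ UTR (`T(5'UTR)`), transcript (`T`), or an annotated neighboring gene's
name.

An apparent difference is demoted to *shared polymorphism* when the
species-b allele also segregates among conspecific strains of species a at
that site. Evidence is a per-site allele table or raw strain reads; a read
contributes only when its global identity against its best-matching
ungapped window of the species-a fragment exceeds 90%. This reproduces the
read-screening contract at desk scale without a heuristic search engine.
Because the matching is ungapped, a read carrying a shared *deletion*
rarely clears the identity bar; shared indels should be supplied through
the allele table. The bundled fragment table carries one internal
inconsistency of its source as-is: GA30092's reported length (1710)
exceeds the span of its reported TSS bounds (1667); the reported length is
used for proportions, the span for coordinate arithmetic.

# The clustering (hotspot) test

For $n$ events at sorted 1-based indices $x_1 < \dots < x_n$ on $N$
positions,

$$G_i = \frac{i}{n} - \frac{x_i}{N}, \qquad
T = \max_{i<j}\,(G_j - G_i).$$

$G_i$ is the gap between the empirical CDF of events and the uniform CDF
at the $i$-th event; a large positive $\Delta G = G_j - G_i$ marks the
stretch $(x_i, x_j]$ accumulating events faster than uniform placement
would predict. The null distribution of $T$ is obtained by Monte Carlo:
$n$ indices drawn uniformly *without replacement* from $1..N$ (100,000
replicates by default), with the add-one convention
$p = (1 + \#\{T^* \ge T\})/(n_{\mathrm{sim}} + 1)$ so $p > 0$ always; the
raw exceedance count is also reported.

Design choices:

* **One-tailed positive convention.** The *a priori* hypothesis is an
  accumulation (hotspot) of substitutions, so $T$ is the signed maximum of
  $\Delta G$, not $\max |\Delta G|$; super-dispersed configurations can
  give $T \le 0$ and are reported as-is. A two-tailed $|\Delta G|$ mode is
  available behind `two_tailed = TRUE`.
* **Inclusive hotspot count.** The maximizing pair $(i, j)$ is reported
  with ties broken towards the smallest $i$, then $j$, and the hotspot
  contains $j - i + 1$ events counting both endpoints (the convention that
  makes the promoter-distal GA22690 window read "8 changes from −751 to
  −525").
* **Regions.** `hotspot_scan()` tests the whole fragment and each domain
  window with ≥ 2 events, BH-correcting across all reported rows. For
  GA22690 the whole-fragment maximizer extends to −289 while the
  PD-restricted maximizer is −751..−525; since the source of the published
  significance call is ambiguous between the two views, both are always
  reported and neither is silently preferred.
* **Oracle.** `exact_null_enumeration()` enumerates all $\binom{N}{n}$
  configurations (refusing above $10^6$) and the test suite checks the
  Monte Carlo null against it within binomial error, plus the uniformity
  of null p-values (Kolmogorov–Smirnov distance < 0.02).
* Indels enter as single point events at their leftmost index, consistent
  with the event caller. Whether the single-base deletion at GA22690
  −1052 belonged in the published event count is not recorded; it is
  included here.
* The Monte Carlo draw is vectorised (with-replacement proposal, exact
  redraw of colliding rows) and seed-deterministic; the seed is stored in
  every result object.

# The synthetic generators

`generate_cq_table()` draws, for every (gene, class, reference,
replicate), a reference and a target Cq with *independent* Gaussian noise
of SD `replicate_sd` on each, so the ΔCq group SD is
$\sqrt{2}\,\times$ `replicate_sd`; the expectation of
$C_q^{\mathrm{ref}} - C_q^{\mathrm{target}}$ equals the scenario mean.
The second reference gene's mean is shifted by `reference_offset`
(default +1 cycle), emulating the uniformly-higher readout of one
reference. Within-group variances are **assumptions, not published
values** — the source experiments report means and significance calls
only; the defaults (SD 0.3 cycles, 5 replicates) are typical for
technical-quality qRT-PCR on pooled fly tissue.

For end-to-end tests the sterile-F1 class mean must also be invented: for
excluded genes it is the mean of their misregulated fertile classes
(those classes reach sterile-like levels — that is what excludes them);
for retained genes it is placed 2 cycles below the gene's lowest class
mean, because the assay panel was *selected* as misregulated uniquely in
sterile F1 males, so the sterile state must be distinct from every fertile
class. Under those conditions the 10-gene retained set is recovered
essentially always (10/10 seeds at ΔCq SD 0.3, n = 5).

`generate_sequence_pair()` plants background differences at
Bernoulli(`background_rate`) sites plus a fixed number of cluster events
drawn without replacement inside a window; differences are SNVs or
single-column deletions (`indel_fraction`), with adjacent planted
deletions demoted to SNVs so planted events stay 1:1 with called events.
Strain reads are fixed-length windows of the reference sequence carrying
the alternate allele at shared-polymorphism sites — the minimal structure
needed to exercise the identity-threshold contract. Real data differ in
ways the generator does not emulate: sequencing error, alignment
ambiguity in repeats, multi-column indels (only consumed from curated
tables, never generated) and linked polymorphism; passing tests show the
*pipeline logic* is right under its stated model, not that these
nuisances are handled.

`generate_fecundity()` draws negative-binomial offspring counts with
variance $\mu + \phi\mu^2$ ($\phi = 0$ → Poisson; a zero mean → a sterile
all-zero class). Overdispersion is the norm for offspring counts; the
source reports means and SEs only, so $\phi$ is a free parameter
(default 0.02).

All generators are byte-reproducible given the scenario seed and restore
the caller's RNG state.

# Problem sizes and runtime choices

The bundled reference analyses are exact or near-instant (brute force over
45 event pairs; 100,000-replicate vectorised Monte Carlo in about a
second). The test suite's simulation studies use: 200 seeds for
planted-cluster power (2,000-replicate inner null), 1,000 seeds for
one-way ANOVA type-I calibration, 10,000 outer × 2,000 inner replicates
for null p-value uniformity (the outer count is chosen so the expected KS
statistic of a truly uniform sample, $\approx 0.87/\sqrt{n}$, sits well
below the 0.02 bound being certified), and 5 seeds for the full end-to-end
expression screen. These sizes were fixed before the checks were run.

# Known limitations

* The Scheffé/FDR machinery assumes homoscedastic Gaussian ΔCq within
  groups; no mixed-effects or amplification-efficiency modelling.
* The exclusion rule consumes significance *flags*; with real data those
  flags inherit all upstream assumptions.
* Shared-polymorphism screening by reads is ungapped and desk-scale; it is
  a filtering contract, not an aligner.
* The hotspot test conditions on $n$; it asks *where* events fall, not
  *how many* there are.
* ΔΔCq fold changes between sample classes are intentionally out of
  scope: the analysis operates on ΔCq directly.
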