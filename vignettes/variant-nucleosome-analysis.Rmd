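---
title: "Calling and classifying histone-variant nucleosomes from tiling-array signal"
author: "varnuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying histone-variant nucleosomes from tiling-array signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varnuc)
```

# The problem

Replication-independent histone variants such as H3.3 mark active,
dynamically regulated chromatin. Mapping where single nucleosomes carrying
the variant sit — promoters, gene bodies, transcription termination sites
(TTSs) — requires three things from probe-level ChIP signal on a tiling
array: (i) positions of well-phased single nucleosomes, (ii) a decision,
per nucleosome, whether the variant is present above background, and
(iii) genome-scale summaries relating those nucleosomes to gene anatomy
and expression. `varnuc` implements that chain for four normalized
log2-scale channels — variant ChIP, bulk-histone ChIP, a non-immune IgG
control and input — plus a gene annotation and a gene-by-condition
expression matrix.

# Nucleosome calling

The caller resamples irregular probes onto a uniform grid (default 10 bp)
by linear interpolation, then applies a Savitzky–Golay filter, which fits
a local least-squares polynomial and therefore preserves peak areas,
extremum positions and widths — precisely the properties the downstream
geometry depends on. Candidate nucleosomes sit at downward zero crossings
of the first derivative; each candidate's support runs between the nearest
second-derivative zero crossings (the inflection points, i.e. the peak
borders). A parabola `y = a(x − c)² + h` is fitted by ordinary least
squares over the support; non-concave fits are rejected, `c` refines the
center and `h` the height. The reported **width is the distance between
the two inflection-point supports**, not the parabola's own roots: the
parabola is a local model of the peak apex, while the inflection points
delimit the peak body.

Defaults: `sg_window = 15` grid points (150 bp at the default step,
about one nucleosome footprint) and `sg_order = 3`. Shorter windows track
noise; substantially longer ones merge neighboring nucleosomes. Calls are
filtered to fitted heights at least `0.5 ×` the track's robust SD
(median absolute deviation, scaled) above the track median — the height
is measured relative to the median so that adding a constant to the
signal changes nothing but the reported heights — and to widths in
[80, 300] bp, discarding sub-nucleosomal noise spikes and unresolved
di-nucleosomes. Variant- and histone-channel call lists are merged with a
74-bp rule (half a footprint): two calls closer than that are one
nucleosome, and the histone-channel geometry is kept because that channel
sees every nucleosome, not only variant-bearing ones.

Numerical details that matter: first-derivative zero crossings are
refined by linear interpolation between the flanking grid points; an
exactly-zero plateau contributes its midpoint; derivative magnitudes
below `1e-10` of the track's maximum derivative are treated as zero so
that flat stretches do not generate spurious crossings. The
Savitzky–Golay fit rings slightly where two kernel tails meet, producing
genuine but tiny local maxima — these are left to the height filter
rather than special-cased in the detector.

# Enrichment scoring and selection

Each positioned nucleosome receives two window-median scores over the
147-bp footprint centered on its dyad: **enrichment** (variant ChIP
normalized to bulk histone) and **noise** (IgG normalized to bulk
histone). Medians over per-probe log2 differences are robust to single
aberrant probes; a nucleosome whose window holds no probe of both
channels is flagged unscored.

The genome-wide enrichment distribution is a mixture of a background
population (nucleosomes without the variant, where the score reflects
the *absence* of variant ChIP signal over a full histone signal) and a
specific population near zero (variant signal comparable to histone
signal). A two-component unequal-variance Gaussian mixture is fitted by
expectation–maximization, initialized at the 25th/75th percentiles with
pooled variances and equal weights, converged when the log-likelihood
improves by less than 1e-8 (cap 500 iterations). The quantile
initialization makes the fit deterministic and data-order invariant;
unequal variances are allowed because the two populations have no reason
to share a spread. Model selection across covariance structures, as a
full model-based clustering package would perform, is deliberately not
replicated — the two-component structure is fixed by design.

Selection applies two strict criteria: the posterior probability of the
higher-mean (specific) component must exceed 0.75, and the enrichment
must exceed twice the nucleosome's own noise score **as a fold change** —
on the log2 scale, `enrichment > 1 + noise`. "Twice the noise" is read as
a fold change because both scores are ratios; the comparison is
per-nucleosome rather than against a global noise level, so locally noisy
regions must clear a locally higher bar. Both the scale and the threshold
are exposed (`scoring_params`).

# Feature association and gene categories

Association distance is measured from the nucleosome center to the
nearest *feature edge*, because the feature set includes non-gene types
(transposable elements, tRNAs, ...) with no meaningful TSS; a nucleosome
farther than 2,000 bp (boundary inclusive) from everything stays
unassociated. Promoter/TTS classification then uses strand-aware gene
anchors: promoter = [TSS − 2000, TSS) on the gene's strand, TTS =
[TTS − 500, TTS + 2000]. A center qualifying for two or more windows —
of different genes or both windows of one gene — is *ambiguous*;
"unequivocally" promoter- or TTS-associated means exactly one qualifying
window of exactly one gene. Gene categories (promoter-only, TTS-only,
both, none) are built from the unambiguous classifications only, and
body-only associations do not create a category.

Feature-type enrichment is tested against a resampling null: random
subsets, of the size of the selected set, drawn from **all positioned
nucleosomes** rather than from uniform genome positions, so the null
respects where nucleosomes can be detected at all (mappability,
probe coverage); the p-value is a two-tailed one-sample t-test of the
resampled fractions against the observed fraction.

# Metagene profiles, expression bins, entropy

Metagene profiles average probes into fixed 50-bp bins over ±3-kb flanks
and 100 percent-bins over the gene body, per gene first and then across
genes; minus-strand genes are coordinate-reversed before binning. A gene
with no probe in a bin contributes nothing to that bin (no zero
imputation). Probe averaging, rather than per-bp interpolation before
binning, is used throughout: it weights each measured probe once and
introduces no fabricated values. Expression bins are quantile quartiles
of the mean across conditions, ties broken by gene id for determinism.
Point-anchored profiles (±600 bp around nucleosome dyads) report
mean ± 1.96·SE across anchors as the 95% band.

Expression entropy is the Shannon entropy, base 2, of a gene's
normalized expression profile across conditions: `p_i = x_i / Σx`,
`H = −Σ p_i log2 p_i`, maximal (`log2 n`) for uniform expression and 0
for single-condition expression. The base and the simple
sum-normalization are conventions — no further cross-condition
normalization is applied, and genes with zero total expression are
flagged invalid rather than given an arbitrary entropy. Group
comparisons use the rank-sum (Mann–Whitney) test — the gene groups are
independent, so the paired signed-rank variant would be inappropriate —
with exact enumeration up to n = 25 per group without ties and a
tie-corrected normal approximation otherwise.

# The synthetic data generator

The generator is first-class, tested code: it defines the conditions the
rest of the package is validated under. Each planted nucleosome
contributes a raised-cosine kernel `0.5(1 + cos(πx/w))` on `|x| ≤ w`
with `w = 147` bp. The kernel's full width at half maximum *and* its
inflection-point separation both equal the footprint, so an isolated
planted nucleosome should be called with width ≈ 147 bp — which is what
makes the fitted-width histogram an internal validation: its mode lands
in the 140–160 bp bins on the reference simulation (2-Mb chromosome,
5,000 planted nucleosomes, 10-bp probes, noise SD 0.3). Peak amplitudes
are log-normal around 2 log2 units (≈4-fold ChIP enrichment at the
dyad). Noise is additive i.i.d. Gaussian on the log2 scale per probe and
channel, matching the behavior of normalized ratio data; the default SD
of 0.3 is moderate array noise. Probes sit on a regular 10-bp grid —
denser than a real tiling array, so grid artifacts do not dominate
caller tests.

Genes are laid out in non-overlapping slots with log-normal lengths
(median 2 kb), random strands, a feature-type vocabulary that is mostly
protein-coding with a minority of TE genes, pseudogenes and ncRNAs, and
core-promoter classes (TATA/GA/coreless) for protein-coding genes.
Expression is log-normal with a configurable zero-inflated fraction of
silent genes; GA-class genes get condition-specific (low-entropy)
profiles. Variant flags are assigned by weighted sampling so the overall
variant fraction equals `h33_fraction` exactly while variant nucleosomes
concentrate in GA-class promoters (independent of expression level) and
at TTSs of high-expression genes — giving the association, metagene and
entropy stages planted effects to recover.

What the generator does *not* emulate: probe sequence affinity and
cross-hybridization, spatially correlated noise, copy-number or
mappability variation, fuzzy/delocalized nucleosomes, and nucleosome
occupancy changes between channels beyond presence/absence of the
variant. Passing tests therefore demonstrate the correctness of the
algorithms under the stated statistical model, not performance on any
particular array platform.

# Reference problem sizes

The packaged analyses and tests run at deliberately modest scale, chosen
so the full chain exercises every code path in minutes on one core: a
2-Mb single chromosome with 5,000 nucleosomes and 400 genes for the
reference simulation (`analysis/` scripts and the acceptance script),
and 0.3–1-Mb genomes for unit tests. All sizes are `simulation_config`
fields and scale linearly.

# Known limitations

- Closely spaced nucleosomes (< ~300 bp) can merge into one smoothed
  peak; the caller reports the merged peak or drops it at the width
  filter, it does not deconvolve overlapping footprints.
- The two-component mixture assumes a unimodal background; strongly
  structured backgrounds (e.g. chromosome-arm versus pericentric
  differences) would call for per-compartment fits, which are out of
  scope.
- The resampling null conditions on the detected nucleosome set; it does
  not model detection bias that correlates with feature type.
- With dense annotations, 2-kb promoter windows overlap many genes and
  the `ambiguous` class grows; window sizes are parameters, not
  constants.
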