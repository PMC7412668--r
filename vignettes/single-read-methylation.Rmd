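---
title: "Single-read analysis of CHH methylation patterns"
author: "srmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-read analysis of CHH methylation patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmeth)
```

## The problem

Bisulfite sequencing reports, for every covered cytosine on every read,
whether that cytosine was methylated (it survives conversion as C) or not
(it is read as T). Standard methylome pipelines average these calls across
reads, discarding the fact that each read is a sample from a single cell's
genome. For plant CHH methylation this average hides a biologically
meaningful axis of variation: the two CHH methyltransferases, DRM2
(RNA-directed) and CMT2 (H3K9me2-coupled), deposit methylation with very
different fine structure. CMT2 activity looks like noisy, per-site
stochastic methylation that is similar in every cell; DRM2 activity
produces a mixture of nearly fully methylated and nearly unmethylated
DNA molecules — a bimodal, cell-to-cell signal with little within-read
noise.

`srmeth` implements a single-read analysis that makes this distinction
quantitative: it segments annotated elements (typically transposable
elements) into small per-strand regions with a fixed number of CHH sites,
converts each fully overlapping read into a binary methylation vector over
those sites, summarises the vectors into three variation features, compares
them against a stochastic null, and scores regions and elements on a 0–1
*pattern score* (0 = DRM2-like, 1 = CMT2-like) fitted by ordinary least
squares on labelled training data.

## Regions

CHH sites (trinucleotide `CHH`, H ∈ {A, C, T}) are detected strand-aware
from the reference sequence of each annotated element; the CHH subcontexts
CWA (`CAA`/`CTA`) and non-CWA are recorded because CMT2 prefers CWA.
Unstranded annotations are scanned on both strands — CHH methylation is
asymmetric, so every region belongs to exactly one strand. Sites whose
trinucleotide would extend past the element end, or contains an N, are
skipped (their context is undefined).

Regions are built greedily left to right: accumulate consecutive sites,
drop the leftmost site whenever the span (first to last cytosine,
inclusive) exceeds `maxSpan`, and emit a region as soon as exactly
`nSites` sites fit, restarting after the emitted region so regions never
share a site. This earliest-end greedy rule yields the maximum possible
number of disjoint regions, which the test-suite verifies against an
exhaustive dynamic-programming oracle. Defaults are 5 sites within 30 bp
(the standard analysis); 50 bp is recommended for CWA-only analyses (the
subcontext is roughly 4–5× sparser), and 5/10/15 sites within 100 bp for
read-level binning summaries.

Because a valid region forces `nSites` cytosines into at most `maxSpan`
bases, its GC content has an analytic floor of `nSites / maxSpan`
(5/30 ≈ 0.17 at the defaults).

## Read vectors and features

A read contributes to a region only if (i) its aligned span covers **all**
of the region's sites and (ii) its bisulfite strand matches the region
strand. For a directional library the bisulfite strand is inferred from
SAM flag 16 (a Bismark-style `XG` tag overrides it when present). Calls
follow conversion logic: on a plus-strand site the reference-forward base
C means methylated and T unmethylated; on a minus-strand site the
complementary pair G/A applies. Any other base is uninformative and drops
the whole read for that region — the features below need complete
vectors, and with no-mismatch alignments such bases are rare. Exact
duplicates (same chromosome, position, orientation and sequence) are
collapsed before extraction.

For a read-by-site matrix the package computes, with population
(uncorrected) standard deviations throughout:

* **mean read methylation** — the region methylation level;
* **SD of read methylation** — cell-to-cell heterogeneity; high for the
  DRM2-like full/empty read mixture;
* **mean read stochasticity** — the fraction of adjacent site pairs
  within a read whose states differ; high for CMT2-like per-site noise;
* **SD of site methylation** — among-site variation of the per-site
  averages.

Uncorrected SDs keep four-read regions well defined and match the common
default of the scientific Python stack; for a complete matrix the mean
read methylation and the mean of per-site fractions coincide exactly (an
identity the tests exercise).

Regions pass to element aggregation only with ≥ 4 reads and ≥ 10% mean
methylation, and an element is summarised (unweighted mean of its
surviving regions' features) only if at least two regions survive. These
defaults — together with the 5/30 region geometry — are the package's
standard operating point and are exposed in `analysisConfig()`.

## The stochastic null

The reference model for "no structure beyond the methylation level" is an
independent Bernoulli draw per site per read at the region's mean level
*p* (historically described as a Poisson single-C model; the stated chance
mechanism is Bernoulli, which is what `simulateNullRegion()` implements).
Its closed forms are `E[mean] = p`, `E[stochasticity] = 2p(1 − p)`, and an
asymptotic read-methylation SD of `sqrt(p(1 − p)/nSites)`.
`nullFeatureDistribution()` simulates one (configurable) matched null
region per observed region, reusing the observed read count so
finite-sample SD inflation is shared, and computes features through the
same code path as real data. CMT2-like data should hug this null; the
DRM2-like read mixture exceeds its read-SD prediction by construction.

```{r null-closed-form}
e <- nullExpectations(0.4, 5)
rv <- simulateNullRegion(0.4, 5, 5000, seed = 1)
c(expected = e$mean_stochasticity,
  simulated = mean(readStochasticity(rv)))
```

## The pattern-score classifier

Training takes two labelled region feature sets — class 0 DRM2-like,
class 1 CMT2-like — filtered to ≥ 10% methylation, and fits an ordinary
least-squares linear probability model of the label on the four features
(constant features are dropped with a warning). The raw linear predictor
is rescaled by its training minimum and maximum so training scores span
exactly [0, 1]; unseen data is clipped into the interval after the same
affine map. Min/max scaling is the simplest map that pins the score to a
0–1 range, and both bounds are stored in the model (and in its plain-text
serialisation) for reproducibility. Marginal single-feature r² values are
recorded; read-methylation SD is typically the strongest single
predictor of enzyme identity.

Evaluation is by an ROC threshold sweep with trapezoidal AUC (verified in
the tests against Mann–Whitney pair counting and against `pROC`), and by
genome-level peak counting of score distributions.

### Peak counting

Score distributions are summarised by a Gaussian KDE on a fixed 512-point
grid over [0, 1] with Scott's rule-of-thumb bandwidth `sd(x)·n^(−1/5)`
passed explicitly. Peaks are local maxima (grid endpoints included) whose
*topographic prominence* — height above the deepest saddle separating the
maximum from higher ground — reaches a configurable fraction (default 5%)
of the global maximum. Prominence, rather than raw height, is used
because at Scott's bandwidth a single ragged mode estimated from ~10²
elements routinely shows near-equal-height micro-maxima; a height
threshold would count these as separate signals, while any genuinely
bimodal mixture passes untouched. One peak means a single dominant
pattern signal; two peaks mean both DRM2-like and CMT2-like activity are
present.

## The synthetic data generator

`generateGenome()` and `simulateReads()` produce complete desk-scale
fixtures (FASTA, GFF3, SAM and a truth table), so the whole pipeline is
testable without any external data. The generator's defaults define the
package's study conditions:

| parameter | default | meaning |
|---|---|---|
| genome length | 100 kb | one chromosome |
| GC content | 0.36 | *A. thaliana*-like base composition |
| TE fraction / element length | 0.4 / 500 bp | non-overlapping elements; each guaranteed ≥ 1 valid region per strand |
| region geometry | 5 CHH sites / 30 bp | standard operating point |
| coverage | 10 per bisulfite strand | reads split 50/50 across strands |
| read length | 100 bp | single-end, ungapped |
| region methylation target | Uniform(0.15, 0.6) | drawn per region, identical range for both regimes |
| CMT2-like regime | per-site Bernoulli, +0.15 at CWA sites | stochastic, unimodal |
| DRM2-like regime | full-read mixture, background 0.05 | per-region full fraction set so the mean matches the target |

Matching the two regimes on methylation level forces the classifier to
learn the *pattern* rather than the level. Coverage is defined per
bisulfite strand so the planning formula
`expected reads per region = coverage · (1 − region size / read length)`
holds exactly for the strand-matched reads a region can actually use
(7 reads at the defaults). Cytosines outside regions are emitted
unmethylated, isolating the signal for testability.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: sequencing errors and base
qualities, PCR duplication, paired-end mates, mappability and alignment
artefacts, methylation outside the annotated regions, linkage between
neighbouring regions, and biological covariates (chromatin state, TE
superfamily structure). Conclusions about real libraries still require
the usual upstream QC.

```{r end-to-end, eval = FALSE}
gen <- generateGenome(1e5, seed = 1)
sites <- findContextSites(gen$genome, gen$elements, "CHH")
regions <- buildRegions(sites, genome = gen$genome)
regime <- setNames(rep(c("drm2_like", "cmt2_like"),
                       length.out = length(gen$elements)),
                   gen$elements$element_id)
sim <- simulateReads(gen$genome, regions, regime, coverage = 10, seed = 2)
fa <- tempfile(fileext = ".fa")
gff <- tempfile(fileext = ".gff3")
sam <- tempfile(fileext = ".sam")
Biostrings::writeXStringSet(gen$genome, fa)
rtracklayer::export(gen$elements, gff, format = "gff3")
writeSam(sim$reads, gen$genome, sam)
res <- runPipeline(fa, gff, sam)
model <- fitPatternModel(
    simulateRegimeFeatures(2000, "drm2_like", seed = 3),
    simulateRegimeFeatures(2000, "cmt2_like", seed = 4))
kdePeaks(scoreElements(model, res$elementTable)$pattern_score)$n_peaks
```

## Numerical choices and degenerate inputs

* Span is measured cytosine-to-cytosine inclusive
  (`last − first + 1`), the minimal consistent reading; it only affects
  boundary cases.
* Coordinates are 1-based inclusive internally (`GRanges`); GFF input is
  native, BED-like TSV output converts to 0-based half-open at the
  boundary.
* GC content excludes N from numerator and denominator; an all-N window
  is `NA` with a warning.
* Hypermethylation selection is strictly greater than the 10% delta.
* ROC with all-tied scores degenerates to the chance diagonal
  (AUC 0.5); stochasticity requires ≥ 2 sites; peak analysis requires
  ≥ 10 values; a KDE bandwidth collapsing to 0 is floored at 1e-4.
* Paired-end mates are treated as independent reads; only exact
  duplicates are collapsed.
* Training sets for the default classifier use 2000 regions per class;
  the end-to-end checks run one 100-kb genome per sample at coverage 10
  (~1.3 × 10³ regions, ~2 × 10⁴ reads per sample), sizes chosen so the
  whole suite runs comfortably on a laptop while keeping Monte-Carlo
  noise far from the asserted margins.

## Known limitations

The classifier is a linear probability model by design (not logistic
regression), so raw scores outside the training hull carry no calibrated
probability meaning — they are clipped and should be read as "at or
beyond the training extremes". Scores are comparable across samples only
when region definitions and filters match. The bisulfite-strand
inference assumes a directional library; non-directional protocols need
the `XG` tag. Aggregation to elements is unweighted, so elements
dominated by a few high-coverage regions are summarised exactly like
uniformly covered ones.
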