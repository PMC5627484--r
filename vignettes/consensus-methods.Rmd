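---
title: "Methods: multi-caller CNV consensus, gene mapping, enrichment and benchmarking"
author: "cnvconsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-caller CNV consensus, gene mapping, enrichment and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvconsensus)
```

## The problem

Whole-exome CNV callers disagree substantially: tools built on different
read-depth models have different size preferences, breakpoint accuracy and
false-positive behaviour, and no single tool is reliable enough on clinical
samples. A standard remedy is integrative calling: run several tools on the
same sample, intersect their segment calls, and treat the number of tools
supporting a region (its *caller multiplicity*) as a confidence tier. This
package implements the post-calling stages of such a pipeline in a
caller-agnostic way — callers enter through a configurable segment-file
contract rather than being wrapped and executed — together with a noise-model
simulator so every stage can be exercised and benchmarked without access to
sequencing data.

## Consensus model

Every call is a half-open interval `[start, end)` on 0-based coordinates with
an integer copy number; copy number above the diploid baseline of 2 is a
*gain*, below it a *loss* (baseline records are not CNVs and are dropped on
read, with a warning). Within one caller, overlapping or bookended calls of
the same direction are merged, keeping the extreme copy number (maximum over
gains, minimum over losses) so the strongest event survives; overlapping
opposite-direction calls within one caller are rejected as malformed input.

`build_consensus()` then works per direction: the union of all callers'
intervals is cut at every distinct call breakpoint, each atomic piece is
labelled with exactly the set of callers covering it (and their copy numbers
on that piece), and maximal runs of identically labelled pieces are merged
back. Multiplicity 1–4 segments are the classic *unique*, *double*, *triple*
and *tetrad* tiers; more callers simply yield higher multiplicities. Three
design choices deserve explanation, because the convention is genuinely open:

* **Direction stratification.** A gain and a loss never co-support a shared
  segment, even when they overlap positionally. Merging opposite directions
  would produce biologically incoherent "shared CNVs", and all reporting in
  this field treats gains and losses separately.
* **No copy-number agreement.** A cn=3 gain and a cn=8 gain co-support a
  segment; sharing is positional. Requiring CN agreement would make the
  consensus hostage to each tool's CN calibration, which is far noisier than
  its breakpoints.
* **No minimum reciprocal overlap.** A 1-bp shared sliver is reported. A
  configurable `min_segment_bp` (default 1) exists for users who want to
  suppress slivers, but no silent threshold is applied.

Because breakpoints are deduplicated before cutting, zero-length pieces
cannot arise, and because callers are canonically ordered internally, the
input order of call sets cannot affect boundaries or labels.

## Gene mapping

A gene is assigned to a multiplicity class when the fraction of its bases
covered by the union of that class's merged regions reaches the coverage
threshold (default 0.7). Two conventions matter:

* The comparison is **inclusive**: exactly 70% coverage qualifies at the
  default threshold. "70% of the gene lies inside the region" reads as
  attainment, and the boundary is pinned by an explicit test.
* Coverage is computed against the **class-wide union of regions**, not a
  single segment. Consensus segmentation fragments regions at every caller
  breakpoint, so per-segment coverage would depend on arbitrary
  fragmentation; a gene split across adjacent same-class regions still
  qualifies.

## Term enrichment

For CNV genes against a user-supplied GMT catalog, each term gets a 2x2
table over a gene universe: `a` CNV genes in the term, `b` CNV genes outside
it, `c` background-only genes in the term, `d` the rest. The p-value is the
one-sided (enrichment) Fisher exact probability, i.e. the hypergeometric
upper tail P(X >= a) with X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b),
computed via `stats::phyper`. One-sided is the right test here — the
question is over-representation, not any departure. Raw p-values are always
reported; Benjamini–Hochberg adjustment is applied within each catalog as
standard practice and clearly labelled as such. The default universe is all
genes in the supplied gene BED (the set that could have been mapped);
`universe = catalog` restricts the background to genes appearing in the
catalog, which is the better choice when the catalog covers only a curated
subspace. Genes outside the universe are ignored on both sides of the table,
and terms with no universe genes are skipped with a warning.

## Evaluation

Calls are scored against a truth profile at **base level**, direction-aware,
with two direction slots (gain/loss) per assayed base: within a slot a base
is TP when call and truth both cover it in that direction, FP when only the
call does, FN when only the truth does, TN otherwise, so
`tp + fp + fn + tn = 2 x assay bp` and a gain call over a truth loss counts
as both an FP and an FN. Base-level scoring is threshold-free (no arbitrary
reciprocal-overlap cutoff deciding when an event "matches") and composes
cleanly across samples. Copy-number magnitude is deliberately ignored —
the metrics of interest (TPR, FDR, precision) concern detection, not CN
accuracy. Undefined ratios (e.g. precision with no calls) are reported as
`NA`, never as 0 or 1, to avoid fake-perfect scores on empty call sets.

## The simulator

The simulator generates **caller outputs**, not sequencing reads. A full
read-level benchmark (simulate tumor/normal reads, run four external CNV
callers, intersect) is the gold standard but requires the callers
themselves; this package's scope is the integration stages, so the
simulator instead models each caller's output channel directly. This
substitution is the package's central limitation and is stated prominently:
passing benchmarks show that *integration behaves as designed given callers
with these error profiles*, not that any particular real caller has those
profiles.

Truth profiles default to the study conditions the package mirrors: 13
samples, 10 CNV events each, copy numbers uniform on {1, 3..20}, sizes
uniform on [500 kb, 4.5 Mb], placed uniformly on a 3 x 60 Mb genome with at
least 1 Mb between events (the 60 Mb chromosomes simply leave ample room for
ten multi-Mb events plus gaps). Note that with one loss state (cn = 1)
against eighteen gain states, losses are rare by construction — that is a
property of the mirrored design, not a modelling choice.

Caller noise profiles have five parameters each, defaults chosen once to
encode the qualitative size preferences reported for common exome tools:

| profile | detection vs size | jitter SD | FP rate /Mb | FP sizes | CN error |
|---|---|---|---|---|---|
| excavator_like | increasing (logistic, mid 1.5 Mb) | 20 kb | 0.03 | 50 kb–1 Mb | 0.10 |
| adtex_like | unimodal (peak 2.5 Mb) | 15 kb | 0.04 | 30–500 kb | 0.10 |
| freec_like | decreasing (linear) | 10 kb | 0.06 | 10–300 kb | 0.15 |
| exomecnv_like | decreasing (exponential) | 10 kb | 0.08 | 10–200 kb | 0.15 |

Detected events get independent Gaussian start/end jitter (clamped to the
chromosome and to positive length); copy-number errors never cross the
gain/loss boundary, so truth direction stays well defined for scoring; false
positives arrive as a Poisson process with log-uniform sizes, placed off the
truth footprint and off the caller's own calls so each caller's output is
internally consistent. Each (caller, sample) pair draws from its own RNG
stream derived from the global seed and a stable label, so adding a caller
or sample never perturbs the draws of the others — reproducibility is by
construction, not by accident of generation order.

What the simulator does **not** model: exome target-capture structure (calls
are genomic intervals, not exon unions), GC and mappability bias, tumor
purity and subclonality, correlated errors between callers (real tools
share failure modes on hard regions; independent FP processes make
consensus filtering look somewhat better than reality), and sex-chromosome
ploidy.

## Numerical and testing choices

Interval arithmetic is exact integer arithmetic on half-open coordinates;
1-based inclusive input dialects are converted on read (`[s, e]` to
`[s-1, e)`). Outputs are sorted by natural chromosome order
(chr1 < chr2 < ... < chr10 < chrX < chrY) and written with fixed
(non-scientific) integer formatting, so identical inputs produce
byte-identical TSVs and HTML; the report carries no timestamps for the same
reason. `threads` parallelises only independent, explicitly seeded units of
work, so any thread count reproduces the serial output.

The test suite checks the consensus partition, gene coverage, confusion
counts and enrichment p-values against independent brute-force oracles
(per-base labelling and recompression on instances up to 100 kb; exact
log-binomial hypergeometric tail sums), and verifies the integration
property on the simulator's default conditions: over 20 replicate seeds of
the 13-sample design, median FDR of the two-caller consensus falls below
every single caller's median, and four-caller precision dominates in at
least 95% of seeds. These problem sizes (200 random consensus instances,
1,000 enrichment tables, 100 metric instances, 20 benchmark seeds) were
chosen to exercise each property densely while keeping a full run of the
suite comfortable on a laptop. Against real data the same caveats as above
apply: the benchmark demonstrates the machinery, not the field performance
of any real caller combination.

## Known limitations

* Consensus requires normalized, per-sample call sets; multi-sample seg
  files must be split upstream.
* Fractional/subclonal copy numbers and B-allele-frequency evidence are out
  of scope; direction is the only CNV state evaluated.
* Enrichment assumes gene-level identifiers match between the gene BED and
  the GMT catalogs; no symbol aliasing is attempted.
* The HTML report is a faithful view of the TSVs, not an interactive
  browser.
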