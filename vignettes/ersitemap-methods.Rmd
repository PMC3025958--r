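---
title: "Methods and design choices in ersitemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in ersitemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ersitemap` implements the downstream, desk-computable part of an
ERα/ERβ ChIP-Seq integration study: given peak lists for the two estrogen
receptor subtypes in wild-type and ERβ-expressing breast cancer cells, plus
gene models, an expression table and pre-miRNA coordinates, it derives
binding regions, a co-binding taxonomy, ERE content, TFBS
over-representation, regulation groups, primary target genes and a
proximity bootstrap. This vignette records the model, the tunable
parameters, and the decisions taken where the published procedure is
under-specified. Every empirical claim below is computed by the test suite
or the acceptance script; nothing is quoted from external results.

## Coordinates and the region model

All coordinates are 0-based half-open (`[start, end)`, BED convention);
1-based input dialects must be converted at the boundary. *Overlap* always
means sharing at least one basepair: book-ended intervals (one ends exactly
where the next starts) do **not** overlap and are not merged. This is the
strictest reading of half-open semantics; the upstream table-browser
procedure the region step emulates is not bit-specified, so the merge
dialect matters and is fixed here once. The test suite checks all interval
operations against a per-basepair mask oracle built at doubled resolution,
which distinguishes book-ended from overlapping intervals.

The cartographic step takes each binding peak, extends it by `flank`
(default 1000 bp, clipped at 0 and the declared chromosome length) and
merges overlapping extensions into *binding regions* — the connected
components of the overlap graph, carrying their member peak ids. Two peaks
therefore share a region exactly when their edge-to-edge distance is below
`2*flank`.

Worth recording: the source study reports two different region totals for
what is described as the same procedure (8536/5371 in one section,
8872/5558 in another). The package implements the single stated procedure
(±1000 bp, merge overlapping) and logs input/output counts at every stage
so both figures can be probed; it does not guess at the source of that
discrepancy.

## Six-class co-binding taxonomy

Three region sets enter: ERβ and ERα regions from ERβ-expressing (TAP)
cells, and ERα regions from wild-type cells. Each ERβ peak is labeled by
its region's overlaps: wild-type-α only → class 1 (competition); both →
class 2 (β+α); neither → class 3 (β-specific); TAP-α only → class 4
(heterodimer-specific). ERα-TAP peaks whose region holds no ERβ binding
are class 5 (α-displacement) when the region also misses every wild-type α
region, class 6 (α-specific) when wild-type α binds there too. The
published wording for classes 5/6 can be read as overlapping definitions;
we resolved the split by the wild-type-α criterion because the taxonomy
must be exhaustive and disjoint, and that is the only reading consistent
with "only in TAP cells" vs "in both cell lines". α-TAP peaks that share a
region with ERβ inherit class 2/4 from the region so every peak in both
universes gets exactly one label.

## ERE and half-ERE scanning

Scoring is MatInspector-style. A matrix is a per-position base-frequency
table `f(l, b)`; its information vector is

    ci(l) = (100 / ln 4) * sum_b f(l,b) ln f(l,b) + 100

(0 for a uniform position, 100 for a conserved one). Window scores are

    matrix similarity = sum_l ci(l) f(l, b_l) / sum_l ci(l) max_b f(l, b)

with `N` contributing zero to the numerator; core similarity is the same
ratio over the *core*, the 4 consecutive positions with maximal summed
information (ties broken leftmost). A hit requires core ≥ 0.75 (published
threshold) and matrix ≥ 0.80. The published matrix threshold, "Optimal −
0.02", refers to a proprietary per-matrix optimization we cannot clone;
0.80 is a conventional default and is configurable (`mat_thresh`).

The proprietary ER matrices themselves are replaced by one open,
documented PWM built from the 13-bp palindromic consensus GGTCAnnnTGACC:
0.85 on the consensus base, 0.05 elsewhere, spacer positions uniform (so
the spacer carries zero information and never affects scores). This
preserves the palindrome structure but *not* any vendor's percentages —
published ERE+ percentage tables are explicitly out of scope. Half-sites
are exact matches to PuGGTCA (`[AG]GGTCA`, reverse strand `TGACC[CT]`).
Site classification is ERE+ if any full matrix hits, else hERE+ if any
half-site matches, else none; full-ERE precedence is absolute, matching
the search-only-the-remaining-sites procedure. Classification is strand
symmetric by construction and tested.

**False positives.** At the defaults, the open consensus PWM admits ≈2
mismatches among the 10 informative positions (≤1 in the core). On 200-bp
i.i.d. uniform sequence the measured chance ERE+ rate is ≈9% (400 sites,
fixed seed, in the test suite; the analytic per-offset hit rate of
~3.7e-4 across ~376 offset-strand pairs bounds it near 13%). A lower-specificity estimate of "<5%" would require a stricter
matrix threshold; we kept the documented default and report the measured
rate in the test suite instead of tuning the threshold to a target.

## TFBS over-representation

For a matrix with background per-bp hit rate `p_bg` (supplied as a
precomputed rate table or estimated by scanning background sequence, both
strands counted over forward-strand basepairs) and `T` scanned basepairs,
the expected count is `E = p_bg * T`, fold enrichment `O/E`, and

    z = (O − E − 0.5) / sqrt(E * (1 − p_bg))

a continuity-corrected normal approximation to the binomial. The exact
formula behind the published Z-scores is unpublished; this is the standard
over-representation statistic matching the described semantics, and the
published enrichment tables are not reproduction targets. Screening keeps
matrices with z ≥ 3 **and** fold ≥ 4 (both inclusive). Overlapping matches
are counted individually. The grid report shows fold where z ≥ 3, "low-z"
where the matrix is present but below the gate, and "absent" where O = 0.
Under the binomial null the z ≥ 3 gate passes well under 1% of matrices
(tested over 400 simulated groups).

## Differential expression

Quantile normalization maps every sample onto the mean order-statistic
distribution, with average-rank tie handling. Significance uses the
Illumina DiffScore convention `ds = 10 * sgn(diff) * log10(1/p)`, anchored
by |40| ↔ p = 1e-4; a gene is regulated in a cell line when it is detected
(detection p < 0.01) and |ds| ≥ 40 at any timepoint. When directions
conflict across timepoints, the 8-h call decides, because the group
analysis is defined on the 8-h data; earlier timepoints only feed the
kinetic heatmap. Genes regulated in one line are wt-only/β-only; in both
lines, concordant directions give "both", discordant give "opposite".
Probe-to-gene merging in the source is unstated; the package keeps the
table's granularity and callers may pre-aggregate (e.g. best |DiffScore|).

## Primary targets and site locations

A region links to a gene when it overlaps the transcription unit extended
by `window` (default 10 kb) on both sides. Location labels are assigned
strand-aware by the site midpoint: the promoter is the `promoter_bp`
(default 1000, configurable and reported) bases immediately 5′ of the TSS
— the source distinguishes "promoter" from "upstream of promoters" without
defining either, so the extent is an explicit parameter rather than a
guess. Precedence at boundaries is promoter > exon > intron; outside the
gene, 5′ is upstream and 3′ downstream. A gene whose linked sites all
share one class keeps it; mixed classes give "combination". A containment
mode (`by = "containment"`) is available for broad regions.

## miRNA proximity bootstrap

"Within 10 kb" is edge-to-edge distance (gap between closest ends, overlap
= 0), boundary inclusive. The matched null preserves, per chromosome, the
site count and the exact length multiset (lengths permuted within the
chromosome) and draws starts uniformly on `[0, chrom_len − length]` — the
strictest reading of "similar distribution among chromosomes"; resampled
sites may overlap each other unless `no_self_overlap` is set. Two
statistics are computed per replicate (sites near ≥1 locus; loci near ≥1
site) because the published replicate statistic is ambiguous between them.
Empirical p uses the add-one rule `p = (1 + #{rep ≥ obs}) / (B + 1)` so p
is never 0; the raw exceedance fraction — the published "% of cases"
quantity — is reported alongside. Same seed, same result, bitwise.

## Synthetic data: what it does and does not emulate

The generator produces the statistical *shapes* the pipeline assumes, with
truth tables as first-class outputs:

- **Peaks**: log-normal lengths (median 400 bp, σ_log 0.4, clipped to
  100–2000 bp — typical ChIP-Seq peak scale), laid out one cluster per
  well-separated genomic slot so the intended class of every cluster
  survives extension/merging; companion α peaks sit within 800 bp
  (< 2×flank) of their β peak. Class proportions default to the published
  six-class split; the default genome is 3×5 Mb plus a 16,569-bp
  mitochondrial surrogate. Infeasible densities error instead of silently
  degrading label recovery.
- **Sequences**: i.i.d. background at configurable GC (a 40% GC option
  reflects the GC-rich context of ERE-less tethering motifs), with planted
  full EREs (k = 1 mismatch by default, still above thresholds) and
  half-sites. By default background segments are rejection-cleaned so each
  sequence classifies exactly as intended — the truth table is then exact;
  `clean = FALSE` exposes raw chance-hit behaviour for false-positive
  measurements.
- **Expression**: |DiffScore| ramps 0/15/30/60 over 0/2/4/8 h for regulated
  gene-lines (significant only at 8 h), flat otherwise; opposite genes are
  repressed in wt and induced in β cells; group proportions default to the
  published split. At σ = 0 recovery is exact by construction.
- **miRNA loci**: fraction `f` placed within the window of a random site,
  the rest uniform.

Not emulated: read-level signal, peak-calling artifacts, probe-level array
noise, realistic chromatin sequence composition, overlapping gene models.
A green test therefore establishes the correctness of the *computations*
on inputs with the stated structure — not that the published counts arise
from real data, which would require the deposited supplementary files and
era-specific annotations (explicitly out of desk scope, see
`reproduce_region_counts()` for the runnable procedure).

## Numerical and degenerate-input conventions

- Tag-density filter: density exactly at the threshold is kept ("below
  0.5" is filtered).
- `enrichment()` with E = 0 and O > 0 flags infinite fold with undefined z.
- Empty interval sets flow through merge/partition/proximity and return
  empty results; a peak matching no region of its own set is a provenance
  error, not a silent drop.
- Chromosomes absent from the opposite set simply never overlap.
- All stochastic stages take explicit integer seeds; generators are
  deterministic given (config, seed).

## Known limitations

- The open consensus PWM is a stand-in: per-site ERE+ percentages are not
  comparable with proprietary-matrix results.
- The z statistic is an approximation chosen for the described semantics,
  not a clone of the unpublished vendor statistic.
- Gene linking uses the region span against the extended TU window; very
  broad merged regions can link to genes their member peaks are far from —
  mirroring the region-based published procedure.
- The bootstrap treats loci as fixed and sites as exchangeable within
  chromosomes; clustering of sites beyond the length/chromosome match is
  not preserved.
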