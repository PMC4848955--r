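---
title: "Methods: comparative small RNA analysis of diploid and autotetraploid pollen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative small RNA analysis of diploid and autotetraploid pollen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pollensmrna` implements a complete small RNA sequencing analysis for a
two-genotype (diploid `2x` vs. autotetraploid `4x`), three-stage
(pre-meiotic interphase `PMA`, meiosis `MA`, single microspore `SCP`)
pollen-development design with one library per condition. This vignette
explains each model and procedure, the tunable parameters, the design
choices made where the method description left room, and what the
synthetic-data tests do and do not demonstrate about real data.

## Read preprocessing

Raw 36-nt single-end reads are cleaned in a fixed order: 3' adapter
removal, quality filtering, length selection, low-complexity removal,
collapsing to unique tags, and ncRNA subtraction.

* **Adapter** (`trim_adapter`): the 3' adapter is located either as a
  full internal occurrence or as the longest adapter *prefix* matching
  the read suffix with at least `min_overlap = 6` bases (small RNA
  inserts are shorter than the read, so the adapter normally runs off
  the read's 3' end). Reads that are pure adapter are counted as
  adapter dimers.
* **Quality** (`quality_filter`): keep iff mean Phred >= 20 and no `N`.
  The original pipeline filter criterion is proprietary; a mean-quality
  rule is the conventional stand-in and is declared as such.
* **Length** (`length_filter`): tags of 18-30 nt are kept (the size
  range of the sequenced tag population); miRNA identification later
  restricts to 18-25 nt (`mirna_len`), the window used for precursor
  matching. Both windows are configuration keys.
* **Complexity** (`low_complexity_filter`): a tag is junk if a single
  base exceeds 80% of its length or if it is a full-length mono- or
  dinucleotide repeat. Again a declared stand-in for an unpublished
  definition.
* **ncRNA** (`filter_ncrna`): a tag is removed iff it occurs as an
  exact substring of any rRNA/tRNA/snRNA/snoRNA reference sequence on
  either strand. Exact matching is deterministic and testable; no
  mismatch tolerance is stated for this step in the source method, so
  none is applied.

Counts are conserved at every step: per library,
`raw = clean + dimers + low-quality + out-of-window + junk + ncRNA`,
and the clean total equals the unique-tag count sum. Both identities
are tested.

## miRNA identification and isomiR naming

Tags in the 18-25 nt window are aligned to precursor hairpins without
gaps on the sense strand, allowing at most **one internal mismatch**
(the first and last tag base must match) and end offsets up to
`max_end_offset = 3` nt on each side of the annotated mature arm — the
largest offset occurring in the published variant names is 3. Matching
a mature arm yields an isomiR name:

* `_L+n` / `_L-n`: 5' end extended / trimmed by `n` nt;
* `_R+n` / `_R-n`: the same at the 3' end; when both are present they
  form one token (`_L-1R+1`);
* `_1ss20CT`: one substitution at tag position 20 (1-based from the
  tag's 5' end), reference C observed T; multiple substitutions
  concatenate (`_2ss5CT12GA`).

The codec (`parse_mirna_name` / `format_mirna_name`) round-trips every
identifier form; novel-candidate names `PC-<arm>-<serial>` keep their
opaque trailing `_<number>` as `candidate_id`.

Classification applies five rules in order, first match wins:

1. tag on an annotated rice mature arm -> known rice miRNA (with
   variant tokens);
2. tag on the *opposite*, unannotated arm of a rice hairpin -> novel
   arm-derived miRNA, named `<precursor>-p5`/`-p3`;
3. tag on the mature arm of an other-species precursor whose hairpin
   sequence maps exactly to the rice genome -> known miRNA with the
   foreign species prefix;
4. tag on the opposite arm of such a hairpin -> novel other-species
   arm;
5. otherwise the tag is a candidate for novel-hairpin detection.

Ambiguous multi-precursor hits are resolved deterministically: fewer
mismatches, then smaller total |end offset|, then lexicographically
smallest precursor name. Whether foreign-species matching also allows
one mismatch is not specified in the source; the same tolerance is
applied uniformly. The category vocabulary reconstructs the five-way
classification from the described identification order.

## Novel hairpin candidates

Thermodynamic folding is out of scope by design; the package uses a
base-pairing heuristic. Two statistics are computed for each exact
genomic locus of an unexplained tag (window = tag +/- `flank` (150 nt)):

* `hairpin_max_pairing`: the maximum number of Watson-Crick/G:U pairs
  in a single-loop (stem-loop) structure of the window — a Nussinov
  recursion restricted so that the innermost pair encloses a loop of
  3-`max_loop` (60) nt, with free interior bulges. This is the
  heuristic's global stem-loop check and is oracle-tested against
  exhaustive enumeration on short sequences.
* `tag_stem_pairing`: the best *ungapped* antiparallel stem between the
  tag and a partner segment across a loop of admissible size.

A candidate is accepted iff the window's maximal pairing reaches
`min_pairs = 18` **and** the tag itself pairs with a partner segment at
`max(min_pairs, 0.7 x tag length)` pairs. The second condition carries
the discrimination: measured on random 321-nt windows, the maximal
single-loop pairing is ~0.28 x window length (~90 pairs), so the
absolute threshold alone would accept *every* genome-mapped tag. An
ungapped tag-partner stem of >= 18/24 pairs has a per-window false
positive rate of a few percent while perfect planted inverted repeats
score their full arm length. The partner's side also gives the arm
(`5p` if the partner lies 3' of the tag) and enforces that the tag lies
wholly on one arm; tags spanning the loop find no admissible partner.
The 70% pairing fraction coincides with `min_pairs` for the typical
24-nt candidate and prevents weak random partners from passing for
longer tags. These thresholds are declared heuristic settings, not a
reimplementation of free-energy folding.

Candidates are serialized deterministically (decreasing total count,
then sequence) as `PC-<arm>-<serial>_<total raw count>`.

## Copy-number normalization

The median-reference regression procedure operates on the full
unique-tag copy-number matrix:

1. the **common set** is every tag with raw count >= 1 in all
   libraries;
2. the **reference** is the per-tag median copy number across
   libraries (even library counts use the mean of the two middle
   values);
3. x = log2(reference), y = log2(sample);
4. the regression **subset** keeps tags with |y - x| < 2 (less than
   4-fold discordance);
5. ordinary least squares of y on x gives slope `a` and intercept `b`
   per library;
6. the fitted line is evaluated at the reference mid value `x_mid`;
   `delta_y = x_mid - (a x_mid + b)` and the arithmetic correction
   factor is `f = 2^delta_y`;
7. every raw count in the library (common set or not) is multiplied by
   `f`; zeros stay zero.

**The mid-value mode.** The procedure's printed formula for the mid
value is `(max(x) - min(x))/2`, the half-range. Whenever `min(x) > 0`
this point lies far *outside* the data range, so evaluating the fitted
line there amplifies any deviation of the slope from 1 into a large
factor error; on synthetic data (reference range [6, 9.2] log2 units)
it turned a true 7% scale offset into a claimed 2.2-fold correction.
The package therefore defaults to `xmid_mode = "midpoint"`,
`(max(x) + min(x))/2` — the centre of the reference range, which is the
evident meaning of a "mid value" — and retains
`xmid_mode = "half_range"` for comparability with the literal formula.
Both modes agree exactly for samples that are scalar multiples of the
reference (slope exactly 1).

Two properties are pinned by tests: samples that are exact scalar
multiples `c` of a common profile recover `f = median(c)/c` exactly
(the procedure normalizes to the median library, so factors are
defined up to that constant); and discordant tags beyond the 4-fold
window leave the regression untouched. Note the window also bounds the
procedure's domain: a library whose overall scale is >= 4-fold away
from the median reference has an *empty* regression subset and the fit
fails — this is the printed procedure's own behaviour, surfaced as an
error.

**Assumption to keep in mind:** the regression assumes the common set
is dominated by tags with no condition effect. In the emulated study
this holds overwhelmingly (TE siRNAs are ~0.1% of over a million
unique tags). The synthetic generator reproduces this structure; see
below for what happens when it is violated.

## Differential expression

Expression is filtered at 10 RPM ("less than 10" is removed, so
exactly 10 is kept — the boundary is tested); a miRNA is tested if it
passes the floor in at least one of the two libraries (configurable to
"both"). Each miRNA's raw count is contrasted against the remainder of
its library in a 2x2 table. Under the `auto` policy the two-sided
Fisher exact test is used when any expected cell is below 5 (Cochran's
rule) and the Pearson chi-square test without continuity correction
otherwise; both branches are oracle-tested against brute-force
hypergeometric enumeration and the hand formula. Fold changes use
normalized counts, substituting 0.01 only for entries whose *raw*
count is zero. A miRNA is differentially expressed iff `p < 0.05` and
`|log2 fold change| > 1`, both strict; no multiple-testing correction
is applied (matching the emulated analysis; a BH option exists but
defaults off). Direction is oriented autotetraploid-over-diploid and
later-stage-over-earlier.

The accounting layer (`summarize_dem`, `venn_partition`,
`stage_specific_partition`) reports per-stage up/down counts, the
distinct DEM union and its percentage of detected miRNAs (rounded
half-up to 2 decimals), the exact 7-region Venn partition over stages,
the stage-specific count, and direction totals in two conventions:
counting a miRNA once per direction ever called (so direction-reversed
miRNAs appear in both totals) and direction-consistent counts with the
number of reversed miRNAs reported separately. Both conventions appear
in the emulated study's own summaries, which differ by exactly the
four reversed miRNAs.

## Target prediction

Complementarity scoring over ungapped windows: the miRNA's position
`i` (1-based from its 5' end) pairs antiparallel with site position
`L - i + 1`. Watson-Crick pairs cost 0, G:U wobbles 0.5, all other
mismatches 1.0, and penalties at miRNA positions 2-13 (the seed) are
doubled. Sites scoring <= 4 are emitted. Gaps and bulges are not
modelled — only the mismatch rules are published, so only they are
implemented, and this is a declared deviation from full
TargetFinder-style alignment. Position 1 and positions past the seed
use the base penalties (no terminal exemption). G:U is recognized in
both orientations (miRNA G : site T, miRNA T : site G).

One caveat surfaced while testing: the scoring rules are *not*
invariant under reverse-complementing both strands — complementation
maps G:U onto C:A (a full mismatch) and the seed window sits
asymmetrically at the miRNA 5' end. The property suite therefore
asserts the invariance that does hold (the positionless pair count
under strand-role swap) and pins the full rules with a 50-case
hand-computed fixture instead.

Transcript identifiers are rolled up to genes by stripping isoform
suffixes (`LOC_Os05g07210.1 -> LOC_Os05g07210`).

## TE-associated siRNAs

Residual tags (no miRNA name, no ncRNA match) that map exactly to the
genome with their full span inside an annotated transposable-element
locus are assigned to that locus's class (I = retrotransposon, II =
DNA transposon) and type (Ty3-gypsy, Copia, LINE, SINE, En/Spm, hAT,
Mutator, Helitron, unclassified). Full containment, not any-overlap,
is required: 24-nt heterochromatic siRNAs are TE-internal products and
boundary-spanning tags are ambiguous. Multi-locus tags count once per
(tag, type) to avoid copy-number inflation; both choices are
configurable policy, documented here. Abundance is the mean
*normalized* copy number of the assigned tags of the focal size class
(default 24 nt) per type and library — the source describes "relative
expression levels" without a formula, and the mean of normalized
copies is the natural reading. Three-point stage series are classified
as decreasing / increasing / non-monotone per genotype.

## Term enrichment

An in-package upper-tail hypergeometric test replaces the original
web-service analysis: for each term with at least one annotated
population gene, `p = P(X >= k)` for `k` study hits of `n` study genes
against `K` of `N` population genes, with Benjamini-Hochberg values
reported alongside. Significance is read at raw `p <= 0.05`, matching
the emulated analysis (whether that analysis used raw p or FDR is not
stated; raw p is the conservative reading of its text). The population
defaults to all genes in the annotation map and is configurable.

## The synthetic study generator

`synth_config()` fixes the study conditions; `make_reference()` and
`simulate_libraries()` are deterministic given the seed (byte-identical
outputs, tested).

* **Design**: 6 libraries (2 genotypes x 3 stages), base depth 2e5
  reads with per-library multipliers 1.00/1.10/0.70/0.95/0.90/0.75 —
  desk-scale versions of the emulated study's ~9e6 raw reads per
  library and its unequal clean-read yields.
* **miRNA channel**: 24 known rice hairpins (both arms annotated), 8
  hairpins with only the 5p arm annotated donating opposite-arm tags,
  6 genome-embedded other-species hairpins (one donating an
  opposite-arm tag), 6 perfect inverted repeats in the genome as novel
  candidates, and 14 isomiR variant tags (3' offsets +1..+3/-1, 5'
  offsets +1/+2/-1/-2, and six single internal substitutions) — all
  within the +/-3 offset and 1-mismatch rules they are meant to
  exercise. Base intensities are lognormal (meanlog log 400), floored
  well above the 10-RPM filter.
* **Planted effects**: 4-fold changes (6 miRNAs up in all stages, 4 up
  at MA only, 3 up at SCP only, 5 down) — comfortably above the
  emulated analysis's 2-fold call threshold. TE siRNAs follow stage
  profiles 3.0/2.0/1.0 (diploid, the "gradual decline") and
  1.5/3.2/2.8 (autotetraploid, depleted at PMA and enriched from MA
  on), matching the reported qualitative pattern.
* **TE channel**: 10 types x 4 loci, 12 distinct 24-nt siRNAs per type
  (the emulated study reports tens of siRNAs per main type), with
  per-tag intensities inside the bulk abundance range.
* **Background**: ncRNA fragments (10% of reads, removed by the
  contaminant filter), adapter dimers (1.5%), and the dominant stable
  junk/degradation channel — 7000 tags with a 24-nt-dominant,
  21-nt-secondary length mixture spanning 18-30 nt, plus 150 abundant
  degradation tags whose intensities span the top of the abundance
  range (as rRNA-derived fragments do in real libraries).

The background composition matters and was chosen to reproduce the
real data's *statistical structure*, in which the overwhelming
majority of unique tags carries no genotype or stage effect. When
planted-effect tags instead form a noticeable share of the common set
— or occupy an abundance stratum of their own — the median-reference
regression is dragged toward them (a 3% contamination share produced
correction-factor errors up to 0.16 log2 units and compressed TE
genotype ratios by 15-30% in early experiments). That sensitivity is a
property of the normalization's stable-majority assumption, not of the
generator; with the realistic composition the per-type TE genotype
ratios are recovered within ~6%.

**What the synthetic tests do not show:** reads have constant Phred-30
qualities and (by default) no sequencing errors; junk tags are
non-genomic, whereas real degradation products map to the genome;
hairpins are perfect inverted repeats rather than thermodynamically
realistic folds; and there are no biological replicates — exactly as
in the emulated single-library-per-condition design, which is why the
differential tests are count-based rather than dispersion-based.

## Numerical and policy choices

* Zero handling: the normalization reference requires count >= 1
  everywhere, so log2(0) cannot occur (guarded); fold changes
  substitute 0.01 for zero-raw entries only; a miRNA with zero raw
  counts in both conditions is `ns` with p = 1 and no test.
* Rounding: printed percentages round half-up to 2 decimals
  (`round_half_up`), so 172/486 -> 35.39 and 142/172 -> 82.56.
* Tie-breaks are deterministic everywhere (catalog multi-hits,
  PC serials, row orderings), making every pipeline stage reproducible
  run-to-run; the end-to-end determinism is tested.
* Problem sizes in the test suite: oracle checks run at the scale
  where exhaustive enumeration is exact (hairpins <= 34 nt, 2x2
  margins <= 200, enrichment N <= 30); the simulation suite uses the
  generator's default depth of 2e5 reads/library, 2000-miRNA null
  panels and 300-replicate power panels — sizes chosen so the whole
  suite completes in about a minute while keeping Monte-Carlo error
  well below the asserted margins.

## Known limitations

* The hairpin heuristic is a pairing-count stand-in: it will accept
  inverted repeats that thermodynamic folding would reject (e.g.
  AU-only stems) and has a few-percent per-locus false positive rate
  for genome-mapped tags in random context.
* Single-library designs cannot separate biological from technical
  variation; the Fisher/chi-square calls inherit the emulated
  analysis's anti-conservatism at very high depths, where tiny fold
  changes become significant (the |log2 FC| > 1 threshold is the
  practical guard).
* The normalization factors are defined only up to the median-library
  convention, and the procedure fails by design for libraries >= 4-fold
  discordant from the reference.
* The enrichment test ignores the term hierarchy (no true-path
  propagation) and treats genes as exchangeable.
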